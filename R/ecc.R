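#' Validate an expert score matrix
#'
#' An expert score matrix holds integer scores 1–10 from `m >= 2` raters
#' (rows) over `n >= 2` items (columns), with no missing cells.
#'
#' @param scores A matrix or data frame, raters x items.
#' @return The validated numeric matrix (rater and item names preserved).
#' @export
as_score_matrix <- function(scores) {
  m <- as.matrix(scores)
  storage.mode(m) <- "numeric"
  if (anyNA(m)) abort("score matrix must be complete (no missing cells)")
  if (nrow(m) < 2L || ncol(m) < 2L) abort("need at least 2 raters and 2 items")
  if (any(m < 1 | m > 10) || any(m != round(m))) {
    abort("scores must be integers in [1, 10]")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("item", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("rater", seq_len(nrow(m)))
  m
}

#' Kendall's coefficient of concordance W
#'
#' Measures agreement among `m` raters ranking `n` items, in \[0, 1\]
#' (1 = identical rankings). Scores are converted to within-rater mid-ranks;
#' with rank sums `R_j` and `S = sum_j (R_j - m(n+1)/2)^2`,
#' `W = 12 S / (m^2 (n^3 - n) - m sum_i T_i)` where
#' `T_i = sum (t^3 - t)` over rater i's tie groups. The significance test
#' uses the large-sample chi-square approximation
#' `chi^2 = m (n - 1) W` on `n - 1` degrees of freedom.
#'
#' If every rater scores all items identically the statistic is undefined
#' (zero corrected denominator); this is signalled as an error.
#'
#' @param scores Raters x items matrix (see [as_score_matrix()]).
#' @return A `kendall_w` list: `W`, `chi_square`, `df`, `p_value`, `m`, `n`;
#'   with a [tidy()] method.
#' @export
#' @examples
#' s <- rbind(c(8, 2, 10), c(7, 3, 9), c(9, 1, 10))
#' kendalls_w(s)
kendalls_w <- function(scores) {
  m0 <- as_score_matrix(scores)
  m <- nrow(m0); n <- ncol(m0)
  ranks <- t(apply(m0, 1, rank))  # mid-ranks within each rater
  Tsum <- sum(apply(m0, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  R <- colSums(ranks)
  S <- sum((R - m * (n + 1) / 2)^2)
  denom <- m^2 * (n^3 - n) - m * Tsum
  if (denom <= 0) {
    abort("Kendall's W is undefined: every rater scored all items identically")
  }
  W <- 12 * S / denom
  chi <- m * (n - 1) * W
  df <- n - 1
  structure(list(W = W, chi_square = chi, df = df,
                 p_value = pchisq(chi, df, lower.tail = FALSE),
                 m = m, n = n),
            class = "kendall_w")
}

#' @export
print.kendall_w <- function(x, ...) {
  cat(sprintf("Kendall's W = %.4f (m = %d raters, n = %d items)\n", x$W, x$m, x$n))
  cat(sprintf("  chi-square = %.3f, df = %d, p = %.4g\n", x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' @method tidy kendall_w
#' @export
tidy.kendall_w <- function(x, ...) {
  tibble::tibble(W = x$W, chi_square = x$chi_square, df = x$df,
                 p_value = x$p_value, raters = x$m, items = x$n)
}

#' Elicit ECC weights from an expert score panel
#'
#' Each item's weight is its mean score across raters divided by the sum of
#' all item means, so the weights are non-negative and sum to 1 and are
#' invariant to rescaling all scores by a constant. With `trim = TRUE` one
#' maximum and one minimum score are removed per item before averaging
#' (requires at least 4 raters), a standard guard against outlier judges.
#' Concordance diagnostics ([kendalls_w()]) are always computed on the full,
#' untrimmed panel.
#'
#' @param scores Raters x items matrix; columns are the ECC features being
#'   weighted.
#' @param trim Drop one max and one min score per item before averaging.
#' @return An `ecc_weights` tibble (`item`, `mean_score`, `weight`) with a
#'   `concordance` attribute (a `kendall_w`) and a `trimmed` flag.
#' @export
#' @examples
#' s <- rbind(c(8, 2, 10), c(8, 2, 10))
#' colnames(s) <- c("specialty", "willingness", "quality")
#' elicit_weights(s)$weight  # 0.4 0.1 0.5
elicit_weights <- function(scores, trim = FALSE) {
  m0 <- as_score_matrix(scores)
  if (trim && nrow(m0) < 4L) {
    abort("trimmed elicitation needs at least 4 raters")
  }
  means <- apply(m0, 2, function(x) {
    if (trim) x <- x[-c(which.max(x), which.min(x))]
    mean(x)
  })
  out <- tibble::tibble(item = colnames(m0), mean_score = as.numeric(means),
                        weight = as.numeric(means / sum(means)))
  structure(tibble::new_tibble(out, class = "ecc_weights"),
            concordance = kendalls_w(m0), trimmed = trim)
}

#' @method tidy ecc_weights
#' @export
tidy.ecc_weights <- function(x, ...) tibble::as_tibble(x)

#' @method glance ecc_weights
#' @export
glance.ecc_weights <- function(x, ...) {
  conc <- attr(x, "concordance")
  dplyr::bind_cols(tibble::tibble(n_items = nrow(x), trimmed = attr(x, "trimmed")),
                   tidy(conc))
}

ecc_weight_vector <- function(weights) {
  if (inherits(weights, "ecc_weights") || is.data.frame(weights)) {
    setNames(weights$weight, weights$item)
  } else {
    weights
  }
}

#' Weighted ECC score of cases
#'
#' The external-characteristics score `Pt = sum_i w_i * x_i~` of each case,
#' where `x_i~` is the ECC value normalized to \[0, 1\] by its declared
#' domain: a 1–10 score maps to `(x - 1) / 9`, a \{0, 1\} flag passes
#' through. Normalizing first keeps `Pt` on the same \[0, 1\] scale as the
#' content similarity, so the two can be fused meaningfully.
#'
#' @param data A case-base tibble carrying the ECC columns.
#' @param weights An `ecc_weights` tibble or a named numeric vector summing
#'   to 1 over exactly the schema's ECC features.
#' @param schema A `cbr_schema`.
#' @return Numeric vector of `Pt` in \[0, 1\], one per row.
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 5, seed = 1)
#' w <- c(specialty = 0.4, willingness = 0.1, quality = 0.5)
#' ecc_score(base, w, fna_schema())
ecc_score <- function(data, weights, schema) {
  w <- ecc_weight_vector(weights)
  ecc <- schema_features(schema, "ecc")
  if (length(ecc) == 0L) abort("schema declares no ECC features")
  if (!setequal(names(w), ecc)) {
    abort("weights must cover exactly the schema's ECC features")
  }
  if (abs(sum(w) - 1) > 1e-8) abort("ECC weights must sum to 1")
  missing_cols <- setdiff(ecc, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("case is missing ECC feature(s): ", paste(missing_cols, collapse = ", ")))
  }
  acc <- rep(0, nrow(data))
  for (f in ecc) {
    sp <- schema_spec(schema, f)
    x <- as.numeric(data[[f]])
    if (anyNA(x)) abort(paste0("missing value in ECC feature '", f, "'"))
    width <- sp$upper - sp$lower
    xn <- if (width == 0) rep(1, length(x)) else (x - sp$lower) / width
    acc <- acc + w[[f]] * xn
  }
  acc
}

#' Binary harmonic mean fusion
#'
#' Fuses a content similarity `s` and an ECC score `p` into
#' `SP = 2 s p / (s + p)`, defined as 0 when `s + p = 0`. The harmonic mean
#' carries a penalty mechanism: `min(s, p) <= SP <= sqrt(s p) <= (s + p)/2`,
#' with equality only at `s = p`, so the fused score is pulled toward the
#' weaker of the two components — a case must be both similar in content and
#' well-appraised to rank high.
#'
#' @param s,p Numeric vectors in \[0, 1\] (recycled).
#' @return `SP` in \[0, 1\].
#' @export
#' @examples
#' harmonic_fuse(0.8, 0.4)
harmonic_fuse <- function(s, p) {
  s <- as.numeric(s); p <- as.numeric(p)
  if (any(s < 0) || any(p < 0)) abort("harmonic_fuse() needs non-negative inputs")
  out <- 2 * s * p / (s + p)
  out[s + p == 0] <- 0
  out
}

#' Re-rank a retrieval by fused similarity and ECC score
#'
#' Decorates each retrieved case with its ECC score `Pt` and fused score
#' `SPt = harmonic_fuse(St, Pt)`, then re-sorts by `SPt` descending (ties by
#' higher `St`, then ascending case id). Both rank columns are kept so the
#' effect of the external characteristics on the recommendation order can be
#' read off directly: a case with modest similarity but strong provenance
#' can be promoted above a more similar but poorly-appraised one.
#'
#' @param retrieval A `ranked_retrieval`.
#' @param base The case base resolving the retrieved ids (must carry the ECC
#'   columns).
#' @param weights ECC weights (see [ecc_score()]).
#' @param schema A `cbr_schema`.
#' @return A `fused_retrieval` tibble: `case_id`, `similarity`, `ecc_score`,
#'   `fused`, `rank_without_ecc`, `rank_with_ecc`, sorted by `rank_with_ecc`.
#' @export
rerank_with_ecc <- function(retrieval, base, weights, schema) {
  base <- tibble::as_tibble(base)
  ids <- retrieval$case_id
  hit <- match(ids, as.character(base$id))
  if (anyNA(hit)) {
    abort(paste0("retrieved id(s) not found in the case base: ",
                 paste(ids[is.na(hit)], collapse = ", ")))
  }
  pt <- ecc_score(base[hit, , drop = FALSE], weights, schema)
  out <- tibble::tibble(case_id = ids,
                        similarity = retrieval$similarity,
                        ecc_score = pt,
                        fused = harmonic_fuse(retrieval$similarity, pt),
                        rank_without_ecc = retrieval$rank)
  ord <- order(-out$fused, -out$similarity, out$case_id)
  out <- out[ord, , drop = FALSE]
  out$rank_with_ecc <- seq_len(nrow(out))
  structure(tibble::new_tibble(out, class = "fused_retrieval"),
            query_id = attr(retrieval, "query_id"),
            k_used = attr(retrieval, "k_used"))
}

#' Plot a re-ranking as a bump chart
#'
#' @param object A `fused_retrieval`.
#' @param ... Unused.
#' @return A ggplot showing each case's rank before and after ECC fusion.
#' @method autoplot fused_retrieval
#' @export
autoplot.fused_retrieval <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("rank_without_ecc", "rank_with_ecc"),
                              names_to = "stage", values_to = "rank")
  long$stage <- factor(long$stage, levels = c("rank_without_ecc", "rank_with_ecc"),
                       labels = c("similarity only", "with ECC"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$rank,
                                     group = .data$case_id)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_text(data = long[long$stage == "with ECC", ],
                       ggplot2::aes(label = .data$case_id),
                       hjust = -0.3, size = 3) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(object))) +
    ggplot2::labs(x = NULL, y = "Rank (1 = recommended first)",
                  title = "Re-ranking after ECC fusion") +
    ggplot2::theme_minimal()
}

#' Serialize ECC weights and fused retrievals
#'
#' `write_ecc_weights()` stores the weights with their concordance
#' diagnostics as JSON. `write_fused()` writes either JSON or — for a `.csv`
#' path — a two-block table juxtaposing the similarity-only ordering and the
#' ECC-fused ordering.
#'
#' @param weights An `ecc_weights`.
#' @param fused A `fused_retrieval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ecc_weights <- function(weights, path) {
  conc <- attr(weights, "concordance")
  out <- list(weights = purrr::pmap(tibble::as_tibble(weights), list),
              trimmed = attr(weights, "trimmed"),
              concordance = unclass(conc))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ecc_weights
#' @export
read_ecc_weights <- function(path) {
  raw <- jsonlite::read_json(path)
  out <- purrr::map_dfr(raw$weights, tibble::as_tibble)
  conc <- structure(purrr::map(raw$concordance, ~.x), class = "kendall_w")
  structure(tibble::new_tibble(out, class = "ecc_weights"),
            concordance = conc, trimmed = isTRUE(raw$trimmed))
}

#' @rdname write_ecc_weights
#' @export
write_fused <- function(fused, path) {
  tab <- tibble::as_tibble(fused)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(query_id = attr(fused, "query_id"),
                              k_used = attr(fused, "k_used"), entries = tab),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    by_sim <- tab[order(tab$rank_without_ecc), ]
    two_block <- tibble::tibble(
      index_without_ecc = by_sim$case_id,
      sorting_value_without_ecc = by_sim$similarity,
      index_with_ecc = tab$case_id,
      sorting_value_with_ecc = tab$fused)
    readr::write_csv(two_block, path, progress = FALSE)
  }
  invisible(path)
}
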
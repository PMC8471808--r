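#' Per-feature local similarity
#'
#' The local similarity of two values of one feature, in \[0, 1\]. Numeric
#' and ordinal features use range-normalized distance,
#' `1 - |a - b| / (upper - lower)`; binary and categorical features use exact
#' match (1 if equal, else 0). The function is symmetric and equals 1 iff
#' the two values are at zero distance. A zero-width numeric domain defines
#' the similarity as 1.
#'
#' @param a,b Values (vectorized).
#' @param spec A one-row feature spec (see [feature_spec()]).
#' @return Numeric vector of similarities in \[0, 1\].
#' @export
#' @examples
#' local_similarity(29, 19, feature_spec("age", "numeric", 10, 95))
local_similarity <- function(a, b, spec) {
  if (spec$kind %in% c("numeric", "ordinal")) {
    width <- spec$upper - spec$lower
    if (!is.finite(width) || width == 0) return(rep(1, max(length(a), length(b))))
    pmax(0, 1 - abs(as.numeric(a) - as.numeric(b)) / width)
  } else {
    as.numeric(as.character(a) == as.character(b))
  }
}

#' Global weighted case similarity
#'
#' The content similarity of two cases: the weighted mean of per-feature
#' local similarities over the internal-channel features,
#' `sum_i w_i * sim(a_i, b_i) / sum_i w_i`. ECC attributes and the label are
#' excluded — they play no part in content matching. Symmetric, in \[0, 1\],
#' and 1 iff the internal feature vectors coincide.
#'
#' @param query,stored One-row tibbles (or named lists) of feature values.
#' @param schema A `cbr_schema`.
#' @return A similarity in \[0, 1\].
#' @export
case_similarity <- function(query, stored, schema) {
  feats <- schema_features(schema, "internal")
  if (length(feats) == 0L) abort("schema declares no internal features")
  w <- schema$weight[match(feats, schema$name)]
  sims <- purrr::map_dbl(feats, function(f) {
    local_similarity(query[[f]], stored[[f]], schema_spec(schema, f))[1]
  })
  sum(w * sims) / sum(w)
}

# similarity of each base row to each query row; returns n_base x n_query matrix
similarity_matrix <- function(base, queries, schema) {
  feats <- schema_features(schema, "internal")
  if (length(feats) == 0L) abort("schema declares no internal features")
  w <- schema$weight[match(feats, schema$name)]
  acc <- matrix(0, nrow(base), nrow(queries))
  for (j in seq_along(feats)) {
    f <- feats[j]
    sp <- schema_spec(schema, f)
    if (sp$kind %in% c("numeric", "ordinal")) {
      width <- sp$upper - sp$lower
      d <- abs(outer(as.numeric(base[[f]]), as.numeric(queries[[f]]), "-"))
      s <- if (width == 0) 1 else pmax(0, 1 - d / width)
    } else {
      s <- outer(as.character(base[[f]]), as.character(queries[[f]]), "==") * 1
    }
    acc <- acc + w[j] * s
  }
  acc / sum(w)
}

#' Retrieve the K nearest stored cases
#'
#' Exhaustively scores every case of the (class-matched) sub-base against the
#' query with [case_similarity()] and returns the top `min(k, n)` cases,
#' sorted by similarity descending with ties broken by ascending case id.
#' At the scale this engine targets (about a thousand cases) an exhaustive
#' scan is exact and fast; no approximate index is used.
#'
#' @param subbase The sub-base to search — normally the benign or malignant
#'   partition matching the query's Phase-I triage class.
#' @param query A one-row tibble in the same schema (label not required).
#' @param schema A `cbr_schema`.
#' @param k Number of neighbours.
#' @return A `ranked_retrieval` tibble with columns `case_id`, `similarity`,
#'   `rank`, and attributes `query_id` and `k_used`.
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 50, seed = 1)
#' retrieve(base, base[1, ], fna_schema(), k = 3)
retrieve <- function(subbase, query, schema, k) {
  subbase <- tibble::as_tibble(subbase)
  if (nrow(subbase) == 0L) {
    abort("retrieval sub-base is empty: Phase-I routing produced no candidates")
  }
  stopifnot(k >= 1)
  query <- tibble::as_tibble(query)[1, , drop = FALSE]
  sims <- similarity_matrix(subbase, query, schema)[, 1]
  ids <- if ("id" %in% names(subbase)) as.character(subbase$id) else as.character(seq_len(nrow(subbase)))
  ord <- order(-sims, ids)
  keep <- head(ord, min(k, nrow(subbase)))
  out <- tibble::tibble(case_id = ids[keep], similarity = sims[keep],
                        rank = seq_along(keep))
  structure(tibble::new_tibble(out, class = "ranked_retrieval"),
            query_id = if ("id" %in% names(query)) as.character(query$id) else NA_character_,
            k_used = as.integer(min(k, nrow(subbase))))
}

#' Distance-weighted fusion score of retrieved neighbours
#'
#' Converts a ranked retrieval into a single outcome score
#' `Sp = sum w * d^-1 * y / sum w * d^-1`, with distance `d = 1 - similarity`
#' and per-case weights `w` (default 1). `Sp` is a convex combination of the
#' neighbour labels, so it lies between the smallest and largest label; an
#' exact match (`d = 0`) short-circuits `Sp` to that case's label.
#'
#' @param retrieval A `ranked_retrieval`.
#' @param labels Named vector, case id to \{0, 1\}.
#' @param weights Optional named per-case weights (default 1 for all).
#' @return `Sp` in \[0, 1\].
#' @export
knn_fusion_score <- function(retrieval, labels, weights = NULL) {
  if (nrow(retrieval) == 0L) abort("retrieval is empty")
  ids <- retrieval$case_id
  missing_ids <- setdiff(ids, names(labels))
  if (length(missing_ids) > 0L) {
    abort(paste0("no label for neighbour id(s): ", paste(missing_ids, collapse = ", ")))
  }
  y <- as.numeric(labels[ids])
  w <- if (is.null(weights)) rep(1, length(ids)) else as.numeric(weights[ids])
  d <- 1 - retrieval$similarity
  exact <- d <= 0
  if (any(exact)) return(y[which(exact)[1]])  # retrieval order breaks ties
  inv <- w / d
  sum(inv * y) / sum(inv)
}

# plain weighted-KNN class decision: Sp > 0.5 -> 1, ties -> benign
knn_predict_matrix <- function(sims, train_labels, k) {
  apply(sims, 2, function(s) {
    ord <- order(-s)
    top <- head(ord, k)
    d <- 1 - s[top]
    y <- train_labels[top]
    if (any(d <= 0)) return(y[which(d <= 0)[1]])
    sp <- sum(y / d) / sum(1 / d)
    as.numeric(sp > 0.5)
  })
}

#' Cross-validated selection of K
#'
#' Stratified K-fold cross-validation of a plain distance-weighted KNN
#' classifier over a grid of K values. Each held-out case is classified
#' against the training folds by its fusion score `Sp` (`Sp > 0.5` means
#' malignant; an exact tie goes to benign, matching the naive Bayes
#' tie-break). The grid of mean accuracies is returned and the smallest K
#' attaining the maximum is selected. Grid points exceeding the smallest
#' per-class training count are skipped with a warning. Fully reproducible
#' from `seed`.
#'
#' @param data A labelled case-base tibble.
#' @param schema A `cbr_schema`.
#' @param k_grid Candidate K values (default 1..25).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed (required).
#' @return A `k_selection` object: `grid` (tibble of `k`, `accuracy`),
#'   `best_k`, `folds`, `seed`; with [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 120, class_separation = 3, seed = 1)
#' sel <- select_optimal_k(base, fna_schema(), k_grid = 1:5, folds = 3, seed = 7)
#' sel$best_k
select_optimal_k <- function(data, schema, k_grid = 1:25, folds = 10, seed) {
  data <- tibble::as_tibble(data)
  label <- schema_label(schema)
  y <- as.numeric(data[[label]])
  if (anyNA(y)) abort("select_optimal_k() needs a fully labelled case base")
  stopifnot(folds >= 2)
  if (min(table(y)) < folds) abort("each class needs at least `folds` members")
  set.seed(as.integer(seed))
  fold_id <- integer(nrow(data))
  for (cl in c(0, 1)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  min_class_train <- min(purrr::map_dbl(seq_len(folds), function(f) {
    min(table(y[fold_id != f]))
  }))
  usable <- k_grid <= min_class_train
  if (any(!usable)) {
    warn(paste0("skipping k > smallest training-fold class count (",
                min_class_train, "): ", paste(k_grid[!usable], collapse = ", ")))
    k_grid <- k_grid[usable]
  }
  if (length(k_grid) == 0L) abort("no usable k in the grid")

  correct <- matrix(0, length(k_grid), folds)
  n_test <- integer(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    sims <- similarity_matrix(data[!test, , drop = FALSE],
                              data[test, , drop = FALSE], schema)
    n_test[f] <- sum(test)
    for (i in seq_along(k_grid)) {
      pred <- knn_predict_matrix(sims, y[!test], k_grid[i])
      correct[i, f] <- sum(pred == y[test])
    }
  }
  grid <- tibble::tibble(k = k_grid,
                         accuracy = as.numeric(correct %*% rep(1, folds)) / sum(n_test))
  best_k <- grid$k[which.max(grid$accuracy)]  # which.max -> smallest maximizer
  structure(list(grid = grid, best_k = best_k, folds = folds,
                 seed = as.integer(seed)),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("K selection by %d-fold stratified CV (seed %d)\n", x$folds, x$seed))
  cat(sprintf("  best K = %d (accuracy %.4f)\n", x$best_k,
              x$grid$accuracy[x$grid$k == x$best_k]))
  invisible(x)
}

#' @method tidy k_selection
#' @export
tidy.k_selection <- function(x, ...) x$grid

#' @method glance k_selection
#' @export
glance.k_selection <- function(x, ...) {
  tibble::tibble(best_k = x$best_k,
                 best_accuracy = x$grid$accuracy[x$grid$k == x$best_k],
                 folds = x$folds, seed = x$seed)
}

#' Plot the cross-validation accuracy profile over K
#'
#' @param object A `k_selection`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot k_selection
#' @export
autoplot.k_selection <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_k, linetype = 2, colour = "red") +
    ggplot2::labs(x = "K (neighbours)", y = "Cross-validation accuracy",
                  title = sprintf("Optimal K = %d", object$best_k)) +
    ggplot2::theme_minimal()
}

#' Serialize a ranked retrieval
#'
#' JSON keeps the full object; the CSV layout is transposed — one column per
#' retrieved case, rows = similarity then the case's feature values — the
#' shape used to present retrieval results to clinicians.
#'
#' @param retrieval A `ranked_retrieval`.
#' @param path Output path.
#' @param base Optional case base supplying feature values for the CSV shape.
#' @param schema Schema used to order feature rows (with `base`).
#' @return `path`, invisibly.
#' @export
write_retrieval <- function(retrieval, path, base = NULL, schema = NULL) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(query_id = attr(retrieval, "query_id"),
                              k_used = attr(retrieval, "k_used"),
                              entries = tibble::as_tibble(retrieval)),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (!is.null(base)) {
    feats <- schema_features(schema, "internal")
    rows <- dplyr::left_join(tibble::as_tibble(retrieval),
                             tibble::as_tibble(base), by = c(case_id = "id"))
    wide <- rbind(rows$similarity,
                  as.matrix(rows[, feats, drop = FALSE]) |> t())
    out <- tibble::as_tibble(as.data.frame(wide), .name_repair = "minimal")
    names(out) <- rows$case_id
    out <- dplyr::bind_cols(tibble::tibble(row = c("similarity", feats)), out)
    readr::write_csv(out, path, progress = FALSE)
  } else {
    readr::write_csv(tibble::as_tibble(retrieval), path, progress = FALSE)
  }
  invisible(path)
}
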
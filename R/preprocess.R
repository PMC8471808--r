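#' Fit a min-max normalizer on a case base
#'
#' Records the observed minimum and maximum of each named feature on the
#' training base. [apply_normalizer()] then maps
#' `x -> scale * (x - min) / (max - min) + shift`, so that with the defaults
#' (`scale = 1`, `shift = 0`) training values land in \[0, 1\], and with
#' `scale = 2, shift = -1` they land in \[-1, 1\]. Constant features are
#' flagged and map to the mid-point `shift + scale / 2`.
#'
#' @param data A case-base tibble.
#' @param schema A `cbr_schema`.
#' @param features Names of features to normalize; defaults to all numeric or
#'   ordinal internal features.
#' @param scale,shift Affine output range controls.
#' @return A `cbr_normalizer`: a tibble with columns `feature`, `min`, `max`,
#'   `constant`, carrying `scale` and `shift` as attributes.
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 50, seed = 1)
#' nrm <- fit_normalizer(base, fna_schema())
#' rng <- range(apply_normalizer(base, nrm)$age)
fit_normalizer <- function(data, schema, features = NULL, scale = 1, shift = 0) {
  validate_schema(schema)
  if (is.null(features)) {
    internal <- schema[schema$channel == "internal", ]
    features <- internal$name[internal$kind %in% c("numeric", "ordinal")]
  }
  for (f in features) {
    sp <- schema_spec(schema, f)
    if (!sp$kind %in% c("numeric", "ordinal")) {
      abort(paste0("feature '", f, "' is ", sp$kind, "; only numeric/ordinal features can be normalized"))
    }
    if (!f %in% names(data)) abort(paste0("feature '", f, "' not present in the data"))
  }
  params <- purrr::map_dfr(features, function(f) {
    x <- as.numeric(data[[f]])
    tibble::tibble(feature = f, min = min(x), max = max(x), constant = min(x) == max(x))
  })
  structure(params, scale = as.numeric(scale), shift = as.numeric(shift),
            class = c("cbr_normalizer", class(params)))
}

#' Apply a fitted normalizer
#'
#' Values outside the training range are clipped to the nearest range end —
#' new query cases may legitimately exceed the training extremes — and the
#' number of clipped values is reported as a warning.
#'
#' @param data A case-base tibble.
#' @param params A `cbr_normalizer` from [fit_normalizer()].
#' @return The tibble with the normalized features replaced in place.
#' @export
apply_normalizer <- function(data, params) {
  if (!inherits(params, "cbr_normalizer")) abort("params must come from fit_normalizer()")
  sc <- attr(params, "scale"); sh <- attr(params, "shift")
  data <- tibble::as_tibble(data)
  n_clipped <- 0L
  for (i in seq_len(nrow(params))) {
    f <- params$feature[i]
    if (!f %in% names(data)) abort(paste0("feature '", f, "' not present in the data"))
    x <- as.numeric(data[[f]])
    lo <- params$min[i]; hi <- params$max[i]
    clip <- x < lo | x > hi
    n_clipped <- n_clipped + sum(clip)
    x <- pmin(pmax(x, lo), hi)
    if (params$constant[i]) {
      data[[f]] <- rep(sh + sc / 2, length(x))
    } else {
      data[[f]] <- sc * (x - lo) / (hi - lo) + sh
    }
  }
  if (n_clipped > 0L) {
    warn(paste0(n_clipped, " value(s) outside the training range were clipped"))
  }
  data
}

#' @rdname fit_normalizer
#' @param path JSON file path.
#' @export
write_normalizer <- function(params, path) {
  out <- list(scale = attr(params, "scale"), shift = attr(params, "shift"),
              features = purrr::pmap(params, list))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname fit_normalizer
#' @export
read_normalizer <- function(path) {
  raw <- jsonlite::read_json(path)
  params <- purrr::map_dfr(raw$features, tibble::as_tibble)
  structure(params, scale = raw$scale, shift = raw$shift,
            class = c("cbr_normalizer", class(params)))
}

#' Binarize a feature
#'
#' Replaces one feature by \{0, 1\}-valued feature(s) and updates the schema
#' alongside. Two rules are supported: a numeric `threshold` (value becomes 1
#' iff `x >= threshold`), or one-hot expansion of a categorical feature into
#' one indicator column per level (`one_hot = TRUE`), which form a partition
#' of unity per case. Binarization is applied only to the named feature,
#' never blanket-applied to the whole base.
#'
#' @param data A case-base tibble.
#' @param schema A `cbr_schema`.
#' @param feature Feature name.
#' @param threshold Numeric cut point (numeric/ordinal features).
#' @param one_hot Expand a categorical feature into per-level indicators.
#' @return `list(data = <tibble>, schema = <cbr_schema>)`.
#' @export
binarize <- function(data, schema, feature, threshold = NULL, one_hot = FALSE) {
  sp <- schema_spec(schema, feature)
  data <- tibble::as_tibble(data)
  i <- match(feature, schema$name)
  if (sp$kind == "binary") return(list(data = data, schema = schema))  # identity
  if (one_hot) {
    if (sp$kind != "categorical") abort("one_hot expansion applies to categorical features")
    levs <- sp$levels[[1]]
    new_specs <- purrr::map(levs, function(l) {
      feature_spec(paste0(feature, "_", l), "binary",
                   channel = sp$channel, weight = sp$weight / length(levs))
    })
    for (l in levs) data[[paste0(feature, "_", l)]] <- as.numeric(data[[feature]] == l)
    data[[feature]] <- NULL
    schema <- dplyr::bind_rows(schema[seq_len(i - 1), ], dplyr::bind_rows(new_specs),
                               schema[-seq_len(i), ])
  } else {
    if (is.null(threshold)) abort("supply a threshold or set one_hot = TRUE")
    if (!(threshold > sp$lower && threshold <= sp$upper)) {
      abort("threshold must cut the feature's declared domain")
    }
    data[[feature]] <- as.numeric(as.numeric(data[[feature]]) >= threshold)
    schema$kind[i] <- "binary"; schema$lower[i] <- 0; schema$upper[i] <- 1
  }
  schema <- feature_schema(tibble::as_tibble(schema))
  list(data = data, schema = schema)
}

#' Greedy low-correlation feature subset
#'
#' Filters candidate features in their declared order, keeping a candidate
#' iff its absolute Pearson correlation with every feature already kept is
#' strictly below `rho_max`. The result depends only on the declared feature
#' order, never on case order. Zero-variance features have no defined
#' correlation; it is treated as 0 with a warning.
#'
#' @param data A case-base tibble with at least two rows.
#' @param candidates Feature names to filter, in priority order.
#' @param rho_max Correlation threshold in \[0, 1\]; default 0.9.
#' @return Character vector of kept feature names.
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 100, seed = 1)
#' select_low_correlation_subset(base, c("age", "consistency", "swabs"))
select_low_correlation_subset <- function(data, candidates, rho_max = 0.9) {
  if (nrow(data) < 2L) abort("need at least 2 cases to estimate correlations")
  stopifnot(rho_max >= 0, rho_max <= 1)
  missing_cols <- setdiff(candidates, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("candidate feature(s) not in the data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- purrr::map(setNames(candidates, candidates), ~ as.numeric(data[[.x]]))
  zero_var <- purrr::map_lgl(X, ~ var(.x) == 0)
  if (any(zero_var)) {
    warn(paste0("zero-variance feature(s) — correlation treated as 0: ",
                paste(candidates[zero_var], collapse = ", ")))
  }
  kept <- character(0)
  for (f in candidates) {
    rho <- purrr::map_dbl(kept, function(g) {
      if (zero_var[[f]] || zero_var[[g]]) 0 else abs(cor(X[[f]], X[[g]]))
    })
    if (all(rho < rho_max)) kept <- c(kept, f)
  }
  kept
}
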
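#' Fit the Phase-I naive Bayes triage model
#'
#' Fits class priors and per-feature class-conditional distributions on a
#' labelled case base. The model assumes class-conditional independence of
#' the features: the posterior for a case x is proportional to
#' `P(Y = y) * prod_i P(x_i | Y = y)`.
#'
#' Numeric and ordinal features get Gaussian class-conditionals (per-class
#' sample mean and variance, with the variance floored at
#' `1e-9 * (domain width)^2` to keep densities finite on degenerate data).
#' Binary and categorical features get multinomial tables with Laplace
#' smoothing: `P(level | class) = (count + alpha) / (n_class + alpha * L)`
#' where `L` is the number of declared levels. `mode` overrides the default
#' per feature, e.g. `c(consistency = "categorical")` treats an ordinal grade
#' as a smoothed table instead of a Gaussian.
#'
#' Only internal-channel features enter the model: ECC attributes describe a
#' case's provenance, not the patient, and must not influence the diagnosis.
#'
#' @param data A labelled case-base tibble (complete `class` column, both
#'   classes present).
#' @param schema A `cbr_schema`.
#' @param alpha Laplace smoothing count (default 1).
#' @param mode Named character vector of per-feature overrides
#'   (`"gaussian"` or `"categorical"`).
#' @return An `nb_model` object with [predict.nb_model()], [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 200, class_separation = 3, seed = 1)
#' model <- fit_nb(base, fna_schema())
#' glance(model)
fit_nb <- function(data, schema, alpha = 1, mode = NULL) {
  validate_schema(schema)
  data <- tibble::as_tibble(data)
  label <- schema_label(schema)
  if (!label %in% names(data) || anyNA(data[[label]])) {
    abort("fit_nb() needs a fully labelled case base")
  }
  if (nrow(data) == 0L) abort("cannot fit on an empty case base")
  y <- as.numeric(data[[label]])
  if (length(unique(y)) < 2L) abort("both classes must be present in the training base")
  feats <- schema_features(schema, "internal")
  n_c <- c("0" = sum(y == 0), "1" = sum(y == 1))
  priors <- n_c / length(y)

  conditionals <- purrr::map(setNames(feats, feats), function(f) {
    sp <- schema_spec(schema, f)
    fmode <- if (!is.null(mode) && f %in% names(mode)) {
      match.arg(mode[[f]], c("gaussian", "categorical"))
    } else if (sp$kind %in% c("numeric", "ordinal")) "gaussian" else "categorical"
    x <- data[[f]]
    if (fmode == "gaussian") {
      x <- as.numeric(x)
      floor_var <- 1e-9 * (sp$upper - sp$lower)^2
      per_class <- purrr::map(c(`0` = 0, `1` = 1), function(cl) {
        xs <- x[y == cl]
        v <- if (length(xs) > 1L) var(xs) else 0
        list(mean = mean(xs), var = max(v, floor_var))
      })
      list(type = "gaussian", params = per_class)
    } else {
      levs <- if (sp$kind == "categorical") sp$levels[[1]] else {
        if (sp$kind == "binary") c("0", "1") else as.character(sp$lower:sp$upper)
      }
      tab <- purrr::map(c(`0` = 0, `1` = 1), function(cl) {
        counts <- table(factor(as.character(x[y == cl]), levels = levs))
        p <- (as.numeric(counts) + alpha) / (n_c[[as.character(cl)]] + alpha * length(levs))
        setNames(p, levs)
      })
      list(type = "categorical", levels = levs, alpha = alpha,
           n_class = as.list(n_c), table = tab)
    }
  })

  structure(list(priors = priors, conditionals = conditionals,
                 features = feats, alpha = alpha, n = length(y)),
            class = "nb_model")
}

log_likelihood_nb <- function(model, data) {
  n <- nrow(data)
  ll <- matrix(rep(log(model$priors), each = n), nrow = n,
               dimnames = list(NULL, c("0", "1")))
  for (f in model$features) {
    if (!f %in% names(data)) abort(paste0("case is missing model feature '", f, "'"))
    cond <- model$conditionals[[f]]
    if (anyNA(data[[f]])) abort(paste0("missing value in model feature '", f, "'"))
    if (cond$type == "gaussian") {
      x <- as.numeric(data[[f]])
      for (cl in c("0", "1")) {
        p <- cond$params[[cl]]
        ll[, cl] <- ll[, cl] + dnorm(x, p$mean, sqrt(p$var), log = TRUE)
      }
    } else {
      x <- as.character(data[[f]])
      for (cl in c("0", "1")) {
        p <- cond$table[[cl]][x]
        # unseen level: smoothed zero-count cell
        unseen <- is.na(p)
        p[unseen] <- cond$alpha / (cond$n_class[[cl]] + cond$alpha * length(cond$levels))
        ll[, cl] <- ll[, cl] + log(p)
      }
    }
  }
  ll
}

#' Posterior class probabilities and triage decisions
#'
#' The posterior is evaluated in log space (log prior plus summed
#' log-conditionals, normalized with the log-sum-exp trick) so that products
#' of many small likelihoods do not underflow. `type = "class"` returns the
#' argmax with ties broken to benign (0).
#'
#' @param object An `nb_model`.
#' @param newdata A case-base tibble (labels not required).
#' @param type `"prob"` for a tibble of posteriors, `"class"` for 0/1
#'   decisions.
#' @param ... Unused.
#' @return `type = "prob"`: tibble with columns `id` (if present),
#'   `p_benign`, `p_malignant`; `type = "class"`: numeric vector of 0/1.
#' @export
predict.nb_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- tibble::as_tibble(newdata)
  ll <- log_likelihood_nb(object, newdata)
  m <- pmax(ll[, "0"], ll[, "1"])
  p1 <- unname(exp(ll[, "1"] - m) / (exp(ll[, "0"] - m) + exp(ll[, "1"] - m)))
  if (type == "class") return(as.numeric(p1 > 0.5))  # tie -> benign
  out <- tibble::tibble(p_benign = 1 - p1, p_malignant = p1)
  if ("id" %in% names(newdata)) out <- dplyr::bind_cols(tibble::tibble(id = newdata$id), out)
  out
}

#' @rdname predict.nb_model
#' @param model An `nb_model`.
#' @param data A case-base tibble.
#' @export
nb_posterior <- function(model, data) predict(model, data, type = "prob")

#' @rdname predict.nb_model
#' @export
nb_classify <- function(model, data) predict(model, data, type = "class")

#' @export
print.nb_model <- function(x, ...) {
  cat("Naive Bayes triage model\n")
  cat(sprintf("  cases: %d   prior(malignant) = %.4f\n", x$n, x$priors[["1"]]))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a naive Bayes model
#'
#' @param x An `nb_model`.
#' @param ... Unused.
#' @return One row per feature, class and parameter: Gaussian features
#'   report `mean`/`variance`, categorical features one row per level with
#'   its smoothed probability.
#' @method tidy nb_model
#' @export
tidy.nb_model <- function(x, ...) {
  purrr::map_dfr(x$features, function(f) {
    cond <- x$conditionals[[f]]
    if (cond$type == "gaussian") {
      purrr::map_dfr(c("0", "1"), function(cl) {
        tibble::tibble(feature = f, class = as.numeric(cl), type = "gaussian",
                       level = NA_character_,
                       mean = cond$params[[cl]]$mean,
                       variance = cond$params[[cl]]$var,
                       probability = NA_real_)
      })
    } else {
      purrr::map_dfr(c("0", "1"), function(cl) {
        tibble::tibble(feature = f, class = as.numeric(cl), type = "categorical",
                       level = cond$levels,
                       mean = NA_real_, variance = NA_real_,
                       probability = as.numeric(cond$table[[cl]]))
      })
    }
  })
}

#' @rdname tidy.nb_model
#' @method glance nb_model
#' @export
glance.nb_model <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = length(x$features),
                 prior_benign = x$priors[["0"]], prior_malignant = x$priors[["1"]],
                 alpha = x$alpha)
}

#' Serialize a naive Bayes model to JSON
#'
#' @param model An `nb_model`.
#' @param path JSON file path.
#' @return `read_nb()` returns an `nb_model`; `write_nb()` returns `path`
#'   invisibly.
#' @export
write_nb <- function(model, path) {
  out <- unclass(model)
  out$priors <- as.list(model$priors)  # keep class names through JSON
  out$conditionals <- purrr::map(model$conditionals, function(cond) {
    if (cond$type == "categorical") cond$table <- purrr::map(cond$table, as.list)
    cond
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_nb
#' @export
read_nb <- function(path) {
  raw <- jsonlite::read_json(path)
  model <- list(
    priors = setNames(as.numeric(unlist(raw$priors)), names(raw$priors)),
    conditionals = purrr::map(raw$conditionals, function(cond) {
      if (cond$type == "gaussian") {
        list(type = "gaussian",
             params = purrr::map(cond$params, ~ list(mean = .x$mean, var = .x$var)))
      } else {
        list(type = "categorical", levels = unlist(cond$levels),
             alpha = as.numeric(cond$alpha), n_class = cond$n_class,
             table = purrr::map(cond$table, ~ unlist(.x)))
      }
    }),
    features = unlist(raw$features), alpha = raw$alpha, n = raw$n)
  structure(model, class = "nb_model")
}
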
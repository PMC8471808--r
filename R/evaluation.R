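#' Confusion counts for binary diagnoses
#'
#' Standard confusion-matrix counts with malignant (1) as the positive
#' class: TP = malignant predicted malignant, TN = benign predicted benign,
#' FP = benign predicted malignant, FN = malignant predicted benign.
#'
#' @param predictions,truth Named \{0, 1\} vectors over the same case ids
#'   (or unnamed vectors of equal length, matched positionally).
#' @return A one-row tibble `tp`, `tn`, `fp`, `fn`.
#' @export
#' @examples
#' confusion(c(a = 1, b = 0), c(a = 1, b = 1))
confusion <- function(predictions, truth) {
  if (!is.null(names(predictions)) && !is.null(names(truth))) {
    if (!setequal(names(predictions), names(truth))) {
      abort("predictions and truth must cover the same case ids")
    }
    predictions <- predictions[names(truth)]
  } else if (length(predictions) != length(truth)) {
    abort("predictions and truth must have the same length")
  }
  p <- as.numeric(predictions); y <- as.numeric(truth)
  if (!all(p %in% c(0, 1)) || !all(y %in% c(0, 1))) abort("classes must be 0 or 1")
  tibble::tibble(tp = sum(p == 1 & y == 1), tn = sum(p == 0 & y == 0),
                 fp = sum(p == 1 & y == 0), fn = sum(p == 0 & y == 1))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' the F-measure (harmonic mean of precision and recall). A ratio with a
#' zero denominator is reported as 0 and flagged in `undefined`.
#'
#' @param counts A one-row tibble from [confusion()].
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `f_measure`,
#'   `undefined` (comma-separated names of degenerate metrics, or `""`).
#' @export
#' @examples
#' classification_metrics(confusion(c(1, 0, 1, 0), c(1, 1, 1, 0)))
classification_metrics <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) abort("no evaluated cases")
  undefined <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); 0 } else num / den
  }
  precision <- safe_div(counts$tp, counts$tp + counts$fp, "precision")
  recall <- safe_div(counts$tp, counts$tp + counts$fn, "recall")
  f <- safe_div(2 * precision * recall, precision + recall, "f_measure")
  tibble::tibble(accuracy = (counts$tp + counts$tn) / total,
                 precision = precision, recall = recall, f_measure = f,
                 undefined = paste(undefined, collapse = ","))
}

#' ROC curve and AUC
#'
#' Sweeps a decision threshold over the distinct scores in descending order
#' (tied scores grouped), producing the (FPR, TPR) staircase from (0, 0) to
#' (1, 1). The AUC is the trapezoid-rule area, which equals the
#' Mann-Whitney probability that a random malignant case outscores a random
#' benign one (ties counting one half).
#'
#' @param scores Named numeric vector — larger means more malignant.
#' @param truth Named \{0, 1\} vector over the same ids.
#' @return A `roc_curve` tibble (`threshold`, `fpr`, `tpr`) with an `auc`
#'   attribute; [autoplot()] draws the curve.
#' @export
#' @examples
#' r <- roc_curve(c(a = .9, b = .2, c = .7), c(a = 1, b = 0, c = 0))
#' attr(r, "auc")
roc_curve <- function(scores, truth) {
  if (!is.null(names(scores)) && !is.null(names(truth))) {
    scores <- scores[names(truth)]
  }
  y <- as.numeric(truth)
  if (length(unique(y)) < 2L) abort("ROC needs both classes present in truth")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  thr <- sort(unique(as.numeric(scores)), decreasing = TRUE)
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- as.numeric(scores >= t)
    tibble::tibble(threshold = t,
                   fpr = sum(pred == 1 & y == 0) / n0,
                   tpr = sum(pred == 1 & y == 1) / n1)
  })
  pts <- dplyr::bind_rows(tibble::tibble(threshold = Inf, fpr = 0, tpr = 0), pts)
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- dplyr::bind_rows(pts, tibble::tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(tibble::new_tibble(pts, class = "roc_curve"), auc = auc)
}

#' @rdname roc_curve
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

# stratified split: floor(test_fraction * n) per stratum
stratified_split <- function(y, test_fraction, seed) {
  set.seed(as.integer(seed))
  test <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- floor(length(idx) * test_fraction)
    test[sample(idx, n_test)] <- TRUE
  }
  test
}

#' Stratified holdout evaluation of the triage/retrieval classifiers
#'
#' Splits the labelled case base into training and test sets (stratified by
#' class, `floor(fraction * n)` test cases per stratum), fits the requested
#' classifier on the training part and reports confusion counts, metrics,
#' ROC points and AUC on the held-out part.
#'
#' Methods:
#' \describe{
#'   \item{`"nb"`}{naive Bayes posteriors ([fit_nb()]); score = posterior
#'     probability of malignancy.}
#'   \item{`"knn"`}{plain distance-weighted KNN over the training base with
#'     the true training labels; score = fusion score `Sp`.}
#'   \item{`"nb_knn"`}{the combined pipeline: the training base is
#'     re-labelled by a naive Bayes model fitted on it (or kept as-is with
#'     `relabel = FALSE`), then each test case is scored by KNN against
#'     those labels.}
#' }
#'
#' @param data A labelled case-base tibble.
#' @param schema A `cbr_schema`.
#' @param method One of `"nb"`, `"knn"`, `"nb_knn"`.
#' @param test_fraction Held-out fraction (default 1/3).
#' @param seed Integer seed (required).
#' @param k Neighbours for the KNN-based methods (default 2).
#' @param alpha Laplace smoothing for the NB-based methods.
#' @param relabel For `"nb_knn"`: use NB predictions as the training labels
#'   seen by KNN (default `TRUE`; `FALSE` keeps the recorded diagnoses).
#' @return An `eval_report`: `metrics`, `counts`, `roc`, `auc`, plus the
#'   configuration; with [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 150, class_separation = 3, seed = 1)
#' rep <- holdout_experiment(base, fna_schema(), method = "nb", seed = 9)
#' glance(rep)
holdout_experiment <- function(data, schema, method = c("nb", "knn", "nb_knn"),
                               test_fraction = 1 / 3, seed, k = 2, alpha = 1,
                               relabel = TRUE) {
  method <- match.arg(method)
  stopifnot(test_fraction > 0, test_fraction < 1)
  data <- tibble::as_tibble(data)
  label <- schema_label(schema)
  y <- as.numeric(data[[label]])
  if (anyNA(y)) abort("holdout_experiment() needs a fully labelled case base")
  test <- stratified_split(y, test_fraction, seed)
  if (length(unique(y[test])) < 2L || length(unique(y[!test])) < 2L) {
    abort("the split emptied a class; use a larger base or different fraction")
  }
  train <- data[!test, , drop = FALSE]
  test_data <- data[test, , drop = FALSE]

  if (method == "nb") {
    model <- fit_nb(train, schema, alpha = alpha)
    scores <- predict(model, test_data, type = "prob")$p_malignant
    pred <- as.numeric(scores > 0.5)
  } else {
    train_y <- y[!test]
    if (method == "nb_knn" && relabel) {
      model <- fit_nb(train, schema, alpha = alpha)
      train_y <- nb_classify(model, train)
    }
    sims <- similarity_matrix(train, test_data, schema)
    scores <- apply(sims, 2, function(s) {
      ord <- order(-s)
      top <- head(ord, k)
      d <- 1 - s[top]
      if (any(d <= 0)) return(train_y[top][which(d <= 0)[1]])
      sum(train_y[top] / d) / sum(1 / d)
    })
    pred <- as.numeric(scores > 0.5)
  }
  ids <- as.character(test_data$id)
  counts <- confusion(setNames(pred, ids), setNames(y[test], ids))
  roc <- roc_curve(setNames(scores, ids), setNames(y[test], ids))
  structure(list(metrics = classification_metrics(counts), counts = counts,
                 roc = tibble::as_tibble(roc), auc = attr(roc, "auc"),
                 method = method, k = if (method == "nb") NA_integer_ else k,
                 test_fraction = test_fraction, seed = as.integer(seed),
                 n_train = nrow(train), n_test = nrow(test_data)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Holdout evaluation (%s%s): %d train / %d test\n", x$method,
              if (!is.na(x$k)) sprintf(", k = %d", x$k) else "",
              x$n_train, x$n_test))
  m <- x$metrics
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F %.4f  AUC %.4f\n",
              m$accuracy, m$precision, m$recall, m$f_measure, x$auc))
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(metric = c("accuracy", "precision", "recall", "f_measure", "auc"),
                 value = c(x$metrics$accuracy, x$metrics$precision,
                           x$metrics$recall, x$metrics$f_measure, x$auc))
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(method = x$method, k = x$k,
                                  n_train = x$n_train, n_test = x$n_test,
                                  seed = x$seed),
                   x$metrics, tibble::tibble(auc = x$auc), x$counts)
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  roc <- structure(tibble::new_tibble(object$roc, class = "roc_curve"),
                   auc = object$auc)
  autoplot(roc) +
    ggplot2::labs(subtitle = sprintf("method: %s", object$method))
}

#' Serialize an evaluation report
#'
#' @param report An `eval_report`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
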
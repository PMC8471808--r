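#' Run the full three-phase pipeline on one query case
#'
#' Composes the engine end to end. Phase I fits (or accepts) a naive Bayes
#' model and triages the query into the benign or malignant sub-base —
#' stored cases are partitioned by their recorded diagnoses by default, or
#' by NB predictions with `partition_on = "nb"`. Phase II retrieves the K
#' most similar cases within that sub-base. Phase III scores the retrieved
#' cases' external characteristics and re-ranks by the harmonic-mean fusion.
#'
#' With `out_dir` set, every intermediate artifact (posterior, ranked
#' retrieval, weights, fused retrieval) is written there along with a run
#' manifest recording the configuration, the seed and MD5 checksums of the
#' outputs; identical inputs and seed reproduce the files byte for byte.
#'
#' @param base A labelled case-base tibble.
#' @param query A one-row tibble in the same schema (no label needed).
#' @param schema A `cbr_schema`.
#' @param weights ECC weights (an `ecc_weights` or named vector); `NULL`
#'   skips Phase III and returns the similarity ordering.
#' @param k Neighbours to retrieve; `"cv"` selects K by cross-validation
#'   with [select_optimal_k()].
#' @param k_grid,folds CV controls when `k = "cv"`.
#' @param alpha Laplace smoothing for the NB model.
#' @param partition_on `"label"` (recorded diagnoses, default) or `"nb"`
#'   (Phase-I predictions) as the sub-base label source.
#' @param seed Integer seed (required).
#' @param out_dir Optional output directory for artifacts and manifest.
#' @return A `fused_retrieval` (or `ranked_retrieval` when `weights` is
#'   `NULL`) with attributes `triage` (a one-row posterior tibble) and
#'   `k_selection` (when CV was used).
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 80, seed = 3)
#' w <- c(specialty = 0.4, willingness = 0.1, quality = 0.5)
#' run_pipeline(base, base[5, ], fna_schema(), weights = w, k = 5, seed = 3)
run_pipeline <- function(base, query, schema, weights = NULL, k = 2,
                         k_grid = 1:25, folds = 10, alpha = 1,
                         partition_on = c("label", "nb"), seed,
                         out_dir = NULL) {
  partition_on <- match.arg(partition_on)
  base <- validate_casebase(base, schema, require_label = TRUE)
  query <- tibble::as_tibble(query)[1, , drop = FALSE]

  # Phase I: triage
  model <- fit_nb(base, schema, alpha = alpha)
  post <- nb_posterior(model, query)
  triage_class <- as.numeric(post$p_malignant > 0.5)
  part_labels <- if (partition_on == "label") {
    setNames(as.numeric(base[[schema_label(schema)]]), base$id)
  } else {
    setNames(nb_classify(model, base), base$id)
  }
  parts <- partition_by_class(base, part_labels)
  subbase <- if (triage_class == 1) parts$malignant else parts$benign
  if (nrow(subbase) == 0L) {
    abort(sprintf("Phase-I routing to the %s sub-base produced no candidates",
                  if (triage_class == 1) "malignant" else "benign"))
  }

  # Phase II: retrieval
  sel <- NULL
  if (identical(k, "cv")) {
    sel <- select_optimal_k(base, schema, k_grid = k_grid, folds = folds,
                            seed = seed)
    k <- sel$best_k
  }
  retrieval <- retrieve(subbase, query, schema, k = k)

  # Phase III: ECC fusion
  result <- if (is.null(weights)) retrieval else {
    rerank_with_ecc(retrieval, base, weights, schema)
  }
  attr(result, "triage") <- post
  attr(result, "triage_class") <- triage_class
  attr(result, "k_selection") <- sel

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(p_benign = post$p_benign, p_malignant = post$p_malignant,
                              triage_class = triage_class),
                         file.path(out_dir, "posterior.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_retrieval(retrieval, file.path(out_dir, "retrieval.json"))
    write_retrieval(retrieval, file.path(out_dir, "retrieval.csv"),
                    base = base, schema = schema)
    if (!is.null(weights)) {
      write_fused(result, file.path(out_dir, "fused.json"))
      write_fused(result, file.path(out_dir, "fused.csv"))
    }
    write_manifest(out_dir, config = list(
      phase = "pipeline", k = k, alpha = alpha, partition_on = partition_on,
      folds = if (is.null(sel)) NULL else folds, seed = as.integer(seed),
      weights = if (is.null(weights)) NULL else as.list(ecc_weight_vector(weights))))
  }
  result
}

#' Run the evaluation protocol on a labelled case base
#'
#' The comparative study behind the engine: a Phase-I holdout comparison of
#' the naive Bayes and plain-KNN classifiers, cross-validated selection of
#' K, and a holdout report of the combined NB-then-KNN pipeline at the
#' selected K.
#'
#' @param base A labelled case-base tibble.
#' @param schema A `cbr_schema`.
#' @param test_fraction Held-out fraction (default 1/3).
#' @param k_grid,folds CV controls for K selection.
#' @param alpha Laplace smoothing.
#' @param seed Integer seed (required).
#' @param out_dir Optional output directory (JSON reports plus manifest).
#' @return A list: `nb` and `knn` (`eval_report`s), `k_selection`
#'   (a `k_selection`), `combined` (`eval_report` at the selected K).
#' @export
run_evaluation <- function(base, schema, test_fraction = 1 / 3,
                           k_grid = 1:25, folds = 10, alpha = 1, seed,
                           out_dir = NULL) {
  base <- validate_casebase(base, schema, require_label = TRUE)
  nb_rep <- holdout_experiment(base, schema, method = "nb",
                               test_fraction = test_fraction, seed = seed,
                               alpha = alpha)
  knn_rep <- holdout_experiment(base, schema, method = "knn",
                                test_fraction = test_fraction, seed = seed, k = 1)
  sel <- select_optimal_k(base, schema, k_grid = k_grid, folds = folds, seed = seed)
  combined <- holdout_experiment(base, schema, method = "nb_knn",
                                 test_fraction = test_fraction, seed = seed,
                                 k = sel$best_k, alpha = alpha)
  out <- list(nb = nb_rep, knn = knn_rep, k_selection = sel, combined = combined)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_eval_report(nb_rep, file.path(out_dir, "phase1_nb.json"))
    write_eval_report(knn_rep, file.path(out_dir, "phase1_knn.json"))
    jsonlite::write_json(list(grid = sel$grid, best_k = sel$best_k,
                              folds = sel$folds, seed = sel$seed),
                         file.path(out_dir, "k_selection.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
    write_eval_report(combined, file.path(out_dir, "combined.json"))
    write_manifest(out_dir, config = list(
      phase = "evaluation", test_fraction = test_fraction,
      k_grid = range(k_grid), folds = folds, alpha = alpha,
      seed = as.integer(seed)))
  }
  out
}

# manifest: config echo + md5 of every other file in the directory
write_manifest <- function(out_dir, config) {
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  jsonlite::write_json(list(config = config,
                            outputs = purrr::map2(files, unname(sums),
                                                  ~ list(file = .x, md5 = .y))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(out_dir, "manifest.json"))
}
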
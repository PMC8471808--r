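#' Simulate a labelled case base
#'
#' Generates a case base with the statistical shape of a hospital
#' breast-cancer FNA archive: about 1,200 cases with a 950:264
#' benign-to-malignant imbalance, clinical features inside the domains of
#' [fna_schema()], and ECC attributes drawn independently of the clinical
#' content (a case's provenance does not depend on its pathology).
#'
#' Internal features are drawn per class from truncated normals (numeric),
#' rounded truncated normals (ordinal) or Bernoulli draws (binary). A single
#' `class_separation` knob controls how far the malignant distributions sit
#' from the benign ones, in units of the within-class standard deviation
#' (one tenth of the domain width): 0 makes the classes indistinguishable,
#' values around 2 give realistic overlap, and values of 6 or more make the
#' classes essentially separable. Values are clipped into the declared
#' domains, so every generated base validates against the schema.
#'
#' @param n_cases Number of cases (default 1214).
#' @param malignant_fraction Expected malignant share (default 264/1214).
#' @param class_separation Effect size shifting malignant feature means, in
#'   within-class standard deviations (default 2).
#' @param schema A `cbr_schema` (default [fna_schema()]).
#' @param seed Integer seed (required; the draw is fully reproducible).
#' @param exact_counts If `TRUE`, exactly `round(n * fraction)` cases are
#'   malignant (labels assigned by permutation); otherwise labels are
#'   Bernoulli draws.
#' @param ecc_profile Optional named list of `c(mean, sd)` pairs overriding
#'   the default uniform draw of each ECC feature.
#' @param ecc_correlation Effect size tying ECC means to the class (default
#'   0, i.e. ECC independent of pathology); for sensitivity analyses only.
#' @return A validated case-base tibble.
#' @export
#' @examples
#' base <- simulate_casebase(n_cases = 100, seed = 42)
#' table(base$class)
simulate_casebase <- function(n_cases = 1214, malignant_fraction = 264 / 1214,
                              class_separation = 2, schema = fna_schema(),
                              seed, exact_counts = FALSE,
                              ecc_profile = NULL, ecc_correlation = 0) {
  stopifnot(n_cases >= 1, malignant_fraction > 0, malignant_fraction < 1,
            class_separation >= 0)
  validate_schema(schema)
  set.seed(as.integer(seed))
  n <- as.integer(n_cases)
  if (exact_counts) {
    n_mal <- round(n * malignant_fraction)
    y <- sample(c(rep(1, n_mal), rep(0, n - n_mal)))
  } else {
    y <- rbinom(n, 1, malignant_fraction)
  }
  data <- tibble::tibble(id = sprintf("case_%05d", seq_len(n)))
  for (i in seq_len(nrow(schema))) {
    sp <- schema[i, ]
    f <- sp$name
    if (sp$channel == "id") next
    if (sp$channel == "label") { data[[f]] <- y; next }
    shift_units <- if (sp$channel == "internal") class_separation else ecc_correlation
    if (sp$kind %in% c("numeric", "ordinal")) {
      width <- sp$upper - sp$lower
      sd_f <- width / 10
      centre <- (sp$lower + sp$upper) / 2
      mu <- centre + ifelse(y == 1, 1, -1) * shift_units * sd_f / 2
      if (sp$channel == "ecc" && is.null(ecc_profile)) {
        x <- runif(n, sp$lower, sp$upper)  # appraisal scores: flat by default
        x <- x + ifelse(y == 1, 1, -1) * shift_units * sd_f / 2
      } else if (sp$channel == "ecc") {
        prof <- ecc_profile[[f]]
        x <- rnorm(n, prof[1], prof[2])
      } else {
        x <- rnorm(n, mu, sd_f)
      }
      x <- pmin(pmax(x, sp$lower), sp$upper)
      if (sp$kind == "ordinal") x <- round(x)
      data[[f]] <- as.numeric(x)
    } else if (sp$kind == "binary") {
      p1 <- stats::plogis(ifelse(y == 1, 1, -1) * shift_units / 2)
      data[[f]] <- rbinom(n, 1, p1)
    } else {
      levs <- sp$levels[[1]]
      data[[f]] <- sample(levs, n, replace = TRUE)
    }
  }
  validate_casebase(data, schema, require_label = TRUE)
}

#' Simulate an expert score panel
#'
#' Generates an `m` raters by `n` items matrix of integer scores 1–10 with a
#' tunable level of agreement. Each item gets a latent quality drawn without
#' replacement from values spread over \[1, 10\]; each score is a convex
#' blend `concordance * quality + (1 - concordance) * noise`, rounded and
#' clipped to \[1, 10\]. At `concordance = 1` every rater reproduces the item
#' qualities exactly, so the rankings agree perfectly (Kendall's W = 1); at
#' `concordance = 0` scores are pure rater noise and W concentrates near 0.
#'
#' @param m Number of raters (>= 2).
#' @param n Number of items (>= 2).
#' @param concordance Agreement level in \[0, 1\].
#' @param seed Integer seed (required).
#' @param items Optional item (column) names.
#' @return A numeric matrix, raters x items.
#' @export
#' @examples
#' s <- simulate_expert_scores(10, 3, concordance = 0.9, seed = 1)
#' kendalls_w(s)
simulate_expert_scores <- function(m, n, concordance, seed, items = NULL) {
  stopifnot(m >= 2, n >= 2, concordance >= 0, concordance <= 1)
  set.seed(as.integer(seed))
  quality <- sample(seq(1, 10, length.out = max(n, 4)), n)
  noise <- matrix(runif(m * n, 1, 10), m, n)
  raw <- concordance * matrix(quality, m, n, byrow = TRUE) +
    (1 - concordance) * noise
  scores <- pmin(pmax(round(raw), 1), 10)
  dimnames(scores) <- list(paste0("rater", seq_len(m)),
                           items %||% paste0("item", seq_len(n)))
  scores
}
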
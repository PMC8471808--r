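test_that("local similarity follows the per-kind rules", {
  age <- feature_spec("age", "numeric", 10, 95)
  expect_equal(local_similarity(29, 29, age), 1)
  expect_equal(local_similarity(10, 95, age), 0)
  expect_equal(local_similarity(29, 19, age), 1 - 10 / 85)
  # symmetric
  expect_equal(local_similarity(29, 19, age), local_similarity(19, 29, age))

  bin <- feature_spec("b", "binary")
  expect_equal(local_similarity(1, 1, bin), 1)
  expect_equal(local_similarity(1, 0, bin), 0)

  cat <- feature_spec("c", "categorical", levels = c("x", "y"))
  expect_equal(local_similarity("x", "y", cat), 0)

  # zero-width domain: similarity defined as 1
  degenerate <- feature_spec("d", "numeric", 3, 3.0000001)
  degenerate$upper <- 3  # bypass constructor check to probe the rule
  expect_equal(local_similarity(3, 3, degenerate), 1)
})

test_that("global similarity is the weighted mean over internal features only", {
  sch <- feature_schema(
    feature_spec("id", "categorical", channel = "id"),
    feature_spec("a", "numeric", 0, 1, weight = 2),
    feature_spec("b", "numeric", 0, 1, weight = 1),
    feature_spec("c", "binary", weight = 1),
    feature_spec("class", "binary", channel = "label"),
    feature_spec("q", "ordinal", 1, 10, channel = "ecc"))
  # local sims (1.0, 0.5, 0.0) with weights (2, 1, 1) -> 0.625
  q <- tibble::tibble(a = 0.3, b = 0.0, c = 1, class = 0, q = 1)
  s <- tibble::tibble(a = 0.3, b = 0.5, c = 0, class = 1, q = 9)
  expect_equal(case_similarity(q, s, sch), 0.625)
  # symmetric; identity case scores 1 regardless of ECC and label differences
  expect_equal(case_similarity(s, q, sch), 0.625)
  q2 <- q; q2$q <- 7; q2$class <- 1
  expect_equal(case_similarity(q, q2, sch), 1)
  # all features maximally dissimilar -> 0
  far <- tibble::tibble(a = 1.3, b = 1, c = 0, class = 1, q = 1)
  q3 <- tibble::tibble(a = 0.3, b = 0, c = 1, class = 0, q = 1)
  expect_equal(case_similarity(q3, far, sch), 0)
})

test_that("retrieve matches the brute-force oracle, including ties", {
  set.seed(202)
  for (rep in 1:60) {
    sch <- toy_schema(sample(2:4, 1))
    n <- sample(c(5, 20, 60, 200), 1, prob = c(.3, .4, .2, .1))
    base <- toy_casebase(sch, n)
    # duplicated rows force similarity ties
    if (n > 5) base[2, -1] <- base[1, -1]
    query <- toy_casebase(sch, 1)
    k <- sample(1:min(10, n), 1)
    got <- retrieve(base, query, sch, k)
    want <- brute_retrieve(base, query, sch, k)
    expect_equal(got$case_id, want$case_id)
    expect_equal(got$similarity, want$similarity, tolerance = 1e-12)
    expect_equal(got$rank, seq_len(min(k, n)))
  }
})

test_that("retrieval saturates, self-matches, and refuses empty sub-bases", {
  base <- simulate_casebase(n_cases = 25, seed = 8)
  sch <- fna_schema()
  all_ranked <- retrieve(base, base[3, ], sch, k = 100)
  expect_equal(nrow(all_ranked), 25)
  expect_equal(attr(all_ranked, "k_used"), 25L)
  # a stored case identical to the query is rank 1 with similarity 1
  expect_equal(all_ranked$case_id[1], base$id[3])
  expect_equal(all_ranked$similarity[1], 1)
  expect_error(retrieve(base[0, ], base[1, ], sch, 2), "empty")
})

test_that("the fusion score is a convex, monotone blend of neighbour labels", {
  rr <- function(sims) {
    structure(tibble::tibble(case_id = paste0("c", seq_along(sims)),
                             similarity = sims, rank = seq_along(sims)),
              class = c("ranked_retrieval", class(tibble::tibble())))
  }
  # hand-computed: d = (0.2, 0.4, 0.5), labels (1, 0, 1) -> (5 + 2) / (5 + 2.5 + 2)
  r <- rr(c(0.8, 0.6, 0.5))
  labs <- c(c1 = 1, c2 = 0, c3 = 1)
  expect_equal(knn_fusion_score(r, labs), 7 / 9.5)
  # unanimity
  expect_equal(knn_fusion_score(r, c(c1 = 1, c2 = 1, c3 = 1)), 1)
  # symmetry: equal distance and weight, labels {0, 1} -> 0.5
  expect_equal(knn_fusion_score(rr(c(0.7, 0.7)), c(c1 = 0, c2 = 1)), 0.5)
  # exact match short-circuits to that label
  expect_equal(knn_fusion_score(rr(c(1, 0.9)), c(c1 = 0, c2 = 1)), 0)

  # properties over random retrievals
  set.seed(77)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    sims <- runif(n, 0, 0.99)
    y <- sample(0:1, n, replace = TRUE)
    labs <- setNames(y, paste0("c", 1:n))
    sp <- knn_fusion_score(rr(sims), labs)
    expect_gte(sp, min(y)); expect_lte(sp, max(y))
    # raising one label 0 -> 1 never decreases Sp
    j <- sample(n, 1)
    y2 <- y; y2[j] <- 1
    expect_gte(knn_fusion_score(rr(sims), setNames(y2, names(labs))), sp)
    # moving a neighbour closer pulls Sp toward its label
    sims3 <- sims; sims3[j] <- min(0.995, sims[j] + (1 - sims[j]) / 2)
    sp3 <- knn_fusion_score(rr(sims3), labs)
    if (y[j] == 1) expect_gte(sp3, sp) else expect_lte(sp3, sp)
  }
})

test_that("cross-validated K selection is reproducible and sound", {
  base <- simulate_casebase(n_cases = 160, class_separation = 8, seed = 21)
  sch <- fna_schema()
  sel <- select_optimal_k(base, sch, k_grid = 1:6, folds = 4, seed = 9)
  # noiseless separable base: best K reaches accuracy 1
  expect_equal(max(sel$grid$accuracy), 1.0)
  expect_equal(sel$grid$accuracy[sel$grid$k == sel$best_k], 1.0)
  # smallest maximizer is chosen
  expect_equal(sel$best_k, min(sel$grid$k[sel$grid$accuracy == max(sel$grid$accuracy)]))

  # identical seeds -> identical results; different seed may differ
  sel2 <- select_optimal_k(base, sch, k_grid = 1:6, folds = 4, seed = 9)
  expect_identical(tidy(sel), tidy(sel2))
  expect_identical(sel$best_k, sel2$best_k)

  # singleton grid
  sel3 <- select_optimal_k(base, sch, k_grid = 3, folds = 4, seed = 9)
  expect_equal(sel3$best_k, 3)

  # k beyond the smallest training-fold class count is skipped with a warning
  tiny <- simulate_casebase(n_cases = 24, malignant_fraction = 0.25,
                            class_separation = 5, seed = 3, exact_counts = TRUE)
  expect_warning(sel4 <- select_optimal_k(tiny, sch, k_grid = c(1, 2, 23),
                                          folds = 2, seed = 1), "skipping")
  expect_false(23 %in% sel4$grid$k)
})
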
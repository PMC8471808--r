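test_that("weight elicitation reproduces known ratios and honours trimming", {
  # the canonical panel: item means in ratio 8:2:10 -> weights (0.4, 0.1, 0.5)
  s <- matrix(rep(c(8, 2, 10), each = 4), nrow = 4,
              dimnames = list(NULL, c("specialty", "willingness", "quality")))
  w <- elicit_weights(s)
  expect_equal(w$weight, c(0.4, 0.1, 0.5))
  expect_equal(sum(w$weight), 1)

  # the bundled synthetic panel has the same means
  panel <- readr::read_csv(system.file("extdata", "synthetic_expert_scores.csv",
                                       package = "cbrecc"),
                           show_col_types = FALSE)
  w2 <- elicit_weights(as_score_matrix(panel[, -1]))
  expect_equal(w2$weight, c(0.4, 0.1, 0.5))

  # identical rater rows: weights proportional to that row
  s3 <- matrix(rep(c(3, 6, 1), 2), nrow = 2, byrow = TRUE)
  expect_equal(elicit_weights(s3)$weight, c(3, 6, 1) / 10)

  # scale invariance (within the 1-10 admissible range)
  s4 <- rbind(c(1, 2, 4), c(2, 1, 3), c(1, 3, 4), c(2, 2, 5))
  expect_equal(elicit_weights(s4 * 2)$weight, elicit_weights(s4)$weight)

  # trimmed means drop one max and one min per item
  s5 <- rbind(c(10, 2), c(4, 2), c(5, 3), c(6, 9), c(5, 4))
  wt <- elicit_weights(s5, trim = TRUE)
  tm <- c(mean(c(5, 5, 6)), mean(c(3, 4, 2)))  # hand-trimmed columns
  expect_equal(wt$mean_score, tm)
  expect_equal(wt$weight, tm / sum(tm))
  expect_true(attr(wt, "trimmed"))
  # concordance is computed on the untrimmed panel either way
  expect_equal(attr(wt, "concordance")$W, kendalls_w(s5)$W)
  expect_error(elicit_weights(s5[1:3, ], trim = TRUE), "at least 4")

  # malformed panels are rejected
  expect_error(as_score_matrix(rbind(c(1, 11), c(2, 3))), "integers in")
  expect_error(as_score_matrix(rbind(c(1, NA), c(2, 3))), "complete")
})

test_that("Kendall's W handles perfect, null and tied concordance", {
  # identical untied rankings -> W = 1
  s <- rbind(c(1, 5, 9), c(2, 6, 10), c(1, 4, 7))
  res <- kendalls_w(s)
  expect_equal(res$W, 1)
  expect_equal(res$df, 2)
  expect_equal(res$chi_square, res$m * (res$n - 1) * res$W)

  # Latin-square rankings: every item's rank total equal -> W = 0
  latin <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  expect_equal(kendalls_w(latin)$W, 0)
  expect_equal(kendalls_w(latin)$p_value, 1)

  # all scores identical for every rater: W undefined
  expect_error(kendalls_w(matrix(5, 3, 4)), "undefined")

  # rater order invariance and monotone-rescoring invariance
  set.seed(31)
  s2 <- simulate_expert_scores(6, 5, concordance = 0.6, seed = 44)
  expect_equal(kendalls_w(s2[sample(6), ])$W, kendalls_w(s2)$W)
  # per-rater shift: monotone, preserves within-rater ranks
  mono <- t(apply(s2, 1, function(r) r + (10 - max(r))))
  expect_equal(kendalls_w(mono)$W, kendalls_w(s2)$W, tolerance = 1e-12)
})

test_that("Kendall's W matches the direct-summation oracle on random panels", {
  set.seed(303)
  for (rep in 1:210) {
    m <- sample(2:12, 1); n <- sample(2:12, 1)
    s <- matrix(sample(1:10, m * n, replace = TRUE), m, n)
    if (all(apply(s, 1, function(r) length(unique(r)) == 1))) next
    expect_equal(kendalls_w(s)$W, kendalls_w_direct(s), tolerance = 1e-12)
  }
  skip_if_not_installed("vegan")
  # external cross-check on an untied panel
  set.seed(9)
  s <- t(replicate(5, sample(1:8)))
  s <- s + 2; s[s > 10] <- 10  # keep scores in range but mostly untied
  expect_equal(kendalls_w(s)$W,
               unname(vegan::kendall.global(t(s))$Concordance_analysis["W", 1]),
               tolerance = 1e-10)
})

test_that("ECC scores are domain-normalized weighted sums in [0, 1]", {
  sch <- fna_schema()
  w <- c(specialty = 0.4, willingness = 0.1, quality = 0.5)
  # hand arithmetic: specialty 5, willingness 1, quality 8
  d <- tibble::tibble(specialty = 5, willingness = 1, quality = 8)
  expect_equal(ecc_score(d, w, sch), 0.4 * 4 / 9 + 0.1 * 1 + 0.5 * 7 / 9)
  # all at domain maximum -> 1
  dmax <- tibble::tibble(specialty = 10, willingness = 1, quality = 10)
  expect_equal(ecc_score(dmax, w, sch), 1)
  # concentrated weight projects one normalized feature
  wq <- c(specialty = 0, willingness = 0, quality = 1)
  expect_equal(ecc_score(d, wq, sch), 7 / 9)
  # errors: missing feature, wrong coverage, bad sum
  expect_error(ecc_score(d[, 1:2], w, sch), "missing ECC")
  expect_error(ecc_score(d, w[1:2], sch), "exactly")
  wbad <- w; wbad["quality"] <- 0.9
  expect_error(ecc_score(d, wbad, sch), "sum to 1")
})

test_that("harmonic fusion obeys its mean inequalities and annihilation", {
  expect_equal(harmonic_fuse(0.8, 0.8), 0.8)
  expect_equal(harmonic_fuse(0.9, 0), 0)
  expect_equal(harmonic_fuse(0, 0), 0)
  expect_equal(harmonic_fuse(0.8, 0.4), 2 * 0.8 * 0.4 / 1.2)
  expect_error(harmonic_fuse(-0.1, 0.5), "non-negative")

  set.seed(12)
  s <- runif(2000); p <- runif(2000)
  sp <- harmonic_fuse(s, p)
  expect_true(all(sp >= pmin(s, p) - 1e-12))
  expect_true(all(sp <= sqrt(s * p) + 1e-12))
  expect_true(all(sqrt(s * p) <= (s + p) / 2 + 1e-12))
  # symmetry and monotonicity
  expect_equal(harmonic_fuse(p, s), sp)
  expect_true(all(harmonic_fuse(pmin(s + 0.05, 1), p) >= sp - 1e-12))
})

test_that("re-ranking fuses, permutes, and promotes well-sourced cases", {
  base <- simulate_casebase(n_cases = 30, seed = 14)
  sch <- fna_schema()
  w <- c(specialty = 0.4, willingness = 0.1, quality = 0.5)
  ret <- retrieve(base, base[4, ], sch, k = 8)
  fused <- rerank_with_ecc(ret, base, w, sch)
  # permutation of the retrieval, both rank columns coherent
  expect_setequal(fused$case_id, ret$case_id)
  expect_equal(sort(fused$rank_with_ecc), 1:8)
  expect_equal(fused$rank_with_ecc, seq_len(8))
  expect_equal(fused$fused, harmonic_fuse(fused$similarity, fused$ecc_score))
  expect_true(all(diff(fused$fused) <= 1e-12))

  # identical ECC across cases -> order identical to similarity order
  flat <- base
  flat$specialty <- 5; flat$willingness <- 1; flat$quality <- 5
  ret_f <- retrieve(flat, flat[4, ], sch, k = 8)
  fused_f <- rerank_with_ecc(ret_f, flat, w, sch)
  expect_equal(fused_f$case_id, ret_f$case_id)
  expect_equal(fused_f$rank_with_ecc, fused_f$rank_without_ecc)

  # the documented promotion: St (0.86, 0.77) with Pt (0.50, 0.95) swaps ranks
  two <- tibble::tibble(
    id = c("hi_sim", "hi_ecc"),
    age = c(30, 30), consistency = c(3, 3), clump_thickness = c(5, 5),
    fna = c(2, 2), swabs = c(5, 5), class = c(0, 0),
    specialty = c(6, 9.5), willingness = c(0, 1), quality = c(6, 9.5))
  pt <- ecc_score(two, w, sch)
  expect_equal(pt, c(0.5, 0.95))
  rr <- structure(tibble::tibble(case_id = two$id, similarity = c(0.86, 0.77),
                                 rank = 1:2),
                  class = c("ranked_retrieval", class(tibble::tibble())))
  swapped <- rerank_with_ecc(rr, two, w, sch)
  expect_equal(swapped$case_id, c("hi_ecc", "hi_sim"))
  expect_equal(swapped$rank_with_ecc[swapped$case_id == "hi_ecc"], 1L)
  expect_equal(swapped$fused,
               harmonic_fuse(c(0.77, 0.86), c(0.95, 0.5)))

  # unresolvable id errors
  rr_bad <- structure(tibble::tibble(case_id = "ghost", similarity = 0.5, rank = 1L),
                      class = c("ranked_retrieval", class(tibble::tibble())))
  expect_error(rerank_with_ecc(rr_bad, base, w, sch), "not found")
})

test_that("weights and fused retrievals round-trip through their files", {
  s <- simulate_expert_scores(10, 3, concordance = 0.8, seed = 1,
                              items = c("specialty", "willingness", "quality"))
  w <- elicit_weights(s)
  f <- withr::local_tempfile(fileext = ".json")
  write_ecc_weights(w, f)
  back <- read_ecc_weights(f)
  expect_equal(back$weight, w$weight)
  expect_equal(attr(back, "concordance")$W, attr(w, "concordance")$W)

  base <- simulate_casebase(n_cases = 20, seed = 15)
  fused <- rerank_with_ecc(retrieve(base, base[2, ], fna_schema(), k = 5),
                           base, w, fna_schema())
  fcsv <- withr::local_tempfile(fileext = ".csv")
  write_fused(fused, fcsv)
  tab <- readr::read_csv(fcsv, show_col_types = FALSE)
  expect_equal(tab$index_with_ecc, fused$case_id)
  expect_equal(tab$sorting_value_without_ecc, sort(fused$similarity, decreasing = TRUE))
})
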
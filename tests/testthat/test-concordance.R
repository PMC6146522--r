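one_pos <- function(sample, counts, pos = 1L) {
  tibble::tibble(chrom = "panel", pos = pos, sample = sample,
                 A = counts[1], C = counts[2], G = counts[3], T = counts[4])
}

test_that("base weights are counts over totals and sum to one", {
  w1 <- base_weights(one_pos("B1", c(100, 0, 0, 0)))
  expect_equal(unlist(w1[c("w_A", "w_C", "w_G", "w_T")], use.names = FALSE),
               c(1, 0, 0, 0))
  w2 <- base_weights(one_pos("B1", c(50, 50, 0, 0)))
  expect_equal(unlist(w2[c("w_A", "w_C", "w_G", "w_T")], use.names = FALSE),
               c(0.5, 0.5, 0, 0))
  expect_equal(w2$TC, 100); expect_equal(w2$MC, 50); expect_equal(w2$BC, 50)

  set.seed(61)
  bc <- simulate_base_count_matrix(100, seed = 61)
  w <- base_weights(bc)
  expect_true(all(abs(w$w_A + w$w_C + w$w_G + w$w_T - 1) < 1e-12))
  # brute-force recomputation
  expect_equal(w$w_G, bc$G / (bc$A + bc$C + bc$G + bc$T))
  expect_true(all(w$BC == w$TC - w$MC & w$BC >= 0))
  expect_true(all(w$MC >= w$TC / 4))

  expect_warning(base_weights(one_pos("B1", c(0, 0, 0, 0))), "uncovered")
})

test_that("base-weight correlation matches its defining formula", {
  bc <- simulate_base_count_matrix(200, seed = 62)
  # a sample against itself
  dup <- dplyr::mutate(bc[bc$sample == "B1", ], sample = "copy")
  expect_equal(pairwise_weight_correlation(dplyr::bind_rows(bc, dup),
                                           "B1", "copy"), 1)

  # direct covariance-formula recomputation
  r_pkg <- pairwise_weight_correlation(bc, "B1", "N1")
  w <- base_weights(bc)
  va <- unlist(w[w$sample == "B1", c("w_A", "w_C", "w_G", "w_T")], use.names = FALSE)
  vb <- unlist(w[w$sample == "N1", c("w_A", "w_C", "w_G", "w_T")], use.names = FALSE)
  r_manual <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(r_pkg, r_manual, tolerance = 1e-12)

  # permuting positions of one sample leaves the weight multiset intact but
  # changes the pairing; the result must still equal the direct formula
  perm <- withr::with_seed(63, sample(200))
  bp <- bc[bc$sample == "B2", ]
  bp <- dplyr::mutate(bp[perm, ], pos = sort(pos), sample = "B2perm")
  bc2 <- dplyr::bind_rows(bc, bp)
  r_p <- pairwise_weight_correlation(bc2, "B2", "B2perm")
  w2 <- base_weights(bc2)
  x <- unlist(w2[w2$sample == "B2", c("w_A", "w_C", "w_G", "w_T")], use.names = FALSE)
  y <- unlist(w2[w2$sample == "B2perm", c("w_A", "w_C", "w_G", "w_T")], use.names = FALSE)
  expect_equal(r_p, stats::cov(x, y) / (stats::sd(x) * stats::sd(y)),
               tolerance = 1e-12)

  # two noise-only deep samples are near-perfectly correlated
  expect_gt(pairwise_weight_correlation(bc, "N1", "N2"), 0.99)

  # zero variance is reported as undefined
  flat <- dplyr::bind_rows(
    one_pos("a", c(10, 10, 10, 10), 1L), one_pos("a", c(10, 10, 10, 10), 2L),
    one_pos("b", c(5, 5, 0, 0), 1L), one_pos("b", c(5, 5, 0, 0), 2L)
  )
  expect_warning(r0 <- pairwise_weight_correlation(flat, "a", "b"), "variance")
  expect_true(is.na(r0))
})

test_that("inter/intra-group t test follows the textbook formula", {
  cors <- tibble::tibble(
    sample_a = c("B1", "B2", "B1", "N1"),
    sample_b = c("N1", "N2", "B2", "N2"),
    r = c(0.1, 0.2, 0.8, 0.9)
  )
  groups <- c(B1 = "B", B2 = "B", N1 = "N", N2 = "N")
  out <- inter_intra_group_test(cors, groups)
  # hand computation: means 0.15 vs 0.85, pooled sd sqrt(0.005),
  # t = -0.7/0.0707 = -9.8995, df = 2, p = 1 - t/sqrt(t^2+2) evaluated
  # exactly = 0.01005050...
  expect_equal(out$statistic, -9.899495, tolerance = 1e-6)
  expect_equal(out$df, 2)
  expect_equal(out$p_value, 0.010050506, tolerance = 1e-6)
  # agreement with stats::t.test (pooled variance), an independent route
  tt <- stats::t.test(cors$r[1:2], cors$r[3:4], var.equal = TRUE)
  expect_equal(out$p_value, tt$p.value)

  # identical values in both groups: no difference, p = 1
  cors0 <- dplyr::mutate(cors, r = 0.5)
  expect_equal(inter_intra_group_test(cors0, groups)$p_value, 1)

  # degenerate variance with distinct means: undefined
  cors1 <- dplyr::mutate(cors, r = c(0.1, 0.1, 0.9, 0.9))
  expect_true(is.na(inter_intra_group_test(cors1, groups)$p_value))

  expect_error(inter_intra_group_test(cors, c(B1 = "B")), "group label")
})

test_that("inter/intra t test is roughly calibrated on null panels", {
  groups <- c(B1 = "B", B2 = "B", B3 = "B", N1 = "N", N2 = "N")
  pvals <- vapply(1:40, function(s) {
    bc <- simulate_base_count_matrix(150, seed = 1000 + s)
    inter_intra_group_test(weight_correlation_matrix(bc), groups)$p_value
  }, numeric(1))
  expect_lte(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.25)   # not piled near zero
})

test_that("genetic distance is the Euclidean metric on weight vectors", {
  expect_equal(genetic_distance(c(0.25, 0.25, 0.25, 0.25),
                                c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(genetic_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), sqrt(2))

  set.seed(64)
  for (i in 1:25) {
    w1 <- as.vector(stats::rmultinom(1, 100, runif(4))) / 100
    w2 <- as.vector(stats::rmultinom(1, 100, runif(4))) / 100
    w3 <- as.vector(stats::rmultinom(1, 100, runif(4))) / 100
    # brute-force componentwise recomputation
    expect_equal(genetic_distance(w1, w2),
                 sqrt((w1[1] - w2[1])^2 + (w1[2] - w2[2])^2 +
                      (w1[3] - w2[3])^2 + (w1[4] - w2[4])^2))
    # metric axioms
    expect_equal(genetic_distance(w1, w2), genetic_distance(w2, w1))
    expect_lte(genetic_distance(w1, w3),
               genetic_distance(w1, w2) + genetic_distance(w2, w3) + 1e-12)
    expect_gte(genetic_distance(w1, w2), 0)
    expect_lte(genetic_distance(w1, w2), sqrt(2))
  }

  bc <- simulate_base_count_matrix(50, seed = 65)
  d <- genetic_distances(bc, "B1", "N1")
  expect_equal(nrow(d), 50)
  expect_true(all(d$distance >= 0 & d$distance <= sqrt(2)))
})

test_that("position error rate and its corrected null probability", {
  bc2 <- dplyr::bind_rows(
    one_pos("N1", c(3980, 10, 5, 5)), one_pos("N2", c(3980, 12, 4, 4))
  )
  em <- position_error_rate(bc2, c("N1", "N2"))
  expect_equal(em$per, 40 / 8000)
  expect_equal(em$tc_ref, 4000)
  expect_equal(em$tc_total, 8000)
  expect_equal(em$p0, 0.005 + qnorm(0.95) * sqrt(0.005 / 4000))

  # summed-TC variant of the correction denominator
  em_sum <- position_error_rate(bc2, c("N1", "N2"), tc_ref = "sum")
  expect_equal(em_sum$p0, 0.005 + qnorm(0.95) * sqrt(0.005 / 8000))

  # clean references: PER = 0, p0 = 0
  clean <- dplyr::bind_rows(one_pos("N1", c(4000, 0, 0, 0)),
                            one_pos("N2", c(4000, 0, 0, 0)))
  em0 <- position_error_rate(clean, c("N1", "N2"))
  expect_equal(em0$per, 0)
  expect_equal(em0$p0, 0)

  expect_error(position_error_rate(bc2, c("N1", "N3")), "absent")
})

test_that("gaussian quantile is validated and agrees with an independent
           rational approximation", {
  expect_equal(round(gaussian_quantile(0.95), 2), 1.64)
  expect_equal(gaussian_quantile(0.5), 0)
  for (p in c(0.01, 0.025, 0.3, 0.5, 0.9, 0.95, 0.975, 0.999)) {
    expect_equal(gaussian_quantile(p), oracle_inv_norm(p), tolerance = 1e-6)
  }
  expect_error(gaussian_quantile(0), "inside")
  expect_error(gaussian_quantile(1), "inside")
})

test_that("binomial background test: exact values, monotonicity, edge cases", {
  em <- tibble::tibble(chrom = "panel", pos = 1L, per = 0.004,
                       tc_ref = 4000, tc_total = 8000, p0 = 0.005)

  # zero background counts: upper tail from zero successes is 1
  clean <- dplyr::bind_rows(one_pos("B1", c(4000, 0, 0, 0)),
                            one_pos("B2", c(4000, 0, 0, 0)),
                            one_pos("B3", c(4000, 0, 0, 0)))
  expect_equal(pbc_test(clean, c("B1", "B2", "B3"), em)$pbc, 1)

  # frozen exact-rational value: P(X >= 10 | 4000, 0.005)
  mk <- function(bg) dplyr::bind_rows(
    one_pos("B1", c(4000 - bg, bg, 0, 0)), one_pos("B2", c(4000 - bg, bg, 0, 0)),
    one_pos("B3", c(4000 - bg, bg, 0, 0))
  )
  out10 <- pbc_test(mk(10), c("B1", "B2", "B3"), em)
  expect_equal(out10$successes, 10)
  expect_equal(out10$trials, 4000)
  expect_equal(out10$pbc, 0.9950842356387072, tolerance = 1e-9)

  # monotone: non-increasing in successes; non-decreasing in p0
  pbcs <- vapply(c(10, 25, 40, 80), function(bg) {
    pbc_test(mk(bg), c("B1", "B2", "B3"), em)$pbc
  }, numeric(1))
  expect_true(all(diff(pbcs) <= 0))
  p0s <- c(0.002, 0.005, 0.01, 0.02)
  pbcs2 <- vapply(p0s, function(p0) {
    pbc_test(mk(25), c("B1", "B2", "B3"), dplyr::mutate(em, p0 = p0))$pbc
  }, numeric(1))
  expect_true(all(diff(pbcs2) >= 0))

  # perfect variant at error-free references: astronomically significant
  em_small <- dplyr::mutate(em, p0 = 0.001)
  varbc <- dplyr::bind_rows(
    one_pos("B1", c(2000, 2000, 0, 0)), one_pos("B2", c(2000, 2000, 0, 0)),
    one_pos("B3", c(2000, 2000, 0, 0))
  )
  expect_lt(pbc_test(varbc, c("B1", "B2", "B3"), em_small)$pbc,
            significance_threshold(0.001, 13855))

  # PER = 0 null is floored so that observed background is never impossible
  em0 <- dplyr::mutate(em, per = 0, p0 = 0)
  out0 <- pbc_test(mk(5), c("B1", "B2", "B3"), em0)
  expect_gt(out0$pbc, 0)
  expect_lt(out0$pbc, 1)
  expect_equal(out0$p0, 1 / 8001)
})

test_that("half-up rounding of averaged counts", {
  # sums 10, 11, 13 -> means 10/3, 11/3, 13/3 -> rounded 3, 4, 4
  em <- tibble::tibble(chrom = "panel", pos = 1:3, per = 0.004,
                       tc_ref = 4000, tc_total = 8000, p0 = 0.005)
  bcs <- dplyr::bind_rows(purrr::map(1:3, function(p) {
    bg <- list(c(4, 3, 3), c(4, 4, 3), c(5, 4, 4))[[p]]
    dplyr::bind_rows(purrr::map(1:3, function(i) {
      one_pos(paste0("B", i), c(4000 - bg[i], bg[i], 0, 0), as.integer(p))
    }))
  }))
  out <- pbc_test(bcs, c("B1", "B2", "B3"), em)
  expect_equal(out$successes, c(3, 4, 4))
})

test_that("significance threshold is the printed Bonferroni division", {
  expect_equal(signif(significance_threshold(0.001, 13855), 4), 7.218e-8)
  expect_equal(significance_threshold(0.05, 1), 0.05)
  expect_equal(significance_threshold(0.001, 1e6), 1e-9)
})
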
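#' Per-position base weights and count summaries
#'
#' For every (position, sample) entry of a base-count table, computes the
#' total count `TC = A + C + G + T`, the major count `MC` (highest single
#' base), the background count `BC = TC - MC`, and the base-weight vector
#' `w_A..w_T = count / TC` — the fraction of reads supporting each base, the
#' 4-vector on which sample concordance is judged.
#'
#' @param bc Base-count tibble (columns `chrom`, `pos`, `sample`,
#'   `A`, `C`, `G`, `T`), e.g. from [read_base_counts()] or
#'   [simulate_base_count_matrix()].
#' @return The input with columns `TC`, `MC`, `BC`, `w_A`, `w_C`, `w_G`,
#'   `w_T` appended. Weights sum to 1 wherever `TC > 0`; uncovered entries
#'   (`TC = 0`) get `NA` weights with a warning — they should have been
#'   dropped at read time.
#' @export
base_weights <- function(bc) {
  out <- dplyr::mutate(bc,
    TC = .data$A + .data$C + .data$G + .data$T,
    MC = pmax(.data$A, .data$C, .data$G, .data$T),
    BC = .data$TC - .data$MC,
    w_A = ifelse(.data$TC > 0, .data$A / .data$TC, NA_real_),
    w_C = ifelse(.data$TC > 0, .data$C / .data$TC, NA_real_),
    w_G = ifelse(.data$TC > 0, .data$G / .data$TC, NA_real_),
    w_T = ifelse(.data$TC > 0, .data$T / .data$TC, NA_real_)
  )
  if (any(out$TC == 0)) {
    warn(sprintf("%d uncovered (TC = 0) entries; weights set to NA.", sum(out$TC == 0)))
  }
  out
}

#' Pearson correlation of base weights between two samples
#'
#' Concatenates the per-position 4-component weight vectors of each sample
#' (positions covered in both) and returns the Pearson correlation between
#' the two long vectors. Near-identical genomes give r close to 1 even in the
#' presence of sequencing error.
#'
#' @param bc Base-count tibble.
#' @param sample_a,sample_b Sample labels.
#' @return Pearson r in `[-1, 1]`, or `NA` (with a warning) if fewer than 2
#'   positions are shared or either vector has zero variance.
#' @export
pairwise_weight_correlation <- function(bc, sample_a, sample_b) {
  w <- base_weights(bc[bc$sample %in% c(sample_a, sample_b), ])
  wa <- w[w$sample == sample_a, ]
  wb <- w[w$sample == sample_b, ]
  j <- dplyr::inner_join(
    wa[c("chrom", "pos", "w_A", "w_C", "w_G", "w_T")],
    wb[c("chrom", "pos", "w_A", "w_C", "w_G", "w_T")],
    by = c("chrom", "pos"), suffix = c("_a", "_b")
  )
  j <- j[stats::complete.cases(j), ]
  if (nrow(j) < 2) {
    warn("Fewer than 2 positions covered in both samples; correlation undefined.")
    return(NA_real_)
  }
  va <- c(j$w_A_a, j$w_C_a, j$w_G_a, j$w_T_a)
  vb <- c(j$w_A_b, j$w_C_b, j$w_G_b, j$w_T_b)
  if (sd(va) == 0 || sd(vb) == 0) {
    warn("Zero variance in a weight vector; correlation undefined.")
    return(NA_real_)
  }
  cor(va, vb)
}

#' Base-weight correlations for every sample pair
#'
#' @param bc Base-count tibble.
#' @return Tibble with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `r`.
#' @export
weight_correlation_matrix <- function(bc) {
  samples <- unique(bc$sample)
  pairs <- combn(samples, 2)
  tibble::tibble(
    sample_a = pairs[1, ],
    sample_b = pairs[2, ],
    r = purrr::map2_dbl(pairs[1, ], pairs[2, ],
                        ~ pairwise_weight_correlation(bc, .x, .y))
  )
}

#' Compare inter-group and intra-group correlations
#'
#' Two-sample two-tailed Student's t test (pooled variance) asking whether
#' sample pairs that straddle the two phenotype groups are less concordant
#' than pairs within a group — the signature a genomically encoded phenotype
#' would leave. Implemented from the textbook pooled-variance formula so that
#' degenerate inputs are handled explicitly: identical group means with zero
#' pooled variance give t = 0, p = 1; zero variance with distinct means is
#' undefined (`NA`).
#'
#' @param correlations Tibble from [weight_correlation_matrix()] (columns
#'   `sample_a`, `sample_b`, `r`).
#' @param groups Named character vector mapping each sample to its group
#'   label; a pair is "inter" when its two samples belong to different groups.
#' @return One-row tibble: `mean_inter`, `mean_intra`, `n_inter`, `n_intra`,
#'   `statistic`, `df`, `p_value`.
#' @export
inter_intra_group_test <- function(correlations, groups) {
  miss <- setdiff(unique(c(correlations$sample_a, correlations$sample_b)),
                  names(groups))
  if (length(miss) > 0) {
    abort(sprintf("No group label for sample(s): %s", paste(miss, collapse = ", ")))
  }
  lab <- ifelse(groups[correlations$sample_a] == groups[correlations$sample_b],
                "intra", "inter")
  x <- correlations$r[lab == "inter"]
  y <- correlations$r[lab == "intra"]
  if (length(x) < 2 || length(y) < 2) {
    abort("Need at least 2 correlations per label for the t test.")
  }
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  delta <- mean(x) - mean(y)
  if (se == 0) {
    t_stat <- if (delta == 0) 0 else NA_real_
  } else {
    t_stat <- delta / se
  }
  p <- if (is.na(t_stat)) NA_real_ else 2 * pt(-abs(t_stat), df)
  tibble::tibble(
    mean_inter = mean(x), mean_intra = mean(y),
    n_inter = n1, n_intra = n2,
    statistic = t_stat, df = df, p_value = p
  )
}

#' Genetic distance between two base-weight vectors
#'
#' Euclidean ("Pythagorean") distance over the four base weights,
#' \eqn{d = \sqrt{\sum_{n \in \{A,T,G,C\}} (w_{1n} - w_{2n})^2}}, ranging
#' from 0 (identical composition) to \eqn{\sqrt 2} (disjoint single-base
#' compositions). See the methods vignette for why the square is placed
#' inside the sum.
#'
#' @param w1,w2 Numeric length-4 weight vectors (same base order).
#' @return Non-negative distance, at most `sqrt(2)` for weight vectors.
#' @export
genetic_distance <- function(w1, w2) {
  stopifnot(length(w1) == 4, length(w2) == 4)
  sqrt(sum((w1 - w2)^2))
}

#' Per-position genetic distances between two samples
#'
#' @param bc Base-count tibble.
#' @param sample_a,sample_b Sample labels.
#' @return Tibble `chrom`, `pos`, `distance` over positions covered in both.
#' @export
genetic_distances <- function(bc, sample_a, sample_b) {
  w <- base_weights(bc[bc$sample %in% c(sample_a, sample_b), ])
  wa <- w[w$sample == sample_a, ]
  wb <- w[w$sample == sample_b, ]
  j <- dplyr::inner_join(
    wa[c("chrom", "pos", "w_A", "w_C", "w_G", "w_T")],
    wb[c("chrom", "pos", "w_A", "w_C", "w_G", "w_T")],
    by = c("chrom", "pos"), suffix = c("_a", "_b")
  )
  tibble::tibble(
    chrom = j$chrom, pos = j$pos,
    distance = sqrt((j$w_A_a - j$w_A_b)^2 + (j$w_C_a - j$w_C_b)^2 +
                    (j$w_G_a - j$w_G_b)^2 + (j$w_T_a - j$w_T_b)^2)
  )
}

#' Quantile of the standard Gaussian
#'
#' Thin validated wrapper around the inverse normal CDF, used for the
#' error-rate correction multiplier (order 0.95 gives about 1.64).
#'
#' @param order Probability in (0, 1), exclusive.
#' @return The standard normal quantile.
#' @export
gaussian_quantile <- function(order) {
  if (!is.numeric(order) || any(is.na(order)) || any(order <= 0) || any(order >= 1)) {
    abort("`order` must lie strictly inside (0, 1).")
  }
  qnorm(order)
}

#' Position-specific error rates from reference samples
#'
#' Estimates, at every position, the background ("error") read fraction of
#' the reference group: `PER = sum(BC) / sum(TC)` over the reference samples.
#' The binomial null probability used downstream is inflated for estimation
#' noise, `p0 = PER + c * sqrt(PER / tc_ref)` (clamped to `[0, 1]`), with `c`
#' the Gaussian quantile of the chosen order and `tc_ref` the mean (default)
#' or summed reference total count at the position.
#'
#' @param bc Base-count tibble covering the reference samples at every
#'   position.
#' @param reference_samples Labels of the reference (e.g. non-sphere-forming)
#'   samples.
#' @param order Gaussian order for the correction multiplier; 0.95 gives
#'   c of about 1.64.
#' @param tc_ref `"mean"` (default; the scale of a single cell's coverage) or
#'   `"sum"` for the correction denominator.
#' @return A tibble of class `"pg_error_model"`: `chrom`, `pos`, `per`,
#'   `tc_ref`, `tc_total`, `p0`, with the multiplier in attribute `"c"`.
#' @export
position_error_rate <- function(bc, reference_samples, order = 0.95,
                                tc_ref = c("mean", "sum")) {
  tc_ref <- match.arg(tc_ref)
  cc <- gaussian_quantile(order)
  w <- base_weights(bc[bc$sample %in% reference_samples, ])
  if (!setequal(unique(w$sample), reference_samples)) {
    abort("Some reference samples are absent from the count table.")
  }
  agg <- dplyr::summarise(
    dplyr::group_by(w, .data$chrom, .data$pos),
    n_samples = dplyr::n(),
    bc_sum = sum(.data$BC),
    tc_total = sum(.data$TC),
    tc_mean = mean(.data$TC),
    .groups = "drop"
  )
  if (any(agg$n_samples != length(reference_samples)) || any(agg$tc_mean == 0)) {
    abort("Every position must be covered in all reference samples.")
  }
  denom <- if (tc_ref == "mean") agg$tc_mean else agg$tc_total
  per <- agg$bc_sum / agg$tc_total
  out <- tibble::tibble(
    chrom = agg$chrom, pos = agg$pos,
    per = per,
    tc_ref = denom,
    tc_total = agg$tc_total,
    p0 = pmin(1, per + cc * sqrt(per / denom))
  )
  attr(out, "c") <- cc
  class(out) <- c("pg_error_model", class(out))
  out
}

#' Binomial background test for the test group
#'
#' At each position, asks whether the test group's background count is larger
#' than sequencing error alone can explain: the per-cell-scale successes
#' `round(sum(BC_test) / k)` are tested against a binomial with
#' `round(sum(TC_test) / k)` trials and the corrected error probability `p0`
#' (upper tail, exact). `k` is the number of test samples; averaged counts are
#' rounded half away from zero. Whenever `p0` underestimates what finite
#' reference data can exclude (in particular `PER = 0`), it is floored at
#' `1 / (sum(TC_ref) + 1)` so that no position can be declared impossible
#' from finite data; a message reports how often the floor binds.
#'
#' @param bc Base-count tibble covering the test samples at every position.
#' @param test_samples Labels of the test (e.g. sphere-derived) samples.
#' @param error_model Output of [position_error_rate()] on the reference
#'   samples.
#' @return Tibble `chrom`, `pos`, `successes`, `trials`, `p0`, `pbc` with
#'   `pbc = P(X >= successes)`; positions with zero trials are dropped with a
#'   message.
#' @export
pbc_test <- function(bc, test_samples, error_model) {
  k <- length(test_samples)
  w <- base_weights(bc[bc$sample %in% test_samples, ])
  agg <- dplyr::summarise(
    dplyr::group_by(w, .data$chrom, .data$pos),
    successes = round_half_up(sum(.data$BC) / k),
    trials = round_half_up(sum(.data$TC) / k),
    .groups = "drop"
  )
  j <- dplyr::inner_join(agg, error_model, by = c("chrom", "pos"))
  if (nrow(j) < nrow(agg)) {
    pg_inform("%d position(s) missing from the error model; skipped.",
              nrow(agg) - nrow(j))
  }
  zero <- j$trials == 0
  if (any(zero)) {
    pg_inform("%d position(s) with zero trials skipped.", sum(zero))
    j <- j[!zero, ]
  }
  floor_p <- 1 / (j$tc_total + 1)
  p0 <- pmax(j$p0, floor_p)
  n_floored <- sum(j$p0 < floor_p)
  if (n_floored > 0) {
    pg_inform("Error floor 1/(sum TC_ref + 1) applied at %d position(s).", n_floored)
  }
  tibble::tibble(
    chrom = j$chrom, pos = j$pos,
    successes = j$successes, trials = j$trials, p0 = p0,
    pbc = pbinom(j$successes - 1, j$trials, p0, lower.tail = FALSE)
  )
}

#' Per-site Bonferroni-style significance threshold
#'
#' @param alpha Family-wise level.
#' @param n_sites Number of positions tested.
#' @return `alpha / n_sites` (e.g. `0.001 / 13855` is about 7.218e-8).
#' @export
significance_threshold <- function(alpha, n_sites) {
  assert_scalar_number(alpha, "alpha", lower = .Machine$double.xmin, upper = 1)
  assert_scalar_number(n_sites, "n_sites", lower = 1)
  alpha / n_sites
}
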
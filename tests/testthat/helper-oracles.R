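# Independent brute-force oracles used to check the package's statistics.
# These deliberately take a different computational route from the
# implementation they verify.

options(phenogeno.quiet = TRUE)

# two-sided Fisher p for [[ra, aa], [rb, ab]] by enumerating every table with
# the observed margins and summing the (conditional hypergeometric)
# probabilities of all tables at most as probable as the observed one
# (standard 1e-7 relative guard for floating-point ties)
oracle_fisher_p <- function(ra, aa, rb, ab) {
  r1 <- ra + aa
  r2 <- rb + ab
  c1 <- ra + rb
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(ra, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hypergeometric upper tail via the complement of the lower-tail CDF summed
# with dhyper (distinct route from the package's log-space upper-tail sum)
oracle_hyper_tail <- function(a, b, n, m) {
  draw <- n + m
  sum(stats::dhyper(m:draw, b, a - b, draw))
}

# exhaustive window-scan hotspot caller on a flag sequence: collect every
# contiguous window that starts and ends with a significant flag, holds at
# most max_gap non-significant flags and at least min_m significant ones,
# then select disjoint windows greedily (leftmost start, then longest)
oracle_window_scan <- function(flags, min_m, max_gap) {
  L <- length(flags)
  cand <- list()
  for (s in seq_len(L)) {
    if (!flags[s]) next
    for (e in s:L) {
      if (!flags[e]) next
      w <- flags[s:e]
      if (sum(!w) <= max_gap && sum(w) >= min_m) {
        cand[[length(cand) + 1L]] <- c(s, e)
      }
    }
  }
  out <- list()
  while (length(cand) > 0) {
    ss <- vapply(cand, `[`, numeric(1), 1)
    ee <- vapply(cand, `[`, numeric(1), 2)
    pick <- which(ss == min(ss))
    pick <- pick[which.max(ee[pick])]
    win <- cand[[pick]]
    out[[length(out) + 1L]] <- win
    keep <- ss > win[2]
    cand <- cand[keep]
  }
  out
}

# turn a flag sequence into positions whose fitted distance model reproduces
# exactly that significance pattern on chr1: significant distances get length
# 1, non-significant get length 1e6, and a padding chromosome of 50 distances
# of 1e6 pins the genome-wide mean so that (for sequences up to length 50)
# the 1% cutoff always falls strictly between 1 and 1e6
positions_from_flags <- function(flags) {
  stopifnot(length(flags) <= 50)
  d <- ifelse(flags, 1, 1e6)
  dplyr::bind_rows(
    tibble::tibble(chrom = "chr0", pos = seq(1, by = 1e6, length.out = 51)),
    tibble::tibble(chrom = "chr1", pos = cumsum(c(1, d)))
  )
}

# inverse normal CDF by Acklam's rational approximation (independent of
# qnorm), absolute error < 1.15e-9
oracle_inv_norm <- function(p) {
  a <- c(-3.969683028665376e+01, 2.209460984245205e+02, -2.759285104469687e+02,
         1.383577518672690e+02, -3.066479806614716e+01, 2.506628277459239e+00)
  b <- c(-5.447609879822406e+01, 1.615858368580409e+02, -1.556989798598866e+02,
         6.680131188771972e+01, -1.328068155288572e+01)
  cc <- c(-7.784894002430293e-03, -3.223964580411365e-01, -2.400758277161838e+00,
          -2.549732539343734e+00, 4.374664141464968e+00, 2.938163982698783e+00)
  d <- c(7.784695709041462e-03, 3.224671290700398e-01, 2.445134137142996e+00,
         3.754408661907416e+00)
  p_low <- 0.02425
  if (p < p_low) {
    q <- sqrt(-2 * log(p))
    (((((cc[1] * q + cc[2]) * q + cc[3]) * q + cc[4]) * q + cc[5]) * q + cc[6]) /
      ((((d[1] * q + d[2]) * q + d[3]) * q + d[4]) * q + 1)
  } else if (p <= 1 - p_low) {
    q <- p - 0.5
    r <- q * q
    (((((a[1] * r + a[2]) * r + a[3]) * r + a[4]) * r + a[5]) * r + a[6]) * q /
      (((((b[1] * r + b[2]) * r + b[3]) * r + b[4]) * r + b[5]) * r + 1)
  } else {
    -oracle_inv_norm(1 - p)
  }
}

# 10 equispaced planted clusters on a 1e7 bp chromosome
make_clusters <- function(multiplier, len) {
  starts <- as.integer(seq(5e5, 9.5e6, length.out = 10))
  tibble::tibble(chrom = "chr1", start = starts, end = starts + as.integer(len),
                 multiplier = multiplier)
}

# overlap-based sensitivity/precision of called hotspots vs planted clusters
recovery_scores <- function(hotspots, clusters) {
  if (nrow(hotspots) == 0) {
    return(c(found = 0, n_clusters = nrow(clusters), true_calls = 0, n_calls = 0))
  }
  hit_cl <- vapply(seq_len(nrow(clusters)), function(i) {
    any(hotspots$chrom == clusters$chrom[i] &
        hotspots$start <= clusters$end[i] & hotspots$end >= clusters$start[i])
  }, logical(1))
  hit_hs <- vapply(seq_len(nrow(hotspots)), function(i) {
    any(clusters$chrom == hotspots$chrom[i] &
        clusters$start <= hotspots$end[i] & clusters$end >= hotspots$start[i])
  }, logical(1))
  c(found = sum(hit_cl), n_clusters = nrow(clusters),
    true_calls = sum(hit_hs), n_calls = nrow(hotspots))
}

# standard single-cell null world used by several tests
sim_null_panel <- function(n_positions, seed, ...) {
  simulate_base_count_matrix(n_positions, n_test = 3, n_ref = 2,
                             mean_depth = 4000, error_mean = 0.005,
                             seed = seed, ...)
}
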
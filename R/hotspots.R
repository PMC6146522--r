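#' Inter-SNV distances within chromosomes
#'
#' Distances between consecutive SNV positions, computed within each
#' chromosome only — never across a chromosome boundary — and kept in genomic
#' order, the order the run-length segmentation consumes. With `s` sites
#' spread over `k` chromosomes that each carry at least one site, there are
#' exactly `s - k` distances.
#'
#' @param positions Tibble with columns `chrom`, `pos`; rows with further
#'   columns (e.g. a selection table filtered to `selected`) are accepted.
#' @return A tibble with columns `chrom`, `start_pos`, `end_pos`, `distance`
#'   (bp, `end_pos - start_pos`), one row per adjacent pair.
#' @export
inter_snv_distances <- function(positions) {
  positions <- dplyr::arrange(
    dplyr::distinct(positions[c("chrom", "pos")]), .data$chrom, .data$pos
  )
  if (nrow(positions) < 2) {
    pg_inform("Fewer than 2 sites; no inter-SNV distances.")
  }
  out <- dplyr::reframe(
    dplyr::group_by(positions, .data$chrom),
    start_pos = head(.data$pos, -1L),
    end_pos = .data$pos[-1L]
  )
  dplyr::mutate(out, distance = .data$end_pos - .data$start_pos)
}

#' Fit the exponential inter-SNV distance model
#'
#' Under a Poisson scatter of mutations, the distance `x` between adjacent
#' SNVs is exponential, and the probability of seeing a distance at most `x`
#' is `P(x) = 1 - exp(-lambda * x)` with `lambda = 1 / mean(x)`. The mean is
#' taken over all adjacent-pair distances genome-wide (not per chromosome).
#' A small `P(x)` marks a distance far shorter than expected — the raw signal
#' of mutation clustering.
#'
#' @param distances Tibble from [inter_snv_distances()].
#' @return An object of class `"distance_model"`: the distance table with a
#'   `p_exp` column, plus `xbar`, `lambda` and the genome-wide totals used for
#'   hotspot significance. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
fit_distance_model <- function(distances) {
  stopifnot(all(c("chrom", "start_pos", "end_pos", "distance") %in% names(distances)))
  if (nrow(distances) == 0) abort("No distances to fit.")
  if (all(distances$distance == 0)) {
    abort("All distances are zero; duplicated positions upstream?")
  }
  xbar <- mean(distances$distance)
  lambda <- 1 / xbar
  d <- dplyr::mutate(tibble::as_tibble(distances),
                     p_exp = -expm1(-lambda * .data$distance))
  structure(
    list(distances = d, xbar = xbar, lambda = lambda, n_distances = nrow(d)),
    class = "distance_model"
  )
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf(
    "Exponential inter-SNV distance model\n  distances: %d\n  mean distance: %.1f bp\n  lambda: %.4g per bp\n",
    x$n_distances, x$xbar, x$lambda
  ))
  invisible(x)
}

#' @rdname fit_distance_model
#' @param x A `distance_model`.
#' @param ... Unused.
#' @method tidy distance_model
#' @export
tidy.distance_model <- function(x, ...) x$distances

#' @rdname fit_distance_model
#' @method glance distance_model
#' @export
glance.distance_model <- function(x, ...) {
  tibble::tibble(n_distances = x$n_distances, xbar = x$xbar, lambda = x$lambda)
}

#' Upper tail of the hypergeometric distribution for hotspot significance
#'
#' Significance of a candidate hotspot that contains `m` significant and `n`
#' non-significant adjacent-pair distances, drawn from a genome with `a`
#' distances of which `b` are significant: the probability that a random draw
#' of `n + m` distances contains at least `m` significant ones,
#' \deqn{P(X \ge m) = \sum_{i=m}^{n+m} \binom{b}{i}\binom{a-b}{n+m-i} /
#'   \binom{a}{n+m}.}
#' Computed by direct log-space summation of the upper tail (log-gamma
#' binomial coefficients), which stays accurate for very small tails.
#'
#' @param a Total number of adjacent-pair distances genome-wide.
#' @param b Number of those distances that are significant.
#' @param n Non-significant distances inside the hotspot.
#' @param m Significant distances inside the hotspot (at least 1).
#' @return The tail probability, in `[0, 1]`.
#' @examples
#' hypergeometric_tail(30774, 4003, 1, 5) # about 1.988e-4
#' @export
hypergeometric_tail <- function(a, b, n, m) {
  for (v in c("a", "b", "n", "m")) assert_scalar_number(get(v), v, lower = 0)
  if (b > a || m < 1 || n + m > a || any(c(a, b, n, m) != floor(c(a, b, n, m)))) {
    abort("Need integers with 0 <= b <= a, n >= 0, m >= 1, n + m <= a.")
  }
  draw <- n + m
  if (min(b, draw) < m) return(0)
  i <- seq(m, min(b, draw))
  i <- i[draw - i <= a - b]
  if (length(i) == 0) return(0)
  lt <- lchoose(b, i) + lchoose(a - b, draw - i) - lchoose(a, draw)
  min(1, exp(logsumexp(lt)))
}

# significant blocks in a logical flag sequence, grown greedily left to
# right: a candidate block starts at a TRUE run and absorbs following
# (gap run, TRUE run) pairs while the total gap count stays <= max_gap, so it
# begins and ends with significant distances and is maximal. A block with
# >= min_m significant distances is emitted and the scan resumes after it
# (emitted blocks never overlap); a failing block only advances the scan to
# its second TRUE run, so a valid window starting inside it is still found.
# Returns start/end indices into the flag vector.
find_blocks <- function(flags, max_gap, min_m) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out_s <- integer(0); out_e <- integer(0)
  k <- if (length(r$values) && !r$values[1]) 2L else 1L
  n_runs <- length(r$lengths)
  while (k <= n_runs) {
    gaps_used <- 0L
    j <- k
    m_count <- r$lengths[k]
    while (j + 2L <= n_runs &&
           gaps_used + r$lengths[j + 1L] <= max_gap) {
      gaps_used <- gaps_used + r$lengths[j + 1L]
      j <- j + 2L
      m_count <- m_count + r$lengths[j]
    }
    if (m_count >= min_m) {
      out_s <- c(out_s, starts[k]); out_e <- c(out_e, ends[j])
      k <- j + 1L
      if (k <= n_runs && !r$values[k]) k <- k + 1L
    } else {
      k <- k + 2L
    }
  }
  list(start = out_s, end = out_e)
}

#' Call mutation hotspots by run-length segmentation
#'
#' Flags each inter-SNV distance as significant when its exponential-model
#' `p_exp` is below `alpha_distance`, then, per chromosome, segments the flag
#' sequence into maximal blocks that begin and end with significant distances
#' and contain at most `max_gap_n` non-significant ones. Blocks with at least
#' `min_m` significant distances whose genomic span does not exceed
#' `max_length` are reported as hotspots, each with the hypergeometric tail
#' probability of its `(m, n)` composition given the genome-wide totals.
#'
#' Blocks are grown greedily left to right, so reported hotspots never
#' overlap; a trailing or leading gap is never included (it would extend the
#' span without evidence).
#'
#' @param model A fitted [fit_distance_model()].
#' @param min_m Minimum significant distances per hotspot.
#' @param max_gap_n Maximum non-significant distances allowed inside.
#' @param max_length Maximum hotspot span in bp (first to last member SNV).
#' @param alpha_distance Significance cutoff on `p_exp`; equivalently,
#'   distances shorter than `-xbar * log(1 - alpha_distance)` are significant.
#' @return A tibble of hotspots: `chrom`, `start`, `end` (positions of the
#'   first and last member SNV, 1-based), `length` (`end - start`),
#'   `site_count`, `m`, `n`, `p_value`, sorted by position.
#' @export
call_hotspots <- function(model, min_m = 5, max_gap_n = 1, max_length = 1e5,
                          alpha_distance = 0.01) {
  stopifnot(inherits(model, "distance_model"))
  d <- dplyr::mutate(model$distances, flag = .data$p_exp < alpha_distance)
  a <- nrow(d)
  b <- sum(d$flag)
  per_chrom <- purrr::map(split(d, d$chrom), function(dc) {
    bl <- find_blocks(dc$flag, max_gap_n, min_m)
    if (length(bl$start) == 0) return(NULL)
    purrr::map_dfr(seq_along(bl$start), function(i) {
      idx <- bl$start[i]:bl$end[i]
      tibble::tibble(
        chrom = dc$chrom[1],
        start = dc$start_pos[bl$start[i]],
        end = dc$end_pos[bl$end[i]],
        site_count = length(idx) + 1L,
        m = sum(dc$flag[idx]),
        n = sum(!dc$flag[idx])
      )
    })
  })
  hs <- dplyr::bind_rows(per_chrom)
  if (nrow(hs) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      length = integer(), site_count = integer(), m = integer(), n = integer(),
      p_value = numeric()
    ))
  }
  hs <- dplyr::mutate(hs, length = .data$end - .data$start)
  hs <- dplyr::filter(hs, .data$m >= min_m, .data$length <= max_length)
  if (nrow(hs) == 0) {
    return(dplyr::mutate(
      hs[c("chrom", "start", "end", "length", "site_count", "m", "n")],
      p_value = numeric(0)
    ))
  }
  hs$p_value <- mapply(function(ni, mi) hypergeometric_tail(a, b, ni, mi),
                       hs$n, hs$m)
  dplyr::arrange(
    hs[c("chrom", "start", "end", "length", "site_count", "m", "n", "p_value")],
    .data$chrom, .data$start
  )
}
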
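#' Simulate SNV positions as a Poisson process with planted clusters
#'
#' Positions fall as a homogeneous Poisson process at `background_rate` per bp
#' along each chromosome, except inside planted cluster intervals where the
#' rate is multiplied. This is exactly the null model the hotspot caller
#' assumes: outside clusters, inter-SNV distances are (asymptotically)
#' exponential with mean `1 / background_rate`.
#'
#' @param genome Named numeric vector of chromosome lengths in bp.
#' @param background_rate Expected SNVs per bp outside clusters.
#' @param clusters `NULL`, or a data frame with columns `chrom`, `start`,
#'   `end`, `multiplier` (rate multiplier >= 1) describing planted high-rate
#'   intervals; overlapping intervals on one chromosome are an error.
#' @param seed Optional integer seed; the same seed gives identical output.
#' @return A tibble with columns `chrom`, `pos` (sorted, deduplicated) and a
#'   `"truth"` attribute recording the planted clusters and rates, retrievable
#'   with [sim_truth()].
#' @examples
#' pos <- simulate_snv_positions(c(chr1 = 1e6), 1e-4, seed = 1)
#' nrow(pos)
#' @export
simulate_snv_positions <- function(genome, background_rate, clusters = NULL,
                                   seed = NULL) {
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    abort("`genome` must be a named vector of chromosome lengths.")
  }
  assert_scalar_number(background_rate, "background_rate", lower = .Machine$double.xmin)
  if (!is.null(clusters)) {
    clusters <- tibble::as_tibble(clusters)
    stopifnot(all(c("chrom", "start", "end", "multiplier") %in% names(clusters)))
    if (any(clusters$multiplier < 1)) abort("Cluster rate multipliers must be >= 1.")
    if (any(clusters$start < 1) || any(clusters$end > genome[clusters$chrom]) ||
        any(clusters$start >= clusters$end)) {
      abort("Planted clusters must lie within the genome with start < end.")
    }
    for (cn in unique(clusters$chrom)) {
      d <- dplyr::arrange(clusters[clusters$chrom == cn, ], .data$start)
      if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])) {
        abort(sprintf("Planted clusters overlap on %s.", cn))
      }
    }
  }
  positions <- with_sim_seed(seed, {
    purrr::map(names(genome), function(cn) {
      len <- genome[[cn]]
      n_bg <- rpois(1, background_rate * len)
      pos <- ceiling(runif(n_bg, 0, len))
      if (!is.null(clusters)) {
        cl <- clusters[clusters$chrom == cn, ]
        for (j in seq_len(nrow(cl))) {
          span <- cl$end[j] - cl$start[j] + 1
          extra_rate <- background_rate * (cl$multiplier[j] - 1)
          n_extra <- rpois(1, extra_rate * span)
          pos <- c(pos, cl$start[j] + ceiling(runif(n_extra, 0, span)) - 1L)
        }
      }
      tibble::tibble(chrom = cn, pos = sort(unique(as.integer(pos))))
    })
  })
  out <- dplyr::bind_rows(positions)
  attr(out, "truth") <- list(
    clusters = clusters,
    background_rate = background_rate,
    genome = genome
  )
  out
}

#' Retrieve the ground truth attached to a simulated object
#' @param x An object returned by one of the `simulate_*()` generators.
#' @return The `"truth"` attribute: a list describing what was planted.
#' @export
sim_truth <- function(x) attr(x, "truth")

# depth law shared by the generators: over-dispersed integer depths with
# floor 1 (every retained site/position has at least one read). Infinite
# dispersion means constant depth.
draw_depth <- function(n, mean_depth, dispersion) {
  if (is.infinite(dispersion)) return(rep(as.integer(mean_depth), n))
  pmax(1L, rnbinom(n, mu = mean_depth, size = dispersion))
}

#' Simulate paired parental/derived read counts at SNV sites
#'
#' Emulates the bulk comparison between a parental population and a
#' phenotype-enriched derivative: each site carries a variant at
#' `base_vaf` in both samples, except `shifted_sites`, whose allele
#' frequency rises to `shifted_vaf` in the derived sample (the signature of a
#' genetically encoded, expanding subpopulation). Alternate read counts are
#' binomial in the sample's VAF at the drawn depth.
#'
#' @param positions Tibble with columns `chrom`, `pos` (e.g. from
#'   [simulate_snv_positions()]).
#' @param mean_depth,depth_dispersion Depth law: negative binomial with this
#'   mean and size, floored at 1; `depth_dispersion = Inf` gives constant
#'   depth.
#' @param base_vaf Variant allele frequency shared by both samples at
#'   unshifted sites.
#' @param shifted_sites Integer vector of row indices of `positions` whose VAF
#'   is `shifted_vaf` in the derived sample.
#' @param shifted_vaf VAF of shifted sites in the derived sample; must exceed
#'   `base_vaf`.
#' @param samples Length-2 character vector `(parental, derived)`.
#' @param seed Optional integer seed.
#' @return A long variant tibble (as from [read_variant_table()]) with a
#'   `"truth"` attribute listing the shifted sites.
#' @export
simulate_paired_counts <- function(positions, mean_depth = 100,
                                   depth_dispersion = 10, base_vaf = 0.1,
                                   shifted_sites = integer(), shifted_vaf = 0.5,
                                   samples = c("2D", "SP4"), seed = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(positions)), length(samples) == 2)
  assert_scalar_number(base_vaf, "base_vaf", lower = 1e-12, upper = 1)
  assert_scalar_number(shifted_vaf, "shifted_vaf", lower = 0, upper = 1)
  if (length(shifted_sites) > 0 && shifted_vaf < base_vaf) {
    abort("`shifted_vaf` must be >= `base_vaf`.")
  }
  n <- nrow(positions)
  shifted <- logical(n); shifted[shifted_sites] <- TRUE
  out <- with_sim_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    per_sample <- purrr::map(seq_along(samples), function(k) {
      vaf <- rep(base_vaf, n)
      if (k == 2) vaf[shifted] <- shifted_vaf
      depth <- draw_depth(n, mean_depth, depth_dispersion)
      alt_count <- rbinom(n, depth, vaf)
      tibble::tibble(
        chrom = positions$chrom, pos = positions$pos, ref = ref, alt = alt,
        sample = samples[k],
        ref_count = depth - alt_count, alt_count = alt_count
      )
    })
    dplyr::bind_rows(per_sample)
  })
  out <- dplyr::arrange(out, .data$chrom, .data$pos, match(.data$sample, samples))
  attr(out, "sample_ids") <- samples
  attr(out, "truth") <- list(
    shifted_sites = positions[shifted, , drop = FALSE],
    base_vaf = base_vaf, shifted_vaf = shifted_vaf,
    parental = samples[1], derived = samples[2]
  )
  out
}

#' Simulate a single-cell nucleotide count matrix
#'
#' Emulates deep amplicon sequencing of a small single-cell panel: at every
#' position one major allele dominates and the three other bases receive reads
#' only through sequencing error, at a position-specific rate drawn once from
#' a low-mean Beta law and shared by all samples (error is a property of the
#' position, not the cell). Optionally, true variants are planted in chosen
#' samples at a stated allele fraction, the signal the concordance framework
#' is meant to detect.
#'
#' @param n_positions Number of panel positions.
#' @param n_test,n_ref Test-group (e.g. sphere-forming cells) and
#'   reference-group sizes; samples are labelled `B1..B<n_test>` and
#'   `N1..N<n_ref>`.
#' @param mean_depth,depth_dispersion Depth law as in
#'   [simulate_paired_counts()]; deep coverage (default mean 4000) is the
#'   regime the binomial error test assumes.
#' @param error_mean Mean per-position error probability; per-position rates
#'   are Beta with this mean and shape `error_shape` (0 disables error).
#' @param error_shape First Beta shape parameter; larger means tighter spread.
#' @param planted_variants `NULL` or a data frame with columns `pos`, `sample`,
#'   `fraction`: true second alleles at the stated allele fraction.
#' @param dropout Probability that a planted variant is lost in a given sample
#'   (whole-genome-amplification allele dropout); defaults to 0 since no
#'   measured rate is available to anchor it.
#' @param seed Optional integer seed.
#' @return A base-count tibble (columns `chrom`, `pos`, `sample`, `A`, `C`,
#'   `G`, `T`) with a `"truth"` attribute holding per-position error rates,
#'   planted variants and group labels.
#' @export
simulate_base_count_matrix <- function(n_positions, n_test = 3, n_ref = 2,
                                       mean_depth = 4000, depth_dispersion = 10,
                                       error_mean = 0.005, error_shape = 5,
                                       planted_variants = NULL, dropout = 0,
                                       seed = NULL) {
  assert_scalar_number(n_positions, "n_positions", lower = 1)
  assert_scalar_number(error_mean, "error_mean", lower = 0, upper = 0.5)
  assert_scalar_number(dropout, "dropout", lower = 0, upper = 1)
  test_ids <- paste0("B", seq_len(n_test))
  ref_ids <- paste0("N", seq_len(n_ref))
  samples <- c(test_ids, ref_ids)
  bases <- c("A", "C", "G", "T")
  if (!is.null(planted_variants)) {
    planted_variants <- tibble::as_tibble(planted_variants)
    stopifnot(all(c("pos", "sample", "fraction") %in% names(planted_variants)))
    if (any(planted_variants$fraction <= 0 | planted_variants$fraction > 1)) {
      abort("Planted allele fractions must be in (0, 1].")
    }
    if (error_mean > 0 && any(planted_variants$fraction <= error_mean)) {
      abort("Planted allele fractions must exceed the mean error probability.")
    }
  }
  out <- with_sim_seed(seed, {
    err <- if (error_mean == 0) rep(0, n_positions) else {
      rbeta(n_positions, error_shape, error_shape * (1 - error_mean) / error_mean)
    }
    major <- sample(bases, n_positions, replace = TRUE)
    alt_base <- vapply(major, function(b) sample(setdiff(bases, b), 1), character(1))
    kept_plants <- NULL
    per_sample <- purrr::map(samples, function(s) {
      depth <- draw_depth(n_positions, mean_depth, depth_dispersion)
      frac <- rep(0, n_positions)
      if (!is.null(planted_variants)) {
        pv <- planted_variants[planted_variants$sample == s, ]
        if (nrow(pv) > 0 && dropout > 0) {
          pv <- pv[runif(nrow(pv)) >= dropout, , drop = FALSE]
        }
        frac[pv$pos] <- pv$fraction
        kept_plants <<- dplyr::bind_rows(kept_plants, pv)
      }
      # multinomial draw by binomial splitting: variant allele, then total
      # error reads among the remainder, then error reads over 3 bases
      alt_n <- rbinom(n_positions, depth, frac)
      rest <- depth - alt_n
      p_err <- ifelse(frac < 1, pmin(1, err / (1 - frac)), 0)
      bg <- rbinom(n_positions, rest, p_err)
      e1 <- rbinom(n_positions, bg, 1 / 3)
      e2 <- rbinom(n_positions, bg - e1, 1 / 2)
      e3 <- bg - e1 - e2
      counts <- matrix(0L, n_positions, 4, dimnames = list(NULL, bases))
      idx <- cbind(seq_len(n_positions), match(major, bases))
      counts[idx] <- rest - bg
      err_bases <- t(vapply(seq_len(n_positions), function(i) {
        setdiff(bases, major[i])
      }, character(3)))
      counts[cbind(seq_len(n_positions), match(err_bases[, 1], bases))] <-
        counts[cbind(seq_len(n_positions), match(err_bases[, 1], bases))] + e1
      counts[cbind(seq_len(n_positions), match(err_bases[, 2], bases))] <-
        counts[cbind(seq_len(n_positions), match(err_bases[, 2], bases))] + e2
      counts[cbind(seq_len(n_positions), match(err_bases[, 3], bases))] <-
        counts[cbind(seq_len(n_positions), match(err_bases[, 3], bases))] + e3
      counts[cbind(seq_len(n_positions), match(alt_base, bases))] <-
        counts[cbind(seq_len(n_positions), match(alt_base, bases))] + alt_n
      tibble::tibble(
        chrom = "panel", pos = seq_len(n_positions), sample = s,
        A = counts[, "A"], C = counts[, "C"], G = counts[, "G"], T = counts[, "T"]
      )
    })
    list(tbl = dplyr::bind_rows(per_sample), err = err, major = major,
         alt_base = alt_base, kept_plants = kept_plants)
  })
  tbl <- dplyr::arrange(out$tbl, .data$chrom, .data$pos, match(.data$sample, samples))
  attr(tbl, "truth") <- list(
    per_position_error = out$err,
    major_base = out$major,
    alt_base = out$alt_base,
    planted_variants = out$kept_plants,
    test_samples = test_ids,
    reference_samples = ref_ids
  )
  tbl
}
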
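#' Filter variant sites by region mask and depth
#'
#' Applies the standard site filters before any inference: sites on excluded
#' chromosomes (mitochondrial genome, Y, unplaced contigs) or inside mask
#' intervals (segmental duplications, repeats) are removed, then sites whose
#' sequencing depth falls outside `[depth_min, depth_max]` are removed. Depth
#' is `ref_count + alt_count` per sample, and a site is dropped when *any*
#' sample is out of range (the stricter of the two possible readings; pooled
#' depth is not used).
#'
#' @param variants Long variant tibble from [read_variant_table()] or
#'   [simulate_paired_counts()].
#' @param mask Optional mask from [read_region_mask()].
#' @param depth_min,depth_max Per-sample depth range kept, inclusive.
#' @return The filtered tibble, with attribute `"filter_counts"`: named vector
#'   of sites removed by each filter. Filtering is idempotent.
#' @export
apply_site_filters <- function(variants, mask = NULL, depth_min = 10,
                               depth_max = 200) {
  samples <- attr(variants, "sample_ids") %||% unique(variants$sample)
  sites <- dplyr::distinct(variants, .data$chrom, .data$pos)
  n0 <- nrow(sites)
  masked <- if (is.null(mask)) rep(FALSE, n0) else in_mask(mask, sites$chrom, sites$pos)
  n_masked <- sum(masked)
  sites <- sites[!masked, , drop = FALSE]
  kept1 <- dplyr::semi_join(variants, sites, by = c("chrom", "pos"))

  depth_ok <- dplyr::summarise(
    dplyr::group_by(kept1, .data$chrom, .data$pos),
    ok = all(.data$ref_count + .data$alt_count >= depth_min &
             .data$ref_count + .data$alt_count <= depth_max),
    .groups = "drop"
  )
  n_depth <- sum(!depth_ok$ok)
  out <- dplyr::semi_join(kept1, dplyr::filter(depth_ok, .data$ok),
                          by = c("chrom", "pos"))
  if (n_masked + n_depth > 0) {
    pg_inform("Removed %d/%d sites (%d masked/excluded, %d out of depth range [%d, %d]).",
              n_masked + n_depth, n0, n_masked, n_depth, depth_min, depth_max)
  }
  attr(out, "sample_ids") <- samples
  attr(out, "filter_counts") <- c(mask = n_masked, depth = n_depth)
  out
}

#' Two-sided Fisher's exact test on paired allele counts
#'
#' Vectorised two-sided exact test on the 2x2 table
#' `[[ref_a, alt_a], [ref_b, alt_b]]`, the test used to ask whether the
#' allele frequency at a site differs between two samples. Wraps
#' [stats::fisher.test()]; duplicate tables are evaluated once.
#'
#' @param ref_a,alt_a,ref_b,alt_b Equal-length non-negative integer vectors.
#' @return Vector of two-sided p-values; `NA` where a sample has zero depth
#'   (`ref + alt = 0`), in which case no VAF is defined and the site is
#'   unevaluable.
#' @export
fisher_vaf_test <- function(ref_a, alt_a, ref_b, alt_b) {
  n <- length(ref_a)
  stopifnot(length(alt_a) == n, length(ref_b) == n, length(alt_b) == n)
  key <- paste(ref_a, alt_a, ref_b, alt_b)
  ok <- (ref_a + alt_a) > 0 & (ref_b + alt_b) > 0
  p <- rep(NA_real_, n)
  uk <- unique(key[ok])
  if (length(uk) == 0) return(p)
  up <- vapply(uk, function(k) {
    v <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
    fisher.test(matrix(v, nrow = 2, byrow = TRUE))$p.value
  }, numeric(1))
  p[ok] <- up[match(key[ok], uk)]
  p
}

#' Select sites with significantly increased allele frequency
#'
#' The two-condition rule for nominating phenotype-associated sites: a site is
#' selected when the two-sided Fisher p-value on its ref/alt counts is below
#' `alpha` *and* the VAF in the parental sample is strictly below the VAF in
#' the derived sample. Sites where either sample has zero depth are
#' unevaluable and never selected.
#'
#' @param variants Long variant tibble carrying both samples.
#' @param parental,derived Sample labels (parental is expected to carry the
#'   lower VAF under the hypothesis of subpopulation expansion).
#' @param alpha Selection threshold on the raw p-value (no multiple-testing
#'   correction at this stage; hotspot-level significance comes later).
#' @return One row per site: counts and VAF per sample, `fisher_p`,
#'   `direction_ok` and `selected`.
#' @export
select_increased_sites <- function(variants, parental = "2D", derived = "SP4",
                                   alpha = 0.1) {
  have <- unique(variants$sample)
  if (!all(c(parental, derived) %in% have)) {
    abort(sprintf("Samples `%s` and `%s` must both be present.", parental, derived))
  }
  wide <- tidyr::pivot_wider(
    dplyr::filter(variants, .data$sample %in% c(parental, derived)),
    id_cols = c("chrom", "pos", "ref", "alt"),
    names_from = "sample", values_from = c("ref_count", "alt_count")
  )
  ra <- wide[[paste0("ref_count_", parental)]]
  aa <- wide[[paste0("alt_count_", parental)]]
  rb <- wide[[paste0("ref_count_", derived)]]
  ab <- wide[[paste0("alt_count_", derived)]]
  vaf_a <- ifelse(ra + aa > 0, aa / (ra + aa), NA_real_)
  vaf_b <- ifelse(rb + ab > 0, ab / (rb + ab), NA_real_)
  p <- fisher_vaf_test(ra, aa, rb, ab)
  n_bad <- sum(is.na(p))
  if (n_bad > 0) {
    pg_inform("%d site(s) unevaluable (zero depth in a sample); not selected.", n_bad)
  }
  direction <- !is.na(vaf_a) & !is.na(vaf_b) & vaf_a < vaf_b
  tibble::tibble(
    chrom = wide$chrom, pos = wide$pos, ref = wide$ref, alt = wide$alt,
    ref_parental = ra, alt_parental = aa, ref_derived = rb, alt_derived = ab,
    vaf_parental = vaf_a, vaf_derived = vaf_b,
    fisher_p = p,
    direction_ok = direction,
    selected = !is.na(p) & p < alpha & direction
  )
}
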
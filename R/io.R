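#' Read a multi-sample variant table
#'
#' Reads per-site reference/alternate read counts for several samples, either
#' from a tab-separated table or from a VCF with per-sample allele depths
#' (`AD`). The result is a long ("tidy") tibble with one row per site and
#' sample, the shape every downstream verb in the package consumes.
#'
#' The TSV layout is wide on disk: columns `chrom`, `pos`, `ref`, `alt`, then a
#' `<sample>_ref_count` / `<sample>_alt_count` pair per sample. Coordinates are
#' 1-based (VCF convention) both on disk and in memory.
#'
#' @param path Path to a TSV or VCF file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `sample`,
#'   `ref_count`, `alt_count`, sorted by `(chrom, pos)`, with the sample labels
#'   in attribute `"sample_ids"`. Duplicated `(chrom, pos)` sites are an error;
#'   unsorted input is sorted with a message.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "chrom\tpos\tref\talt\t2D_ref_count\t2D_alt_count\tSP4_ref_count\tSP4_alt_count",
#'   "chr1\t100\tA\tG\t90\t10\t50\t50"
#' ), tf)
#' read_variant_table(tf)
#' @export
read_variant_table <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  long <- switch(format,
    tsv = read_variant_tsv(path),
    vcf = read_variant_vcf(path)
  )
  validate_variant_table(long)
}

read_variant_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(wide))
  if (length(missing) > 0) {
    abort(sprintf("Variant TSV is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  count_cols <- grep("_(ref|alt)_count$", names(wide), value = TRUE)
  samples <- unique(sub("_(ref|alt)_count$", "", count_cols))
  if (nrow(wide) > 0 && length(samples) == 0) {
    abort("Variant TSV has no `<sample>_ref_count`/`<sample>_alt_count` columns.")
  }
  for (s in samples) {
    for (suffix in c("_ref_count", "_alt_count")) {
      cl <- paste0(s, suffix)
      if (!cl %in% names(wide)) {
        abort(sprintf("Sample `%s` is missing its `%s` column.", s, cl))
      }
      if (any(is.na(wide[[cl]]))) {
        abort(sprintf("Sample `%s` has missing counts (column `%s`).", s, cl))
      }
    }
  }
  if (nrow(wide) == 0) {
    out <- tibble::tibble(
      chrom = character(), pos = integer(), ref = character(), alt = character(),
      sample = character(), ref_count = integer(), alt_count = integer()
    )
    attr(out, "sample_ids") <- samples
    return(out)
  }
  long <- tidyr::pivot_longer(
    wide,
    cols = dplyr::all_of(count_cols),
    names_to = c("sample", ".value"),
    names_pattern = "^(.*)_(ref_count|alt_count)$"
  )
  long <- dplyr::select(
    long, "chrom", "pos", "ref", "alt", "sample", "ref_count", "alt_count"
  )
  attr(long, "sample_ids") <- samples
  long
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("Reading VCF requires the VariantAnnotation package.")
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) abort("VCF has no per-sample AD (allele depth) field.")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  samples <- colnames(vcf)
  rows <- purrr::map(seq_len(nrow(vcf)), function(i) {
    alts <- as.character(alt_list[[i]])
    purrr::map(samples, function(s) {
      depths <- ad[i, s][[1]]
      if (length(depths) < 2 || any(is.na(depths))) {
        abort(sprintf("Missing AD counts for sample `%s` at record %d.", s, i))
      }
      tibble::tibble(
        chrom = as.character(GenomicRanges::seqnames(rr)[i]),
        pos = GenomicRanges::start(rr)[i],
        ref = as.character(VariantAnnotation::ref(vcf)[i]),
        alt = alts[1],
        sample = s,
        ref_count = as.integer(depths[1]),
        alt_count = as.integer(depths[2])
      )
    })
  })
  long <- dplyr::bind_rows(purrr::flatten(rows))
  attr(long, "sample_ids") <- samples
  long
}

validate_variant_table <- function(long) {
  samples <- attr(long, "sample_ids") %||% unique(long$sample)
  if (nrow(long) == 0) return(long)
  assert_count_columns(long, c("ref_count", "alt_count"), "variant table")
  sites <- dplyr::distinct(long, .data$chrom, .data$pos)
  per_site <- dplyr::count(long, .data$chrom, .data$pos)
  if (any(per_site$n != length(samples))) {
    bad <- per_site[per_site$n != length(samples), ][1, ]
    abort(sprintf(
      "Site %s:%d does not have counts for every sample.", bad$chrom, bad$pos
    ))
  }
  dup <- dplyr::count(long, .data$chrom, .data$pos, .data$sample)
  if (any(dup$n > 1)) {
    bad <- dup[dup$n > 1, ][1, ]
    abort(sprintf("Duplicated site %s:%d in input.", bad$chrom, bad$pos))
  }
  ord <- order(long$chrom, long$pos, match(long$sample, samples))
  if (is.unsorted(order(sites$chrom, sites$pos)) || !identical(ord, seq_len(nrow(long)))) {
    if (!identical(order(sites$chrom, sites$pos), seq_len(nrow(sites)))) {
      pg_inform("Input sites were not sorted by (chrom, pos); sorting.")
    }
    long <- long[ord, ]
  }
  attr(long, "sample_ids") <- samples
  long
}

#' Write a variant table to TSV
#'
#' Inverse of [read_variant_table()] for the TSV layout (wide on disk).
#'
#' @param x Long variant tibble as returned by [read_variant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  wide <- tidyr::pivot_wider(
    x,
    id_cols = c("chrom", "pos", "ref", "alt"),
    names_from = "sample",
    values_from = c("ref_count", "alt_count"),
    names_glue = "{sample}_{.value}"
  )
  samples <- unique(x$sample)
  ord <- c("chrom", "pos", "ref", "alt",
           as.vector(rbind(paste0(samples, "_ref_count"), paste0(samples, "_alt_count"))))
  readr::write_tsv(wide[, ord], path, progress = FALSE)
  invisible(path)
}

#' Read an exclusion mask from a BED file
#'
#' Builds the region mask used by [apply_site_filters()]: genomic intervals to
#' exclude (segmental duplications, repeats, ...) plus whole chromosomes to
#' drop (mitochondrial genome, Y, unplaced contigs).
#'
#' BED input is 0-based half-open; intervals are stored 1-based inclusive to
#' match variant coordinates, so BED line `chr1 99 200` masks positions
#' 100..200.
#'
#' @param path Path to a BED3+ file, or `NULL` for a mask with no intervals.
#' @param excluded_chromosomes Character vector of chromosome names removed
#'   wholesale.
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive)
#'   and attribute `"excluded_chromosomes"`, of class `"region_mask"`.
#' @export
read_region_mask <- function(path = NULL, excluded_chromosomes = character()) {
  if (is.null(path)) {
    iv <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  } else {
    if (!file.exists(path)) abort(sprintf("File not found: %s", path))
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    iv <- purrr::imap(lines, function(ln, i) {
      if (!keep[i]) return(NULL)
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) abort(sprintf("Malformed BED line %d: fewer than 3 fields.", i))
      s0 <- suppressWarnings(as.numeric(f[2])); e0 <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s0) || is.na(e0) || s0 < 0 || e0 <= s0 || s0 != floor(s0) || e0 != floor(e0)) {
        abort(sprintf("Malformed BED line %d: bad interval [%s, %s).", i, f[2], f[3]))
      }
      tibble::tibble(chrom = f[1], start = as.integer(s0) + 1L, end = as.integer(e0))
    })
    iv <- dplyr::bind_rows(iv)
  }
  iv <- dplyr::arrange(iv, .data$chrom, .data$start, .data$end)
  attr(iv, "excluded_chromosomes") <- unique(as.character(excluded_chromosomes))
  class(iv) <- c("region_mask", class(iv))
  iv
}

#' Test positions for mask membership
#'
#' Vectorised membership query: a position is masked when its chromosome is
#' excluded or it falls inside any interval (1-based inclusive). Overlapping
#' intervals are merged internally, which cannot change membership.
#'
#' @param mask A mask from [read_region_mask()].
#' @param chrom,pos Equal-length vectors of chromosome names and 1-based
#'   positions.
#' @return Logical vector.
#' @export
in_mask <- function(mask, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  excluded <- attr(mask, "excluded_chromosomes") %||% character()
  hit <- chrom %in% excluded
  if (nrow(mask) > 0) {
    by_chrom <- split(mask[c("start", "end")], mask$chrom)
    merged <- purrr::map(by_chrom, function(d) {
      d <- d[order(d$start, d$end), ]
      starts <- integer(0); ends <- integer(0)
      for (j in seq_len(nrow(d))) {
        if (length(ends) > 0 && d$start[j] <= ends[length(ends)] + 1L) {
          ends[length(ends)] <- max(ends[length(ends)], d$end[j])
        } else {
          starts <- c(starts, d$start[j]); ends <- c(ends, d$end[j])
        }
      }
      list(starts = starts, ends = ends)
    })
    for (cn in names(merged)) {
      sel <- which(chrom == cn & !hit)
      if (length(sel) == 0) next
      iv <- merged[[cn]]
      idx <- findInterval(pos[sel], iv$starts)
      inside <- idx > 0 & pos[sel] <= iv$ends[pmax(idx, 1L)]
      hit[sel] <- inside
    }
  }
  hit
}

#' Read a per-position nucleotide count matrix
#'
#' Reads the positions x samples x \{A, C, G, T\} count table that the
#' single-cell concordance statistics consume. Positions not covered by every
#' sample (absent, or zero total count) are dropped, with the number dropped
#' reported via a message — only positions covered in all samples are
#' comparable across groups.
#'
#' @param path TSV with columns `chrom`, `pos`, `sample`, `A`, `C`, `G`, `T`
#'   (non-negative integer counts).
#' @return A tibble in the same long layout, restricted to fully covered
#'   positions, sorted by `(chrom, pos, sample)`.
#' @export
read_base_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("chrom", "pos", "sample", "A", "C", "G", "T")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(sprintf("Base-count TSV is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  assert_count_columns(x, c("A", "C", "G", "T"), "base-count table")
  keep_covered_positions(x)
}

# drop positions absent (or at zero depth) in any sample
keep_covered_positions <- function(x) {
  if (nrow(x) == 0) return(dplyr::arrange(x, .data$chrom, .data$pos, .data$sample))
  samples <- unique(x$sample)
  cov <- dplyr::mutate(x, tc = .data$A + .data$C + .data$G + .data$T)
  by_pos <- dplyr::summarise(
    dplyr::group_by(cov, .data$chrom, .data$pos),
    covered = dplyr::n_distinct(.data$sample[.data$tc > 0]) == length(samples),
    .groups = "drop"
  )
  n_drop <- sum(!by_pos$covered)
  if (n_drop > 0) {
    pg_inform("Dropped %d position(s) not covered by all %d samples.", n_drop, length(samples))
  }
  kept <- dplyr::semi_join(
    x, dplyr::filter(by_pos, .data$covered), by = c("chrom", "pos")
  )
  dplyr::arrange(kept, .data$chrom, .data$pos, .data$sample)
}

#' Write a base-count matrix to TSV
#' @param x Tibble as returned by [read_base_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_base_counts <- function(x, path) {
  readr::write_tsv(
    dplyr::select(x, "chrom", "pos", "sample", "A", "C", "G", "T"),
    path, progress = FALSE
  )
  invisible(path)
}

#' Write called hotspots as BED and TSV
#'
#' The TSV carries every field of the hotspot table; the BED (0-based
#' half-open) carries the genomic span, so a hotspot whose member SNVs run
#' from 1-based 1001 to 1318 becomes `chrom 1000 1318`.
#'
#' @param hotspots Hotspot tibble from [call_hotspots()].
#' @param bed_path,tsv_path Output paths (`NULL` to skip one of the two).
#' @return Invisibly, a list of the paths written.
#' @export
write_hotspots <- function(hotspots, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- tibble::tibble(
      chrom = hotspots$chrom,
      start = hotspots$start - 1L,
      end = hotspots$end,
      name = sprintf("hotspot_%d", seq_len(nrow(hotspots)))
    )
    readr::write_tsv(bed, bed_path, col_names = FALSE, progress = FALSE)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(hotspots, tsv_path, progress = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}

#' Read a hotspot TSV written by [write_hotspots()]
#' @param path TSV path.
#' @return Hotspot tibble.
#' @export
read_hotspots <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
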
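#' Enumerate reference/test group assignments of a sample panel
#'
#' All unordered choices of a reference pair (more generally, a reference set
#' of the case pair's size) from the sample panel; each choice induces the
#' complementary test set. With 5 samples and a reference pair this yields
#' `choose(5, 2) = 10` schemes: the true grouping (the case) and 9
#' permutation groups used to calibrate the false-positive load.
#'
#' @param samples Character vector of distinct sample labels.
#' @param case_reference_pair The reference set of the true grouping; must be
#'   a subset of `samples`.
#' @return Tibble with one row per scheme: `scheme_id`, list-columns
#'   `reference` and `test` (sorted labels), and `is_case` (exactly one row).
#' @export
enumerate_permutations <- function(samples, case_reference_pair) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) abort("Sample labels must be distinct.")
  r <- length(case_reference_pair)
  if (!all(case_reference_pair %in% samples)) {
    abort("`case_reference_pair` must be drawn from `samples`.")
  }
  refs <- combn(sort(samples), r, simplify = FALSE)
  case_sorted <- sort(as.character(case_reference_pair))
  tibble::tibble(
    scheme_id = seq_along(refs),
    reference = refs,
    test = purrr::map(refs, ~ sort(setdiff(samples, .x))),
    is_case = purrr::map_lgl(refs, ~ identical(.x, case_sorted))
  )
}

#' Case-permutation ratio curve
#'
#' The end-to-end calibration of the binomial background test: for every
#' grouping scheme (the case and its permutations), the reference set yields
#' a position error model, the test set a per-position background p-value;
#' for every threshold `t` the number of positions with `p < t` (NP) is
#' counted, and each permutation scheme is compared with the case through
#' `CPR = NP_case / (NP_perm + NP_case)`. Under a genome with no
#' group-specific variants CPR hovers around 0.5 at every threshold; a
#' genomically encoded phenotype pushes it towards 1 at stringent thresholds.
#'
#' @param bc Base-count tibble covering all samples at every position.
#' @param case_reference_pair Reference samples of the true grouping.
#' @param thresholds Numeric grid of p-value thresholds (default 101 evenly
#'   spaced points on `[0, 0.1]`).
#' @param order,tc_ref Passed to [position_error_rate()].
#' @return An object of class `"cpr_curve"`: a tibble with one row per
#'   (threshold, scheme) holding `np` and, for permutation rows, `np_case`
#'   and `cpr` (`NA` when `NP_case + NP_perm = 0`: 0/0 is reported missing,
#'   not 0.5). The per-scheme p-values are kept in attribute `"pbc"`. Has
#'   [glance()] and [autoplot()] methods.
#' @export
cpr_curve <- function(bc, case_reference_pair,
                      thresholds = seq(0, 0.1, length.out = 101),
                      order = 0.95, tc_ref = c("mean", "sum")) {
  if (length(thresholds) == 0) abort("`thresholds` must not be empty.")
  tc_ref <- match.arg(tc_ref)
  samples <- unique(bc$sample)
  schemes <- enumerate_permutations(samples, case_reference_pair)
  pbc_by_scheme <- purrr::map(seq_len(nrow(schemes)), function(i) {
    em <- position_error_rate(bc, schemes$reference[[i]], order = order,
                              tc_ref = tc_ref)
    pbc_test(bc, schemes$test[[i]], em)
  })
  np <- purrr::map_dfr(seq_len(nrow(schemes)), function(i) {
    p <- pbc_by_scheme[[i]]$pbc
    tibble::tibble(
      threshold = thresholds,
      scheme_id = schemes$scheme_id[i],
      is_case = schemes$is_case[i],
      np = vapply(thresholds, function(t) sum(p < t), numeric(1))
    )
  })
  case_np <- np[np$is_case, c("threshold", "np")]
  names(case_np)[2] <- "np_case"
  out <- dplyr::left_join(np, case_np, by = "threshold")
  out <- dplyr::mutate(out,
    cpr = dplyr::if_else(
      .data$is_case, NA_real_,
      dplyr::if_else(.data$np + .data$np_case > 0,
                     .data$np_case / (.data$np + .data$np_case), NA_real_)
    )
  )
  attr(out, "pbc") <- stats::setNames(pbc_by_scheme, schemes$scheme_id)
  attr(out, "schemes") <- schemes
  class(out) <- c("cpr_curve", class(out))
  out
}

#' @rdname cpr_curve
#' @param x A `cpr_curve`.
#' @param ... Unused.
#' @method glance cpr_curve
#' @export
glance.cpr_curve <- function(x, ...) {
  perm <- x[!x$is_case, ]
  tibble::tibble(
    n_thresholds = length(unique(x$threshold)),
    n_permutations = length(unique(perm$scheme_id)),
    mean_cpr = mean(perm$cpr, na.rm = TRUE),
    n_defined = sum(!is.na(perm$cpr))
  )
}

#' @rdname cpr_curve
#' @method tidy cpr_curve
#' @export
tidy.cpr_curve <- function(x, ...) {
  tibble::as_tibble(x[!x$is_case, c("threshold", "scheme_id", "np", "np_case", "cpr")])
}
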
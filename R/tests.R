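het_test_row <- function(test, groups, statistic, p_value, bonferroni_n,
                         alpha, n, n_zeros_dropped = NA_integer_) {
  p_adj <- min(1, p_value * bonferroni_n)
  data.frame(
    test = test, groups = groups, n = n,
    statistic = statistic, p_value = p_value,
    p_adjusted = p_adj, bonferroni_n = bonferroni_n,
    significant = p_adj < alpha,
    n_zeros_dropped = n_zeros_dropped,
    stringsAsFactors = FALSE
  )
}

#' One-sample Wilcoxon signed-rank test of zero shift
#'
#' Two-sided test that the normalized heteroplasmy shifts are centred on
#' zero, the neutral-transmission expectation. Exactly-zero shifts are
#' dropped before ranking (classical convention); the number dropped is
#' reported. The exact null distribution is used for 25 or fewer nonzero
#' shifts, the continuity- and tie-corrected normal approximation above.
#'
#' @param shifts numeric vector of shifts.
#' @param bonferroni_n number of tests in the family; the adjusted p-value is
#'   \code{min(1, p * bonferroni_n)}.
#' @param alpha family significance level, default 0.05.
#' @param groups label recorded in the output row.
#' @return One-row data.frame: \code{test}, \code{groups}, \code{n},
#'   \code{statistic} (V), \code{p_value}, \code{p_adjusted},
#'   \code{bonferroni_n}, \code{significant}, \code{n_zeros_dropped}.
#' @export
wilcoxon_zero_shift <- function(shifts, bonferroni_n = 1, alpha = 0.05,
                                groups = NA_character_) {
  if (!length(shifts)) stop("no shifts supplied", call. = FALSE)
  nz <- shifts[shifts != 0]
  dropped <- length(shifts) - length(nz)
  if (!length(nz))
    stop("degenerate sample: all shifts are exactly zero", call. = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, alternative = "two.sided",
                       exact = length(nz) <= 25, correct = TRUE)
  )
  het_test_row("wilcoxon_zero", groups, unname(wt$statistic), wt$p.value,
               bonferroni_n, alpha, length(nz), dropped)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided KS test of whether two samples (typically shift distributions)
#' come from the same distribution. The statistic is the maximum absolute
#' difference between the empirical CDFs; the p-value uses the asymptotic
#' formula, appropriate here because integer-percent heteroplasmy induces
#' ties that invalidate the exact small-sample distribution.
#'
#' @param a,b numeric vectors, both nonempty.
#' @param bonferroni_n,alpha,groups as in \code{\link{wilcoxon_zero_shift}}.
#' @return One-row data.frame as in \code{\link{wilcoxon_zero_shift}}, with
#'   \code{statistic} = D and \code{n} the combined sample size.
#' @export
ks_two_sample <- function(a, b, bonferroni_n = 1, alpha = 0.05,
                          groups = NA_character_) {
  if (!length(a) || !length(b))
    stop("both samples must be nonempty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  het_test_row("ks_two_sample", groups, unname(kt$statistic), kt$p.value,
               bonferroni_n, alpha, length(a) + length(b))
}

# raw asymptotic two-sided KS p-value, no data.frame overhead (hot loop)
ks_p <- function(a, b) {
  suppressWarnings(stats::ks.test(a, b, exact = FALSE)$p.value)
}

#' Wilcoxon zero-shift battery over all groups
#'
#' Runs \code{\link{wilcoxon_zero_shift}} on each genotype group's shifts
#' with a Bonferroni correction for the number of groups tested
#' simultaneously (6 in the full design).
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @param bonferroni_n family size; defaults to the number of groups tested.
#' @param alpha family significance level.
#' @return data.frame, one row per group with at least two pups; groups with
#'   fewer are dropped with a warning.
#' @export
per_group_zero_battery <- function(cohort, bonferroni_n = NULL, alpha = 0.05) {
  st <- shift_table(cohort)
  groups <- sort(unique(st$group))
  sizes <- vapply(groups, function(g) sum(st$group == g), integer(1))
  small <- groups[sizes < 2]
  if (length(small)) {
    warning("group(s) with fewer than 2 pups excluded from zero-shift ",
            "battery: ", paste(small, collapse = ", "), call. = FALSE)
    groups <- setdiff(groups, small)
  }
  if (is.null(bonferroni_n)) bonferroni_n <- length(groups)
  rows <- lapply(groups, function(g)
    wilcoxon_zero_shift(st$shift[st$group == g], bonferroni_n, alpha, g))
  do.call(rbind, rows)
}

#' KS battery of one reference group against all others
#'
#' Compares the shift distribution of a reference group (by default the
#' larger control group) against every other group by two-sided KS tests,
#' Bonferroni-corrected for the number of comparisons (5 in the full design).
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @param reference_group group label to test against the rest.
#' @param alpha family significance level.
#' @return data.frame, one row per comparison, \code{groups} formatted as
#'   \code{"reference vs other"}.
#' @export
control_vs_groups_battery <- function(cohort, reference_group = "bcl2l13_wt",
                                      alpha = 0.05) {
  st <- shift_table(cohort)
  if (!reference_group %in% st$group)
    stop("reference group not present: ", reference_group, call. = FALSE)
  ref <- st$shift[st$group == reference_group]
  others <- setdiff(sort(unique(st$group)), reference_group)
  if (!length(others))
    stop("no other groups to compare against", call. = FALSE)
  rows <- lapply(others, function(g)
    ks_two_sample(ref, st$shift[st$group == g],
                  bonferroni_n = length(others), alpha = alpha,
                  groups = paste(reference_group, "vs", g)))
  do.call(rbind, rows)
}
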
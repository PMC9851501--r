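#' Enumerate all fixed-size subsets of the control mothers
#'
#' Builds every possible subsampled control dataset: each subset is exactly
#' \code{k} control mothers together with all of their pups' shifts. With the
#' full design's 10 pooled control mothers and \code{k = 6} this yields
#' \code{choose(10, 6) = 210} subsets. Order is lexicographic over sorted
#' mother ids, so enumeration is deterministic.
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @param k subset size (number of mothers).
#' @param controls labels of the control groups pooled for subsampling.
#' @param max_subsets guard against combinatorial blow-up: error if
#'   \code{choose(n, k)} exceeds this ceiling (exhaustive enumeration only,
#'   no random approximation).
#' @return List of subsets; each element is a list with \code{mother_ids}
#'   (character, sorted) and \code{shifts} (all shifts of those mothers'
#'   pups).
#' @export
enumerate_control_subsets <- function(cohort, k = 6,
                                      controls = control_groups(),
                                      max_subsets = 10000) {
  stopifnot(inherits(cohort, "het_cohort"))
  cm <- sort(cohort$mothers$mother_id[cohort$mothers$group %in% controls])
  n <- length(cm)
  if (k < 1 || k > n)
    stop("subset size k = ", k, " must be between 1 and the number of ",
         "pooled control mothers (", n, ")", call. = FALSE)
  if (choose(n, k) > max_subsets)
    stop("choose(", n, ", ", k, ") = ", choose(n, k),
         " exceeds the enumeration ceiling of ", max_subsets, call. = FALSE)
  st <- shift_table(cohort)
  by_mother <- split(st$shift, st$mother_id)
  combos <- utils::combn(cm, k, simplify = FALSE)
  lapply(combos, function(ids) {
    list(mother_ids = ids,
         shifts = unlist(by_mother[ids], use.names = FALSE))
  })
}

#' Exhaustive subsampled-control KS battery for one target group
#'
#' The robustness procedure that sidesteps the non-independence of pups
#' within litters: rather than one test against the pooled controls, the
#' target group's shift distribution is KS-tested against every enumerated
#' control subset, and the fraction of significant outcomes is reported. A
#' target group whose shifts are distributed like the controls' should be
#' significant only rarely and have a median p-value near 0.5. When the
#' target group is itself a control group its mothers are not excluded from
#' the subsets (overlap permitted).
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @param target_group group whose shifts are tested.
#' @param k subset size, see \code{\link{enumerate_control_subsets}}.
#' @param thresholds significance levels at which to count p-values; the
#'   defaults are the Bonferroni-corrected headline level 0.008 (0.05/6)
#'   plus the plain 1\% and 5\% levels.
#' @param controls control group labels pooled for subsampling.
#' @param max_subsets enumeration ceiling.
#' @return Object of class \code{subsample_battery}: list with
#'   \code{target_group}, \code{k}, \code{n_subsets}, \code{p_values} (one
#'   per subset, enumeration order), \code{subset_mothers}
#'   (semicolon-joined ids), \code{thresholds}, \code{n_below},
#'   \code{proportions_below}, \code{median_p}.
#' @export
subsample_battery <- function(cohort, target_group, k = 6,
                              thresholds = c(0.008, 0.01, 0.05),
                              controls = control_groups(),
                              max_subsets = 10000) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  st <- shift_table(cohort)
  target <- st$shift[st$group == target_group]
  if (!length(target))
    stop("target group empty or absent: ", target_group, call. = FALSE)
  subsets <- enumerate_control_subsets(cohort, k, controls, max_subsets)
  p <- vapply(subsets, function(s) ks_p(target, s$shifts), numeric(1))
  thresholds <- sort(thresholds)
  n_below <- vapply(thresholds, function(t) sum(p < t), numeric(1))
  structure(
    list(target_group = target_group, k = k, n_subsets = length(p),
         p_values = p,
         subset_mothers = vapply(subsets, function(s)
           paste(s$mother_ids, collapse = ";"), character(1)),
         thresholds = thresholds, n_below = n_below,
         proportions_below = n_below / length(p),
         median_p = stats::median(p)),
    class = "subsample_battery"
  )
}

#' @export
print.subsample_battery <- function(x, ...) {
  cat(sprintf("Subsampled-control KS battery: %s vs %d control subsets (k = %d)\n",
              x$target_group, x$n_subsets, x$k))
  for (i in seq_along(x$thresholds))
    cat(sprintf("  p < %-6s %4d / %d  (%.2f%%)\n",
                format(x$thresholds[i]), x$n_below[i], x$n_subsets,
                100 * x$proportions_below[i]))
  cat(sprintf("  median p = %.4g\n", x$median_p))
  invisible(x)
}

#' Summarize subsample batteries across groups
#'
#' @param batteries list of \code{\link{subsample_battery}} objects (or a
#'   single one).
#' @return data.frame, one row per battery: \code{target_group},
#'   \code{n_subsets}, \code{median_p}, and per threshold \code{t} the
#'   columns \code{n_below_<t>} and \code{prop_below_<t>}.
#' @export
battery_report <- function(batteries) {
  if (inherits(batteries, "subsample_battery")) batteries <- list(batteries)
  if (!length(batteries)) stop("no batteries supplied", call. = FALSE)
  rows <- lapply(batteries, function(b) {
    row <- data.frame(target_group = b$target_group,
                      n_subsets = b$n_subsets,
                      median_p = b$median_p,
                      stringsAsFactors = FALSE)
    for (i in seq_along(b$thresholds)) {
      row[[paste0("n_below_", b$thresholds[i])]] <- b$n_below[i]
      row[[paste0("prop_below_", b$thresholds[i])]] <- b$proportions_below[i]
    }
    row
  })
  do.call(rbind, rows)
}

#' Subsample battery with NNT-carrier mothers excluded from the target group
#'
#' Repeats \code{\link{subsample_battery}} after removing, from the target
#' group only, mothers flagged as carrying the NNT marker mutation (residual
#' C57BL/6J background) together with their pups. Control subsets are built
#' from the unmodified control groups.
#'
#' @inheritParams subsample_battery
#' @return A \code{\link{subsample_battery}} object.
#' @export
nnt_excluded_battery <- function(cohort, target_group, k = 6,
                                 thresholds = c(0.008, 0.01, 0.05),
                                 controls = control_groups(),
                                 max_subsets = 10000) {
  stopifnot(inherits(cohort, "het_cohort"))
  m <- cohort$mothers
  drop <- m$mother_id[m$group == target_group & m$nnt_carrier]
  out <- cohort
  out$mothers <- m[!(m$mother_id %in% drop), , drop = FALSE]
  out$pups <- cohort$pups[!(cohort$pups$mother_id %in% drop), , drop = FALSE]
  subsample_battery(out, target_group, k, thresholds, controls, max_subsets)
}

#' KS test of shift distributions between NNT and non-NNT mothers
#'
#' Within one genotype group, compares the pooled shifts of pups born to
#' NNT-carrier mothers against those of non-carrier mothers, to check that
#' the residual genetic background does not itself alter transmission.
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @param group group label to stratify.
#' @param alpha significance level.
#' @return One-row data.frame as returned by \code{\link{ks_two_sample}}.
#' @export
nnt_stratified_test <- function(cohort, group, alpha = 0.05) {
  st <- shift_table(cohort)
  m <- cohort$mothers
  carriers <- m$mother_id[m$group == group & m$nnt_carrier]
  noncarr <- m$mother_id[m$group == group & !m$nnt_carrier]
  a <- st$shift[st$mother_id %in% noncarr]
  b <- st$shift[st$mother_id %in% carriers]
  if (!length(b))
    stop("no NNT-carrier mothers in group ", group, call. = FALSE)
  ks_two_sample(a, b, alpha = alpha,
                groups = paste0(group, ": WT vs NNT mothers"))
}
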
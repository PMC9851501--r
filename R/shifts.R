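#' Normalized mother-to-pup heteroplasmy shift
#'
#' The logit-scale difference between pup and mother heteroplasmy,
#' \deqn{shift = \ln\frac{H_{pup}}{1-H_{pup}} - \ln\frac{H_{mother}}{1-H_{mother}},}
#' which removes the dependence of raw heteroplasmy change on the mother's
#' starting level. Under neutral transmission its mean is zero; a negative
#' mean indicates purifying selection against the mutant mtDNA.
#'
#' @param h_pup,h_mother heteroplasmy fractions, strictly in (0, 1);
#'   vectorized with the usual recycling.
#' @return Numeric vector of dimensionless shifts. Antisymmetric:
#'   swapping the arguments negates the value.
#' @export
normalized_shift <- function(h_pup, h_mother) {
  if (!is.numeric(h_pup) || !is.numeric(h_mother))
    stop("heteroplasmy must be numeric", call. = FALSE)
  if (any(is.na(h_pup)) || any(is.na(h_mother)) ||
      any(h_pup <= 0 | h_pup >= 1) || any(h_mother <= 0 | h_mother >= 1))
    stop("heteroplasmy fractions must lie strictly inside (0, 1)",
         call. = FALSE)
  stats::qlogis(h_pup) - stats::qlogis(h_mother)
}

#' Per-pup shift table
#'
#' Computes the normalized heteroplasmy shift for every pup in a cohort,
#' carrying mother and genotype group through, together with the raw
#' heteroplasmy difference in percentage points.
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @return data.frame with columns \code{pup_id}, \code{mother_id},
#'   \code{group}, \code{shift}, \code{raw_difference} (percentage points,
#'   \eqn{100 (H_{pup} - H_{mother})}).
#' @export
shift_table <- function(cohort) {
  stopifnot(inherits(cohort, "het_cohort"))
  p <- cohort$pups
  idx <- match(p$mother_id, cohort$mothers$mother_id)
  hm <- cohort$mothers$heteroplasmy[idx]
  data.frame(
    pup_id = p$pup_id,
    mother_id = p$mother_id,
    group = cohort$mothers$group[idx],
    shift = normalized_shift(p$heteroplasmy, hm),
    raw_difference = 100 * (p$heteroplasmy - hm),
    stringsAsFactors = FALSE
  )
}

#' Normalized heteroplasmy variance of a litter
#'
#' Sample variance of the pups' heteroplasmy fractions divided by
#' \eqn{\bar H (1 - \bar H)}, a scale-free measure of pup-to-pup spread used
#' to gauge germline bottleneck intensity. Invariant under the reflection
#' \eqn{H \to 1 - H} of all pups.
#'
#' @param pup_heteroplasmies numeric vector of at least two fractions in
#'   (0, 1).
#' @return Nonnegative scalar.
#' @export
normalized_variance <- function(pup_heteroplasmies) {
  h <- pup_heteroplasmies
  if (length(h) < 2)
    stop("normalized variance needs at least 2 pups", call. = FALSE)
  if (any(is.na(h)) || any(h <= 0 | h >= 1))
    stop("heteroplasmy fractions must lie strictly inside (0, 1)",
         call. = FALSE)
  m <- mean(h)
  stats::var(h) / (m * (1 - m))
}

#' Per-mother normalized heteroplasmy variances
#'
#' Applies \code{\link{normalized_variance}} to each litter with at least two
#' pups.
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @return data.frame with columns \code{mother_id}, \code{group},
#'   \code{n_pups}, \code{normalized_variance}; mothers with fewer than two
#'   pups are omitted.
#' @export
mother_variances <- function(cohort) {
  stopifnot(inherits(cohort, "het_cohort"))
  sp <- split(cohort$pups$heteroplasmy, cohort$pups$mother_id)
  sp <- sp[lengths(sp) >= 2]
  ids <- names(sp)
  idx <- match(ids, cohort$mothers$mother_id)
  data.frame(
    mother_id = ids,
    group = cohort$mothers$group[idx],
    n_pups = lengths(sp),
    normalized_variance = vapply(sp, normalized_variance, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-group cohort summaries
#'
#' One row per genotype group: mother and pup counts, pup heteroplasmy
#' (percent), raw mother-to-pup heteroplasmy difference (percentage points)
#' and normalized heteroplasmy shift, each as mean and sample (n-1) standard
#' deviation, plus the group's maximum pup heteroplasmy.
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @return data.frame with columns \code{group}, \code{n_mothers},
#'   \code{n_pups}, \code{pup_het_mean}, \code{pup_het_sd} (percent),
#'   \code{diff_mean}, \code{diff_sd} (percentage points),
#'   \code{shift_mean}, \code{shift_sd}, \code{max_pup_het} (percent).
#'   Standard deviations are \code{NA} for single-pup groups.
#' @export
group_summaries <- function(cohort) {
  stopifnot(inherits(cohort, "het_cohort"))
  st <- shift_table(cohort)
  pg <- pup_groups(cohort)
  groups <- sort(unique(cohort$mothers$group))
  rows <- lapply(groups, function(g) {
    gm <- cohort$mothers$group == g
    gp <- pg == g
    hp <- 100 * cohort$pups$heteroplasmy[gp]
    sh <- st$shift[st$group == g]
    dd <- st$raw_difference[st$group == g]
    sdv <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
    data.frame(
      group = g,
      n_mothers = sum(gm),
      n_pups = sum(gp),
      pup_het_mean = if (length(hp)) mean(hp) else NA_real_,
      pup_het_sd = sdv(hp),
      diff_mean = if (length(dd)) mean(dd) else NA_real_,
      diff_sd = sdv(dd),
      shift_mean = if (length(sh)) mean(sh) else NA_real_,
      shift_sd = sdv(sh),
      max_pup_het = if (length(hp)) max(hp) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Maximum tolerated heteroplasmy per group
#'
#' For each genotype group with at least one pup, the highest observed pup
#' heteroplasmy and the number of pups strictly above a threshold. Used to
#' ask whether a knockout raises the ceiling on transmissible mutation load.
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @param threshold percent, in (0, 100); default 80, the empirical ceiling
#'   observed for this mutation.
#' @return data.frame with columns \code{group}, \code{max_pup_het}
#'   (percent), \code{n_above_threshold}.
#' @export
max_tolerated <- function(cohort, threshold = 80) {
  stopifnot(inherits(cohort, "het_cohort"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 100)
    stop("threshold must be a percent in (0, 100)", call. = FALSE)
  pg <- pup_groups(cohort)
  hp <- 100 * cohort$pups$heteroplasmy
  groups <- sort(unique(pg))
  data.frame(
    group = groups,
    max_pup_het = vapply(groups, function(g) max(hp[pg == g]), numeric(1)),
    n_above_threshold = vapply(groups, function(g)
      sum(hp[pg == g] > threshold), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
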
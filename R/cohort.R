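#' Canonical nuclear genotype group labels
#'
#' The six genotype groups of the breeding design: two wildtype control
#' groups and four autophagy-gene knockout groups, all on the same
#' heteroplasmic mtDNA background.
#'
#' @return Character vector of the six canonical group labels.
#' @export
het_groups <- function() {
  c("parkin_wt", "bcl2l13_wt", "parkin_ko", "bcl2l13_ko", "ulk1_ko", "ulk2_ko")
}

#' Control group labels
#'
#' The two wildtype groups pooled as the control reference throughout the
#' robustness and power analyses.
#'
#' @return Character vector of length two.
#' @export
control_groups <- function() {
  c("parkin_wt", "bcl2l13_wt")
}

#' Default alias map for genotype group labels
#'
#' Maps common spellings of the genotype labels (as they appear in data
#' files, e.g. \code{"Parkin:+/+"}) onto the canonical labels of
#' \code{\link{het_groups}}. Matching is case-insensitive and ignores
#' whitespace. Extend or replace the map to admit additional groups.
#'
#' @return Named character vector: names are lowercased aliases, values are
#'   canonical labels.
#' @export
group_aliases <- function() {
  c(
    "parkin:+/+"  = "parkin_wt",  "parkin+/+"  = "parkin_wt",
    "bcl2l13:+/+" = "bcl2l13_wt", "bcl2l13+/+" = "bcl2l13_wt",
    "parkin:-/-"  = "parkin_ko",  "parkin-/-"  = "parkin_ko",
    "bcl2l13:-/-" = "bcl2l13_ko", "bcl2l13-/-" = "bcl2l13_ko",
    "ulk1:-/-"    = "ulk1_ko",    "ulk1-/-"    = "ulk1_ko",
    "ulk2:-/-"    = "ulk2_ko",    "ulk2-/-"    = "ulk2_ko",
    "parkin_wt" = "parkin_wt", "bcl2l13_wt" = "bcl2l13_wt",
    "parkin_ko" = "parkin_ko", "bcl2l13_ko" = "bcl2l13_ko",
    "ulk1_ko" = "ulk1_ko", "ulk2_ko" = "ulk2_ko"
  )
}

canonical_group <- function(x, aliases = group_aliases(), extra_groups = character()) {
  key <- gsub("[[:space:]]", "", tolower(as.character(x)))
  out <- unname(aliases[key])
  out[is.na(out) & x %in% extra_groups] <- x[is.na(out) & x %in% extra_groups]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown genotype group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Construct a pedigreed heteroplasmy cohort
#'
#' Bundles per-mother and per-pup heteroplasmy measurements into a validated
#' cohort object, the input to every analysis stage. Heteroplasmy is stored
#' as a fraction strictly inside (0, 1); values of exactly 0 or 1 are
#' rejected because the logit-scale shift statistic is undefined there.
#'
#' @param mothers data.frame with columns \code{mother_id}, \code{group},
#'   \code{heteroplasmy} (fraction in (0,1)) and optionally
#'   \code{nnt_carrier} (logical; defaults to \code{FALSE}).
#' @param pups data.frame with columns \code{pup_id}, \code{mother_id},
#'   \code{heteroplasmy} and optionally \code{heteroplasmy_remeasured}
#'   (second measurement of a flagged sample; kept for the record, never used
#'   as the analysis value).
#' @param units_declared \code{"fraction"} or \code{"percent"}: the unit the
#'   source file stored. Values are always held as fractions internally.
#' @param extra_groups additional group labels (beyond
#'   \code{\link{het_groups}}) to accept, e.g. for synthetic scenarios.
#'
#' @return An object of class \code{het_cohort}: a list with elements
#'   \code{mothers}, \code{pups}, \code{units_declared}, \code{extra_groups}.
#' @export
het_cohort <- function(mothers, pups, units_declared = "fraction",
                       extra_groups = character()) {
  mothers <- as.data.frame(mothers, stringsAsFactors = FALSE)
  pups <- as.data.frame(pups, stringsAsFactors = FALSE)

  need_m <- c("mother_id", "group", "heteroplasmy")
  miss <- setdiff(need_m, names(mothers))
  if (length(miss))
    stop("mothers table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  need_p <- c("pup_id", "mother_id", "heteroplasmy")
  miss <- setdiff(need_p, names(pups))
  if (length(miss))
    stop("pups table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  if (is.null(mothers$nnt_carrier))
    mothers$nnt_carrier <- logical(nrow(mothers))
  mothers$nnt_carrier <- as.logical(mothers$nnt_carrier)
  mothers$nnt_carrier[is.na(mothers$nnt_carrier)] <- FALSE
  if (is.null(pups$heteroplasmy_remeasured))
    pups$heteroplasmy_remeasured <- rep(NA_real_, nrow(pups))

  mothers$mother_id <- as.character(mothers$mother_id)
  pups$mother_id <- as.character(pups$mother_id)
  pups$pup_id <- as.character(pups$pup_id)

  known <- c(het_groups(), extra_groups)
  bad <- setdiff(unique(mothers$group), known)
  if (length(bad))
    stop("unknown genotype group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  if (anyDuplicated(mothers$mother_id))
    stop("duplicate mother_id: ",
         paste(unique(mothers$mother_id[duplicated(mothers$mother_id)]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(pups$pup_id))
    stop("duplicate pup_id: ",
         paste(unique(pups$pup_id[duplicated(pups$pup_id)]), collapse = ", "),
         call. = FALSE)

  orphan <- setdiff(pups$mother_id, mothers$mother_id)
  if (length(orphan)) {
    bad_pups <- pups$pup_id[pups$mother_id %in% orphan]
    stop("pup(s) reference unknown mother(s): ",
         paste(bad_pups, collapse = ", "), call. = FALSE)
  }

  check_het <- function(h, what) {
    if (!is.numeric(h)) stop(what, " heteroplasmy must be numeric", call. = FALSE)
    if (anyNA(h)) stop(what, " heteroplasmy contains missing values", call. = FALSE)
    if (any(h <= 0 | h >= 1))
      stop(what, " heteroplasmy must lie strictly inside (0, 1) as a ",
           "fraction; got values outside: ",
           paste(signif(h[h <= 0 | h >= 1], 4), collapse = ", "), call. = FALSE)
  }
  check_het(mothers$heteroplasmy, "mother")
  check_het(pups$heteroplasmy, "pup")
  ok <- is.na(pups$heteroplasmy_remeasured)
  if (any(!ok)) {
    hr <- pups$heteroplasmy_remeasured[!ok]
    if (any(hr <= 0 | hr >= 1))
      stop("remeasured pup heteroplasmy must lie strictly inside (0, 1)",
           call. = FALSE)
  }

  units_declared <- match.arg(units_declared, c("fraction", "percent"))

  structure(
    list(mothers = mothers[need_m_order(mothers)],
         pups = pups[c("pup_id", "mother_id", "heteroplasmy",
                       "heteroplasmy_remeasured")],
         units_declared = units_declared,
         extra_groups = extra_groups),
    class = "het_cohort"
  )
}

need_m_order <- function(mothers) {
  c("mother_id", "group", "heteroplasmy", "nnt_carrier")
}

#' @export
print.het_cohort <- function(x, ...) {
  cat("Pedigreed heteroplasmy cohort\n")
  cat(sprintf("  %d mothers, %d pups, %d group(s); source units: %s\n",
              nrow(x$mothers), nrow(x$pups),
              length(unique(x$mothers$group)), x$units_declared))
  gs <- table(x$mothers$group)
  for (g in names(gs)) {
    np <- sum(x$pups$mother_id %in%
                x$mothers$mother_id[x$mothers$group == g])
    cat(sprintf("  %-12s %2d mothers, %4d pups\n", g, gs[[g]], np))
  }
  invisible(x)
}

#' @export
summary.het_cohort <- function(object, ...) {
  group_summaries(object)
}

# group of each pup, via its mother
pup_groups <- function(cohort) {
  idx <- match(cohort$pups$mother_id, cohort$mothers$mother_id)
  cohort$mothers$group[idx]
}

#' Restrict a cohort to selected groups and/or non-NNT mothers
#'
#' Subsets a cohort by genotype group and optionally removes mothers carrying
#' the NNT marker mutation (a flag for residual C57BL/6J background) together
#' with all their pups.
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @param groups character vector of group labels to keep, or \code{NULL} to
#'   keep all groups.
#' @param exclude_nnt if \code{TRUE}, drop NNT-carrier mothers and their pups.
#'
#' @return A \code{het_cohort} restricted accordingly.
#' @export
filter_cohort <- function(cohort, groups = NULL, exclude_nnt = FALSE) {
  stopifnot(inherits(cohort, "het_cohort"))
  m <- cohort$mothers
  if (!is.null(groups)) {
    known <- c(het_groups(), cohort$extra_groups)
    bad <- setdiff(groups, known)
    if (length(bad))
      stop("unknown genotype group label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    m <- m[m$group %in% groups, , drop = FALSE]
  }
  if (isTRUE(exclude_nnt)) m <- m[!m$nnt_carrier, , drop = FALSE]
  p <- cohort$pups[cohort$pups$mother_id %in% m$mother_id, , drop = FALSE]
  out <- cohort
  out$mothers <- m
  out$pups <- p
  out
}
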
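#' Default per-group simulation parameters
#'
#' The six-group parameterization whose shift moments mirror the observed
#' cohort: generative selection shift means of -0.20, -0.12, -0.20, -0.01,
#' -0.04, -0.08 and shift standard deviations of 0.29-0.34 for the
#' parkin_wt, bcl2l13_wt, parkin_ko, bcl2l13_ko, ulk1_ko and ulk2_ko groups,
#' with 4, 6, 5, 9, 10 and 6 mothers respectively and 4 of the 10 ulk1_ko
#' mothers flagged as NNT carriers.
#'
#' @return data.frame with columns \code{group},
#'   \code{selection_shift_mean}, \code{shift_sd}, \code{n_mothers},
#'   \code{nnt_fraction}.
#' @export
default_sim_groups <- function() {
  data.frame(
    group = het_groups(),
    selection_shift_mean = c(-0.20, -0.12, -0.20, -0.01, -0.04, -0.08),
    shift_sd = c(0.29, 0.33, 0.34, 0.32, 0.30, 0.33),
    n_mothers = c(4L, 6L, 5L, 9L, 10L, 6L),
    nnt_fraction = c(0, 0, 0, 0, 0.4, 0),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic cohorts
#'
#' Parameterizes the logit-normal transmission model used to generate
#' synthetic cohorts: mothers are drawn uniformly on a heteroplasmy range,
#' litter sizes from a truncated rounded normal, and each pup's heteroplasmy
#' is \eqn{logit^{-1}(logit(H_{mother}) + e)} with
#' \eqn{e \sim N(s_g, \sigma_g^2)}, where \eqn{s_g} is the group's
#' selection shift mean (0 means neutral transmission) and \eqn{\sigma_g}
#' the shift standard deviation.
#'
#' @param groups data.frame like \code{\link{default_sim_groups}}; columns
#'   \code{group}, \code{selection_shift_mean}, \code{shift_sd}
#'   (positive), \code{n_mothers} (>= 1), \code{nnt_fraction} (in [0, 1]).
#' @param mother_het_range length-2 fractions, 0 < low < high < 1; default
#'   c(0.60, 0.78), the high-heteroplasmy breeding window.
#' @param pups_per_mother length-2 (mean, sd) of the litter-size normal,
#'   rounded and truncated at 1; default c(24.73, 9.76).
#' @param measurement_rounding \code{"integer_percent"} (measurements
#'   reported on the 1\% grid, as a pyrosequencing readout is) or
#'   \code{"none"}.
#' @param ceiling maximum transmissible pup heteroplasmy (fraction); pups
#'   above it are redrawn (rejection), emulating a hard cap on tolerated
#'   mutation load. Default 0.80; \code{NULL} disables it.
#' @param seed integer seed; the cohort is fully determined by the
#'   configuration including the seed.
#' @return Object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(groups = default_sim_groups(),
                       mother_het_range = c(0.60, 0.78),
                       pups_per_mother = c(24.73, 9.76),
                       measurement_rounding = c("integer_percent", "none"),
                       ceiling = 0.80,
                       seed = 1L) {
  measurement_rounding <- match.arg(measurement_rounding)
  problems <- character()
  need <- c("group", "selection_shift_mean", "shift_sd", "n_mothers",
            "nnt_fraction")
  if (!is.data.frame(groups) || length(setdiff(need, names(groups))))
    problems <- c(problems, paste("groups must be a data.frame with columns",
                                  paste(need, collapse = ", ")))
  else {
    if (any(groups$shift_sd <= 0))
      problems <- c(problems, "shift_sd must be positive for every group")
    if (any(groups$n_mothers < 1))
      problems <- c(problems, "n_mothers must be at least 1 for every group")
    if (any(groups$nnt_fraction < 0 | groups$nnt_fraction > 1))
      problems <- c(problems, "nnt_fraction must lie in [0, 1]")
    if (anyDuplicated(groups$group))
      problems <- c(problems, "group labels must be unique")
  }
  if (length(mother_het_range) != 2 ||
      !(mother_het_range[1] > 0 && mother_het_range[1] < mother_het_range[2] &&
        mother_het_range[2] < 1))
    problems <- c(problems,
                  "mother_het_range must satisfy 0 < low < high < 1")
  if (length(pups_per_mother) != 2 || pups_per_mother[2] <= 0 ||
      pups_per_mother[1] < 1)
    problems <- c(problems,
                  "pups_per_mother must be (mean >= 1, sd > 0)")
  if (!is.null(ceiling)) {
    if (length(ceiling) != 1 || ceiling >= 1 ||
        (length(mother_het_range) == 2 && ceiling <= mother_het_range[2]))
      problems <- c(problems,
                    "ceiling must lie in (mother_het_range[2], 1) or be NULL")
  }
  if (length(seed) != 1 || is.na(seed) || seed != round(seed))
    problems <- c(problems, "seed must be a single integer")
  if (length(problems))
    stop("invalid simulation configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(
    list(groups = groups, mother_het_range = mother_het_range,
         pups_per_mother = pups_per_mother,
         measurement_rounding = measurement_rounding,
         ceiling = ceiling, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  mothers ~ U(%.2f, %.2f); litter ~ round(N(%.2f, %.2f)) >= 1\n",
              x$mother_het_range[1], x$mother_het_range[2],
              x$pups_per_mother[1], x$pups_per_mother[2]))
  cat(sprintf("  rounding: %s; ceiling: %s; seed: %d\n",
              x$measurement_rounding,
              if (is.null(x$ceiling)) "none" else format(x$ceiling), x$seed))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

round_measurement <- function(h, rounding) {
  if (rounding == "integer_percent") {
    h <- round(h, 2)
    h <- pmin(pmax(h, 0.01), 0.99)
  }
  h
}

#' Simulate a pedigreed heteroplasmy cohort
#'
#' Generates a cohort under the logit-normal transmission model of
#' \code{\link{sim_config}}. Mother heteroplasmy is uniform on the configured
#' range; litter sizes are rounded truncated normal (minimum 1); pup
#' heteroplasmy is the inverse logit of the mother's logit plus a normal
#' selection-shift deviate; pups above the ceiling are redrawn; measurements
#' are optionally rounded to the 1\% grid and clamped inside (0, 1). The
#' output is fully determined by the configuration's seed and leaves the
#' caller's RNG state untouched.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A \code{\link{het_cohort}} (with \code{extra_groups} set to any
#'   non-canonical labels in the configuration).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$groups
  lo <- config$mother_het_range[1]
  hi <- config$mother_het_range[2]
  mu_l <- config$pups_per_mother[1]
  sd_l <- config$pups_per_mother[2]

  with_seed(config$seed, {
    mothers <- list(); pups <- list()
    for (i in seq_len(nrow(g))) {
      grp <- g$group[i]
      nm <- g$n_mothers[i]
      hm <- round_measurement(stats::runif(nm, lo, hi),
                              config$measurement_rounding)
      n_nnt <- round(g$nnt_fraction[i] * nm)
      nnt <- rep(FALSE, nm)
      if (n_nnt > 0) nnt[sample.int(nm, n_nnt)] <- TRUE
      mid <- sprintf("%s_M%02d", grp, seq_len(nm))
      mothers[[i]] <- data.frame(
        mother_id = mid, group = grp, heteroplasmy = hm, nnt_carrier = nnt,
        stringsAsFactors = FALSE)
      gp <- lapply(seq_len(nm), function(j) {
        litter <- max(1L, as.integer(round(stats::rnorm(1, mu_l, sd_l))))
        base <- stats::qlogis(hm[j])
        h <- stats::plogis(base + stats::rnorm(litter, g$selection_shift_mean[i],
                                               g$shift_sd[i]))
        if (!is.null(config$ceiling)) {
          repeat {
            bad <- which(h > config$ceiling)
            if (!length(bad)) break
            h[bad] <- stats::plogis(base +
              stats::rnorm(length(bad), g$selection_shift_mean[i],
                           g$shift_sd[i]))
          }
        }
        h <- round_measurement(h, config$measurement_rounding)
        data.frame(
          pup_id = sprintf("%s_P%03d", mid[j], seq_len(litter)),
          mother_id = mid[j], heteroplasmy = h,
          stringsAsFactors = FALSE)
      })
      pups[[i]] <- do.call(rbind, gp)
    }
    het_cohort(do.call(rbind, mothers), do.call(rbind, pups),
               units_declared = "fraction",
               extra_groups = setdiff(g$group, het_groups()))
  })
}

#' Parameter-recovery experiment over repeated simulations
#'
#' Simulates cohorts under a configuration across several seeds, runs the
#' requested pipeline stages on each, and reports how well the per-group
#' sample shift means recover the generative selection shift means.
#'
#' @param config a \code{\link{sim_config}}; its seed field is replaced by
#'   each experiment seed in turn.
#' @param n_seeds number of simulated cohorts.
#' @param seeds explicit seeds; default \code{seq_len(n_seeds)}.
#' @param stages subset of \code{c("zero_battery", "robustness", "power")} to
#'   run in addition to the recovery summaries.
#' @param k,thresholds passed to \code{\link{subsample_battery}} when the
#'   robustness stage is requested.
#' @param power_target,power_sizes,power_reps bootstrap-power stage settings.
#' @return List with \code{recovery} (data.frame: seed, group, true shift
#'   mean, estimated mean, standard error, bias, and whether the truth lies
#'   within 3 standard errors of the estimate) plus, per requested stage,
#'   \code{zero_batteries}, \code{robustness} (battery_report rows) and
#'   \code{power} (one curve per seed).
#' @export
recovery_experiment <- function(config, n_seeds, seeds = seq_len(n_seeds),
                                stages = character(),
                                k = 6, thresholds = c(0.008, 0.01, 0.05),
                                power_target = "bcl2l13_ko",
                                power_sizes = seq(50, 235, by = 5),
                                power_reps = 500) {
  stopifnot(inherits(config, "sim_config"), length(seeds) >= 1)
  rec <- list(); zb <- list(); rb <- list(); pw <- list()
  for (s in seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    cohort <- simulate_cohort(cfg)
    st <- shift_table(cohort)
    g <- config$groups
    est <- vapply(g$group, function(gr) mean(st$shift[st$group == gr]),
                  numeric(1))
    se <- vapply(g$group, function(gr) {
      x <- st$shift[st$group == gr]
      stats::sd(x) / sqrt(length(x))
    }, numeric(1))
    rec[[length(rec) + 1]] <- data.frame(
      seed = s, group = g$group, s_true = g$selection_shift_mean,
      shift_mean_est = unname(est), se = unname(se),
      bias = unname(est) - g$selection_shift_mean,
      within_3se = abs(unname(est) - g$selection_shift_mean) <= 3 * unname(se),
      stringsAsFactors = FALSE)
    if ("zero_battery" %in% stages)
      zb[[length(zb) + 1]] <- cbind(seed = s, per_group_zero_battery(cohort))
    if ("robustness" %in% stages) {
      bats <- lapply(g$group, function(gr)
        subsample_battery(cohort, gr, k = k, thresholds = thresholds))
      rb[[length(rb) + 1]] <- cbind(seed = s, battery_report(bats))
    }
    if ("power" %in% stages) {
      ctrl <- st$shift[st$group %in% control_groups()]
      pw[[as.character(s)]] <- bootstrap_power(
        st$shift[st$group == power_target], ctrl,
        sizes = power_sizes, n_replicates = power_reps, seed = as.integer(s))
    }
  }
  out <- list(recovery = do.call(rbind, rec))
  if (length(zb)) out$zero_batteries <- do.call(rbind, zb)
  if (length(rb)) out$robustness <- do.call(rbind, rb)
  if (length(pw)) out$power <- pw
  out
}
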
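#' Run the full heteroplasmy-shift selection analysis
#'
#' Sequences every stage of the pipeline on one cohort: per-group summaries,
#' maximum tolerated heteroplasmy, the Wilcoxon zero-shift battery, the
#' reference-control KS battery, the exhaustive subsampled-control
#' robustness batteries for every group (plus the NNT-excluded variant for
#' groups with NNT-carrier mothers), and the bootstrap power curve for one
#' target group against the pooled controls. Results are written as CSVs and
#' a plain-text report; a MANIFEST file records which stages completed, so a
#' failed run leaves its partial outputs interpretable.
#'
#' @param cohort a \code{\link{het_cohort}}.
#' @param out_dir output directory, created if needed.
#' @param controls control group labels pooled for subsampling and power.
#' @param reference_group reference for the control-vs-groups KS battery.
#' @param subset_size control-subset size k for the robustness stage.
#' @param thresholds significance thresholds counted in the batteries.
#' @param max_threshold percent threshold for \code{\link{max_tolerated}}.
#' @param power_target group whose detectability the bootstrap stage
#'   measures; \code{NULL} skips the stage.
#' @param power_sizes,power_reps,alpha_levels bootstrap power grid settings.
#' @param seed integer seed for the bootstrap stage.
#' @param alpha family significance level for the test batteries.
#' @return Invisibly, an object of class \code{het_analysis}: list with
#'   \code{summaries}, \code{max_tolerated}, \code{tests},
#'   \code{batteries} (list of \code{subsample_battery}),
#'   \code{battery_summary}, \code{nnt_batteries}, \code{power},
#'   \code{out_dir}, \code{files}.
#' @export
run_full_analysis <- function(cohort, out_dir,
                              controls = control_groups(),
                              reference_group = "bcl2l13_wt",
                              subset_size = 6,
                              thresholds = c(0.008, 0.01, 0.05),
                              max_threshold = 80,
                              power_target = "bcl2l13_ko",
                              power_sizes = seq(50, 235, by = 5),
                              power_reps = 500,
                              alpha_levels = c(0.01, 0.05),
                              seed = 1L,
                              alpha = 0.05) {
  stopifnot(inherits(cohort, "het_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  done <- character()
  manifest <- function(state) {
    writeLines(c(sprintf("state: %s", state),
                 sprintf("completed: %s",
                         paste(done, collapse = ", "))),
               file.path(out_dir, "MANIFEST"))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest("failed")
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    done <<- c(done, name)
    res
  }
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    name
  }

  files <- character()
  summ <- stage("summaries", group_summaries(cohort))
  files <- c(files, wcsv(round_numeric(summ, 4), "summaries.csv"))
  shifts <- stage("shifts", shift_table(cohort))
  files <- c(files, wcsv(shifts, "shifts.csv"))
  maxtol <- stage("max_tolerated", max_tolerated(cohort, max_threshold))

  tests <- stage("tests", {
    zb <- per_group_zero_battery(cohort, alpha = alpha)
    cb <- control_vs_groups_battery(cohort, reference_group, alpha = alpha)
    rbind(zb, cb)
  })
  files <- c(files, wcsv(tests, "tests.csv"))

  groups <- sort(unique(cohort$mothers$group))
  batteries <- stage("robustness", lapply(groups, function(g)
    subsample_battery(cohort, g, k = subset_size, thresholds = thresholds,
                      controls = controls)))
  names(batteries) <- groups
  rob_rows <- do.call(rbind, lapply(batteries, function(b) data.frame(
    target_group = b$target_group,
    subset_index = seq_len(b$n_subsets),
    mother_ids = b$subset_mothers,
    p_value = b$p_values, stringsAsFactors = FALSE)))
  files <- c(files, wcsv(rob_rows, "robustness.csv"))
  bsum <- battery_report(batteries)
  files <- c(files, wcsv(bsum, "robustness_summary.csv"))

  nnt_groups <- unique(cohort$mothers$group[cohort$mothers$nnt_carrier])
  nnt_batteries <- stage("nnt_robustness", lapply(nnt_groups, function(g)
    nnt_excluded_battery(cohort, g, k = subset_size,
                         thresholds = thresholds, controls = controls)))
  names(nnt_batteries) <- nnt_groups
  if (length(nnt_batteries)) {
    nsum <- battery_report(nnt_batteries)
    files <- c(files, wcsv(nsum, "robustness_nnt_excluded.csv"))
  }

  power <- NULL
  if (!is.null(power_target)) {
    power <- stage("power", {
      ctrl <- shifts$shift[shifts$group %in% controls]
      bootstrap_power(shifts$shift[shifts$group == power_target], ctrl,
                      sizes = power_sizes, n_replicates = power_reps,
                      alpha_levels = alpha_levels, seed = seed)
    })
    files <- c(files, wcsv(as.data.frame(power), "power.csv"))
  }

  stage("report", write_report(out_dir, summ, maxtol, tests, bsum,
                               if (length(nnt_batteries))
                                 battery_report(nnt_batteries) else NULL,
                               power, max_threshold))
  files <- c(files, "report.txt")
  manifest("complete")

  invisible(structure(
    list(summaries = summ, max_tolerated = maxtol, tests = tests,
         batteries = batteries, battery_summary = bsum,
         nnt_batteries = nnt_batteries, power = power,
         out_dir = out_dir, files = files),
    class = "het_analysis"
  ))
}

round_numeric <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

fmt_pm <- function(m, s, digits = 2) {
  ifelse(is.na(s), sprintf("%.*f", digits, m),
         sprintf("%.*f +/- %.*f", digits, m, digits, s))
}

write_report <- function(out_dir, summ, maxtol, tests, bsum, nsum, power,
                         max_threshold) {
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("Heteroplasmy shift selection analysis")
  add("=====================================")
  add("")
  add("Group summaries (heteroplasmy in percent, shift dimensionless):")
  for (i in seq_len(nrow(summ))) {
    add("  %-12s %2d mothers %4d pups  pup het %s  diff %s  shift %s",
        summ$group[i], summ$n_mothers[i], summ$n_pups[i],
        fmt_pm(summ$pup_het_mean[i], summ$pup_het_sd[i]),
        fmt_pm(summ$diff_mean[i], summ$diff_sd[i]),
        fmt_pm(summ$shift_mean[i], summ$shift_sd[i]))
  }
  add("")
  add("Maximum tolerated pup heteroplasmy (threshold %g%%):", max_threshold)
  for (i in seq_len(nrow(maxtol)))
    add("  %-12s max %5.1f%%  pups above threshold: %d",
        maxtol$group[i], maxtol$max_pup_het[i], maxtol$n_above_threshold[i])
  add("")
  add("Hypothesis tests (Bonferroni-adjusted):")
  for (i in seq_len(nrow(tests)))
    add("  %-14s %-28s p = %.4g  adj = %.4g (n = %d)%s",
        tests$test[i], tests$groups[i], tests$p_value[i],
        tests$p_adjusted[i], tests$bonferroni_n[i],
        if (tests$significant[i]) "  *" else "")
  add("")
  add("Subsampled-control robustness (KS vs every control subset):")
  prop_cols <- grep("^prop_below_", names(bsum), value = TRUE)
  for (i in seq_len(nrow(bsum))) {
    props <- vapply(prop_cols, function(cn) bsum[[cn]][i], numeric(1))
    add("  %-12s %s  median p = %.4g", bsum$target_group[i],
        paste(sprintf("%s: %.2f%%", sub("prop_below_", "p<", prop_cols),
                      100 * props), collapse = "  "),
        bsum$median_p[i])
  }
  if (!is.null(nsum)) {
    add("")
    add("Robustness with NNT-carrier mothers excluded from the target group:")
    for (i in seq_len(nrow(nsum))) {
      props <- vapply(prop_cols, function(cn) nsum[[cn]][i], numeric(1))
      add("  %-12s %s  median p = %.4g", nsum$target_group[i],
          paste(sprintf("%s: %.2f%%", sub("prop_below_", "p<", prop_cols),
                        100 * props), collapse = "  "),
          nsum$median_p[i])
    }
  }
  if (!is.null(power)) {
    add("")
    add("Bootstrap power (%d replicates per size, seed %d):",
        power$n_replicates, power$seed)
    for (j in seq_along(power$alpha_levels)) {
      i120 <- which(power$sizes == 120)
      if (length(i120))
        add("  at n = 120, alpha = %g: %.1f%% of replicates significant",
            power$alpha_levels[j],
            100 * power$fraction_significant[i120, j])
    }
  }
  writeLines(ln, file.path(out_dir, "report.txt"))
  invisible(NULL)
}

#' @export
print.het_analysis <- function(x, ...) {
  cat("Heteroplasmy shift analysis\n")
  cat(sprintf("  output: %s (%s)\n", x$out_dir,
              paste(x$files, collapse = ", ")))
  cat(sprintf("  groups: %s\n", paste(x$summaries$group, collapse = ", ")))
  sig <- x$battery_summary$target_group[
    x$battery_summary[[grep("^prop_below_", names(x$battery_summary),
                            value = TRUE)[1]]] > 0.5]
  if (length(sig))
    cat(sprintf("  groups significant vs >50%% of control subsets: %s\n",
                paste(sig, collapse = ", ")))
  invisible(x)
}
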
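# small cohorts and simulation configs shared across test files

toy_cohort <- function() {
  het_cohort(
    mothers = data.frame(mother_id = "M1", group = "parkin_wt",
                         heteroplasmy = 0.70, nnt_carrier = FALSE),
    pups = data.frame(pup_id = c("P1", "P2"), mother_id = "M1",
                      heteroplasmy = c(0.65, 0.72))
  )
}

# a compact multi-group cohort with known values
mini_cohort <- function() {
  mothers <- data.frame(
    mother_id = c("A", "B", "C"),
    group = c("parkin_wt", "bcl2l13_wt", "ulk1_ko"),
    heteroplasmy = c(0.70, 0.65, 0.72),
    nnt_carrier = c(FALSE, FALSE, TRUE)
  )
  pups <- data.frame(
    pup_id = paste0("P", 1:6),
    mother_id = c("A", "A", "B", "B", "C", "C"),
    heteroplasmy = c(0.66, 0.71, 0.60, 0.68, 0.74, 0.70)
  )
  het_cohort(mothers, pups)
}

# configurable small/fast simulation config; rounding and ceiling off so
# generative moments are exactly recoverable
fast_cfg <- function(groups, litter = c(10, 3), seed = 1,
                     ceiling = NULL, rounding = "none") {
  sim_config(groups = groups, pups_per_mother = litter,
             measurement_rounding = rounding, ceiling = ceiling, seed = seed)
}

# two control groups + one target group, all with the same generative shift:
# the null scenario of the subsampling battery, at the study's dimensions
null_groups <- function(s = -0.15, sd = 0.30) {
  data.frame(
    group = c("parkin_wt", "bcl2l13_wt", "bcl2l13_ko"),
    selection_shift_mean = s,
    shift_sd = sd,
    n_mothers = c(4L, 6L, 9L),
    nnt_fraction = 0
  )
}

# brute-force two-sample KS statistic: maximum absolute ECDF difference
# evaluated at every observed point
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}
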
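test_that("normalized shift matches hand-computed values and is antisymmetric", {
  expect_equal(normalized_shift(0.5, 0.5), 0)
  # ln(0.69/0.31) - ln(0.73/0.27), computed independently
  expect_equal(normalized_shift(0.69, 0.73), -0.1945033, tolerance = 1e-4)

  set.seed(42)
  h1 <- runif(200, 0.01, 0.99)
  h2 <- runif(200, 0.01, 0.99)
  expect_equal(normalized_shift(h1, h2), -normalized_shift(h2, h1))
  expect_equal(sign(normalized_shift(h1, h2)), sign(h1 - h2))

  expect_error(normalized_shift(0, 0.5), "strictly inside")
  expect_error(normalized_shift(0.5, 1), "strictly inside")
})

test_that("shift is monotone in pup heteroplasmy and antitone in mother heteroplasmy", {
  grid <- seq(0.05, 0.95, by = 0.05)
  for (hm in c(0.2, 0.5, 0.8))
    expect_true(all(diff(normalized_shift(grid, hm)) > 0))
  for (hp in c(0.2, 0.5, 0.8))
    expect_true(all(diff(normalized_shift(hp, grid)) < 0))
})

test_that("normalized variance matches arithmetic and is reflection invariant", {
  expect_equal(normalized_variance(c(0.4, 0.6)), 0.08)
  expect_equal(normalized_variance(rep(0.37, 5)), 0)
  expect_error(normalized_variance(0.5), "at least 2")

  set.seed(7)
  for (i in 1:20) {
    h <- runif(sample(2:30, 1), 0.05, 0.95)
    expect_equal(normalized_variance(h), normalized_variance(1 - h))
  }
})

test_that("shift_table carries pedigree context and zero shifts for identical pairs", {
  co <- mini_cohort()
  st <- shift_table(co)
  expect_equal(nrow(st), nrow(co$pups))
  expect_identical(st$group[st$mother_id == "C"], rep("ulk1_ko", 2))
  expect_equal(st$raw_difference[st$pup_id == "P1"], -4, tolerance = 1e-9)

  same <- het_cohort(
    data.frame(mother_id = "M", group = "ulk2_ko", heteroplasmy = 0.7),
    data.frame(pup_id = c("a", "b"), mother_id = "M", heteroplasmy = 0.7))
  expect_equal(shift_table(same)$shift, c(0, 0))
})

test_that("group summaries use sample sd, report percent, and conserve counts", {
  co <- mini_cohort()
  gs <- group_summaries(co)
  expect_equal(sum(gs$n_pups), nrow(co$pups))
  expect_equal(sum(gs$n_mothers), nrow(co$mothers))
  pw <- gs[gs$group == "parkin_wt", ]
  expect_equal(pw$pup_het_mean, mean(c(66, 71)))
  expect_equal(pw$pup_het_sd, sd(c(66, 71)))
  expect_equal(pw$max_pup_het, 71)

  single <- het_cohort(
    data.frame(mother_id = "M", group = "ulk1_ko", heteroplasmy = 0.7),
    data.frame(pup_id = "a", mother_id = "M", heteroplasmy = 0.72))
  gs1 <- group_summaries(single)
  expect_equal(gs1$n_pups, 1)
  expect_true(is.na(gs1$shift_sd))
})

test_that("mother_variances computes per-litter normalized variance", {
  co <- mini_cohort()
  mv <- mother_variances(co)
  expect_setequal(mv$mother_id, c("A", "B", "C"))
  expect_equal(mv$normalized_variance[mv$mother_id == "A"],
               var(c(0.66, 0.71)) / (mean(c(0.66, 0.71)) *
                                       (1 - mean(c(0.66, 0.71)))))
  one_pup <- het_cohort(
    data.frame(mother_id = "M", group = "ulk1_ko", heteroplasmy = 0.7),
    data.frame(pup_id = "a", mother_id = "M", heteroplasmy = 0.72))
  expect_equal(nrow(mother_variances(one_pup)), 0)
})

test_that("max_tolerated reports per-group maxima and counts above threshold", {
  mothers <- data.frame(mother_id = c("M1", "M2"),
                        group = c("bcl2l13_wt", "bcl2l13_ko"),
                        heteroplasmy = c(0.70, 0.71))
  pups <- data.frame(pup_id = paste0("P", 1:4),
                     mother_id = c("M1", "M1", "M2", "M2"),
                     heteroplasmy = c(0.86, 0.74, 0.79, 0.60))
  co <- het_cohort(mothers, pups)
  mt <- max_tolerated(co, threshold = 80)
  expect_equal(mt$max_pup_het[mt$group == "bcl2l13_wt"], 86)
  expect_equal(mt$n_above_threshold[mt$group == "bcl2l13_wt"], 1)
  expect_equal(mt$max_pup_het[mt$group == "bcl2l13_ko"], 79)
  expect_equal(mt$n_above_threshold[mt$group == "bcl2l13_ko"], 0)
  expect_false("ulk1_ko" %in% mt$group)
  expect_error(max_tolerated(co, threshold = 0), "percent")
})

test_that("grand mean shift converges to the generative selection shift", {
  groups <- data.frame(group = "parkin_ko", selection_shift_mean = -0.2,
                       shift_sd = 0.3, n_mothers = 10L, nnt_fraction = 0)
  cfg <- fast_cfg(groups, litter = c(1000, 1), seed = 11)
  st <- shift_table(simulate_cohort(cfg))
  n <- nrow(st)
  expect_gt(n, 5000)
  se <- sd(st$shift) / sqrt(n)
  expect_lt(abs(mean(st$shift) - (-0.2)), 3 * se)
})
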
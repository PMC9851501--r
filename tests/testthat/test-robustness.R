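test_that("subset enumeration matches the binomial coefficient", {
  # recursion oracle, independent of choose()
  n_subsets <- function(n, k) {
    if (k == 0 || k == n) return(1)
    if (k < 0 || k > n) return(0)
    n_subsets(n - 1, k - 1) + n_subsets(n - 1, k)
  }
  make <- function(n) {
    het_cohort(
      data.frame(mother_id = sprintf("M%02d", 1:n), group = "parkin_wt",
                 heteroplasmy = 0.7),
      data.frame(pup_id = sprintf("P%02d", 1:n),
                 mother_id = sprintf("M%02d", 1:n), heteroplasmy = 0.68))
  }
  for (n in c(6, 7, 10, 12)) {
    co <- make(n)
    for (k in unique(c(1, 3, 6, n))) {
      subs <- enumerate_control_subsets(co, k)
      expect_length(subs, n_subsets(n, k))
    }
  }
  expect_length(enumerate_control_subsets(make(6), 6), 1)
  expect_length(enumerate_control_subsets(make(7), 6), 7)
  expect_error(enumerate_control_subsets(make(5), 6), "between 1 and")
  expect_error(enumerate_control_subsets(make(12), 6, max_subsets = 100),
               "ceiling")
})

test_that("each subset carries exactly its mothers' pups' shifts", {
  co <- simulate_cohort(fast_cfg(default_sim_groups(), litter = c(8, 2),
                                 seed = 4))
  subs <- enumerate_control_subsets(co, 6)
  expect_length(subs, choose(10, 6))
  st <- shift_table(co)
  counts <- table(st$mother_id)
  for (s in subs[c(1, 50, 210)]) {
    expect_length(s$shifts, sum(counts[s$mother_ids]))
  }
  # deterministic order and content
  subs2 <- enumerate_control_subsets(co, 6)
  expect_identical(subs, subs2)
})

test_that("battery reports monotone proportions, medians and is deterministic", {
  co <- simulate_cohort(fast_cfg(default_sim_groups(), litter = c(10, 3),
                                 seed = 9))
  b <- subsample_battery(co, "bcl2l13_ko")
  expect_equal(b$n_subsets, 210)
  expect_length(b$p_values, 210)
  expect_true(all(diff(b$proportions_below) >= 0))
  expect_equal(b$median_p, median(b$p_values))
  expect_identical(b, subsample_battery(co, "bcl2l13_ko"))
  expect_error(subsample_battery(co, "no_such"), "no_such")
  expect_error(subsample_battery(co, "bcl2l13_ko", thresholds = c(0, 0.05)),
               "thresholds")

  rep <- battery_report(list(b, subsample_battery(co, "ulk1_ko")))
  expect_equal(nrow(rep), 2)
  expect_equal(rep$n_below_0.05 / rep$n_subsets, rep$prop_below_0.05)
})

test_that("a target generated like the controls is calibrated to median p near 0.5", {
  med <- vapply(1:20, function(s) {
    co <- simulate_cohort(fast_cfg(null_groups(), litter = c(24.73, 9.76),
                                   seed = s))
    subsample_battery(co, "bcl2l13_ko")$median_p
  }, numeric(1))
  expect_gte(median(med), 0.35)
  expect_lte(median(med), 0.65)
})

test_that("battery power grows with the generative effect size", {
  prop_sig <- vapply(c(0, 0.2, 0.4), function(delta) {
    mean(vapply(1:10, function(s) {
      g <- null_groups(s = -0.15)
      g$selection_shift_mean[g$group == "bcl2l13_ko"] <- -0.15 - delta
      co <- simulate_cohort(fast_cfg(g, litter = c(24.73, 9.76), seed = s))
      b <- subsample_battery(co, "bcl2l13_ko")
      b$proportions_below[b$thresholds == 0.008]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(prop_sig) >= 0))
  expect_gt(prop_sig[3], prop_sig[1])
})

test_that("NNT exclusion removes carrier mothers from the target group only", {
  g <- default_sim_groups()
  co <- simulate_cohort(fast_cfg(g, litter = c(10, 3), seed = 13))
  carriers <- co$mothers$mother_id[co$mothers$nnt_carrier]
  expect_gt(length(carriers), 0)

  plain <- subsample_battery(co, "ulk1_ko")
  excl <- nnt_excluded_battery(co, "ulk1_ko")
  expect_equal(excl$n_subsets, plain$n_subsets)
  expect_false(identical(excl$p_values, plain$p_values))

  # a target group without carriers is untouched
  same <- nnt_excluded_battery(co, "parkin_ko")
  expect_identical(same$p_values, subsample_battery(co, "parkin_ko")$p_values)

  strat <- nnt_stratified_test(co, "ulk1_ko")
  expect_true(strat$p_value >= 0 && strat$p_value <= 1)
  expect_error(nnt_stratified_test(co, "parkin_ko"), "NNT")
})
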
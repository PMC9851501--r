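test_that("percent values are auto-detected and converted to fractions", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mother_id,group,mother_het,pup_id,pup_het,nnt",
               "M1,parkin_wt,70,P1,65,0",
               "M1,parkin_wt,70,P2,72,0"), f)
  co <- read_cohort(f)
  expect_equal(nrow(co$mothers), 1)
  expect_equal(nrow(co$pups), 2)
  expect_equal(co$mothers$heteroplasmy, 0.70)
  expect_equal(sort(co$pups$heteroplasmy), c(0.65, 0.72))
  expect_identical(co$units_declared, "percent")
})

test_that("percent and fraction encodings of the same data give identical shift tables", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mother_id,group,mother_het,pup_id,pup_het,nnt",
               "M1,parkin_wt,70,P1,65,0",
               "M2,bcl2l13_wt,64,P2,72,1"), f1)
  writeLines(c("mother_id,group,mother_het,pup_id,pup_het,nnt",
               "M1,parkin_wt,0.70,P1,0.65,0",
               "M2,bcl2l13_wt,0.64,P2,0.72,1"), f2)
  expect_equal(shift_table(read_cohort(f1)), shift_table(read_cohort(f2)))
})

test_that("schema, referential and range violations produce named errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mother_id,group,mother_het,pup_id",
               "M1,parkin_wt,70,P1"), f)
  expect_error(read_cohort(f), "pup_het")

  writeLines(c("mother_id,group,mother_het,pup_id,pup_het",
               "M1,parkin_wt,70,P1,65",
               "M9,parkin_wt,70,P2,66"), f)
  # M9 appears only with its own pup, so it is a known mother; orphan needs
  # the pup to cite a mother that never appears
  co <- read_cohort(f)
  expect_equal(nrow(co$mothers), 2)

  expect_error(
    het_cohort(
      data.frame(mother_id = "M1", group = "parkin_wt", heteroplasmy = 0.7),
      data.frame(pup_id = "P1", mother_id = "MISSING", heteroplasmy = 0.6)),
    "P1")

  writeLines(c("mother_id,group,mother_het,pup_id,pup_het",
               "M1,parkin_wt,70,P1,120"), f)
  expect_error(read_cohort(f), "outside")

  writeLines(c("mother_id,group,mother_het,pup_id,pup_het",
               "M1,parkin_wt,70,P1,100"), f)
  expect_error(read_cohort(f), "strictly inside")

  writeLines(c("mother_id,group,mother_het,pup_id,pup_het",
               "M1,parkin_wt,70,P1,0.65"), f)
  expect_error(read_cohort(f), "mixed")

  writeLines(c("mother_id,group,mother_het,pup_id,pup_het",
               "M1,made_up_group,70,P1,65"), f)
  expect_error(read_cohort(f), "made_up_group")
})

test_that("group label aliases map onto canonical labels", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mother_id,group,mother_het,pup_id,pup_het",
               "M1,Parkin:+/+,70,P1,65",
               "M2,Bcl2l13:-/-,68,P2,66"), f)
  co <- read_cohort(f)
  expect_setequal(co$mothers$group, c("parkin_wt", "bcl2l13_ko"))
})

test_that("write/read round trip reproduces the cohort", {
  cfg <- fast_cfg(default_sim_groups(), seed = 7,
                  ceiling = 0.80, rounding = "integer_percent")
  co <- simulate_cohort(cfg)
  # add a pupless mother and a remeasured pup to cover both edge paths
  co$mothers <- rbind(co$mothers, data.frame(
    mother_id = "LONE", group = "parkin_wt", heteroplasmy = 0.66,
    nnt_carrier = TRUE))
  co$pups$heteroplasmy_remeasured[1] <- 0.71

  for (fmt in c("csv", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_cohort(co, f, format = fmt)
    back <- read_cohort(f, format = fmt)
    m0 <- co$mothers[order(co$mothers$mother_id), ]
    m1 <- back$mothers[order(back$mothers$mother_id), ]
    expect_equal(m1$heteroplasmy, m0$heteroplasmy, tolerance = 1e-9)
    expect_identical(m1$group, m0$group)
    expect_identical(m1$nnt_carrier, m0$nnt_carrier)
    p0 <- co$pups[order(co$pups$pup_id), ]
    p1 <- back$pups[order(back$pups$pup_id), ]
    expect_equal(p1$heteroplasmy, p0$heteroplasmy, tolerance = 1e-9)
    expect_equal(p1$heteroplasmy_remeasured, p0$heteroplasmy_remeasured,
                 tolerance = 1e-9)
    expect_equal(table(m1$group), table(m0$group))
  }
})

test_that("an empty cohort writes a header-only file", {
  co <- het_cohort(
    data.frame(mother_id = character(), group = character(),
               heteroplasmy = numeric()),
    data.frame(pup_id = character(), mother_id = character(),
               heteroplasmy = numeric()))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  expect_length(readLines(f), 1L)
  back <- read_cohort(f)
  expect_equal(nrow(back$mothers), 0)
  expect_equal(nrow(back$pups), 0)
})

test_that("filter_cohort restricts groups and can drop NNT mothers", {
  co <- mini_cohort()
  expect_identical(filter_cohort(co, exclude_nnt = FALSE), co)
  expect_error(filter_cohort(co, groups = "nonsense"), "nonsense")

  two <- filter_cohort(co, groups = c("parkin_wt", "ulk1_ko"))
  by_hand <- sum(co$pups$mother_id %in%
                   co$mothers$mother_id[co$mothers$group %in%
                                          c("parkin_wt", "ulk1_ko")])
  expect_equal(nrow(two$pups), by_hand)

  none <- filter_cohort(co, exclude_nnt = TRUE)
  expect_false(any(none$mothers$nnt_carrier))
  expect_false(any(none$pups$mother_id == "C"))
})

test_that("simulated 6-group cohort keeps group counts through a round trip", {
  co <- simulate_cohort(fast_cfg(default_sim_groups(), seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(table(pup_group <- back$mothers$group),
               table(co$mothers$group))
  expect_equal(nrow(back$pups), nrow(co$pups))
})
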
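test_that("colonoscopy detection fractions follow the performance parameters", {
  split <- apply_colonoscopy(c(1, 1, 1, 1), default_performance(),
                             "screening")$split
  expect_equal(split$fraction_detected, c(0, 0.75, 0.95, 0.95))
  expect_equal(split$fraction_negative + split$fraction_detected,
               rep(1, 4))
})

test_that("a zero-sensitivity exam detects nothing; a perfect exam clears everyone", {
  none <- apply_colonoscopy(c(10, 20, 5, 1), tibble::tibble(
    sens_na = 0, sens_advanced = 0, specificity = 1), "screening")
  expect_equal(none$split$fraction_detected, rep(0, 4))
  stays <- none$dispositions[none$dispositions$disposition == "stay", ]
  expect_equal(stays$persons, c(10, 20, 5, 1))

  perfect <- apply_colonoscopy(c(10, 20, 5, 1), tibble::tibble(
    sens_na = 1, sens_advanced = 1, specificity = 1), "screening")
  stays <- perfect$dispositions[perfect$dispositions$disposition == "stay", ]
  expect_equal(stays$persons, c(10, 0, 0, 0))
})

test_that("screening exams fall due at the scheduled ages for the right strata", {
  ps <- test_ps(p_na = 0.1)
  sc <- screening_scenario(50, 65)
  state <- cohort_state_init(ps, 50)
  due <- exams_due(state, sc)
  expect_equal(nrow(due), 1)  # all mass sits in one routine/screen0 cell
  expect_equal(due$context, "screening")
  expect_equal(due$screen_stratum, "screen0")
  expect_equal(due$occupancy, 1e5)

  # between exams, and for already-examined strata, nothing is due
  state$age <- 57L
  expect_equal(nrow(exams_due(state, sc)), 0)

  # second exam only reaches the screen-negative stratum
  state <- cohort_state_init(ps, 65)
  state$undiag[, , 2, ] <- state$undiag[, , 1, ]  # move mass to screen1_negative
  state$undiag[, , 1, ] <- 0
  due <- exams_due(state, sc)
  expect_true(all(due$screen_stratum == "screen1_negative"))

  # no exams at or beyond the age limit
  state$age <- 85L
  expect_equal(nrow(exams_due(state, sc)), 0)
})

test_that("post-polypectomy surveillance runs on 3- and 10-year clocks", {
  ps <- test_ps(p_na = 0.3, p_adv = 0.1, sens_na = 1, sens_advanced = 1)
  sc <- screening_scenario(50, 60)
  run <- run_cohort(ps, sc)
  t <- run$tallies
  surv_ages <- t$age[t$exams_surveillance > 0]
  # advanced-adenoma carriers cleared at 50 return at 53, 56, ...;
  # non-advanced carriers at 60, 70, 80
  expect_true(all(c(53, 56, 59, 60, 62) %in% surv_ages))
  expect_false(any(c(51, 52) %in% surv_ages))
  expect_true(max(surv_ages) <= 84)
  # screening exams happen only at the two scheduled ages
  expect_equal(t$age[t$exams_screening > 0], c(50, 60))
})

test_that("no individual ever receives more than two screening colonoscopies", {
  ps <- quick_bundle(seed = 12, cohort_size = 5000)
  for (sc in list(screening_scenario(45, 55), screening_scenario(50, 70))) {
    st <- run_cohort_stochastic(ps, sc, n_individuals = 5000, seed = 2)
    expect_lte(max(st$screens_used), 2)
  }
  # deterministic flow accounting: total screening exams cannot exceed the
  # first-exam attendance plus the negatives eligible for a second
  det <- run_cohort(ps, screening_scenario(50, 60))
  expect_lte(sum(det$tallies$exams_screening), 2 * ps$cohort_size)
})

test_that("adenoma detection at the first exam replaces the second screening exam", {
  # everyone starts with a non-advanced adenoma and a perfect exam: all
  # leave the screening track at 50, so no screening exams occur at 60,
  # and the 10-year surveillance exam falls at the same age instead
  ps <- test_ps(p_na = 1, sens_na = 1)
  run <- run_cohort(ps, screening_scenario(50, 60))
  t <- run$tallies
  expect_equal(t$exams_screening[t$age == 50], 1e5)
  expect_equal(t$exams_screening[t$age == 60], 0)
  expect_equal(t$exams_surveillance[t$age == 60], 1e5)
})

test_that("with perfect specificity screening never worsens outcomes (monotone benefit)", {
  ps <- quick_bundle(seed = 14)
  base <- glance(run_cohort(ps))$cases
  grid <- scenario_grid()
  for (i in seq_len(nrow(grid))) {
    cases <- glance(run_cohort(ps, grid$scenario[[i]]))$cases
    expect_lte(cases, base + 1e-9 * ps$cohort_size)
  }
})

test_that("a perfect exam at 45 with no later lesion formation eliminates later cases", {
  ps <- test_ps(r2 = 0.05, r3 = 0.05, r4 = 0.3,
                p_na = 0.2, p_adv = 0.05, p_pre = 0.01,
                sens_na = 1, sens_advanced = 1)
  run <- run_cohort(ps, screening_scenario(45, 55))
  t <- run$tallies
  expect_gt(t$cases_screen[t$age == 45], 0)   # prevalent preclinical found
  expect_equal(sum(t$cases_clinical[t$age > 45]), 0)
  expect_equal(sum(t$cases_surveillance), 0)
})

test_that("the scenario grid is exactly the nine start-age/interval combinations", {
  grid <- scenario_grid()
  expect_equal(nrow(grid), 9)
  expect_setequal(
    paste(grid$first_age, grid$second_age),
    c("45 55", "50 60", "55 65", "60 70",
      "45 60", "50 65", "55 70", "45 65", "50 70")
  )
  expect_equal(grid$second_age - grid$first_age, grid$interval)
})

test_that("malformed scenarios are rejected", {
  expect_error(screening_scenario(44, 55), "first_age")
  expect_error(screening_scenario(55, 55), "second_age must exceed")
  expect_error(screening_scenario(50, 90), "below the age limit")
  expect_error(screening_scenario(50, 60, surveillance_interval_nonadvanced = 12),
               "intervals")
})
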
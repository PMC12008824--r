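test_that("with no disease flows, other-cause deaths are q times the living", {
  ps <- test_ps(q = 0.02, p_na = 0.1)
  state <- cohort_state_init(ps)
  res <- advance_one_year(state, ps)
  expect_equal(res$tally$other_deaths, 0.02 * 1e5)
  expect_equal(res$tally$cases_clinical, 0)
  expect_equal(sum(res$state$undiag), 0.98 * 1e5)
})

test_that("certain progression empties the preclinical compartment in one year", {
  ps <- test_ps(r4 = 1, p_pre = 0.01)
  state <- cohort_state_init(ps)
  res <- advance_one_year(state, ps)
  expect_equal(res$tally$cases_clinical, 1000)
  expect_equal(sum(res$state$undiag[4, , , ]), 0)
  expect_equal(sum(res$state$diag), 1000)
})

test_that("engine equals the 5-state matrix-power oracle with strata and interventions off", {
  ps <- test_ps(r1 = 0.014, r2 = 0.015, r3 = 0.035, r4 = 0.22,
                p_na = 0.12, p_adv = 0.04, p_pre = 0.005)
  run <- run_cohort(ps, keep_trajectory = TRUE)
  v0 <- engine_chain_vector(run$trajectory[[1]])
  oracle <- oracle_chain_evolve(ps$transition_rates, v0, 45, 85)
  for (i in seq_along(run$trajectory)) {
    expect_lt(max(abs(engine_chain_vector(run$trajectory[[i]]) - oracle[i, ])),
              1e-12 * 1e5)
  }
})

test_that("mass is conserved at every age, with and without screening", {
  ps <- quick_bundle(seed = 6)
  for (sc in list(NULL, screening_scenario(50, 60))) {
    run <- run_cohort(ps, sc, keep_trajectory = TRUE)
    for (st in run$trajectory) {
      total <- sum(st$undiag) + sum(st$diag) + st$dead_other + st$dead_crc
      expect_lt(abs(total - ps$cohort_size), 1e-9 * ps$cohort_size)
    }
  }
})

test_that("no-disease cohort reproduces the life-table survival computation", {
  ps <- test_ps(q = 0)
  ps$life_table$q_other <- pmin(0.001 * exp(0.09 * (ps$life_table$age - 45)), 1)
  run <- run_cohort(ps)
  q <- ps$life_table$q_other[match(45:84, ps$life_table$age)]
  surv_to <- c(1, cumprod(1 - q))[1:40]
  expect_equal(run$tallies$other_deaths, 1e5 * surv_to * q, tolerance = 1e-12)
})

test_that("zero cancer mortality gives cases but no cancer deaths", {
  ps <- test_ps(r1 = 0.014, r2 = 0.015, r3 = 0.035, r4 = 0.22,
                p_na = 0.12, p_adv = 0.04, p_pre = 0.005, q = 0.003)
  g <- glance(run_cohort(ps))
  expect_equal(g$deaths, 0)
  expect_gt(g$cases, 0)
})

test_that("a zero-sensitivity scenario is an exact null intervention", {
  ps <- quick_bundle(seed = 6)
  ps$performance <- tibble::tibble(sens_na = 0, sens_advanced = 0,
                                   specificity = 1)
  r_none <- run_cohort(ps)
  r_null <- run_cohort(ps, screening_scenario(50, 60))
  expect_equal(r_null$tallies[setdiff(names(r_null$tallies),
                                      c("exams_screening",
                                        "exams_surveillance"))],
               r_none$tallies[setdiff(names(r_none$tallies),
                                      c("exams_screening",
                                        "exams_surveillance"))],
               tolerance = 1e-12)
  expect_gt(sum(r_null$tallies$exams_screening), 0)
})

test_that("advancing a state respects diagnosed survival schedules by mode and year", {
  ps <- test_ps()
  sched <- flat_survival(0, 0)
  sched$p_crc_death[sched$detection_mode == "clinically_detected" &
                      sched$year_since_dx == "1"] <- 0.3
  sched$p_crc_death[sched$detection_mode == "clinically_detected" &
                      sched$year_since_dx == "2"] <- 0.1
  ps$crc_survival <- sched
  state <- cohort_state_init(ps)
  state$undiag[1, 1, 1, 1] <- 0
  state$diag["clinically_detected", "1"] <- 1000
  state$dead_other <- 1e5 - 1000
  res1 <- advance_one_year(state, ps)
  expect_equal(res1$tally$crc_deaths, 300)
  expect_equal(res1$state$diag["clinically_detected", "2"], 700)
  res2 <- advance_one_year(res1$state, ps)
  expect_equal(res2$tally$crc_deaths, 70)
})

test_that("stochastic runs are reproducible and agree with themselves", {
  ps <- quick_bundle(seed = 6, cohort_size = 2000)
  a <- run_cohort_stochastic(ps, screening_scenario(50, 60),
                             n_individuals = 2000, seed = 9)
  b <- run_cohort_stochastic(ps, screening_scenario(50, 60),
                             n_individuals = 2000, seed = 9)
  expect_identical(a$tallies, b$tallies)
  expect_identical(a$screens_used, b$screens_used)
  c <- run_cohort_stochastic(ps, screening_scenario(50, 60),
                             n_individuals = 2000, seed = 10)
  expect_false(identical(a$tallies, c$tallies))
})

test_that("a lone immortal individual survives to 85 without events", {
  ps <- test_ps(cohort_size = 1)
  run <- run_cohort_stochastic(ps, n_individuals = 1, seed = 3)
  expect_equal(sum(run$tallies$other_deaths), 0)
  expect_equal(sum(run$tallies$crc_deaths), 0)
  expect_equal(sum(run$tallies$cases_clinical), 0)
})

test_that("stochastic tallies agree with the deterministic engine within sampling error", {
  ps <- quick_bundle(seed = 6, cohort_size = 20000)
  det <- glance(run_cohort(ps, screening_scenario(50, 60)))
  st <- run_cohort_stochastic(ps, screening_scenario(50, 60),
                              n_individuals = 20000, seed = 31)
  cases <- sum(st$tallies$cases_clinical + st$tallies$cases_screen +
                 st$tallies$cases_surveillance)
  deaths <- sum(st$tallies$crc_deaths)
  # binomial-scale standard deviations
  expect_lt(abs(cases - det$cases), 4 * sqrt(det$cases))
  expect_lt(abs(deaths - det$deaths), 4 * sqrt(det$deaths))
})
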
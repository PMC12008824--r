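test_that("generation is deterministic given the spec", {
  a <- generate_parameters(synthetic_spec("female", seed = 21))
  b <- generate_parameters(synthetic_spec("female", seed = 21))
  attr(a, "calibration") <- attr(b, "calibration") <- NULL
  expect_identical(a, b)
  c <- generate_parameters(synthetic_spec("female", seed = 22))
  expect_false(identical(a$transition_rates, c$transition_rates))
})

test_that("generated rates have the registry structure: 45-54 copied from 55-59, near-constant above", {
  ps <- generate_parameters(synthetic_spec("male", seed = 13))
  tr <- ps$transition_rates
  for (tn in c("r_none_to_na", "r_na_to_adv", "r_adv_to_pre", "r_pre_to_clin")) {
    expect_equal(tr[[tn]][1], tr[[tn]][3])  # 45-49 == 55-59
    expect_equal(tr[[tn]][2], tr[[tn]][3])  # 50-54 == 55-59
    spread <- max(tr[[tn]][3:8]) / min(tr[[tn]][3:8])
    expect_lt(spread, 1.1 / 0.9 + 1e-12)
  }
  expect_equal(nrow(validate_parameter_set(ps)), 0)
})

test_that("zero-dynamics forward simulation is the identity on prevalences", {
  ps <- test_ps(p_na = 0.2, p_adv = 0.05, p_pre = 0.01)
  fw <- forward_prevalence(ps)
  expect_equal(fw$p_na, 0.2)
  expect_equal(fw$p_adv, 0.05)
  expect_equal(fw$p_pre, 0.01)
})

test_that("single-transition accrual matches the geometric closed form", {
  r <- 0.013
  ps <- test_ps(r1 = r)
  for (to_age in c(50, 55, 62)) {
    n <- to_age - 45
    fw <- forward_prevalence(ps, to_age = to_age)
    expect_equal(fw$p_na, 1 - (1 - r)^n, tolerance = 1e-12)
  }
})

test_that("uniform other-cause mortality cancels out of conditional prevalences", {
  ps_dead <- test_ps(r1 = 0.01, r2 = 0.02, r3 = 0.03, r4 = 0.2,
                     p_na = 0.1, p_adv = 0.03, p_pre = 0.005, q = 0.01)
  ps_immortal <- test_ps(r1 = 0.01, r2 = 0.02, r3 = 0.03, r4 = 0.2,
                         p_na = 0.1, p_adv = 0.03, p_pre = 0.005, q = 0)
  expect_equal(forward_prevalence(ps_dead), forward_prevalence(ps_immortal),
               tolerance = 1e-12)
})

test_that("calibration under identity dynamics returns the target in one iteration", {
  ps <- test_ps()
  tgt <- prevalence_target("male", p_na = 0.2, p_adv = 0.05, p_pre = 0.01)
  cal <- calibrate_starting_prevalence(ps, tgt)
  expect_equal(cal$iterations, 1)
  expect_equal(cal$starting_prevalence$p_na_45, 0.2)
  expect_equal(cal$starting_prevalence$p_adv_45, 0.05)
  expect_equal(cal$starting_prevalence$p_pre_45, 0.01)
})

test_that("single-compartment calibration matches the algebraic solution", {
  # with only none->NA flow at rate r, p_na(55) = 1 - (1 - s)(1 - r)^10,
  # so the start solving p_na(55) = 0.25 is s = 1 - 0.75 / (1 - r)^10
  r <- 0.01
  ps <- test_ps(r1 = r)
  tgt <- prevalence_target("male", p_na = 0.25, p_adv = 0, p_pre = 0)
  cal <- calibrate_starting_prevalence(ps, tgt, tol = 1e-10)
  expect_equal(cal$starting_prevalence$p_na_45, 1 - 0.75 / (1 - r)^10,
               tolerance = 1e-8)
})

test_that("calibration round-trips random feasible targets", {
  ps <- quick_bundle(seed = 4)
  set.seed(42)
  for (i in 1:5) {
    start <- tibble::tibble(p_na_45 = runif(1, 0, 0.3),
                            p_adv_45 = runif(1, 0, 0.1),
                            p_pre_45 = runif(1, 0, 0.02))
    fw <- forward_prevalence(ps, start = start)
    tgt <- prevalence_target("male", p_na = fw$p_na, p_adv = fw$p_adv,
                             p_pre = fw$p_pre)
    cal <- calibrate_starting_prevalence(ps, tgt, tol = 1e-8)
    hit <- forward_prevalence(ps, start = cal$starting_prevalence)
    expect_lt(max(abs(c(hit$p_na - tgt$p_na_target,
                        hit$p_adv - tgt$p_adv_target,
                        hit$p_pre - tgt$p_pre_target))), 1e-6)
  }
})

test_that("forward prevalence is monotone in the starting prevalence", {
  ps <- quick_bundle(seed = 4)
  lo <- forward_prevalence(ps, start = tibble::tibble(
    p_na_45 = 0.05, p_adv_45 = 0.02, p_pre_45 = 0.002))
  hi <- forward_prevalence(ps, start = tibble::tibble(
    p_na_45 = 0.15, p_adv_45 = 0.02, p_pre_45 = 0.002))
  expect_gt(hi$p_na, lo$p_na)
  hi_adv <- forward_prevalence(ps, start = tibble::tibble(
    p_na_45 = 0.05, p_adv_45 = 0.06, p_pre_45 = 0.002))
  expect_gt(hi_adv$p_adv, lo$p_adv)
})

test_that("generated bundles hit their age-55 prevalence targets", {
  ps <- generate_parameters(synthetic_spec("male", seed = 8))
  cal <- attr(ps, "calibration")
  expect_lt(cal$residual, 1e-6)
  fw <- forward_prevalence(ps)
  tgt <- prevalence_target("male")
  expect_equal(fw$p_na, tgt$p_na_target, tolerance = 1e-6)
  expect_equal(fw$p_adv, tgt$p_adv_target, tolerance = 1e-6)
})

test_that("an infeasible target errors instead of silently stagnating", {
  # flows alone push p_na at 55 above 0.10 here; a lower target cannot be
  # reached from any non-negative start
  ps <- test_ps(r1 = 0.02)
  tgt <- prevalence_target("male", p_na = 0.05, p_adv = 0, p_pre = 0)
  expect_error(calibrate_starting_prevalence(ps, tgt),
               "infeasible|did not converge")
})

test_that("invalid synthetic specs are rejected", {
  expect_error(synthetic_spec("male", rate_ranges = list(
    r_none_to_na = c(0.4, 0.2), r_na_to_adv = c(0, 0.1),
    r_adv_to_pre = c(0, 0.1), r_pre_to_clin = c(0, 0.1))),
    "r_none_to_na")
  expect_error(synthetic_spec("male", screen_hazard_multiplier = 0),
               "screen_hazard_multiplier")
  expect_error(prevalence_target("male", p_na = 0.9, p_adv = 0.2),
               "sum to at most 1")
})
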
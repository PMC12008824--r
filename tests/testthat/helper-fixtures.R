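# Programmatic fixtures: tiny hand-built parameter sets with controllable
# dynamics, plus an independent 5-state matrix oracle for the lesion chain.

flat_transition_rates <- function(r1 = 0, r2 = 0, r3 = 0, r4 = 0) {
  tibble::tibble(
    age_group = c("45-49", "50-54", "55-59", "60-64",
                  "65-69", "70-74", "75-79", "80+"),
    r_none_to_na = r1, r_na_to_adv = r2, r_adv_to_pre = r3,
    r_pre_to_clin = r4
  )
}

const_life_table <- function(q = 0, le = 30) {
  tibble::tibble(age = 45:100, q_other = q, le_resid = le)
}

flat_survival <- function(p_screen = 0, p_clin = 0, y_max = 10) {
  yrs <- c(as.character(seq_len(y_max)), "beyond")
  tibble::tibble(
    detection_mode = rep(c("screen_detected", "clinically_detected"),
                         each = y_max + 1),
    year_since_dx = rep(yrs, 2),
    p_crc_death = c(rep(p_screen, y_max + 1), rep(p_clin, y_max + 1))
  )
}

# A minimal valid parameter set: every piece overridable, defaults inert
# (no flows, no deaths).
test_ps <- function(r1 = 0, r2 = 0, r3 = 0, r4 = 0,
                    p_na = 0, p_adv = 0, p_pre = 0,
                    q = 0, le = 30,
                    p_crc_screen = 0, p_crc_clin = 0,
                    sens_na = 0.75, sens_advanced = 0.95, specificity = 1,
                    cohort_size = 1e5, sex = "male") {
  crc_parameter_set(
    sex = sex,
    transition_rates = flat_transition_rates(r1, r2, r3, r4),
    starting_prevalence = tibble::tibble(p_na_45 = p_na, p_adv_45 = p_adv,
                                         p_pre_45 = p_pre),
    performance = tibble::tibble(sens_na = sens_na,
                                 sens_advanced = sens_advanced,
                                 specificity = specificity),
    crc_survival = flat_survival(p_crc_screen, p_crc_clin),
    life_table = const_life_table(q, le),
    disability_weights = default_disability_weights(),
    cohort_size = cohort_size
  )
}

# Independent oracle: the 5-state pure-progression chain (no lesion, NA
# adenoma, advanced adenoma, preclinical, clinical) as an explicit annual
# transition matrix, with age binning done by an if-chain rather than the
# package's lookup.
oracle_rates_at_age <- function(transition_rates, age) {
  grp <- if (age < 50) "45-49" else if (age < 55) "50-54" else
    if (age < 60) "55-59" else if (age < 65) "60-64" else
      if (age < 70) "65-69" else if (age < 75) "70-74" else
        if (age < 80) "75-79" else "80+"
  i <- match(grp, transition_rates$age_group)
  c(transition_rates$r_none_to_na[i], transition_rates$r_na_to_adv[i],
    transition_rates$r_adv_to_pre[i], transition_rates$r_pre_to_clin[i])
}

oracle_chain_matrix <- function(r) {
  matrix(c(
    1 - r[1], 0,        0,        0,        0,
    r[1],     1 - r[2], 0,        0,        0,
    0,        r[2],     1 - r[3], 0,        0,
    0,        0,        r[3],     1 - r[4], 0,
    0,        0,        0,        r[4],     1
  ), nrow = 5, byrow = TRUE)
}

# Evolve a 5-state occupancy vector over [start_age, end_age) with the
# age-appropriate matrices.
oracle_chain_evolve <- function(transition_rates, v0, start_age, end_age) {
  out <- matrix(NA_real_, nrow = end_age - start_age + 1L, ncol = 5)
  out[1, ] <- v0
  v <- v0
  for (a in seq.int(start_age, end_age - 1L)) {
    v <- oracle_chain_matrix(oracle_rates_at_age(transition_rates, a)) %*% v
    out[a - start_age + 2L, ] <- v
  }
  out
}

# 5-state occupancy vector of an engine state with strata collapsed:
# the four undiagnosed states plus everything ever diagnosed.
engine_chain_vector <- function(state) {
  c(apply(state$undiag, 1, sum), sum(state$diag) + state$dead_crc)
}

# Small, fast synthetic bundle for tests that need a realistic one.
quick_bundle <- function(seed = 1, sex = "male", cohort_size = 1e5) {
  generate_parameters(synthetic_spec(sex, seed = seed,
                                     cohort_size = cohort_size))
}
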
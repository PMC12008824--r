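# Synthetic parameter generation and starting-prevalence calibration.
#
# Registry-derived natural-history inputs for this model class have a very
# characteristic structure: annual transition probabilities that are nearly
# constant across the observed 5-year age groups (55-59 and older), values
# for the unobserved 45-49 and 50-54 bands copied from 55-59, and age-45
# starting prevalences chosen so that an interventions-free forward
# simulation reproduces the prevalences observed at age 55 (the youngest
# screened age). The generator emulates exactly that structure; its default
# constants are documented, epidemiologically plausible values and are NOT
# the estimates of any specific registry analysis.

#' Age-55 prevalence targets for calibration
#'
#' @param sex `"male"` or `"female"`.
#' @param p_na,p_adv,p_pre Prevalences of non-advanced adenoma, advanced
#'   adenoma and preclinical cancer to be matched at `age_target`.
#'   Sex-specific adenoma defaults reflect the typical
#'   screening-colonoscopy finding that men carry roughly 1.3-1.5 times
#'   the neoplasm prevalence of women in their late fifties. `p_pre`
#'   defaults to `NA`, meaning [generate_parameters()] derives a
#'   self-consistent target: the preclinical compartment has a short
#'   memory (its age-45 start is almost entirely washed out by age 55), so
#'   its age-55 prevalence is pinned by the adenoma flows; the generator
#'   measures that flow-determined value and targets 5% above it, keeping
#'   the calibrated age-45 preclinical start small and realistic.
#' @param age_target Age at which the targets apply (55).
#' @return A one-row tibble.
#' @export
prevalence_target <- function(sex = c("male", "female"),
                              p_na = NULL, p_adv = NULL, p_pre = NULL,
                              age_target = 55L) {
  sex <- match.arg(sex)
  def <- if (sex == "male") c(0.18, 0.06) else c(0.13, 0.045)
  out <- tibble::tibble(
    sex = sex,
    age_target = as.integer(age_target),
    p_na_target = if (is.null(p_na)) def[1] else p_na,
    p_adv_target = if (is.null(p_adv)) def[2] else p_adv,
    p_pre_target = if (is.null(p_pre)) NA_real_ else p_pre
  )
  vals <- c(out$p_na_target, out$p_adv_target, out$p_pre_target)
  vals <- vals[!is.na(vals)]
  if (any(vals < 0 | vals > 1) || sum(vals) > 1) {
    stop("prevalence targets must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  out
}

#' Specification for a synthetic parameter set
#'
#' Collects everything [generate_parameters()] draws from: uniform ranges
#' for the four annual transition probabilities (male reference values; a
#' multiplicative factor scales them for women), the within-age-group
#' jitter, Gompertz life-table shape, a geometric post-diagnosis survival
#' schedule with a screen-detected hazard multiplier below one, and the
#' age-55 prevalence targets.
#'
#' @param sex `"male"` or `"female"`.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param rate_ranges Named list of `c(low, high)` ranges for
#'   `r_none_to_na`, `r_na_to_adv`, `r_adv_to_pre`, `r_pre_to_clin`
#'   (annual probabilities, male reference).
#' @param female_rate_factor Multiplier applied to all transition draws for
#'   women (default 0.75, reflecting the roughly 5-year lag of female
#'   age-specific incidence).
#' @param group_jitter Maximum relative perturbation of a transition across
#'   age groups 55-59 and older (default 0.10, i.e. near-constant rates).
#' @param prevalence_target Targets as from [prevalence_target()].
#' @param life_q0 Other-cause mortality at age 45 (Gompertz intercept);
#'   sex-specific default.
#' @param life_b Gompertz log-slope per year of age.
#' @param surv_p1 Annual cancer-death probability in the first year after a
#'   clinical diagnosis.
#' @param surv_decay Geometric decay of that probability per year since
#'   diagnosis.
#' @param screen_hazard_multiplier Ratio of screen-detected to clinically
#'   detected cancer mortality, in (0, 1] (stage shift at detection).
#' @param y_max Years since diagnosis tracked individually before the
#'   open-ended "beyond" stratum (default 10, a typical survival follow-up
#'   horizon).
#' @param cohort_size Cohort size (default 100,000).
#' @param calibration_tol Tolerance for the starting-prevalence calibration.
#' @return A list of class `crc_synthetic_spec`.
#' @export
synthetic_spec <- function(sex = c("male", "female"),
                           seed = 1L,
                           rate_ranges = list(
                             r_none_to_na = c(0.012, 0.016),
                             r_na_to_adv = c(0.012, 0.018),
                             r_adv_to_pre = c(0.030, 0.040),
                             r_pre_to_clin = c(0.22, 0.25)
                           ),
                           female_rate_factor = 0.75,
                           group_jitter = 0.10,
                           prevalence_target = NULL,
                           life_q0 = NULL,
                           life_b = 0.088,
                           surv_p1 = 0.12,
                           surv_decay = 0.80,
                           screen_hazard_multiplier = 0.5,
                           y_max = 10L,
                           cohort_size = 1e5,
                           calibration_tol = 1e-8) {
  sex <- match.arg(sex)
  if (is.null(prevalence_target)) {
    prevalence_target <- default_prevalence_target(sex)
  }
  if (is.null(life_q0)) life_q0 <- if (sex == "male") 0.0025 else 0.0015
  for (rn in TRANSITION_NAMES) {
    rng <- rate_ranges[[rn]]
    if (is.null(rng) || length(rng) != 2 || any(rng < 0 | rng > 1) ||
        rng[1] > rng[2]) {
      stop("rate_ranges$", rn, " must be c(low, high) within [0, 1]",
           call. = FALSE)
    }
  }
  if (screen_hazard_multiplier <= 0 || screen_hazard_multiplier > 1) {
    stop("screen_hazard_multiplier must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(sex = sex, seed = as.integer(seed), rate_ranges = rate_ranges,
         female_rate_factor = female_rate_factor,
         group_jitter = group_jitter,
         prevalence_target = prevalence_target,
         life_q0 = life_q0, life_b = life_b,
         surv_p1 = surv_p1, surv_decay = surv_decay,
         screen_hazard_multiplier = screen_hazard_multiplier,
         y_max = as.integer(y_max),
         cohort_size = cohort_size,
         calibration_tol = calibration_tol),
    class = "crc_synthetic_spec"
  )
}

# alias so synthetic_spec()'s argument of the same name cannot shadow the
# constructor
default_prevalence_target <- function(sex) prevalence_target(sex)

# Gompertz life table over single years of age with residual life
# expectancy computed from the table itself (extended to age 120 so le at
# 100 is well defined; le includes the customary half-year for the year of
# death).
make_life_table <- function(q0, b, age_min = 45L, age_max = 100L) {
  ages_ext <- seq.int(age_min, 120L)
  q_ext <- pmin(q0 * exp(b * (ages_ext - age_min)), 1)
  le <- numeric(length(ages_ext))
  for (i in seq_along(ages_ext)) {
    surv <- cumprod(1 - q_ext[i:length(q_ext)])
    le[i] <- sum(surv) + 0.5
  }
  keep <- ages_ext <= age_max
  tibble::tibble(age = ages_ext[keep], q_other = q_ext[keep],
                 le_resid = le[keep])
}

make_survival_schedule <- function(p1, decay, multiplier, y_max) {
  yrs <- c(as.character(seq_len(y_max)), "beyond")
  p_clin <- pmin(p1 * decay^(seq_len(y_max + 1L) - 1L), 1)
  tibble::tibble(
    detection_mode = rep(DETECTION_MODES, each = y_max + 1L),
    year_since_dx = rep(yrs, 2L),
    p_crc_death = c(pmin(multiplier * p_clin, 1), p_clin)
  )
}

#' Generate a complete synthetic parameter set
#'
#' Draws one base value per transition from the spec's ranges, perturbs it
#' by at most `group_jitter` across age groups 55-59 to 80+, copies the
#' 55-59 values down to 45-49 and 50-54, builds the Gompertz life table and
#' geometric survival schedule, and calibrates the age-45 starting
#' prevalences so a screening-free forward simulation reproduces the
#' age-55 targets. Deterministic given the spec (including its seed).
#'
#' @param spec A `crc_synthetic_spec`.
#' @return A validated `crc_parameter_set`. The calibration diagnostics are
#'   attached as attribute `"calibration"` (iterations and final residual).
#' @export
generate_parameters <- function(spec) {
  stopifnot(inherits(spec, "crc_synthetic_spec"))
  withr::with_seed(spec$seed, {
    sex_factor <- if (spec$sex == "female") spec$female_rate_factor else 1
    n_obs <- 6L  # observed groups 55-59 .. 80+
    rates <- sapply(TRANSITION_NAMES, function(rn) {
      rng <- spec$rate_ranges[[rn]]
      base <- stats::runif(1, rng[1], rng[2]) * sex_factor
      jit <- stats::runif(n_obs, 1 - spec$group_jitter, 1 + spec$group_jitter)
      obs <- pmin(pmax(base * jit, 0), 1)
      c(obs[1], obs[1], obs)  # 45-49 and 50-54 copied from 55-59
    })
    tr <- tibble::as_tibble(as.data.frame(rates))
    tr <- tibble::add_column(tr, age_group = AGE_GROUP_LABELS, .before = 1)

    lt <- make_life_table(spec$life_q0, spec$life_b)
    sv <- make_survival_schedule(spec$surv_p1, spec$surv_decay,
                                 spec$screen_hazard_multiplier, spec$y_max)

    ps <- crc_parameter_set(
      sex = spec$sex,
      transition_rates = tr,
      starting_prevalence = tibble::tibble(
        p_na_45 = spec$prevalence_target$p_na_target,
        p_adv_45 = spec$prevalence_target$p_adv_target,
        p_pre_45 = if (is.na(spec$prevalence_target$p_pre_target)) 0 else
          spec$prevalence_target$p_pre_target
      ),
      performance = default_performance(),
      crc_survival = sv,
      life_table = lt,
      disability_weights = default_disability_weights(),
      cohort_size = spec$cohort_size
    )

    target <- spec$prevalence_target
    if (is.na(target$p_pre_target)) {
      # self-consistent preclinical target: calibrate the adenoma
      # compartments with a zero preclinical start, measure the
      # flow-determined preclinical prevalence at the target age, and aim
      # 5% above it (see ?prevalence_target)
      pre0 <- target
      pre0$p_pre_target <- 0
      cal0 <- calibrate_starting_prevalence(ps, pre0,
                                            tol = spec$calibration_tol,
                                            free = c(TRUE, TRUE, FALSE))
      floor_pre <- forward_prevalence(ps, start = cal0$starting_prevalence,
                                      to_age = target$age_target)$p_pre
      target$p_pre_target <- 1.05 * floor_pre
      ps$starting_prevalence <- cal0$starting_prevalence
    }
    cal <- calibrate_starting_prevalence(ps, target,
                                         tol = spec$calibration_tol)
    ps$starting_prevalence <- cal$starting_prevalence
    assert_parameter_set(ps)
    attr(ps, "calibration") <- list(iterations = cal$iterations,
                                    residual = cal$residual)
    ps
  })
}

#' Lesion prevalences after an interventions-free forward simulation
#'
#' Runs the cohort engine with no screening from `from_age` to `to_age` and
#' reports the prevalences of non-advanced adenoma, advanced adenoma and
#' preclinical cancer among persons alive and not diagnosed at `to_age`.
#'
#' @param ps A valid `crc_parameter_set`.
#' @param start Optional one-row starting-prevalence tibble overriding
#'   `ps$starting_prevalence`.
#' @param from_age,to_age Simulation window (45 <= from < to <= 85).
#' @return A one-row tibble: `p_na`, `p_adv`, `p_pre`.
#' @export
forward_prevalence <- function(ps, start = NULL, from_age = 45L,
                               to_age = 55L) {
  if (from_age < 45 || to_age <= from_age || to_age > 85) {
    stop("require 45 <= from_age < to_age <= 85", call. = FALSE)
  }
  if (!is.null(start)) ps$starting_prevalence <- tibble::as_tibble(start)
  run <- run_cohort(ps, scenario = NULL, start_age = from_age,
                    end_age = to_age)
  U <- run$final_state$undiag
  alive_undiag <- sum(U)
  if (alive_undiag <= 0) {
    stop("no undiagnosed survivors at age ", to_age, call. = FALSE)
  }
  by_state <- unname(apply(U, 1, sum))
  tibble::tibble(p_na = by_state[2] / alive_undiag,
                 p_adv = by_state[3] / alive_undiag,
                 p_pre = by_state[4] / alive_undiag)
}

#' Calibrate age-45 starting prevalences to age-55 targets
#'
#' Damped fixed-point iteration on the prevalence residual:
#' `start <- clip(start + damp * (target - forward(start)), 0, 1)`, all
#' three compartments updated simultaneously. The 45-to-55 map is monotone
#' and near-affine, so the iteration contracts; the damping factor is
#' halved whenever the residual norm grows (oscillation guard) and relaxed
#' back towards 1 while it shrinks.
#'
#' @param ps Parameter set whose starting prevalence serves as the initial
#'   iterate (its value is otherwise ignored).
#' @param target Targets as from [prevalence_target()].
#' @param tol Convergence tolerance on the maximum absolute prevalence
#'   residual (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @param free Logical vector of length 3: which compartments
#'   (non-advanced, advanced, preclinical) to calibrate; the residual of a
#'   fixed compartment is ignored and its start left at the initial
#'   iterate. Used internally when deriving a self-consistent preclinical
#'   target.
#' @return A list: `starting_prevalence` (one-row tibble), `iterations`,
#'   `residual` (final max absolute residual), `converged`. Non-convergence
#'   or an infeasible target (residual pinned at the zero floor) is an
#'   error carrying the final residual.
#' @export
calibrate_starting_prevalence <- function(ps, target, tol = 1e-8,
                                          max_iter = 500L,
                                          free = c(TRUE, TRUE, TRUE)) {
  stopifnot(tol > 0, length(free) == 3)
  tgt <- c(target$p_na_target, target$p_adv_target, target$p_pre_target)
  if (anyNA(tgt[free])) {
    stop("calibration targets must be concrete for free compartments",
         call. = FALSE)
  }
  to_age <- target$age_target
  start <- c(ps$starting_prevalence$p_na_45,
             ps$starting_prevalence$p_adv_45,
             ps$starting_prevalence$p_pre_45)
  damp <- 1
  prev_norm <- Inf
  floor_hits <- 0L
  resid <- rep(NA_real_, 3)
  for (it in seq_len(max_iter)) {
    fwd <- forward_prevalence(
      ps,
      start = tibble::tibble(p_na_45 = start[1], p_adv_45 = start[2],
                             p_pre_45 = start[3]),
      from_age = 45L, to_age = to_age
    )
    resid <- tgt - c(fwd$p_na, fwd$p_adv, fwd$p_pre)
    resid[!free] <- 0
    norm <- max(abs(resid))
    if (norm <= tol) {
      start <- unname(start)
      return(list(
        starting_prevalence = tibble::tibble(
          p_na_45 = start[1], p_adv_45 = start[2], p_pre_45 = start[3]),
        iterations = it - 1L, residual = norm, converged = TRUE
      ))
    }
    # infeasible target: a compartment pinned at 0 while the simulation
    # still overshoots its target (prevalence accrued from other
    # compartments alone already exceeds it)
    if (any(start == 0 & resid < -tol)) {
      floor_hits <- floor_hits + 1L
      if (floor_hits >= 10L) {
        stop("infeasible prevalence target: residual stagnates at the zero ",
             "floor (max residual ", signif(norm, 4), ")", call. = FALSE)
      }
    } else {
      floor_hits <- 0L
    }
    damp <- if (norm > prev_norm) max(damp / 2, 0.05) else min(damp * 1.2, 1)
    prev_norm <- norm
    start <- pmin(pmax(start + damp * resid, 0), 1)
    if (sum(start) > 1) start <- start / sum(start)
  }
  stop("starting-prevalence calibration did not converge in ", max_iter,
       " iterations (max residual ", signif(max(abs(resid)), 4), ")",
       call. = FALSE)
}
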
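# Annual-cycle deterministic cohort engine.
#
# Living undiagnosed persons occupy a 4-dimensional array:
#   state (4)  x  surveillance stratum (3)  x  screening-history stratum (4)
#   x  surveillance clock (0..10 years since last polypectomy/exam).
# Diagnosed persons occupy a 2 x (y_max + 1) matrix: detection mode by
# years since diagnosis (1..y_max, then "beyond"). Two absorbing masses
# hold other-cause and cancer deaths. All occupancies are expected persons
# out of cohort_size; mass is conserved exactly (checked to 1e-9 relative
# each cycle).
#
# Event order within a year, isolated here so alternatives can be tested:
#   (1) scheduled colonoscopies, (2) other-cause death on all living
#   states, (3) lesion progression on survivors (at most one forward step
#   per year), (4) cancer death on diagnosed states, then the
#   year-since-diagnosis and surveillance clocks advance.

N_CLOCK <- 11L  # clock values 0..10 (index = clock + 1)

TALLY_FIELDS <- c("age", "cases_clinical", "cases_screen", "cases_surveillance",
                  "crc_deaths", "other_deaths",
                  "exams_screening", "exams_surveillance",
                  "py_diagnosis_treatment", "py_remission",
                  "py_metastatic_terminal")

#' Initialise a cohort state at the simulation entry age
#'
#' Places `cohort_size` x starting prevalences in the lesion states and the
#' remainder in the lesion-free state, all in the routine surveillance
#' stratum with no screening history.
#'
#' @param ps A valid `crc_parameter_set`.
#' @param start_age Entry age (default 45, where starting prevalences are
#'   defined).
#' @return An object of class `cohort_state`.
#' @export
cohort_state_init <- function(ps, start_age = 45L) {
  sm <- survival_matrix(ps)
  U <- array(0, dim = c(4L, 3L, 4L, N_CLOCK),
             dimnames = list(UNDIAG_STATES, SURV_STRATA, SCREEN_STRATA, NULL))
  sp <- ps$starting_prevalence
  N <- ps$cohort_size
  U[1, 1, 1, 1] <- N * (1 - sp$p_na_45 - sp$p_adv_45 - sp$p_pre_45)
  U[2, 1, 1, 1] <- N * sp$p_na_45
  U[3, 1, 1, 1] <- N * sp$p_adv_45
  U[4, 1, 1, 1] <- N * sp$p_pre_45
  structure(
    list(age = as.integer(start_age), undiag = U,
         diag = matrix(0, nrow = 2L, ncol = ncol(sm),
                       dimnames = dimnames(sm)),
         dead_other = 0, dead_crc = 0, cohort_size = N),
    class = "cohort_state"
  )
}

#' @export
print.cohort_state <- function(x, ...) {
  cat("<cohort_state> age", x$age, "\n")
  cat(sprintf("  undiagnosed %.1f | diagnosed %.1f | dead (other %.1f, crc %.1f)\n",
              sum(x$undiag), sum(x$diag), x$dead_other, x$dead_crc))
  invisible(x)
}

#' Tabulate a cohort state
#'
#' One row per occupied living cell (state x surveillance stratum x
#' screening stratum x clock, plus diagnosed mode x year cells and the two
#' absorbing masses).
#'
#' @param x A `cohort_state`.
#' @param ... Unused.
#' @return A tibble with columns `age`, `compartment`, `state`, `stratum`,
#'   `detail`, `persons`.
#' @export
as_tibble.cohort_state <- function(x, ...) {
  idx <- which(x$undiag > 0, arr.ind = TRUE)
  und <- tibble::tibble(
    age = x$age, compartment = "undiagnosed",
    state = UNDIAG_STATES[idx[, 1]],
    stratum = paste(SURV_STRATA[idx[, 2]], SCREEN_STRATA[idx[, 3]], sep = "/"),
    detail = paste0("clock=", idx[, 4] - 1L),
    persons = x$undiag[idx]
  )
  di <- which(x$diag > 0, arr.ind = TRUE)
  dia <- tibble::tibble(
    age = x$age, compartment = "diagnosed",
    state = "crc", stratum = rownames(x$diag)[di[, 1]],
    detail = paste0("year_since_dx=", colnames(x$diag)[di[, 2]]),
    persons = x$diag[di]
  )
  ded <- tibble::tibble(
    age = x$age, compartment = "dead", state = c("dead_other", "dead_crc"),
    stratum = "", detail = "", persons = c(x$dead_other, x$dead_crc)
  )
  dplyr::bind_rows(und, dia, ded[ded$persons > 0, ])
}

# Internal: list of exam cells due this year, screening before surveillance.
# Each element: list(context, s = surveillance stratum index,
# g = screening stratum index, k = clock index).
due_cells <- function(state, scenario) {
  if (is.null(scenario)) return(list())
  a <- state$age
  if (a >= scenario$age_limit) return(list())
  occ <- apply(state$undiag, c(2, 3, 4), sum)
  cells <- list()
  screening_mask <- array(FALSE, dim = dim(occ))
  if (a == scenario$first_age) screening_mask[, 1, ] <- TRUE
  if (!is.null(scenario$second_age) && a == scenario$second_age) {
    screening_mask[, 2, ] <- TRUE
  }
  surv_mask <- array(FALSE, dim = dim(occ))
  k_na <- scenario$surveillance_interval_nonadvanced + 1L
  k_adv <- scenario$surveillance_interval_advanced + 1L
  if (k_na <= N_CLOCK) surv_mask[2, , k_na:N_CLOCK] <- TRUE
  if (k_adv <= N_CLOCK) surv_mask[3, , k_adv:N_CLOCK] <- TRUE
  surv_mask[screening_mask] <- FALSE
  for (mask_ctx in list(list(screening_mask, "screening"),
                        list(surv_mask, "surveillance"))) {
    hit <- which(mask_ctx[[1]] & occ > 0, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      for (i in seq_len(nrow(hit))) {
        cells[[length(cells) + 1L]] <-
          list(context = mask_ctx[[2]], s = hit[i, 1], g = hit[i, 2],
               k = hit[i, 3])
      }
    }
  }
  cells
}

# Internal core step. `cells` as from due_cells(); `sm` the survival matrix
# (precomputed by callers that loop). Returns list(state, tally).
advance_core <- function(state, ps, cells, sm) {
  a <- state$age
  U <- state$undiag
  D <- state$diag
  N <- state$cohort_size
  perf <- ps$performance

  exams_screening <- 0; exams_surveillance <- 0
  cases_screen <- 0; cases_surveillance <- 0
  new_screen_dx <- 0

  # (1) scheduled colonoscopies
  for (cell in cells) {
    m <- U[, cell$s, cell$g, cell$k]
    tot <- sum(m)
    if (tot == 0) next
    U[, cell$s, cell$g, cell$k] <- 0
    det_fp <- (1 - perf$specificity) * m[1]
    det_na <- perf$sens_na * m[2]
    det_adv <- perf$sens_advanced * m[3]
    det_crc <- perf$sens_advanced * m[4]
    stay <- c(m[1] - det_fp, m[2] - det_na, m[3] - det_adv, m[4] - det_crc)
    if (cell$context == "screening") {
      # a missed lesion counts as "no neoplastic polyp detected" for
      # scheduling: the person proceeds towards the second screening exam
      g2 <- if (cell$g == 1L) 2L else if (cell$g == 2L) 3L else cell$g
      U[, cell$s, g2, cell$k] <- U[, cell$s, g2, cell$k] + stay
      # detected adenomas: polypectomy, leave the screening track, enter
      # surveillance with a fresh clock
      U[1, 2, 4, 1] <- U[1, 2, 4, 1] + det_na + det_fp
      U[1, 3, 4, 1] <- U[1, 3, 4, 1] + det_adv
      exams_screening <- exams_screening + tot
      cases_screen <- cases_screen + det_crc
    } else {
      # surveillance exam: clock resets; stratum reassigned by the class
      # of any detected lesion, unchanged for a negative exam
      U[, cell$s, cell$g, 1] <- U[, cell$s, cell$g, 1] + stay
      U[1, 2, cell$g, 1] <- U[1, 2, cell$g, 1] + det_na + det_fp
      U[1, 3, cell$g, 1] <- U[1, 3, cell$g, 1] + det_adv
      exams_surveillance <- exams_surveillance + tot
      cases_surveillance <- cases_surveillance + det_crc
    }
    new_screen_dx <- new_screen_dx + det_crc
  }

  # (2) other-cause death on every living state (including this year's
  # screen-detected diagnoses)
  q <- q_other_at(ps, a)
  other_deaths <- q * (sum(U) + sum(D) + new_screen_dx)
  if (q > 0) {
    U <- U * (1 - q)
    D <- D * (1 - q)
    new_screen_dx <- new_screen_dx * (1 - q)
  }

  # (3) lesion progression on survivors, at most one forward step per year;
  # flows are computed from start-of-step occupancies (update from the top
  # of the chain downward)
  r <- rate_vector(ps, a)
  new_clin <- sum(U[4, , , ]) * r[4]
  U[4, , , ] <- U[4, , , ] * (1 - r[4]) + U[3, , , ] * r[3]
  U[3, , , ] <- U[3, , , ] * (1 - r[3]) + U[2, , , ] * r[2]
  U[2, , , ] <- U[2, , , ] * (1 - r[2]) + U[1, , , ] * r[1]
  U[1, , , ] <- U[1, , , ] * (1 - r[1])

  # (4) cancer death by detection mode and year since diagnosis; diagnosed
  # person-years (for YLD) are counted on post-other-cause-death occupancy,
  # with the death year assigned to the metastatic/terminal phase
  d <- D * sm
  crc_deaths <- sum(d)
  Ds <- D - d
  py_dx <- sum(Ds[, 1])
  py_rem <- sum(Ds[, -1])
  py_term <- crc_deaths

  # year-since-diagnosis shift; this year's diagnoses enter at year 1 and
  # first face cancer mortality next cycle
  ncolD <- ncol(Ds)
  Dn <- Ds
  Dn[, ncolD] <- Ds[, ncolD] + Ds[, ncolD - 1L]
  if (ncolD > 2L) Dn[, 3:(ncolD - 1L)] <- Ds[, 2:(ncolD - 2L)]
  Dn[, 2] <- Ds[, 1]
  Dn[, 1] <- c(new_screen_dx, new_clin)

  # surveillance clocks advance (capped at 10)
  U[, 2:3, , N_CLOCK] <- U[, 2:3, , N_CLOCK] + U[, 2:3, , N_CLOCK - 1L]
  for (k in (N_CLOCK - 1L):2L) U[, 2:3, , k] <- U[, 2:3, , k - 1L]
  U[, 2:3, , 1] <- 0

  state$undiag <- U
  state$diag <- Dn
  state$dead_other <- state$dead_other + other_deaths
  state$dead_crc <- state$dead_crc + crc_deaths
  state$age <- a + 1L

  defect <- abs(sum(U) + sum(Dn) + state$dead_other + state$dead_crc - N)
  if (defect > 1e-9 * N) {
    stop("internal consistency error: mass defect ", defect, " at age ",
         state$age, call. = FALSE)
  }

  tally <- c(age = a,
             cases_clinical = new_clin,
             cases_screen = cases_screen,
             cases_surveillance = cases_surveillance,
             crc_deaths = crc_deaths,
             other_deaths = other_deaths,
             exams_screening = exams_screening,
             exams_surveillance = exams_surveillance,
             py_diagnosis_treatment = py_dx,
             py_remission = py_rem,
             py_metastatic_terminal = py_term)
  list(state = state, tally = tally)
}

#' Advance a cohort state by one year
#'
#' Applies, in order: any scheduled colonoscopies, other-cause death,
#' lesion progression (one forward step at most), cancer death with the
#' year-since-diagnosis increment, and the surveillance-clock increment.
#'
#' @param state A `cohort_state`.
#' @param ps A valid `crc_parameter_set`.
#' @param scenario A `crc_screening_scenario`, or `NULL` for no
#'   intervention; exams due this year are derived with [exams_due()].
#' @return A list with the advanced `state` and a one-row `tally` tibble
#'   (incident cases by detection route, deaths by cause, exams performed,
#'   diagnosed person-years by phase).
#' @export
advance_one_year <- function(state, ps, scenario = NULL) {
  res <- advance_core(state, ps, due_cells(state, scenario),
                      survival_matrix(ps))
  res$tally <- tibble::as_tibble(as.list(res$tally))
  res
}

#' Run a cohort through the simulation horizon
#'
#' Iterates the annual cycle from `start_age` to `end_age`; outcomes
#' accumulate over ages `start_age` to `end_age - 1` inclusive (default
#' 45-84, i.e. the 40-year horizon of a cohort followed from 45 to 85).
#'
#' @param ps A valid `crc_parameter_set`.
#' @param scenario A `crc_screening_scenario` or `NULL` (no screening).
#' @param start_age,end_age Simulation window in years of age.
#' @param keep_trajectory Keep the full per-age `cohort_state` list
#'   (default `FALSE`; the per-age tallies are always kept).
#' @return An object of class `crc_run`: per-age tallies, the final state,
#'   optionally the trajectory, and run metadata.
#' @export
run_cohort <- function(ps, scenario = NULL, start_age = 45L, end_age = 85L,
                       keep_trajectory = FALSE) {
  if (start_age < 45 || end_age <= start_age) {
    stop("require 45 <= start_age < end_age", call. = FALSE)
  }
  if (!is.null(scenario)) validate_scenario(scenario, start_age, end_age)
  sm <- survival_matrix(ps)
  state <- cohort_state_init(ps, start_age)
  n_years <- end_age - start_age
  tallies <- matrix(NA_real_, nrow = n_years, ncol = length(TALLY_FIELDS),
                    dimnames = list(NULL, TALLY_FIELDS))
  trajectory <- if (keep_trajectory) vector("list", n_years + 1L) else NULL
  if (keep_trajectory) trajectory[[1]] <- state
  for (i in seq_len(n_years)) {
    res <- advance_core(state, ps, due_cells(state, scenario), sm)
    state <- res$state
    tallies[i, ] <- res$tally
    if (keep_trajectory) trajectory[[i + 1L]] <- state
  }
  structure(
    list(
      tallies = tibble::as_tibble(as.data.frame(tallies)),
      final_state = state,
      trajectory = trajectory,
      scenario = scenario,
      ps = ps,
      label = scenario_label(scenario)
    ),
    class = "crc_run"
  )
}

#' @export
print.crc_run <- function(x, ...) {
  s <- summarize_outcomes(x)
  cat("<crc_run>", x$ps$sex, "cohort of", format(x$ps$cohort_size, big.mark = ","),
      "| scenario:", x$label, "\n")
  cat(sprintf("  cases %.0f | deaths %.0f | YPLL %.0f | DALYs %.0f | exams %.0f\n",
              s$cases, s$deaths, s$ypll, s$dalys,
              s$colonoscopies_screening + s$colonoscopies_surveillance))
  invisible(x)
}
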
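# Screening-colonoscopy intervention logic: the two-lifetime-exam
# constraint, detection and polypectomy at an exam, and 3-/10-year
# post-polypectomy surveillance scheduling.

#' Define a screening-colonoscopy scenario
#'
#' A scenario offers at most two lifetime screening colonoscopies: the
#' first at `first_age`, and a second at `second_age` only to persons whose
#' first exam detected nothing. Persons with adenomas detected (and
#' removed) at any exam leave the screening track and instead undergo
#' surveillance colonoscopies every 3 years (after an advanced-adenoma
#' finding) or 10 years (after a non-advanced finding); surveillance exams
#' are not capped. No exam of any kind is offered at or beyond `age_limit`.
#'
#' @param first_age Age at first screening colonoscopy.
#' @param second_age Age at second screening colonoscopy (or `NULL` for a
#'   single-exam scenario).
#' @param surveillance_interval_advanced Years between surveillance exams
#'   after an advanced-adenoma polypectomy (default 3).
#' @param surveillance_interval_nonadvanced As above after a non-advanced
#'   finding (default 10; at most 10).
#' @param age_limit No exams at or after this age (default 85, following
#'   guideline practice of discouraging screening beyond 85).
#' @param max_screening_cs Lifetime cap on screening colonoscopies; the
#'   scheduling strata implement a cap of 2.
#' @return An object of class `crc_screening_scenario`.
#' @export
screening_scenario <- function(first_age, second_age = NULL,
                               surveillance_interval_advanced = 3L,
                               surveillance_interval_nonadvanced = 10L,
                               age_limit = 85L,
                               max_screening_cs = 2L) {
  sc <- structure(
    list(first_age = as.integer(first_age),
         second_age = if (!is.null(second_age)) as.integer(second_age),
         surveillance_interval_advanced = as.integer(surveillance_interval_advanced),
         surveillance_interval_nonadvanced = as.integer(surveillance_interval_nonadvanced),
         age_limit = as.integer(age_limit),
         max_screening_cs = as.integer(max_screening_cs)),
    class = "crc_screening_scenario"
  )
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc, start_age = 45L, end_age = 85L) {
  if (sc$first_age < start_age) {
    stop("first_age must be >= ", start_age, call. = FALSE)
  }
  if (!is.null(sc$second_age)) {
    if (sc$second_age <= sc$first_age) {
      stop("second_age must exceed first_age", call. = FALSE)
    }
    if (sc$second_age >= sc$age_limit) {
      stop("second_age must be below the age limit (", sc$age_limit, ")",
           call. = FALSE)
    }
  }
  if (sc$first_age >= sc$age_limit) {
    stop("first_age must be below the age limit", call. = FALSE)
  }
  if (sc$surveillance_interval_advanced < 1 ||
      sc$surveillance_interval_nonadvanced < 1 ||
      sc$surveillance_interval_nonadvanced > 10) {
    stop("surveillance intervals must be in 1..10 years", call. = FALSE)
  }
  if (sc$max_screening_cs != 2L) {
    stop("the scheduling strata implement exactly two lifetime screening exams",
         call. = FALSE)
  }
  invisible(sc)
}

scenario_label <- function(sc) {
  if (is.null(sc)) return("no_screening")
  if (is.null(sc$second_age)) return(paste0(sc$first_age, "/-"))
  paste0(sc$first_age, "/", sc$second_age)
}

#' @export
print.crc_screening_scenario <- function(x, ...) {
  cat("<crc_screening_scenario>", scenario_label(x), "\n")
  cat("  surveillance: advanced every", x$surveillance_interval_advanced,
      "y, non-advanced every", x$surveillance_interval_nonadvanced,
      "y; age limit", x$age_limit, "\n")
  invisible(x)
}

#' The nine-scenario grid of two-exam strategies
#'
#' All combinations of starting age and inter-exam interval evaluated in
#' the default experiment: intervals of 10 years (first exam at 45, 50, 55
#' or 60), 15 years (45, 50 or 55) and 20 years (45 or 50), with the second
#' exam always before the age limit of 85.
#'
#' @return A tibble with columns `interval`, `first_age`, `second_age` and
#'   a list-column `scenario` of `crc_screening_scenario` objects.
#' @export
scenario_grid <- function() {
  grid <- tibble::tibble(
    interval = c(10L, 10L, 10L, 10L, 15L, 15L, 15L, 20L, 20L),
    first_age = c(45L, 50L, 55L, 60L, 45L, 50L, 55L, 45L, 50L)
  )
  grid$second_age <- grid$first_age + grid$interval
  grid$scenario <- purrr::map2(grid$first_age, grid$second_age,
                               screening_scenario)
  grid
}

#' Which exam cells are due this year?
#'
#' Screening exams are due at `first_age` for persons with no screening
#' history and at `second_age` for persons whose single previous screening
#' exam was negative. Surveillance exams are due whenever a
#' post-polypectomy surveillance clock has reached its interval. Diagnosed
#' and dead persons are never due, and nothing is due at or after the age
#' limit.
#'
#' @param state A `cohort_state`.
#' @param scenario A `crc_screening_scenario` or `NULL`.
#' @return A tibble with one row per due cell: `context`, `surv_stratum`,
#'   `screen_stratum`, `clock`, `occupancy`.
#' @export
exams_due <- function(state, scenario) {
  cells <- due_cells(state, scenario)
  if (length(cells) == 0) {
    return(tibble::tibble(context = character(), surv_stratum = character(),
                          screen_stratum = character(), clock = integer(),
                          occupancy = double()))
  }
  purrr::map_dfr(cells, function(cell) {
    tibble::tibble(
      context = cell$context,
      surv_stratum = SURV_STRATA[cell$s],
      screen_stratum = SCREEN_STRATA[cell$g],
      clock = cell$k - 1L,
      occupancy = sum(state$undiag[, cell$s, cell$g, cell$k])
    )
  })
}

#' Apply a colonoscopy to a slice of examinees
#'
#' Splits examinee occupancy by true state into detected and undetected
#' fractions and reports where each fraction is routed: detected adenomas
#' are removed (polypectomy) and enter the corresponding surveillance
#' stratum; detected preclinical cancer is diagnosed (screen-detected) and
#' counted as an incident case; missed lesions remain in state and, at a
#' screening exam, are scheduled as if the exam had been negative. With
#' perfect specificity no lesion-free examinee is touched; with imperfect
#' specificity the false-positive fraction is routed to non-advanced
#' surveillance (an unnecessary polypectomy) without a state change.
#'
#' @param examinees Numeric vector of length 4: occupancy by true state
#'   (`no_lesion`, `nonadv_adenoma`, `adv_adenoma`, `preclinical_crc`).
#' @param performance One-row tibble as from [default_performance()].
#' @param context `"screening"` or `"surveillance"` (affects scheduling,
#'   reported for bookkeeping).
#' @return A list with `dispositions` (tibble: `true_state`, `disposition`,
#'   `persons`) and `split` (tibble of within-state fractions, each row
#'   summing to 1 across `fraction_negative` + `fraction_detected`).
#' @export
apply_colonoscopy <- function(examinees, performance,
                              context = c("screening", "surveillance")) {
  context <- match.arg(context)
  stopifnot(length(examinees) == 4, all(examinees >= 0))
  p_det <- c(1 - performance$specificity, performance$sens_na,
             performance$sens_advanced, performance$sens_advanced)
  detected <- examinees * p_det
  stay <- examinees - detected
  dispositions <- tibble::tibble(
    true_state = rep(UNDIAG_STATES, 2L),
    disposition = c(rep("stay", 4L),
                    "polypectomy_nonadvanced", "polypectomy_nonadvanced",
                    "polypectomy_advanced", "diagnosed_screen_detected"),
    persons = c(stay, detected)
  )
  split <- tibble::tibble(
    true_state = UNDIAG_STATES,
    fraction_negative = ifelse(examinees > 0, stay / examinees,
                               1 - p_det),
    fraction_detected = ifelse(examinees > 0, detected / examinees, p_det)
  )
  list(dispositions = dispositions, split = split, context = context)
}

#' Run one screening scenario end to end
#'
#' Composes exam scheduling and colonoscopy application into the cohort
#' engine and summarises the burden outcomes.
#'
#' @param ps A valid `crc_parameter_set`.
#' @param scenario A `crc_screening_scenario` or `NULL` for no screening.
#' @param ... Passed to [run_cohort()].
#' @return A `crc_run` whose `summary` element holds the one-row
#'   [summarize_outcomes()] tibble.
#' @export
run_screening_scenario <- function(ps, scenario = NULL, ...) {
  run <- run_cohort(ps, scenario, ...)
  run$summary <- summarize_outcomes(run)
  run
}
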
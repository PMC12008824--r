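# Burden-of-disease accounting: YPLL, YLD, DALYs and the comparison
# statistics versus a reference strategy.

#' Years of potential life lost
#'
#' YPLL is the sum over ages of cancer deaths at that age multiplied by the
#' residual life expectancy at that age (taken from the life table at the
#' integer age of death, without interpolation).
#'
#' @param crc_deaths_by_age Tibble with columns `age` and `deaths`.
#' @param life_table Life-table tibble (`age`, `q_other`, `le_resid`).
#' @return YPLL in years (a single number).
#' @export
compute_ypll <- function(crc_deaths_by_age, life_table) {
  i <- match(crc_deaths_by_age$age, life_table$age)
  if (anyNA(i)) {
    stop("ages outside the life table: ",
         paste(crc_deaths_by_age$age[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  sum(crc_deaths_by_age$deaths * life_table$le_resid[i])
}

#' Years lived with disability
#'
#' YLD is the sum over diagnosed-cancer phases of person-years lived in
#' that phase multiplied by the phase's disability weight. The engine
#' assigns the first year after diagnosis to `diagnosis_treatment`,
#' subsequent diagnosed years to `remission`, and the year of cancer death
#' to `metastatic_terminal`.
#'
#' @param person_years_by_phase Tibble with columns `phase` and
#'   `person_years`.
#' @param disability_weights Tibble with columns `phase` and `weight`.
#' @return YLD in years (a single number).
#' @export
compute_yld <- function(person_years_by_phase, disability_weights) {
  i <- match(person_years_by_phase$phase, disability_weights$phase)
  if (anyNA(i)) {
    stop("unknown phase(s): ",
         paste(person_years_by_phase$phase[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  sum(person_years_by_phase$person_years * disability_weights$weight[i])
}

#' Summarise a cohort run into the four burden outcomes
#'
#' Cumulative incident cancer cases and cancer deaths over the simulated
#' ages, YPLL, YLD, and DALYs = YPLL + YLD, plus colonoscopy counts.
#'
#' @param run A `crc_run` (deterministic or stochastic), or a tally tibble
#'   in which case `ps` must be given.
#' @param ps Parameter set supplying the life table and disability weights
#'   (taken from `run` when omitted).
#' @param label Scenario label (taken from `run` when omitted).
#' @return A one-row tibble: `label`, `sex`, `cases`, `deaths`, `ypll`,
#'   `yld`, `dalys`, `colonoscopies_screening`, `colonoscopies_surveillance`.
#' @export
summarize_outcomes <- function(run, ps = NULL, label = NULL) {
  if (inherits(run, "crc_run") || inherits(run, "crc_run_stochastic")) {
    tallies <- run$tallies
    if (is.null(ps)) ps <- run$ps
    if (is.null(label)) label <- run$label
  } else {
    tallies <- run
    if (is.null(ps)) stop("ps must be supplied with raw tallies", call. = FALSE)
    if (is.null(label)) label <- "run"
  }
  ypll <- compute_ypll(
    tibble::tibble(age = tallies$age, deaths = tallies$crc_deaths),
    ps$life_table
  )
  yld <- compute_yld(
    tibble::tibble(
      phase = CRC_PHASES,
      person_years = c(sum(tallies$py_diagnosis_treatment),
                       sum(tallies$py_remission),
                       sum(tallies$py_metastatic_terminal))
    ),
    ps$disability_weights
  )
  tibble::tibble(
    label = label,
    sex = ps$sex,
    cases = sum(tallies$cases_clinical + tallies$cases_screen +
                  tallies$cases_surveillance),
    deaths = sum(tallies$crc_deaths),
    ypll = ypll,
    yld = yld,
    dalys = ypll + yld,
    colonoscopies_screening = sum(tallies$exams_screening),
    colonoscopies_surveillance = sum(tallies$exams_surveillance)
  )
}

#' Signed percent change versus a reference
#'
#' Returns `100 * (value / reference - 1)` rounded to the nearest integer,
#' halves away from zero, as used in strategy-comparison tables.
#'
#' @param value,reference Outcome counts; `reference` must be positive.
#' @return Integer signed percent, vectorised.
#' @export
relative_change <- function(value, reference) {
  if (any(reference <= 0)) stop("reference must be positive", call. = FALSE)
  # (value - reference) first: exact for integer inputs, so printed-table
  # halves (e.g. +1.5%) round predictably
  pct <- 100 * (value - reference) / reference
  as.integer(sign(pct) * floor(abs(pct) + 0.5))
}

#' Format a signed percent change for a report table
#'
#' Positive changes get an explicit `+`, a change rounding to zero prints
#' as `±0%`, and `NA` (the reference row itself) prints as an em dash.
#'
#' @param pct Integer percent change, as from [relative_change()].
#' @return Character vector.
#' @export
format_change <- function(pct) {
  dplyr::case_when(
    is.na(pct) ~ "—",
    pct == 0 ~ "±0%",
    pct > 0 ~ paste0("+", pct, "%"),
    TRUE ~ paste0("−", abs(pct), "%")
  )
}
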
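#' Default colonoscopy performance
#'
#' Detection sensitivity of 75% for non-advanced adenomas and 95% for
#' advanced neoplasms (advanced adenomas and preclinical cancer), with
#' ideal (100%) specificity, as established by tandem-colonoscopy miss-rate
#' studies.
#'
#' @return A one-row tibble with columns `sens_na`, `sens_advanced`,
#'   `specificity`.
#' @export
default_performance <- function() {
  tibble::tibble(sens_na = 0.75, sens_advanced = 0.95, specificity = 1.0)
}

#' Default disability weights for the diagnosed-cancer phases
#'
#' Phase weights follow the global burden-of-disease convention for cancer:
#' diagnosis and primary therapy, controlled disease (remission), and
#' metastatic/terminal disease. The numeric values are documented
#' placeholders in the usual range for colorectal cancer; users reproducing
#' a specific published analysis should substitute the weights that
#' analysis applied.
#'
#' @return A tibble with columns `phase` and `weight`.
#' @export
default_disability_weights <- function() {
  tibble::tibble(
    phase = CRC_PHASES,
    weight = c(0.288, 0.049, 0.451)
  )
}

#' Assemble a complete model parameter set for one sex
#'
#' Bundles every input the cohort engine needs: annual lesion transition
#' probabilities by 5-year age group, starting prevalences at age 45,
#' colonoscopy performance, annual post-diagnosis cancer mortality by
#' detection mode and year since diagnosis, a population life table, and
#' disability weights.
#'
#' @param sex `"male"` or `"female"`.
#' @param transition_rates Tibble with columns `age_group` (the eight
#'   5-year bands `"45-49"` ... `"80+"`) and the four annual transition
#'   probabilities `r_none_to_na`, `r_na_to_adv`, `r_adv_to_pre`,
#'   `r_pre_to_clin`.
#' @param starting_prevalence One-row tibble with `p_na_45`, `p_adv_45`,
#'   `p_pre_45`: prevalences of non-advanced adenoma, advanced adenoma and
#'   preclinical cancer at age 45.
#' @param performance One-row tibble as from [default_performance()].
#' @param crc_survival Tibble with columns `detection_mode`
#'   (`"screen_detected"`, `"clinically_detected"`), `year_since_dx`
#'   (`"1"` ... `"<y_max>"` and `"beyond"`) and `p_crc_death`, the annual
#'   probability of cancer death.
#' @param life_table Tibble with columns `age` (single years, 45 upward,
#'   covering at least 45-85), `q_other` (annual other-cause mortality
#'   probability) and `le_resid` (residual life expectancy in years).
#' @param disability_weights Tibble as from [default_disability_weights()].
#' @param cohort_size Number of persons entering the cohort at age 45.
#' @param validate If `TRUE` (default), stop on any invariant violation.
#'
#' @return An object of class `crc_parameter_set`.
#' @export
crc_parameter_set <- function(sex,
                              transition_rates,
                              starting_prevalence,
                              performance = default_performance(),
                              crc_survival,
                              life_table,
                              disability_weights = default_disability_weights(),
                              cohort_size = 1e5,
                              validate = TRUE) {
  ps <- structure(
    list(
      sex = sex,
      cohort_size = cohort_size,
      transition_rates = tibble::as_tibble(transition_rates),
      starting_prevalence = tibble::as_tibble(starting_prevalence),
      performance = tibble::as_tibble(performance),
      crc_survival = tibble::as_tibble(crc_survival),
      life_table = tibble::as_tibble(life_table),
      disability_weights = tibble::as_tibble(disability_weights)
    ),
    class = "crc_parameter_set"
  )
  if (validate) assert_parameter_set(ps)
  ps
}

#' @export
print.crc_parameter_set <- function(x, ...) {
  cat("<crc_parameter_set>\n")
  cat("  sex:         ", x$sex, "\n")
  cat("  cohort size: ", format(x$cohort_size, big.mark = ","), "\n")
  cat("  age groups:  ", nrow(x$transition_rates), "\n")
  cat("  life table:  ages", min(x$life_table$age), "-",
      max(x$life_table$age), "\n")
  sp <- x$starting_prevalence
  cat(sprintf("  start prevalence (45): NA %.4f, Adv %.4f, Pre %.4f\n",
              sp$p_na_45, sp$p_adv_45, sp$p_pre_45))
  invisible(x)
}

violation <- function(code, table, where, message) {
  tibble::tibble(code = code, table = table, where = where, message = message)
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter tables (probability bounds,
#' completeness of the eight age groups, prevalence sum, matching survival
#' year ranges across detection modes, life-table monotonicity) and reports
#' violations instead of throwing.
#'
#' @param ps A `crc_parameter_set`.
#' @return A tibble of violations with machine-readable `code`, the `table`
#'   and cell (`where`) concerned, and a human-readable `message`. Zero
#'   rows means the set is valid.
#' @export
validate_parameter_set <- function(ps) {
  out <- list()
  add <- function(v) out[[length(out) + 1L]] <<- v

  if (!ps$sex %in% c("male", "female")) {
    add(violation("bad_sex", "manifest", "sex",
                  paste0("sex must be 'male' or 'female', got '", ps$sex, "'")))
  }
  if (!is.numeric(ps$cohort_size) || length(ps$cohort_size) != 1 ||
      is.na(ps$cohort_size) || ps$cohort_size <= 0) {
    add(violation("bad_cohort_size", "manifest", "cohort_size",
                  "cohort_size must be a single positive number"))
  }

  # transition rates: all eight groups, in order, all four probabilities in [0,1]
  tr <- ps$transition_rates
  if (!identical(tr$age_group, AGE_GROUP_LABELS)) {
    add(violation("age_groups_incomplete", "transition_rates", "age_group",
                  paste0("age_group must be exactly: ",
                         paste(AGE_GROUP_LABELS, collapse = ", "))))
  }
  for (tn in TRANSITION_NAMES) {
    if (!tn %in% names(tr)) {
      add(violation("missing_column", "transition_rates", tn,
                    paste0("missing transition column ", tn)))
      next
    }
    bad <- which(is.na(tr[[tn]]) | tr[[tn]] < 0 | tr[[tn]] > 1)
    for (i in bad) {
      add(violation("rate_out_of_range", "transition_rates",
                    paste0(tn, "[", tr$age_group[i], "]"),
                    sprintf("%s for age group %s is %g, outside [0, 1]",
                            tn, tr$age_group[i], tr[[tn]][i])))
    }
  }

  # starting prevalence
  sp <- ps$starting_prevalence
  for (pn in c("p_na_45", "p_adv_45", "p_pre_45")) {
    v <- sp[[pn]]
    if (is.null(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      add(violation("prevalence_out_of_range", "starting_prevalence", pn,
                    paste0(pn, " must be a single value in [0, 1]")))
    }
  }
  tot <- sum(sp$p_na_45, sp$p_adv_45, sp$p_pre_45)
  if (is.finite(tot) && tot > 1) {
    add(violation("prevalence_sum", "starting_prevalence", "p_na_45+p_adv_45+p_pre_45",
                  sprintf("starting prevalences sum to %g > 1", tot)))
  }

  # colonoscopy performance
  pf <- ps$performance
  for (pn in c("sens_na", "sens_advanced", "specificity")) {
    v <- pf[[pn]]
    if (is.null(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      add(violation("performance_out_of_range", "performance", pn,
                    paste0(pn, " must be a single value in [0, 1]")))
    }
  }

  # survival schedule: both modes present, same year set, probabilities in range
  sv <- ps$crc_survival
  modes <- unique(sv$detection_mode)
  for (m in DETECTION_MODES) {
    if (!m %in% modes) {
      add(violation("missing_detection_mode", "crc_survival", m,
                    paste0("detection mode ", m, " absent from crc_survival")))
    }
  }
  yr_sets <- split(sv$year_since_dx, sv$detection_mode)
  if (length(yr_sets) > 1) {
    ref_years <- sort(yr_sets[[1]])
    same <- vapply(yr_sets, function(y) identical(sort(y), ref_years), logical(1))
    if (!all(same)) {
      add(violation("mode_year_mismatch", "crc_survival", "year_since_dx",
                    "detection modes do not cover the same years since diagnosis"))
    }
  }
  bad <- which(is.na(sv$p_crc_death) | sv$p_crc_death < 0 | sv$p_crc_death > 1)
  for (i in bad) {
    add(violation("survival_out_of_range", "crc_survival",
                  paste0(sv$detection_mode[i], "[", sv$year_since_dx[i], "]"),
                  sprintf("p_crc_death for %s year %s is %g, outside [0, 1]",
                          sv$detection_mode[i], sv$year_since_dx[i],
                          sv$p_crc_death[i])))
  }

  # life table: contiguous single years from 45 covering at least 45-85,
  # q in [0,1], positive and non-increasing residual life expectancy
  lt <- ps$life_table
  ages <- lt$age
  if (length(ages) == 0 || min(ages) > 45 || max(ages) < 85 ||
      !identical(as.integer(ages), seq.int(min(ages), max(ages)))) {
    add(violation("life_table_coverage", "life_table", "age",
                  "life table must cover single years of age spanning at least 45-85"))
  }
  bad <- which(is.na(lt$q_other) | lt$q_other < 0 | lt$q_other > 1)
  for (i in bad) {
    add(violation("q_out_of_range", "life_table", paste0("q_other[age ", ages[i], "]"),
                  sprintf("q_other at age %d is %g, outside [0, 1]",
                          as.integer(ages[i]), lt$q_other[i])))
  }
  bad <- which(is.na(lt$le_resid) | lt$le_resid <= 0)
  for (i in bad) {
    add(violation("le_nonpositive", "life_table", paste0("le_resid[age ", ages[i], "]"),
                  sprintf("le_resid at age %d must be > 0", as.integer(ages[i]))))
  }
  if (nrow(lt) > 1) {
    inc <- which(diff(lt$le_resid) > 1e-9)
    for (i in inc) {
      add(violation("le_increasing", "life_table",
                    paste0("le_resid[age ", ages[i], "->", ages[i + 1], "]"),
                    sprintf("le_resid increases from age %d (%.4f) to %d (%.4f)",
                            as.integer(ages[i]), lt$le_resid[i],
                            as.integer(ages[i + 1]), lt$le_resid[i + 1])))
    }
  }

  # disability weights
  dw <- ps$disability_weights
  for (ph in CRC_PHASES) {
    if (!ph %in% dw$phase) {
      add(violation("missing_phase", "disability_weights", ph,
                    paste0("phase ", ph, " absent from disability_weights")))
    }
  }
  bad <- which(is.na(dw$weight) | dw$weight < 0 | dw$weight > 1)
  for (i in bad) {
    add(violation("weight_out_of_range", "disability_weights", dw$phase[i],
                  sprintf("weight for phase %s is %g, outside [0, 1]",
                          dw$phase[i], dw$weight[i])))
  }

  if (length(out) == 0) {
    violation(character(), character(), character(), character())
  } else {
    dplyr::bind_rows(out)
  }
}

assert_parameter_set <- function(ps) {
  rep <- validate_parameter_set(ps)
  if (nrow(rep) > 0) {
    stop("invalid parameter set:\n",
         paste0("  [", rep$code, "] ", rep$table, "/", rep$where, ": ",
                rep$message, collapse = "\n"),
         call. = FALSE)
  }
  invisible(ps)
}

#' Look up an annual transition probability by exact age
#'
#' Transition probabilities are stored per 5-year age group. Ages 85 and
#' above use the open-ended 80+ group (outcomes are only accumulated to age
#' 84, but the engine can evaluate any age). Ages 45-54 return the values
#' stored for their own bands; synthetic generation copies the 55-59
#' estimates down into those bands, mirroring how registry-derived rates
#' are extended below the youngest observed screening ages.
#'
#' @param transition_rates The `transition_rates` tibble of a parameter set.
#' @param transition One of `"r_none_to_na"`, `"r_na_to_adv"`,
#'   `"r_adv_to_pre"`, `"r_pre_to_clin"`.
#' @param age Integer age(s) in years, each >= 45.
#' @return Annual transition probability, vectorised over `age`.
#' @export
lookup_rate <- function(transition_rates, transition, age) {
  transition <- match.arg(transition, TRANSITION_NAMES)
  if (any(age < 45)) {
    stop("lookup_rate: age must be >= 45 (got ",
         paste(age[age < 45], collapse = ", "), ")", call. = FALSE)
  }
  grp <- pmin(findInterval(age, AGE_GROUP_LOWER), length(AGE_GROUP_LOWER))
  transition_rates[[transition]][grp]
}

# Age-indexed lookups used by the engines -----------------------------------

rate_vector <- function(ps, age) {
  grp <- min(findInterval(age, AGE_GROUP_LOWER), length(AGE_GROUP_LOWER))
  c(ps$transition_rates$r_none_to_na[grp],
    ps$transition_rates$r_na_to_adv[grp],
    ps$transition_rates$r_adv_to_pre[grp],
    ps$transition_rates$r_pre_to_clin[grp])
}

q_other_at <- function(ps, age) {
  i <- match(age, ps$life_table$age)
  if (is.na(i)) stop("age ", age, " outside life table", call. = FALSE)
  ps$life_table$q_other[i]
}

# Survival schedule as a matrix: rows = screen_detected, clinically_detected;
# columns = years since diagnosis 1..y_max plus a final "beyond" column.
survival_matrix <- function(ps) {
  sv <- ps$crc_survival
  yrs <- unique(sv$year_since_dx)
  num <- suppressWarnings(as.integer(yrs[yrs != "beyond"]))
  y_max <- max(num)
  cols <- c(as.character(seq_len(y_max)), "beyond")
  m <- matrix(NA_real_, nrow = 2, ncol = y_max + 1L,
              dimnames = list(DETECTION_MODES, cols))
  for (mode in DETECTION_MODES) {
    sub <- sv[sv$detection_mode == mode, ]
    m[mode, ] <- sub$p_crc_death[match(cols, sub$year_since_dx)]
  }
  if (anyNA(m)) stop("crc_survival does not cover years 1..", y_max,
                     " plus 'beyond' for both detection modes", call. = FALSE)
  m
}
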
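# Individual-level Bernoulli microsimulation with the same annual event
# order as the deterministic engine. Serves as a validation harness: its
# replicate means must agree with the deterministic expected-value engine
# within Monte-Carlo error. Fully vectorised over individuals.

#' Run an individual-level stochastic cohort
#'
#' Simulates `n_individuals` persons through the identical annual event
#' sequence as [run_cohort()] (exams, other-cause death, lesion
#' progression, cancer death), drawing every event as a Bernoulli trial.
#' Reproducible given `seed`.
#'
#' @param ps A valid `crc_parameter_set` (its `cohort_size` is ignored in
#'   favour of `n_individuals`).
#' @param scenario A `crc_screening_scenario` or `NULL`.
#' @param n_individuals Number of simulated persons.
#' @param seed Integer seed.
#' @param start_age,end_age Simulation window.
#' @return An object of class `crc_run_stochastic`: per-age `tallies`
#'   (same schema as the deterministic engine, in whole persons), the
#'   per-individual count of lifetime screening exams (`screens_used`),
#'   and run metadata.
#' @export
run_cohort_stochastic <- function(ps, scenario = NULL, n_individuals = 10000L,
                                  seed = 1L, start_age = 45L, end_age = 85L) {
  if (!is.null(scenario)) validate_scenario(scenario, start_age, end_age)
  n <- as.integer(n_individuals)
  sm <- survival_matrix(ps)
  y_beyond <- ncol(sm)
  perf <- ps$performance
  p_det_by_state <- c(1 - perf$specificity, perf$sens_na,
                      perf$sens_advanced, perf$sens_advanced)

  withr::with_seed(seed, {
    sp <- ps$starting_prevalence
    st <- sample.int(4L, n, replace = TRUE,
                     prob = c(1 - sp$p_na_45 - sp$p_adv_45 - sp$p_pre_45,
                              sp$p_na_45, sp$p_adv_45, sp$p_pre_45))
    dead <- integer(n)        # 0 alive, 1 other-cause, 2 cancer
    diag <- logical(n)
    mode <- integer(n)        # 1 screen-detected, 2 clinically detected
    ysd <- integer(n)         # 0 = diagnosed this year
    surv <- rep(1L, n)        # surveillance stratum index
    scr <- rep(1L, n)         # screening-history stratum index
    clock <- integer(n)
    screens_used <- integer(n)

    ages <- seq.int(start_age, end_age - 1L)
    tallies <- matrix(0, nrow = length(ages), ncol = length(TALLY_FIELDS),
                      dimnames = list(NULL, TALLY_FIELDS))
    tallies[, "age"] <- ages

    for (i in seq_along(ages)) {
      a <- ages[i]

      # (1) exams
      if (!is.null(scenario) && a < scenario$age_limit) {
        eligible <- dead == 0L & !diag
        due_screen <- eligible &
          ((a == scenario$first_age & scr == 1L) |
             (!is.null(scenario$second_age) &&
                a == scenario$second_age) & scr == 2L)
        due_surv <- eligible & !due_screen &
          ((surv == 2L & clock >= scenario$surveillance_interval_nonadvanced) |
             (surv == 3L & clock >= scenario$surveillance_interval_advanced))
        for (ctx in c("screening", "surveillance")) {
          idx <- which(if (ctx == "screening") due_screen else due_surv)
          if (length(idx) == 0) next
          u <- stats::runif(length(idx))
          det <- u < p_det_by_state[st[idx]]
          i_det <- idx[det]
          i_neg <- idx[!det]
          if (ctx == "screening") {
            screens_used[idx] <- screens_used[idx] + 1L
            tallies[i, "exams_screening"] <-
              tallies[i, "exams_screening"] + length(idx)
            # negatives (including missed lesions) advance along the
            # screening track
            scr[i_neg] <- ifelse(scr[i_neg] == 1L, 2L,
                                 ifelse(scr[i_neg] == 2L, 3L, scr[i_neg]))
            scr[i_det] <- 4L
          } else {
            tallies[i, "exams_surveillance"] <-
              tallies[i, "exams_surveillance"] + length(idx)
            clock[i_neg] <- 0L
          }
          if (length(i_det) > 0) {
            s_det <- st[i_det]
            # polypectomy for detected adenomas (and false positives)
            poly_na <- i_det[s_det <= 2L]
            poly_adv <- i_det[s_det == 3L]
            found_crc <- i_det[s_det == 4L]
            st[poly_na] <- 1L; surv[poly_na] <- 2L; clock[poly_na] <- 0L
            st[poly_adv] <- 1L; surv[poly_adv] <- 3L; clock[poly_adv] <- 0L
            diag[found_crc] <- TRUE
            mode[found_crc] <- 1L
            ysd[found_crc] <- 0L
            col <- if (ctx == "screening") "cases_screen" else "cases_surveillance"
            tallies[i, col] <- tallies[i, col] + length(found_crc)
          }
        }
      }

      # (2) other-cause death
      q <- q_other_at(ps, a)
      if (q > 0) {
        alive <- which(dead == 0L)
        die <- alive[stats::runif(length(alive)) < q]
        dead[die] <- 1L
        tallies[i, "other_deaths"] <- length(die)
      }

      # (3) lesion progression (one forward step at most)
      r <- rate_vector(ps, a)
      undx <- which(dead == 0L & !diag)
      if (length(undx) > 0) {
        move <- stats::runif(length(undx)) < r[st[undx]]
        movers <- undx[move]
        to_clin <- movers[st[movers] == 4L]
        st[movers] <- st[movers] + 1L
        st[to_clin] <- 4L  # state bookkeeping irrelevant once diagnosed
        diag[to_clin] <- TRUE
        mode[to_clin] <- 2L
        ysd[to_clin] <- 0L
        tallies[i, "cases_clinical"] <- length(to_clin)
      }

      # (4) cancer death for established diagnoses (ysd >= 1) and
      # person-years by phase
      dx <- which(dead == 0L & diag & ysd >= 1L)
      if (length(dx) > 0) {
        p <- sm[cbind(mode[dx], pmin(ysd[dx], y_beyond))]
        die <- stats::runif(length(dx)) < p
        i_die <- dx[die]
        dead[i_die] <- 2L
        tallies[i, "crc_deaths"] <- length(i_die)
        i_live <- dx[!die]
        tallies[i, "py_metastatic_terminal"] <- length(i_die)
        tallies[i, "py_diagnosis_treatment"] <- sum(ysd[i_live] == 1L)
        tallies[i, "py_remission"] <- sum(ysd[i_live] >= 2L)
      }

      # clocks advance
      adv_ysd <- dead == 0L & diag
      ysd[adv_ysd] <- ysd[adv_ysd] + 1L
      adv_clock <- dead == 0L & !diag & surv > 1L
      clock[adv_clock] <- pmin(clock[adv_clock] + 1L, 10L)
    }

    structure(
      list(tallies = tibble::as_tibble(as.data.frame(tallies)),
           screens_used = screens_used,
           n_individuals = n, seed = seed, scenario = scenario, ps = ps,
           label = scenario_label(scenario)),
      class = "crc_run_stochastic"
    )
  })
}

#' @export
print.crc_run_stochastic <- function(x, ...) {
  cat("<crc_run_stochastic>", x$ps$sex, "n =", x$n_individuals,
      "| seed", x$seed, "| scenario:", x$label, "\n")
  cat(sprintf("  cases %d | crc deaths %d | max screening exams/person %d\n",
              as.integer(sum(x$tallies$cases_clinical +
                               x$tallies$cases_screen +
                               x$tallies$cases_surveillance)),
              as.integer(sum(x$tallies$crc_deaths)),
              max(x$screens_used)))
  invisible(x)
}
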
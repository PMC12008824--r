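# Orchestration of the full strategy grid (no screening + the nine
# two-exam scenarios, separately per sex) and the strategy-comparison
# tables.

#' Run the full screening-strategy experiment
#'
#' Runs a no-screening comparator plus every scenario of the grid for each
#' supplied sex-specific parameter set, and computes signed percent changes
#' of all four burden outcomes versus the reference strategy of that sex
#' (defaults: men first/second exam at 50/60, women at 55/65, the earliest
#' use of a typical statutory two-exam offer). Deterministic mode is
#' bit-reproducible; stochastic mode uses `seed`.
#'
#' @param bundles Named list of `crc_parameter_set` objects, e.g.
#'   `list(male = ps_m, female = ps_f)` (any non-empty subset).
#' @param grid Scenario grid as from [scenario_grid()].
#' @param reference Named list giving `c(first_age, second_age)` of the
#'   reference scenario per sex; must be a member of the grid.
#' @param engine `"deterministic"` or `"stochastic"`.
#' @param seed,n_individuals Used in stochastic mode only.
#' @return An object of class `crc_experiment` with a `summaries` tibble
#'   (one row per sex x strategy: absolute outcomes, percent changes,
#'   `is_reference`) and metadata including a parameter-bundle hash per sex
#'   for traceability.
#' @export
run_experiment <- function(bundles,
                           grid = scenario_grid(),
                           reference = list(male = c(50L, 60L),
                                            female = c(55L, 65L)),
                           engine = c("deterministic", "stochastic"),
                           seed = 1L, n_individuals = 10000L) {
  engine <- match.arg(engine)
  stopifnot(length(bundles) >= 1, !is.null(names(bundles)))
  out <- list()
  hashes <- list()
  for (sex in names(bundles)) {
    ps <- bundles[[sex]]
    if (!identical(ps$sex, sex)) {
      stop("bundle named '", sex, "' has sex '", ps$sex, "'", call. = FALSE)
    }
    ref_ages <- reference[[sex]]
    in_grid <- any(grid$first_age == ref_ages[1] &
                     grid$second_age == ref_ages[2])
    if (!in_grid) {
      stop("reference scenario ", ref_ages[1], "/", ref_ages[2],
           " for ", sex, " is not in the grid", call. = FALSE)
    }
    hashes[[sex]] <- rlang::hash(ps)

    scenarios <- c(list(NULL), grid$scenario)
    rows <- purrr::imap(scenarios, function(sc, j) {
      s <- if (engine == "deterministic") {
        summarize_outcomes(run_cohort(ps, sc))
      } else {
        summarize_outcomes(
          run_cohort_stochastic(ps, sc, n_individuals = n_individuals,
                                seed = seed + j)
        )
      }
      s$interval <- if (is.null(sc)) NA_integer_ else
        sc$second_age - sc$first_age
      s$first_age <- if (is.null(sc)) NA_integer_ else sc$first_age
      s$second_age <- if (is.null(sc)) NA_integer_ else sc$second_age
      s
    })
    tab <- dplyr::bind_rows(rows)
    tab$is_reference <- !is.na(tab$first_age) &
      tab$first_age == ref_ages[1] & tab$second_age == ref_ages[2]
    ref_row <- tab[tab$is_reference, ]
    for (oc in c("cases", "deaths", "ypll", "dalys")) {
      chg <- relative_change(tab[[oc]], ref_row[[oc]])
      chg[tab$is_reference] <- NA_integer_
      tab[[paste0(oc, "_change_pct")]] <- chg
    }
    out[[sex]] <- tab
  }
  structure(
    list(summaries = dplyr::bind_rows(out),
         reference = reference, engine = engine,
         bundle_hash = hashes,
         seed = if (engine == "stochastic") seed else NULL),
    class = "crc_experiment"
  )
}

#' @export
print.crc_experiment <- function(x, ...) {
  cat("<crc_experiment>", x$engine, "engine;",
      nrow(x$summaries), "sex x strategy rows\n")
  print(render_change_table(x, style = "long"))
  invisible(x)
}

#' Render the strategy-comparison table
#'
#' `"paper"` style mirrors the conventional report layout: one block per
#' sex, columns interval / first / second exam age, then each outcome's
#' absolute number and formatted percent change, with the reference row's
#' change printed as an em dash. `"long"` style is a tidy tibble with one
#' row per strategy x outcome.
#'
#' @param experiment A `crc_experiment`.
#' @param style `"paper"` or `"long"`.
#' @param path Optional file to write (TSV); rendering is deterministic so
#'   re-rendering the same results writes identical bytes.
#' @return The rendered tibble, invisibly if `path` is given.
#' @export
render_change_table <- function(experiment, style = c("paper", "long"),
                                path = NULL) {
  style <- match.arg(style)
  s <- experiment$summaries
  if (nrow(s) == 0) stop("empty experiment", call. = FALSE)
  if (style == "paper") {
    out <- tibble::tibble(
      sex = s$sex,
      interval = ifelse(is.na(s$interval), "", as.character(s$interval)),
      first = ifelse(is.na(s$first_age), "no screening",
                     as.character(s$first_age)),
      second = ifelse(is.na(s$second_age), "", as.character(s$second_age)),
      cases = round(s$cases),
      cases_change = format_change(s$cases_change_pct),
      deaths = round(s$deaths),
      deaths_change = format_change(s$deaths_change_pct),
      ypll = round(s$ypll),
      ypll_change = format_change(s$ypll_change_pct),
      dalys = round(s$dalys),
      dalys_change = format_change(s$dalys_change_pct)
    )
  } else {
    out <- purrr::map_dfr(c("cases", "deaths", "ypll", "dalys"), function(oc) {
      tibble::tibble(sex = s$sex, label = s$label, outcome = oc,
                     value = s[[oc]],
                     change_pct = s[[paste0(oc, "_change_pct")]])
    })
    out <- dplyr::arrange(out, .data$sex, .data$label, .data$outcome)
  }
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}

# Broom-style accessors -------------------------------------------------------

#' Tidy a cohort run into per-age tallies
#'
#' @param x A `crc_run` or `crc_run_stochastic`.
#' @param ... Unused.
#' @return The per-age tally tibble (incident cases by detection route,
#'   deaths by cause, exams, diagnosed person-years by phase).
#' @export
tidy.crc_run <- function(x, ...) x$tallies

#' @rdname tidy.crc_run
#' @export
tidy.crc_run_stochastic <- function(x, ...) x$tallies

#' One-row outcome summary of a cohort run
#'
#' @param x A `crc_run` or `crc_run_stochastic`.
#' @param ... Unused.
#' @return The [summarize_outcomes()] row.
#' @export
glance.crc_run <- function(x, ...) summarize_outcomes(x)

#' @rdname glance.crc_run
#' @export
glance.crc_run_stochastic <- function(x, ...) summarize_outcomes(x)

#' Tidy an experiment into one row per strategy and outcome
#'
#' @param x A `crc_experiment`.
#' @param ... Unused.
#' @return A tibble: `sex`, `label`, `outcome`, `value`, `change_pct`.
#' @export
tidy.crc_experiment <- function(x, ...) render_change_table(x, style = "long")

#' One-row description of an experiment
#'
#' @param x A `crc_experiment`.
#' @param ... Unused.
#' @return A tibble with the engine, sexes, strategy count and per-sex
#'   reference labels and bundle hashes.
#' @export
glance.crc_experiment <- function(x, ...) {
  sexes <- unique(x$summaries$sex)
  ref <- paste(
    vapply(sexes, function(s)
      paste0(s, ":", x$reference[[s]][1], "/", x$reference[[s]][2]),
      character(1)),
    collapse = " ")
  hash <- paste(
    vapply(sexes, function(s) substr(x$bundle_hash[[s]], 1, 8),
           character(1)),
    collapse = " ")
  tibble::tibble(
    engine = x$engine,
    sexes = paste(sexes, collapse = ","),
    n_strategies = nrow(x$summaries) / length(sexes),
    reference = ref,
    bundle_hash = hash
  )
}
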
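# ggplot2 views of runs and experiments.

#' Plot per-age incidence and mortality of a cohort run
#'
#' Line plot of incident cancer cases (all detection routes combined) and
#' cancer deaths per year of age.
#'
#' @param object A `crc_run` or `crc_run_stochastic`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crc_run <- function(object, ...) {
  t <- object$tallies
  d <- dplyr::bind_rows(
    tibble::tibble(age = t$age, series = "incident CRC cases",
                   persons = t$cases_clinical + t$cases_screen +
                     t$cases_surveillance),
    tibble::tibble(age = t$age, series = "CRC deaths",
                   persons = t$crc_deaths)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age, y = .data$persons,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Age (years)", y = "Persons per year", colour = NULL,
      title = paste0("Cohort run (", object$ps$sex, "): ", object$label)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.crc_run
#' @export
autoplot.crc_run_stochastic <- autoplot.crc_run

#' Bar chart of percent changes versus the reference strategy
#'
#' One bar per two-exam strategy, faceted by outcome and sex; the
#' no-screening comparator is excluded by default because its several-fold
#' increase dwarfs the between-strategy differences.
#'
#' @param object A `crc_experiment`.
#' @param include_no_screening Include the no-screening row (default
#'   `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crc_experiment <- function(object, include_no_screening = FALSE,
                                    ...) {
  d <- tidy.crc_experiment(object)
  d <- d[!is.na(d$change_pct), ]
  if (!include_no_screening) d <- d[d$label != "no_screening", ]
  d$outcome <- factor(d$outcome, levels = c("cases", "deaths", "ypll", "dalys"),
                      labels = c("CRC cases", "CRC deaths", "YPLL", "DALYs"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$change_pct,
                                  fill = .data$change_pct > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$outcome),
                        cols = ggplot2::vars(.data$sex)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "#2166ac")) +
    ggplot2::labs(x = "First/second screening colonoscopy age",
                  y = "Change vs reference strategy (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
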
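#' Published burden estimates for two-exam screening strategies in Germany
#'
#' Reference table of cumulative CRC cases, CRC deaths, YPLL and DALYs per
#' 100,000 persons aged 45-84, as reported by a published German
#' modelling analysis of screening-colonoscopy strategies: the
#' no-screening comparator and the nine two-exam strategies, separately
#' for men and women, with each outcome's printed percent change versus
#' the sex-specific reference strategy (men 50/60, women 55/65). Used to
#' regression-test the comparison arithmetic; the absolute numbers are
#' inputs here, not outputs of this package.
#'
#' @return A tibble with one row per sex x strategy: `sex`, `interval`,
#'   `first_age`, `second_age`, `is_reference`, and for each outcome the
#'   absolute number and the printed integer percent change (`NA` on the
#'   reference row).
#' @export
published_burden_tables <- function() {
  path <- system.file("extdata", "published_burden_tables.tsv",
                      package = "crcscreen", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    sex = readr::col_character(),
    interval = readr::col_integer(),
    first_age = readr::col_integer(),
    second_age = readr::col_integer(),
    is_reference = readr::col_logical(),
    .default = readr::col_integer()
  ), progress = FALSE)
}
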
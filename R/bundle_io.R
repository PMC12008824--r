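# Parameter bundles on disk: one directory holding plain tab-separated
# tables (one per parameter block) plus a YAML manifest. The layout mirrors
# the tabular supplements that registry-based natural-history analyses
# publish, and diffs cleanly under version control.

BUNDLE_FILES <- list(
  transition_rates = c("age_group", TRANSITION_NAMES),
  starting_prevalence = c("p_na_45", "p_adv_45", "p_pre_45"),
  performance = c("sens_na", "sens_advanced", "specificity"),
  crc_survival = c("detection_mode", "year_since_dx", "p_crc_death"),
  life_table = c("age", "q_other", "le_resid"),
  disability_weights = c("phase", "weight")
)

BUNDLE_SCHEMA_VERSION <- 1L

# Double columns are parsed from text with base R's strtod (via
# as.double) rather than the reader's fast path, so that values written at
# full precision reload bit-identically.
BUNDLE_CHARACTER_COLS <- c("age_group", "detection_mode", "year_since_dx",
                           "phase")
BUNDLE_INTEGER_COLS <- c("age")

#' Write a parameter set to a bundle directory
#'
#' Writes one TSV per parameter table plus `manifest.yml` (sex, cohort
#' size, schema version). Writing is refused, with the full validation
#' report, if the set violates any invariant. Two writes of the same set
#' produce byte-identical files.
#'
#' @param ps A valid `crc_parameter_set`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_parameter_bundle <- function(ps, path) {
  rep <- validate_parameter_set(ps)
  if (nrow(rep) > 0) {
    stop("refusing to write invalid parameter set:\n",
         paste0("  [", rep$code, "] ", rep$table, "/", rep$where, ": ",
                rep$message, collapse = "\n"),
         call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (tbl in names(BUNDLE_FILES)) {
    # render doubles at full precision so a reload is bit-identical
    x <- dplyr::mutate(ps[[tbl]], dplyr::across(
      dplyr::where(is.double), ~ sprintf("%.17g", .x)))
    readr::write_tsv(x, file.path(path, paste0(tbl, ".tsv")))
  }
  manifest <- list(
    schema_version = BUNDLE_SCHEMA_VERSION,
    sex = ps$sex,
    cohort_size = ps$cohort_size
  )
  yaml::write_yaml(manifest, file.path(path, "manifest.yml"))
  invisible(path)
}

#' Read a parameter set from a bundle directory
#'
#' Reads the TSV tables written by [write_parameter_bundle()], rejects
#' unknown columns by name, and validates the assembled set; any
#' out-of-range value is reported with its table, row and column.
#'
#' @param path Bundle directory.
#' @return A validated `crc_parameter_set`.
#' @export
read_parameter_bundle <- function(path) {
  if (!dir.exists(path)) {
    stop("parameter bundle directory not found: ", path, call. = FALSE)
  }
  man_path <- file.path(path, "manifest.yml")
  if (!file.exists(man_path)) {
    stop("missing table: manifest.yml in ", path, call. = FALSE)
  }
  manifest <- yaml::read_yaml(man_path)

  tabs <- list()
  for (tbl in names(BUNDLE_FILES)) {
    f <- file.path(path, paste0(tbl, ".tsv"))
    if (!file.exists(f)) {
      stop("missing table: ", tbl, ".tsv in ", path, call. = FALSE)
    }
    x <- readr::read_tsv(f, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    for (cn in names(x)) {
      if (cn %in% BUNDLE_CHARACTER_COLS) next
      x[[cn]] <- if (cn %in% BUNDLE_INTEGER_COLS) as.integer(x[[cn]]) else
        as.double(x[[cn]])
    }
    unknown <- setdiff(names(x), BUNDLE_FILES[[tbl]])
    if (length(unknown) > 0) {
      stop("unknown column(s) in ", tbl, ".tsv: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    missing <- setdiff(BUNDLE_FILES[[tbl]], names(x))
    if (length(missing) > 0) {
      stop("missing column(s) in ", tbl, ".tsv: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tabs[[tbl]] <- x[, BUNDLE_FILES[[tbl]]]
  }

  ps <- crc_parameter_set(
    sex = manifest$sex,
    transition_rates = tabs$transition_rates,
    starting_prevalence = tabs$starting_prevalence,
    performance = tabs$performance,
    crc_survival = tabs$crc_survival,
    life_table = tabs$life_table,
    disability_weights = tabs$disability_weights,
    cohort_size = manifest$cohort_size,
    validate = FALSE
  )
  rep <- validate_parameter_set(ps)
  if (nrow(rep) > 0) {
    stop("parameter bundle at ", path, " failed validation:\n",
         paste0("  [", rep$code, "] ", rep$table, "/", rep$where, ": ",
                rep$message, collapse = "\n"),
         call. = FALSE)
  }
  ps
}
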
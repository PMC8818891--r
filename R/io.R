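# Delimited-text readers and writers for every pipeline table. All files are
# plain CSV with headers; readers validate column presence and types so a
# malformed file fails at the door rather than mid-pipeline.

read_csv_quiet <- function(path, col_types) {
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Read a cohort table
#'
#' Columns: `patient_id`, `diagnosed`, `management_change`, `modeled`
#' (logical flags).
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  read_csv_quiet(path, readr::cols(
    patient_id = readr::col_character(),
    diagnosed = readr::col_logical(),
    management_change = readr::col_logical(),
    modeled = readr::col_logical(),
    .default = readr::col_guess()))
}

#' Read a cost-ledger table
#'
#' Columns: `item_id`, `patient_id`, `category`, `direction`, `amount_usd`,
#' `source_question_id`, `description`.
#' @inheritParams read_cohort
#' @return A validated ledger tibble.
#' @export
read_ledger <- function(path) {
  validate_ledger(read_csv_quiet(path, readr::cols(
    item_id = readr::col_character(),
    patient_id = readr::col_character(),
    category = readr::col_character(),
    direction = readr::col_character(),
    amount_usd = readr::col_double(),
    source_question_id = readr::col_character(),
    description = readr::col_character())))
}

#' Read a Delphi response table
#'
#' Columns: `question_id`, `patient_id`, `panelist_id`, `round`, `label`.
#' @inheritParams read_cohort
#' @return A tibble.
#' @export
read_delphi_responses <- function(path) {
  read_csv_quiet(path, readr::cols(
    question_id = readr::col_character(),
    patient_id = readr::col_character(),
    panelist_id = readr::col_character(),
    round = readr::col_integer(),
    label = readr::col_character()))
}

#' Read a QALY-component table
#'
#' Columns: `patient_id`, `component`, `value`, optionally
#' `source_question_id`.
#' @inheritParams read_cohort
#' @return A tibble.
#' @export
read_qaly_components <- function(path) {
  read_csv_quiet(path, readr::cols(
    patient_id = readr::col_character(),
    component = readr::col_character(),
    value = readr::col_double(),
    .default = readr::col_character()))
}

#' Read a sequencing-cost table
#'
#' Columns: `patient_id`, `configuration`, `cost_usd`.
#' @inheritParams read_cohort
#' @return A tibble.
#' @export
read_sequencing_costs <- function(path) {
  read_csv_quiet(path, readr::cols(
    patient_id = readr::col_character(),
    configuration = readr::col_character(),
    cost_usd = readr::col_double()))
}

#' Write a cohort bundle to a directory of CSV files
#'
#' Writes the five pipeline tables (`cohort.csv`, `ledger.csv`,
#' `delphi_responses.csv`, `qaly_components.csv`, `sequencing.csv`) so an
#' analysis can be round-tripped through plain text.
#'
#' @param bundle A list with elements `cohort`, `ledger`, `delphi_responses`,
#'   `qaly_components`, `sequencing` (as produced by [reference_cohort()] or
#'   [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("cohort", "ledger", "delphi_responses", "qaly_components",
              "sequencing")
  for (tb in tables) {
    readr::write_csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort_bundle()]
#'
#' @param dir Directory containing the five CSV tables.
#' @return A list of tibbles with the same shapes the pipeline consumes.
#' @export
read_cohort_bundle <- function(dir) {
  list(
    cohort = read_cohort(file.path(dir, "cohort.csv")),
    ledger = read_ledger(file.path(dir, "ledger.csv")),
    delphi_responses = read_delphi_responses(
      file.path(dir, "delphi_responses.csv")),
    qaly_components = read_qaly_components(
      file.path(dir, "qaly_components.csv")),
    sequencing = read_sequencing_costs(file.path(dir, "sequencing.csv")))
}
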
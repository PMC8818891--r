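# Counterfactual cost ledger.
#
# Each monetary effect of a genomic diagnosis is one line item: an avoided
# cost (care the patient would have received without the diagnosis) or an
# incurred cost (care triggered by it). Amounts are unsigned nominal USD; the
# `direction` field carries the sign, so savings enter the net positively and
# incurred costs negatively. Items tied to a Delphi question only count when
# that question reached consensus.

.ledger_categories <- c("hospital_day", "procedure", "medication",
                        "professional_fee", "other")
.ledger_directions <- c("avoided", "incurred")

#' Estimate a daily hospitalization cost from the last three inpatient days
#'
#' The counterfactual value of an avoided (or added) hospital day is proxied
#' by the mean charge over the patient's last three days of hospitalization,
#' with procedure charges excluded. The rule is specific to three days.
#'
#' @param charges Numeric vector of exactly three non-negative daily charges
#'   (USD, procedures excluded).
#' @return The daily cost estimate (arithmetic mean of the three charges).
#' @examples
#' estimate_daily_cost(c(1000, 1200, 1400))  # 1200
#' @export
estimate_daily_cost <- function(charges) {
  if (!is.numeric(charges) || length(charges) != 3L) {
    stop("`charges` must be exactly three daily charge values; got ",
         length(charges), call. = FALSE)
  }
  if (any(!is.finite(charges)) || any(charges < 0)) {
    stop("daily charges must be finite and >= 0", call. = FALSE)
  }
  mean(charges)
}

#' Value an avoided (or added) length of stay
#'
#' @param days Non-negative number of hospital days avoided.
#' @param daily_cost Non-negative daily cost (USD), typically from
#'   [estimate_daily_cost()].
#' @return `days * daily_cost` in USD.
#' @examples
#' avoided_stay_value(10, 1200)  # 12000
#' @export
avoided_stay_value <- function(days, daily_cost) {
  assert_nonneg_scalar(days, "days")
  assert_nonneg_scalar(daily_cost, "daily_cost")
  days * daily_cost
}

#' Estimate professional fees from accrued hospital costs
#'
#' Physician-service charges are modeled as a fixed published ratio of the
#' accrued hospital charges. The ratio is a configuration input — it is never
#' hard-coded, since the applicable published value depends on setting and
#' year.
#'
#' @param hospital_amount Non-negative accrued hospital cost (USD).
#' @param ratio Non-negative professional-to-hospital fee ratio.
#' @return `hospital_amount * ratio` in USD.
#' @export
professional_fee <- function(hospital_amount, ratio) {
  assert_nonneg_scalar(hospital_amount, "hospital_amount")
  assert_nonneg_scalar(ratio, "ratio")
  hospital_amount * ratio
}

validate_ledger <- function(items) {
  items <- tibble::as_tibble(items)
  needed <- c("item_id", "patient_id", "category", "direction", "amount_usd")
  missing_cols <- setdiff(needed, names(items))
  if (length(missing_cols) > 0) {
    stop("ledger is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"source_question_id" %in% names(items)) {
    items$source_question_id <- NA_character_
  }
  if (!"description" %in% names(items)) items$description <- NA_character_
  bad_cat <- setdiff(unique(items$category), .ledger_categories)
  if (length(bad_cat) > 0) {
    stop("unknown ledger category: ", paste(sQuote(bad_cat), collapse = ", "),
         call. = FALSE)
  }
  bad_dir <- setdiff(unique(items$direction), .ledger_directions)
  if (length(bad_dir) > 0) {
    stop("direction must be 'avoided' or 'incurred', got: ",
         paste(sQuote(bad_dir), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(items$amount_usd)) || any(items$amount_usd < 0)) {
    stop("amount_usd must be finite and >= 0 (sign is carried by direction)",
         call. = FALSE)
  }
  items
}

# Resolve the consensus gate: keep items without a source question and items
# whose question reached consensus; drop (and log) the rest.
gate_items <- function(items, consensus) {
  if (is.data.frame(consensus)) {
    consensus <- setNames(consensus$final_status, consensus$question_id)
  }
  linked <- !is.na(items$source_question_id)
  unknown <- setdiff(items$source_question_id[linked], names(consensus))
  if (length(unknown) > 0) {
    stop("ledger item(s) reference unknown Delphi question(s): ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  }
  status <- rep("unlinked", nrow(items))
  status[linked] <- unname(consensus[items$source_question_id[linked]])
  included <- status %in% c("unlinked", "consensus_agree", "consensus_disagree")
  list(
    included = items[included, , drop = FALSE],
    excluded = dplyr::mutate(items[!included, , drop = FALSE],
                             exclusion_reason = status[!included])
  )
}

#' Net counterfactual cost effect for one patient
#'
#' Sums a patient's consensus-gated line items into savings (avoided items),
#' incurred costs, and their signed net. Items whose source Delphi question
#' was discarded for lack of consensus are excluded and reported in the
#' `excluded` attribute.
#'
#' @param items Ledger tibble for a single patient (columns `item_id`,
#'   `patient_id`, `category`, `direction`, `amount_usd`, optionally
#'   `source_question_id`, `description`).
#' @param consensus Either a named character vector mapping question ids to
#'   final statuses, or the tibble from [delphi_consensus()].
#' @return A one-row tibble: `patient_id`, `savings_usd`, `incurred_usd`,
#'   `net_usd` (= savings - incurred), with excluded items as an attribute.
#' @examples
#' items <- tibble::tibble(
#'   item_id = c("i1", "i2"), patient_id = "p1",
#'   category = c("hospital_day", "medication"),
#'   direction = c("avoided", "incurred"),
#'   amount_usd = c(10000, 3000))
#' patient_net_effect(items, consensus = character())
#' @export
patient_net_effect <- function(items, consensus = character()) {
  items <- validate_ledger(items)
  if (nrow(items) > 0 && length(unique(items$patient_id)) != 1L) {
    stop("`items` must belong to a single patient; see ledger_totals() for cohorts",
         call. = FALSE)
  }
  gated <- gate_items(items, consensus)
  inc <- gated$included
  savings  <- sum(inc$amount_usd[inc$direction == "avoided"])
  incurred <- sum(inc$amount_usd[inc$direction == "incurred"])
  out <- tibble::tibble(
    patient_id   = if (nrow(items) > 0) items$patient_id[1] else NA_character_,
    savings_usd  = savings,
    incurred_usd = incurred,
    net_usd      = savings - incurred
  )
  attr(out, "excluded") <- gated$excluded
  out
}

#' Per-patient net effects for a whole ledger
#'
#' @param items Ledger tibble covering any number of patients.
#' @inheritParams patient_net_effect
#' @return A tibble with one row per patient (as [patient_net_effect()]),
#'   excluded items in the `excluded` attribute.
#' @export
ledger_totals <- function(items, consensus = character()) {
  items <- validate_ledger(items)
  if (nrow(items) == 0) {
    out <- tibble::tibble(patient_id = character(), savings_usd = numeric(),
                          incurred_usd = numeric(), net_usd = numeric())
    attr(out, "excluded") <- items
    return(out)
  }
  parts <- lapply(split(items, items$patient_id),
                  patient_net_effect, consensus = consensus)
  out <- dplyr::bind_rows(parts)
  attr(out, "excluded") <- dplyr::bind_rows(lapply(parts, attr, "excluded"))
  out
}

#' Cohort-level cost totals
#'
#' @param effects Tibble of per-patient net effects (one row per modeled
#'   patient), e.g. from [ledger_totals()].
#' @return A list: `total_savings_usd`, `total_incurred_usd`,
#'   `total_net_usd` (= savings - incurred), `n_patients`.
#' @examples
#' eff <- tibble::tibble(patient_id = c("a", "b"),
#'                       savings_usd = c(500, 0),
#'                       incurred_usd = c(0, 200),
#'                       net_usd = c(500, -200))
#' cohort_cost_totals(eff)$total_net_usd  # 300
#' @export
cohort_cost_totals <- function(effects) {
  effects <- tibble::as_tibble(effects)
  if (anyDuplicated(effects$patient_id)) {
    stop("duplicate patient_id in cost effects: ",
         paste(unique(effects$patient_id[duplicated(effects$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  list(
    total_savings_usd  = sum(effects$savings_usd),
    total_incurred_usd = sum(effects$incurred_usd),
    total_net_usd      = sum(effects$net_usd),
    n_patients         = nrow(effects)
  )
}
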
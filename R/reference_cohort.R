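# Bundled reference cohort: 38 PICU probands who received rapid trio genome
# sequencing, with published cohort-level results — 17 molecular diagnoses,
# 13 management changes, 8 counterfactuals put to Delphi panels (7 reaching
# consensus), six per-patient cost effects, two patients with QALY gains,
# and a cohort sequencing spend of $239,400. Panelist-level Likert responses
# were not published; the bundled responses are synthesized to be consistent
# with the recorded per-question consensus statuses only, and are flagged as
# such in the metadata.

#' Reference PICU rWGS cohort
#'
#' Returns the packaged reference cohort as a bundle of pipeline tables:
#' cohort flags, cost ledger, Delphi responses, QALY components and
#' sequencing costs, plus a `metadata` list of quantities recorded at cohort
#' level only (hospital vs professional-fee savings split, the per-trio
#' reference price, and the published risk inputs behind the Factor XIII
#' QALY model).
#'
#' Running [run_analysis()] on this bundle reproduces the cohort's headline
#' economics: $184,846 net savings, 12.1 QALYs, $239,400 sequencing cost,
#' $54,554 net cost, and an ICER of $4,509 per QALY.
#'
#' The sequencing table stores the authoritative cohort total spread evenly
#' over the 38 families ($6,300 each); the quoted per-trio price ($7,400) is
#' carried in `metadata$per_trio_reference_usd` because the two figures
#' imply mixed family configurations that were not itemized — see
#' `metadata$reconciliation_note`.
#'
#' @return A list with tibbles `cohort`, `ledger`, `delphi_responses`,
#'   `qaly_components`, `sequencing`, and a `metadata` list.
#' @examples
#' fix <- reference_cohort()
#' nrow(fix$cohort)  # 38
#' @export
reference_cohort <- function() {
  modeled_ids <- c("6007", "6052", "6147", "6153", "6159", "6180", "6193",
                   "6207")
  change_not_modeled <- c("6031", "6118", "7002", "6183", "7039")
  diagnosed_only <- sprintf("dx%02d", 1:4)       # synthetic ids
  undiagnosed <- sprintf("nd%02d", 1:21)         # synthetic ids

  cohort <- tibble::tibble(
    patient_id = c(modeled_ids, change_not_modeled, diagnosed_only,
                   undiagnosed),
    diagnosed = c(rep(TRUE, 17), rep(FALSE, 21)),
    management_change = c(rep(TRUE, 13), rep(FALSE, 25)),
    modeled = c(rep(TRUE, 8), rep(FALSE, 30))
  )

  ledger <- tibble::tibble(
    item_id = c("L6007", "L6052", "L6147", "L6159", "L6180", "L6193",
                "L6207"),
    patient_id = c("6007", "6052", "6147", "6159", "6180", "6193", "6207"),
    category = c("hospital_day", "hospital_day", "hospital_day",
                 "procedure", "medication", "hospital_day", "medication"),
    direction = c("avoided", "avoided", "avoided", "avoided", "incurred",
                  "avoided", "incurred"),
    amount_usd = c(9795, 21450, 74556, 8108, 9856, 134538, 32295),
    source_question_id = paste0("q_", patient_id),
    description = c(
      "pulse steroids instead of ICU transfer for midazolam infusion",
      "reduced stay for metabolic crisis (synthetic amount; no consensus)",
      "avoided hospitalization, skin biopsy and EGD/intestinal biopsies",
      "avoided renal biopsy",
      "six additional IVIG doses",
      "home NPPV on hospice instead of continued hospitalization",
      "earlier prophylactic Factor XIII replacement")
  )

  qaly_components <- tibble::tibble(
    patient_id = c("6153", "6207", "6207"),
    component = c("avoided_infection_mortality", "avoided_mortality",
                  "avoided_neurologic_morbidity"),
    value = c(0.12, 9.08, 2.90),
    source_question_id = c("q_6153", "q_6207", "q_6207")
  )

  sequencing <- tibble::tibble(
    patient_id = cohort$patient_id,
    configuration = "trio",
    cost_usd = 239400 / 38
  )

  delphi_responses <- reference_delphi_responses(modeled_ids)

  metadata <- list(
    hospital_savings_usd = 156575,
    professional_fee_savings_usd = 28271,
    per_trio_reference_usd = 7400,
    reconciliation_note = paste(
      "The cohort sequencing total ($239,400) is authoritative; it does not",
      "equal 38 x the quoted per-trio price ($7,400), implying mixed family",
      "configurations that were not itemized. Entries carry the even",
      "per-family share."),
    delphi_note = paste(
      "Panelist-level responses are synthesized to match the recorded",
      "per-question consensus statuses; individual scores were not",
      "published."),
    factor13_risk_inputs = list(
      p_death_second_cns_bleed = 0.12,
      p_neuro_complication_in_survivors = 0.726,
      mean_age_death_years = 1.5,
      sd_age_death_years = 2),
    factor13_example_tree = factor13_example_trees()
  )

  list(cohort = cohort, ledger = ledger,
       delphi_responses = delphi_responses,
       qaly_components = qaly_components, sequencing = sequencing,
       metadata = metadata)
}

# Synthesized Likert responses reproducing the recorded statuses: seven
# questions reach agreement consensus in round one; the question for
# patient 6052 misses consensus in both rounds and is discarded. The panel
# is ten intensivists, except the hematology question (6207), put to five
# pediatric hematologists.
reference_delphi_responses <- function(modeled_ids) {
  intensivists <- sprintf("int%02d", 1:10)
  hematologists <- sprintf("hem%02d", 1:5)

  one_round <- function(qid, pid, panel, labels, round) {
    tibble::tibble(question_id = qid, patient_id = pid,
                   panelist_id = panel[seq_along(labels)],
                   round = as.integer(round), label = labels)
  }
  agree10 <- c(rep("agree", 6), rep("strongly_agree", 4))          # mean 4.4
  agree_with_abstain <- c(rep("agree", 5), rep("strongly_agree", 4),
                          "unable_to_comment")                      # mean 4.44
  agree5 <- c(rep("agree", 3), rep("strongly_agree", 2))           # mean 4.4
  r1_6052 <- c(rep("agree", 3), rep("neutral", 7))                 # mean 3.3
  r2_6052 <- c(rep("agree", 5), rep("neutral", 5))                 # mean 3.5

  dplyr::bind_rows(
    one_round("q_6007", "6007", intensivists, agree10, 1),
    one_round("q_6052", "6052", intensivists, r1_6052, 1),
    one_round("q_6052", "6052", intensivists, r2_6052, 2),
    one_round("q_6147", "6147", intensivists, agree10, 1),
    one_round("q_6153", "6153", intensivists, agree10, 1),
    one_round("q_6159", "6159", intensivists, agree_with_abstain, 1),
    one_round("q_6180", "6180", intensivists, agree10, 1),
    one_round("q_6193", "6193", intensivists, agree10, 1),
    one_round("q_6207", "6207", hematologists, agree5, 1)
  )
}

#' Illustrative outcome trees for the Factor XIII deficiency case
#'
#' A reconstructed with/without-prophylaxis tree pair built from the
#' published risk inputs (12% mortality given a second CNS bleed; 72.6%
#' neurologic complications among survivors of one). The quality-of-life
#' weights and durations are illustrative placeholders — the
#' condition-specific parameterization behind the recorded 9.08 and 2.9 QALY
#' components was not published — so these trees demonstrate the model
#' structure and are not asserted to reproduce those components.
#'
#' @return A list with `with_prophylaxis` and `without_prophylaxis` outcome
#'   trees and the undiscounted `illustrative_gain` between them.
#' @export
factor13_example_trees <- function() {
  survival_split <- outcome_node(
    list(prob = 0.726,
         node = outcome_leaf("neurologic complication", 0.5, 70)),
    list(prob = 0.274, node = outcome_leaf("intact survival", 1, 70)),
    label = "survives second CNS bleed")
  without <- outcome_node(
    list(prob = 0.12, node = outcome_leaf("death", 0, 0)),
    list(prob = 0.88, node = survival_split),
    label = "second CNS bleed without prophylaxis")
  with_p <- outcome_leaf("intact survival on prophylaxis", 1, 70)
  list(with_prophylaxis = with_p, without_prophylaxis = without,
       illustrative_gain = qaly_gain(with_p, without))
}
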
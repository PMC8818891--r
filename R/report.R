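# Reporting: human-readable summary, cohort table, and the savings /
# sequencing-cost / QALY bar chart.

fmt_usd <- function(x) {
  paste0(ifelse(x < 0, "-$", "$"),
         format(abs(round_half_away(x)), big.mark = ",", scientific = FALSE,
                trim = TRUE))
}

#' @export
print.cea_icer <- function(x, ...) {
  msg <- switch(x$flag,
    finite = paste0(fmt_usd(x$usd_per_qaly_rounded), " per QALY"),
    dominant = "dominant (cost-saving and QALY-gaining; no finite ICER)",
    no_benefit = "no QALY gain at positive net cost (no finite ICER)")
  cat("ICER:", msg, "\n")
  invisible(x)
}

#' @export
print.cea_result <- function(x, ...) {
  s <- x$cohort_summary
  cat("Cost-utility analysis of rapid genome sequencing\n")
  cat(sprintf("  Cohort: %d probands; %d diagnosed (%s%%); %d management changes (%s%%); %d modeled\n",
              s$n, s$n_diagnosed, format(s$yield_diagnosed_pct),
              s$n_management_change, format(s$yield_management_change_pct),
              s$n_modeled))
  cat(sprintf("  Savings (net of incurred costs): %s\n",
              fmt_usd(x$total_net_savings_usd)))
  cat(sprintf("    avoided costs %s, incurred costs %s\n",
              fmt_usd(x$total_savings_usd), fmt_usd(x$total_incurred_usd)))
  cat(sprintf("  Sequencing cost: %s\n", fmt_usd(x$sequencing_total_usd)))
  cat(sprintf("  Net cost: %s\n", fmt_usd(x$net_cost_usd)))
  cat(sprintf("  QALYs gained: %s\n", format(x$total_qalys)))
  print(x$icer)
  cat(sprintf("  Value class: %s\n", x$value_class))
  if (nrow(x$exclusions) > 0) {
    cat(sprintf("  Exclusions logged: %d (see $exclusions)\n",
                nrow(x$exclusions)))
  }
  invisible(x)
}

#' Per-patient summary table of a pipeline run
#'
#' One row per modeled patient with the net cost effect and QALY savings —
#' the layout clinicians expect from a precision-medicine intervention
#' table — plus a cohort total row.
#'
#' @param result A `cea_result` from [run_analysis()].
#' @return A tibble with columns `patient_id`, `consensus`,
#'   `net_cost_effect_usd`, `qaly_savings`.
#' @export
cea_table <- function(result) {
  stopifnot(inherits(result, "cea_result"))
  eff <- tibble::as_tibble(result$patient_effects)
  qal <- result$patient_qalys
  by_patient <- dplyr::full_join(
    dplyr::select(eff, "patient_id", net_cost_effect_usd = "net_usd"),
    dplyr::rename(qal, qaly_savings = "total_qalys"),
    by = "patient_id")
  cons <- result$consensus
  if (!is.null(cons) && nrow(cons) > 0) {
    pc <- cons |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        consensus = ifelse(any(.data$final_status %in%
                                 c("consensus_agree", "consensus_disagree")),
                           "Y", "N"),
        .groups = "drop")
    by_patient <- dplyr::left_join(by_patient, pc, by = "patient_id")
  } else {
    by_patient$consensus <- NA_character_
  }
  total <- tibble::tibble(
    patient_id = "Total",
    net_cost_effect_usd = sum(by_patient$net_cost_effect_usd, na.rm = TRUE),
    qaly_savings = sum(by_patient$qaly_savings, na.rm = TRUE),
    consensus = NA_character_)
  dplyr::bind_rows(
    dplyr::arrange(by_patient, .data$patient_id),
    total) |>
    dplyr::select("patient_id", "consensus", "net_cost_effect_usd",
                  "qaly_savings")
}

#' Bar chart of savings, sequencing cost, and QALYs
#'
#' A two-panel figure: cohort cost savings next to total sequencing cost
#' (USD), and total QALYs gained on its own scale.
#'
#' @param result A `cea_result` from [run_analysis()].
#' @return A ggplot object.
#' @export
plot_cea <- function(result) {
  stopifnot(inherits(result, "cea_result"))
  df <- tibble::tibble(
    quantity = factor(
      c("Cost savings", "Sequencing cost", "QALYs gained"),
      levels = c("Cost savings", "Sequencing cost", "QALYs gained")),
    value = c(result$total_net_savings_usd, result$sequencing_total_usd,
              result$total_qalys),
    panel = c("US dollars", "US dollars", "QALYs"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quantity, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Cost savings, sequencing costs, and QALY savings") +
    ggplot2::theme_minimal()
}
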
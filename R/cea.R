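# Cost-effectiveness aggregation: sequencing costs, net cost, ICER,
# willingness-to-pay classification, cohort descriptive yields, and the
# end-to-end pipeline gluing the Delphi, ledger and QALY stages together.

.seq_configurations <- c("singleton", "duo", "trio", "other")

#' Willingness-to-pay thresholds
#'
#' US cost-per-QALY benchmarks used to classify an ICER: a conservative
#' $20,000/QALY bar that even strict analysts accept, the conventional
#' $50,000/QALY benchmark, and a $100,000/QALY upper bound of the range
#' funders commonly apply.
#'
#' @param conservative_usd_per_qaly,standard_usd_per_qaly,upper_usd_per_qaly
#'   Thresholds in USD per QALY; must be non-decreasing.
#' @return A `wtp_thresholds` list.
#' @export
wtp_thresholds <- function(conservative_usd_per_qaly = 20000,
                           standard_usd_per_qaly = 50000,
                           upper_usd_per_qaly = 100000) {
  if (!(conservative_usd_per_qaly <= standard_usd_per_qaly &&
        standard_usd_per_qaly <= upper_usd_per_qaly)) {
    stop("thresholds must satisfy conservative <= standard <= upper",
         call. = FALSE)
  }
  structure(list(conservative_usd_per_qaly = conservative_usd_per_qaly,
                 standard_usd_per_qaly = standard_usd_per_qaly,
                 upper_usd_per_qaly = upper_usd_per_qaly),
            class = "wtp_thresholds")
}

#' Total sequencing cost over a cohort
#'
#' @param entries Tibble with one row per proband family: `patient_id`,
#'   `configuration` (singleton/duo/trio/other), `cost_usd`.
#' @return Summed sequencing cost in USD.
#' @export
sequencing_total <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0) return(0)
  stopifnot(all(c("patient_id", "cost_usd") %in% names(entries)))
  if (anyDuplicated(entries$patient_id)) {
    stop("duplicate proband in sequencing entries: ",
         paste(unique(entries$patient_id[duplicated(entries$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  if ("configuration" %in% names(entries)) {
    bad <- setdiff(unique(entries$configuration), .seq_configurations)
    if (length(bad) > 0) {
      stop("unknown sequencing configuration: ",
           paste(sQuote(bad), collapse = ", "), call. = FALSE)
    }
  }
  if (any(!is.finite(entries$cost_usd)) || any(entries$cost_usd < 0)) {
    stop("sequencing cost_usd must be finite and >= 0", call. = FALSE)
  }
  sum(entries$cost_usd)
}

#' Net cost of the intervention
#'
#' Sequencing spend minus the savings it generated; positive is a net
#' financial loss, negative a net saving.
#'
#' @param sequencing_total Total sequencing cost (USD).
#' @param total_savings Total net savings from the cost ledger (USD).
#' @return `sequencing_total - total_savings`.
#' @examples
#' net_cost(239400, 184846)  # 54554
#' @export
net_cost <- function(sequencing_total, total_savings) {
  assert_finite_scalar(sequencing_total, "sequencing_total")
  assert_finite_scalar(total_savings, "total_savings")
  sequencing_total - total_savings
}

#' Incremental cost-effectiveness ratio
#'
#' Net cost per QALY gained. When the intervention both saves money and
#' gains QALYs it dominates the comparator and no finite ICER is reported;
#' when it costs money and gains nothing there is likewise no finite ratio.
#'
#' @param net_cost Net cost in USD (may be negative).
#' @param total_qalys Total QALYs gained, `>= 0`.
#' @return A `cea_icer` list: `flag` (`"finite"`, `"dominant"`, or
#'   `"no_benefit"`), `usd_per_qaly` (unrounded; `NA` unless finite), and
#'   `usd_per_qaly_rounded` (whole dollars, ties away from zero).
#' @examples
#' icer(54554, 12.1)$usd_per_qaly_rounded  # 4509
#' @export
icer <- function(net_cost, total_qalys) {
  assert_finite_scalar(net_cost, "net_cost")
  assert_finite_scalar(total_qalys, "total_qalys")
  if (total_qalys < 0) stop("`total_qalys` must be >= 0", call. = FALSE)
  if (net_cost <= 0 && total_qalys > 0) {
    flag <- "dominant"; value <- NA_real_
  } else if (total_qalys == 0) {
    flag <- "no_benefit"; value <- NA_real_
  } else {
    flag <- "finite"; value <- net_cost / total_qalys
  }
  structure(list(flag = flag,
                 usd_per_qaly = value,
                 usd_per_qaly_rounded = if (is.na(value)) NA_real_
                                        else round_half_away(value)),
            class = "cea_icer")
}

#' Classify an ICER against willingness-to-pay thresholds
#'
#' Brackets use strict inequality below the conservative and standard
#' thresholds and an inclusive upper bound: dominant; < conservative ->
#' `high_value_conservative`; < standard -> `high_value`; <= upper ->
#' `borderline`; above -> `low_value`. An intervention with positive net
#' cost and no QALY gain is `low_value`.
#'
#' @param icer_value A `cea_icer` from [icer()], or a bare USD-per-QALY
#'   number.
#' @param thresholds A [wtp_thresholds()] object.
#' @return One of `"dominant"`, `"high_value_conservative"`, `"high_value"`,
#'   `"borderline"`, `"low_value"`.
#' @examples
#' classify_value(4509)    # high_value_conservative
#' classify_value(50000)   # borderline (strict < for high_value)
#' @export
classify_value <- function(icer_value, thresholds = wtp_thresholds()) {
  stopifnot(inherits(thresholds, "wtp_thresholds"))
  if (inherits(icer_value, "cea_icer")) {
    if (icer_value$flag == "dominant") return("dominant")
    if (icer_value$flag == "no_benefit") return("low_value")
    icer_value <- icer_value$usd_per_qaly
  }
  assert_finite_scalar(icer_value, "icer_value")
  if (icer_value < thresholds$conservative_usd_per_qaly) return("high_value_conservative")
  if (icer_value < thresholds$standard_usd_per_qaly) return("high_value")
  if (icer_value <= thresholds$upper_usd_per_qaly) return("borderline")
  "low_value"
}

#' Cohort descriptive yields
#'
#' Diagnostic yield (diagnosed / tested) and the management-change rate
#' among diagnosed patients, as counts and nearest-integer percentages.
#' Flags must be consistent: a management change implies a diagnosis, and a
#' modeled patient implies a management change.
#'
#' @param cohort Tibble with logical columns `diagnosed`,
#'   `management_change`, `modeled` and a `patient_id` column.
#' @return A list of counts (`n`, `n_diagnosed`, `n_management_change`,
#'   `n_modeled`) and percentages (`yield_diagnosed_pct`,
#'   `yield_management_change_pct`, rounded to the nearest integer).
#' @export
cohort_summary <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  stopifnot(all(c("patient_id", "diagnosed", "management_change", "modeled")
                %in% names(cohort)))
  bad <- cohort$patient_id[(cohort$management_change & !cohort$diagnosed) |
                           (cohort$modeled & !cohort$management_change)]
  if (length(bad) > 0) {
    stop("inconsistent cohort flags (change requires diagnosis, modeling ",
         "requires change) for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  n_dx <- sum(cohort$diagnosed)
  n_change <- sum(cohort$management_change)
  list(
    n = n,
    n_diagnosed = n_dx,
    n_management_change = n_change,
    n_modeled = sum(cohort$modeled),
    yield_diagnosed_pct =
      if (n > 0) round_half_away(100 * n_dx / n) else NA_real_,
    yield_management_change_pct =
      if (n_dx > 0) round_half_away(100 * n_change / n_dx) else NA_real_
  )
}

#' Run configuration for the pipeline
#'
#' @param thresholds A [wtp_thresholds()] object.
#' @param discount_rate Annual QALY discount rate (default 0, matching a
#'   one-shot undiscounted decision tree).
#' @param professional_fee_ratio Optional published professional-to-hospital
#'   fee ratio, available to ledger construction; `NA` when professional
#'   fees arrive as pre-computed line items.
#' @return A `cea_config` list.
#' @export
cea_config <- function(thresholds = wtp_thresholds(), discount_rate = 0,
                       professional_fee_ratio = NA_real_) {
  stopifnot(inherits(thresholds, "wtp_thresholds"))
  if (discount_rate < 0) stop("`discount_rate` must be >= 0", call. = FALSE)
  structure(list(thresholds = thresholds, discount_rate = discount_rate,
                 professional_fee_ratio = professional_fee_ratio),
            class = "cea_config")
}

#' Run the full cost-utility analysis
#'
#' Orchestrates the stages end to end: Delphi adjudication gates which
#' counterfactual items enter modeling; the cost ledger is summed to cohort
#' savings; QALY components are summed per patient and over the cohort;
#' sequencing costs are totaled; and net cost, ICER, value class and
#' descriptive yields are derived. Every patient or item excluded by the
#' consensus gate is logged with a reason. Identical inputs produce an
#' identical result object.
#'
#' @param cohort Cohort tibble (`patient_id`, `diagnosed`,
#'   `management_change`, `modeled`, ...).
#' @param items Cost-ledger tibble (see [patient_net_effect()]).
#' @param delphi_responses Long response tibble (see [delphi_score()]), or
#'   `NULL` if `consensus` is given directly.
#' @param qaly_components Tibble with `patient_id`, `component`, `value` and
#'   optionally `source_question_id`.
#' @param sequencing Sequencing-cost tibble (see [sequencing_total()]).
#' @param config A [cea_config()].
#' @param consensus Optional pre-computed consensus tibble
#'   (`question_id`, `final_status`), bypassing `delphi_responses`.
#' @return A `cea_result` list with the headline totals (`total_savings_usd`,
#'   `total_incurred_usd`, `sequencing_total_usd`, `net_cost_usd`,
#'   `total_qalys`, `icer`, `value_class`, yields) and per-stage audit tables
#'   (`delphi`, `patient_effects`, `patient_qalys`, `exclusions`).
#' @examples
#' fix <- reference_cohort()
#' res <- run_analysis(fix$cohort, fix$ledger, fix$delphi_responses,
#'                     fix$qaly_components, fix$sequencing)
#' res$icer$usd_per_qaly_rounded
#' @export
run_analysis <- function(cohort, items, delphi_responses, qaly_components,
                         sequencing, config = cea_config(),
                         consensus = NULL) {
  stopifnot(inherits(config, "cea_config"))

  summary <- with_stage("cohort", cohort_summary(cohort))

  delphi_table <- NULL
  if (is.null(consensus)) {
    if (is.null(delphi_responses)) {
      consensus <- tibble::tibble(question_id = character(),
                                  patient_id = character(),
                                  final_status = character())
    } else {
      delphi_table <- with_stage("delphi", delphi_score(delphi_responses))
      consensus <- delphi_consensus(delphi_table)
    }
  }

  effects <- with_stage("cost_ledger", ledger_totals(items, consensus))
  cost_tot <- with_stage("cost_ledger", cohort_cost_totals(effects))

  exclusions <- tibble::tibble(stage = character(), id = character(),
                               reason = character())
  excl_items <- attr(effects, "excluded")
  if (!is.null(excl_items) && nrow(excl_items) > 0) {
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      stage = "cost_ledger", id = excl_items$item_id,
      reason = paste0("source question ", excl_items$source_question_id,
                      ": ", excl_items$exclusion_reason)))
  }

  qaly_components <- tibble::as_tibble(qaly_components)
  patient_qalys <- with_stage("qaly", {
    comps <- qaly_components
    if (nrow(comps) > 0 && "source_question_id" %in% names(comps)) {
      gated <- gate_items(
        dplyr::mutate(comps, item_id = paste0("qaly:", .data$patient_id, ":",
                                              .data$component)),
        consensus)
      if (nrow(gated$excluded) > 0) {
        exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
          stage = "qaly", id = gated$excluded$item_id,
          reason = paste0("source question ",
                          gated$excluded$source_question_id, ": ",
                          gated$excluded$exclusion_reason)))
      }
      comps <- dplyr::select(gated$included, -"item_id")
    }
    if (nrow(comps) == 0) {
      tibble::tibble(patient_id = character(), total_qalys = numeric())
    } else {
      comps |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::summarise(total_qalys = sum(.data$value), .groups = "drop")
    }
  })
  total_qalys <- with_stage("qaly", cohort_qaly_total(patient_qalys))

  seq_total <- with_stage("sequencing", sequencing_total(sequencing))
  nc <- net_cost(seq_total, cost_tot$total_net_usd)
  icer_res <- icer(nc, total_qalys)
  value_class <- classify_value(icer_res, config$thresholds)

  # Log modeled patients whose every linked question was discarded, and
  # management-change patients never modeled.
  cohort <- tibble::as_tibble(cohort)
  non_modeled <- cohort$patient_id[cohort$management_change & !cohort$modeled]
  if (length(non_modeled) > 0) {
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      stage = "cohort", id = as.character(non_modeled),
      reason = "management change not quantitatively modelable"))
  }
  discarded_q <- consensus$patient_id[
    consensus$final_status == "no_consensus_discarded"]
  if (length(discarded_q) > 0) {
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      stage = "delphi", id = as.character(discarded_q),
      reason = "Delphi panel failed to reach consensus"))
  }

  structure(list(
    cohort_summary       = summary,
    total_savings_usd    = cost_tot$total_savings_usd,
    total_incurred_usd   = cost_tot$total_incurred_usd,
    total_net_savings_usd = cost_tot$total_net_usd,
    sequencing_total_usd = seq_total,
    net_cost_usd         = nc,
    total_qalys          = total_qalys,
    icer                 = icer_res,
    value_class          = value_class,
    config               = config,
    delphi               = delphi_table,
    consensus            = consensus,
    patient_effects      = effects,
    patient_qalys        = patient_qalys,
    exclusions           = exclusions
  ), class = "cea_result")
}
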
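test_that("sequencing totals sum per-family entries and reject duplicates", {
  entries <- tibble::tibble(patient_id = c("a", "b"),
                            configuration = c("trio", "duo"),
                            cost_usd = c(7400, 5200))
  expect_equal(sequencing_total(entries), 12600)
  expect_equal(sequencing_total(entries[1, ]), 7400)
  expect_equal(sequencing_total(entries[0, ]), 0)
  expect_error(sequencing_total(entries[c(1, 1), ]), "duplicate")
  entries$configuration[1] <- "quartet"
  expect_error(sequencing_total(entries), "configuration")
})

test_that("net cost is sequencing spend minus savings", {
  expect_equal(net_cost(239400, 184846), 54554)
  expect_equal(net_cost(1000, 1000), 0)
  expect_equal(net_cost(100000, 150000), -50000)
})

test_that("ICER divides net cost by QALYs and flags dominance", {
  r <- icer(54554, 12.1)
  expect_identical(r$flag, "finite")
  expect_equal(r$usd_per_qaly, 54554 / 12.1)
  expect_equal(r$usd_per_qaly_rounded, 4509)
  expect_equal(icer(10000, 4)$usd_per_qaly_rounded, 2500)
  expect_identical(icer(-10000, 5)$flag, "dominant")
  expect_identical(icer(10000, 0)$flag, "no_benefit")
  expect_error(icer(1000, -1), ">= 0")
  # rounding identity: icer * qalys recovers net cost within half a dollar
  # per QALY
  for (q in c(0.7, 3.3, 12.1, 40)) {
    nc <- 54554
    expect_lt(abs(icer(nc, q)$usd_per_qaly_rounded * q - nc), 0.5 * q + 1e-9)
  }
})

test_that("value classes bracket the willingness-to-pay thresholds", {
  expect_identical(classify_value(4509), "high_value_conservative")
  expect_identical(classify_value(20000), "high_value")     # strict < below
  expect_identical(classify_value(49999), "high_value")
  expect_identical(classify_value(50000), "borderline")     # strict < below
  expect_identical(classify_value(100000), "borderline")    # inclusive upper
  expect_identical(classify_value(100001), "low_value")
  expect_identical(classify_value(250000), "low_value")
  expect_identical(classify_value(icer(-1, 2)), "dominant")
  expect_identical(classify_value(icer(10, 0)), "low_value")
  expect_error(wtp_thresholds(50000, 20000, 100000), "conservative")
  custom <- wtp_thresholds(1000, 2000, 3000)
  expect_identical(classify_value(1500, custom), "high_value")
})

test_that("cohort yields round to the nearest integer percent", {
  cohort <- tibble::tibble(
    patient_id = as.character(1:38),
    diagnosed = c(rep(TRUE, 17), rep(FALSE, 21)),
    management_change = c(rep(TRUE, 13), rep(FALSE, 25)),
    modeled = c(rep(TRUE, 8), rep(FALSE, 30)))
  s <- cohort_summary(cohort)
  expect_equal(s$yield_diagnosed_pct, 45)          # 44.74 -> 45
  expect_equal(s$yield_management_change_pct, 76)  # 76.47 -> 76
  all10 <- tibble::tibble(patient_id = as.character(1:10), diagnosed = TRUE,
                          management_change = TRUE, modeled = TRUE)
  expect_equal(cohort_summary(all10)$yield_diagnosed_pct, 100)
  small <- tibble::tibble(
    patient_id = as.character(1:8),
    diagnosed = c(rep(TRUE, 3), rep(FALSE, 5)),
    management_change = c(TRUE, rep(FALSE, 7)),
    modeled = FALSE)
  s <- cohort_summary(small)
  expect_equal(s$yield_diagnosed_pct, 38)          # 37.5 rounds away from 0
  expect_equal(s$yield_management_change_pct, 33)  # 33.33 -> 33

  bad <- all10
  bad$diagnosed[1] <- FALSE
  expect_error(cohort_summary(bad), "inconsistent cohort flags.*1")
})

test_that("dollar rounding is half away from zero", {
  expect_equal(round_half_away(4508.595), 4509)
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(2.5), 3)  # base round() would give 2
  expect_equal(round_half_away(1.125, 2), 1.13)  # exactly representable tie
})

test_that("the pipeline equals its stages computed in isolation", {
  syn <- generate_cohort(cohort_config(n_probands = 60, seed = 123))
  res <- run_analysis(syn$cohort, syn$ledger, syn$delphi_responses,
                      syn$qaly_components, syn$sequencing)

  consensus <- delphi_consensus(delphi_score(syn$delphi_responses))
  eff <- ledger_totals(syn$ledger, consensus)
  tot <- cohort_cost_totals(eff)
  expect_equal(res$total_net_savings_usd, tot$total_net_usd)
  expect_equal(res$sequencing_total_usd, sequencing_total(syn$sequencing))
  expect_equal(res$net_cost_usd,
               net_cost(sequencing_total(syn$sequencing), tot$total_net_usd))
  ok_q <- consensus$question_id[consensus$final_status %in%
                                  c("consensus_agree", "consensus_disagree")]
  manual_q <- sum(syn$qaly_components$value[
    syn$qaly_components$source_question_id %in% ok_q])
  expect_equal(res$total_qalys, manual_q)
  if (res$icer$flag == "finite") {
    expect_equal(res$icer$usd_per_qaly, res$net_cost_usd / res$total_qalys)
  }
})

test_that("identical inputs give identical results, and gating is idempotent", {
  fix <- reference_cohort()
  run <- function(ledger) run_analysis(fix$cohort, ledger,
                                       fix$delphi_responses,
                                       fix$qaly_components, fix$sequencing)
  r1 <- run(fix$ledger)
  r2 <- run(fix$ledger)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))

  # dropping the non-consensus patient's items changes no totals
  pruned <- fix$ledger[fix$ledger$patient_id != "6052", ]
  r3 <- run(pruned)
  expect_equal(r3$total_net_savings_usd, r1$total_net_savings_usd)
  expect_equal(r3$total_qalys, r1$total_qalys)
  expect_equal(r3$icer$usd_per_qaly, r1$icer$usd_per_qaly)
})

test_that("a cohort with no modeled patients yields no finite ICER", {
  cohort <- tibble::tibble(patient_id = c("a", "b"), diagnosed = FALSE,
                           management_change = FALSE, modeled = FALSE)
  seq_tbl <- tibble::tibble(patient_id = c("a", "b"),
                            configuration = "trio", cost_usd = 7400)
  empty_items <- tibble::tibble(item_id = character(),
                                patient_id = character(),
                                category = character(),
                                direction = character(),
                                amount_usd = numeric())
  res <- run_analysis(cohort, empty_items, NULL,
                      tibble::tibble(patient_id = character(),
                                     component = character(),
                                     value = numeric()),
                      seq_tbl)
  expect_equal(res$total_net_savings_usd, 0)
  expect_equal(res$net_cost_usd, 14800)
  expect_identical(res$icer$flag, "no_benefit")
  expect_identical(res$value_class, "low_value")
})

test_that("stage failures abort with a stage-tagged message", {
  fix <- reference_cohort()
  bad_ledger <- fix$ledger
  bad_ledger$source_question_id[1] <- "q_nowhere"
  expect_error(
    run_analysis(fix$cohort, bad_ledger, fix$delphi_responses,
                 fix$qaly_components, fix$sequencing),
    "\\[cost_ledger\\].*q_nowhere")
  bad_cohort <- fix$cohort
  bad_cohort$diagnosed[1] <- FALSE
  expect_error(
    run_analysis(bad_cohort, fix$ledger, fix$delphi_responses,
                 fix$qaly_components, fix$sequencing),
    "\\[cohort\\]")
})

test_that("the summary table mirrors the per-patient layout with a total row", {
  res <- fixture_analysis()
  tab <- cea_table(res)
  expect_identical(tab$patient_id[nrow(tab)], "Total")
  expect_equal(tab$net_cost_effect_usd[nrow(tab)], 184846)
  expect_equal(tab$qaly_savings[nrow(tab)], 12.1)
  expect_identical(tab$consensus[tab$patient_id == "6052"], "N")
  p <- plot_cea(res)
  expect_s3_class(p, "ggplot")
})
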
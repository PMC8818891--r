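# Modified-Delphi consensus engine.
#
# Counterfactual care trajectories are adjudicated by an expert panel on a
# five-point Likert scale over at most two survey rounds. A question reaches
# consensus when the panel's mean score is >= 4 (agree) or <= 2 (disagree);
# questions still unresolved after round two are discarded and contribute
# nothing to downstream cost or QALY modeling.

.likert_levels <- c(
  strongly_disagree = 1L,
  disagree          = 2L,
  neutral           = 3L,
  agree             = 4L,
  strongly_agree    = 5L
)
.likert_excluded <- "unable_to_comment"

# Comparisons against the 4.0 / 2.0 consensus thresholds tolerate binary
# floating-point representation error in the mean.
.consensus_tol <- 1e-9

canonical_likert <- function(label) {
  gsub("[ /-]+", "_", tolower(trimws(as.character(label))))
}

#' Encode Likert labels as numeric scores
#'
#' Maps the five substantive panel responses to integer scores 1 (strongly
#' disagree) through 5 (strongly agree). A panelist who marks a question
#' "unable to comment" is excluded from that question's mean; the encoding
#' carries that exclusion as `NA`. Matching is case-insensitive and treats
#' spaces, hyphens and underscores as interchangeable.
#'
#' @param label Character vector of response labels.
#' @return Integer vector: 1-5 for substantive responses, `NA` for
#'   `unable_to_comment` (the exclusion marker).
#' @examples
#' encode_likert(c("strongly agree", "neutral", "unable to comment"))
#' @export
encode_likert <- function(label) {
  canon <- canonical_likert(label)
  out <- .likert_levels[canon]
  out[canon == .likert_excluded] <- NA_integer_
  unknown <- canon[!(canon %in% c(names(.likert_levels), .likert_excluded))]
  if (length(unknown) > 0) {
    stop(sprintf("unknown Likert label(s): %s",
                 paste(sQuote(unique(unknown)), collapse = ", ")),
         call. = FALSE)
  }
  unname(out)
}

#' Score one Delphi round
#'
#' Computes the panel's mean consensus score for a single question and round,
#' excluding `unable_to_comment` responses from both numerator and
#' denominator.
#'
#' @param labels Character vector of Likert labels, one per responding
#'   panelist.
#' @return A list with `mean_score` (`NA` when no valid responses),
#'   `n_valid`, and `n_excluded`.
#' @examples
#' score_round(c("agree", "agree", "neutral", "unable to comment"))
#' @export
score_round <- function(labels) {
  scores <- encode_likert(labels)
  valid <- scores[!is.na(scores)]
  if (length(valid) == 0 && length(scores) > 0) {
    warning("no valid responses in round; question cannot reach consensus",
            call. = FALSE)
  }
  list(
    mean_score = if (length(valid) > 0) mean(valid) else NA_real_,
    n_valid    = length(valid),
    n_excluded = sum(is.na(scores))
  )
}

#' Classify a round mean against the consensus thresholds
#'
#' A mean of 4 or above is agreement consensus; 2 or below is disagreement
#' consensus; anything strictly between is no consensus. Both thresholds are
#' inclusive, with an absolute tolerance of 1e-9 guarding float artifacts.
#'
#' @param mean_score The round's mean consensus score (or the list returned
#'   by [score_round()]).
#' @return One of `"consensus_agree"`, `"consensus_disagree"`, `"none"`.
#' @examples
#' classify_consensus(4.0)  # consensus_agree (inclusive boundary)
#' classify_consensus(3.0)  # none
#' @export
classify_consensus <- function(mean_score) {
  if (is.list(mean_score)) mean_score <- mean_score$mean_score
  if (is.na(mean_score)) return("none")
  stopifnot(is.numeric(mean_score), length(mean_score) == 1L)
  if (mean_score >= 4 - .consensus_tol) return("consensus_agree")
  if (mean_score <= 2 + .consensus_tol) return("consensus_disagree")
  "none"
}

#' Adjudicate one Delphi question over its rounds
#'
#' Applies the two-round stopping rule: consensus in round one finalizes the
#' question immediately (a supplied round two is ignored with a warning);
#' otherwise round two decides; a question without consensus after two rounds
#' is discarded. A question lacking its decisive round is left `pending`.
#'
#' @param rounds A list of one or two character vectors of Likert labels
#'   (round 1, optionally round 2).
#' @param question_id,patient_id Optional identifiers carried into the result.
#' @return A list with `question_id`, `patient_id`, `final_status` (one of
#'   `consensus_agree`, `consensus_disagree`, `no_consensus_discarded`,
#'   `pending`), `decided_in_round`, and `rounds`, a tibble of per-round
#'   scores.
#' @examples
#' run_question(list(c("agree", "strongly agree", "agree")))
#' @export
run_question <- function(rounds, question_id = NA_character_,
                         patient_id = NA_character_) {
  stopifnot(is.list(rounds), length(rounds) >= 1L)
  if (length(rounds) > 2L) {
    stop("at most two Delphi rounds are run; got ", length(rounds),
         call. = FALSE)
  }
  r1 <- score_round(rounds[[1]])
  s1 <- classify_consensus(r1)
  scores <- tibble::tibble(
    round      = 1L,
    mean_score = r1$mean_score,
    n_valid    = r1$n_valid,
    n_excluded = r1$n_excluded,
    status     = s1
  )
  if (s1 != "none") {
    if (length(rounds) == 2L) {
      warning(sprintf(
        "question %s reached consensus in round 1; round 2 responses ignored",
        question_id), call. = FALSE)
    }
    final <- s1
    decided <- 1L
  } else if (length(rounds) == 2L) {
    r2 <- score_round(rounds[[2]])
    s2 <- classify_consensus(r2)
    scores <- dplyr::bind_rows(scores, tibble::tibble(
      round = 2L, mean_score = r2$mean_score, n_valid = r2$n_valid,
      n_excluded = r2$n_excluded, status = s2))
    final <- if (s2 == "none") "no_consensus_discarded" else s2
    decided <- 2L
  } else {
    warning(sprintf(
      "question %s: no consensus in round 1 and no round 2 supplied; pending",
      question_id), call. = FALSE)
    final <- "pending"
    decided <- NA_integer_
  }
  list(question_id = question_id, patient_id = patient_id,
       final_status = final, decided_in_round = decided, rounds = scores)
}

#' Score a table of Delphi responses
#'
#' Adjudicates every question in a long response table (one row per panelist
#' per question per round) and returns per-question, per-round scores with
#' final statuses — the consensus gate consumed by the cost ledger and QALY
#' stages.
#'
#' @param responses A data frame with columns `question_id`, `patient_id`,
#'   `panelist_id`, `round` (1 or 2), `label`.
#' @return A tibble with one row per question and scored round:
#'   `question_id`, `patient_id`, `round`, `mean_score`, `n_valid`,
#'   `n_excluded`, `round_status`, `final_status`, `panel_size`.
#' @examples
#' resp <- tibble::tibble(
#'   question_id = "q1", patient_id = "p1",
#'   panelist_id = paste0("r", 1:3), round = 1L,
#'   label = c("agree", "agree", "strongly agree"))
#' delphi_score(resp)
#' @export
delphi_score <- function(responses) {
  responses <- tibble::as_tibble(responses)
  needed <- c("question_id", "patient_id", "panelist_id", "round", "label")
  missing_cols <- setdiff(needed, names(responses))
  if (length(missing_cols) > 0) {
    stop("response table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(responses$round %in% c(1L, 2L))) {
    stop("`round` must be 1 or 2", call. = FALSE)
  }
  dup <- responses |>
    dplyr::count(.data$question_id, .data$round, .data$panelist_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    stop("a panelist answered the same question twice in one round: ",
         paste(unique(dup$panelist_id), collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(split(responses, responses$question_id), function(q) {
    rounds <- lapply(sort(unique(q$round)), function(r) q$label[q$round == r])
    res <- run_question(rounds, question_id = q$question_id[1],
                        patient_id = q$patient_id[1])
    dplyr::mutate(res$rounds,
      question_id  = res$question_id,
      patient_id   = res$patient_id,
      round_status = .data$status,
      final_status = res$final_status,
      panel_size   = .data$n_valid + .data$n_excluded
    ) |>
      dplyr::select("question_id", "patient_id", "round", "mean_score",
                    "n_valid", "n_excluded", "round_status", "final_status",
                    "panel_size")
  })
}

#' Extract the final consensus status per question
#'
#' @param scored Output of [delphi_score()].
#' @return A tibble with `question_id`, `patient_id`, `final_status` (one row
#'   per question).
#' @export
delphi_consensus <- function(scored) {
  scored |>
    dplyr::distinct(.data$question_id, .data$patient_id, .data$final_status)
}
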
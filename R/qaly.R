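# QALY decision-tree model.
#
# Outcomes are modeled as a one-shot probability-weighted tree: internal
# nodes split probability mass over mutually exclusive clinical outcomes,
# leaves carry a quality-of-life weight Q in [0, 1] and a duration in years,
# and a leaf's QALYs are Q x years (optionally discounted annually).
# Expected QALYs are the probability-weighted sum over root-to-leaf paths.

.prob_tol <- 1e-9

#' Construct an outcome leaf
#'
#' @param label Short outcome description (e.g. "death",
#'   "moderate impairment", "intact survival").
#' @param qol_weight Quality-of-life weight in `[0, 1]` (0 = death,
#'   1 = perfect health).
#' @param duration_years Non-negative remaining life expectancy, in years,
#'   under this outcome.
#' @return An `outcome_leaf` object.
#' @examples
#' outcome_leaf("intact survival", qol_weight = 1, duration_years = 70)
#' @export
outcome_leaf <- function(label, qol_weight, duration_years) {
  assert_nonneg_scalar(duration_years, "duration_years")
  if (!is.numeric(qol_weight) || length(qol_weight) != 1L ||
      !is.finite(qol_weight) || qol_weight < 0 || qol_weight > 1) {
    stop("`qol_weight` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(
    list(label = as.character(label), qol_weight = qol_weight,
         duration_years = duration_years),
    class = "outcome_leaf"
  )
}

#' Construct an internal outcome-tree node
#'
#' @param ... Branches, each a list with elements `prob` (branch probability)
#'   and `node` (an `outcome_leaf` or another `outcome_node`). Branch
#'   probabilities must sum to 1 within 1e-9.
#' @param label Optional node label used in validation messages and the
#'   audit trail.
#' @return An `outcome_node` object.
#' @examples
#' outcome_node(
#'   list(prob = 0.12, node = outcome_leaf("death", 0, 0)),
#'   list(prob = 0.88, node = outcome_leaf("survival", 1, 70)),
#'   label = "second CNS bleed")
#' @export
outcome_node <- function(..., label = NULL) {
  branches <- list(...)
  if (length(branches) == 1L && is.null(branches[[1]]$prob) &&
      is.null(branches[[1]]$node)) {
    branches <- branches[[1]]  # allow a pre-built list of branches
  }
  if (length(branches) == 0) stop("an outcome node needs branches", call. = FALSE)
  node <- structure(list(branches = branches, label = label),
                    class = "outcome_node")
  validate_outcome_tree(node)
  node
}

#' Validate an outcome tree
#'
#' Checks recursively that every internal node's branch probabilities are in
#' `[0, 1]` and sum to 1 within 1e-9, and that every leaf is well formed.
#'
#' @param tree An `outcome_leaf` or `outcome_node`.
#' @return The tree, invisibly; errors name the offending node.
#' @export
validate_outcome_tree <- function(tree) {
  if (inherits(tree, "outcome_leaf")) return(invisible(tree))
  if (!inherits(tree, "outcome_node")) {
    stop("outcome tree nodes must be outcome_leaf or outcome_node objects",
         call. = FALSE)
  }
  where <- if (is.null(tree$label)) "unnamed node" else sQuote(tree$label)
  probs <- vapply(tree$branches, function(b) {
    if (is.null(b$prob) || is.null(b$node)) {
      stop(sprintf("branch of %s must have `prob` and `node`", where),
           call. = FALSE)
    }
    b$prob
  }, numeric(1))
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop(sprintf("branch probabilities of %s must lie in [0, 1]", where),
         call. = FALSE)
  }
  if (abs(sum(probs) - 1) > .prob_tol) {
    stop(sprintf("branch probabilities of %s sum to %.12g, not 1",
                 where, sum(probs)), call. = FALSE)
  }
  for (b in tree$branches) validate_outcome_tree(b$node)
  invisible(tree)
}

# Discounted year-sum: full years discounted at (1+r)^-t, t = 1..floor(Y);
# a fractional final year is prorated linearly at the next year's factor.
discounted_years <- function(years, discount_rate) {
  if (discount_rate == 0) return(years)
  full <- floor(years)
  frac <- years - full
  v <- if (full > 0) sum((1 + discount_rate)^-(seq_len(full))) else 0
  if (frac > 0) v <- v + frac * (1 + discount_rate)^-(full + 1)
  v
}

#' QALYs accrued at one outcome leaf
#'
#' Undiscounted, a leaf is worth `qol_weight * duration_years`. With an
#' annual discount rate r > 0, each full year t contributes
#' `(1+r)^-t` and a fractional final year is prorated linearly, so the
#' discounted value converges to the undiscounted one as r -> 0.
#'
#' @param leaf An [outcome_leaf()].
#' @param discount_rate Annual discount rate, `>= 0` (default 0).
#' @return Non-negative QALYs.
#' @examples
#' leaf_qaly(outcome_leaf("survival", 0.5, 70))  # 35
#' @export
leaf_qaly <- function(leaf, discount_rate = 0) {
  stopifnot(inherits(leaf, "outcome_leaf"))
  if (!is.numeric(discount_rate) || length(discount_rate) != 1L ||
      !is.finite(discount_rate) || discount_rate < 0) {
    stop("`discount_rate` must be a single number >= 0", call. = FALSE)
  }
  leaf$qol_weight * discounted_years(leaf$duration_years, discount_rate)
}

#' Expected QALYs of an outcome tree
#'
#' The probability-weighted sum over all root-to-leaf paths of each leaf's
#' QALYs — the standard expected value of a one-shot decision tree.
#'
#' @param tree An `outcome_leaf` or `outcome_node`.
#' @inheritParams leaf_qaly
#' @return Non-negative expected QALYs.
#' @examples
#' tree <- outcome_node(
#'   list(prob = 0.12, node = outcome_leaf("death", 0, 0)),
#'   list(prob = 0.88, node = outcome_leaf("survival", 1, 70)))
#' expected_qalys(tree)  # 0.88 * 70
#' @export
expected_qalys <- function(tree, discount_rate = 0) {
  validate_outcome_tree(tree)
  if (inherits(tree, "outcome_leaf")) return(leaf_qaly(tree, discount_rate))
  sum(vapply(tree$branches,
             function(b) b$prob * expected_qalys(b$node, discount_rate),
             numeric(1)))
}

#' Enumerate an outcome tree's root-to-leaf paths
#'
#' Audit trail for a tree evaluation: every path, its probability, the
#' leaf's QALYs and its contribution to the expectation. The contributions
#' sum to [expected_qalys()].
#'
#' @inheritParams expected_qalys
#' @return A tibble with columns `path`, `probability`, `qol_weight`,
#'   `duration_years`, `leaf_qalys`, `contribution`.
#' @export
outcome_paths <- function(tree, discount_rate = 0) {
  validate_outcome_tree(tree)
  walk <- function(node, prob, trail) {
    if (inherits(node, "outcome_leaf")) {
      lq <- leaf_qaly(node, discount_rate)
      return(tibble::tibble(
        path = paste(c(trail, node$label), collapse = " > "),
        probability = prob,
        qol_weight = node$qol_weight,
        duration_years = node$duration_years,
        leaf_qalys = lq,
        contribution = prob * lq))
    }
    here <- c(trail, if (!is.null(node$label)) node$label)
    dplyr::bind_rows(lapply(node$branches,
                            function(b) walk(b$node, prob * b$prob, here)))
  }
  walk(tree, 1, character())
}

#' QALY gain attributable to an intervention
#'
#' Difference in expected QALYs between the trajectory with the intervention
#' and the counterfactual trajectory without it; negative when the
#' intervention is harmful.
#'
#' @param with_intervention,without_intervention Outcome trees.
#' @inheritParams leaf_qaly
#' @return Expected QALYs(with) - expected QALYs(without).
#' @export
qaly_gain <- function(with_intervention, without_intervention,
                      discount_rate = 0) {
  expected_qalys(with_intervention, discount_rate) -
    expected_qalys(without_intervention, discount_rate)
}

#' Total QALYs for one patient from named components
#'
#' Patient-level QALY gains often decompose into named components (e.g.
#' avoided-mortality and avoided-morbidity QALYs); the patient total is their
#' exact sum.
#'
#' @param components Named numeric vector of QALY components (may be empty).
#' @param patient_id Optional identifier carried into the result.
#' @return A list with `patient_id`, `components`, `total_qalys`.
#' @examples
#' patient_qaly_total(c(mortality = 9.08, morbidity = 2.90))$total_qalys
#' @export
patient_qaly_total <- function(components, patient_id = NA_character_) {
  if (length(components) > 0 &&
      (!is.numeric(components) || any(!is.finite(components)))) {
    stop("QALY components must be finite numbers", call. = FALSE)
  }
  list(patient_id = patient_id,
       components = components,
       total_qalys = if (length(components) > 0) sum(components) else 0)
}

#' Cohort total QALYs
#'
#' @param results A list of [patient_qaly_total()] results, or a tibble with
#'   columns `patient_id` and `total_qalys`.
#' @return The summed cohort QALYs.
#' @export
cohort_qaly_total <- function(results) {
  if (is.data.frame(results)) {
    ids <- results$patient_id
    totals <- results$total_qalys
  } else {
    ids <- vapply(results, `[[`, character(1), "patient_id")
    totals <- vapply(results, `[[`, numeric(1), "total_qalys")
  }
  dup <- unique(ids[duplicated(ids) & !is.na(ids)])
  if (length(dup) > 0) {
    stop("duplicate patient_id in QALY results: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  sum(totals)
}

#' Sex-specific remaining life expectancy lookup
#'
#' Linear interpolation in age within each sex over a life table of
#' (sex, age_years, remaining_years) rows; ages outside the table range are
#' clamped to the nearest tabulated age.
#'
#' @param table Data frame with columns `sex`, `age_years`,
#'   `remaining_years`.
#' @param sex,age_years The lookup key.
#' @return Remaining life expectancy in years.
#' @export
life_expectancy <- function(table, sex, age_years) {
  table <- tibble::as_tibble(table)
  rows <- table[table$sex == sex, ]
  if (nrow(rows) == 0) {
    stop("no life-table rows for sex ", sQuote(sex), call. = FALSE)
  }
  rows <- rows[order(rows$age_years), ]
  stats::approx(rows$age_years, rows$remaining_years, xout = age_years,
                rule = 2, ties = "ordered")$y
}

#' Read an outcome tree from a JSON document
#'
#' The document is a nested object: internal nodes have a `branches` array
#' (each element with `prob` and `node`), leaves have `label`, `qol_weight`
#' and `duration_years`.
#'
#' @param path Path to a JSON file.
#' @return A validated outcome tree.
#' @export
read_outcome_tree <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_outcome_tree(doc)
}

# Recursive conversion from plain nested lists (e.g. parsed JSON).
as_outcome_tree <- function(x) {
  if (inherits(x, c("outcome_leaf", "outcome_node"))) return(x)
  if (!is.null(x$branches)) {
    branches <- lapply(x$branches, function(b) {
      list(prob = b$prob, node = as_outcome_tree(b$node))
    })
    return(outcome_node(branches, label = x$label))
  }
  outcome_leaf(x$label %||% "outcome", x$qol_weight, x$duration_years)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
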
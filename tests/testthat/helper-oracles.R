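# Independent oracles used across tests.

# Brute-force expected QALYs: explicit stack-based enumeration of every
# root-to-leaf path, with the leaf value computed from first principles
# (closed-form geometric series for discounting) rather than via leaf_qaly().
oracle_expected_qalys <- function(tree, discount_rate = 0) {
  leaf_value <- function(leaf) {
    y <- leaf$duration_years
    if (discount_rate == 0) return(leaf$qol_weight * y)
    r <- discount_rate
    full <- floor(y)
    frac <- y - full
    yrs <- (1 - (1 + r)^(-full)) / r            # sum_{t=1..full} (1+r)^-t
    if (frac > 0) yrs <- yrs + frac * (1 + r)^(-(full + 1))
    leaf$qol_weight * yrs
  }
  total <- 0
  stack <- list(list(node = tree, prob = 1))
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (inherits(cur$node, "outcome_leaf")) {
      total <- total + cur$prob * leaf_value(cur$node)
    } else {
      for (b in cur$node$branches) {
        stack[[length(stack) + 1L]] <- list(node = b$node,
                                            prob = cur$prob * b$prob)
      }
    }
  }
  total
}

# Random outcome tree, depth <= max_depth, 2-4 children per internal node.
random_tree <- function(max_depth = 4) {
  build <- function(depth) {
    if (depth >= max_depth || runif(1) < 0.4) {
      return(outcome_leaf(paste0("leaf", round(runif(1) * 1e6)),
                          qol_weight = runif(1),
                          duration_years = runif(1, 0, 80)))
    }
    k <- sample(2:4, 1)
    w <- runif(k)
    p <- w / sum(w)
    branches <- lapply(seq_len(k), function(i) {
      list(prob = p[i], node = build(depth + 1))
    })
    outcome_node(branches)
  }
  build(0)
}

# Strip classes so a tree can be serialized to plain JSON.
unclass_tree <- function(tree) {
  if (inherits(tree, "outcome_leaf")) return(unclass(tree))
  list(label = tree$label,
       branches = lapply(tree$branches, function(b) {
         list(prob = b$prob, node = unclass_tree(b$node))
       }))
}

fixture_analysis <- function() {
  fix <- reference_cohort()
  run_analysis(fix$cohort, fix$ledger, fix$delphi_responses,
               fix$qaly_components, fix$sequencing)
}
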
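test_that("leaf QALYs are QOL times years, with validation", {
  expect_equal(leaf_qaly(outcome_leaf("intact", 1, 10)), 10)
  expect_equal(leaf_qaly(outcome_leaf("death", 0, 50)), 0)
  expect_equal(leaf_qaly(outcome_leaf("impaired", 0.5, 70)), 35)
  expect_error(outcome_leaf("bad", 1.2, 10), "\\[0, 1\\]")
  expect_error(outcome_leaf("bad", 0.5, -3), ">= 0")
  expect_error(leaf_qaly(outcome_leaf("x", 1, 10), discount_rate = -0.01),
               ">= 0")
})

test_that("annual discounting matches the closed form and is continuous at 0", {
  leaf <- outcome_leaf("x", 0.8, 12.4)
  r <- 0.03
  closed <- 0.8 * ((1 - 1.03^-12) / 0.03 + 0.4 * 1.03^-13)
  expect_equal(leaf_qaly(leaf, r), closed, tolerance = 1e-12)
  # r -> 0 recovers the undiscounted value continuously
  expect_equal(leaf_qaly(leaf, 1e-9), leaf_qaly(leaf, 0), tolerance = 1e-6)
  expect_lt(leaf_qaly(leaf, 0.05), leaf_qaly(leaf, 0))
})

test_that("expected QALYs weight leaves by path probability", {
  expect_equal(expected_qalys(outcome_leaf("only", 1, 10)), 10)
  tree <- outcome_node(
    list(prob = 0.12, node = outcome_leaf("death", 0, 0)),
    list(prob = 0.88, node = outcome_node(
      list(prob = 0.726, node = outcome_leaf("impaired", 0.5, 70)),
      list(prob = 0.274, node = outcome_leaf("intact", 1, 70)))))
  # frozen: 0.88 * (0.726*35 + 0.274*70) = 39.2392
  expect_equal(expected_qalys(tree), 39.2392, tolerance = 1e-12)
  zero <- outcome_node(
    list(prob = 0.5, node = outcome_leaf("a", 0, 10)),
    list(prob = 0.5, node = outcome_leaf("b", 0, 20)))
  expect_equal(expected_qalys(zero), 0)
  expect_error(outcome_node(
    list(prob = 0.5, node = outcome_leaf("a", 1, 1)),
    list(prob = 0.6, node = outcome_leaf("b", 1, 1)),
    label = "bad node"), "bad node")
})

test_that("expected QALYs equal brute-force path enumeration on random trees", {
  set.seed(11)
  for (i in 1:50) {
    tree <- random_tree()
    expect_equal(expected_qalys(tree), oracle_expected_qalys(tree),
                 tolerance = 1e-9)
    r <- runif(1, 0, 0.08)
    expect_equal(expected_qalys(tree, r), oracle_expected_qalys(tree, r),
                 tolerance = 1e-9)
  }
})

test_that("expected QALYs are bounded and monotone in leaf quality", {
  set.seed(12)
  for (i in 1:20) {
    tree <- random_tree()
    paths <- outcome_paths(tree)
    expect_lte(expected_qalys(tree), max(paths$duration_years) + 1e-9)
    # raise one random leaf's qol weight; expectation must not decrease
    bump <- function(node) {
      if (inherits(node, "outcome_leaf")) {
        node$qol_weight <- min(1, node$qol_weight + runif(1, 0, 0.5))
        return(node)
      }
      j <- sample(length(node$branches), 1)
      node$branches[[j]]$node <- bump(node$branches[[j]]$node)
      node
    }
    expect_gte(expected_qalys(bump(tree)), expected_qalys(tree) - 1e-12)
  }
})

test_that("shifting probability mass toward the better child cannot lose QALYs", {
  set.seed(13)
  for (i in 1:20) {
    a <- random_tree(); b <- random_tree()
    va <- expected_qalys(a); vb <- expected_qalys(b)
    p <- runif(1, 0.1, 0.9)
    shift <- runif(1, 0, min(p, 1 - p))
    tree_at <- function(p) outcome_node(list(prob = p, node = a),
                                        list(prob = 1 - p, node = b))
    towards_better <- if (va >= vb) p + shift else p - shift
    expect_gte(expected_qalys(tree_at(towards_better)),
               expected_qalys(tree_at(p)) - 1e-12)
  }
})

test_that("intervention gain is a tree difference and antisymmetric", {
  a <- outcome_leaf("intact", 1, 20)
  b <- outcome_leaf("death", 0, 0)
  expect_equal(qaly_gain(a, a), 0)
  expect_equal(qaly_gain(a, b), 20)
  set.seed(14)
  for (i in 1:10) {
    x <- random_tree(); y <- random_tree()
    expect_equal(qaly_gain(x, y), -qaly_gain(y, x), tolerance = 1e-12)
  }
  # removing a fatal branch gains exactly its probability-weighted loss
  survive <- outcome_leaf("intact", 1, 70)
  without <- outcome_node(list(prob = 0.12, node = outcome_leaf("death", 0, 0)),
                          list(prob = 0.88, node = survive))
  expect_equal(qaly_gain(survive, without), 0.12 * 70, tolerance = 1e-12)
})

test_that("patient and cohort QALY totals are exact sums with duplicate guard", {
  p <- patient_qaly_total(c(mortality = 9.08, morbidity = 2.90), "6207")
  expect_equal(p$total_qalys, 11.98)
  expect_equal(patient_qaly_total(numeric(0))$total_qalys, 0)
  expect_equal(patient_qaly_total(c(a = 0.12))$total_qalys, 0.12)
  expect_error(patient_qaly_total(c(a = NaN)), "finite")

  res <- list(patient_qaly_total(c(a = 0.12), "6153"),
              patient_qaly_total(c(m = 9.08, n = 2.90), "6207"))
  expect_equal(cohort_qaly_total(res), 12.1)
  expect_equal(cohort_qaly_total(list()), 0)
  expect_equal(cohort_qaly_total(
    tibble::tibble(patient_id = c("a", "b", "c"),
                   total_qalys = c(1.5, 2.5, 3.0))), 7)
  expect_error(cohort_qaly_total(
    tibble::tibble(patient_id = c("a", "a"), total_qalys = c(1, 2))),
    "duplicate")
})

test_that("life expectancy interpolates within sex and clamps at the ends", {
  lt <- tibble::tibble(
    sex = rep(c("male", "female"), each = 3),
    age_years = rep(c(0, 40, 80), 2),
    remaining_years = c(76, 39, 8, 81, 43, 10))
  expect_equal(life_expectancy(lt, "male", 40), 39)
  expect_equal(life_expectancy(lt, "female", 20), (81 + 43) / 2)
  expect_equal(life_expectancy(lt, "male", 100), 8)   # clamped
  expect_error(life_expectancy(lt, "unknown", 10), "no life-table rows")
})

test_that("outcome trees round-trip through JSON and audit paths sum up", {
  tree <- outcome_node(
    list(prob = 0.3, node = outcome_leaf("death", 0, 0)),
    list(prob = 0.7, node = outcome_node(
      list(prob = 0.4, node = outcome_leaf("impaired", 0.6, 50)),
      list(prob = 0.6, node = outcome_leaf("intact", 1, 65)))),
    label = "root")
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(unclass_tree(tree), auto_unbox = TRUE), path)
  back <- read_outcome_tree(path)
  expect_equal(expected_qalys(back), expected_qalys(tree))
  paths <- outcome_paths(tree)
  expect_equal(sum(paths$contribution), expected_qalys(tree))
  expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
})
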
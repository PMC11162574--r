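test_that("euclidean distance matches hand values and is symmetric", {
  expect_identical(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(euclidean_distance(c(0, 0, 0, 0), c(3, 4, 0, 0)), 5)
  p <- c(0.3, 5, 2, 1)
  q <- c(4, 0.1, 2, 9)
  expect_identical(euclidean_distance(p, q), euclidean_distance(q, p))
  expect_error(euclidean_distance(1:3, 1:4), "length mismatch")
})

test_that("euclidean distance agrees with a naive summation oracle", {
  set.seed(21)
  for (i in 1:200) {
    p <- stats::rnorm(4, 3, 2)
    q <- stats::rnorm(4, 3, 2)
    expect_equal(euclidean_distance(p, q), oracle_euclidean(p, q),
                 tolerance = 1e-12)
  }
})

test_that("combined profiles add on the raw scale", {
  # all-zero raw child leaves the parent unchanged
  parent <- c(2, 1, 0.5, 0)
  expect_equal(combined_profile(parent, c(0, 0, 0, 0), scale = "log2p1"),
               parent)
  # raw-scale addition is plain addition
  expect_identical(combined_profile(c(1, 1, 1, 1), c(1, 1, 1, 1), scale = "raw"),
                   c(2, 2, 2, 2))
  # log 1 + log 1: raw 1 + 1 = 2, re-logged log2(3)
  expect_equal(combined_profile(1, 1), log2(3))
})

test_that("E_div selection uses the linear-interpolation quantile", {
  expect_equal(as.numeric(select_ediv(rep(1, 100), q = 0.5)), 1)
  ed <- select_ediv(1:100, q = 0.9)
  expect_equal(as.numeric(ed), 90.1)
  expect_identical(attr(ed, "q"), 0.9)
  expect_error(select_ediv(1:10, q = 0.9), "supply e_div explicitly")
  expect_error(select_ediv(1:100, q = 1.2), "between 0 and 1")
})

test_that("the fate rules fire one branch per distance pattern", {
  expect_identical(as.character(classify_fate(0.1, 0.2, 0.1, 0.5)), "conserved")
  expect_identical(as.character(classify_fate(0.1, 0.9, 0.8, 0.5)),
                   "neofunctionalized(child)")
  expect_identical(as.character(classify_fate(0.9, 0.1, 0.8, 0.5)),
                   "neofunctionalized(parent)")
  expect_identical(as.character(classify_fate(0.9, 0.9, 0.3, 0.5)),
                   "subfunctionalized")
  expect_identical(as.character(classify_fate(0.9, 0.9, 0.9, 0.5)),
                   "specialized")
  # ties at the cutoff go toward conservation
  expect_identical(as.character(classify_fate(0.5, 0.5, 0.9, 0.5)), "conserved")
})

test_that("the five fate branches partition every sign pattern", {
  e_div <- 1
  lo <- 0.4
  hi <- 1.7
  for (ep in c(lo, hi)) for (ec in c(lo, hi)) for (eb in c(lo, hi)) {
    fate <- classify_fate(ep, ec, eb, e_div)
    expect_length(fate, 1)
    expect_false(is.na(fate))
    # recompute the expected branch independently
    expected <- if (ep <= e_div && ec <= e_div) "conserved"
    else if (ep <= e_div) "neofunctionalized(child)"
    else if (ec <= e_div) "neofunctionalized(parent)"
    else if (eb <= e_div) "subfunctionalized"
    else "specialized"
    expect_identical(as.character(fate), expected)
  }
})

test_that("fate x duplication-type tables count and normalize correctly", {
  calls <- data.frame(fate = rep("conserved", 10), dup_type = rep("WGD", 10),
                      stringsAsFactors = FALSE)
  ft <- fate_by_dup_type(calls)
  expect_identical(sum(ft$counts), 10L)
  expect_identical(as.integer(ft$counts["conserved", "WGD"]), 10L)
  expect_equal(unname(colSums(ft$proportions)[colSums(ft$counts) > 0]), 1)

  mixed <- data.frame(fate = c("conserved", "specialized", "conserved"),
                      dup_type = c("WGD", "TD", "TD"), stringsAsFactors = FALSE)
  fm <- fate_by_dup_type(mixed)
  expect_equal(unname(colSums(fm$proportions)[c("WGD", "TD")]), c(1, 1))
  expect_identical(sum(fm$counts), 3L)

  empty <- fate_by_dup_type(data.frame(fate = character(),
                                       dup_type = character()))
  expect_identical(sum(empty$counts), 0L)
  expect_error(fate_by_dup_type(data.frame(fate = "conserved", dup_type = "XX")),
               "unknown duplication type")
})

test_that("fate_analysis wires distances, cutoff and calls together", {
  sim <- simulate_fate_dataset(31, n_single = 200, n_per_fate = 10)
  res <- fate_analysis(log_transform(sim$expr_ref), log_transform(sim$expr_dup),
                       sim$pairs)
  expect_identical(nrow(res$calls), 40L)
  expect_length(res$single_distances, 200)
  expect_gt(res$e_div, 0)
  expect_identical(res$q, 0.9)
  # user-supplied cutoff overrides selection
  res2 <- fate_analysis(log_transform(sim$expr_ref), log_transform(sim$expr_dup),
                        sim$pairs, e_div = 99)
  expect_identical(res2$e_div, 99)
  expect_true(all(res2$calls$fate == "conserved"))
  # scale guard
  expect_error(fate_analysis(sim$expr_ref, log_transform(sim$expr_dup), sim$pairs),
               "log2")
})
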
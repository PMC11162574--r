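test_that("A/B log ratios match hand calculations", {
  # balanced everywhere
  ct <- tiny_counts(c(100, 100), c(100, 100), c(100, 100), c(100, 100),
                    ids = "p1")
  r <- compute_ratios(ct, pseudocount = 0, lib_norm = FALSE)$ratios
  expect_equal(r$A, 0)
  expect_equal(r$B, 0)
  expect_equal(r$trans, 0)

  # two-fold everywhere: A = B = 1, trans = 0
  ct <- tiny_counts(c(200, 200), c(100, 100), c(200, 200), c(100, 100),
                    ids = "p1")
  r <- compute_ratios(ct, pseudocount = 0, lib_norm = FALSE)$ratios
  expect_equal(r$A, 1)
  expect_equal(r$B, 1)
  expect_equal(r$trans, 0)

  # divergence only in the allopolyploid: A = 0, B = 1, trans = -1
  ct <- tiny_counts(c(100, 100), c(100, 100), c(200, 200), c(100, 100),
                    ids = "p1")
  r <- compute_ratios(ct, pseudocount = 0, lib_norm = FALSE)$ratios
  expect_equal(r$A, 0)
  expect_equal(r$B, 1)
  expect_equal(r$trans, -1)
})

test_that("all-zero ratios are flagged untestable", {
  ct <- tiny_counts(c(0, 0), c(0, 0), c(5, 5), c(5, 5), ids = "p1")
  r <- compute_ratios(ct)$ratios
  expect_true(r$untestable_A)
  expect_false(r$untestable_B)
})

test_that("the divergence test matches closed-form binomial tails", {
  expect_equal(test_divergence(50, 50), 1)
  expect_equal(test_divergence(10, 0), 2 * 0.5^10)
  expect_identical(test_divergence(0, 0), NA_real_)
  # dispersion deflates the evidence: p can only grow
  p0 <- test_divergence(c(300, 310, 290), c(110, 90, 100), dispersion = 0)
  p1 <- test_divergence(c(300, 310, 290), c(110, 90, 100), dispersion = 0.05)
  expect_gt(p1, p0)
})

test_that("the trans t-test matches the pooled-variance oracle", {
  expect_equal(test_trans(c(1, 1, 1), c(1, 1, 1)), 1)
  # near-identical vectors stay far from significance (what little
  # variation exists is all within-group)
  expect_gt(test_trans(c(1, 1, 1), c(1, 1, 1.0000001)), 0.05)
  expect_identical(test_trans(1, c(1, 2)), NA_real_)
  x <- c(0, 0, 0.1)
  y <- c(2, 2, 2.1)
  t_stat <- oracle_student_t(x, y)
  p_want <- 2 * stats::pt(-abs(t_stat), length(x) + length(y) - 2)
  expect_equal(test_trans(x, y), p_want, tolerance = 1e-10)
})

test_that("BH adjustment reproduces the hand-worked step-up", {
  expect_equal(bh_fdr(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.02 * 4 / 3, 0.04))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.031), 0.031)
  expect_identical(bh_fdr(c(0.2, NA, 0.01)), c(0.2, NA, 0.02))
  expect_error(bh_fdr(c(0.1, 1.3)), "\\[0, 1\\]")
})

test_that("BH output matches the oracle and respects monotonicity", {
  set.seed(51)
  for (i in 1:50) {
    p <- stats::runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  # lowering any p never raises any q
  p <- stats::runif(20)
  q0 <- bh_fdr(p)
  p2 <- p
  p2[7] <- p2[7] / 10
  expect_true(all(bh_fdr(p2) <= q0 + 1e-12))
})

test_that("the seven categories partition all flag/sign combinations", {
  combos <- expand.grid(sig_a = c(TRUE, FALSE), sig_b = c(TRUE, FALSE),
                        sig_ab = c(TRUE, FALSE), sign_b = c(-1, 1),
                        sign_trans = c(-1, 1))
  cat <- assign_category(combos$sig_a, combos$sig_b, combos$sig_ab,
                         combos$sign_b, combos$sign_trans)
  expect_false(any(is.na(cat)))
  # every combination lands in exactly one of the seven categories
  expect_true(all(cat %in% cis_trans_categories$category))
  # the labelled anchor cases
  expect_identical(as.character(assign_category(FALSE, FALSE, FALSE, 1, 1)), "VI")
  expect_identical(as.character(assign_category(TRUE, TRUE, FALSE, 1, 1)), "I")
  expect_identical(as.character(assign_category(TRUE, FALSE, TRUE, 1, 1)), "II")
  expect_identical(as.character(assign_category(FALSE, TRUE, TRUE, 1, 1)), "V")
  expect_identical(as.character(assign_category(TRUE, TRUE, TRUE, 1, 1)), "III")
  expect_identical(as.character(assign_category(TRUE, TRUE, TRUE, 1, -1)), "IV")
  # untestable flags route to ambiguous
  expect_identical(as.character(assign_category(NA, TRUE, TRUE, 1, 1)), "VII")
})

test_that("category summaries normalize and compare distributions", {
  calls <- data.frame(category = rep("VI", 8), stringsAsFactors = FALSE)
  s <- category_summary(calls)
  expect_equal(s$proportion[s$category == "VI"], 1)
  expect_equal(sum(s$proportion), 1)
  expect_error(category_summary(calls[0, , drop = FALSE]), "no category calls")

  cmp_same <- compare_category_sets(calls, calls)
  expect_equal(cmp_same$p, 1)
  expect_equal(cmp_same$statistic, 0)

  c1 <- data.frame(category = rep(c("I", "VI"), c(10, 20)))
  c2 <- data.frame(category = rep(c("I", "VI"), c(20, 10)))
  cmp <- compare_category_sets(c1, c2)
  expect_equal(cmp$statistic, oracle_chisq(cmp$table), tolerance = 1e-12)
})

test_that("planted regulatory categories are recovered from counts", {
  sim <- simulate_count_dataset(52, n_pairs = 300)
  calls <- call_cis_trans(sim$counts)
  truth <- sim$truth$category[match(calls$pair_id, sim$truth$pair_id)]
  keep <- truth %in% c("I", "II", "III", "VI")
  expect_gt(mean(as.character(calls$category)[keep] == truth[keep]), 0.85)
  # ratio estimates track the planted effects
  expect_lt(stats::median(abs(calls$A - (sim$truth$cis + sim$truth$trans))), 0.3)
})

test_that("the noiseless deterministic limit recovers every planted category", {
  sim <- simulate_count_dataset(53, n_pairs = 120, noiseless = TRUE)
  calls <- call_cis_trans(sim$counts, dispersion = 0, lib_norm = FALSE)
  expect_identical(as.character(calls$category), sim$truth$category)
})
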
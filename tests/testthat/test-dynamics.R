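# Concentration dynamics: Bland-Altman, baseline and delta summaries,
# exact rank-sum test, Spearman correlation.

part1_clusters <- function() {
  tp <- schedule_timepoints("part1")
  list(baseline = tp[1:2], chemo = tp[3:5], rt = tp[6:8])
}

test_that("Bland-Altman collapses to zero on perfect test-retest agreement", {
  s <- series_from_matrix(matrix(c(4, 4, 7, 7), nrow = 2, byrow = TRUE),
                          patients = c("p1", "p2"),
                          histology = c("AC", "SCC"),
                          timepoints = c("baseline_test",
                                         "baseline_retest"))
  ba <- bland_altman(s, grouping = list(baseline = c("baseline_test",
                                                     "baseline_retest")))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$lower, ba$upper), c(0, 0))
})

test_that("Bland-Altman limits match the hand-computed n-1 form", {
  s <- series_from_matrix(matrix(c(4, 6), nrow = 1),
                          patients = "p1", histology = "AC",
                          timepoints = c("baseline_test",
                                         "baseline_retest"))
  ba <- bland_altman(s, grouping = list(baseline = c("baseline_test",
                                                     "baseline_retest")))
  expect_equal(sort(ba$differences$diff), c(-1, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$upper, 1.96 * sqrt(2))          # ~2.772
  expect_equal(ba$lower, -1.96 * sqrt(2))
})

test_that("Bland-Altman limits equal a first-principles recomputation", {
  pats <- data.frame(patient = sprintf("p%02d", 1:12),
                     histology = rep(c("AC", "SCC"), 6),
                     baseline = runif(12, 2, 10))
  s <- simulate_concentrations(schedule_timepoints("part1"), pats,
                               sd_meas = 1, seed = 5)
  ba <- bland_altman(s, grouping = part1_clusters())
  d <- ba$differences$diff
  expect_equal(ba$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(ba$sd_diff, sd(d), tolerance = 1e-12)
  expect_equal(ba$upper, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$lower, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
})

test_that("simulated part-1 limits match the closed-form deviation SD", {
  # deviations from a size-m cluster mean have SD sigma*sqrt(1 - 1/m);
  # pooling one pair and two triplets gives sigma*sqrt(5/8)
  pats <- data.frame(patient = seq_len(200), histology = "AC",
                     baseline = rep(5, 200))
  s <- simulate_concentrations(schedule_timepoints("part1"), pats,
                               sd_meas = 1, seed = 8)
  ba <- bland_altman(s, grouping = part1_clusters())
  expect_equal(ba$sd_diff, sqrt(5 / 8), tolerance = 0.05)
  expect_equal(ba$upper - ba$lower, 2 * 1.96 * sqrt(5 / 8),
               tolerance = 0.05)
})

test_that("singleton clusters are refused with the patient named", {
  s <- series_from_matrix(matrix(c(4, 6, 3), nrow = 1),
                          patients = "p9", histology = "AC",
                          timepoints = c("baseline_test",
                                         "baseline_retest", "rt_30min"))
  expect_error(
    bland_altman(s, grouping = list(base = c("baseline_test",
                                             "baseline_retest"),
                                    rt = c("rt_30min", "rt_60min"))),
    "p9")
})

test_that("baseline summaries average test/retest and respect subsets", {
  s <- series_from_matrix(
    matrix(c(4, 6, 8, 8), nrow = 2, byrow = TRUE),
    patients = c("p1", "p2"), histology = c("AC", "SCC"),
    timepoints = c("baseline_test", "baseline_retest"))
  bs <- summarize_baseline(s)
  expect_equal(bs$per_patient$ng_per_ml, c(5, 8))  # 4/6 averaged first
  expect_equal(bs$median, 6.5)
  expect_equal(c(bs$min, bs$max), c(5, 8))

  single <- summarize_baseline(s, group_subset = "p1")
  expect_equal(unname(single$group_means["AC"]), 5)

  lone <- series_from_matrix(matrix(3.3), "p1", "AC", "baseline")
  ls <- summarize_baseline(lone)
  expect_equal(c(ls$median, ls$min, ls$max), rep(3.3, 3))
})

test_that("baseline summaries are invariant to row order and duplication", {
  s <- cohort_baseline(as_series = TRUE)
  ref <- summarize_baseline(s)
  shuffled <- s[rev(seq_len(nrow(s))), ]
  doubled <- rbind(s, s[sample(nrow(s)), ])
  class(shuffled) <- class(doubled) <- class(s)
  for (variant in list(shuffled, doubled)) {
    v <- summarize_baseline(variant)
    expect_equal(v$median, ref$median)
    expect_equal(c(v$min, v$max), c(ref$min, ref$max))
    expect_equal(sort(v$group_means), sort(ref$group_means))
  }
})

test_that("change from baseline reports per-histology means and exclusions", {
  tp <- c("baseline", "rt_fx22")
  s <- series_from_matrix(
    matrix(c(5, 5 - 2.2,
             4, 4 + 1.27,
             3, 3 + 3.0), nrow = 3, byrow = TRUE),
    patients = c("a1", "a2", "a3"), histology = rep("AC", 3),
    timepoints = tp)
  d <- change_from_baseline(s, "rt_fx22")
  expect_equal(d$groups$mean, mean(c(-2.2, 1.27, 3.0)))  # 0.69
  expect_equal(d$groups$mean, 0.69)
  expect_equal(c(d$groups$min, d$groups$max), c(-2.2, 3.0))

  # constant series: all deltas zero
  const <- series_from_matrix(matrix(4, 2, 2), c("p1", "p2"),
                              c("AC", "AC"), tp)
  expect_equal(change_from_baseline(const, "rt_fx22")$deltas$delta,
               c(0, 0))

  # a patient missing the timepoint is excluded, not imputed
  partial <- s[!(s$patient == "a3" & s$timepoint == "rt_fx22"), ]
  class(partial) <- class(s)
  dp <- change_from_baseline(partial, "rt_fx22")
  expect_equal(dp$excluded, "a3")
  expect_equal(dp$n_included, 2)
  expect_equal(dp$n_total, 3)

  # a patient with no baseline is an error
  nobase <- s[!(s$patient == "a2" & s$timepoint == "baseline"), ]
  class(nobase) <- class(s)
  expect_error(change_from_baseline(nobase, "rt_fx22"), "a2.*baseline")
})

test_that("zero-trend simulations center the mean delta on zero", {
  pats <- data.frame(patient = 1:6, histology = rep(c("AC", "SCC"), 3),
                     baseline = c(3, 5, 2, 8, 4, 6))
  means <- vapply(1:40, function(seed) {
    s <- simulate_concentrations(schedule_timepoints("part2"), pats,
                                 sd_meas = 1, seed = 500 + seed)
    mean(change_from_baseline(s, "rt_fx22")$deltas$delta)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("exact rank-sum p-values match hand enumeration", {
  expect_equal(rank_sum_exact(1, 1)$p_value, 1)
  expect_equal(rank_sum_exact(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  # p-values for 3 vs 3 live on the grid k/20
  for (seed in 1:10) {
    set.seed(seed)
    p <- rank_sum_exact(rnorm(3), rnorm(3))$p_value
    expect_equal(p * 20, round(p * 20), tolerance = 1e-12)
  }
  expect_error(rank_sum_exact(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum equals brute-force enumeration for all sizes <= 5", {
  set.seed(17)
  for (i in 1:100) {
    n_a <- sample(1:5, 1); n_b <- sample(1:5, 1)
    # integer pools force ties, exercising the midrank path
    a <- sample(1:6, n_a, replace = TRUE)
    b <- sample(1:6, n_b, replace = TRUE)
    expect_equal(rank_sum_exact(a, b)$p_value, brute_rank_sum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("exact rank-sum agrees with wilcox.test on tie-free data", {
  set.seed(23)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    ours <- rank_sum_exact(a, b)$p_value
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("large samples fall back to a tie-corrected normal approximation", {
  set.seed(31)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  ours <- rank_sum_exact(a, b)
  expect_false(ours$exact)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(ours$p_value, ref, tolerance = 1e-9)
})

test_that("Spearman correlation follows midranks", {
  expect_equal(spearman_rho(1:5, 2:6), 1)
  expect_equal(spearman_rho(1:5, 6:2), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_warning(rho <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "undefined")
  expect_true(is.na(rho))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})
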
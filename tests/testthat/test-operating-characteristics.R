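test_that("rejection thresholds are ordered and at the right quantiles", {
  thr <- rejection_thresholds(0.025)
  expect_equal(thr$c_two, qnorm(0.975))
  expect_equal(thr$c_one, qnorm(1 - 0.025^2))
  expect_true(thr$c_one > thr$c_two && thr$c_two > 0)
  expect_error(rejection_thresholds(0.7), "level_a")
})

test_that("two-trial rejection probability matches its closed form", {
  expect_equal(p_two_trial(list(d1 = 0, d2 = 0)), 0.000625)
  # each factor exactly 1/2 when the noncentrality sits at the threshold
  c2 <- qnorm(0.975)
  expect_equal(p_two_trial(list(d1 = c2, d2 = c2)), 0.25)
  # boundary case: one effect huge, the other zero
  expect_equal(p_two_trial(list(d1 = 10, d2 = 0)), 0.025, tolerance = 1e-6)
  expect_error(p_two_trial(list(d = 1)), "d1")
})

test_that("one-trial rejection probability matches closed form and MC oracle", {
  expect_equal(p_one_trial(0), 0.000625)
  expect_equal(p_one_trial(qnorm(1 - 0.000625)), 0.5)
  # independent oracle: simulate the combined statistic directly from the
  # trivariate normal model (z = sqrt(f) z1 + sqrt(1-f) z2 is standard
  # normal around delta)
  set.seed(33)
  z <- sqrt(0.5) * rnorm(1e6) + sqrt(0.5) * rnorm(1e6) + 2.4004
  p_hat <- mean(z > qnorm(1 - 0.025^2))
  p <- p_one_trial(2.4004)
  expect_equal(p, 0.204170, tolerance = 1e-5)
  expect_lt(abs(p - p_hat), 4 * sqrt(p_hat * (1 - p_hat) / 1e6))
  # accepts a noncentrality triple too
  nc <- noncentrality(trial_config(400, 0.1), effect_scenario(0.6, 0.2))
  expect_equal(p_one_trial(nc), p_one_trial(2.4))
})

test_that("both probabilities increase strictly in every noncentrality", {
  ds <- seq(-3, 3, by = 0.5)
  p2_d1 <- p_two_trial(list(d1 = ds, d2 = 0.7))
  p2_d2 <- p_two_trial(list(d1 = -0.4, d2 = ds))
  p1 <- p_one_trial(ds)
  expect_true(all(diff(p2_d1) > 0))
  expect_true(all(diff(p2_d2) > 0))
  expect_true(all(diff(p1) > 0))
})

test_that("rejection-region membership uses strict inequalities", {
  thr <- rejection_thresholds(0.025)
  expect_true(in_two_region(2.5, 2.5, thr))
  expect_false(in_two_region(3.5, 1.0, thr))   # one trial fails
  expect_false(in_two_region(thr$c_two, 2.5, thr))  # exactly at the cutoff
  expect_true(in_one_region(2.4, 2.4, 0.5, thr))
  expect_false(in_one_region(0, 0, 0.5, thr))
  # the larger trial can drag a negative smaller trial across the boundary
  expect_true(in_one_region(4.0, -0.5, 0.9, thr))
  expect_false(in_one_region(-0.5, 4.0, 0.9, thr))
  expect_false(in_one_region(thr$c_one / sqrt(0.5) / 2,
                             thr$c_one / sqrt(0.5) / 2, 0.5, thr))
  expect_error(in_one_region(1, 1, 1.2, thr), "fraction_f")
})

test_that("membership agrees with the decision implied by the statistics", {
  thr <- rejection_thresholds(0.025)
  set.seed(44)
  z1 <- rnorm(500, 1, 2)
  z2 <- rnorm(500, 1, 2)
  expect_identical(in_two_region(z1, z2, thr),
                   z1 > thr$c_two & z2 > thr$c_two)
  for (f in c(0.2, 0.5, 0.8)) {
    expect_identical(in_one_region(z1, z2, f, thr),
                     sqrt(f) * z1 + sqrt(1 - f) * z2 > thr$c_one)
  }
})

test_that("oc_grid evaluates scenarios consistently with the point formulas", {
  cfg <- trial_config(500, 0.5)
  g0 <- oc_grid(cfg, 0, 0)
  expect_identical(nrow(g0), 1L)
  expect_equal(g0$p_two, 0.000625)
  expect_equal(g0$p_one, 0.000625)
  expect_identical(g0$union_null_label, "boundary")

  g <- oc_grid(cfg, c(-0.2, 0.1), c(-0.1, 0.3))
  expect_identical(nrow(g), 4L)
  for (i in seq_len(nrow(g))) {
    nc <- noncentrality(cfg, effect_scenario(g$delta1[i], g$delta2[i]))
    expect_equal(g$p_two[i], p_two_trial(nc, cfg$level_a))
    expect_equal(g$p_one[i], p_one_trial(nc, cfg$level_a))
  }
  expect_error(oc_grid(cfg, numeric(0), 0), "delta1_values")
})

test_that("one-trial rule dominates on the identical-populations diagonal", {
  # same sign structure for any f: less type I error under the null half
  # of the diagonal, more power on the alternative half
  deltas_null <- seq(-1, 0, by = 0.05)
  deltas_alt <- seq(0.01, 1, by = 0.05)
  for (f in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    cfg <- trial_config(500, f)
    g <- do.call(rbind, lapply(deltas_null, function(d) oc_grid(cfg, d, d)))
    expect_true(all(g$p_one <= g$p_two + 1e-15))
    expect_true(all(g$p_one <= 0.000625 + 1e-15))
    expect_true(all(g$p_two <= 0.000625 + 1e-15))
    ga <- do.call(rbind, lapply(deltas_alt, function(d) oc_grid(cfg, d, d)))
    expect_true(all(ga$p_one >= ga$p_two - 1e-15))
  }
})

test_that("two-trial probability is symmetric in f <-> 1-f with swapped effects", {
  set.seed(55)
  for (i in 1:20) {
    f <- runif(1, 0.05, 0.95)
    d1 <- runif(1, -1, 1)
    d2 <- runif(1, -1, 1)
    a <- oc_grid(trial_config(500, f), d1, d2)
    b <- oc_grid(trial_config(500, 1 - f), d2, d1)
    expect_equal(a$p_two, b$p_two)
  }
})

test_that("boundary suprema return the analytic limits", {
  cfg <- trial_config(500, 0.5)
  expect_identical(boundary_sup("two_trial", cfg, "union_null"), 0.025)
  expect_identical(boundary_sup("one_trial", cfg, "union_null"), 1)
  expect_equal(boundary_sup("one_trial", cfg, "average_null"), 0.000625)
  expect_error(boundary_sup("two_trial", cfg, "average_null"),
               "average-effect null")
})

test_that("numerical sweeps back the analytic suprema", {
  # along the union-null boundary delta2 = 0 with delta1 growing, the
  # two-trial probability approaches alpha/2 from below and the one-trial
  # probability approaches 1
  d1 <- seq(0, 8, by = 0.1)
  p2 <- p_two_trial(list(d1 = d1, d2 = 0))
  expect_true(all(p2 <= 0.025 + 1e-12))
  expect_gt(max(p2), 0.025 - 1e-6)
  d1_long <- seq(0, 20, by = 0.1)
  for (f in c(0.2, 0.5, 0.8)) {
    # delta2 = 0 on the noncentrality scale; the combined mean is
    # sqrt(f) * delta1, so smaller f needs a longer sweep to approach 1
    p1 <- p_one_trial(sqrt(f) * d1_long)
    expect_true(all(diff(p1) >= 0))             # saturates at 1 in the tail
    expect_true(all(diff(p1[d1_long <= 6]) > 0))
    expect_gt(max(p1), 0.999)
  }
})

test_that("known-heterogeneity RE probability reduces to and reorders the rules", {
  cfg <- trial_config(500, 0.5)
  # tau^2 = 0 coincides with the one-trial probability
  for (d1 in c(-0.6, -0.2, 0, 0.3)) {
    eff <- effect_scenario(d1, 0)
    expect_equal(p_re_known(cfg, eff, 0),
                 p_one_trial(noncentrality(cfg, eff)))
  }
  # with small heterogeneity the RE error exceeds both rules for negative
  # effects yet stays below (alpha/2)^2
  for (d1 in seq(-1, -0.05, by = 0.05)) {
    eff <- effect_scenario(d1, 0)
    nc <- noncentrality(cfg, eff)
    p_re <- p_re_known(cfg, eff, tau2 = 0.01)
    expect_gt(p_re, p_one_trial(nc))
    expect_gt(p_re, p_two_trial(nc))
    expect_lt(p_re, 0.000625)
  }
  expect_error(p_re_known(cfg, effect_scenario(0, 0), -0.1), "tau2")
})
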
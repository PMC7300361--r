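# Net nitrification rates, qPCR growth detection, the stability index and
# the classical test machinery (summary t-tests, ANOVA + Tukey).

test_that("net NOx production handles null and exact cases", {
  same <- c(10, 11, 12)
  nn <- net_nox_production(same, same)
  expect_equal(nn$delta, 0)
  expect_false(nn$significant)

  exact <- net_nox_production(c(10, 10, 10), c(40, 40, 40))
  expect_equal(exact$delta, 30)
  expect_equal(exact$se, 0)
  expect_true(exact$significant)
})

test_that("mismatched soil or condition labels are rejected", {
  d0 <- data.frame(soil_id = "LF", condition = "native", nox = c(1, 2, 3))
  dT <- data.frame(soil_id = "E", condition = "native", nox = c(4, 5, 6))
  expect_error(net_nox_production(d0, dT), "soil_id")
})

test_that("net NOx recovers a known oxidation rate from noisy replicates", {
  # standing population oxidizes exactly 1.5 ug N/g/d for 30 days
  cfg <- sim_config(chem_cv = 0.1, sample_days = c(0, 30), seed = 2)
  sc <- test_scenario(list(test_guild(init = 1e10, r_nat = 0, activity = 1)),
                      mineralization = 1.5, nh4 = 0, nox = 5)
  tr <- simulate_dynamics(sc, "native", cfg)
  m <- simulate_measurements(tr, cfg, seed = 2)
  nn <- net_nox_production(m$chemistry$nox[m$chemistry$day == 0],
                           m$chemistry$nox[m$chemistry$day == 30])
  expect_lt(abs(nn$delta - 45), 3 * nn$se)
})

test_that("qPCR growth is a significant increase, never a decline", {
  s0 <- summary_stats(c(1e6, 1.1e6, 0.9e6))
  expect_false(growth_by_qpcr(s0, s0)$detected)

  down <- growth_by_qpcr(list(mean = 2e6, se = 1e5, n = 3),
                         list(mean = 1e6, se = 1e5, n = 3))
  expect_lt(down$value, 0)
  expect_false(down$detected)

  up <- growth_by_qpcr(list(mean = 5.0e7, se = 2e6, n = 3),
                       list(mean = 7.7e7, se = 3.2e6, n = 3))
  expect_equal(up$value, 2.7e7)
  expect_equal(up$t, 7.15, tolerance = 0.01)
  expect_true(up$detected)
})

test_that("single-replicate growth yields an estimate but no inference", {
  expect_warning(
    g <- growth_by_qpcr(list(mean = 1e6, se = 0, n = 1),
                        list(mean = 3e6, se = 0, n = 1)),
    "replicates")
  expect_equal(g$value, 2e6)
  expect_true(is.na(g$detected))
})

test_that("stability index endpoints and compensation classes", {
  neutral <- stability_index(c(2e6, 2e6), c(2e6, 2e6))
  expect_equal(neutral$value, 0)
  expect_identical(neutral$compensation, "neutral")

  gone <- stability_index(c(0, 0, 0), c(1e5, 2e5, 3e5))
  expect_equal(gone$value, -100)
  expect_identical(gone$compensation, "under")

  # forest-soil AOB: labelled abundance 1.8e5 under acidification vs 2.2e6
  # at native pH
  aob <- stability_index(1.8e5, 2.2e6)
  expect_equal(aob$value, -91.8, tolerance = 0.001)

  expect_error(stability_index(c(1, 2), c(0, 0)), "undefined")
})

test_that("stability value is the mean of its per-replicate indices and
           bounded below by -100", {
  set.seed(31)
  for (i in 1:25) {
    m <- runif(6, 0, 10) * 10^runif(1, 3, 8)
    n <- runif(6, 0.1, 10) * 10^runif(1, 3, 8)
    s <- stability_index(m, n)
    expect_equal(s$value, mean(s$per_replicate), tolerance = 1e-9)
    expect_gte(s$value, -100)
  }
})

test_that("stability comparison t-tests behave at the extremes", {
  a <- stability_index(c(1e6, 1e6, 1e6), c(1e6, 1.1e6, 0.9e6))
  eq <- compare_stability(a, a)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)

  lo <- structure(list(guild = "AOB", value = -91,
                       per_replicate = c(-90, -91, -92),
                       compensation = "under", n_modified = 3, n_native = 3),
                  class = "stability_index")
  hi <- structure(list(guild = "AOA", value = -11,
                       per_replicate = c(-10, -11, -12),
                       compensation = "under", n_modified = 3, n_native = 3),
                  class = "stability_index")
  expect_lt(compare_stability(lo, hi)$p, 0.001)
})

test_that("summary-statistic t-test matches the raw-data t-test exactly", {
  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    pooled <- summary_ttest(summary_stats(a), summary_stats(b), "pooled")
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(pooled$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(pooled$p, ref$p.value, tolerance = 1e-9)
    welch <- summary_ttest(summary_stats(a), summary_stats(b), "welch")
    refw <- t.test(a, b)
    expect_equal(welch$t, unname(refw$statistic), tolerance = 1e-9)
    expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-9)
  }
})

test_that("summary t-test reproduces the worked riparian-soil AOA contrast", {
  high <- list(mean = 1.2e7, se = 6.0e5, n = 3)
  low <- list(mean = 4.1e6, se = 4.6e5, n = 3)
  tt <- summary_ttest(high, low)
  expect_equal(tt$t, 10.45, tolerance = 0.001)
  expect_lt(tt$p, 0.05)
  expect_equal(summary_ttest(high, high)$t, 0)
})

test_that("ANOVA degenerates correctly and matches the t-test identity", {
  # identical value sets in every group: between-group SS is zero
  d <- data.frame(y = rep(c(1, 2, 3), 3),
                  g = rep(c("a", "b", "c"), each = 3))
  res <- anova_with_posthoc(d, "y", "g")
  expect_equal(res$anova_table$statistic, 0)
  expect_true(all(res$letters == res$letters[1]))

  set.seed(5)
  d2 <- data.frame(y = c(rnorm(6, 0), rnorm(6, 2)),
                   g = rep(c("a", "b"), each = 6))
  res2 <- anova_with_posthoc(d2, "y", "g")
  tt <- t.test(y ~ g, data = d2, var.equal = TRUE)
  expect_equal(res2$anova_table$statistic, unname(tt$statistic)^2,
               tolerance = 1e-9)

  expect_error(anova_with_posthoc(data.frame(y = 1:4, g = "a"), "y", "g"),
               "fewer than 2 levels")
})

test_that("two-way ANOVA separates a real factor from a null factor", {
  set.seed(61)
  soil_means <- c(A = 0, B = 3, C = 6)
  p_soil <- p_cond <- numeric(50)
  for (i in 1:50) {
    d <- expand.grid(soil = names(soil_means), cond = c("native", "modified"),
                     rep = 1:3)
    d$y <- soil_means[d$soil] + rnorm(nrow(d))
    res <- anova_with_posthoc(d, "y", c("soil", "cond"))
    p_soil[i] <- res$anova_table$p[res$anova_table$term == "soil"]
    p_cond[i] <- res$anova_table$p[res$anova_table$term == "cond"]
  }
  expect_gte(mean(p_soil < 0.05), 0.9)
  # the null factor's p-values should look uniform
  expect_gt(mean(p_cond), 0.35)
  expect_lt(mean(p_cond), 0.65)
  expect_lte(mean(p_cond < 0.05), 0.15)
})
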
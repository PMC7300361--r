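# Simulator: daily dynamics, measurement noise model, gradient construction
# and full-design dataset generation.

test_that("a no-flux system is a fixed point of the daily update", {
  sc <- test_scenario(list(test_guild(r_nat = 0, r_mod = 0, activity = 0.5)),
                      mineralization = 0, nh4 = 0, nox = 2)
  tr <- simulate_dynamics(sc, "native", sim_config())
  expect_equal(unique(tr$chem$nox), 2)
  expect_equal(unique(tr$chem$ph), sc$native_ph)
  expect_equal(unique(tr$guilds$abundance), 1e7)
})

test_that("unlimited exponential growth matches the closed form", {
  sc <- test_scenario(list(test_guild(r_nat = 0.1, activity = 0)),
                      nh4 = 1e6)
  tr <- simulate_dynamics(sc, "native", sim_config(), n_days = 30)
  final <- tr$guilds$abundance[tr$guilds$day == 30]
  expect_equal(final / 1e7, exp(3), tolerance = 1e-12)
})

test_that("growth halts below the NH4 threshold but decline continues", {
  grow <- test_guild(r_nat = 0.1, activity = 0)
  sc <- test_scenario(list(grow), nh4 = 0.5, mineralization = 0)
  tr <- simulate_dynamics(sc, "native", sim_config(), n_days = 10)
  expect_equal(unique(tr$guilds$abundance), 1e7)

  die <- test_guild(r_nat = -0.1, activity = 0)
  sc2 <- test_scenario(list(die), nh4 = 0.5, mineralization = 0)
  tr2 <- simulate_dynamics(sc2, "native", sim_config(), n_days = 10)
  expect_equal(tr2$guilds$abundance[tr2$guilds$day == 10] / 1e7, exp(-1),
               tolerance = 1e-12)
})

test_that("supply-limited oxidation drives the stated pH decline", {
  # huge standing population, mineralization 1 ug N/g/d, buffer 100:
  # oxidation is exactly 1 ug N/g/d and pH falls 0.30 over 30 days
  sc <- test_scenario(list(test_guild(init = 1e10, r_nat = 0, activity = 1)),
                      mineralization = 1, nh4 = 0, buffer = 100)
  tr <- simulate_dynamics(sc, "native", sim_config(), n_days = 30)
  expect_equal(tr$chem$ph[tr$chem$day == 30], sc$native_ph - 0.30,
               tolerance = 1e-9)
  expect_equal(tr$chem$nox[tr$chem$day == 30], 30, tolerance = 1e-9)
})

test_that("mass balance holds at every step across random scenarios", {
  set.seed(42)
  for (i in 1:10) {
    sc <- test_scenario(
      list(test_guild(init = 10^runif(1, 4, 8),
                      r_nat = runif(1, -0.1, 0.15),
                      activity = runif(1, 0, 5))),
      mineralization = runif(1, 0, 5), nh4 = runif(1, 0, 50),
      nox = runif(1, 0, 20))
    tr <- simulate_dynamics(sc, "native", sim_config(), n_days = 30)
    pool <- tr$chem$nh4 + tr$chem$nox
    expect_true(all(abs(diff(pool) - sc$mineralization_rate) < 1e-9))
  }
})

test_that("invalid guild parameters are rejected with the field name", {
  expect_error(test_guild(init = NaN), "initial_abundance")
  expect_error(test_guild(af = 1.5), "autotroph_fraction")
  expect_error(test_guild(gc = 1), "gc_content")
  expect_error(test_guild(cpc = 0.5), "amoa_copies_per_cell")
})

test_that("zero-CV measurements reproduce the truth exactly", {
  cfg <- sim_config(qpcr_cv = 0, chem_cv = 0, ph_cv = 0)
  sc <- test_scenario(list(test_guild(activity = 0.1)), mineralization = 2,
                      nh4 = 10)
  tr <- simulate_dynamics(sc, "native", cfg)
  m <- simulate_measurements(tr, cfg, seed = 1)
  truth30 <- tr$chem[tr$chem$day == 30, ]
  got30 <- m$chemistry[m$chemistry$day == 30, ]
  expect_equal(unique(got30$nox), truth30$nox)
  expect_equal(unique(got30$nh4), truth30$nh4)
  ab30 <- m$abundance[m$abundance$day == 30, ]
  expect_equal(unique(ab30$copies),
               tr$guilds$abundance[tr$guilds$day == 30])
})

test_that("measurement noise realizes the configured CV and unit mean", {
  cfg <- sim_config(replicates = 1500, sample_days = 0, qpcr_cv = 0.2,
                    chem_cv = 0.2)
  sc <- test_scenario(list(test_guild(activity = 0)), nox = 50)
  tr <- simulate_dynamics(sc, "native", cfg, n_days = 0)
  m <- simulate_measurements(tr, cfg, seed = 7)
  x <- m$chemistry$nox
  expect_length(x, 1500)
  expect_equal(sd(x) / mean(x), 0.2, tolerance = 0.1)  # within +/- 0.02
  expect_equal(mean(x), 50, tolerance = 0.02)
})

test_that("identical seeds give identical datasets", {
  cfg <- sim_config(seed = 99)
  sc <- example_scenarios()[c("LF", "RR")]
  d1 <- generate_dataset(sc, cfg)
  d2 <- generate_dataset(sc, cfg)
  expect_identical(d1$chemistry, d2$chemistry)
  expect_identical(d1$abundance, d2$abundance)
  expect_identical(d1$gradient, d2$gradient)
})

test_that("gradient peaks sit at the GC / labelling model positions", {
  cfg <- sim_config(qpcr_cv = 0)
  g <- test_guild(gc = 0.5)
  unlab <- simulate_gradient(1e8, 0, g, "12C", cfg)
  # unlabelled peak: 1.66 + 0.098 * 0.5 = 1.709 g/ml
  peak_u <- unlab$buoyant_density[which.max(unlab$copies_true)]
  expect_lt(abs(peak_u - 1.709), (1.76 - 1.66) / 15)
  lab <- simulate_gradient(1e8, 1, g, "13C", cfg)
  wmd_shift <- sum(lab$buoyant_density * lab$copies_true) / 1e8 -
    sum(unlab$buoyant_density * unlab$copies_true) / 1e8
  expect_equal(wmd_shift, 0.036, tolerance = 0.05)  # full-label shift
})

test_that("pre-noise gradient copies conserve the input abundance", {
  cfg <- sim_config()
  for (lf in c(0, 0.3, 1)) {
    gr <- simulate_gradient(3.7e7, lf, test_guild(gc = 0.44), "13C", cfg,
                            seed = 1)
    expect_equal(sum(gr$copies_true), 3.7e7, tolerance = 1e-6)
  }
})

test_that("the labelled mixture component carries its nominal mass", {
  cfg <- sim_config(qpcr_cv = 0)
  g <- test_guild(gc = 0.45)
  gr <- simulate_gradient(1, 0.4, g, "13C", cfg)
  mid <- (1.66 + 0.098 * 0.45) + 0.036 / 2   # between the two peaks
  shifted_mass <- sum(gr$copies_true[gr$buoyant_density >= mid])
  # overlap of the two Gaussians at 4.5 sd separation adds ~1% leakage
  expect_equal(shifted_mass, 0.40, tolerance = 0.05)
})

test_that("12C gradients ignore the labelled fraction", {
  cfg <- sim_config(qpcr_cv = 0)
  g <- test_guild()
  a <- simulate_gradient(1e6, 0.8, g, "12C", cfg)
  b <- simulate_gradient(1e6, 0, g, "13C", cfg)
  expect_equal(a$copies_true, b$copies_true)
  expect_error(simulate_gradient(1e6, 1.3, g, "13C", cfg),
               "labeled_fraction")
})

test_that("weighted mean density increases monotonically with labelling", {
  cfg <- sim_config(qpcr_cv = 0)
  g <- test_guild(gc = 0.5)
  wmds <- vapply(seq(0, 1, by = 0.1), function(lf) {
    gr <- simulate_gradient(1e7, lf, g, "13C", cfg)
    gr$copies <- gr$copies_true
    weighted_mean_density(normalize_profile(gr, cfg$quantified_fractions))
  }, 0)
  expect_true(all(diff(wmds) >= 0))
})

test_that("the default design produces the full factorial row counts", {
  ds <- generate_dataset(example_scenarios(), sim_config(seed = 3))
  # 5 soils x 2 pH x (3 day-0 + 2 isotopes x 3 reps at days 15 and 30)
  expect_equal(nrow(ds$chemistry), 5 * 2 * (3 + 6 + 6))
  expect_equal(sum(ds$chemistry$day == 15), 60)
  expect_equal(sum(ds$chemistry$day == 30), 60)
  expect_equal(nrow(ds$abundance), nrow(ds$chemistry) * 3)
  # gradients: day-30 microcosms x 3 guilds x 13 quantified fractions
  expect_equal(nrow(ds$gradient), 60 * 3 * 13)
})

test_that("row counts follow the design arithmetic for a reduced design", {
  cfg <- sim_config(replicates = 1, sample_days = c(0, 30), seed = 5)
  ds <- generate_dataset(list(test_scenario(list(test_guild(activity = 0.01)),
                                            nh4 = 30)), cfg)
  # per condition: 1 day-0 + 2 isotopes at day 30 = 3 microcosms
  expect_equal(nrow(ds$chemistry), 2 * 3)
  expect_equal(nrow(ds$abundance), 2 * 3 * 1)
  expect_equal(nrow(ds$gradient), 2 * 2 * 1 * 13)
})

test_that("duplicate soil ids are rejected", {
  sc <- test_scenario(list(test_guild()))
  expect_error(generate_dataset(list(sc, sc), sim_config()),
               "duplicate soil_id")
})

test_that("simulator ground truth conserves oxidized N within each soil", {
  cfg <- sim_config(seed = 11)
  ds <- generate_dataset(closure_scenarios(), cfg)
  per_guild <- aggregate(true_oxidized_ug ~ soil_id + condition,
                         data = as.data.frame(ds$truth_guilds), FUN = sum)
  joined <- merge(per_guild, as.data.frame(ds$truth_soils))
  # every oxidized ug of N is attributed to exactly one guild
  expect_true(all(abs(joined$true_oxidized_ug - joined$true_net_nox) < 1e-9))
  expect_true(all(joined$true_net_nox > 0))
})
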
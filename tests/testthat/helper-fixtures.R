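# Shared fixtures: minimal guilds/scenarios and an independent lognormal
# noise oracle used for calibration experiments.

test_guild <- function(guild = "AOA", init = 1e7, r_nat = 0.1, r_mod = 0.1,
                       activity = 0, af = 1, gc = 0.5, cpc = 1) {
  guild_params(guild, init, r_nat, r_mod, per_cell_activity = activity,
               autotroph_fraction = af, gc_content = gc,
               amoa_copies_per_cell = cpc)
}

test_scenario <- function(guilds = list(test_guild()), soil_id = "S1",
                          mineralization = 0, nh4 = 1e6, nox = 0,
                          buffer = 100, native_ph = 6, modified_ph = 4.5) {
  soil_scenario(soil_id, native_ph, modified_ph,
                mineralization_rate = mineralization,
                buffer_capacity = buffer,
                initial_nh4 = nh4, initial_nox = nox, guilds = guilds)
}

# unit-mean multiplicative lognormal noise, written independently of the
# package's internal noise model
lognoise <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  mean * exp(rnorm(n, -s2 / 2, sqrt(s2)))
}

# simulate one labelling experiment: triplicate 12C and 13C gradients of one
# guild, returning the labelling call and the heavy-window proportion
labeling_trial <- function(lf, config = sim_config(), guild = test_guild(),
                           abundance = 1e7, reps = 3, delta_min = 0.005,
                           alpha = 0.05, heavy_threshold = 1.725) {
  profs <- function(iso) {
    lapply(seq_len(reps), function(i) {
      gr <- simulate_gradient(abundance, lf, guild, iso, config)
      normalize_profile(gr, config$quantified_fractions)
    })
  }
  p12 <- profs("12C")
  p13 <- profs("13C")
  call <- detect_labeling(p12, p13, delta_min = delta_min, alpha = alpha)
  la <- labeled_abundance(p13, abundance, heavy_threshold = heavy_threshold)
  list(call = call, prop_pct = 100 * la$estimate / abundance)
}
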
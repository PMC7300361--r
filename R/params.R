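# Parameter containers for the synthetic microcosm simulator: per-guild
# biology, per-soil chemistry, and the experiment/measurement configuration.

check_number <- function(x, field, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", field), call. = FALSE)
  }
  if (x < min || x > max) {
    stop(sprintf("`%s` must be in [%s, %s], got %s", field, min, max, x),
         call. = FALSE)
  }
  invisible(x)
}

#' Per-guild simulator parameters
#'
#' Describes one ammonia-oxidizer guild in a simulated soil: its starting
#' *amoA* abundance, exponential growth (or decline) rates under the native
#' and the pH-modified condition, the fraction of its growth that is
#' autotrophic (and therefore incorporates \eqn{^{13}}C from labelled CO2),
#' its genomic GC content (which sets the unlabelled buoyant density of its
#' DNA), the number of *amoA* copies per cell, and its realized per-cell
#' ammonia oxidation activity.
#'
#' @param guild_name One of `"AOA"`, `"AOB"`, `"comammox"`.
#' @param initial_abundance Starting abundance, *amoA* copies per g dry soil.
#' @param growth_rate_native,growth_rate_modified Specific growth rates
#'   (d^-1) under each pH condition; negative values mean decline.
#' @param per_cell_activity Realized ammonia oxidation activity,
#'   fmol NH3 cell^-1 h^-1. This is the rate cells actually run at in soil,
#'   typically far below the maximum activity of pure cultures used for
#'   apportionment (see [default_cell_activities()]).
#' @param autotroph_fraction Fraction of growth incorporating 13C, in [0, 1].
#' @param gc_content Genomic GC content, strictly between 0 and 1.
#' @param amoa_copies_per_cell *amoA* copies per cell, >= 1.
#'
#' @return A `guild_params` object (validated list).
#' @export
#' @examples
#' guild_params("AOA", 1e7, 0.06, 0.04, per_cell_activity = 0.02)
guild_params <- function(guild_name, initial_abundance, growth_rate_native,
                         growth_rate_modified, per_cell_activity,
                         autotroph_fraction = 1, gc_content = 0.5,
                         amoa_copies_per_cell = 1) {
  guild_name <- match.arg(guild_name, .guild_levels)
  check_number(initial_abundance, "initial_abundance", min = 0)
  check_number(growth_rate_native, "growth_rate_native")
  check_number(growth_rate_modified, "growth_rate_modified")
  check_number(per_cell_activity, "per_cell_activity", min = 0)
  check_number(autotroph_fraction, "autotroph_fraction", min = 0, max = 1)
  check_number(gc_content, "gc_content")
  if (gc_content <= 0 || gc_content >= 1) {
    stop("`gc_content` must be strictly between 0 and 1", call. = FALSE)
  }
  check_number(amoa_copies_per_cell, "amoa_copies_per_cell", min = 1)
  structure(
    list(guild_name = guild_name,
         initial_abundance = initial_abundance,
         growth_rate_native = growth_rate_native,
         growth_rate_modified = growth_rate_modified,
         per_cell_activity = per_cell_activity,
         autotroph_fraction = autotroph_fraction,
         gc_content = gc_content,
         amoa_copies_per_cell = amoa_copies_per_cell),
    class = "guild_params"
  )
}

#' Per-soil simulator scenario
#'
#' Chemistry and community parameterization of one simulated soil: its pH
#' under the native and modified condition, its N mineralization rate, a
#' linear pH buffer capacity (micrograms of N oxidized per unit pH drop), the
#' initial NH4+ and NOx- pools, and the list of guilds present.
#'
#' @param soil_id Soil label (e.g. `"LF"`, `"OP7"`).
#' @param native_ph,modified_ph Soil pH under each condition, in [3, 9].
#' @param mineralization_rate N mineralization, ug N g^-1 dry soil d^-1.
#' @param buffer_capacity ug N oxidized per unit of pH decrease (> 0).
#' @param initial_nh4,initial_nox Initial pools, ug N g^-1 dry soil.
#' @param guilds List of [guild_params()] objects.
#'
#' @return A `soil_scenario` object.
#' @export
soil_scenario <- function(soil_id, native_ph, modified_ph, mineralization_rate,
                          buffer_capacity, initial_nh4, initial_nox, guilds) {
  stopifnot(is.character(soil_id), length(soil_id) == 1L, nzchar(soil_id))
  check_number(native_ph, "native_ph", min = 3, max = 9)
  check_number(modified_ph, "modified_ph", min = 3, max = 9)
  check_number(mineralization_rate, "mineralization_rate", min = 0)
  check_number(buffer_capacity, "buffer_capacity")
  if (buffer_capacity <= 0) stop("`buffer_capacity` must be > 0", call. = FALSE)
  check_number(initial_nh4, "initial_nh4", min = 0)
  check_number(initial_nox, "initial_nox", min = 0)
  if (!is.list(guilds) || length(guilds) < 1L ||
      !all(vapply(guilds, inherits, logical(1), "guild_params"))) {
    stop("`guilds` must be a non-empty list of guild_params objects",
         call. = FALSE)
  }
  nm <- vapply(guilds, `[[`, character(1), "guild_name")
  if (anyDuplicated(nm)) {
    stop("duplicate guild_name in `guilds`", call. = FALSE)
  }
  structure(
    list(soil_id = soil_id, native_ph = native_ph, modified_ph = modified_ph,
         mineralization_rate = mineralization_rate,
         buffer_capacity = buffer_capacity,
         initial_nh4 = initial_nh4, initial_nox = initial_nox,
         guilds = stats::setNames(guilds, nm)),
    class = "soil_scenario"
  )
}

#' Simulator configuration
#'
#' Experiment design and measurement-model settings shared by all simulator
#' operations: replication, sampling days, qPCR / chemistry noise levels
#' (lognormal coefficients of variation), the CsCl gradient discretization,
#' and the buoyant-density model. Fraction 1 is the heaviest fraction (bottom
#' of the tube); buoyant density decreases with fraction index.
#'
#' The buoyant density of unlabelled DNA is `bd_intercept + bd_gc_slope * GC`
#' (g ml^-1), the standard linear GC relation; full 13C labelling shifts a
#' population by `max_label_shift`. A population spreads over the gradient as
#' a Gaussian of standard deviation `density_sd`.
#'
#' @param replicates Microcosm replicates per isotope (default 3).
#' @param sample_days Destructive sampling days (default 0, 15, 30).
#' @param qpcr_cv,chem_cv Lognormal CV of qPCR and chemistry measurements.
#' @param ph_cv Lognormal CV of pH measurement (small; pH meters are precise).
#' @param n_fractions Number of gradient fractions (default 15, >= 3).
#' @param quantified_fractions Fraction indices quantified by qPCR
#'   (default 2:14, mirroring the common practice of discarding the extreme
#'   fractions).
#' @param density_min,density_max Gradient density range, g ml^-1.
#' @param density_sd Spread of one population's distribution, g ml^-1.
#' @param bd_intercept,bd_gc_slope Buoyant-density model constants, g ml^-1.
#' @param max_label_shift Density shift under full 13C labelling, g ml^-1.
#' @param nh4_threshold NH4+ level (ug N g^-1) below which growth halts.
#' @param seed Integer seed; identical configs give identical datasets.
#'
#' @return A `sim_config` object.
#' @export
sim_config <- function(replicates = 3, sample_days = c(0, 15, 30),
                       qpcr_cv = 0.2, chem_cv = 0.1, ph_cv = 0.01,
                       n_fractions = 15, quantified_fractions = 2:14,
                       density_min = 1.66, density_max = 1.76,
                       density_sd = 0.008, bd_intercept = 1.66,
                       bd_gc_slope = 0.098, max_label_shift = 0.036,
                       nh4_threshold = 1, seed = 1L) {
  check_number(replicates, "replicates", min = 1)
  if (!is.numeric(sample_days) || length(sample_days) < 1L ||
      any(sample_days < 0) || anyDuplicated(sample_days)) {
    stop("`sample_days` must be distinct non-negative days", call. = FALSE)
  }
  check_number(qpcr_cv, "qpcr_cv", min = 0)
  check_number(chem_cv, "chem_cv", min = 0)
  check_number(ph_cv, "ph_cv", min = 0)
  check_number(n_fractions, "n_fractions", min = 3)
  check_number(density_min, "density_min")
  check_number(density_max, "density_max")
  if (density_min >= density_max) {
    stop("`density_min` must be smaller than `density_max`", call. = FALSE)
  }
  check_number(density_sd, "density_sd", min = 0)
  check_number(bd_intercept, "bd_intercept")
  check_number(bd_gc_slope, "bd_gc_slope")
  check_number(max_label_shift, "max_label_shift", min = 0)
  check_number(nh4_threshold, "nh4_threshold", min = 0)
  check_number(seed, "seed")
  if (!all(quantified_fractions %in% seq_len(n_fractions))) {
    stop("`quantified_fractions` must be indices within 1..n_fractions",
         call. = FALSE)
  }
  structure(
    list(replicates = as.integer(replicates),
         sample_days = sort(as.integer(sample_days)),
         qpcr_cv = qpcr_cv, chem_cv = chem_cv, ph_cv = ph_cv,
         n_fractions = as.integer(n_fractions),
         quantified_fractions = as.integer(quantified_fractions),
         density_min = density_min, density_max = density_max,
         density_sd = density_sd, bd_intercept = bd_intercept,
         bd_gc_slope = bd_gc_slope, max_label_shift = max_label_shift,
         nh4_threshold = nh4_threshold, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Example soil scenarios along a land-use gradient
#'
#' Five soils emulating a tropical land-use gradient: two forest soils (LF,
#' E), a riparian soil (RR) and two oil palm soils (OP2, OP7). The three
#' near-neutral soils are acidified under the modified condition and the two
#' acidic oil palm soils are limed. Guild parameters are chosen so that
#' acidification depresses AOB strongly and AOA mildly, liming boosts both,
#' and comammox responds weakly — the qualitative behaviour expected from pH
#' niche specialization of the three guilds. GC contents reflect typical
#' genome GC of each guild (AOA low, comammox high); realized per-cell
#' activities are far below pure-culture maxima, as in soil.
#'
#' @return A named list of five [soil_scenario()] objects.
#' @export
example_scenarios <- function() {
  sc <- list(
    soil_scenario("LF", native_ph = 6.8, modified_ph = 4.5,
                  mineralization_rate = 2.5, buffer_capacity = 150,
                  initial_nh4 = 15, initial_nox = 5,
                  guilds = list(
                    guild_params("AOA", 8e6, 0.00, -0.020, per_cell_activity = 0.015,
                                 autotroph_fraction = 0.8, gc_content = 0.41),
                    guild_params("AOB", 5e5, 0.05, -0.080, per_cell_activity = 0.60,
                                 autotroph_fraction = 0.9, gc_content = 0.53),
                    guild_params("comammox", 1e5, 0.03, 0.000, per_cell_activity = 0.10,
                                 autotroph_fraction = 0.6, gc_content = 0.59))),
    soil_scenario("E", native_ph = 5.9, modified_ph = 4.5,
                  mineralization_rate = 3.0, buffer_capacity = 120,
                  initial_nh4 = 20, initial_nox = 8,
                  guilds = list(
                    guild_params("AOA", 2e6, 0.01, -0.015, per_cell_activity = 0.03,
                                 autotroph_fraction = 0.7, gc_content = 0.41),
                    guild_params("AOB", 2e6, 0.08, -0.070, per_cell_activity = 0.25,
                                 autotroph_fraction = 0.9, gc_content = 0.53),
                    guild_params("comammox", 5e4, 0.00, 0.000, per_cell_activity = 0.10,
                                 autotroph_fraction = 0.5, gc_content = 0.59))),
    soil_scenario("RR", native_ph = 6.3, modified_ph = 4.5,
                  mineralization_rate = 0.5, buffer_capacity = 100,
                  initial_nh4 = 6, initial_nox = 10,
                  guilds = list(
                    guild_params("AOA", 1e7, 0.06, 0.040, per_cell_activity = 0.004,
                                 autotroph_fraction = 0.85, gc_content = 0.41),
                    guild_params("AOB", 3e5, 0.07, 0.040, per_cell_activity = 0.15,
                                 autotroph_fraction = 0.9, gc_content = 0.53),
                    guild_params("comammox", 8e4, 0.01, 0.000, per_cell_activity = 0.05,
                                 autotroph_fraction = 0.5, gc_content = 0.59))),
    soil_scenario("OP2", native_ph = 5.0, modified_ph = 6.5,
                  mineralization_rate = 1.2, buffer_capacity = 80,
                  initial_nh4 = 10, initial_nox = 3,
                  guilds = list(
                    guild_params("AOA", 1.5e5, 0.00, 0.040, per_cell_activity = 0.05,
                                 autotroph_fraction = 0.7, gc_content = 0.41),
                    guild_params("AOB", 2.5e4, 0.04, 0.120, per_cell_activity = 1.0,
                                 autotroph_fraction = 0.9, gc_content = 0.53),
                    guild_params("comammox", 1e5, 0.05, 0.060, per_cell_activity = 0.15,
                                 autotroph_fraction = 0.6, gc_content = 0.59))),
    soil_scenario("OP7", native_ph = 5.0, modified_ph = 6.5,
                  mineralization_rate = 1.5, buffer_capacity = 90,
                  initial_nh4 = 12, initial_nox = 6,
                  guilds = list(
                    guild_params("AOA", 3e7, 0.05, 0.100, per_cell_activity = 0.002,
                                 autotroph_fraction = 0.85, gc_content = 0.41),
                    guild_params("AOB", 4e4, 0.06, 0.130, per_cell_activity = 0.50,
                                 autotroph_fraction = 0.9, gc_content = 0.53),
                    guild_params("comammox", 2e5, 0.01, 0.020, per_cell_activity = 0.05,
                                 autotroph_fraction = 0.5, gc_content = 0.59)))
  )
  stats::setNames(sc, vapply(sc, `[[`, character(1), "soil_id"))
}

#' Idealized closure scenarios
#'
#' The [example_scenarios()] soils with every guild made fully autotrophic
#' (`autotroph_fraction = 1`), growing at 0.1 d^-1 under both conditions, and
#' with ample ammonium, so that every oxidized N atom is attributable to a
#' growing, labelled population. Per-cell activities are standardized across
#' soils (see [closure_activities()]) so that apportionment can be run at
#' exactly the true rates. Used for end-to-end conservation checks of the
#' apportionment accounting: when contributions are computed at the true
#' per-cell activities, the summed guild contributions must cover the whole
#' measured NOx production (zero unaccounted residual).
#'
#' @return A named list of [soil_scenario()] objects.
#' @export
closure_scenarios <- function() {
  act <- closure_activities()
  lapply(example_scenarios(), function(sc) {
    sc$initial_nh4 <- 500
    sc$guilds <- lapply(sc$guilds, function(g) {
      g$autotroph_fraction <- 1
      g$growth_rate_native <- 0.1
      g$growth_rate_modified <- 0.1
      g$per_cell_activity <- act[[g$guild_name]]
      g
    })
    sc
  })
}

#' True per-guild activities of the closure scenarios
#'
#' @return Named numeric vector, fmol NH3 cell^-1 h^-1.
#' @export
closure_activities <- function() {
  c(AOA = 0.01, AOB = 0.5, comammox = 0.1)
}

#' @export
print.guild_params <- function(x, ...) {
  cat(sprintf(
    "<guild_params> %s: N0 = %.3g copies/g, r(native) = %+.3g /d, r(modified) = %+.3g /d\n",
    x$guild_name, x$initial_abundance, x$growth_rate_native,
    x$growth_rate_modified))
  cat(sprintf(
    "  activity %.3g fmol NH3/cell/h, autotroph fraction %.2f, GC %.2f, %g amoA copies/cell\n",
    x$per_cell_activity, x$autotroph_fraction, x$gc_content,
    x$amoa_copies_per_cell))
  invisible(x)
}

#' @export
print.soil_scenario <- function(x, ...) {
  cat(sprintf("<soil_scenario> %s: pH %.1f -> %.1f, mineralization %.2g ug N/g/d, guilds: %s\n",
              x$soil_id, x$native_ph, x$modified_ph, x$mineralization_rate,
              paste(names(x$guilds), collapse = ", ")))
  invisible(x)
}
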
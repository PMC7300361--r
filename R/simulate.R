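# Synthetic microcosm simulator: discrete daily dynamics of NH4+/NOx-/pH and
# guild abundances, lognormal measurement noise, CsCl gradient profiles, and
# full-design dataset generation with a ground-truth record.

# Multiplicative lognormal noise with a given CV and unit mean.
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep_len(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  out <- mean * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  out[mean == 0] <- 0
  out
}

#' Simulate daily microcosm dynamics
#'
#' Discrete-time (daily) simulation of one soil microcosm under one pH
#' condition. Each day: (1) every guild with a positive growth rate grows
#' exponentially while NH4+ exceeds the limitation threshold (declining
#' guilds always decline); (2) the community oxidizes
#' `min(NH4 + mineralization, total oxidation potential)` micrograms of N,
#' where the potential is the summed `cells x per_cell_activity x 24 h` of
#' all guilds, converted to ug N; (3) pools update (NH4 +=
#' mineralization - oxidation, NOx += oxidation) and pH drops by
#' oxidation / buffer_capacity. Oxidized N is attributed to guilds in
#' proportion to their oxidation potential, giving the true per-guild
#' contribution used in recovery tests. Growth that occurs on a given day
#' adds `autotroph_fraction` of the new copies to the guild's 13C-labelled
#' pool; decline shrinks the labelled pool proportionally.
#'
#' @param scenario A [soil_scenario()].
#' @param condition `"native"` or `"modified"`.
#' @param config A [sim_config()].
#' @param n_days Number of days to simulate (default: last sampling day).
#'
#' @return A `microcosm_trajectory`: list with `soil_id`, `condition`,
#'   `chem` (tibble day, nh4, nox, ph) and `guilds` (tibble day, guild,
#'   abundance, labeled, oxidized_cum in ug N g^-1).
#' @export
simulate_dynamics <- function(scenario, condition = c("native", "modified"),
                              config = sim_config(),
                              n_days = max(config$sample_days)) {
  stopifnot(inherits(scenario, "soil_scenario"), inherits(config, "sim_config"))
  condition <- match.arg(condition)
  check_number(n_days, "n_days", min = 0)

  rate_field <- paste0("growth_rate_", condition)
  g <- scenario$guilds
  guild <- names(g)
  ab <- vapply(g, `[[`, 0, "initial_abundance")
  rates <- vapply(g, `[[`, 0, rate_field)
  act <- vapply(g, `[[`, 0, "per_cell_activity")
  cpc <- vapply(g, `[[`, 0, "amoa_copies_per_cell")
  af <- vapply(g, `[[`, 0, "autotroph_fraction")

  labeled <- rep(0, length(g))
  ox_cum <- rep(0, length(g))
  nh4 <- scenario$initial_nh4
  nox <- scenario$initial_nox
  ph <- if (condition == "native") scenario$native_ph else scenario$modified_ph

  days <- 0:n_days
  chem <- matrix(NA_real_, nrow = length(days), ncol = 3,
                 dimnames = list(NULL, c("nh4", "nox", "ph")))
  gmat_ab <- gmat_lab <- gmat_ox <- matrix(NA_real_, nrow = length(days),
                                           ncol = length(g))
  chem[1, ] <- c(nh4, nox, ph)
  gmat_ab[1, ] <- ab; gmat_lab[1, ] <- labeled; gmat_ox[1, ] <- ox_cum

  for (d in seq_len(n_days)) {
    can_grow <- nh4 > config$nh4_threshold
    mult <- exp(rates)
    mult[rates > 0 & !can_grow] <- 1     # growth halts, decline continues
    delta <- ab * (mult - 1)
    labeled <- ifelse(delta >= 0, labeled + af * delta, labeled * mult)
    ab <- ab + delta
    labeled <- pmin(labeled, ab)

    potential <- ab / cpc * act * 24 * .ug_n_per_fmol   # ug N g^-1 d^-1
    supply <- nh4 + scenario$mineralization_rate
    ox_tot <- min(supply, sum(potential))
    alloc <- if (sum(potential) > 0) ox_tot * potential / sum(potential) else
      rep(0, length(g))
    nh4 <- max(0, nh4 + scenario$mineralization_rate - ox_tot)
    nox <- nox + ox_tot
    ph <- ph - ox_tot / scenario$buffer_capacity
    ox_cum <- ox_cum + alloc

    chem[d + 1, ] <- c(nh4, nox, ph)
    gmat_ab[d + 1, ] <- ab
    gmat_lab[d + 1, ] <- labeled
    gmat_ox[d + 1, ] <- ox_cum
  }

  structure(
    list(soil_id = scenario$soil_id, condition = condition,
         chem = tibble::tibble(day = days, nh4 = chem[, "nh4"],
                               nox = chem[, "nox"], ph = chem[, "ph"]),
         guilds = tibble::tibble(
           day = rep(days, times = length(g)),
           guild = rep(guild, each = length(days)),
           abundance = as.vector(gmat_ab),
           labeled = as.vector(gmat_lab),
           oxidized_cum = as.vector(gmat_ox))),
    class = "microcosm_trajectory"
  )
}

#' Simulate noisy chemistry and abundance measurements
#'
#' Turns true trajectories into replicated measurement tables following the
#' microcosm design: triplicate (by default) day-0 microcosms (isotope
#' `"none"`, sampled before CO2 amendment) and, for every later sampling day,
#' `replicates` microcosms per isotope (12C and 13C). Every true value is
#' perturbed by independent multiplicative lognormal noise with the
#' configured CV (`chem_cv` for NH4+/NOx-, `ph_cv` for pH, `qpcr_cv` for
#' abundances); noise has unit mean, so measurements are unbiased.
#'
#' @param trajectory A `microcosm_trajectory` from [simulate_dynamics()].
#' @param config A [sim_config()].
#' @param seed Optional integer; set for standalone reproducible use, leave
#'   `NULL` when the caller manages the RNG stream (as [generate_dataset()]
#'   does).
#'
#' @return List of two tibbles, `chemistry` (microcosm_id, soil_id,
#'   condition, isotope, replicate, day, nh4, nox, ph) and `abundance`
#'   (same keys plus guild, copies).
#' @export
simulate_measurements <- function(trajectory, config = sim_config(),
                                  seed = NULL) {
  stopifnot(inherits(trajectory, "microcosm_trajectory"),
            inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)

  days <- intersect(config$sample_days, trajectory$chem$day)
  chem_rows <- list(); ab_rows <- list()
  for (day in days) {
    truth <- trajectory$chem[trajectory$chem$day == day, ]
    gtruth <- trajectory$guilds[trajectory$guilds$day == day, ]
    isotopes <- if (day == 0) "none" else c("12C", "13C")
    for (iso in isotopes) {
      for (rep_i in seq_len(config$replicates)) {
        id <- sprintf("%s_%s_%s_d%d_r%d", trajectory$soil_id,
                      trajectory$condition, iso, day, rep_i)
        chem_rows[[length(chem_rows) + 1L]] <- tibble::tibble(
          microcosm_id = id, soil_id = trajectory$soil_id,
          condition = trajectory$condition, isotope = iso,
          replicate = rep_i, day = day,
          nh4 = rlnorm_cv(1, truth$nh4, config$chem_cv),
          nox = rlnorm_cv(1, truth$nox, config$chem_cv),
          ph = rlnorm_cv(1, truth$ph, config$ph_cv))
        ab_rows[[length(ab_rows) + 1L]] <- tibble::tibble(
          microcosm_id = id, soil_id = trajectory$soil_id,
          condition = trajectory$condition, isotope = iso,
          replicate = rep_i, day = day, guild = gtruth$guild,
          copies = vapply(gtruth$abundance, function(a)
            rlnorm_cv(1, a, config$qpcr_cv), 0))
      }
    }
  }
  list(chemistry = dplyr::bind_rows(chem_rows),
       abundance = dplyr::bind_rows(ab_rows))
}

#' Simulate one CsCl gradient for one guild
#'
#' Distributes a guild's *amoA* copies over the gradient fractions as a
#' two-component Gaussian mixture: the unlabelled pool is centred at
#' `bd_intercept + bd_gc_slope * gc_content` and the 13C-labelled pool is
#' shifted upward by `max_label_shift * atom_excess`. Component masses are
#' integrated over the fraction bins spanning `[density_min, density_max]`
#' and renormalized over the bins, so pre-noise per-fraction copies sum
#' exactly to `guild_abundance`. Fraction 1 is the heaviest. Under 12C the
#' labelled pool is empty regardless of `labeled_fraction`. Per-fraction
#' counts are then perturbed with lognormal qPCR noise.
#'
#' @param guild_abundance Total *amoA* copies in the gradient (>= 0).
#' @param labeled_fraction Fraction of copies that are 13C-labelled, in
#'   [0, 1]; only applies under `isotope = "13C"`.
#' @param guild A [guild_params()] (supplies `gc_content`).
#' @param isotope `"12C"` or `"13C"`.
#' @param config A [sim_config()].
#' @param atom_excess 13C atom fraction excess of the labelled pool
#'   (default 1, i.e. fully labelled DNA).
#' @param seed Optional integer seed (see [simulate_measurements()]).
#'
#' @return Tibble with fraction_index, buoyant_density (bin centre, g ml^-1),
#'   copies_true (pre-noise), copies (noisy), quantified (logical), guild,
#'   isotope.
#' @export
simulate_gradient <- function(guild_abundance, labeled_fraction, guild,
                              isotope = c("12C", "13C"),
                              config = sim_config(), atom_excess = 1,
                              seed = NULL) {
  stopifnot(inherits(guild, "guild_params"), inherits(config, "sim_config"))
  isotope <- match.arg(isotope)
  check_number(guild_abundance, "guild_abundance", min = 0)
  check_number(labeled_fraction, "labeled_fraction", min = 0, max = 1)
  check_number(atom_excess, "atom_excess", min = 0, max = 1)
  if (!is.null(seed)) set.seed(seed)

  nf <- config$n_fractions
  width <- (config$density_max - config$density_min) / nf
  upper <- config$density_max - (seq_len(nf) - 1) * width
  lower <- upper - width
  centre <- (upper + lower) / 2

  bin_mass <- function(mu) {
    m <- stats::pnorm(upper, mu, config$density_sd) -
      stats::pnorm(lower, mu, config$density_sd)
    m / sum(m)
  }
  mu_unlab <- config$bd_intercept + config$bd_gc_slope * guild$gc_content
  mu_lab <- mu_unlab + config$max_label_shift * atom_excess
  lf <- if (isotope == "13C") labeled_fraction else 0

  mass <- (1 - lf) * bin_mass(mu_unlab) + lf * bin_mass(mu_lab)
  copies_true <- guild_abundance * mass
  tibble::tibble(
    fraction_index = seq_len(nf),
    buoyant_density = centre,
    copies_true = copies_true,
    copies = rlnorm_cv(nf, copies_true, config$qpcr_cv),
    quantified = seq_len(nf) %in% config$quantified_fractions,
    guild = guild$guild_name,
    isotope = isotope)
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Runs [simulate_dynamics()], [simulate_measurements()] and
#' [simulate_gradient()] over every scenario and both pH conditions,
#' producing the three analysis tables (chemistry, abundance, gradient — the
#' gradient is fractionated for every day-30 microcosm, quantified fractions
#' only) plus a ground-truth record with the true growth, labelled fraction
#' and per-guild oxidized N of every soil x condition x guild.
#'
#' @param scenarios A [soil_scenario()] or list of them (unique soil_ids).
#' @param config A [sim_config()]; `config$seed` makes output deterministic.
#'
#' @return A `sip_dataset`: list with tibbles `chemistry`, `abundance`,
#'   `gradient`, ground truth (`truth_guilds`, `truth_soils`) and the
#'   echoed `config`.
#' @export
generate_dataset <- function(scenarios, config = sim_config()) {
  if (inherits(scenarios, "soil_scenario")) scenarios <- list(scenarios)
  stopifnot(length(scenarios) >= 1,
            all(vapply(scenarios, inherits, logical(1), "soil_scenario")),
            inherits(config, "sim_config"))
  ids <- vapply(scenarios, `[[`, character(1), "soil_id")
  if (anyDuplicated(ids)) {
    stop("duplicate soil_id among scenarios: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)

  gradient_day <- max(config$sample_days)
  chem_l <- ab_l <- grad_l <- tg_l <- ts_l <- list()
  for (sc in scenarios) {
    for (cond in c("native", "modified")) {
      traj <- simulate_dynamics(sc, cond, config)
      meas <- simulate_measurements(traj, config, seed = NULL)
      chem_l[[length(chem_l) + 1L]] <- meas$chemistry
      ab_l[[length(ab_l) + 1L]] <- meas$abundance

      final <- traj$guilds[traj$guilds$day == gradient_day, ]
      init <- traj$guilds[traj$guilds$day == 0, ]
      lf_true <- ifelse(final$abundance > 0, final$labeled / final$abundance, 0)
      for (iso in c("12C", "13C")) {
        for (rep_i in seq_len(config$replicates)) {
          id <- sprintf("%s_%s_%s_d%d_r%d", sc$soil_id, cond, iso,
                        gradient_day, rep_i)
          for (k in seq_len(nrow(final))) {
            gr <- simulate_gradient(final$abundance[k], lf_true[k],
                                    sc$guilds[[final$guild[k]]], iso, config,
                                    seed = NULL)
            gr <- gr[gr$quantified, c("fraction_index", "buoyant_density",
                                      "copies", "guild", "isotope")]
            gr$microcosm_id <- id
            gr$soil_id <- sc$soil_id
            gr$condition <- cond
            gr$replicate <- rep_i
            grad_l[[length(grad_l) + 1L]] <- gr
          }
        }
      }
      tg_l[[length(tg_l) + 1L]] <- tibble::tibble(
        soil_id = sc$soil_id, condition = cond, guild = final$guild,
        initial_abundance = init$abundance,
        final_abundance = final$abundance,
        true_growth = final$abundance - init$abundance,
        true_labeled = final$labeled,
        true_labeled_fraction = lf_true,
        true_oxidized_ug = final$oxidized_cum)
      chem0 <- traj$chem[traj$chem$day == 0, ]
      chemT <- traj$chem[traj$chem$day == gradient_day, ]
      ts_l[[length(ts_l) + 1L]] <- tibble::tibble(
        soil_id = sc$soil_id, condition = cond,
        true_net_nox = chemT$nox - chem0$nox,
        final_ph = chemT$ph, final_nh4 = chemT$nh4)
    }
  }

  grad <- dplyr::bind_rows(grad_l)
  grad <- grad[, c("microcosm_id", "soil_id", "condition", "isotope",
                   "replicate", "guild", "fraction_index", "buoyant_density",
                   "copies")]
  structure(
    list(chemistry = dplyr::bind_rows(chem_l),
         abundance = dplyr::bind_rows(ab_l),
         gradient = grad,
         truth_guilds = dplyr::bind_rows(tg_l),
         truth_soils = dplyr::bind_rows(ts_l),
         config = config),
    class = "sip_dataset"
  )
}

#' @export
print.sip_dataset <- function(x, ...) {
  cat(sprintf(
    "<sip_dataset> %d soils x %d conditions; %d chemistry, %d abundance, %d gradient rows\n",
    length(unique(x$chemistry$soil_id)),
    length(unique(x$chemistry$condition)),
    nrow(x$chemistry), nrow(x$abundance), nrow(x$gradient)))
  if (!is.null(x$truth_guilds)) cat("  ground truth attached\n")
  invisible(x)
}
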
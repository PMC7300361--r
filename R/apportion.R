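# Cell-activity-based apportionment of measured nitrification among guilds:
# derivation of per-cell activities from culture kinetics, conversion of
# growing-population counts into putative NOx production, and the
# unaccounted residual.

#' Reference maximum cell-specific activities
#'
#' The highest recorded maximum specific ammonia oxidation activities of
#' cultivated representatives of each guild, in fmol NH3 cell^-1 h^-1:
#' 2.6 for AOA (*Nitrososphaera viennensis*), 23 for AOB (*Nitrosospira
#' multiformis*) and 2.6 for comammox (*Nitrospira inopinata*, derived from
#' its Vmax via [derive_cell_activity()]). Used as the upper-bound activity
#' when apportioning measured NOx production among growing populations.
#'
#' @return Named numeric vector (AOA, AOB, comammox).
#' @export
default_cell_activities <- function() {
  c(AOA = 2.6, AOB = 23, comammox = 2.6)
}

#' Derive per-cell activity from culture kinetics
#'
#' Converts a biomass-normalized maximum ammonia oxidation rate into a
#' per-cell activity:
#' `activity = vmax [umol NH3 mg^-1 protein h^-1] * 1e3 [mg/g protein]
#'  / wet_weight_per_protein [g wet / g protein] / cells_per_g_wet
#'  * 1e9 [fmol/umol]`.
#' With the literature constants for *Nitrospira inopinata*
#' (Vmax = 14.8 umol NH3 mg^-1 protein h^-1, 5.7 g wet weight per g protein,
#' 1e12 cells per g wet weight) this gives 2.5965, i.e. 2.6 fmol NH3
#' cell^-1 h^-1 at two significant figures. The value is returned unrounded;
#' rounding is presentation-only (see the print method).
#'
#' @param vmax Maximum activity, umol NH3 mg^-1 protein h^-1 (> 0).
#' @param wet_weight_per_protein g wet weight per g protein (> 0).
#' @param cells_per_g_wet Cells per g wet weight (> 0).
#' @param guild Optional guild label.
#' @return A `cell_activity`: guild, activity (fmol NH3 cell^-1 h^-1),
#'   provenance.
#' @export
#' @examples
#' derive_cell_activity(14.8, 5.7, 1e12)
derive_cell_activity <- function(vmax, wet_weight_per_protein = 5.7,
                                 cells_per_g_wet = 1e12, guild = NULL) {
  check_number(vmax, "vmax")
  check_number(wet_weight_per_protein, "wet_weight_per_protein")
  check_number(cells_per_g_wet, "cells_per_g_wet")
  if (vmax <= 0 || wet_weight_per_protein <= 0 || cells_per_g_wet <= 0) {
    stop("all kinetic inputs must be > 0", call. = FALSE)
  }
  # umol g^-1 protein h^-1 -> per g wet -> per cell -> fmol
  activity <- vmax * 1e3 / wet_weight_per_protein / cells_per_g_wet * 1e9
  structure(list(guild = guild, activity = activity,
                 provenance = sprintf(
                   "derived: Vmax %g umol/mg protein/h, %g g wet/g protein, %g cells/g wet",
                   vmax, wet_weight_per_protein, cells_per_g_wet)),
            class = "cell_activity")
}

#' @export
print.cell_activity <- function(x, ...) {
  cat(sprintf("<cell_activity>%s %.2g fmol NH3 cell^-1 h^-1\n",
              if (is.null(x$guild)) "" else paste0(" ", x$guild),
              signif(x$activity, 2)))
  cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Putative NOx production of a growing guild
#'
#' Converts a growing-population abundance into the N it could have oxidized
#' over the incubation, holding every grown cell at the given activity for
#' the whole duration (the upper-bound convention): `cells = growth /
#' copies_per_cell`, `ug N = cells * activity * hours * 1.4e-8` (1 fmol NH3
#' = 1.4e-8 ug N). Undetected or negative growth contributes zero — a
#' declining guild is never a negative N flux. A trapezoidal option halves
#' the exposure (mean of zero initial and final growing population), for
#' users who prefer a time-averaged cell count.
#'
#' @param growth A `growth_estimate` or a number (amoA copies g^-1 dry
#'   soil); only detected growth contributes when a `growth_estimate` is
#'   given.
#' @param activity A `cell_activity` or number (fmol NH3 cell^-1 h^-1).
#' @param hours Incubation duration in hours (> 0; default 720 = 30 days).
#' @param copies_per_cell *amoA* copies per cell (>= 1; default 1).
#' @param integration `"endpoint"` (default, upper bound) or
#'   `"trapezoidal"`.
#' @return Putative NOx production, ug N g^-1 dry soil.
#' @export
guild_contribution <- function(growth, activity, hours = 720,
                               copies_per_cell = 1,
                               integration = c("endpoint", "trapezoidal")) {
  integration <- match.arg(integration)
  check_number(hours, "hours")
  if (hours <= 0) stop("`hours` must be > 0", call. = FALSE)
  check_number(copies_per_cell, "copies_per_cell", min = 1)
  if (inherits(growth, "growth_estimate")) {
    growth <- if (isFALSE(growth$detected)) 0 else growth$value
  }
  check_number(growth, "growth")
  if (inherits(activity, "cell_activity")) activity <- activity$activity
  check_number(activity, "activity", min = 0)
  growth <- max(0, growth)
  cells <- growth / copies_per_cell
  if (integration == "trapezoidal") cells <- cells / 2
  cells * activity * hours * .ug_n_per_fmol
}

#' Apportion measured NOx production among guilds
#'
#' Compares the summed putative per-guild contributions with the measured
#' net NOx production. The unexplained residual is
#' `max(0, measured - sum(contributions))`; when the theoretical sum exceeds
#' the measurement the breakdown is flagged `overexplained` and the
#' contributions are reported as-is, never rescaled (they are upper bounds,
#' not a partition).
#'
#' @param measured_nox Measured net NOx production, ug N g^-1 dry soil
#'   (>= 0).
#' @param contributions Named non-negative numeric vector of per-guild
#'   putative contributions (ug N g^-1).
#' @param soil_id,condition,growth_method Optional labels carried through.
#' @return A `contribution_breakdown`: contributions, unaccounted,
#'   overexplained, measured_nox plus the labels.
#' @export
apportion <- function(measured_nox, contributions, soil_id = NULL,
                      condition = NULL, growth_method = NULL) {
  check_number(measured_nox, "measured_nox", min = 0)
  if (!is.numeric(contributions) || length(contributions) < 1) {
    stop("`contributions` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(contributions)) || any(contributions < 0)) {
    stop("contributions must be finite and >= 0", call. = FALSE)
  }
  total <- sum(contributions)
  structure(list(soil_id = soil_id, condition = condition,
                 growth_method = growth_method,
                 contributions = contributions,
                 unaccounted = max(0, measured_nox - total),
                 overexplained = total > measured_nox,
                 measured_nox = measured_nox),
            class = "contribution_breakdown")
}

#' @export
print.contribution_breakdown <- function(x, ...) {
  hdr <- paste(c(x$soil_id, x$condition, x$growth_method), collapse = " / ")
  cat(sprintf("<contribution_breakdown>%s measured %.3g ug N/g\n",
              if (nzchar(hdr)) paste0(" ", hdr, ":") else "", x$measured_nox))
  for (g in names(x$contributions)) {
    cat(sprintf("  %-10s %.3g\n", g, x$contributions[[g]]))
  }
  cat(sprintf("  %-10s %.3g%s\n", "unaccounted", x$unaccounted,
              if (x$overexplained) "  (overexplained)" else ""))
  invisible(x)
}

#' Scale a per-area emission rate to a global total
#'
#' `rate [kg N ha^-1 yr^-1] * area [ha] * 1e-9 [Tg/kg]`. For example, an
#' annual N2O emission of 1.2 kg N ha^-1 over the 19 million ha of global
#' oil palm cultivation is 0.0228, i.e. 0.02 Tg N2O-N per year at two
#' decimals. Returned unrounded; round at presentation.
#'
#' @param per_area_rate kg N ha^-1 yr^-1 (>= 0).
#' @param area ha (>= 0).
#' @return Tg N yr^-1.
#' @export
scale_area_emission <- function(per_area_rate, area) {
  check_number(per_area_rate, "per_area_rate", min = 0)
  check_number(area, "area", min = 0)
  per_area_rate * area * 1e-9
}
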
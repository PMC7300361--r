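# Dataset I/O, run configuration and the end-to-end pipeline chaining
# rates -> growth -> SIP labelling -> stability -> apportionment.

.chem_cols <- c("microcosm_id", "soil_id", "condition", "isotope",
                "replicate", "day", "nh4", "nox", "ph")
.ab_cols <- c("microcosm_id", "soil_id", "condition", "isotope",
              "replicate", "day", "guild", "copies")
.grad_cols <- c("microcosm_id", "soil_id", "condition", "isotope",
                "replicate", "guild", "fraction_index", "buoyant_density",
                "copies")

check_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s table is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

check_nonneg <- function(df, col, what) {
  bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
  if (length(bad)) {
    stop(sprintf("%s table: negative %s at row(s) %s", what, col,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
}

#' Write a dataset to CSV tables
#'
#' Writes `chemistry.csv`, `abundance.csv` and `gradient.csv` (plus, when
#' ground truth is attached, `truth_guilds.csv` and `truth_soils.csv`) and a
#' `config.json` provenance sidecar echoing the simulator configuration.
#'
#' @param dataset A `sip_dataset` (see [generate_dataset()], [read_dataset()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sip_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$chemistry, file.path(dir, "chemistry.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$abundance, file.path(dir, "abundance.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$gradient, file.path(dir, "gradient.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$truth_guilds)) {
    utils::write.csv(dataset$truth_guilds, file.path(dir, "truth_guilds.csv"),
                     row.names = FALSE)
    utils::write.csv(dataset$truth_soils, file.path(dir, "truth_soils.csv"),
                     row.names = FALSE)
  }
  if (!is.null(dataset$config)) {
    jsonlite::write_json(unclass(dataset$config),
                         file.path(dir, "config.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Read and validate a dataset from CSV tables
#'
#' Reads the chemistry, abundance and gradient tables (written by
#' [write_dataset()] or assembled externally with the same headers) and
#' validates them: required columns present, guild labels known, no negative
#' concentrations or counts (errors name the offending rows), and
#' referential integrity — every gradient row's microcosm must exist in the
#' abundance table.
#'
#' @param dir Directory containing `chemistry.csv`, `abundance.csv`,
#'   `gradient.csv`; alternatively pass explicit paths.
#' @param chemistry,abundance,gradient Optional explicit file paths,
#'   overriding `dir`.
#' @return A validated `sip_dataset` (ground-truth tables attached when
#'   present alongside).
#' @export
read_dataset <- function(dir = NULL, chemistry = NULL, abundance = NULL,
                         gradient = NULL) {
  path_of <- function(explicit, file) {
    if (!is.null(explicit)) explicit else file.path(dir, file)
  }
  pc <- path_of(chemistry, "chemistry.csv")
  pa <- path_of(abundance, "abundance.csv")
  pg <- path_of(gradient, "gradient.csv")
  for (p in c(pc, pa, pg)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  chem <- tibble::as_tibble(utils::read.csv(pc, stringsAsFactors = FALSE))
  ab <- tibble::as_tibble(utils::read.csv(pa, stringsAsFactors = FALSE))
  grad <- tibble::as_tibble(utils::read.csv(pg, stringsAsFactors = FALSE))

  check_cols(chem, .chem_cols, "chemistry")
  check_cols(ab, .ab_cols, "abundance")
  check_cols(grad, .grad_cols, "gradient")
  check_nonneg(chem, "nh4", "chemistry")
  check_nonneg(chem, "nox", "chemistry")
  check_nonneg(ab, "copies", "abundance")
  check_nonneg(grad, "copies", "gradient")
  bad_guild <- setdiff(unique(c(ab$guild, grad$guild)), .guild_levels)
  if (length(bad_guild)) {
    stop("unknown guild label(s): ", paste(bad_guild, collapse = ", "),
         call. = FALSE)
  }
  orphan <- setdiff(unique(grad$microcosm_id), unique(ab$microcosm_id))
  if (length(orphan)) {
    stop("gradient rows reference unknown microcosm(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }

  truth_g <- truth_s <- NULL
  if (!is.null(dir)) {
    tg <- file.path(dir, "truth_guilds.csv")
    ts <- file.path(dir, "truth_soils.csv")
    if (file.exists(tg)) truth_g <- tibble::as_tibble(utils::read.csv(tg))
    if (file.exists(ts)) truth_s <- tibble::as_tibble(utils::read.csv(ts))
  }
  structure(list(chemistry = chem, abundance = ab, gradient = grad,
                 truth_guilds = truth_g, truth_soils = truth_s,
                 config = NULL),
            class = "sip_dataset")
}

#' Analysis run configuration
#'
#' All tunable analysis parameters in one object, echoed verbatim into every
#' result bundle for provenance.
#'
#' @param heavy_threshold Heavy-window density threshold, g ml^-1.
#' @param delta_min Minimum WMD shift for a labelling call, g ml^-1.
#' @param alpha Significance level for every test.
#' @param ttest_variant `"pooled"` or `"welch"`.
#' @param hours Incubation duration for contributions (h).
#' @param copies_per_cell *amoA* copies per cell used in apportionment.
#' @param activities Named per-guild maximum activities, fmol NH3 cell^-1
#'   h^-1 (default [default_cell_activities()]).
#' @param subtract_12C Subtract 12C heavy-window background in
#'   [labeled_abundance()].
#' @param seed Optional integer recorded for provenance.
#' @return A `run_config` object.
#' @export
run_config <- function(heavy_threshold = 1.725, delta_min = 0.005,
                       alpha = 0.05, ttest_variant = c("pooled", "welch"),
                       hours = 720, copies_per_cell = 1,
                       activities = default_cell_activities(),
                       subtract_12C = FALSE, seed = NULL) {
  ttest_variant <- match.arg(ttest_variant)
  check_number(heavy_threshold, "heavy_threshold")
  check_number(delta_min, "delta_min", min = 0)
  check_number(alpha, "alpha", min = 0, max = 1)
  check_number(hours, "hours")
  if (hours <= 0) stop("`hours` must be > 0", call. = FALSE)
  check_number(copies_per_cell, "copies_per_cell", min = 1)
  if (!all(.guild_levels %in% names(activities))) {
    stop("`activities` must be named for AOA, AOB and comammox",
         call. = FALSE)
  }
  structure(list(heavy_threshold = heavy_threshold, delta_min = delta_min,
                 alpha = alpha, ttest_variant = ttest_variant, hours = hours,
                 copies_per_cell = copies_per_cell,
                 activities = activities[.guild_levels],
                 subtract_12C = subtract_12C, seed = seed),
            class = "run_config")
}

profiles_for <- function(gradient, soil, cond, guild, iso, quantified_range) {
  sub <- gradient[gradient$soil_id == soil & gradient$condition == cond &
                    gradient$guild == guild & gradient$isotope == iso, ]
  lapply(split(sub, sub$microcosm_id), normalize_profile,
         quantified_range = quantified_range)
}

#' Run the full analysis pipeline
#'
#' Chains every analysis stage over a dataset, per soil x condition:
#' net NOx production with its t-test; per-guild growth by qPCR and by
#' DNA-SIP (labelling call + heavy-window quantification); stability indices
#' (per soil x guild) with pairwise guild comparisons; contribution
#' apportionment for both growth methods at the configured maximum cell
#' activities; and a two-way soil x condition ANOVA (with Tukey letters) on
#' replicate-level net NOx production. The pipeline is deterministic given
#' its inputs and configuration.
#'
#' @param dataset A `sip_dataset`.
#' @param config A [run_config()].
#' @return A `pipeline_result`: list of tibbles `rates`, `growth`,
#'   `labeling`, `stability`, `stability_comparisons`, `apportionment`,
#'   the `anova` list, and the echoed `config`.
#' @export
run_pipeline <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "sip_dataset"), inherits(config, "run_config"))
  chem <- dataset$chemistry
  ab <- dataset$abundance
  grad <- dataset$gradient
  day0 <- min(chem$day)
  dayT <- max(chem$day)
  quantified_range <- sort(unique(grad$fraction_index))
  soils <- unique(chem$soil_id)
  conds <- unique(chem$condition)
  guilds <- intersect(.guild_levels, unique(ab$guild))

  rates_l <- growth_l <- label_l <- app_l <- nox_rep_l <- list()
  stab_objs <- list()

  for (soil in soils) {
    for (cond in conds) {
      c0 <- chem[chem$soil_id == soil & chem$condition == cond &
                   chem$day == day0, ]
      cT <- chem[chem$soil_id == soil & chem$condition == cond &
                   chem$day == dayT, ]
      if (nrow(c0) == 0 || nrow(cT) == 0) {
        stop(sprintf("stage rates: no day %d/%d chemistry for %s/%s",
                     day0, dayT, soil, cond), call. = FALSE)
      }
      nn <- net_nox_production(c0$nox, cT$nox, alpha = config$alpha)
      rates_l[[length(rates_l) + 1L]] <- tibble::tibble(
        soil_id = soil, condition = cond, delta_nox = nn$delta, se = nn$se,
        t = nn$t, df = nn$df, p = nn$p, significant = nn$significant)
      nox_rep_l[[length(nox_rep_l) + 1L]] <- tibble::tibble(
        soil_id = soil, condition = cond,
        delta_nox = cT$nox - mean(c0$nox))
      measured <- max(0, nn$delta)

      contrib <- list(qpcr = numeric(0), sip = numeric(0))
      for (g in guilds) {
        a0 <- ab$copies[ab$soil_id == soil & ab$condition == cond &
                          ab$day == day0 & ab$guild == g]
        aT <- ab$copies[ab$soil_id == soil & ab$condition == cond &
                          ab$day == dayT & ab$guild == g]
        gq <- growth_by_qpcr(a0, aT, alpha = config$alpha, guild = g)
        growth_l[[length(growth_l) + 1L]] <- tibble::tibble(
          soil_id = soil, condition = cond, guild = g, method = "qpcr",
          value = gq$value, se = gq$se, p = gq$p, detected = gq$detected)

        p12 <- profiles_for(grad, soil, cond, g, "12C", quantified_range)
        p13 <- profiles_for(grad, soil, cond, g, "13C", quantified_range)
        lc <- detect_labeling(p12, p13, delta_min = config$delta_min,
                                alpha = config$alpha, guild = g)
        usable13 <- Filter(Negate(is_no_signal), p13)
        total13 <- mean(ab$copies[ab$soil_id == soil & ab$condition == cond &
                                    ab$day == dayT & ab$guild == g &
                                    ab$isotope == "13C"])
        if (length(usable13) > 0 && is.finite(total13)) {
          la <- labeled_abundance(usable13, total13,
                                  heavy_threshold = config$heavy_threshold,
                                  profiles_12C = p12,
                                  subtract_12C = config$subtract_12C)
          gs <- growth_by_sip(lc, la)
          label_pct <- if (total13 > 0)
            labeled_proportion(min(la$estimate, total13), total13) else NA_real_
        } else {
          la <- list(estimate = NA_real_, se = NA_real_)
          gs <- structure(list(guild = g, method = "sip", value = NA_real_,
                               se = NA_real_, t = NA_real_, df = NA_real_,
                               p = NA_real_, detected = NA),
                          class = "growth_estimate")
          label_pct <- NA_real_
        }
        growth_l[[length(growth_l) + 1L]] <- tibble::tibble(
          soil_id = soil, condition = cond, guild = g, method = "sip",
          value = gs$value, se = gs$se, p = gs$p, detected = gs$detected)
        label_l[[length(label_l) + 1L]] <- tibble::tibble(
          soil_id = soil, condition = cond, guild = g, call = lc$call,
          delta_wmd = lc$delta_wmd, p = lc$p_value,
          labeled_abundance = la$estimate, labeled_se = la$se,
          labeled_pct = label_pct)

        act <- config$activities[[g]]
        contrib$qpcr[g] <- guild_contribution(gq, act, hours = config$hours,
                                              copies_per_cell = config$copies_per_cell)
        contrib$sip[g] <- guild_contribution(gs, act, hours = config$hours,
                                             copies_per_cell = config$copies_per_cell)
      }
      for (method in c("qpcr", "sip")) {
        bd <- apportion(measured, contrib[[method]], soil_id = soil,
                        condition = cond, growth_method = method)
        app_l[[length(app_l) + 1L]] <- tibble::tibble(
          soil_id = soil, condition = cond, method = method,
          component = c(names(bd$contributions), "unaccounted"),
          nox_ug = c(unname(bd$contributions), bd$unaccounted),
          measured_nox = measured, overexplained = bd$overexplained)
      }
    }

    # stability: modified vs native day-30 abundances, per guild
    if (all(c("native", "modified") %in% conds)) {
      for (g in guilds) {
        m <- ab$copies[ab$soil_id == soil & ab$condition == "modified" &
                         ab$day == dayT & ab$guild == g]
        n <- ab$copies[ab$soil_id == soil & ab$condition == "native" &
                         ab$day == dayT & ab$guild == g]
        stab_objs[[paste(soil, g, sep = ".")]] <-
          stability_index(m, n, guild = g)
      }
    }
  }

  stab_l <- lapply(names(stab_objs), function(key) {
    s <- stab_objs[[key]]
    soil <- sub("\\..*$", "", key)
    tibble::tibble(soil_id = soil, guild = s$guild, stability = s$value,
                   compensation = s$compensation, n = s$n_modified)
  })
  comp_l <- list()
  for (soil in soils) {
    pairs <- utils::combn(guilds, 2, simplify = FALSE)
    for (pr in pairs) {
      ka <- paste(soil, pr[1], sep = "."); kb <- paste(soil, pr[2], sep = ".")
      if (!is.null(stab_objs[[ka]]) && !is.null(stab_objs[[kb]])) {
        ct <- compare_stability(stab_objs[[ka]], stab_objs[[kb]],
                                variant = config$ttest_variant)
        comp_l[[length(comp_l) + 1L]] <- tibble::tibble(
          soil_id = soil, guild_a = pr[1], guild_b = pr[2],
          t = ct$t, p = ct$p)
      }
    }
  }

  nox_rep <- dplyr::bind_rows(nox_rep_l)
  anova <- if (length(unique(nox_rep$soil_id)) > 1 &&
               length(unique(nox_rep$condition)) > 1) {
    anova_with_posthoc(as.data.frame(nox_rep), "delta_nox",
                       c("soil_id", "condition"))
  } else NULL

  structure(list(rates = dplyr::bind_rows(rates_l),
                 growth = dplyr::bind_rows(growth_l),
                 labeling = dplyr::bind_rows(label_l),
                 stability = dplyr::bind_rows(stab_l),
                 stability_comparisons = dplyr::bind_rows(comp_l),
                 apportionment = dplyr::bind_rows(app_l),
                 anova = anova,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d soil x condition sets; tables: rates (%d), growth (%d), labeling (%d), stability (%d), apportionment (%d)\n",
    nrow(x$rates), nrow(x$rates), nrow(x$growth), nrow(x$labeling),
    nrow(x$stability), nrow(x$apportionment)))
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Writes each result table as CSV plus a `summary.json` carrying the echoed
#' configuration and headline per-soil results.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("rates", "growth", "labeling", "stability",
                "stability_comparisons", "apportionment")) {
    utils::write.csv(result[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  summary <- list(
    config = unclass(result$config),
    n_soils = length(unique(result$rates$soil_id)),
    rates = result$rates,
    stability = result$stability)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
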
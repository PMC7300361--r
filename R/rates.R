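# Net nitrification rates, qPCR growth estimation, the stability index with
# compensation classification, and the classical significance tests
# (summary-statistic t-tests, ANOVA + Tukey letters).

#' Summary statistics of replicate measurements
#'
#' @param x Numeric vector of replicate values.
#' @return A `summary_stats` object: mean, se, n.
#' @export
summary_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 1) stop("no non-missing values", call. = FALSE)
  structure(list(mean = mean(x),
                 se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
                 n = length(x)),
            class = "summary_stats")
}

as_summary_stats <- function(x, field = "x") {
  if (inherits(x, "summary_stats")) return(x)
  if (is.numeric(x) && length(x) >= 1) return(summary_stats(x))
  if (is.list(x) && all(c("mean", "se", "n") %in% names(x))) {
    check_number(x$mean, paste0(field, "$mean"))
    check_number(x$se, paste0(field, "$se"), min = 0)
    check_number(x$n, paste0(field, "$n"), min = 1)
    return(structure(list(mean = x$mean, se = x$se, n = as.integer(x$n)),
                     class = "summary_stats"))
  }
  stop(sprintf("`%s` must be a numeric vector or a summary_stats-like list",
               field), call. = FALSE)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> mean %.4g +/- %.3g SE (n = %d)\n",
              x$mean, x$se, x$n))
  invisible(x)
}

#' Two-sample t-test from summary statistics
#'
#' Reconstructs the two-sample Student's (pooled-variance, default) or Welch
#' t statistic from group means, standard errors and sample sizes. When the
#' summaries derive from raw replicates, the pooled variant equals
#' `t.test(..., var.equal = TRUE)` on the raw data exactly.
#'
#' @param a,b `summary_stats` objects (or numeric replicate vectors, or
#'   lists with mean/se/n).
#' @param variant `"pooled"` (Student) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided), `mean_diff`, `se_diff`.
#' @export
summary_ttest <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as_summary_stats(a, "a"); b <- as_summary_stats(b, "b")
  if (a$se < 0 || b$se < 0) stop("standard errors must be >= 0", call. = FALSE)
  if (a$n < 2 || b$n < 2) {
    stop("need n >= 2 in both groups for inference", call. = FALSE)
  }
  va <- a$se^2 * a$n   # group variance
  vb <- b$se^2 * b$n
  diff <- a$mean - b$mean
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / df
    se_diff <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se_diff <- sqrt(a$se^2 + b$se^2)
    df <- if (se_diff == 0) a$n + b$n - 2 else
      se_diff^4 / (a$se^4 / (a$n - 1) + b$se^4 / (b$n - 1))
  }
  t <- if (se_diff == 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / se_diff
  }
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_diff = diff, se_diff = se_diff,
       variant = variant)
}

#' Net NOx- production over an incubation
#'
#' The net nitrification rate of a microcosm set: the increase in nitrite
#' plus nitrate between day 0 and the end of incubation, with a Student's
#' t-test of the null hypothesis of no change. Inputs are replicate NOx-
#' measurements (numeric vectors, or data frames carrying `nox` plus
#' `soil_id`/`condition` columns, which are checked for consistency).
#'
#' @param day0,dayT Replicate NOx- measurements (ug N g^-1 dry soil) at the
#'   start and end of incubation; >= 2 replicates each.
#' @param alpha Significance level.
#' @return List with `delta` (ug N g^-1), `se` (propagated
#'   `sqrt(se0^2 + seT^2)`), `t`, `df`, `p`, `significant`, and the two
#'   group summaries.
#' @export
net_nox_production <- function(day0, dayT, alpha = 0.05) {
  extract <- function(x, field) {
    if (is.data.frame(x)) {
      if (!"nox" %in% names(x)) {
        stop(sprintf("`%s` data frame must have a `nox` column", field),
             call. = FALSE)
      }
      x$nox
    } else x
  }
  for (key in c("soil_id", "condition")) {
    if (is.data.frame(day0) && is.data.frame(dayT) &&
        key %in% names(day0) && key %in% names(dayT)) {
      if (!setequal(unique(day0[[key]]), unique(dayT[[key]]))) {
        stop(sprintf("mismatched `%s` between day0 and dayT measurements", key),
             call. = FALSE)
      }
    }
  }
  x0 <- extract(day0, "day0"); xT <- extract(dayT, "dayT")
  if (length(x0) < 2 || length(xT) < 2) {
    stop("need >= 2 replicates at each time point", call. = FALSE)
  }
  s0 <- summary_stats(x0); sT <- summary_stats(xT)
  tt <- summary_ttest(sT, s0, variant = "pooled")
  list(delta = sT$mean - s0$mean,
       se = sqrt(s0$se^2 + sT$se^2),
       t = tt$t, df = tt$df, p = tt$p,
       significant = is.finite(tt$p) && tt$p < alpha,
       day0 = s0, dayT = sT)
}

#' Guild growth from qPCR time series
#'
#' Growth as the temporal increase in total *amoA* abundance over the
#' incubation (final minus initial mean). Growth is "detected" only when the
#' increase is positive and a one-sided two-sample t-test (from the summary
#' statistics, pooled df) rejects at `alpha`; a decline is by definition not
#' growth. With fewer than 2 replicates on either side the point estimate is
#' still returned but inference is refused (`detected = NA`).
#'
#' @param day0,day30 `summary_stats` (or replicate vectors) of *amoA*
#'   copies g^-1 dry soil.
#' @param alpha Significance level for detection.
#' @param guild Optional guild label.
#' @return A `growth_estimate`: guild, method `"qpcr"`, `value` (copies
#'   g^-1, may be negative), `se`, `t`, `df`, `p` (one-sided), `detected`.
#' @export
growth_by_qpcr <- function(day0, day30, alpha = 0.05, guild = NULL) {
  check_number(alpha, "alpha", min = 0, max = 1)
  s0 <- as_summary_stats(day0, "day0")
  s30 <- as_summary_stats(day30, "day30")
  value <- s30$mean - s0$mean
  se <- sqrt(s0$se^2 + s30$se^2)
  if (s0$n < 2 || s30$n < 2) {
    warning("fewer than 2 replicates: point estimate only, no inference")
    out <- list(guild = guild, method = "qpcr", value = value, se = se,
                t = NA_real_, df = NA_real_, p = NA_real_, detected = NA)
    return(structure(out, class = "growth_estimate"))
  }
  tt <- summary_ttest(s30, s0, variant = "pooled")
  p_one <- if (is.infinite(tt$t)) {
    if (tt$t > 0) 0 else 1
  } else {
    stats::pt(tt$t, tt$df, lower.tail = FALSE)
  }
  detected <- (value > 0) && (p_one < alpha)
  structure(list(guild = guild, method = "qpcr", value = value, se = se,
                 t = tt$t, df = tt$df, p = p_one, detected = detected),
            class = "growth_estimate")
}

#' Guild growth from DNA-SIP heavy fractions
#'
#' Wraps a [detect_labeling()] call and a [labeled_abundance()] estimate into
#' a `growth_estimate` on the same footing as [growth_by_qpcr()]: the
#' growing-population abundance is the 13C-labelled abundance in the heavy
#' window, and growth is "detected" when the labelling call is positive.
#'
#' @param call A `labeling_call` from [detect_labeling()].
#' @param labeled A [labeled_abundance()] result.
#' @return A `growth_estimate` with method `"sip"`.
#' @export
growth_by_sip <- function(call, labeled) {
  stopifnot(inherits(call, "labeling_call"))
  structure(list(guild = call$guild, method = "sip",
                 value = labeled$estimate, se = labeled$se,
                 t = NA_real_, df = NA_real_, p = call$p_value,
                 detected = if (identical(call$call, "no_call")) NA else
                   isTRUE(call$labeled)),
            class = "growth_estimate")
}

#' @export
print.growth_estimate <- function(x, ...) {
  status <- if (isTRUE(x$detected)) "detected" else
    if (isFALSE(x$detected)) "n.d." else "no inference"
  cat(sprintf("<growth_estimate>%s %s: %.3g copies/g (%s)\n",
              if (is.null(x$guild)) "" else paste0(" ", x$guild),
              x$method, x$value, status))
  invisible(x)
}

#' Ecosystem-function stability index
#'
#' The proportional change of a guild's day-30 abundance in pH-modified (M)
#' soil relative to native-pH (N) soil:
#' `stability = 100 * (mean(M) - mean(N)) / mean(N)`. The index ranges from
#' -100 (complete loss) upward without bound; 0 is the neutral point
#' (highest stability), negative values indicate undercompensation and
#' positive values overcompensation following the perturbation.
#'
#' Because modified and native microcosms are independent (no pairing is
#' possible), per-replicate indices are formed by referencing each modified
#' replicate to the native mean: `100 * (M_i - mean(N)) / mean(N)`. Their
#' mean equals the index, and they carry the replicate spread used by
#' [compare_stability()].
#'
#' @param modified,native Replicate day-30 abundances (copies g^-1, >= 0)
#'   under the modified and native condition.
#' @param guild Optional guild label.
#' @return A `stability_index`: value (percent), per_replicate,
#'   compensation (`"under"`, `"over"`, `"neutral"`), guild.
#' @export
stability_index <- function(modified, native, guild = NULL) {
  if (any(modified < 0) || any(native < 0)) {
    stop("abundances must be >= 0", call. = FALSE)
  }
  nm <- mean(native)
  if (!is.finite(nm) || nm <= 0) {
    stop("native mean abundance must be > 0: stability is undefined",
         call. = FALSE)
  }
  value <- 100 * (mean(modified) - nm) / nm
  per_rep <- 100 * (modified - nm) / nm
  compensation <- if (value < 0) "under" else if (value > 0) "over" else "neutral"
  structure(list(guild = guild, value = value, per_replicate = per_rep,
                 compensation = compensation,
                 n_modified = length(modified), n_native = length(native)),
            class = "stability_index")
}

#' @export
print.stability_index <- function(x, ...) {
  cat(sprintf("<stability_index>%s %+.1f%% (%scompensation, n = %d)\n",
              if (is.null(x$guild)) "" else paste0(" ", x$guild),
              x$value,
              if (x$compensation == "neutral") "no " else x$compensation,
              x$n_modified))
  invisible(x)
}

#' Compare two stability indices
#'
#' Independent Student's t-test (pooled variance by default, Welch by flag)
#' on the per-replicate stability values of two guilds, answering whether a
#' perturbation induced different compensation in the two communities.
#'
#' @param index_a,index_b `stability_index` objects.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided), and the two index values.
#' @export
compare_stability <- function(index_a, index_b,
                              variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(inherits(index_a, "stability_index"),
            inherits(index_b, "stability_index"))
  ra <- index_a$per_replicate; rb <- index_b$per_replicate
  if (length(ra) < 2 || length(rb) < 2) {
    stop("need >= 2 per-replicate stability values on both sides",
         call. = FALSE)
  }
  if (stats::sd(ra) == 0 && stats::sd(rb) == 0) {
    t <- if (mean(ra) == mean(rb)) 0 else sign(mean(ra) - mean(rb)) * Inf
    df <- length(ra) + length(rb) - 2
    return(list(t = t, df = df, p = if (t == 0) 1 else 0,
                value_a = index_a$value, value_b = index_b$value))
  }
  tt <- stats::t.test(ra, rb, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, value_a = index_a$value, value_b = index_b$value)
}

#' Fixed-effects ANOVA with Tukey post hoc letters
#'
#' Classical one- or two-way ANOVA (with interaction for two factors) on a
#' measurement table, followed by Tukey's HSD and compact letter display
#' groupings of the (cell) means — the lettering shown above bars in
#' standard figures. Letters are computed on the single grouping factor for
#' one-way designs and on the factor-combination cells for two-way designs.
#'
#' @param data Data frame with the response and factor columns.
#' @param response Name of the response column.
#' @param factors Character vector of 1 or 2 factor column names; each must
#'   have >= 2 levels.
#' @return List with `anova_table` (term, df, statistic, p), `tukey`
#'   (`TukeyHSD` result on the cell factor) and `letters` (named character
#'   vector of group letters).
#' @export
anova_with_posthoc <- function(data, response, factors) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)),
            length(factors) %in% c(1L, 2L))
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) {
      stop(sprintf("factor `%s` has fewer than 2 levels", f), call. = FALSE)
    }
  }
  rhs <- paste(factors, collapse = " * ")
  fit <- stats::aov(stats::as.formula(paste(response, "~", rhs)), data = data)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  keep <- terms != "Residuals"
  anova_table <- tibble::tibble(term = terms[keep],
                                df = sm[keep, "Df"],
                                statistic = sm[keep, "F value"],
                                p = sm[keep, "Pr(>F)"])

  cells <- interaction(data[factors], sep = ":", drop = TRUE)
  cell_data <- data.frame(.y = data[[response]], .grp = cells)
  cell_fit <- stats::aov(.y ~ .grp, data = cell_data)
  tukey <- stats::TukeyHSD(cell_fit)
  letters <- tryCatch({
    glht <- multcomp::glht(cell_fit, linfct = multcomp::mcp(.grp = "Tukey"))
    multcomp::cld(glht)$mcletters$Letters
  }, error = function(e) {
    # degenerate designs (e.g. zero residual variance): single group
    stats::setNames(rep("a", nlevels(cells)), levels(cells))
  })
  list(anova_table = anova_table, tukey = tukey,
       letters = letters[levels(cells)])
}
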
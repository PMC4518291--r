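#' Oocyte geometry for water-permeability calculations
#'
#' The osmotically active surface `S` is taken as `folding_factor` times the
#' apparent (optical) area, the standard correction for the extensive
#' microvillar folding of the Xenopus oocyte membrane (default 9).
#'
#' @param V0 Initial oocyte volume, cm^3.
#' @param apparent_area Apparent surface area from imaging, cm^2.
#' @param folding_factor Dimensionless folding correction (default 9).
#' @return Object of class `oocyte_geometry` with derived `S` (cm^2).
#' @export
oocyte_geometry <- function(V0, apparent_area, folding_factor = 9) {
  if (any(c(V0, apparent_area, folding_factor) <= 0))
    stop("V0, apparent_area and folding_factor must all be positive")
  structure(list(V0 = V0, apparent_area = apparent_area,
                 folding_factor = folding_factor,
                 S = folding_factor * apparent_area),
            class = "oocyte_geometry")
}

#' Swelling time-course of one oocyte
#'
#' Relative volume `V/V0` sampled at stated times after transfer from
#' isotonic medium (`osm_in`, the oocyte's internal osmolality at t = 0,
#' equal to the isotonic bath) into hypotonic medium (`osm_out`). The
#' default protocol images every 2 s over the first 20 s.
#'
#' @param times Seconds, strictly increasing, starting at 0.
#' @param rel_volume `V/V0`, same length as `times`; must start at 1 within
#'   `tol`.
#' @param osm_in,osm_out Osmolalities, mOsm. Swelling requires
#'   `osm_in > osm_out`.
#' @param geometry An [oocyte_geometry].
#' @param group Construct/dose label.
#' @param tol Tolerance on `rel_volume[1] == 1` (default 0.05).
#' @return Object of class `swelling_timecourse`.
#' @export
swelling_timecourse <- function(times, rel_volume, osm_in, osm_out,
                                geometry, group = NA_character_,
                                tol = 0.05) {
  if (length(times) != length(rel_volume))
    stop("times and rel_volume must have equal length")
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0")
  if (abs(rel_volume[1] - 1) > tol)
    stop("rel_volume must start at 1 (found ", rel_volume[1], ")")
  if (osm_in <= osm_out)
    stop("swelling assay requires osm_in > osm_out")
  stopifnot(inherits(geometry, "oocyte_geometry"))
  structure(list(times = times, rel_volume = rel_volume,
                 osm_in = osm_in, osm_out = osm_out,
                 geometry = geometry, group = group),
            class = "swelling_timecourse")
}

#' Initial swelling slope d(V/V0)/dt by ordinary least squares
#'
#' @param tc A [swelling_timecourse].
#' @param window Time window `c(lo, hi)` in seconds over which to fit
#'   (default the full course). At least 3 samples must fall inside.
#'   Longer windows are more precise but underestimate the initial rate as
#'   the osmotic gradient dissipates.
#' @return List with `slope` (s^-1), `fit_r2`, `n_points`.
#' @export
estimate_initial_slope <- function(tc, window = NULL) {
  stopifnot(inherits(tc, "swelling_timecourse"))
  if (is.null(window)) window <- range(tc$times)
  sel <- tc$times >= window[1] & tc$times <= window[2]
  if (sum(sel) < 3L)
    stop("need at least 3 samples in the fit window (found ", sum(sel), ")")
  fit <- lm(y ~ t, data = data.frame(t = tc$times[sel], y = tc$rel_volume[sel]))
  # noise-free courses fit exactly; summary.lm's perfect-fit warning is moot
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]),
       fit_r2 = if (is.finite(r2)) r2 else NA_real_,
       n_points = sum(sel))
}

#' Osmotic water permeability from geometry, slope and gradient
#'
#' The bare permeability formula
#' `Pf = V0 * slope / (S * Vw * delta_c)` in caller-supplied units; the
#' higher-level [compute_pf()] handles the mOsm conversion. Exposed
#' separately so unit and linearity properties can be checked directly.
#'
#' @param V0 Initial volume. @param S Membrane surface.
#' @param slope d(V/V0)/dt. @param delta_c Osmotic gradient (mol per volume
#'   unit consistent with `V0`/`S`). @param Vw Partial molar volume of water.
#' @return Pf in the consistent unit system.
#' @export
pf_formula <- function(V0, S, slope, delta_c, Vw = 18) {
  if (delta_c == 0)
    stop("osmotic gradient is zero: Pf is undefined when osm_in == osm_out")
  V0 * slope / (S * Vw * delta_c)
}

#' Osmotic water permeability of one swelling time-course
#'
#' Applies `Pf = V0 [d(V/V0)/dt] / (S * Vw * (Osm_in - Osm_out))` with
#' `Vw = 18 cm^3 mol^-1` and the osmotic gradient converted from mOsm to
#' mol cm^-3 (1 mOsm = 1e-6 mol of osmotically active particles per cm^3).
#'
#' @param tc A [swelling_timecourse].
#' @param slope Initial slope in s^-1; computed via
#'   [estimate_initial_slope()] when omitted.
#' @param window Passed to [estimate_initial_slope()] when `slope` missing.
#' @param Vw Partial molar volume of water, cm^3 mol^-1.
#' @return Object of class `pf_estimate`: list with `Pf` (cm s^-1), `slope`,
#'   `delta_c_mol_cm3`, `V0`, `S`, `Vw`, `fit_r2`, `n_points`.
#' @export
compute_pf <- function(tc, slope = NULL, window = NULL, Vw = 18) {
  stopifnot(inherits(tc, "swelling_timecourse"))
  fit_r2 <- NA_real_; n_points <- NA_integer_
  if (is.null(slope)) {
    est <- estimate_initial_slope(tc, window)
    slope <- est$slope; fit_r2 <- est$fit_r2; n_points <- est$n_points
  }
  delta_c <- (tc$osm_in - tc$osm_out) * 1e-6  # mOsm -> mol cm^-3
  g <- tc$geometry
  structure(list(Pf = pf_formula(g$V0, g$S, slope, delta_c, Vw),
                 slope = slope, delta_c_mol_cm3 = delta_c,
                 V0 = g$V0, S = g$S, Vw = Vw,
                 fit_r2 = fit_r2, n_points = n_points),
            class = "pf_estimate")
}

#' @export
print.pf_estimate <- function(x, ...) {
  cat(sprintf("<pf_estimate> Pf = %.3g cm/s (slope %.3g 1/s)\n",
              x$Pf, x$slope))
  invisible(x)
}

#' Radiotracer uptake measurement
#'
#' Per-oocyte scintillation counts after a timed exposure to a hot tracer
#' diluted in cold solute, together with a zero-time group whose counts
#' estimate externally bound (not transported) label.
#'
#' @param counts Per-oocyte counts (counts per minute), exposed group.
#' @param zero_time_counts Counts of the zero-time background group.
#' @param specific_activity_ci_mmol Tracer specific activity, Ci mmol^-1.
#' @param hot_conc_um Tracer concentration, micromolar (default 5).
#' @param cold_conc_mm Cold solute concentration, millimolar (default 1).
#' @param exposure_min Exposure, minutes (default 10).
#' @param group Construct label.
#' @return Object of class `uptake_measurement`.
#' @export
uptake_measurement <- function(counts, zero_time_counts,
                               specific_activity_ci_mmol = 50,
                               hot_conc_um = 5, cold_conc_mm = 1,
                               exposure_min = 10, group = NA_character_) {
  if (any(counts < 0) || any(zero_time_counts < 0))
    stop("scintillation counts cannot be negative")
  if (length(zero_time_counts) == 0L)
    stop("a non-empty zero-time group is required for background subtraction")
  if (exposure_min <= 0) stop("exposure time must be positive")
  structure(list(counts = counts, zero_time_counts = zero_time_counts,
                 specific_activity_ci_mmol = specific_activity_ci_mmol,
                 hot_conc_um = hot_conc_um, cold_conc_mm = cold_conc_mm,
                 exposure_min = exposure_min, group = group),
            class = "uptake_measurement")
}

#' Solute uptake per oocyte from scintillation counts
#'
#' Subtracts the mean zero-time background, converts the excess counts to
#' moles of tracer via specific activity and counting efficiency, and scales
#' by the total/hot concentration ratio (isotope dilution by the cold
#' solute) to total solute uptake in pmol per oocyte over the exposure.
#' Negative post-subtraction values are clamped to 0 and counted in
#' `n_clamped`.
#'
#' @param m An [uptake_measurement].
#' @param counting_efficiency Counts registered per disintegration
#'   (default 1; only relative group comparisons depend on it).
#' @param conversion Optional override: counts per pmol of total solute.
#'   When supplied, specific activity / efficiency / dilution are bypassed.
#' @return List with `per_oocyte` (pmol/oocyte), `mean`, `sem`, `n`,
#'   `n_clamped`, `conversion` (counts per pmol), `background`.
#' @export
compute_uptake <- function(m, counting_efficiency = 1, conversion = NULL) {
  stopifnot(inherits(m, "uptake_measurement"))
  if (is.null(conversion)) {
    # counts per pmol tracer: Ci/mmol * 2.22e12 dpm/Ci * 1e-9 mmol/pmol * eff
    cpm_per_pmol_tracer <-
      m$specific_activity_ci_mmol * 2.22e12 * 1e-9 * counting_efficiency
    hot_frac <- m$hot_conc_um * 1e-6 /
      (m$hot_conc_um * 1e-6 + m$cold_conc_mm * 1e-3)
    conversion <- cpm_per_pmol_tracer * hot_frac
  }
  if (conversion <= 0)
    stop("degenerate configuration: counts-to-pmol conversion must be positive")
  bg <- mean(m$zero_time_counts)
  raw <- (m$counts - bg) / conversion
  n_clamped <- sum(raw < 0)
  per <- pmax(0, raw)
  n <- length(per)
  list(per_oocyte = per, mean = mean(per),
       sem = sd(per) / sqrt(n), n = n, n_clamped = n_clamped,
       conversion = conversion, background = bg)
}

#' Dose at which the response plateaus
#'
#' Finds the smallest cRNA dose whose mean Pf is not significantly lower
#' (one-sided Welch test at `alpha`) than that of the dose with maximal mean
#' — the operational definition of "the dose at which maximal water
#' permeability is obtained". Identical-constant groups (zero variance, no
#' evidence of a difference) count as at plateau.
#'
#' @param doses Numeric dose (ng cRNA) per replicate.
#' @param pf Pf values, same length as `doses`.
#' @param alpha Test level (default 0.05).
#' @return List with `plateau_dose`, `max_mean_dose` and a per-dose summary
#'   data.frame (`dose`, `mean`, `sem`, `n`, `p_vs_max`).
#' @export
dose_response_plateau <- function(doses, pf, alpha = 0.05) {
  if (length(doses) != length(pf)) stop("doses and pf must match in length")
  split_pf <- split(pf, doses)
  lev <- as.numeric(names(split_pf))
  if (length(lev) < 2L) stop("need at least 2 doses")
  ns <- lengths(split_pf)
  if (any(ns < 2L))
    stop("every dose needs >= 2 replicates (violated at dose ",
         paste(lev[ns < 2], collapse = ", "), ")")
  means <- vapply(split_pf, mean, 0)
  dmax <- which.max(means)
  p_vs_max <- vapply(seq_along(lev), function(i) {
    if (i == dmax) return(1)
    tryCatch(
      t.test(split_pf[[i]], split_pf[[dmax]], alternative = "less")$p.value,
      error = function(e) 1)  # zero-variance: no evidence of being lower
  }, numeric(1))
  at_plateau <- p_vs_max >= alpha
  plateau <- lev[which(at_plateau)[1]]
  list(plateau_dose = plateau, max_mean_dose = lev[dmax],
       summary = data.frame(dose = lev, mean = unname(means),
                            sem = vapply(split_pf, function(v)
                              sd(v) / sqrt(length(v)), 0),
                            n = unname(ns), p_vs_max = p_vs_max))
}

#' One-way ANOVA with each-vs-control comparisons
#'
#' Overall one-way analysis of variance across construct groups, followed by
#' Dunnett many-to-one comparisons against the control (or Holm-adjusted
#' Welch t-tests with `method = "holm"`). Significance stars: `*` for
#' adjusted p < 0.05, `**` for < 0.01. If every observation is identical the
#' F statistic is undefined and p is reported as 1.
#'
#' @param values Numeric response (e.g. Pf or uptake).
#' @param group Group labels, same length as `values`.
#' @param control Label of the control group (e.g. water-injected).
#' @param method `"dunnett"` (default) or `"holm"`.
#' @return Object of class `group_comparison`: list with `f_statistic`,
#'   `p_value`, `group_summary` (mean, sem, n per group) and `vs_control`
#'   (comparison, estimate, p_adjusted, stars).
#' @export
compare_groups_anova <- function(values, group, control, method = "dunnett") {
  group <- as.character(group)
  if (length(unique(group)) < 2L) stop("need at least 2 groups")
  if (!(control %in% group)) stop("control group '", control, "' not found")
  tab <- table(group)
  if (any(tab < 2L)) stop("every group needs n >= 2")
  g <- factor(group, levels = c(control, setdiff(sort(unique(group)), control)))
  dat <- data.frame(y = values, g = g)
  others <- levels(g)[-1]
  if (diff(range(values)) == 0) {
    # all observations identical: F is 0/0, no evidence of any difference
    vs <- data.frame(comparison = paste(others, "-", control),
                     estimate = 0, p_adjusted = 1, stars = "")
    gs <- data.frame(group = levels(g), mean = values[1], sem = 0,
                     n = as.integer(table(g)[levels(g)]))
    return(structure(list(f_statistic = NA_real_, p_value = 1,
                          group_summary = gs, vs_control = vs,
                          control = control, method = method),
                     class = "group_comparison"))
  }
  fit <- aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  Fstat <- an[1, "F value"]; p <- an[1, "Pr(>F)"]
  if (!is.finite(Fstat)) { Fstat <- NA_real_; p <- 1 }
  if (method == "dunnett") {
    vs <- tryCatch({
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
      sm <- summary(gl)
      data.frame(comparison = paste(others, "-", control),
                 estimate = unname(sm$test$coefficients),
                 p_adjusted = unname(sm$test$pvalues))
    }, error = function(e) NULL)
    if (is.null(vs)) method <- "holm"
  }
  if (method == "holm") {
    praw <- vapply(others, function(lev) {
      tryCatch(t.test(dat$y[dat$g == lev], dat$y[dat$g == control])$p.value,
               error = function(e) 1)
    }, numeric(1))
    vs <- data.frame(comparison = paste(others, "-", control),
                     estimate = vapply(others, function(lev)
                       mean(dat$y[dat$g == lev]) -
                         mean(dat$y[dat$g == control]), 0),
                     p_adjusted = p.adjust(praw, "holm"))
  }
  vs$stars <- ifelse(vs$p_adjusted < 0.01, "**",
                     ifelse(vs$p_adjusted < 0.05, "*", ""))
  gs <- do.call(rbind, lapply(levels(g), function(lev) {
    v <- dat$y[dat$g == lev]
    data.frame(group = lev, mean = mean(v),
               sem = sd(v) / sqrt(length(v)), n = length(v))
  }))
  structure(list(f_statistic = Fstat, p_value = p,
                 group_summary = gs, vs_control = vs,
                 control = control, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F = %.3f, p = %.4g (%s vs '%s')\n",
              x$f_statistic, x$p_value, x$method, x$control))
  print(x$vs_control, row.names = FALSE)
  invisible(x)
}
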
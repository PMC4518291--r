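#' Read a tidy swelling table and compute per-oocyte Pf
#'
#' The expected layout is one row per sampled frame:
#' `oocyte_id, group, time_s, rel_volume, osm_in, osm_out, V0, apparent_area`
#' (tab- or comma-separated; geometry and osmolalities constant within an
#' oocyte). Each oocyte's course is fitted and converted to Pf.
#'
#' @param path Delimited file as above.
#' @param window Fit window passed to [estimate_initial_slope()].
#' @param folding_factor Membrane folding correction (default 9).
#' @return data.frame: `oocyte_id`, `group`, `slope_per_s`, `fit_r2`,
#'   `pf_cm_per_s`.
#' @export
pf_from_table <- function(path, window = NULL, folding_factor = 9) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  needed <- c("oocyte_id", "group", "time_s", "rel_volume", "osm_in",
              "osm_out", "V0", "apparent_area")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("swelling table lacks column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$oocyte_id), function(d) {
    d <- d[order(d$time_s), ]
    tc <- swelling_timecourse(
      d$time_s, d$rel_volume, d$osm_in[1], d$osm_out[1],
      oocyte_geometry(d$V0[1], d$apparent_area[1], folding_factor),
      group = d$group[1])
    est <- estimate_initial_slope(tc, window)
    pf <- compute_pf(tc, slope = est$slope)
    data.frame(oocyte_id = d$oocyte_id[1], group = d$group[1],
               slope_per_s = est$slope, fit_r2 = est$fit_r2,
               pf_cm_per_s = pf$Pf)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a tidy uptake table and compute group uptake summaries
#'
#' Layout: one row per oocyte with columns `oocyte_id, group, counts,
#' is_zero_time` (logical or 0/1). Zero-time rows within each group supply
#' the background.
#'
#' @param path Delimited file.
#' @param ... Passed to [uptake_measurement()] (specific activity,
#'   concentrations, exposure).
#' @param conversion Optional counts-per-pmol override for [compute_uptake()].
#' @return data.frame: `group`, `mean_pmol`, `sem_pmol`, `n`, `n_clamped`.
#' @export
uptake_from_table <- function(path, ..., conversion = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  needed <- c("oocyte_id", "group", "counts", "is_zero_time")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("uptake table lacks column(s): ", paste(miss, collapse = ", "))
  df$is_zero_time <- as.logical(df$is_zero_time)
  out <- lapply(split(df, df$group), function(d) {
    m <- uptake_measurement(d$counts[!d$is_zero_time],
                            d$counts[d$is_zero_time],
                            group = d$group[1], ...)
    u <- compute_uptake(m, conversion = conversion)
    data.frame(group = d$group[1], mean_pmol = u$mean, sem_pmol = u$sem,
               n = u$n, n_clamped = u$n_clamped)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
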
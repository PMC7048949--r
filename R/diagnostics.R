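# Diagnostics: mixing-layer depth, integrated biomass, bloom phenology,
# limitation-factor medians, cross-mixing-layer-base vertical iron fluxes,
# the snapshot-anomaly eddy-flux operator, and scenario comparison.

#' Mixing-layer depth from a boundary-layer-depth sample
#'
#' The transport-relevant mixing-layer depth is the 99th percentile (by
#' default) of the daily boundary-layer-depth sample across the statistical
#' band, with the linear-interpolation order-statistic convention
#' (`stats::quantile` type 7).
#'
#' @param bl_sample Numeric vector of boundary-layer depths (m, positive).
#' @param prob Percentile (default 0.99).
#' @param type Quantile convention passed to [stats::quantile()].
#' @return Mixing-layer depth (m).
#' @export
mixing_layer_depth <- function(bl_sample, prob = 0.99, type = 7) {
  if (!length(bl_sample)) stop("empty boundary-layer sample", call. = FALSE)
  unname(stats::quantile(bl_sample, prob, type = type, names = FALSE))
}

#' Vertically integrated phytoplankton biomass
#'
#' At each depth level, take the spatial median of phytoplankton carbon over
#' the meridional band (the biomass distribution is approximately
#' log-normal, so the median is the robust center), then integrate over the
#' full depth: `<C_p> = sum_k median_y(P[, k]) * dz_k / 1000` (g C m^-2).
#'
#' @param P Phytoplankton field (ny x nz, mg C m^-3).
#' @param grid A [build_grid()] object.
#' @param band Meridional range `c(y0, y1)` in m (default 600-1400 km).
#' @return `<C_p>` in g C m^-2.
#' @export
integrated_biomass <- function(P, grid, band = c(6e5, 1.4e6)) {
  if (band[1] < 0 || band[2] > grid$Ly) {
    stop("band lies outside the domain [0, ", grid$Ly, "] m", call. = FALSE)
  }
  idx <- band_index(grid, band)
  med <- apply(P[idx, , drop = FALSE], 2, stats::median)
  sum(med * grid$dz) / 1000
}

# fold a daily series over whole years into a 365-day climatology (mean
# across years per day of year)
climatology_series <- function(x, period = 365) {
  n <- length(x)
  nyr <- n %/% period
  if (nyr < 1) stop("series shorter than one year", call. = FALSE)
  rowMeans(matrix(x[seq_len(nyr * period)], period, nyr))
}

#' Bloom onset and apex from a climatological biomass series
#'
#' The bloom onset is the day of the `<C_p>` minimum and the apex the day of
#' the maximum, over the 365-day climatology; ties are broken by the
#' earliest day.  A constant series is flagged degenerate (warning) and
#' both days are set to 0.
#'
#' @param cp Climatological `<C_p>` series, length 365 (day 0 = 1 January).
#' @return List with integer `onset_day` and `apex_day` in `[0, 365)`.
#' @export
bloom_metrics <- function(cp) {
  stopifnot(length(cp) == 365)
  if (max(cp) == min(cp)) {
    warning("constant biomass series: bloom metrics degenerate",
            call. = FALSE)
    return(list(onset_day = 0L, apex_day = 0L, degenerate = TRUE))
  }
  list(onset_day = as.integer(which.min(cp) - 1L),
       apex_day = as.integer(which.max(cp) - 1L),
       degenerate = FALSE)
}

#' Cross-mixing-layer-base vertical iron flux
#'
#' Evaluates the per-process vertical iron fluxes at the mixing-layer base
#' or 100 m, whichever is deeper (the depth scale that excludes KPP mixing
#' by construction), by linear interpolation of each day's band-mean flux
#' profile, and accumulates the annual mean of the total.
#'
#' @param flux_fe Array day x z-face x process of band-mean vertical flux
#'   densities (umol Fe m^-2 s^-1, positive upward), as stored in a
#'   `channel_run`.
#' @param mld Mixing-layer depth per day (m, positive), length = number of
#'   days.
#' @param grid A [build_grid()] object.
#' @param min_depth Evaluation floor (m), default 100.
#' @return List with `fz_fe` (daily total flux at the evaluation depth,
#'   umol Fe m^-2 d^-1), `per_process` (day x process matrix, same units),
#'   `eval_depth` (m per day) and `annual_mean` (umol Fe m^-2 yr^-1, the
#'   mean daily total times 365).
#' @export
cross_mlbase_flux <- function(flux_fe, mld, grid, min_depth = 100) {
  nd <- dim(flux_fe)[1]
  stopifnot(length(mld) == nd)
  depth_eval <- pmax(mld, min_depth)
  if (any(depth_eval > grid$H)) {
    stop("mixing-layer depth exceeds the domain depth", call. = FALSE)
  }
  zf_depth <- -grid$z_faces   # 0 .. H increasing
  nproc <- dim(flux_fe)[3]
  per <- matrix(0, nd, nproc, dimnames = list(NULL, dimnames(flux_fe)[[3]]))
  k <- findInterval(depth_eval, zf_depth, all.inside = TRUE)
  wgt <- (depth_eval - zf_depth[k]) / (zf_depth[k + 1] - zf_depth[k])
  for (ip in seq_len(nproc)) {
    f0 <- flux_fe[cbind(seq_len(nd), k, ip)]
    f1 <- flux_fe[cbind(seq_len(nd), k + 1, ip)]
    per[, ip] <- (f0 + (f1 - f0) * wgt) * 86400
  }
  total <- rowSums(per)
  list(fz_fe = total, per_process = per, eval_depth = depth_eval,
       annual_mean = mean(total) * 365)
}

#' Band medians of the limitation factors and mean iron over the top 100 m
#'
#' Spatial medians of the nutrient and light limitation factors, and the
#' spatial mean of dissolved iron, over cells whose centers are shallower
#' than 100 m within the meridional band.
#'
#' @param gammaN,gammaI Limitation-factor fields (ny x nz).
#' @param Fe Dissolved iron (ny x nz, umol Fe m^-3).
#' @param grid A [build_grid()] object.
#' @param band Meridional range `c(y0, y1)` in m.
#' @param depth Mask depth (m), default 100.
#' @return List with `gammaN_med`, `gammaI_med`, `fe_top100`.
#' @export
limitation_medians <- function(gammaN, gammaI, Fe, grid,
                               band = c(6e5, 1.4e6), depth = 100) {
  iy <- band_index(grid, band)
  iz <- top_index(grid, depth)
  list(gammaN_med = stats::median(gammaN[iy, iz]),
       gammaI_med = stats::median(gammaI[iy, iz]),
       fe_top100 = mean(Fe[iy, iz]))
}

#' Eddy flux from snapshot anomalies relative to the seasonal climatology
#'
#' Computes `w'Fe'` from snapshot series: the climatology is the mean over
#' years at each day-of-year position (and over the zonal axis for 4-D
#' input), primes are snapshot minus climatology, and the result is the
#' mean over all samples (and zonal positions) of the product, one value
#' per (y, z).
#'
#' @param w,fe Arrays of snapshots: 3-D `[time, y, z]` or 4-D
#'   `[time, x, y, z]`, same shape.
#' @param day Day index of each snapshot (strictly increasing; cadence
#'   `cadence` days).
#' @param cadence Snapshot cadence in days (default 15).
#' @param period Length of the climatological year in days.
#' @return List with `wpFep` (y x z matrix), `w_prime`, `fe_prime` (same
#'   shape as input), `n_years`.
#' @export
snapshot_anomaly_flux <- function(w, fe, day, cadence = 15, period = 365) {
  stopifnot(all(dim(w) == dim(fe)))
  nt <- dim(w)[1]
  stopifnot(length(day) == nt)
  per_year <- period %/% cadence
  n_years <- nt %/% per_year
  if (n_years < 2) {
    stop("need at least 2 years of snapshots to define the climatology",
         call. = FALSE)
  }
  phase <- ((day - day[1]) %/% cadence) %% per_year   # position in the year

  clim_of <- function(x) {
    out <- x * 0
    for (ph in unique(phase)) {
      sel <- which(phase == ph)
      if (length(dim(x)) == 3) {
        cl <- apply(x[sel, , , drop = FALSE], c(2, 3), mean)
        for (s in sel) out[s, , ] <- cl
      } else {
        cl <- apply(x[sel, , , , drop = FALSE], c(3, 4), mean)  # + zonal
        for (s in sel) out[s, , , ] <- rep(cl, each = dim(x)[2]) |>
            array(dim(x)[2:4])
      }
    }
    out
  }
  wp <- w - clim_of(w)
  fep <- fe - clim_of(fe)
  prod <- wp * fep
  wpFep <- if (length(dim(w)) == 3) apply(prod, c(2, 3), mean)
           else apply(prod, c(3, 4), mean)
  list(wpFep = wpFep, w_prime = wp, fe_prime = fep, n_years = n_years)
}

#' Bloom series for a run
#'
#' Folds the daily diagnostics of a `channel_run` into a 365-day
#' climatology, appends the daily total cross-mixing-layer-base iron flux,
#' and attaches the bloom onset/apex metadata.
#'
#' @param run A [run_experiment()] result.
#' @return Data frame with columns `t` (day of climatological year, 0-364),
#'   `Cp_int` (g C m^-2), `mld` (m), `gammaN_med`, `gammaI_med`,
#'   `fe_top100` (umol Fe m^-3) and `fz_fe` (umol Fe m^-2 d^-1), with
#'   attributes `onset_day`, `apex_day` and `fz_annual`
#'   (umol Fe m^-2 yr^-1).
#' @export
bloom_series <- function(run) {
  stopifnot(inherits(run, "channel_run"))
  d <- run$daily
  cmf <- cross_mlbase_flux(run$flux_fe, d$mld, run$grid)
  out <- data.frame(
    t = 0:364,
    Cp_int = climatology_series(d$Cp_int),
    mld = climatology_series(d$mld),
    gammaN_med = climatology_series(d$gammaN_med),
    gammaI_med = climatology_series(d$gammaI_med),
    fe_top100 = climatology_series(d$fe_top100),
    fz_fe = climatology_series(cmf$fz_fe)
  )
  bm <- bloom_metrics(out$Cp_int)
  attr(out, "onset_day") <- bm$onset_day
  attr(out, "apex_day") <- bm$apex_day
  attr(out, "fz_annual") <- cmf$annual_mean
  out
}

#' Compare scenarios: biomass against cross-mixing-layer-base iron supply
#'
#' One row per run: scenario label, the annual median of daily `<C_p>` over
#' the final output year, and the annual-mean total vertical iron flux at
#' the mixing-layer base (or 100 m, whichever is deeper).
#'
#' @param runs List of [run_experiment()] results on identical grids.
#' @return Data frame with columns `scenario`, `cp_annual_median`
#'   (g C m^-2), `fz_fe_annual` (umol Fe m^-2 yr^-1).
#' @export
scenario_compare <- function(runs) {
  stopifnot(length(runs) >= 1)
  dims <- vapply(runs, function(r) c(r$grid$ny, r$grid$nz), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("runs are on mismatched grids", call. = FALSE)
  }
  rows <- lapply(runs, function(r) {
    nd <- nrow(r$daily)
    final <- (nd - 364):nd
    cmf <- cross_mlbase_flux(
      r$flux_fe[final, , , drop = FALSE], r$daily$mld[final], r$grid)
    data.frame(scenario = r$config$run$scenario,
               cp_annual_median = stats::median(r$daily$Cp_int[final]),
               fz_fe_annual = cmf$annual_mean)
  })
  do.call(rbind, rows)
}
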
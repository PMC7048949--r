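# Synthetic seasonal forcing for the channel: insolation and mixing-layer
# cycles, mean overturning, northern-boundary relaxation profiles, and the
# initial stratification.  Austral calendar: 365-day year, day 0 = 1 January,
# insolation peaks in summer (Dec-Jan) and the mixing layer is deepest in
# late winter (Jul-Sep).

#' Default forcing parameters
#'
#' Returns the full list of forcing parameters, with any entries in `config`
#' overriding the defaults.  Unknown keys are rejected.
#'
#' @param config Named list of overrides.
#' @return Named list of forcing parameters.
#' @details Key defaults: mixing-layer depth cycles between `h_min = 50` m
#'   (late February) and `h_max = 250` m (late August); surface downwelling
#'   irradiance cycles between 20 and 200 W m^-2 peaking in mid January;
#'   the mean overturning is a prescribed Deacon cell of amplitude
#'   `psi0_m2s` (m^2 s^-1 per unit zonal extent) confined to the upper
#'   1200 m with the analysis band in its upwelling limb; the northern
#'   sponge relaxes iron to a ferrocline profile with 0.05 umol Fe m^-3 at
#'   the surface and roughly 0.4 umol Fe m^-3 at 1000 m; stratification is
#'   a surface-intensified exponential plus a uniform meridional buoyancy
#'   gradient `M2_s2` (optionally augmented by a Gaussian mid-channel
#'   front, `M2_front_s2`), chosen so the mid-channel first-mode
#'   deformation radius is about 14 km.
#' @export
forcing_params <- function(config = list()) {
  defaults <- list(
    h_min = 50,            # m, summer mixing-layer depth
    h_max = 250,           # m, winter mixing-layer depth
    h_phase_day = 240,     # day of year of deepest mixing layer (late Aug)
    I0_mean = 105,         # W m^-2, annual-mean surface PAR
    I0_amp = 95,           # W m^-2, seasonal amplitude
    I0_phase_day = 15,     # day of year of peak insolation (mid Jan)
    psi0_m2s = 1.25,       # m^2 s^-1, mean (Deacon-cell) overturning amplitude
    f0 = -1e-4,            # s^-1, Coriolis parameter (Southern Hemisphere)
    beta = 1e-11,          # m^-1 s^-1
    sponge_width_m = 2e5,  # m, northern relaxation band
    sponge_days = 20,      # d, relaxation timescale at the boundary
    fe_surface = 0.05,     # umol Fe m^-3, surface boundary iron
    fe_deep = 0.401,       # umol Fe m^-3, abyssal asymptote
    z_ferrocline = 150,    # m, ferrocline e-folding depth scale
    N2_surf = 2.2e-5,      # s^-2, surface-intensified stratification
    N2_deep = 8e-7,        # s^-2, abyssal stratification
    N2_escale = 300,       # m, pycnocline e-folding scale
    M2_s2 = 4e-9,          # s^-2, meridional buoyancy gradient (db/dy)
    M2_front_s2 = 0,       # s^-2, optional extra gradient at a mid-channel front
    front_y_m = 1e6,       # m, front position
    front_width_m = 4e5,   # m, Gaussian front half-width
    tau_b_days = 30        # d, restoring timescale of buoyancy to its target
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown forcing parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, config)
}

#' Northern-boundary dissolved-iron profile
#'
#' Saturating-exponential ferrocline: low near-surface iron increasing
#' monotonically with depth toward an abyssal asymptote, emulating the
#' median open-Southern-Ocean profile (about 0.4 umol Fe m^-3 at 1000 m
#' under the defaults).
#'
#' @param z Depths at which to evaluate (m, non-positive, 0 = surface).
#' @param fe_surface Surface concentration (umol Fe m^-3).
#' @param fe_deep Deep asymptote (umol Fe m^-3); must be >= `fe_surface`.
#' @param z_ferrocline e-folding depth scale (m, positive).
#' @return Numeric vector of concentrations, same length as `z`.
#' @examples
#' make_boundary_iron_profile(-1000)  # ~0.4
#' @export
make_boundary_iron_profile <- function(z, fe_surface = 0.05, fe_deep = 0.401,
                                       z_ferrocline = 150) {
  if (fe_surface < 0 || fe_surface > fe_deep) {
    stop("invalid configuration: need 0 <= fe_surface <= fe_deep",
         call. = FALSE)
  }
  if (z_ferrocline <= 0) {
    stop("invalid configuration: z_ferrocline must be positive", call. = FALSE)
  }
  fe_surface + (fe_deep - fe_surface) * (1 - exp(z / z_ferrocline))
}

# internal: 365-day periodic cosine peaking at `phase_day`
seasonal_cosine <- function(t, phase_day) {
  cos(2 * pi * ((t %% 365) - phase_day) / 365)
}

#' Build the seasonal forcing battery for a channel grid
#'
#' Synthesizes every field the integrator needs: 365-day periodic insolation
#' and mixing-layer-depth cycles (anti-phased: deepest mixing layer near the
#' insolation minimum), a prescribed mean overturning streamfunction that
#' vanishes on all solid boundaries, the northern sponge-relaxation mask,
#' the boundary iron profile, the initial buoyancy field, and the seasonal
#' buoyancy restoring target.
#'
#' @param grid A [build_grid()] object.
#' @param config Named list of overrides for [forcing_params()].
#' @return An object of class `seasonal_forcing` with elements `params`,
#'   `insolation(t)` and `mld_target(t)` (functions of time in days returning
#'   a value per y-column), `psi_mean` ((ny+1) x (nz+1) corner field, m^2
#'   s^-1), `f0`, `beta`, `f_y` (Coriolis at y-centers), `sponge_rate`
#'   (s^-1 per y-column), `fe_north` (per z-center), `b_init` (ny x nz) and
#'   `b_target(t)`.
#' @export
make_seasonal_forcing <- function(grid, config = list()) {
  stopifnot(inherits(grid, "channel_grid"))
  p <- forcing_params(config)
  if (p$h_max > grid$H) {
    stop("invalid configuration: h_max exceeds the domain depth H",
         call. = FALSE)
  }
  if (p$h_min <= 0 || p$h_min > p$h_max) {
    stop("invalid configuration: need 0 < h_min <= h_max", call. = FALSE)
  }

  ny <- grid$ny; nz <- grid$nz

  insolation <- function(t) {
    I0 <- p$I0_mean + p$I0_amp * seasonal_cosine(t, p$I0_phase_day)
    rep(max(I0, 0), ny)
  }
  mld_target <- function(t) {
    h <- p$h_min + (p$h_max - p$h_min) *
      0.5 * (1 + seasonal_cosine(t, p$h_phase_day))
    rep(h, ny)
  }

  # Deacon-cell mean overturning on corners: a surface-intensified cell
  # whose maximum sits at y = 2/3 Ly, so the analysis band lies in the
  # upwelling limb (deep water rises equatorward of the cell center, as in
  # the ACC); exactly zero on all solid boundaries.
  yhat <- grid$y_faces / grid$Ly
  s_y <- yhat^2 * (1 - yhat) / (4 / 27)          # peak value 1 at 2/3
  dhat <- pmin(-grid$z_faces / 1200, 1)          # cell confined above 1200 m
  q_z <- sin(pi * dhat)
  psi_mean <- p$psi0_m2s * outer(s_y, q_z)
  psi_mean[c(1, ny + 1), ] <- 0
  psi_mean[, c(1, nz + 1)] <- 0

  # quadratic ramp into the northern sponge band
  ramp <- pmax(0, (grid$y_centers - (grid$Ly - p$sponge_width_m)) /
                    p$sponge_width_m)
  sponge_rate <- ramp^2 / (p$sponge_days * 86400)

  fe_north <- make_boundary_iron_profile(grid$z_centers, p$fe_surface,
                                         p$fe_deep, p$z_ferrocline)

  # b(y, z) = integral of N^2 in z plus the integral of M^2(y) in y, with
  # M^2(y) a uniform background gradient plus a Gaussian mid-channel front
  # (the ACC-like jet); depth-independent M^2 keeps every column stable.
  b_profile <- function(z) {
    p$N2_deep * z + p$N2_surf * p$N2_escale * exp(z / p$N2_escale)
  }
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  b_lateral <- function(y) {
    p$M2_s2 * (y - grid$Ly / 2) +
      p$M2_front_s2 * p$front_width_m * sqrt(pi) / 2 *
        erf((y - p$front_y_m) / p$front_width_m)
  }
  b_init <- outer(b_lateral(grid$y_centers), rep(1, nz)) +
    outer(rep(1, ny), b_profile(grid$z_centers))

  # seasonal target: b_init homogenized over the current mixing layer
  b_target <- function(t) {
    h <- mld_target(t)
    bt <- b_init
    for (iy in seq_len(ny)) {
      ml <- grid$z_centers > -h[iy]
      if (any(ml)) {
        bt[iy, ml] <- b_lateral(grid$y_centers[iy]) + b_profile(-h[iy])
      }
    }
    bt
  }

  structure(list(
    params = p,
    insolation = insolation,
    mld_target = mld_target,
    psi_mean = psi_mean,
    f0 = p$f0, beta = p$beta,
    f_y = p$f0 + p$beta * (grid$y_centers - grid$Ly / 2),
    sponge_rate = sponge_rate,
    fe_north = fe_north,
    b_init = b_init,
    b_target = b_target
  ), class = "seasonal_forcing")
}

#' First-baroclinic Rossby deformation radius at mid-channel
#'
#' WKB first-mode estimate `R = (1 / (pi |f0|)) * integral of N dz` from the
#' buoyancy field's mid-channel column.  Under the default stratification
#' this is about 14 km, so the default 100 km meridional grid spacing does
#' not resolve mesoscale eddies and their transport must be parametrized.
#'
#' @param b Buoyancy field (ny x nz, m s^-2).
#' @param grid A [build_grid()] object.
#' @param f0 Coriolis parameter (s^-1); its magnitude is used.
#' @return Deformation radius in km.
#' @export
diagnose_rossby_radius <- function(b, grid, f0) {
  iy <- which.min(abs(grid$y_centers - grid$Ly / 2))
  bc <- b[iy, ]
  nz <- grid$nz
  # N^2 on interior z-faces from center differences (z decreasing with index)
  dzc <- grid$z_centers[-nz] - grid$z_centers[-1]
  N2 <- (bc[-nz] - bc[-1]) / dzc
  if (any(N2 <= 0)) {
    stop("unstable stratification in column y index ", iy,
         " (y = ", round(grid$y_centers[iy] / 1e3), " km)", call. = FALSE)
  }
  N <- sqrt(N2)
  # trapezoid-like integral; exact (N * H) for uniform N
  int_N <- sum(N * dzc) + N[1] * grid$dz[1] / 2 + N[nz - 1] * grid$dz[nz] / 2
  int_N / (pi * abs(f0)) / 1e3
}
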
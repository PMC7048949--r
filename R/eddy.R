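# Eddy-transport operator battery: isopycnal slopes, Visbeck-scaled GM
# streamfunction with boundary-layer tapering, Redi isopycnal diffusion,
# mixed-layer-instability (MLI) restratification streamfunction, KPP-like
# boundary-layer vertical mixing, and finite-volume tracer advection.
#
# Stagger conventions (see grid.R): scalars ny x nz; y-face fields
# (ny+1) x nz; z-face fields ny x (nz+1); streamfunctions on corners,
# (ny+1) x (nz+1).  Vertical fluxes are positive upward.

#' Eddy-parametrization parameters
#'
#' Constructor with validation for the transport-operator parameters.
#'
#' @param kappa_gm_min,kappa_gm_max Bounds on the Visbeck-scaled GM
#'   coefficient (m^2 s^-1). Defaults 200 and 2500.
#' @param visbeck_alpha Dimensionless Visbeck scaling constant.
#' @param visbeck_length Mixing length of the baroclinic zone (m).
#' @param kappa_redi Redi isopycnal diffusivity (m^2 s^-1): 1000 for the
#'   coarse scenario, 200 for the mesoscale-permitting scenario, 0 disables.
#' @param slope_max Maximum isopycnal slope; slopes are clipped to this.
#' @param n2_min Minimum stratification (s^-2) below which the slope is set
#'   to the clipped limit.
#' @param mli_ce MLI efficiency coefficient (dimensionless).
#' @param mli_lf MLI front-width scale (m); the streamfunction carries a
#'   factor (grid spacing / mli_lf), equal to 1 at the default.
#' @param kappa_bl Boundary-layer vertical diffusivity (m^2 s^-1).
#' @param kappa_bg Background (interior) vertical diffusivity (m^2 s^-1).
#' @param gm_on,mli_on Logical switches for the GM and MLI streamfunctions.
#' @return A list of class `eddy_params`.
#' @export
eddy_params <- function(kappa_gm_min = 200, kappa_gm_max = 2500,
                        visbeck_alpha = 0.015, visbeck_length = 2e5,
                        kappa_redi = 1000, slope_max = 1e-2, n2_min = 1e-8,
                        mli_ce = 0.06, mli_lf = 1e5,
                        kappa_bl = 0.1, kappa_bg = 5e-5,
                        gm_on = TRUE, mli_on = FALSE) {
  p <- list(kappa_gm_min = kappa_gm_min, kappa_gm_max = kappa_gm_max,
            visbeck_alpha = visbeck_alpha, visbeck_length = visbeck_length,
            kappa_redi = kappa_redi, slope_max = slope_max, n2_min = n2_min,
            mli_ce = mli_ce, mli_lf = mli_lf,
            kappa_bl = kappa_bl, kappa_bg = kappa_bg,
            gm_on = isTRUE(gm_on), mli_on = isTRUE(mli_on))
  if (!(kappa_gm_min >= 0 && kappa_gm_min <= kappa_gm_max)) {
    stop("invalid configuration: need 0 <= kappa_gm_min <= kappa_gm_max",
         call. = FALSE)
  }
  if (kappa_redi < 0) stop("kappa_redi must be >= 0", call. = FALSE)
  if (slope_max <= 0) stop("slope_max must be > 0", call. = FALSE)
  if (!(kappa_bl >= kappa_bg && kappa_bg >= 0) ||
      (kappa_bg == 0 && kappa_bl > 0)) {
    stop("invalid configuration: need kappa_bl > kappa_bg > 0 ",
         "(both exactly zero disables vertical mixing)", call. = FALSE)
  }
  class(p) <- "eddy_params"
  p
}

# ---- buoyancy gradients on staggered positions -------------------------

# b_y on y-faces ((ny+1) x nz); boundary faces 0
grad_b_yface <- function(b, grid) {
  ny <- grid$ny
  by <- matrix(0, ny + 1, grid$nz)
  by[2:ny, ] <- (b[-1, , drop = FALSE] - b[-ny, , drop = FALSE]) / grid$dy
  by
}

# b_z on z-faces (ny x (nz+1)); surface/bottom faces 0
grad_b_zface <- function(b, grid) {
  nz <- grid$nz
  bz <- matrix(0, grid$ny, nz + 1)
  bz[, 2:nz] <- sweep(b[, -nz, drop = FALSE] - b[, -1, drop = FALSE], 2,
                      grid$dz_faces[2:nz], "/")
  bz
}

# clip rule: S = -by/bz bounded by slope_max; weakly stratified points get
# the clipped limit with the sign of -by
clip_slope <- function(by, bz, slope_max, n2_min) {
  S <- ifelse(bz < n2_min, sign(-by) * slope_max, -by / pmax(bz, n2_min))
  pmin(pmax(S, -slope_max), slope_max)
}

# slopes interpolated to y-faces, z-faces and corners
slope_faces <- function(b, grid, slope_max = 1e-2, n2_min = 1e-8) {
  ny <- grid$ny; nz <- grid$nz
  by_f <- grad_b_yface(b, grid)        # (ny+1) x nz
  bz_f <- grad_b_zface(b, grid)        # ny x (nz+1)

  # bz averaged to y-faces: mean of the 4 surrounding z-face values
  bz_c <- 0.5 * (bz_f[, -1, drop = FALSE] + bz_f[, -(nz + 1), drop = FALSE])
  bz_yf <- matrix(0, ny + 1, nz)
  bz_yf[2:ny, ] <- 0.5 * (bz_c[-1, , drop = FALSE] + bz_c[-ny, , drop = FALSE])
  bz_yf[1, ] <- bz_c[1, ]; bz_yf[ny + 1, ] <- bz_c[ny, ]

  # by averaged to z-faces
  by_c <- 0.5 * (by_f[-1, , drop = FALSE] + by_f[-(ny + 1), , drop = FALSE])
  by_zf <- matrix(0, ny, nz + 1)
  by_zf[, 2:nz] <- 0.5 * (by_c[, -1, drop = FALSE] + by_c[, -nz, drop = FALSE])
  by_zf[, 1] <- by_c[, 1]; by_zf[, nz + 1] <- by_c[, nz]

  # corner values
  by_corner <- matrix(0, ny + 1, nz + 1)
  by_corner[, 2:nz] <- 0.5 * (by_f[, -1, drop = FALSE] +
                                by_f[, -nz, drop = FALSE])
  by_corner[, 1] <- by_f[, 1]; by_corner[, nz + 1] <- by_f[, nz]
  bz_corner <- matrix(0, ny + 1, nz + 1)
  bz_corner[2:ny, ] <- 0.5 * (bz_f[-1, , drop = FALSE] +
                                bz_f[-ny, , drop = FALSE])
  bz_corner[1, ] <- bz_f[1, ]; bz_corner[ny + 1, ] <- bz_f[ny, ]

  list(S_yf = clip_slope(by_f, bz_yf, slope_max, n2_min),
       S_zf = clip_slope(by_zf, bz_f, slope_max, n2_min),
       S_corner = clip_slope(by_corner, bz_corner, slope_max, n2_min))
}

#' Isopycnal slope field
#'
#' `S = -(db/dy) / (db/dz)`, clipped to `|S| <= slope_max`; where the
#' stratification `db/dz` falls below `n2_min` the slope is set to the
#' clipped limit with the sign of `-db/dy`.
#'
#' @param b Buoyancy (ny x nz, m s^-2).
#' @param grid A [build_grid()] object.
#' @param slope_max Clipping bound (dimensionless).
#' @param n2_min Minimum stratification (s^-2).
#' @param where `"center"` (default), `"yface"`, `"zface"` or `"corner"`.
#' @return Slope field at the requested stagger.
#' @export
isopycnal_slope <- function(b, grid, slope_max = 1e-2, n2_min = 1e-8,
                            where = c("center", "yface", "zface", "corner")) {
  where <- match.arg(where)
  sf <- slope_faces(b, grid, slope_max, n2_min)
  if (where == "yface") return(sf$S_yf)
  if (where == "zface") return(sf$S_zf)
  if (where == "corner") return(sf$S_corner)
  ny <- grid$ny
  # centers: average adjacent y-face values (interior faces only at walls)
  by_f <- grad_b_yface(b, grid)
  by_f[1, ] <- by_f[2, ]; by_f[ny + 1, ] <- by_f[ny, ]
  by_c <- 0.5 * (by_f[-1, , drop = FALSE] + by_f[-(ny + 1), , drop = FALSE])
  bz_f <- grad_b_zface(b, grid)
  nz <- grid$nz
  bz_f[, 1] <- bz_f[, 2]; bz_f[, nz + 1] <- bz_f[, nz]
  bz_c <- 0.5 * (bz_f[, -1, drop = FALSE] + bz_f[, -(nz + 1), drop = FALSE])
  clip_slope(by_c, bz_c, slope_max, n2_min)
}

#' Visbeck-scaled GM coefficient
#'
#' Scales the GM thickness diffusivity with the inverse square root of the
#' vertical-mean Richardson number of each column,
#' `kappa = alpha * |f| / sqrt(Ri) * L^2`, clipped to
#' `[kappa_gm_min, kappa_gm_max]` (200--2500 m^2 s^-1 by default).  `Ri` is
#' computed from thickness-weighted vertical means of `N^2` and of the
#' squared thermal-wind shear `(db/dy / f)^2`.
#'
#' @param b Buoyancy (ny x nz).
#' @param grid A [build_grid()] object.
#' @param params An [eddy_params()] object.
#' @param f Coriolis parameter: scalar or one value per y-column (s^-1).
#' @return kappa_GM per y-column (length ny, m^2 s^-1).  Columns with zero
#'   shear return `kappa_gm_min` (quiescent limit).
#' @export
visbeck_kappa <- function(b, grid, params, f) {
  ny <- grid$ny; nz <- grid$nz
  f <- rep_len(abs(f), ny)
  bz <- grad_b_zface(b, grid)
  bz[, 1] <- bz[, 2]; bz[, nz + 1] <- bz[, nz]
  N2c <- pmax(0.5 * (bz[, -1, drop = FALSE] + bz[, -(nz + 1), drop = FALSE]),
              params$n2_min)
  by <- grad_b_yface(b, grid)
  by[1, ] <- by[2, ]; by[ny + 1, ] <- by[ny, ]
  by_c <- 0.5 * (by[-1, , drop = FALSE] + by[-(ny + 1), , drop = FALSE])
  w <- grid$dz / sum(grid$dz)
  N2_vm <- as.numeric(N2c %*% w)
  by2_vm <- as.numeric(by_c^2 %*% w)
  # kappa = alpha * |f| / sqrt(Ri) * L^2 with Ri = N2_vm * f^2 / by2_vm
  Ri <- ifelse(by2_vm > 0, N2_vm * f^2 / by2_vm, Inf)
  kap <- ifelse(is.finite(Ri),
                params$visbeck_alpha * f / sqrt(Ri) * params$visbeck_length^2,
                params$kappa_gm_min)
  pmin(pmax(kap, params$kappa_gm_min), params$kappa_gm_max)
}

# interpolate a per-y-center vector to y-faces (endpoints copied)
to_yface <- function(x, ny) c(x[1], 0.5 * (x[-1] + x[-ny]), x[ny])

#' GM eddy-induced streamfunction with boundary-layer tapering
#'
#' In the adiabatic interior the streamfunction is `psi = kappa_GM * S`; in
#' the surface boundary layer it transitions linearly in z from its value at
#' the boundary-layer base to zero at the surface (Ferrari-style diabatic
#' matching), and it vanishes on the bottom and lateral walls.
#'
#' @param S_corner Clipped isopycnal slope on cell corners
#'   ((ny+1) x (nz+1)), e.g. `isopycnal_slope(b, grid, where = "corner")`.
#' @param kappa_gm GM coefficient: scalar or per y-column (m^2 s^-1).
#' @param bl_depth Boundary-layer depth per y-column (m, positive).
#' @param grid A [build_grid()] object.
#' @param bl_bottom Bottom boundary-layer thickness (m) over which the
#'   streamfunction ramps linearly to zero at the sea floor.
#' @return Streamfunction on corners ((ny+1) x (nz+1), m^2 s^-1).
#' @export
gm_streamfunction <- function(S_corner, kappa_gm, bl_depth, grid,
                              bl_bottom = 300) {
  ny <- grid$ny; nz <- grid$nz
  kap_f <- to_yface(rep_len(kappa_gm, ny), ny)
  h_f <- to_yface(rep_len(bl_depth, ny), ny)
  psi <- S_corner * kap_f   # recycles kap_f down columns
  depth <- -grid$z_faces    # 0 .. H, increasing

  # psi at the boundary-layer base by linear interpolation in depth
  kbelow <- findInterval(h_f, depth, all.inside = TRUE)  # depth[k] <= h
  i <- seq_len(ny + 1)
  d0 <- depth[kbelow]; d1 <- depth[kbelow + 1]
  p0 <- psi[cbind(i, kbelow)]; p1 <- psi[cbind(i, kbelow + 1)]
  psi_base <- p0 + (p1 - p0) * (h_f - d0) / (d1 - d0)

  # linear taper psi(z) = psi_base * (-z)/h within the boundary layer
  inside <- outer(rep(1, ny + 1), depth) < h_f  # recycle h_f over rows
  ramp <- outer(1 / h_f, depth)
  psi[inside] <- (psi_base * ramp)[inside]

  # smooth approach to the flat bottom: linear ramp over bl_bottom
  if (bl_bottom > 0) {
    ramp_b <- pmin(1, (grid$z_faces + grid$H) / bl_bottom)
    psi <- sweep(psi, 2, ramp_b, "*")
  }
  psi[c(1, ny + 1), ] <- 0
  psi[, nz + 1] <- 0
  psi[, 1] <- 0
  psi
}

#' Eddy-induced (bolus) velocities from a streamfunction
#'
#' `v = -dpsi/dz` on y-faces and `w = dpsi/dy` on z-faces.  The pair is
#' discretely non-divergent in every cell by construction.
#'
#' @param psi Streamfunction on corners ((ny+1) x (nz+1), m^2 s^-1).
#' @param grid A [build_grid()] object.
#' @return List with `v` ((ny+1) x nz, m s^-1) and `w` (ny x (nz+1), m s^-1).
#' @export
bolus_velocity <- function(psi, grid) {
  nz <- grid$nz
  v <- -sweep(psi[, -(nz + 1), drop = FALSE] - psi[, -1, drop = FALSE],
              2, grid$dz, "/")
  w <- (psi[-1, , drop = FALSE] - psi[-(grid$ny + 1), , drop = FALSE]) /
    grid$dy
  list(v = v, w = w)
}

# discrete divergence of face fluxes -> cell tendency (per unit volume).
# Fy: flux density through y-faces ((ny+1) x nz, C m s^-1), positive north;
# Fz: flux density through z-faces (ny x (nz+1)), positive UP.
flux_divergence <- function(Fy, Fz, grid) {
  ny <- grid$ny; nz <- grid$nz
  out_y <- sweep(Fy[-1, , drop = FALSE] - Fy[-(ny + 1), , drop = FALSE],
                 2, grid$dz, "*")
  out_z <- (Fz[, -(nz + 1), drop = FALSE] - Fz[, -1, drop = FALSE]) * grid$dy
  -(out_y + out_z) / grid$cell_volume
}

#' Redi isopycnal diffusive fluxes
#'
#' Small-slope tensor form of along-isopycnal tracer diffusion:
#' `F_y = -kappa (dC/dy + S dC/dz)` and `F_z = -kappa (S dC/dy + S^2 dC/dz)`
#' with the clipped isopycnal slope `S`.  Fluxes vanish on all boundaries.
#' When `bl_depth` is supplied the slope entering the tensor is tapered
#' linearly to zero across the boundary layer (diabatic-layer treatment),
#' so the flux rotates toward horizontal diffusion near the surface.
#'
#' @param C Tracer field (ny x nz).
#' @param b Buoyancy field (ny x nz) from which slopes are computed.
#' @param kappa_redi Isopycnal diffusivity (m^2 s^-1, >= 0).
#' @param grid A [build_grid()] object.
#' @param slope_max,n2_min Slope clipping parameters (see
#'   [isopycnal_slope()]).
#' @param bl_depth Optional boundary-layer depth per y-column (m); `NULL`
#'   (default) applies no near-surface taper.
#' @return List with `F_y` ((ny+1) x nz), `F_z` (ny x (nz+1)), both flux
#'   densities (tracer units x m s^-1, `F_z` positive upward), and
#'   `tendency` (ny x nz) equal to minus the discrete flux divergence.
#' @export
redi_flux <- function(C, b, kappa_redi, grid, slope_max = 1e-2,
                      n2_min = 1e-8, bl_depth = NULL) {
  ny <- grid$ny; nz <- grid$nz
  sf <- slope_faces(b, grid, slope_max, n2_min)
  S_yf <- sf$S_yf; S_zf <- sf$S_zf
  if (!is.null(bl_depth)) {
    h_f <- to_yface(rep_len(bl_depth, ny), ny)
    taper_yf <- pmin(outer(1 / h_f, -grid$z_centers), 1)
    S_yf <- S_yf * taper_yf
    h_c <- rep_len(bl_depth, ny)
    taper_zf <- pmin(outer(1 / h_c, -grid$z_faces), 1)
    S_zf <- S_zf * taper_zf
  }

  Cy <- matrix(0, ny + 1, nz)
  Cy[2:ny, ] <- (C[-1, , drop = FALSE] - C[-ny, , drop = FALSE]) / grid$dy
  Cz <- matrix(0, ny, nz + 1)
  Cz[, 2:nz] <- sweep(C[, -nz, drop = FALSE] - C[, -1, drop = FALSE], 2,
                      grid$dz_faces[2:nz], "/")

  # Cz averaged to y-faces; Cy averaged to z-faces
  Cz_c <- 0.5 * (Cz[, -1, drop = FALSE] + Cz[, -(nz + 1), drop = FALSE])
  Cz_yf <- matrix(0, ny + 1, nz)
  Cz_yf[2:ny, ] <- 0.5 * (Cz_c[-1, , drop = FALSE] + Cz_c[-ny, , drop = FALSE])
  Cy_c <- 0.5 * (Cy[-1, , drop = FALSE] + Cy[-(ny + 1), , drop = FALSE])
  Cy_zf <- matrix(0, ny, nz + 1)
  Cy_zf[, 2:nz] <- 0.5 * (Cy_c[, -1, drop = FALSE] + Cy_c[, -nz, drop = FALSE])

  Fy <- -kappa_redi * (Cy + S_yf * Cz_yf)
  Fz <- -kappa_redi * (S_zf * Cy_zf + S_zf^2 * Cz)
  Fy[c(1, ny + 1), ] <- 0
  Fz[, c(1, nz + 1)] <- 0
  list(F_y = Fy, F_z = Fz, tendency = flux_divergence(Fy, Fz, grid))
}

#' Mixed-layer-instability restratification streamfunction
#'
#' Fox-Kemper-type overturning confined to the mixing layer:
#' `psi = -ce * (dy/lf) * h^2 * (db_ml/dy) / |f| * mu(z/h)` with the
#' canonical vertical structure
#' `mu(s) = (1 - (2s+1)^2) (1 + (5/21)(2s+1)^2)` (clipped at 0), which
#' vanishes at the surface and at `z = -h`, so the associated vertical flux
#' at the mixing-layer base is exactly zero.  `db_ml/dy` is the gradient of
#' the mixing-layer-mean buoyancy; the sign restratifies the front under the
#' `v = -dpsi/dz`, `w = dpsi/dy` convention (same sense as GM).
#'
#' @param b Buoyancy field (ny x nz).
#' @param h Mixing-layer depth per y-column (m, positive).
#' @param f Coriolis parameter, scalar or per column (s^-1, nonzero).
#' @param params An [eddy_params()] object (`mli_ce`, `mli_lf`).
#' @param grid A [build_grid()] object.
#' @return Streamfunction on corners ((ny+1) x (nz+1), m^2 s^-1); zero for
#'   `z <= -h` and on all boundaries.
#' @export
mli_streamfunction <- function(b, h, f, params, grid) {
  ny <- grid$ny; nz <- grid$nz
  f <- rep_len(f, ny)
  if (any(f == 0)) {
    stop("invalid configuration: f = 0 (channel is off-equator)",
         call. = FALSE)
  }
  h <- rep_len(h, ny)
  if (any(h <= 0)) stop("mixing-layer depth must be positive", call. = FALSE)

  # mixing-layer-mean buoyancy per column (thickness-weighted)
  b_ml <- numeric(ny)
  for (iy in seq_len(ny)) {
    ml <- which(grid$z_centers > -h[iy])
    if (!length(ml)) ml <- 1L
    b_ml[iy] <- sum(b[iy, ml] * grid$dz[ml]) / sum(grid$dz[ml])
  }
  gby <- c(0, diff(b_ml) / grid$dy, 0)          # on y-faces, walls zero
  h_f <- to_yface(h, ny)
  f_f <- to_yface(abs(f), ny)

  sig <- outer(1 / h_f, grid$z_faces)           # z/h on corners, in [-H/h, 0]
  u <- 2 * sig + 1
  mu <- pmax((1 - u^2) * (1 + (5 / 21) * u^2), 0)
  mu[sig < -1] <- 0

  amp <- -params$mli_ce * (grid$dy / params$mli_lf) * h_f^2 * gby / f_f
  psi <- amp * mu                                # recycles amp down columns
  psi[c(1, ny + 1), ] <- 0
  psi[, nz + 1] <- 0
  psi
}

#' KPP-like vertical diffusivity profile
#'
#' `kappa_v = kappa_bg + kappa_bl * G(sigma)` with `sigma = -z/h` and the
#' cubic shape `G = (27/4) sigma (1 - sigma)^2` inside the boundary layer
#' (`sigma < 1`), and `kappa_v = kappa_bg` below; `G` vanishes at the base
#' so the profile is continuous there and the boundary-layer contribution
#' to any diffusive flux is exactly zero at and below `z = -h`.
#'
#' @param h Mixing-layer depth per y-column (m, non-negative; `h = 0` gives
#'   background everywhere).
#' @param grid A [build_grid()] object.
#' @param params An [eddy_params()] object (`kappa_bl`, `kappa_bg`).
#' @return Diffusivity on z-faces (ny x (nz+1), m^2 s^-1).
#' @export
kpp_mixing_profile <- function(h, grid, params) {
  h <- rep_len(h, grid$ny)
  # 1/pmax(h, tiny) avoids Inf * 0 = NaN at the surface face when h = 0
  sig <- outer(1 / pmax(h, 1e-300), -grid$z_faces)
  G <- ifelse(sig < 1, (27 / 4) * sig * (1 - sig)^2, 0)
  params$kappa_bg + params$kappa_bl * G
}

# ---- finite-volume advection ------------------------------------------

vanleer_limiter <- function(a, b) {
  ifelse(a * b > 0, 2 * a * b / (a + b), 0)
}

# 1-D MUSCL fluxes along the ROW dimension of C (n x m), u on interior
# faces ((n-1) x m) positive toward increasing row index, dx row widths.
# Returns interior-face fluxes ((n-1) x m), tracer units x m s^-1.
muscl_flux_1d <- function(C, u, dx, dt, scheme = "muscl") {
  n <- nrow(C)
  if (scheme == "muscl" && n >= 3) {
    xc_diff_lo <- 0.5 * (dx[-n] + dx[-1])             # center spacings
    a <- sweep(C[-1, , drop = FALSE] - C[-n, , drop = FALSE], 1,
               xc_diff_lo, "/")                       # (n-1) x m slopes
    sigma <- matrix(0, n, ncol(C))
    sigma[2:(n - 1), ] <- vanleer_limiter(a[-(n - 1), , drop = FALSE],
                                          a[-1, , drop = FALSE])
  } else {
    sigma <- matrix(0, n, ncol(C))
  }
  up <- u >= 0
  don <- ifelse(up, row(u), row(u) + 1L)              # donor row per face
  ij <- cbind(as.vector(don), as.vector(col(u)))
  Cd <- matrix(C[ij], nrow(u), ncol(u))
  sd <- matrix(sigma[ij], nrow(u), ncol(u))
  dxd <- dx[don]; dim(dxd) <- dim(u)
  nu <- abs(u) * dt / dxd
  Cf <- Cd + ifelse(up, 1, -1) * 0.5 * dxd * (1 - nu) * sd
  u * Cf
}

#' Finite-volume tracer advection by a non-divergent velocity field
#'
#' Flux-form update with a van Leer (MUSCL) limited reconstruction: second
#' order on smooth fields, monotonicity-preserving (no new extrema), exactly
#' conservative.  Walls are closed; velocities on boundary faces are assumed
#' zero.
#'
#' @param C Tracer (ny x nz).
#' @param vel List with `v` ((ny+1) x nz) and `w` (ny x (nz+1), positive
#'   upward), e.g. from [bolus_velocity()].
#' @param grid A [build_grid()] object.
#' @param dt Time step (s).
#' @param scheme `"muscl"` (default) or `"upwind"` (first-order, linear in
#'   `C`, used by the operator-assembly cross-checks).
#' @param check_cfl Error if the CFL number exceeds 1.
#' @return List with `C_new`, face fluxes `F_y`, `F_z` (flux densities,
#'   `F_z` positive upward) and `tendency = (C_new - C)/dt`.
#' @export
advect_tracer <- function(C, vel, grid, dt,
                          scheme = c("muscl", "upwind"), check_cfl = TRUE) {
  scheme <- match.arg(scheme)
  ny <- grid$ny; nz <- grid$nz
  v <- vel$v; w <- vel$w
  if (all(v == 0) && all(w == 0)) {
    return(list(C_new = C, F_y = matrix(0, ny + 1, nz),
                F_z = matrix(0, ny, nz + 1),
                tendency = matrix(0, ny, nz)))
  }
  if (check_cfl) {
    cfl_y <- abs(v) * dt / grid$dy
    cfl_z <- sweep(abs(w), 2, dt / grid$dz_faces, "*")
    if (max(cfl_y) > 1 || max(cfl_z) > 1) {
      if (max(cfl_y) >= max(cfl_z)) {
        iw <- which(cfl_y == max(cfl_y), arr.ind = TRUE)[1, ]
        stop(sprintf(
          "CFL violation: max CFL %.3f at y-face %d, z level %d",
          max(cfl_y), iw[1], iw[2]), call. = FALSE)
      } else {
        iw <- which(cfl_z == max(cfl_z), arr.ind = TRUE)[1, ]
        stop(sprintf(
          "CFL violation: max CFL %.3f at column %d, z-face %d",
          max(cfl_z), iw[1], iw[2]), call. = FALSE)
      }
    }
  }

  Fy <- matrix(0, ny + 1, nz)
  Fy[2:ny, ] <- muscl_flux_1d(C, v[2:ny, , drop = FALSE], rep(grid$dy, ny),
                              dt, scheme)
  # z: row dimension = depth index (increasing downward); w positive upward
  # means negative index velocity
  Ct <- t(C)
  uz <- -t(w[, 2:nz, drop = FALSE])
  Fz_idx <- muscl_flux_1d(Ct, uz, grid$dz, dt, scheme)
  Fz <- matrix(0, ny, nz + 1)
  Fz[, 2:nz] <- -t(Fz_idx)        # back to positive-upward convention

  # donor-cell outflow limiting: guards positivity of near-empty cells
  # against the (small) multidimensional overdraw of the unsplit update
  lim <- limit_fluxes(Fy, Fz, C, grid, dt)
  Fy <- lim$F_y; Fz <- lim$F_z

  tend <- flux_divergence(Fy, Fz, grid)
  list(C_new = C + dt * tend, F_y = Fy, F_z = Fz, tendency = tend)
}

# ---- implicit vertical diffusion --------------------------------------

# Backward-Euler vertical diffusion, tridiagonal solve vectorized across
# columns.  kappa_zf on z-faces (ny x (nz+1)); no flux through surface or
# bottom.  Returns C_new and the upward flux implied by C_new, so that
# (C_new - C)/dt equals minus the discrete flux divergence exactly.
diffuse_implicit <- function(C, kappa_zf, grid, dt) {
  ny <- grid$ny; nz <- grid$nz
  dz <- grid$dz; dzf <- grid$dz_faces
  # coupling coefficient across interior face k: kappa/dzf
  g <- kappa_zf
  g[, c(1, nz + 1)] <- 0
  gf <- sweep(g, 2, dzf, "/")            # ny x (nz+1)

  # tridiagonal: -A C_{k-1} + B C_k - D C_{k+1} = C_old
  A <- sweep(gf[, 1:nz, drop = FALSE], 2, dt / dz, "*")       # upper neighbor
  D <- sweep(gf[, 2:(nz + 1), drop = FALSE], 2, dt / dz, "*") # lower neighbor
  B <- 1 + A + D

  # Thomas algorithm, sweep over z with vectors across y
  cp <- matrix(0, ny, nz); dp <- matrix(0, ny, nz)
  cp[, 1] <- -D[, 1] / B[, 1]
  dp[, 1] <- C[, 1] / B[, 1]
  for (k in 2:nz) {
    m <- B[, k] + A[, k] * cp[, k - 1]
    cp[, k] <- -D[, k] / m
    dp[, k] <- (C[, k] + A[, k] * dp[, k - 1]) / m
  }
  Cn <- matrix(0, ny, nz)
  Cn[, nz] <- dp[, nz]
  for (k in (nz - 1):1) {
    Cn[, k] <- dp[, k] - cp[, k] * Cn[, k + 1]
  }

  Fz <- matrix(0, ny, nz + 1)
  Fz[, 2:nz] <- -g[, 2:nz, drop = FALSE] *
    sweep(Cn[, -nz, drop = FALSE] - Cn[, -1, drop = FALSE], 2,
          dzf[2:nz], "/")
  list(C_new = Cn, F_z = Fz)
}
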
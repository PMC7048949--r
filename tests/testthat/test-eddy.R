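test_that("isopycnal slope: flat, linear and clipped regimes", {
  g <- tiny_grid(8, 10)
  # flat isopycnals: b depends on z only
  b_flat <- outer(rep(1, 8), 4e-6 * g$z_centers)
  expect_true(all(isopycnal_slope(b_flat, g) == 0))
  # linear front: S = -M2/N2 everywhere
  N2 <- 4e-6; M2 <- 2e-9
  S <- isopycnal_slope(linear_b(g, N2, M2), g)
  expect_equal(unname(as.vector(S)), rep(-M2 / N2, length(S)),
               tolerance = 1e-12)
  # near-vertical isopycnals: clip active at exactly slope_max
  S_steep <- isopycnal_slope(linear_b(g, 1e-9, 1e-5), g, slope_max = 1e-2)
  expect_true(all(S_steep == -1e-2))
})

test_that("Visbeck kappa clips at the stated bounds and matches a
           column-loop recomputation", {
  g <- tiny_grid(8, 10)
  p <- eddy_params()
  # flat isopycnals: infinite Ri -> lower clip
  b_flat <- outer(rep(1, 8), 4e-6 * g$z_centers)
  expect_equal(visbeck_kappa(b_flat, g, p, 1e-4), rep(200, 8))
  # very steep front: tiny Ri -> upper clip
  expect_equal(visbeck_kappa(linear_b(g, 1e-7, 5e-8), g, p, 1e-4),
               rep(2500, 8))
  # mid-range: independent column-wise loop over the definition
  b <- linear_b(g, 4e-6, 2e-9) +
    outer(sin(g$y_centers / 3e5), 1e-7 * g$z_centers / 100)
  kap <- visbeck_kappa(b, g, p, 1e-4)
  for (iy in c(2, 4, 7)) {
    # N^2 on interior faces, one-sided copies at edges, then interior mean
    bc <- b[iy, ]
    dzc <- g$z_centers[-g$nz] - g$z_centers[-1]
    N2f <- (bc[-g$nz] - bc[-1]) / dzc
    N2f <- c(N2f[1], N2f, N2f[g$nz - 1])
    N2c <- pmax(0.5 * (N2f[-1] + N2f[-(g$nz + 1)]), p$n2_min)
    by <- numeric(g$nz)
    for (k in seq_len(g$nz)) {
      e <- (b[, k][-1] - b[, k][-g$ny]) / g$dy
      e <- c(e[1], e, e[g$ny - 1])
      by[k] <- 0.5 * (e[iy] + e[iy + 1])
    }
    w <- g$dz / sum(g$dz)
    Ri <- sum(N2c * w) * (1e-4)^2 / sum(by^2 * w)
    kap_oracle <- min(max(p$visbeck_alpha * 1e-4 / sqrt(Ri) *
                            p$visbeck_length^2, 200), 2500)
    expect_equal(kap[iy], kap_oracle, tolerance = 1e-12)
  }
})

test_that("GM streamfunction: interior kappa*S, linear surface taper,
           vanishing on boundaries", {
  g <- build_grid(6, 30, H = 3000, stretching = "uniform")  # dz = 100 m
  S <- matrix(-2e-3, 7, 31)
  psi <- gm_streamfunction(S, kappa_gm = 1000, bl_depth = 100, g)
  expect_true(all(psi[c(1, 7), ] == 0))     # lateral walls
  expect_true(all(psi[, 31] == 0))          # bottom
  expect_true(all(psi[, 1] == 0))           # surface
  # interior: kappa * S below the boundary layer
  expect_equal(psi[3, 5], 1000 * -2e-3)
  # z-face 2 is exactly z = -100 m = boundary-layer base
  expect_equal(psi[3, 2], 1000 * -2e-3)
  # taper midpoint: half the base value at z = -50 m (refined grid)
  g2 <- build_grid(6, 60, H = 3000, stretching = "uniform")  # dz = 50 m
  psi2 <- gm_streamfunction(matrix(-2e-3, 7, 61), 1000, 100, g2)
  expect_equal(psi2[3, 2], 0.5 * 1000 * -2e-3)
  # zero slope gives zero streamfunction
  expect_true(all(gm_streamfunction(0 * S, 1000, 100, g) == 0))
})

test_that("GM streamfunction is continuous across the boundary-layer base
           under grid refinement", {
  # smooth slope field; measure the jump in psi across the face nearest -h
  jump <- vapply(c(30, 60, 120), function(nzz) {
    g <- build_grid(6, nzz, H = 3000, stretching = "uniform")
    b <- linear_b(g, 4e-6, 2e-9)
    S <- isopycnal_slope(b, g, where = "corner")
    psi <- gm_streamfunction(S, 800, 95, g)
    kf <- which.min(abs(-g$z_faces - 95))
    max(abs(psi[3, kf + 1] - 2 * psi[3, kf] + psi[3, kf - 1]))
  }, numeric(1))
  expect_true(all(diff(jump) < 0))   # second difference shrinks as dz -> 0
})

test_that("bolus velocities are exactly non-divergent and converge to the
           analytic derivatives", {
  g <- tiny_grid(6, 8)
  psi_const <- matrix(3, 7, 9)
  vel <- bolus_velocity(psi_const, g)
  expect_true(all(vel$v == 0) && all(vel$w == 0))

  # random streamfunction: per-cell discrete divergence at round-off
  set.seed(7)
  psi <- matrix(rnorm(7 * 9), 7, 9)
  vel <- bolus_velocity(psi, g)
  Fy <- sweep(vel$v, 2, g$dz, "*")
  Fz <- vel$w * g$dy
  div <- (Fy[-1, ] - Fy[-7, ]) + (Fz[, -9] - Fz[, -1])
  expect_lt(max(abs(div)), 1e-12 * max(abs(Fy)))

  # smooth psi: centered-difference velocities converge at 2nd order
  err <- vapply(c(16, 32, 64), function(n) {
    gg <- build_grid(n, n, Ly = 1e6, H = 1000, stretching = "uniform")
    psi <- outer(sin(pi * gg$y_faces / gg$Ly), sin(pi * gg$z_faces / gg$H))
    vel <- bolus_velocity(psi, gg)
    v_true <- outer(sin(pi * gg$y_faces / gg$Ly),
                    -pi / gg$H * cos(pi * gg$z_centers / gg$H))
    max(abs(vel$v - v_true))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3.5)
  expect_gt(err[2] / err[3], 3.5)
})

test_that("Redi fluxes: degenerate cases and the along-isopycnal bound", {
  g <- tiny_grid(8, 10)
  b <- linear_b(g)
  # constant tracer: no flux
  rf <- redi_flux(matrix(2, 8, 10), b, 1000, g)
  expect_true(all(rf$F_y == 0) && all(rf$F_z == 0))
  # flat isopycnals: purely lateral diffusion, no vertical flux
  b_flat <- outer(rep(1, 8), 4e-6 * g$z_centers)
  set.seed(1)
  C <- outer(seq(1, 2, length.out = 8), seq(2, 1, length.out = 10))
  rf <- redi_flux(C, b_flat, 1000, g)
  expect_true(all(rf$F_z == 0))
  expect_false(all(rf$F_y == 0))

  # small-slope form: |F . grad b| bounded by O(S^2 |grad b| |grad C|)
  N2 <- 4e-6; M2 <- 4e-9; kap <- 1000
  b_lin <- linear_b(g, N2, M2)
  C <- outer(exp(g$y_centers / 1e6), exp(g$z_centers / 800))
  rf <- redi_flux(C, b_lin, kap, g)
  S <- M2 / N2
  # interior y-faces: F dot grad b using the same staggered gradients
  Fy_c <- 0.5 * (rf$F_y[-1, ] + rf$F_y[-9, ])
  Fz_c <- 0.5 * (rf$F_z[, -1] + rf$F_z[, -11])
  resid <- abs(Fy_c * M2 + Fz_c * N2)
  Cy_max <- max(abs(C[-1, ] - C[-8, ])) / g$dy
  Cz_max <- max(abs(C[, -1] - C[, -10])) / min(g$dz)
  bound <- 5 * kap * S^2 * N2 * (Cy_max + Cz_max)
  expect_true(all(resid[2:7, 2:9] <= bound))
})

test_that("Redi tendency matches an independent cell-by-cell assembly", {
  g <- tiny_grid(6, 8)
  set.seed(11)
  b <- linear_b(g) + outer(rnorm(6, 0, 1e-5), exp(g$z_centers / 1500))
  C <- matrix(runif(48, 1, 2), 6, 8)
  kap <- 700
  rf <- redi_flux(C, b, kap, g, slope_max = 5e-3)
  # independent loop assembly of the same discrete operator
  ny <- 6; nz <- 8
  sf <- channelfe:::slope_faces(b, g, 5e-3, 1e-8)
  Fy <- matrix(0, ny + 1, nz); Fz <- matrix(0, ny, nz + 1)
  for (i in 2:ny) for (k in 1:nz) {
    Cy <- (C[i, k] - C[i - 1, k]) / g$dy
    cz <- function(ii, kk) {     # dC/dz on z-face kk of column ii
      if (kk == 1 || kk == nz + 1) return(0)
      (C[ii, kk - 1] - C[ii, kk]) / g$dz_faces[kk]
    }
    Czm <- 0.25 * (cz(i - 1, k) + cz(i - 1, k + 1) + cz(i, k) + cz(i, k + 1))
    Fy[i, k] <- -kap * (Cy + sf$S_yf[i, k] * Czm)
  }
  for (i in 1:ny) for (k in 2:nz) {
    Cz <- (C[i, k - 1] - C[i, k]) / g$dz_faces[k]
    cy <- function(ii, kk) {     # dC/dy on y-face ii at z-center kk
      if (ii == 1 || ii == ny + 1) return(0)
      (C[ii, kk] - C[ii - 1, kk]) / g$dy
    }
    Cym <- 0.25 * (cy(i, k - 1) + cy(i, k) + cy(i + 1, k - 1) + cy(i + 1, k))
    Fz[i, k] <- -kap * (sf$S_zf[i, k] * Cym + sf$S_zf[i, k]^2 * Cz)
  }
  tend <- matrix(0, ny, nz)
  for (i in 1:ny) for (k in 1:nz) {
    tend[i, k] <- -((Fy[i + 1, k] - Fy[i, k]) * g$dz[k] +
                      (Fz[i, k] - Fz[i, k + 1]) * g$dy) /
      g$cell_volume[i, k]
  }
  scale <- max(abs(rf$tendency))
  expect_lt(max(abs(rf$tendency - tend)), 1e-12 * scale)
})

test_that("upwind advective tendency matches an independent loop assembly", {
  g <- tiny_grid(6, 8)
  set.seed(3)
  psi <- matrix(0, 7, 9)
  psi[2:6, 2:8] <- rnorm(35, 0, 2)
  vel <- bolus_velocity(psi, g)
  C <- matrix(runif(48, 0.5, 1.5), 6, 8)
  a <- advect_tracer(C, vel, g, dt = 3600, scheme = "upwind")
  Fy <- matrix(0, 7, 8); Fz <- matrix(0, 6, 9)
  for (i in 2:6) for (k in 1:8) {
    don <- if (vel$v[i, k] >= 0) i - 1 else i
    Fy[i, k] <- vel$v[i, k] * C[don, k]
  }
  for (i in 1:6) for (k in 2:8) {
    don <- if (-vel$w[i, k] >= 0) k - 1 else k   # upward = toward low index
    don <- if (vel$w[i, k] >= 0) k else k - 1
    Fz[i, k] <- vel$w[i, k] * C[i, don]
  }
  tend <- matrix(0, 6, 8)
  for (i in 1:6) for (k in 1:8) {
    tend[i, k] <- -((Fy[i + 1, k] - Fy[i, k]) * g$dz[k] +
                      (Fz[i, k] - Fz[i, k + 1]) * g$dy) /
      g$cell_volume[i, k]
  }
  expect_lt(max(abs(a$tendency - tend)), 1e-12 * max(abs(tend)))
})

test_that("MLI streamfunction: structure, base value and h^2 scaling", {
  g <- build_grid(10, 30, H = 3000, stretching = "uniform")  # dz = 100 m
  p <- eddy_params(mli_on = TRUE)
  # no mixed-layer gradient: identically zero
  b_flat <- outer(rep(1, 10), 4e-6 * g$z_centers)
  expect_true(all(mli_streamfunction(b_flat, 200, -1e-4, p, g) == 0))
  # psi vanishes exactly at z = -h (face 3 is exactly -200 m) and below
  b <- linear_b(g, 4e-6, 3e-9)
  psi <- mli_streamfunction(b, 200, -1e-4, p, g)
  expect_true(all(psi[, 3] == 0))
  expect_true(all(psi[, 3:31] == 0))
  expect_true(all(psi[, 1] == 0))                 # surface
  # mu >= 0 inside, so psi has a single sign inside the layer
  expect_true(all(psi[2:10, 2] * sign(psi[5, 2]) >= 0))
  # with a depth-independent lateral gradient, doubling h quadruples max
  psi2 <- mli_streamfunction(b, 400, -1e-4, p, g)
  expect_equal(max(abs(psi2)), 4 * max(abs(psi)), tolerance = 1e-10)
  expect_error(mli_streamfunction(b, 200, 0, p, g), "f = 0")
})

test_that("KPP profile: shape, continuity and degenerate limits", {
  g <- build_grid(6, 30, H = 3000, stretching = "uniform")
  p <- eddy_params(kappa_bl = 0.1, kappa_bg = 1e-5)
  kap <- kpp_mixing_profile(200, g, p)
  # z-face 3 is exactly the base: background value (continuity)
  expect_equal(kap[1, 3], 1e-5)
  expect_true(all(kap[, 4:31] == 1e-5))           # below the mixing layer
  expect_true(all(kap[, 2] > 1e-5))               # enhanced inside
  # boundary-layer diffusive flux contribution vanishes at the base:
  # flux with full kappa at -h equals the background-only flux
  fe_z <- 2e-4                                    # an iron gradient
  expect_equal(-kap[1, 3] * fe_z, -1e-5 * fe_z)
  # h -> 0: background everywhere
  expect_true(all(kpp_mixing_profile(0, g, p) == 1e-5))
})

test_that("advection: bitwise no-op, conservation, positivity and CFL", {
  g <- tiny_grid(6, 8)
  C <- matrix(runif(48), 6, 8)
  still <- list(v = matrix(0, 7, 8), w = matrix(0, 6, 9))
  expect_identical(advect_tracer(C, still, g, 3600)$C_new, C)

  # closed-domain conservation and no new extrema under a rotating cell
  psi <- outer(sin(pi * g$y_faces / g$Ly), sin(pi * g$z_faces / g$H)) * 5
  vel <- bolus_velocity(psi, g)
  C <- outer(exp(-((g$y_centers - 4e5) / 2e5)^2),
             exp(-((g$z_centers + 1000) / 500)^2))
  tot0 <- sum(C * g$cell_volume)
  Ct <- C
  for (i in 1:50) Ct <- advect_tracer(Ct, vel, g, 7200)$C_new
  expect_lt(abs(sum(Ct * g$cell_volume) - tot0) / tot0, 1e-10)
  expect_gte(min(Ct), 0)
  expect_lte(max(Ct), max(C) + 1e-12)

  expect_error(advect_tracer(C, vel, g, 1e8), "CFL violation")
})

test_that("a Gaussian advected by uniform flow lands within one cell of
           the analytic translation", {
  g <- build_grid(40, 10, Ly = 4e5, H = 1000, stretching = "uniform")
  C <- outer(exp(-((g$y_centers - 1e5) / 3e4)^2), rep(1, 10))
  v <- matrix(0.05, 41, 10); v[c(1, 41), ] <- 0
  vel <- list(v = v, w = matrix(0, 40, 11))
  Ct <- C
  for (i in 1:56) Ct <- advect_tracer(Ct, vel, g, 3600)$C_new
  centroid <- function(x) sum(g$y_centers * x[, 1]) / sum(x[, 1])
  displacement <- centroid(Ct) - centroid(C)
  expect_lt(abs(displacement - 0.05 * 56 * 3600), g$dy)
})

test_that("implicit vertical diffusion conserves mass, preserves
           positivity and closes its flux ledger", {
  g <- build_grid(5, 25)
  C <- outer(runif(5, 0.5, 1), exp(g$z_centers / 300))
  kap <- kpp_mixing_profile(150, g, eddy_params())
  di <- channelfe:::diffuse_implicit(C, kap, g, 43200)
  expect_lt(abs(sum((di$C_new - C) * g$cell_volume)) /
              sum(C * g$cell_volume), 1e-12)
  expect_gte(min(di$C_new), 0)
  tend <- (di$C_new - C) / 43200
  div <- channelfe:::flux_divergence(matrix(0, 6, 25), di$F_z, g)
  expect_lt(max(abs(tend - div)), 1e-10 * max(abs(tend)))
})
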
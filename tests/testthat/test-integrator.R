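off_config <- function(...) {
  run_config(
    grid = list(ny = 5, nz = 10),
    forcing = list(psi0_m2s = 0, sponge_days = Inf, tau_b_days = Inf),
    eddy = list(gm_on = FALSE, mli_on = FALSE, kappa_redi = 0,
                kappa_bl = 0, kappa_bg = 0),
    eco = list(mu_max = 0, g_max = 0, m_p = 0, m_z = 0, r_remin = 0,
               lambda_scav = 0, w_sink = 0, k_chl = 0),
    run = utils::modifyList(list(scenario = "custom", init_noise_sd = 0),
                            list(...)))
}

test_that("with every process disabled a step leaves the state bitwise
           unchanged", {
  cfg <- off_config()
  setup <- channelfe:::model_setup(cfg)
  st <- channelfe:::step_model(setup$state, 0, setup$grid, setup$forcing,
                               cfg$eddy, cfg$eco, cfg$run$dt,
                               setup$vel_mean)
  for (tr in c("b", "Fe", "P", "Z", "D")) {
    expect_identical(st$state[[tr]], setup$state[[tr]])
  }
})

test_that("biology-only stepping matches the scalar tendency oracle cell
           by cell", {
  cfg <- off_config()
  cfg$eco <- eco_params(w_sink = 0)   # biology on, transport still off
  setup <- channelfe:::model_setup(cfg)
  state <- setup$state
  dt <- cfg$run$dt
  st <- channelfe:::step_model(state, 10, setup$grid, setup$forcing,
                               cfg$eddy, cfg$eco, dt, setup$vel_mean)
  # scalar forward-Euler oracle at two probe cells (limiting inactive)
  gI <- light_limitation(setup$forcing$insolation(10), state$P,
                         setup$grid, cfg$eco)
  gN <- nutrient_limitation(state$Fe, cfg$eco)
  for (probe in list(c(2, 1), c(4, 3))) {
    i <- probe[1]; k <- probe[2]
    td <- ecosystem_tendencies(
      list(P = state$P[i, k], Z = state$Z[i, k], D = state$D[i, k],
           Fe = state$Fe[i, k]), gI[i, k], gN[i, k], cfg$eco)
    expect_equal(st$state$P[i, k], state$P[i, k] + td$dP * dt / 86400,
                 tolerance = 1e-12)
    expect_equal(st$state$Fe[i, k], state$Fe[i, k] + td$dFe * dt / 86400,
                 tolerance = 1e-12)
  }
})

test_that("sponge-only relaxation follows the configured e-folding
           timescale", {
  tau_days <- 50
  cfg <- off_config()
  cfg$forcing$sponge_days <- tau_days
  cfg$forcing$sponge_width_m <- 6e5   # cover the coarse northern column
  setup <- channelfe:::model_setup(cfg)
  g <- setup$grid
  state <- setup$state
  state$Fe <- state$Fe + 0.2          # uniform offset from the target
  iy <- g$ny                           # deepest inside the sponge
  r <- setup$forcing$sponge_rate[iy]
  expect_gt(r, 0)
  dt <- cfg$run$dt
  n <- ceiling(5 / (r * dt))           # five e-folding times
  dev0 <- state$Fe[iy, 5] - setup$forcing$fe_north[5]
  for (s in seq_len(n)) {
    state <- channelfe:::step_model(state, 0, g, setup$forcing, cfg$eddy,
                                    cfg$eco, dt, setup$vel_mean)$state
  }
  dev <- state$Fe[iy, 5] - setup$forcing$fe_north[5]
  # exact discrete decay, and effective timescale within 1% of configured
  expect_equal(dev, dev0 * (1 - r * dt)^n, tolerance = 1e-10)
  tau_eff <- -dt / log(1 - r * dt)
  expect_lt(abs(tau_eff - 1 / r) / (1 / r), 0.01)
})

test_that("per-step iron budget closes: total change equals the sum of all
           ledgered process tendencies", {
  cfg <- run_config(run = list(init_noise_sd = 0))
  setup <- channelfe:::model_setup(cfg)
  g <- setup$grid
  state <- setup$state
  t <- 180
  for (s in 1:8) {
    st <- channelfe:::step_model(state, t, g, setup$forcing, cfg$eddy,
                                 cfg$eco, cfg$run$dt, setup$vel_mean)
    led <- st$ledger
    tend_sum <- led$fe_bio + led$fe_sponge
    for (p in channelfe:::FE_PROCS) tend_sum <- tend_sum + led$fe[[p]]$tend
    d_actual <- sum((st$state$Fe - state$Fe) * g$cell_volume)
    d_ledger <- sum(tend_sum * g$cell_volume) * cfg$run$dt
    gross <- sum(abs(tend_sum) * g$cell_volume) * cfg$run$dt
    expect_lt(abs(d_actual - d_ledger), 1e-8 * gross)
    state <- st$state
    t <- t + cfg$run$dt / 86400
  }
})

test_that("every ledgered process tendency equals minus the divergence of
           its flux field", {
  cfg <- run_config(eddy = list(mli_on = TRUE), run = list(
    scenario = "custom", init_noise_sd = 0))
  setup <- channelfe:::model_setup(cfg)
  g <- setup$grid
  st <- channelfe:::step_model(setup$state, 200, g, setup$forcing,
                               cfg$eddy, cfg$eco, cfg$run$dt,
                               setup$vel_mean)
  for (p in channelfe:::FE_PROCS) {
    led <- st$ledger$fe[[p]]
    div <- channelfe:::flux_divergence(led$flux_y, led$flux, g)
    scale <- max(abs(led$tend), 1e-300)
    expect_lt(max(abs(led$tend - div)) / scale, 1e-10)
  }
  # KPP flux vanishes at and below the mixing-layer base
  h <- setup$forcing$mld_target(200)
  below <- outer(rep(1, g$ny), -g$z_faces) >= h + 1e-9
  expect_true(all(st$ledger$fe$kpp$flux[below] == 0))
})

test_that("identical configuration and seed give identical biomass series
           and scenario twins differ only in the Redi coefficient", {
  cfg_a <- test_config("gm_redi", years_spinup = 0, years_output = 1,
                       init_noise_sd = 0.05)
  cfg_b <- test_config("gm_redi", years_spinup = 0, years_output = 1,
                       init_noise_sd = 0.05)
  r1 <- suppressWarnings(run_experiment(cfg_a))
  r2 <- suppressWarnings(run_experiment(cfg_b))
  expect_identical(r1$daily$Cp_int, r2$daily$Cp_int)

  on <- run_config(run = list(scenario = "gm_redi"))
  off <- run_config(run = list(scenario = "redi_off"))
  expect_equal(off$eddy$kappa_redi, 0)
  on$eddy$kappa_redi <- 0
  on$run$scenario <- "redi_off"
  expect_identical(on, off)
})

test_that("a tiny two-year experiment completes with increasing time,
           positive tracers and a stable drift report", {
  cfg <- run_config(grid = list(ny = 6, nz = 12),
                    run = list(years_spinup = 1, years_output = 2,
                               init_noise_sd = 0))
  run <- suppressWarnings(run_experiment(cfg))
  expect_s3_class(run, "channel_run")
  expect_equal(nrow(run$daily), 730)
  expect_true(all(diff(run$daily$day) > 0))
  expect_true(all(run$daily$Cp_int > 0))
  expect_true(all(run$state$Fe >= 0) && all(run$state$P >= 0))
  expect_equal(nrow(run$drift), 1)
  expect_equal(length(run$snapshots$day), 48)
})

test_that("spin-up drift decreases and the equilibrated cycle repeats
           within two percent", {
  run <- get_run("gm_redi")
  dr <- run$drift$drift_p[-1]
  expect_lt(dr[length(dr)], min(dr[1], 0.2))  # tail below early drift
  d <- run$daily$Cp_int
  expect_lt(max(abs(d[1:365] - d[366:730])) / max(d), 0.02)
})
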
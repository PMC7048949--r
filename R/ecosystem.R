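# Reduced iron-phytoplankton-zooplankton-detritus ecosystem with
# multiplicative light and iron limitation, Holling-II grazing, partial
# local remineralization, detrital remineralization, linear above-threshold
# scavenging and a fixed Fe:C quota.
#
# Units: biomass pools in mg C m^-3, dissolved iron in umol Fe m^-3, rates
# per day; the integrator converts to per-second internally.

#' Ecosystem parameters
#'
#' Constructor with validation for the reduced ecosystem.  The iron
#' half-saturation default `K_Fe = 0.065` umol Fe m^-3 places the seasonal
#' surface-iron swing of roughly 0.13 (late winter) to 0.03 (post-bloom)
#' umol Fe m^-3 on the steep part of the Monod uptake curve, so the
#' nutrient limitation factor falls from about 0.67 to about 0.32 over the
#' bloom.
#'
#' @param mu_max Maximum phytoplankton growth rate (d^-1).
#' @param K_Fe Iron half-saturation (umol Fe m^-3, > 0).
#' @param k_w Light attenuation of seawater (m^-1).
#' @param k_chl Self-shading attenuation per unit depth-integrated biomass
#'   (m^-1 per (mg C m^-2)); 0 disables self-shading.
#' @param I_k Light saturation scale (W m^-2).
#' @param g_max Maximum zooplankton grazing rate (d^-1).
#' @param K_P Grazing half-saturation (mg C m^-3).
#' @param assim Zooplankton assimilation efficiency (0-1).
#' @param m_p,m_z Phytoplankton and zooplankton linear mortality (d^-1).
#' @param remin_frac Fraction of non-grazing losses remineralized locally
#'   (the rest enters detritus).
#' @param w_sink Detritus sinking speed (m d^-1).
#' @param r_remin Detritus remineralization rate (d^-1).
#' @param R_FeC Iron:carbon quota (umol Fe per mg C).
#' @param lambda_scav Scavenging rate (d^-1) applied above the ligand
#'   threshold.
#' @param fe_ligand Free-ligand threshold (umol Fe m^-3): no scavenging at
#'   or below this concentration.
#' @param limitation `"product"` (default) multiplies the light and
#'   nutrient factors; `"min"` takes the Liebig minimum.
#' @return A list of class `eco_params`.
#' @export
eco_params <- function(mu_max = 0.9, K_Fe = 0.065, k_w = 0.04, k_chl = 1e-3,
                       I_k = 25, g_max = 1.0, K_P = 25, assim = 0.3,
                       m_p = 0.05, m_z = 0.08, remin_frac = 0.65,
                       w_sink = 12, r_remin = 0.04, R_FeC = 3e-3,
                       lambda_scav = 5e-3, fe_ligand = 0.6,
                       limitation = c("product", "min")) {
  p <- list(mu_max = mu_max, K_Fe = K_Fe, k_w = k_w, k_chl = k_chl,
            I_k = I_k, g_max = g_max, K_P = K_P, assim = assim,
            m_p = m_p, m_z = m_z, remin_frac = remin_frac,
            w_sink = w_sink, r_remin = r_remin, R_FeC = R_FeC,
            lambda_scav = lambda_scav, fe_ligand = fe_ligand,
            limitation = match.arg(limitation))
  rates <- c("mu_max", "k_w", "k_chl", "g_max", "m_p", "m_z", "w_sink",
             "r_remin", "lambda_scav", "R_FeC")
  if (any(unlist(p[rates]) < 0)) {
    stop("invalid configuration: all rates must be >= 0", call. = FALSE)
  }
  if (p$K_Fe <= 0) stop("K_Fe must be > 0", call. = FALSE)
  if (p$remin_frac < 0 || p$remin_frac > 1) {
    stop("remin_frac must lie in [0, 1]", call. = FALSE)
  }
  if (p$assim < 0 || p$assim > 1) stop("assim must lie in [0, 1]",
                                       call. = FALSE)
  class(p) <- "eco_params"
  p
}

#' Light limitation factor
#'
#' Exponentially attenuated irradiance `I(z) = I0 exp(k_w z)` (z negative
#' down), optionally further attenuated by the overlying depth-integrated
#' phytoplankton biomass (self-shading), with saturating response
#' `gamma_I = 1 - exp(-I/I_k)`, bounded in `[0, 1]` and monotone in `I`.
#'
#' @param I0 Surface irradiance (W m^-2): scalar or one value per y-column.
#' @param P Phytoplankton field (ny x nz); only used when `k_chl > 0`.
#' @param grid A [build_grid()] object.
#' @param params An [eco_params()] object.
#' @return gamma_I (ny x nz) in `[0, 1]`.
#' @export
light_limitation <- function(I0, P, grid, params) {
  if (any(I0 < 0)) stop("I0 must be >= 0", call. = FALSE)
  I0 <- rep_len(I0, grid$ny)
  tau <- outer(rep(1, grid$ny), params$k_w * grid$z_centers)  # <= 0
  if (params$k_chl > 0) {
    # biomass integrated from the surface down to each cell top
    Pint <- t(apply(sweep(P, 2, grid$dz, "*"), 1, cumsum))
    Pabove <- cbind(0, Pint[, -grid$nz, drop = FALSE])
    tau <- tau - params$k_chl * Pabove
  }
  Iz <- I0 * exp(tau)   # recycles I0 down columns
  1 - exp(-Iz / params$I_k)
}

#' Iron (nutrient) limitation factor
#'
#' Monod uptake `gamma_N = Fe / (Fe + K_Fe)`, 0 at zero iron, saturating to
#' 1, monotone increasing.
#'
#' @param Fe Dissolved iron (umol Fe m^-3, >= 0; negative input is a
#'   contract violation and errors).
#' @param params An [eco_params()] object.
#' @return gamma_N, same shape as `Fe`, in `[0, 1]`.
#' @export
nutrient_limitation <- function(Fe, params) {
  if (any(Fe < 0)) {
    stop("contract violation: negative iron concentration passed to ",
         "nutrient_limitation (positivity must be enforced upstream)",
         call. = FALSE)
  }
  Fe / (Fe + params$K_Fe)
}

#' Scavenging sink of dissolved iron
#'
#' Linear above-threshold form standing in for ligand chemistry:
#' `sink = lambda_scav * max(Fe - fe_ligand, 0)` (umol Fe m^-3 d^-1).
#'
#' @param Fe Dissolved iron (umol Fe m^-3).
#' @param params An [eco_params()] object.
#' @return Sink rate, same shape as `Fe` (umol Fe m^-3 d^-1, >= 0).
#' @export
scavenge <- function(Fe, params) {
  params$lambda_scav * pmax(Fe - params$fe_ligand, 0)
}

#' Ecosystem tendencies
#'
#' Per-tracer source/sink tendencies (per day) for the reduced ecosystem:
#' primary production `PP = mu_max * gamma * P` (with `gamma` the product,
#' or optionally the minimum, of the light and iron factors), Holling-II
#' grazing `G = g_max * P/(P + K_P) * Z`, linear mortalities, partial local
#' remineralization of losses with the remainder routed to detritus,
#' detrital remineralization, and iron uptake/release locked to carbon
#' conversions by the fixed quota `R_FeC`.  Detritus sinking is handled by
#' the transport step, not here.
#'
#' @param state List with fields `P`, `Z`, `D` (mg C m^-3) and `Fe`
#'   (umol Fe m^-3), all the same shape.
#' @param gammaI,gammaN Limitation factors in `[0, 1]`, same shape.
#' @param params An [eco_params()] object.
#' @return List of tendencies `dP`, `dZ`, `dD` (mg C m^-3 d^-1), `dFe`
#'   (umol Fe m^-3 d^-1) and diagnostic rates `PP`, `grazing`, `remin`,
#'   `scav`, `uptake`.
#' @export
ecosystem_tendencies <- function(state, gammaI, gammaN, params) {
  P <- state$P; Z <- state$Z; D <- state$D; Fe <- state$Fe
  gamma <- if (params$limitation == "product") gammaI * gammaN
           else pmin(gammaI, gammaN)
  PP <- params$mu_max * gamma * P
  G <- params$g_max * P / (P + params$K_P) * Z
  losses <- params$m_p * P + params$m_z * Z + (1 - params$assim) * G
  remin <- params$remin_frac * losses + params$r_remin * D
  scav <- scavenge(Fe, params)

  list(
    dP = PP - G - params$m_p * P,
    dZ = params$assim * G - params$m_z * Z,
    dD = (1 - params$remin_frac) * losses - params$r_remin * D,
    dFe = params$R_FeC * (remin - PP) - scav,
    PP = PP, grazing = G, remin = remin, scav = scav,
    uptake = params$R_FeC * PP
  )
}

# Forward-Euler ecosystem update over dt (seconds) with sink limiting:
# for each pool the total sink is scaled so the pool cannot go negative
# within the step, and the iron uptake is scaled together with PP so the
# fixed-quota link between carbon and iron conversions is preserved.
eco_step <- function(state, gammaI, gammaN, params, dt) {
  dtd <- dt / 86400
  P <- state$P; Z <- state$Z; D <- state$D; Fe <- state$Fe
  gamma <- if (params$limitation == "product") gammaI * gammaN
           else pmin(gammaI, gammaN)
  PP <- params$mu_max * gamma * P
  # limit iron uptake so Fe stays non-negative
  lim_fe <- pmin(1, Fe / pmax(params$R_FeC * PP * dtd, 1e-300))
  PP <- PP * lim_fe
  G <- params$g_max * P / (P + params$K_P) * Z
  # limit P sinks
  sinkP <- (G + params$m_p * P) * dtd
  limP <- pmin(1, (P + PP * dtd) / pmax(sinkP, 1e-300))
  G <- G * limP
  mortP <- params$m_p * P * limP
  mortZ <- params$m_z * Z
  losses <- mortP + mortZ + (1 - params$assim) * G
  reminD <- params$r_remin * D
  remin <- params$remin_frac * losses + reminD
  scav <- scavenge(Fe, params)
  lim_sc <- pmin(1, pmax(Fe - params$fe_ligand, 0) /
                   pmax(scav * dtd, 1e-300))
  scav <- scav * lim_sc

  dP <- PP - G - mortP
  dZ <- params$assim * G - mortZ
  dD <- (1 - params$remin_frac) * losses - reminD
  dFe <- params$R_FeC * (remin - PP) - scav

  list(state = list(P = pmax(P + dP * dtd, 0), Z = pmax(Z + dZ * dtd, 0),
                    D = pmax(D + dD * dtd, 0), Fe = pmax(Fe + dFe * dtd, 0)),
       tend = list(dP = dP / 86400, dZ = dZ / 86400, dD = dD / 86400,
                   dFe = dFe / 86400),   # per second, for the ledger
       rates = list(PP = PP, grazing = G, remin = remin, scav = scav,
                    uptake = params$R_FeC * PP))
}
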
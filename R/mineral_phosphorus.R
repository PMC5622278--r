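#' Release-to-fixation equilibrium fraction
#'
#' The fraction of total mineral P held in the available pool at
#' equilibrium, derived from two Olsen-P vs total-P regressions (mg kg-1
#' domain): `V = (alpha P_Tot + beta) / P_Tot` with the upper-branch
#' coefficients above the branch junction and the lower-branch ones below
#' it, clamped to keep the release:fixation ratio finite and positive.
#'
#' @param p_tot total mineral P, mg per kg soil
#' @param params model parameters
#' @return V in \[0.001, 0.95\]
#' @export
equilibrium_fraction <- function(p_tot, params = landsim_params()) {
  stopifnot(all(p_tot > 0))
  pp <- params$phosphorus
  junction <- (pp$beta_a - pp$beta_b) / (pp$alpha_b - pp$alpha_a)
  v <- ifelse(p_tot > junction,
              (pp$alpha_b * p_tot + pp$beta_b) / p_tot,
              (pp$alpha_a * p_tot + pp$beta_a) / p_tot)
  pmin(pmax(v, pp$v_clamp[1]), pp$v_clamp[2])
}

# conversion between kg P ha-1 and mg P per kg soil for a layer:
# layer soil mass (t ha-1) = delta (mm) * BD (g cm-3) * 10
layer_soil_mass <- function(layer) layer$delta * layer$bulk_density * 10
kgha_to_mgkg <- function(kgha, layer) kgha * 1000 / layer_soil_mass(layer)

#' Daily re-equilibration between available and non-available P
#'
#' Simultaneous first-order exchange: `P_Av->NA = lambda P_Av f_pH` and
#' `P_NA->Av = lambda P_NonAv RRF f_pH` with `RRF = V / (1 - V)`.  Total
#' mineral P is conserved exactly; an available-P excess decays at rate
#' `lambda (1 + RRF) f_pH`.
#'
#' @param layer soil layer (P_Av, P_NonAv, delta, bulk_density, ph)
#' @param params model parameters
#' @return updated layer
#' @export
reequilibrate <- function(layer, params = landsim_params()) {
  pp <- params$phosphorus
  p_tot_kg <- layer$P_Av + layer$P_NonAv
  if (p_tot_kg <= 0) return(layer)
  p_tot_mg <- kgha_to_mgkg(p_tot_kg, layer)
  v <- equilibrium_fraction(p_tot_mg, params)
  rrf <- v / (1 - v)
  fp <- f_ph(layer$ph)
  to_na <- pp$lambda * layer$P_Av * fp
  to_av <- pp$lambda * layer$P_NonAv * rrf * fp
  layer$P_NonAv <- layer$P_NonAv + to_na - to_av
  layer$P_Av <- layer$P_Av - to_na + to_av
  layer
}

#' Apply mineral P fertiliser
#'
#' Eighty percent of the dose enters the available pool, twenty percent the
#' non-available pool.
#'
#' @param layer soil layer
#' @param dose kg P ha-1
#' @param params model parameters
#' @return updated layer
#' @export
fertilise_p <- function(layer, dose, params = landsim_params()) {
  stopifnot(dose >= 0)
  f <- params$phosphorus$fert_split_available
  layer$P_Av <- layer$P_Av + f * dose
  layer$P_NonAv <- layer$P_NonAv + (1 - f) * dose
  layer
}

#' Phosphorus lost in runoff and leaching
#'
#' Runoff carries a share of the mobile P (10 percent of available P) in the
#' top 20 mm, mixing like mineral N; leaching moves the solution P
#' (1 percent of available P) with the drainage water through the layer
#' cascade.
#'
#' @param profile list of soil layers
#' @param w_run runoff, mm
#' @param w_surf surface mixing water, mm
#' @param f_w per-layer downward water fluxes, mm
#' @param params model parameters
#' @return list(profile, p_runoff, p_leached), kg P ha-1
#' @export
runoff_and_leach_p <- function(profile, w_run, w_surf, f_w,
                               params = landsim_params()) {
  stopifnot(w_run >= 0, w_surf >= 0, all(f_w >= 0))
  pp <- params$phosphorus
  mix <- params$water$mix_depth
  layer1 <- profile[[1]]
  p_run <- 0
  if (w_run + w_surf > 0) {
    p_m <- pp$mobile_frac * layer1$P_Av
    p_surf <- (mix / layer1$delta) * p_m
    p_run <- p_surf * w_run / (w_run + w_surf)
    p_run <- min(p_run, layer1$P_Av)
    layer1$P_Av <- layer1$P_Av - p_run
    profile[[1]] <- layer1
  }
  # leaching: solution P moves with water at its concentration in layer water
  inflow <- 0
  nl <- length(profile)
  for (l in seq_len(nl)) {
    profile[[l]]$P_Av <- profile[[l]]$P_Av + inflow
    w <- profile[[l]]$W
    sol <- pp$solution_frac * profile[[l]]$P_Av
    if (w > 0 && f_w[l] > 0) {
      out <- max(0, min(sol, sol / w * f_w[l]))
    } else out <- 0
    profile[[l]]$P_Av <- profile[[l]]$P_Av - out
    inflow <- out
  }
  list(profile = profile, p_runoff = p_run, p_leached = inflow)
}

#' Deliver available P to the crop
#'
#' Uptake met from available P in the rooted layers, limited by demand, the
#' pool, and a cap of 2 kg P ha-1 d-1, drawn pro-rata root fraction.
#'
#' @param profile list of soil layers
#' @param demand kg P ha-1 d-1
#' @param f_rl per-layer root fractions
#' @param params model parameters
#' @return list(profile, delivered)
#' @export
supply_p_uptake <- function(profile, demand, f_rl,
                            params = landsim_params()) {
  stopifnot(demand >= 0)
  cap <- params$phosphorus$uptake_cap
  avail <- vapply(profile, `[[`, 0, "P_Av") * (f_rl > 0)
  want <- min(demand, sum(avail), cap)
  if (want <= 0) return(list(profile = profile, delivered = 0))
  take <- pmin(avail, want * f_rl / sum(f_rl))
  shortfall <- want - sum(take)
  if (shortfall > 1e-12) {
    head <- avail - take
    extra <- pmin(head, shortfall * head / sum(head))
    take <- take + extra
  }
  for (l in seq_along(profile)) profile[[l]]$P_Av <- profile[[l]]$P_Av - take[l]
  list(profile = profile, delivered = sum(take))
}

# draw immobilised P: available first, then non-available (may leave a
# shortfall of zero; decomposition is never halted for P)
draw_immobilised_p <- function(layer, amount) {
  from_av <- min(layer$P_Av, amount)
  layer$P_Av <- layer$P_Av - from_av
  rest <- amount - from_av
  from_na <- min(layer$P_NonAv, rest)
  layer$P_NonAv <- layer$P_NonAv - from_na
  list(layer = layer, drawn = from_av + from_na)
}
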
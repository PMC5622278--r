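#' Atmospheric nitrogen deposition
#'
#' The annual deposition rate declines linearly from 35 kg N yr-1 in 1966 to
#' 20 kg N yr-1 in 2012 (clamped outside that span) and is spread evenly
#' through the year as nitrate.
#'
#' @param date a `Date`
#' @param params model parameters
#' @return kg N ha-1 added to the nitrate pool that day
#' @export
atmospheric_deposition <- function(date, params = landsim_params()) {
  pn <- params$nitrogen
  yr <- as.integer(format(date, "%Y"))
  frac <- (yr - pn$dep_year0) / (pn$dep_year1 - pn$dep_year0)
  frac <- min(max(frac, 0), 1)
  annual <- pn$dep_rate0 + frac * (pn$dep_rate1 - pn$dep_rate0)
  days <- if (is_leap_year(yr)) 366 else 365
  annual / days
}

is_leap_year <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Mineral nitrogen lost in surface runoff
#'
#' Runoff mixes with the top 20 mm of soil.  The surface N is the layer-1
#' mineral N scaled by `20 / delta1`; the runoff carries the fraction
#' `W_Run / (W_Run + W_Surf)` of it, removed from the layer-1 pools pro-rata
#' their NH4:NO3 shares.
#'
#' @param layer1 topsoil layer
#' @param w_run runoff water, mm
#' @param w_surf surface mixing water, mm (saturation minus air-dry over
#'   20 mm)
#' @param params model parameters
#' @return list(n_removed, layer1)
#' @export
runoff_n <- function(layer1, w_run, w_surf, params = landsim_params()) {
  stopifnot(w_run >= 0, w_surf >= 0)
  if (w_run + w_surf == 0) return(list(n_removed = 0, layer1 = layer1))
  mix <- params$water$mix_depth
  pool <- layer1$N_NH4 + layer1$N_NO3
  n_surf <- (mix / layer1$delta) * pool
  n_run <- n_surf * w_run / (w_run + w_surf)
  if (pool > 0) {
    layer1$N_NH4 <- layer1$N_NH4 - n_run * layer1$N_NH4 / pool
    layer1$N_NO3 <- layer1$N_NO3 - n_run * layer1$N_NO3 / pool
  }
  list(n_removed = n_run, layer1 = layer1)
}

#' Convective nitrate leaching down the profile
#'
#' Nitrate moves with drainage water at the layer concentration:
#' the flux out of layer l is `min(N_NO3(l), N_NO3(l)/W(l) * F_W(l))`,
#' applied top-down so that nitrate cascades within the day; the flux out of
#' the bottom layer is the leaching loss.
#'
#' @param profile list of soil layers
#' @param f_w per-layer downward water fluxes, mm (from [drain_cascade()])
#' @return list(profile, leached) with leached in kg N ha-1
#' @export
leach_no3 <- function(profile, f_w) {
  stopifnot(all(f_w >= 0), length(f_w) == length(profile))
  nl <- length(profile)
  inflow <- 0
  leached <- 0
  for (l in seq_len(nl)) {
    profile[[l]]$N_NO3 <- profile[[l]]$N_NO3 + inflow
    w <- profile[[l]]$W
    if (w > 0 && f_w[l] > 0) {
      conc <- profile[[l]]$N_NO3 / w
      out <- max(0, min(profile[[l]]$N_NO3, conc * f_w[l]))
    } else out <- 0
    profile[[l]]$N_NO3 <- profile[[l]]$N_NO3 - out
    inflow <- out
  }
  leached <- inflow
  list(profile = profile, leached = leached)
}

# nitrification temperature response: saturating, 0.5 at 10 deg C, capped 1
nitrif_f_t <- function(temp) {
  pmin(1, pmax(0, 2^((temp - 10) / 10) * 0.5))
}

# nitrification moisture response: linear in plant-available water fraction
nitrif_g_m <- function(layer) {
  avail <- layer$W / layer$delta - layer$theta_wp
  span <- layer$theta_fc - layer$theta_wp
  pmin(1, pmax(0, avail / span))
}

#' Nitrification with N2O by-product
#'
#' N2O is emitted as `k_N2O * N_NH4 * S_pH * (1 - WFPS)`; the nitrate
#' produced is `(N_NH4 - N2O - N_min) * (1 - exp(-k f_T g_M))`, floored at
#' zero.  Both are drawn from the ammonium pool.
#'
#' @param layer soil layer
#' @param f_t temperature response in \[0, 1\]
#' @param g_m moisture response in \[0, 1\]
#' @param params model parameters
#' @return list(layer, no3_produced, n2o)
#' @export
nitrify <- function(layer, f_t, g_m, params = landsim_params()) {
  stopifnot(f_t >= 0, f_t <= 1, g_m >= 0, g_m <= 1)
  pn <- params$nitrogen
  wfps <- layer$W / (layer$theta_sat * layer$delta)
  wfps <- min(max(wfps, 0), 1)
  s_ph <- f_ph(layer$ph)
  n2o <- pn$k_n2o * layer$N_NH4 * s_ph * (1 - wfps)
  n2o <- min(n2o, layer$N_NH4)
  no3 <- max((layer$N_NH4 - n2o - pn$n_min) *
               (1 - exp(-pn$k_nitrif * f_t * g_m)), 0)
  no3 <- min(no3, layer$N_NH4 - n2o)
  layer$N_NH4 <- layer$N_NH4 - n2o - no3
  layer$N_NO3 <- layer$N_NO3 + no3
  list(layer = layer, no3_produced = no3, n2o = n2o)
}

# water-filled-pore-space response for denitrification (natural log, squared
# log-ratio; symmetric about WFPS = 0.5)
denit_f_wfps <- function(wfps, params = landsim_params()) {
  co <- params$nitrogen$wfps_coefs
  wfps <- pmin(pmax(wfps, 0.01), 0.99)
  exp(-co[1] * log(wfps / (1 - wfps))^2 - co[2])
}

#' Denitrification: N2O and N2 emission
#'
#' N2O: `0.000735 * N_NO3 * f(WFPS) * exp(-0.00045 (T - 23.65)^2)`;
#' N2: `0.0052 * N_NO3 * logistic(0.14975 T - 4.0) *
#' logistic(12 (WFPS - 0.62))`.  Applied to the top two layers only; both
#' fluxes are drawn from nitrate and capped at the pool.
#'
#' @param profile list of soil layers
#' @param temp soil temperature, deg C (air temperature proxy)
#' @param params model parameters
#' @return list(profile, n2o, n2) with per-layer flux vectors, kg N ha-1 d-1
#' @export
denitrify <- function(profile, temp, params = landsim_params()) {
  pn <- params$nitrogen
  nl <- length(profile)
  n2o <- numeric(nl)
  n2 <- numeric(nl)
  sigma <- function(x) 1 / (1 + exp(-x))
  for (l in seq_len(min(2, nl))) {
    layer <- profile[[l]]
    wfps <- layer$W / (layer$theta_sat * layer$delta)
    f <- denit_f_wfps(wfps, params)
    e_n2o <- pn$denit_a * layer$N_NO3 * f *
      exp(-pn$denit_t_w * (temp - pn$denit_t_opt)^2)
    lg <- pn$n2_logistic
    e_n2 <- pn$n2_coef * layer$N_NO3 * sigma(lg[1] * temp - lg[2]) *
      sigma(lg[3] * (wfps - lg[4]))
    tot <- e_n2o + e_n2
    if (tot > layer$N_NO3 && tot > 0) {
      sc <- layer$N_NO3 / tot
      e_n2o <- e_n2o * sc
      e_n2 <- e_n2 * sc
    }
    layer$N_NO3 <- layer$N_NO3 - e_n2o - e_n2
    profile[[l]] <- layer
    n2o[l] <- e_n2o
    n2[l] <- e_n2
  }
  list(profile = profile, n2o = n2o, n2 = n2)
}

#' Deliver nitrate to the crop
#'
#' Uptake is met from the nitrate pools of the rooted layers, limited by the
#' demand, the nitrate present, and a cap of 6 kg N ha-1 d-1; drawn
#' pro-rata the root fraction in each layer (excess demand in a depleted
#' layer falls to the others in a second pass).
#'
#' @param profile list of soil layers
#' @param demand crop N demand, kg N ha-1 d-1
#' @param f_rl per-layer root fractions (sums to 1)
#' @param params model parameters
#' @return list(profile, delivered)
#' @export
supply_n_uptake <- function(profile, demand, f_rl,
                            params = landsim_params()) {
  stopifnot(demand >= 0)
  cap <- params$nitrogen$uptake_cap
  avail <- vapply(profile, `[[`, 0, "N_NO3") * (f_rl > 0)
  want <- min(demand, sum(avail), cap)
  if (want <= 0) return(list(profile = profile, delivered = 0))
  take <- pmin(avail, want * f_rl / sum(f_rl))
  shortfall <- want - sum(take)
  if (shortfall > 1e-12) {
    head <- avail - take
    extra <- pmin(head, shortfall * head / sum(head))
    take <- take + extra
  }
  for (l in seq_along(profile)) profile[[l]]$N_NO3 <- profile[[l]]$N_NO3 - take[l]
  list(profile = profile, delivered = sum(take))
}
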
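#' HYPRES pedotransfer retention anchors
#'
#' Evaluates the continuous HYPRES pedotransfer regressions (topsoil and
#' subsoil variants) for the van Genuchten retention parameters and returns
#' the water contents at the five tensions the water model uses: saturation,
#' -5 kPa (`theta_a`), -10 kPa (field capacity), -40 kPa (`theta_d`) and
#' -1500 kPa (wilting point).
#'
#' @param clay,silt clay and silt mass percent (sand is the remainder)
#' @param om organic matter percent (TOC x 1.724 if converting from carbon)
#' @param bd bulk density, g cm-3
#' @param topsoil logical, use the topsoil regression variant
#' @return named numeric: theta_sat, theta_a, theta_fc, theta_d, theta_wp
#'   (volumetric fractions)
#' @export
hypres_retention <- function(clay, silt, om, bd, topsoil = TRUE) {
  # clamp to the pedotransfer calibration domain
  cl <- function(x, lo, hi, what) {
    if (x < lo || x > hi) {
      warning(sprintf("%s = %.3g outside pedotransfer range [%g, %g]; clamped",
                      what, x, lo, hi))
      x <- min(max(x, lo), hi)
    }
    x
  }
  clay <- cl(clay, 0.5, 80, "clay")
  silt <- cl(silt, 0.5, 80, "silt")
  om   <- cl(om, 0.05, 20, "organic matter")
  bd   <- cl(bd, 0.6, 1.9, "bulk density")
  ts <- as.numeric(topsoil)

  theta_s <- 0.7919 + 0.001691 * clay - 0.29619 * bd -
    0.000001491 * silt^2 + 0.0000821 * om^2 +
    0.02427 / clay + 0.01113 / silt + 0.01472 * log(silt) -
    0.0000733 * om * clay - 0.000619 * bd * clay -
    0.001183 * bd * om - 0.0001664 * ts * silt

  alpha <- exp(-14.96 + 0.03135 * clay + 0.0351 * silt + 0.646 * om +
    15.29 * bd - 0.192 * ts - 4.671 * bd^2 - 0.000781 * clay^2 -
    0.00687 * om^2 + 0.0449 / om + 0.0663 * log(silt) +
    0.1482 * log(om) - 0.04546 * bd * silt - 0.4852 * bd * om +
    0.00673 * ts * clay)

  n <- 1 + exp(-25.23 - 0.02195 * clay + 0.0074 * silt - 0.1940 * om +
    45.5 * bd - 7.24 * bd^2 + 0.0003658 * clay^2 + 0.002885 * om^2 -
    12.81 / bd - 0.1524 / silt - 0.01958 / om - 0.2876 * log(silt) -
    0.0709 * log(om) - 44.6 * log(bd) - 0.02264 * bd * clay +
    0.0896 * bd * om + 0.00718 * ts * clay)

  theta_r <- 0.01
  m <- 1 - 1 / n
  vg <- function(h_cm) theta_r + (theta_s - theta_r) / (1 + (alpha * h_cm)^n)^m
  # tensions in cm of water (1 kPa = 10.197 cm)
  out <- c(
    theta_sat = theta_s,
    theta_a   = vg(5 * 10.197),
    theta_fc  = vg(10 * 10.197),
    theta_d   = vg(40 * 10.197),
    theta_wp  = vg(1500 * 10.197)
  )
  out
}

#' Slope-reduced surface storage
#'
#' Surface storage capacity of a cell shrinks linearly with its mean
#' gradient: `S = (1 - g/g_max) * S_max`, so a cell at the gradient ceiling
#' stores nothing and sheds all excess water.
#'
#' @param s_max maximum (flat-cell) storage, mm
#' @param g mean cell gradient (dimensionless, e.g. 0.05 = 5 percent)
#' @param g_max upper limit on the gradient
#' @return storage capacity S, mm
#' @export
slope_storage <- function(s_max, g, g_max) {
  stopifnot(g_max > 0, s_max >= 0)
  if (g < 0) stop("gradient must be >= 0")
  if (g > g_max) {
    warning("gradient exceeds g_max; storage clamped to 0")
    g <- g_max
  }
  (1 - g / g_max) * s_max
}

#' Partition surface water into infiltration and runoff
#'
#' Capacity-excess (saturation-excess) runoff: water in excess of the
#' slope-reduced surface storage plus the remaining infiltration capacity of
#' layer 1 (to saturation) runs off; the rest infiltrates.
#'
#' @param rain water arriving at the surface (rain plus lateral inflow), mm
#' @param s surface storage capacity from [slope_storage()], mm
#' @param layer1_deficit infiltration capacity of layer 1, mm
#'   (`theta_sat * delta - W`)
#' @return list(infiltration, runoff) in mm
#' @export
partition_rain <- function(rain, s, layer1_deficit) {
  stopifnot(rain >= 0, s >= 0, layer1_deficit >= -1e-9)
  runoff <- max(0, rain - s - max(0, layer1_deficit))
  list(infiltration = rain - runoff, runoff = runoff)
}

#' Drainage cascade through the three-layer profile
#'
#' Infiltrating water fills each layer to field capacity starting from the
#' top; excess passes to the layer below and outflow from layer 3 is
#' drainage.  Water mass is conserved exactly.
#'
#' @param profile list of soil layers (each with `W`, `theta_fc`, `delta`)
#' @param infiltration mm entering layer 1
#' @return list(profile, drainage, flux) where `flux[l]` is the water leaving
#'   layer l downward (mm), `flux[3]` equalling `drainage`
#' @export
drain_cascade <- function(profile, infiltration) {
  stopifnot(infiltration >= 0)
  nl <- length(profile)
  flux <- numeric(nl)
  inflow <- infiltration
  for (l in seq_len(nl)) {
    cap <- profile[[l]]$theta_fc * profile[[l]]$delta
    w <- profile[[l]]$W + inflow
    out <- max(0, w - cap)
    profile[[l]]$W <- w - out
    flux[l] <- out
    inflow <- out
  }
  list(profile = profile, drainage = flux[nl], flux = flux)
}

# Penman potential evaporation and transpiration (LINTUL formulation).
# Returns mm d-1 potential soil evaporation (pevap) and potential crop
# transpiration (ptran), split by canopy interception exp(-0.5 LAI).
penman_pet <- function(tmean, rad, vp, wind, lai, params = landsim_params()) {
  boltzm <- 5.668e-8
  lhvap  <- 2.4e6
  psycon <- 0.067
  bbrad  <- boltzm * (tmean + 273)^4 * 86400
  svp    <- 0.611 * exp(17.4 * tmean / (tmean + 239))
  slope  <- 4158.6 * svp / (tmean + 239)^2
  vp     <- min(vp, svp)
  rlwn   <- bbrad * max(0, 0.55 * (1 - vp / svp))
  nrads  <- rad * 1e6 * (1 - params$water$albedo_soil) - rlwn
  nradc  <- rad * 1e6 * (1 - params$water$albedo_crop) - rlwn
  penmrs <- nrads * slope / (slope + psycon)
  penmrc <- nradc * slope / (slope + psycon)
  wdf    <- 2.63 * (1 + 0.54 * wind)
  penmd  <- lhvap * wdf * (svp - vp) * psycon / (slope + psycon)
  pevap  <- max(0, exp(-0.5 * lai) * (penmrs + penmd) / lhvap)
  ptran  <- max(0, (1 - exp(-0.5 * lai)) * (penmrc + penmd) / lhvap)
  list(pevap = pevap, ptran = ptran)
}

#' Soil surface evaporation
#'
#' The soil share of potential evapotranspiration, `(1 - cover) * potential`,
#' limited by the water stored above air-dry in layer 1.
#'
#' @param weather one weather day (list/row with tmin, tmax, rad, vp, wind)
#' @param cover canopy cover fraction in \[0, 1\]
#' @param layer1 topsoil layer (W, delta, theta_wp)
#' @param params model parameters
#' @return list(evaporation, layer1) with the layer water store reduced
#' @export
soil_evaporation <- function(weather, cover, layer1,
                             params = landsim_params()) {
  stopifnot(cover >= 0, cover <= 1)
  tmean <- (weather$tmin + weather$tmax) / 2
  pet <- penman_pet(tmean, weather$rad, weather$vp, weather$wind, lai = 0,
                    params = params)
  demand <- (1 - cover) * pet$pevap
  air_dry <- params$water$air_dry_frac * layer1$theta_wp * layer1$delta
  supply <- max(0, layer1$W - air_dry)
  evap <- min(demand, supply)
  layer1$W <- layer1$W - evap
  list(evaporation = evap, layer1 = layer1)
}

# Bulk density (g cm-3) from sand, clay and organic carbon via a smooth
# surface patterned on the Rawls mineral/organic nomogram: the mineral
# fraction density (from texture) and the organic matter density (0.224)
# combine harmonically on a mass basis.
rawls_bd <- function(sand, clay, oc) {
  om <- oc * 1.724
  om <- min(om, 60)
  bd_min <- 1.55 + 0.0027 * sand - 0.0022 * clay
  bd_min <- min(max(bd_min, 1.2), 1.8)
  100 / (om / 0.224 + (100 - om) / bd_min)
}

#' Update topsoil bulk density and thickness
#'
#' Bulk density follows sand, clay and organic carbon through a
#' nomogram-style mineral/organic mixing relationship; the topsoil thickness
#' is rescaled so that the layer's soil mass is conserved
#' (`delta_new * BD_new = delta_old * BD_old`), and the retention anchors are
#' re-evaluated for the new density.
#'
#' @param layer1 topsoil layer (delta, bulk_density, clay, silt, W, pools)
#' @param oc_pct topsoil organic carbon, mass percent
#' @return updated layer with refreshed retention anchors
#' @export
update_bulk_density <- function(layer1, oc_pct) {
  stopifnot(oc_pct >= 0)
  sand <- 100 - layer1$clay - layer1$silt
  bd_new <- rawls_bd(sand, layer1$clay, oc_pct)
  delta_new <- layer1$delta * layer1$bulk_density / bd_new
  layer1$bulk_density <- bd_new
  layer1$delta <- delta_new
  anchors <- hypres_retention(layer1$clay, layer1$silt,
                              om = max(oc_pct * 1.724, 0.1),
                              bd = bd_new, topsoil = TRUE)
  layer1[names(anchors)] <- as.list(anchors)
  layer1$W <- min(layer1$W, layer1$theta_sat * layer1$delta)
  layer1
}

#' Construct a soil layer
#'
#' @param delta thickness mm; @param clay,silt texture percent; @param ph pH
#' @param bulk_density g cm-3; @param toc_pct organic C percent (topsoil)
#' @param n_nh4,n_no3 mineral N pools kg N ha-1
#' @param p_av,p_nonav mineral P pools kg P ha-1
#' @param topsoil logical
#' @param w_frac initial water as a fraction of field capacity
#' @return soil layer list with retention anchors and water store
#' @export
new_soil_layer <- function(delta = 230, clay = 25, silt = 55, ph = 7,
                           bulk_density = 1.3, toc_pct = 1.2,
                           n_nh4 = 1, n_no3 = 5, p_av = 100, p_nonav = 900,
                           topsoil = FALSE, w_frac = 1) {
  anchors <- hypres_retention(clay, silt, om = max(toc_pct * 1.724, 0.1),
                              bd = bulk_density, topsoil = topsoil)
  layer <- list(delta = delta, clay = clay, silt = silt, ph = ph,
                bulk_density = bulk_density,
                N_NH4 = n_nh4, N_NO3 = n_no3, P_Av = p_av, P_NonAv = p_nonav)
  layer[names(anchors)] <- as.list(anchors)
  layer$W <- w_frac * layer$theta_fc * delta
  layer
}

#' Total water stored in a profile, mm
#' @param profile list of soil layers
#' @return mm
#' @export
profile_water <- function(profile) sum(vapply(profile, `[[`, 0, "W"))
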
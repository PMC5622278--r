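#' Default model parameters
#'
#' Returns the full set of model constants as a nested list.  Every constant
#' used by the process modules lives here so that a single configuration file
#' can override any of them; functions take a `params` argument defaulting to
#' `landsim_params()`.
#'
#' Units are stated per entry.  Soil water contents are volumetric fractions,
#' water stores are mm, nutrient pools are kg ha-1 (mineral) or t ha-1
#' (organic), biomasses g DM m-2.
#'
#' @param ... named overrides, e.g. `landsim_params(water = list(g_max = 0.1))`.
#'   Overrides are merged recursively into the defaults.
#' @return nested list of parameters.
#' @export
landsim_params <- function(...) {
  p <- list(
    water = list(
      layer_thickness = c(230, 230, 230), # mm, initial
      g_max          = 0.2,    # upper limit on cell gradient (slope storage)
      s_max          = 10,     # mm, maximum surface storage of a flat cell
      air_dry_frac   = 0.33,   # air-dry water content as fraction of theta_wp
      albedo_soil    = 0.15,
      albedo_crop    = 0.25,
      mix_depth      = 20      # mm, surface mixing depth for runoff chemistry
    ),
    organic = list(
      k = c(DPM = 10, RPM = 0.3, BIO = 0.66, HUM = 0.02), # yr-1 rate constants
      bio_hum_split  = c(BIO = 0.46, HUM = 0.54),
      cn_bio         = 8.5,
      cn_hum         = 8.5,
      cp_bio         = 50.0,
      cp_hum         = 100.0,
      dpm_rpm_residue = c(DPM = 0.59, RPM = 0.41),
      fym_split      = c(DPM = 0.49, RPM = 0.49, HUM = 0.02),
      fcov_vegetated = 0.6,    # plant-retainment rate modifier
      fcov_bare      = 1.0
    ),
    fym = list(
      dm_frac    = 0.25,   # fresh weight -> dry matter
      c_of_dm    = 0.40,   # C fraction of dry matter
      n_per_35t  = 250,    # kg N in 35 t fresh
      p_per_35t  = 45      # kg P in 35 t fresh (typical cattle FYM)
    ),
    nitrogen = list(
      k_n2o       = 1e-4,   # nitrification N2O fraction constant
      n_min       = 0.05,   # kg N ha-1 NH4 floor for nitrification
      k_nitrif    = 0.15,   # d-1
      denit_a     = 0.000735,
      denit_t_opt = 23.65,  # deg C
      denit_t_w   = 0.00045,
      n2_coef     = 0.0052,
      n2_logistic = c(0.14975, 4.0, 12.0, 0.62),
      wfps_coefs  = c(0.6151, 1.192),
      uptake_cap  = 6.0,    # kg N ha-1 d-1
      dep_year0   = 1966, dep_rate0 = 35,   # kg N yr-1
      dep_year1   = 2012, dep_rate1 = 20
    ),
    phosphorus = list(
      alpha_b = 0.113,  beta_b = -49.3,  # Olsen vs total P, upper branch
      alpha_a = 0.0201, beta_a = -5.1,   # lower branch
      v_clamp = c(0.001, 0.95),
      lambda  = 0.01,    # d-1 re-equilibration rate
      fert_split_available = 0.8,
      mobile_frac   = 0.10,  # of available P (runoff)
      solution_frac = 0.01,  # of available P (leaching carrier)
      uptake_cap    = 2.0    # kg P ha-1 d-1
    ),
    evaluation = list(),
    routing = list(
      within_day = TRUE,
      field_drains_to_ditch = TRUE
    )
  )
  overrides <- list(...)
  modify_list_recursive(p, overrides)
}

modify_list_recursive <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(upd[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_recursive(base[[nm]], upd[[nm]])
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

#' Crop parameter presets
#'
#' Parameter sets for winter wheat and perennial ryegrass-type grassland.
#' The growth model is generic; the preset fixes light-use efficiency,
#' phenology, partitioning tables, nutrient maxima/residuals and
#' senescence/death rates.
#'
#' Partitioning tables are linear-interpolation knots over development stage
#' (DVS): `froot` is the fraction of new biomass sent below ground and the
#' shoot fractions (`fleaf`, `fstem`, `fstorage`) partition the remainder.
#'
#' @param kind "wheat" or "grass".
#' @return list of crop parameters.
#' @export
crop_params <- function(kind = c("wheat", "grass")) {
  kind <- match.arg(kind)
  common <- list(
    kind = kind,
    extinction_k = 0.6,     # canopy extinction coefficient (PAR)
    par_frac     = 0.5,     # PAR fraction of global radiation
    root_growth  = 12.0,    # mm d-1
    f_r          = 0.98,    # root fraction above d_root
    litter_frac  = 0.5,     # of dead leaves becoming litter daily
    c_frac_dm    = 0.45,    # carbon fraction of dry matter
    leaf_death_base  = 0.002, # d-1 background leaf turnover
    leaf_death_nstress = 0.01, # d-1 at full N stress
    rgrl = 0.009,             # juvenile relative LAI growth, (deg C d)-1
    juvenile_lai = 0.75,      # exponential leaf expansion below this LAI
    juvenile_dvs = 0.3,       #   and before this DVS
    leaf_death_heat  = 0.03,  # d-1 above heat threshold
    heat_threshold   = 30,    # deg C daily maximum
    leaf_death_shade = 0.03,  # d-1 when LAI exceeds critical
    lai_crit         = 4.0
  )
  if (kind == "wheat") {
    sp <- list(
      lue = 3.0,            # g DM MJ-1 PAR
      sla = 0.022,          # m2 g-1
      t_base = 0,
      tsum1 = 1550, tsum2 = 900,   # deg C d to anthesis / to maturity
      vern_days = 50,       # vernalisation requirement (0 disables)
      vern_t = c(-4, 17),   # effective vernalising temperature range
      max_root_depth = 1200,
      n_res = 0.004,
      n_max_leaf = function(D) 0.046 * exp(-1.7 * D) + 0.014,
      stem_factor = 0.5,
      root_n_factor = 0.5,  # root max N prop relative to leaf
      p_res_leaf = 0.0003, p_res_stem = 0.00018,
      p_max_leaf_knots = cbind(dvs = c(0, 0.7, 1, 2),
                               p   = c(0.0066, 0.0036, 0.0009, 0.0009)),
      root_death_rate = 0.02, root_death_dvs = 1.5,
      storage_n_max = 0.025, storage_p_max = 0.0035,
      transloc_rate = 0.03, # d-1 of translocatable N/P moved to storage
      grass_floor = NA,
      r_lue_ramp = NULL, t_lue_ramp = NULL,
      ws_floor = 0,        # water stress floor between theta_d and theta_w
      sat_stress = TRUE,
      part = list(
        root = cbind(dvs = c(0, 0.1, 0.2, 0.35, 0.5, 0.7, 0.9, 1.2, 3),
                     f   = c(0.5, 0.5, 0.4, 0.22, 0.13, 0.07, 0.03, 0, 0)),
        leaf = cbind(dvs = c(0, 0.1, 0.25, 0.5, 0.65, 0.95, 3),
                     f   = c(0.65, 0.65, 0.7, 0.5, 0.3, 0, 0)),
        stem = cbind(dvs = c(0, 0.1, 0.25, 0.5, 0.65, 0.95, 1.05, 3),
                     f   = c(0.35, 0.35, 0.3, 0.5, 0.7, 1, 0, 0))
        # storage gets the remainder of the shoot fraction
      )
    )
  } else {
    sp <- list(
      lue = 3.0,
      sla = 0.025,
      t_base = 0,
      tsum1 = 600, tsum2 = Inf,  # grass never flowers; DVS < 1
      vern_days = 0, vern_t = c(-4, 17),
      max_root_depth = 600,
      n_res = 0.01,
      n_max_leaf = function(D) rep(0.0425, length(D)),
      stem_factor = 0.5,
      root_n_factor = 0.5,
      p_res_leaf = 0.001, p_res_stem = 0.001,
      p_max_leaf_knots = cbind(dvs = c(0, 2), p = c(0.0035, 0.0035)),
      root_death_rate = 0.01, root_death_dvs = 0.01,
      storage_n_max = 0, storage_p_max = 0,
      transloc_rate = 0,
      grass_floor = 50,    # g m-2 aboveground after cutting/grazing
      r_lue_ramp = c(10, 40, 1.0, 0.33),  # rad (MJ) from,to ; factor from,to
      t_lue_ramp = c(6, 9),               # deg C, factor 0 -> 1
      ws_floor = 0.4,
      sat_stress = FALSE,
      part = list(
        root = cbind(dvs = c(0, 1), f = c(0.35, 0.35)),
        leaf = cbind(dvs = c(0, 1), f = c(0.75, 0.75)),
        stem = cbind(dvs = c(0, 1), f = c(0.25, 0.25))
      )
    )
  }
  c(common, sp)
}

# linear interpolation in a two-column knot table, constant beyond ends
interp_table <- function(knots, x) {
  stats::approx(knots[, 1], knots[, 2], xout = x, rule = 2)$y
}

#' Manure deposition rates per head per day while grazing
#' @param animal "beef", "dairy" or "sheep"
#' @return list with `c_kg` (kg C head-1 d-1) and `n_kg` (kg N head-1 d-1)
#' @export
manure_rates <- function(animal = c("beef", "dairy", "sheep")) {
  animal <- match.arg(animal)
  switch(animal,
    beef  = list(c_kg = 4.03, n_kg = 0.22),
    dairy = list(c_kg = 6.45, n_kg = 0.35),
    sheep = list(c_kg = 0.45, n_kg = 0.02))
}

#' pH rate-modifying tent function
#'
#' Rises linearly 0 to 1 over pH 0 to 7, falls back to 0 over pH 7 to 14.
#' Shared by the nitrification pH response and the mineral-P re-equilibration.
#'
#' @param ph soil pH
#' @return factor in \[0, 1\]
#' @export
f_ph <- function(ph) {
  ifelse(ph <= 7, pmax(0, ph / 7), pmax(0, (14 - ph) / 7))
}
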
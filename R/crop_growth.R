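#' Create a freshly sown crop
#'
#' Organ masses start from small seed reserves so that the canopy can begin
#' intercepting light; development stage is 0.
#'
#' @param cp crop parameter set from [crop_params()]
#' @param seed_mass initial biomass, g DM m-2 (half leaf, half root)
#' @return crop state list
#' @export
new_crop_state <- function(cp, seed_mass = 3) {
  m <- c(root = seed_mass / 2, stem = 0, leaf = seed_mass / 2, storage = 0)
  n0 <- cp$n_max_leaf(0)
  n <- c(root = m[["root"]] * n0 * cp$root_n_factor, stem = 0,
         leaf = m[["leaf"]] * n0, storage = 0)
  p0 <- interp_table(cp$p_max_leaf_knots, 0)
  p <- c(root = m[["root"]] * p0 * 0.5, stem = 0,
         leaf = m[["leaf"]] * p0, storage = 0)
  list(cp = cp, dvs = 0, vdays = 0, age = 0,
       mass = m, n = n, p = p, dead_leaf = 0, dead_leaf_n = 0,
       dead_leaf_p = 0, d_root = 100)
}

crop_lai <- function(state) state$cp$sla * state$mass[["leaf"]]
crop_cover <- function(state) {
  if (is.null(state)) return(0)
  1 - exp(-state$cp$extinction_k * crop_lai(state))
}

#' Advance crop development
#'
#' Thermal time above the base temperature, divided by the stage duration
#' (pre-anthesis modified by the vernalisation factor), advances DVS.
#' Grass is capped just below 1 and never flowers.
#'
#' @param state crop state
#' @param weather one weather day
#' @return updated state
#' @export
develop <- function(state, weather) {
  cp <- state$cp
  tmean <- (weather$tmin + weather$tmax) / 2
  teff <- max(0, tmean - cp$t_base)
  vf <- 1
  if (cp$vern_days > 0 && state$dvs < 1) {
    if (tmean >= cp$vern_t[1] && tmean <= cp$vern_t[2]) {
      state$vdays <- state$vdays + 1
    }
    vf <- min(1, state$vdays / cp$vern_days)
  }
  if (cp$kind == "grass") {
    state$dvs <- min(0.999, state$dvs + teff / cp$tsum1)
  } else if (state$dvs < 1) {
    state$dvs <- state$dvs + vf * teff / cp$tsum1
  } else {
    state$dvs <- state$dvs + teff / cp$tsum2
  }
  state$age <- state$age + 1
  state
}

#' Root distribution over soil layers
#'
#' Root length falls off exponentially with depth such that a fraction
#' `F_r = 0.98` lies above the rooting depth:
#' `a = -ln(1 - F_r) / d_root`, layer mass proportional to
#' `exp(-a z_upper) - exp(-a z_lower)`, truncated at `d_root` and
#' normalised to sum to one.
#'
#' @param d_root rooting depth, mm
#' @param bounds layer interface depths, mm (e.g. `c(0, 230, 460, 690)`)
#' @param f_r fraction of root length above `d_root`
#' @return per-layer root fractions
#' @export
root_distribution <- function(d_root, bounds, f_r = 0.98) {
  stopifnot(d_root > 0)
  a <- -log(1 - f_r) / d_root
  nl <- length(bounds) - 1
  mass <- numeric(nl)
  for (l in seq_len(nl)) {
    z1 <- bounds[l]
    z2 <- min(bounds[l + 1], d_root)
    if (z1 >= d_root) break
    mass[l] <- exp(-a * z1) - exp(-a * z2)
  }
  if (sum(mass) == 0) mass[1] <- 1
  mass / sum(mass)
}

#' Water stress factor and per-layer transpiration
#'
#' The per-layer stress `W_S` is 1 between -5 kPa and -40 kPa, falls
#' linearly towards saturation (arable only) and towards wilting (grass
#' bottoming out at 0.4 and feeling no saturation stress).  Actual
#' transpiration from layer l is
#' `P_Tran W_S(l)^2 F_RL(l) / sum(W_S F_RL)`, capped by the water stored
#' above wilting; the transpiration reduction factor is the ratio of total
#' actual to potential transpiration.
#'
#' @param profile list of soil layers
#' @param p_tran potential transpiration, mm d-1
#' @param f_rl per-layer root fractions
#' @param cp crop parameter set
#' @return list(w_rf, atran) with `atran` per layer in mm
#' @export
water_stress <- function(profile, p_tran, f_rl, cp) {
  stopifnot(p_tran >= 0)
  nl <- length(profile)
  ws <- numeric(nl)
  headroom <- numeric(nl)
  for (l in seq_len(nl)) {
    lay <- profile[[l]]
    th <- lay$W / lay$delta
    if (th > lay$theta_a) {
      ws[l] <- if (cp$sat_stress) {
        max(0, (lay$theta_sat - th) / (lay$theta_sat - lay$theta_a))
      } else 1
    } else if (th > lay$theta_d) {
      ws[l] <- 1
    } else if (th > lay$theta_wp) {
      base <- (th - lay$theta_wp) / (lay$theta_d - lay$theta_wp)
      ws[l] <- cp$ws_floor + (1 - cp$ws_floor) * base
    } else {
      ws[l] <- cp$ws_floor
    }
    headroom[l] <- max(0, lay$W - lay$theta_wp * lay$delta)
  }
  if (p_tran <= 0) return(list(w_rf = 1, atran = numeric(nl)))
  denom <- sum(ws * f_rl)
  if (denom <= 0) return(list(w_rf = 0, atran = numeric(nl)))
  atran <- p_tran * ws^2 * f_rl / denom
  atran <- pmin(atran, headroom)
  list(w_rf = sum(atran) / p_tran, atran = atran)
}

#' Nitrogen and phosphorus nutrition indices
#'
#' Ratio of the leaf-plus-stem nutrient concentration above the residual
#' (structural) concentration to the corresponding maximum headroom, both
#' mass-weighted over leaf and stem, clamped to \[0, 1\].  An empty canopy
#' is unstressed.
#'
#' @param state crop state
#' @return named numeric (n_ni, p_ni)
#' @export
nutrition_indices <- function(state) {
  cp <- state$cp
  wl <- state$mass[["leaf"]]
  ws <- state$mass[["stem"]]
  tot <- wl + ws
  if (tot <= 0) return(c(n_ni = 1, p_ni = 1))
  nmax_l <- cp$n_max_leaf(state$dvs)
  nmax_s <- cp$stem_factor * nmax_l
  n_conc <- (state$n[["leaf"]] + state$n[["stem"]]) / tot
  n_max <- (wl * nmax_l + ws * nmax_s) / tot
  n_ni <- (n_conc - cp$n_res) / (n_max - cp$n_res)
  pmax_l <- interp_table(cp$p_max_leaf_knots, state$dvs)
  pmax_s <- cp$stem_factor * pmax_l
  p_res <- wl * cp$p_res_leaf + ws * cp$p_res_stem
  p_num <- state$p[["leaf"]] + state$p[["stem"]] - p_res
  p_den <- wl * pmax_l + ws * pmax_s - p_res
  p_ni <- if (p_den > 0) p_num / p_den else 1
  c(n_ni = min(max(n_ni, 0), 1), p_ni = min(max(p_ni, 0), 1))
}

# grass light-use-efficiency modifiers: radiation and temperature ramps
grass_lue_factors <- function(cp, rad, tmean) {
  r <- 1
  if (!is.null(cp$r_lue_ramp)) {
    rr <- cp$r_lue_ramp
    fr <- (rad - rr[1]) / (rr[2] - rr[1])
    r <- rr[3] + (rr[4] - rr[3]) * min(max(fr, 0), 1)
  }
  t <- 1
  if (!is.null(cp$t_lue_ramp)) {
    tr <- cp$t_lue_ramp
    t <- min(max((tmean - tr[1]) / (tr[2] - tr[1]), 0), 1)
  }
  r * t
}

#' Daily biomass production and partitioning
#'
#' `dB = Q epsilon W_rf N_NI P_NI` with `Q` the intercepted PAR (half the
#' global radiation through a Beer's-law canopy); for grass the LUE is
#' further scaled by the radiation and temperature ramps.  New biomass is
#' split root/shoot and the shoot into leaf, stem and storage by the
#' DVS-dependent partitioning tables.
#'
#' @param state crop state
#' @param weather one weather day
#' @param w_rf,n_ni,p_ni stress factors in \[0, 1\]
#' @return list(state, db) with `db` in g DM m-2 d-1
#' @export
daily_growth <- function(state, weather, w_rf, n_ni, p_ni) {
  cp <- state$cp
  tmean <- (weather$tmin + weather$tmax) / 2
  lai <- crop_lai(state)
  q <- cp$par_frac * weather$rad * (1 - exp(-cp$extinction_k * lai))
  eps <- cp$lue
  if (cp$kind == "grass") eps <- eps * grass_lue_factors(cp, weather$rad, tmean)
  db <- q * eps * w_rf * n_ni * p_ni
  if (db > 0) {
    froot <- interp_table(cp$part$root, state$dvs)
    fleaf <- interp_table(cp$part$leaf, state$dvs)
    fstem <- interp_table(cp$part$stem, state$dvs)
    fstor <- max(0, 1 - fleaf - fstem)
    shoot <- db * (1 - froot)
    state$mass[["root"]] <- state$mass[["root"]] + db * froot
    state$mass[["leaf"]] <- state$mass[["leaf"]] + shoot * fleaf
    state$mass[["stem"]] <- state$mass[["stem"]] + shoot * fstem
    state$mass[["storage"]] <- state$mass[["storage"]] + shoot * fstor
  }
  list(state = state, db = max(0, db))
}

#' Crop nutrient demand
#'
#' The sum over roots, stems and leaves of the gap between maximum and
#' actual organ nutrient content; zero after anthesis (all uptake happens
#' before DVS 1; storage organs are filled by translocation).
#'
#' @param state crop state
#' @return list(n_demand, p_demand) in kg ha-1 d-1
#' @export
nutrient_demand <- function(state) {
  cp <- state$cp
  if (state$dvs >= 1) return(list(n_demand = 0, p_demand = 0))
  nmax_l <- cp$n_max_leaf(state$dvs)
  nmax <- c(root = cp$root_n_factor * nmax_l, stem = cp$stem_factor * nmax_l,
            leaf = nmax_l)
  pmax_l <- interp_table(cp$p_max_leaf_knots, state$dvs)
  pmax <- c(root = 0.5 * pmax_l, stem = cp$stem_factor * pmax_l,
            leaf = pmax_l)
  nd <- pd <- 0
  for (o in c("root", "stem", "leaf")) {
    nd <- nd + max(0, state$mass[[o]] * nmax[[o]] - state$n[[o]])
    pd <- pd + max(0, state$mass[[o]] * pmax[[o]] - state$p[[o]])
  }
  list(n_demand = nd * 10, p_demand = pd * 10)  # g m-2 -> kg ha-1
}

# distribute delivered nutrients (kg ha-1) into organs pro-rata shortfall
apply_uptake <- function(state, n_kg, p_kg) {
  cp <- state$cp
  nmax_l <- cp$n_max_leaf(state$dvs)
  pmax_l <- interp_table(cp$p_max_leaf_knots, state$dvs)
  nmax <- c(root = cp$root_n_factor * nmax_l, stem = cp$stem_factor * nmax_l,
            leaf = nmax_l)
  pmax <- c(root = 0.5 * pmax_l, stem = cp$stem_factor * pmax_l, leaf = pmax_l)
  organs <- c("root", "stem", "leaf")
  ngap <- vapply(organs, function(o)
    max(0, state$mass[[o]] * nmax[[o]] - state$n[[o]]), 0)
  pgap <- vapply(organs, function(o)
    max(0, state$mass[[o]] * pmax[[o]] - state$p[[o]]), 0)
  if (sum(ngap) > 0 && n_kg > 0) {
    add <- (n_kg / 10) * ngap / sum(ngap)
    for (i in seq_along(organs)) {
      state$n[[organs[i]]] <- state$n[[organs[i]]] + add[i]
    }
  }
  if (sum(pgap) > 0 && p_kg > 0) {
    add <- (p_kg / 10) * pgap / sum(pgap)
    for (i in seq_along(organs)) {
      state$p[[organs[i]]] <- state$p[[organs[i]]] + add[i]
    }
  }
  state
}

# post-anthesis translocation of N and P above the structural residual into
# the storage organ, at `transloc_rate` per day, capped by the storage
# concentration ceilings
translocate_to_storage <- function(state) {
  cp <- state$cp
  if (state$dvs < 1 || cp$transloc_rate <= 0) return(state)
  sto <- state$mass[["storage"]]
  if (sto <= 0) return(state)
  move_nutrient <- function(stocks, res_conc, cap_conc, slot) {
    room <- max(0, cap_conc * sto - state[[slot]][["storage"]])
    avail <- vapply(c("root", "stem", "leaf"), function(o)
      max(0, stocks[[o]] - state$mass[[o]] * res_conc[[o]]), 0)
    mv <- min(cp$transloc_rate * sum(avail), room)
    if (mv > 0 && sum(avail) > 0) {
      take <- mv * avail / sum(avail)
      for (i in seq_along(take)) {
        o <- names(take)[i]
        state[[slot]][[o]] <<- state[[slot]][[o]] - take[i]
      }
      state[[slot]][["storage"]] <<- state[[slot]][["storage"]] + mv
    }
  }
  n_res <- list(root = cp$n_res, stem = cp$n_res, leaf = cp$n_res)
  p_res <- list(root = cp$p_res_stem, stem = cp$p_res_stem,
                leaf = cp$p_res_leaf)
  move_nutrient(state$n, n_res, cp$storage_n_max, "n")
  move_nutrient(state$p, p_res, cp$storage_p_max, "p")
  state
}

#' Senescence: leaf and root death, litter formation
#'
#' The leaf death rate combines a background turnover with heat stress,
#' nitrogen stress and self-shading terms.  Dead leaves accumulate in a
#' standing-dead pool of which half becomes litter each day; roots die at
#' the crop rate once DVS passes the crop threshold (continuously for
#' established grass).  All dead C, N and P is returned for incorporation
#' into the soil organic pools.
#'
#' @param state crop state
#' @param weather one weather day
#' @param n_ni current N nutrition index
#' @return list(state, litter) where `litter` has `c` (t C ha-1), `n`, `p`
#'   (kg ha-1)
#' @export
senesce_and_return <- function(state, weather, n_ni) {
  cp <- state$cp
  rate <- cp$leaf_death_base +
    cp$leaf_death_nstress * (1 - n_ni) +
    cp$leaf_death_heat * (weather$tmax > cp$heat_threshold) +
    cp$leaf_death_shade * (crop_lai(state) > cp$lai_crit)
  rate <- min(rate, 0.1)
  dead <- state$mass[["leaf"]] * rate
  frac_n <- if (state$mass[["leaf"]] > 0) state$n[["leaf"]] /
    state$mass[["leaf"]] else 0
  frac_p <- if (state$mass[["leaf"]] > 0) state$p[["leaf"]] /
    state$mass[["leaf"]] else 0
  state$mass[["leaf"]] <- state$mass[["leaf"]] - dead
  state$n[["leaf"]] <- state$n[["leaf"]] - dead * frac_n
  state$p[["leaf"]] <- state$p[["leaf"]] - dead * frac_p
  state$dead_leaf <- state$dead_leaf + dead
  state$dead_leaf_n <- state$dead_leaf_n + dead * frac_n
  state$dead_leaf_p <- state$dead_leaf_p + dead * frac_p

  litter_m <- state$dead_leaf * cp$litter_frac
  litter_n <- state$dead_leaf_n * cp$litter_frac
  litter_p <- state$dead_leaf_p * cp$litter_frac
  state$dead_leaf <- state$dead_leaf - litter_m
  state$dead_leaf_n <- state$dead_leaf_n - litter_n
  state$dead_leaf_p <- state$dead_leaf_p - litter_p

  root_dies <- if (cp$kind == "grass") {
    state$dvs >= cp$root_death_dvs || state$age > 90
  } else {
    state$dvs > cp$root_death_dvs
  }
  if (root_dies && state$mass[["root"]] > 0) {
    dr <- state$mass[["root"]] * cp$root_death_rate
    rn <- state$n[["root"]] * cp$root_death_rate
    rp <- state$p[["root"]] * cp$root_death_rate
    state$mass[["root"]] <- state$mass[["root"]] - dr
    state$n[["root"]] <- state$n[["root"]] - rn
    state$p[["root"]] <- state$p[["root"]] - rp
    litter_m <- litter_m + dr
    litter_n <- litter_n + rn
    litter_p <- litter_p + rp
  }
  litter <- list(c = litter_m * cp$c_frac_dm * 0.01,  # g m-2 DM -> t C ha-1
                 n = litter_n * 10,                   # g m-2 -> kg ha-1
                 p = litter_p * 10)
  list(state = state, litter = litter)
}

#' Cut or graze grassland
#'
#' Cutting removes aboveground biomass down to the standing floor
#' (50 g m-2).  A grazing day removes the herd intake (bounded by the same
#' floor) and deposits manure C and N at the per-head daily rates times the
#' stocking rate, to be incorporated as a fresh FYM-like organic input.
#'
#' @param state crop state (must be grass)
#' @param kind "cut" or "graze"
#' @param animal,stocking grazing herd ("beef", "dairy", "sheep") and
#'   head ha-1
#' @param intake_dm kg DM head-1 d-1 eaten while grazing
#' @return list(state, removed_dm, removed_n, removed_p, manure_c, manure_n)
#'   with removals in t DM ha-1 and kg ha-1, manure in kg ha-1 d-1
#' @export
cut_or_graze <- function(state, kind = c("cut", "graze"), animal = "beef",
                         stocking = 0, intake_dm = NULL) {
  kind <- match.arg(kind)
  cp <- state$cp
  if (cp$kind != "grass") stop("cutting and grazing apply to grass only")
  floor <- cp$grass_floor
  above <- state$mass[["leaf"]] + state$mass[["stem"]] + state$dead_leaf
  removable <- max(0, above - floor)
  if (kind == "cut") {
    take <- removable
    manure_c <- manure_n <- 0
  } else {
    if (is.null(intake_dm)) {
      intake_dm <- switch(animal, beef = 10, dairy = 16, sheep = 1.5)
    }
    take <- min(removable, intake_dm * stocking * 0.1)  # kg ha-1 -> g m-2
    mr <- manure_rates(animal)
    manure_c <- mr$c_kg * stocking
    manure_n <- mr$n_kg * stocking
  }
  removed_n <- removed_p <- 0
  if (take > 0 && above > 0) {
    frac <- take / above
    for (o in c("leaf", "stem")) {
      removed_n <- removed_n + state$n[[o]] * frac
      removed_p <- removed_p + state$p[[o]] * frac
      state$n[[o]] <- state$n[[o]] * (1 - frac)
      state$p[[o]] <- state$p[[o]] * (1 - frac)
      state$mass[[o]] <- state$mass[[o]] * (1 - frac)
    }
    removed_n <- removed_n + state$dead_leaf_n * frac
    removed_p <- removed_p + state$dead_leaf_p * frac
    state$dead_leaf <- state$dead_leaf * (1 - frac)
    state$dead_leaf_n <- state$dead_leaf_n * (1 - frac)
    state$dead_leaf_p <- state$dead_leaf_p * (1 - frac)
  }
  list(state = state,
       removed_dm = take * 0.01,         # g m-2 -> t ha-1
       removed_n = removed_n * 10, removed_p = removed_p * 10,
       manure_c = manure_c, manure_n = manure_n)
}

#' Harvest a mature crop
#'
#' Yield is the storage-organ dry mass expressed at 85 percent dry matter
#' (t ha-1); grain N and P are the storage-organ stocks.  Crop residues
#' (straw, standing dead, remaining roots) are reported for return to the
#' soil.
#'
#' @param state crop state
#' @return list(yield, grain_n, grain_p, residue) where residue carries
#'   `c` (t C ha-1), `n`, `p` (kg ha-1)
#' @export
harvest_crop <- function(state) {
  cp <- state$cp
  sto <- state$mass[["storage"]]
  if (sto <= 0) warning("harvest before storage-organ formation: zero yield")
  yield <- sto * 0.01 / 0.85
  res_m <- state$mass[["root"]] + state$mass[["stem"]] +
    state$mass[["leaf"]] + state$dead_leaf
  res_n <- state$n[["root"]] + state$n[["stem"]] + state$n[["leaf"]] +
    state$dead_leaf_n
  res_p <- state$p[["root"]] + state$p[["stem"]] + state$p[["leaf"]] +
    state$dead_leaf_p
  list(yield = yield,
       grain_n = state$n[["storage"]] * 10,
       grain_p = state$p[["storage"]] * 10,
       residue = list(c = res_m * cp$c_frac_dm * 0.01,
                      n = res_n * 10, p = res_p * 10))
}
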
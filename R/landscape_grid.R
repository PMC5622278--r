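#' Construct a grid cell
#'
#' A cell is the spatial simulation unit: a three-layer soil profile,
#' organic pools, an optional crop, an elevation, edge designations and
#' neighbour links.
#'
#' @param id integer cell id
#' @param area m2
#' @param elevation m
#' @param profile list of three soil layers ([new_soil_layer()])
#' @param pools organic pools ([new_organic_pools()])
#' @param crop crop state ([new_crop_state()]) or NULL for fallow
#' @return cell list
#' @export
new_cell <- function(id, area = 10000, elevation = 100,
                     profile = NULL, pools = NULL, crop = NULL) {
  if (is.null(profile)) {
    profile <- list(new_soil_layer(topsoil = TRUE), new_soil_layer(),
                    new_soil_layer())
  }
  if (is.null(pools)) pools <- new_organic_pools()
  list(id = id, area = area, elevation = elevation,
       edges = c(N = "field", E = "field", S = "field", W = "field"),
       neighbours = c(), profile = profile, pools = pools, crop = crop,
       grazing = NULL, gradient = 0)
}

#' Assemble cells into a grid
#'
#' Computes each cell's mean gradient from its neighbours' elevations and
#' checks neighbour symmetry.
#'
#' @param cells list of cells from [new_cell()]
#' @param cell_size centre-to-centre distance, m
#' @return grid list (cells + geometry)
#' @export
new_grid <- function(cells, cell_size = 100) {
  ids <- vapply(cells, `[[`, 0, "id")
  names(cells) <- as.character(ids)
  for (i in seq_along(cells)) {
    nb <- cells[[i]]$neighbours
    if (length(nb) > 0) {
      for (j in nb) {
        other <- cells[[as.character(j)]]
        if (is.null(other)) stop("neighbour ", j, " of cell ",
                                 cells[[i]]$id, " not in grid")
        if (!cells[[i]]$id %in% other$neighbours) {
          stop("neighbour link ", cells[[i]]$id, " -> ", j,
               " is not symmetric")
        }
      }
      slopes <- abs(cells[[i]]$elevation -
                      vapply(as.character(nb),
                             function(j) cells[[j]]$elevation, 0)) / cell_size
      cells[[i]]$gradient <- mean(slopes)
    }
  }
  list(cells = cells, cell_size = cell_size)
}

# columns of the daily flux record
flux_columns <- c(
  "cell", "rain", "lat_in", "runoff", "ditch_water", "reinfiltrated",
  "drainage", "evaporation", "transpiration", "w_store",
  "fert_n", "dep_n", "fym_n", "manure_n", "net_min_n",
  "nitrif_n2o", "denit_n2o", "n2o", "n2", "n_leached", "n_runoff",
  "n_lat_in", "n_ditch", "uptake_n", "min_n_store",
  "fert_p", "fym_p", "manure_p", "net_min_p", "p_runoff", "p_leached",
  "p_lat_in", "p_ditch", "uptake_p", "min_p_store",
  "c_in", "co2", "toc", "org_n", "org_p",
  "litter_c", "litter_n", "litter_p",
  "plant_mass", "plant_n", "plant_p", "lai", "dvs",
  "w_rf", "n_ni", "p_ni",
  "yield", "grain_n", "grain_p", "cut_dm", "removed_n", "removed_p")

# organic C percent of the topsoil, from pool stocks and layer soil mass
topsoil_oc_pct <- function(cell) {
  toc <- total_toc(cell$pools)              # t C ha-1
  mass <- layer_soil_mass(cell$profile[[1]]) # t soil ha-1
  100 * toc / mass
}

# add fresh organic input and return the C:N:P bookkeeping, skipping
# degenerate zero-carbon or zero-nutrient litter
incorporate_organic <- function(pools, c_t, n_kg, p_kg, source, params) {
  if (c_t <= 0 || n_kg <= 0 || p_kg <= 0) {
    return(list(pools = pools, c = 0, n = 0, p = 0))
  }
  pools <- add_organic_input(pools, c_t, source = source,
                             cn = c_t * 1000 / n_kg, cp = c_t * 1000 / p_kg,
                             params = params)
  list(pools = pools, c = c_t, n = n_kg, p = p_kg)
}

#' Advance the whole grid one day
#'
#' Cells are processed in descending elevation order so that surface runoff
#' and its dissolved nitrogen and phosphorus cascade through the grid within
#' the day.  Within a cell the order is: management events; bulk-density and
#' retention update; atmospheric deposition; rain partition and runoff
#' generation (lateral inflow from upslope cells counts as rain); lateral
#' routing of the runoff and its solutes; drainage cascade; soil
#' evaporation; crop development, growth, uptake and senescence;
#' decomposition and mineralisation; nitrification; denitrification;
#' nitrate and phosphorus leaching.
#'
#' @param grid grid state
#' @param wday one row of a weather data.frame
#' @param events management events dated today (may be empty)
#' @param params model parameters
#' @return list(grid, records) where records is a numeric matrix with one
#'   row per cell (columns `landsim:::flux_columns`)
#' @export
step_day <- function(grid, wday, events, params = landsim_params()) {
  cells <- grid$cells
  n <- length(cells)
  ids <- vapply(cells, `[[`, 0, "id")
  ord <- order(-vapply(cells, `[[`, 0, "elevation"), ids)
  # pending lateral inflow (water volume m3; solutes kg)
  pend_w <- stats::setNames(numeric(n), names(cells))
  pend_n <- pend_w; pend_p <- pend_w
  rec <- matrix(0, nrow = n, ncol = length(flux_columns),
                dimnames = list(names(cells), flux_columns))
  tmean <- (wday$tmin + wday$tmax) / 2
  pw <- params$water

  for (ci in ord) {
    cell <- cells[[ci]]
    key <- names(cells)[ci]
    r <- rec[ci, ]
    r["cell"] <- cell$id
    ha <- cell$area / 10000

    ## -- management ------------------------------------------------------
    ev_today <- events[events$date == wday$date, , drop = FALSE]
    if (nrow(ev_today) > 0) {
      for (k in seq_len(nrow(ev_today))) {
        ev <- ev_today[k, ]
        if (ev$kind == "sow") {
          kindc <- if (is.na(ev$crop)) "wheat" else ev$crop
          cell$crop <- new_crop_state(crop_params(kindc))
        } else if (ev$kind == "fertilise_N") {
          dose <- ev$amount
          if (ev$n_form == "ammonium") {
            cell$profile[[1]]$N_NH4 <- cell$profile[[1]]$N_NH4 + dose
          } else if (ev$n_form == "nitrate") {
            cell$profile[[1]]$N_NO3 <- cell$profile[[1]]$N_NO3 + dose
          } else {
            cell$profile[[1]]$N_NH4 <- cell$profile[[1]]$N_NH4 + dose / 2
            cell$profile[[1]]$N_NO3 <- cell$profile[[1]]$N_NO3 + dose / 2
          }
          r["fert_n"] <- r["fert_n"] + dose
        } else if (ev$kind == "fertilise_P") {
          cell$profile[[1]] <- fertilise_p(cell$profile[[1]], ev$amount,
                                           params)
          r["fert_p"] <- r["fert_p"] + ev$amount
        } else if (ev$kind == "apply_FYM") {
          fy <- params$fym
          c_t <- ev$amount * fy$dm_frac * fy$c_of_dm        # t C ha-1
          n_kg <- ev$amount / 35 * fy$n_per_35t
          p_kg <- ev$amount / 35 * fy$p_per_35t
          inc <- incorporate_organic(cell$pools, c_t, n_kg, p_kg, "fym",
                                     params)
          cell$pools <- inc$pools
          r["fym_n"] <- r["fym_n"] + inc$n
          r["fym_p"] <- r["fym_p"] + inc$p
          r["c_in"] <- r["c_in"] + inc$c
        } else if (ev$kind == "cut") {
          if (!is.null(cell$crop) && cell$crop$cp$kind == "grass") {
            cg <- cut_or_graze(cell$crop, "cut")
            cell$crop <- cg$state
            r["cut_dm"] <- r["cut_dm"] + cg$removed_dm
            r["removed_n"] <- r["removed_n"] + cg$removed_n
            r["removed_p"] <- r["removed_p"] + cg$removed_p
          }
        } else if (ev$kind == "graze_start") {
          cell$grazing <- list(animal = ev$animal, stocking = ev$stocking)
        } else if (ev$kind == "graze_stop") {
          cell$grazing <- NULL
        } else if (ev$kind == "harvest") {
          if (!is.null(cell$crop)) {
            h <- harvest_crop(cell$crop)
            r["yield"] <- h$yield
            r["grain_n"] <- h$grain_n
            r["grain_p"] <- h$grain_p
            inc <- incorporate_organic(cell$pools, h$residue$c, h$residue$n,
                                       h$residue$p, "residue", params)
            cell$pools <- inc$pools
            r["litter_c"] <- r["litter_c"] + inc$c
            r["litter_n"] <- r["litter_n"] + inc$n
            r["litter_p"] <- r["litter_p"] + inc$p
            r["c_in"] <- r["c_in"] + inc$c
            cell$crop <- NULL
          }
        } else if (ev$kind == "fallow") {
          if (!is.null(cell$crop)) {
            st <- cell$crop
            res_m <- sum(st$mass) + st$dead_leaf
            res_n <- sum(st$n) + st$dead_leaf_n
            res_p <- sum(st$p) + st$dead_leaf_p
            inc <- incorporate_organic(cell$pools,
                                       res_m * st$cp$c_frac_dm * 0.01,
                                       res_n * 10, res_p * 10, "residue",
                                       params)
            cell$pools <- inc$pools
            r["litter_c"] <- r["litter_c"] + inc$c
            r["litter_n"] <- r["litter_n"] + inc$n
            r["litter_p"] <- r["litter_p"] + inc$p
            r["c_in"] <- r["c_in"] + inc$c
            cell$crop <- NULL
          }
        }
      }
    }

    ## -- bulk density / retention update ---------------------------------
    cell$profile[[1]] <- update_bulk_density(cell$profile[[1]],
                                             topsoil_oc_pct(cell))

    ## -- atmospheric deposition ------------------------------------------
    dep <- atmospheric_deposition(wday$date, params)
    cell$profile[[1]]$N_NO3 <- cell$profile[[1]]$N_NO3 + dep
    r["dep_n"] <- dep

    ## -- lateral inflow arrives at the surface ---------------------------
    lat_mm <- pend_w[key] * 1000 / cell$area
    r["lat_in"] <- lat_mm
    r["n_lat_in"] <- pend_n[key] / ha
    r["p_lat_in"] <- pend_p[key] / ha
    cell$profile[[1]]$N_NH4 <- cell$profile[[1]]$N_NH4   # (NO3 carrier below)
    cell$profile[[1]]$N_NO3 <- cell$profile[[1]]$N_NO3 + pend_n[key] / ha
    cell$profile[[1]]$P_Av <- cell$profile[[1]]$P_Av + pend_p[key] / ha

    ## -- rain partition and runoff generation ----------------------------
    l1 <- cell$profile[[1]]
    g <- min(cell$gradient, pw$g_max)
    s_cap <- slope_storage(pw$s_max, g, pw$g_max)
    deficit1 <- max(0, l1$theta_sat * l1$delta - l1$W)
    part <- partition_rain(wday$rain + lat_mm, s_cap, deficit1)
    runoff <- part$runoff
    w_surf <- (l1$theta_sat - pw$air_dry_frac * l1$theta_wp) * pw$mix_depth

    n_run <- 0; p_run <- 0
    if (runoff > 0) {
      rn <- runoff_n(cell$profile[[1]], runoff, w_surf, params)
      cell$profile[[1]] <- rn$layer1
      n_run <- rn$n_removed
      rp <- runoff_and_leach_p(cell$profile, runoff, w_surf,
                               numeric(length(cell$profile)), params)
      cell$profile <- rp$profile
      p_run <- rp$p_runoff
    }

    ## -- lateral routing of runoff + solutes -----------------------------
    if (runoff > 0) {
      nb <- cell$neighbours
      slopes <- c()
      targets <- c()
      if (length(nb) > 0) {
        for (e in names(nb)) {
          other <- cells[[as.character(nb[e])]]
          sl <- (cell$elevation - other$elevation) / grid$cell_size
          if (sl > 0) {
            slopes <- c(slopes, sl)
            targets <- c(targets, as.character(nb[e]))
          }
        }
      }
      ditch_edges <- sum(cell$edges == "ditch" &
                           !(names(cell$edges) %in% names(nb)))
      if (ditch_edges > 0) {
        slopes <- c(slopes, rep(max(g, 0.001), ditch_edges))
        targets <- c(targets, rep("__ditch__", ditch_edges))
      }
      if (length(slopes) == 0) {
        # closed depression: water and solutes re-infiltrate locally
        r["reinfiltrated"] <- runoff
        part$infiltration <- part$infiltration + runoff
        cell$profile[[1]]$N_NO3 <- cell$profile[[1]]$N_NO3 + n_run
        cell$profile[[1]]$P_Av <- cell$profile[[1]]$P_Av + p_run
        runoff <- 0; n_run <- 0; p_run <- 0
      } else {
        shares <- slopes / sum(slopes)
        for (t in seq_along(targets)) {
          w_vol <- runoff * cell$area / 1000 * shares[t]   # m3
          n_mass <- n_run * ha * shares[t]                 # kg
          p_mass <- p_run * ha * shares[t]
          if (targets[t] == "__ditch__") {
            r["ditch_water"] <- r["ditch_water"] + runoff * shares[t]
            r["n_ditch"] <- r["n_ditch"] + n_run * shares[t]
            r["p_ditch"] <- r["p_ditch"] + p_run * shares[t]
          } else {
            pend_w[targets[t]] <- pend_w[targets[t]] + w_vol
            pend_n[targets[t]] <- pend_n[targets[t]] + n_mass
            pend_p[targets[t]] <- pend_p[targets[t]] + p_mass
          }
        }
      }
    }
    r["rain"] <- wday$rain
    r["runoff"] <- runoff
    r["n_runoff"] <- n_run
    r["p_runoff"] <- p_run

    ## -- drainage cascade -------------------------------------------------
    dc <- drain_cascade(cell$profile, part$infiltration)
    cell$profile <- dc$profile
    f_w <- dc$flux
    r["drainage"] <- dc$drainage

    ## -- potential ET and soil evaporation --------------------------------
    lai <- if (!is.null(cell$crop)) crop_lai(cell$crop) else 0
    pet <- penman_pet(tmean, wday$rad, wday$vp, wday$wind, lai, params)
    l1 <- cell$profile[[1]]
    air_dry <- pw$air_dry_frac * l1$theta_wp * l1$delta
    evap <- min(pet$pevap, max(0, l1$W - air_dry))
    cell$profile[[1]]$W <- l1$W - evap
    r["evaporation"] <- evap

    ## -- crop --------------------------------------------------------------
    if (!is.null(cell$crop)) {
      st <- develop(cell$crop, wday)
      st$d_root <- min(st$d_root + st$cp$root_growth, st$cp$max_root_depth)
      bounds <- cumsum(c(0, vapply(cell$profile, `[[`, 0, "delta")))
      f_rl <- root_distribution(st$d_root, bounds, st$cp$f_r)
      wst <- water_stress(cell$profile, pet$ptran, f_rl, st$cp)
      for (l in seq_along(cell$profile)) {
        cell$profile[[l]]$W <- cell$profile[[l]]$W - wst$atran[l]
      }
      r["transpiration"] <- sum(wst$atran)
      ni <- nutrition_indices(st)
      r["w_rf"] <- wst$w_rf
      r["n_ni"] <- ni["n_ni"]
      r["p_ni"] <- ni["p_ni"]
      gr <- daily_growth(st, wday, wst$w_rf, ni["n_ni"], ni["p_ni"])
      st <- gr$state
      dem <- nutrient_demand(st)
      un <- supply_n_uptake(cell$profile, dem$n_demand, f_rl, params)
      cell$profile <- un$profile
      up <- supply_p_uptake(cell$profile, dem$p_demand, f_rl, params)
      cell$profile <- up$profile
      st <- apply_uptake(st, un$delivered, up$delivered)
      r["uptake_n"] <- un$delivered
      r["uptake_p"] <- up$delivered
      st <- translocate_to_storage(st)
      sen <- senesce_and_return(st, wday, ni["n_ni"])
      st <- sen$state
      inc <- incorporate_organic(cell$pools, sen$litter$c, sen$litter$n,
                                 sen$litter$p, "residue", params)
      cell$pools <- inc$pools
      r["litter_c"] <- inc$c
      r["litter_n"] <- inc$n
      r["litter_p"] <- inc$p
      r["c_in"] <- r["c_in"] + inc$c

      if (!is.null(cell$grazing)) {
        cg <- cut_or_graze(st, "graze", animal = cell$grazing$animal,
                           stocking = cell$grazing$stocking)
        st <- cg$state
        r["cut_dm"] <- r["cut_dm"] + cg$removed_dm
        r["removed_n"] <- r["removed_n"] + cg$removed_n
        r["removed_p"] <- r["removed_p"] + cg$removed_p
        if (cg$manure_c > 0) {
          inc <- incorporate_organic(cell$pools, cg$manure_c / 1000,
                                     cg$manure_n, cg$manure_n / 5, "fym",
                                     params)
          cell$pools <- inc$pools
          r["manure_n"] <- inc$n
          r["manure_p"] <- inc$p
          r["c_in"] <- r["c_in"] + inc$c
        }
      }

      if (st$cp$kind != "grass" && st$dvs >= 2) {
        h <- harvest_crop(st)
        r["yield"] <- h$yield
        r["grain_n"] <- h$grain_n
        r["grain_p"] <- h$grain_p
        inc <- incorporate_organic(cell$pools, h$residue$c, h$residue$n,
                                   h$residue$p, "residue", params)
        cell$pools <- inc$pools
        r["litter_c"] <- r["litter_c"] + inc$c
        r["litter_n"] <- r["litter_n"] + inc$n
        r["litter_p"] <- r["litter_p"] + inc$p
        r["c_in"] <- r["c_in"] + inc$c
        cell$crop <- NULL
      } else {
        cell$crop <- st
      }
    }

    ## -- decomposition and mineralisation ---------------------------------
    l1 <- cell$profile[[1]]
    smd <- max(0, l1$theta_fc * l1$delta - l1$W)
    mods <- rate_modifiers(tmean, smd, max_tsmd(l1$clay, l1$delta),
                           covered = !is.null(cell$crop), params)
    stp <- decompose_pools(cell$pools, mods, l1$clay, params = params)
    pools_before <- cell$pools
    mn <- mineralise(stp, cell$pools, l1$N_NH4 + l1$N_NO3, params)
    if (mn$performed && mn$net_p < 0 &&
        -mn$net_p > l1$P_Av + l1$P_NonAv) {
      mn <- list(pools = pools_before, net_n = 0, net_p = 0, co2 = 0,
                 performed = FALSE)
    }
    cell$pools <- mn$pools
    if (mn$performed) {
      if (mn$net_n >= 0) {
        cell$profile[[1]]$N_NH4 <- cell$profile[[1]]$N_NH4 + mn$net_n
      } else {
        need <- -mn$net_n
        from_nh4 <- min(cell$profile[[1]]$N_NH4, need)
        cell$profile[[1]]$N_NH4 <- cell$profile[[1]]$N_NH4 - from_nh4
        cell$profile[[1]]$N_NO3 <- cell$profile[[1]]$N_NO3 -
          (need - from_nh4)
      }
      if (mn$net_p >= 0) {
        cell$profile[[1]]$P_Av <- cell$profile[[1]]$P_Av + mn$net_p
      } else {
        dp <- draw_immobilised_p(cell$profile[[1]], -mn$net_p)
        cell$profile[[1]] <- dp$layer
      }
    }
    r["net_min_n"] <- mn$net_n
    r["net_min_p"] <- mn$net_p
    r["co2"] <- mn$co2

    ## -- nitrification -----------------------------------------------------
    ft <- nitrif_f_t(tmean)
    for (l in seq_along(cell$profile)) {
      gm <- nitrif_g_m(cell$profile[[l]])
      nf <- nitrify(cell$profile[[l]], ft, gm, params)
      cell$profile[[l]] <- nf$layer
      r["nitrif_n2o"] <- r["nitrif_n2o"] + nf$n2o
    }

    ## -- denitrification ---------------------------------------------------
    dn <- denitrify(cell$profile, tmean, params)
    cell$profile <- dn$profile
    r["denit_n2o"] <- sum(dn$n2o)
    r["n2"] <- sum(dn$n2)
    r["n2o"] <- r["nitrif_n2o"] + r["denit_n2o"]

    ## -- leaching -----------------------------------------------------------
    ln <- leach_no3(cell$profile, f_w)
    cell$profile <- ln$profile
    r["n_leached"] <- ln$leached
    lp <- runoff_and_leach_p(cell$profile, 0, 0, f_w, params)
    cell$profile <- lp$profile
    r["p_leached"] <- lp$p_leached

    ## -- state summaries ----------------------------------------------------
    r["w_store"] <- profile_water(cell$profile)
    r["min_n_store"] <- sum(vapply(cell$profile, function(x)
      x$N_NH4 + x$N_NO3, 0))
    r["min_p_store"] <- sum(vapply(cell$profile, function(x)
      x$P_Av + x$P_NonAv, 0))
    r["toc"] <- total_toc(cell$pools)
    r["org_n"] <- sum(cell$pools$N) * 1000
    r["org_p"] <- sum(cell$pools$P) * 1000
    if (!is.null(cell$crop)) {
      r["plant_mass"] <- sum(cell$crop$mass) + cell$crop$dead_leaf
      r["plant_n"] <- (sum(cell$crop$n) + cell$crop$dead_leaf_n) * 10
      r["plant_p"] <- (sum(cell$crop$p) + cell$crop$dead_leaf_p) * 10
      r["lai"] <- crop_lai(cell$crop)
      r["dvs"] <- cell$crop$dvs
    }

    rec[ci, ] <- r
    cells[[ci]] <- cell
  }
  grid$cells <- cells
  list(grid = grid, records = rec)
}

#' Run the simulator over a weather series
#'
#' @param grid grid state
#' @param weather weather data.frame ([read_weather()] / [synth_weather()])
#' @param management management schedule ([read_management()]); applied to
#'   every cell
#' @param params model parameters
#' @param progress print a yearly progress line
#' @return list with `fluxes` (data.frame, one row per cell per day),
#'   `harvest` (rows with non-zero yield or cut), and the final `grid`
#' @export
run_simulation <- function(grid, weather, management = NULL,
                           params = landsim_params(), progress = FALSE) {
  if (is.null(management)) {
    management <- data.frame(date = as.Date(character()), kind = character(),
                             amount = numeric(), n_form = character(),
                             animal = character(), stocking = numeric(),
                             crop = character())
  }
  nd <- nrow(weather)
  nc <- length(grid$cells)
  out <- matrix(0, nrow = nd * nc, ncol = length(flux_columns),
                dimnames = list(NULL, flux_columns))
  dates <- rep(weather$date, each = nc)
  for (d in seq_len(nd)) {
    wday <- weather[d, ]
    ev <- management[management$date == wday$date, , drop = FALSE]
    stepped <- step_day(grid, wday, ev, params)
    grid <- stepped$grid
    out[((d - 1) * nc + 1):(d * nc), ] <- stepped$records
    if (progress && format(wday$date, "%m-%d") == "12-31") {
      message("completed ", format(wday$date, "%Y"))
    }
  }
  fluxes <- data.frame(date = dates, out, check.names = FALSE)
  harvest <- fluxes[fluxes$yield > 0 | fluxes$cut_dm > 0,
                    c("date", "cell", "yield", "grain_n", "grain_p",
                      "cut_dm", "removed_n", "removed_p")]
  list(fluxes = fluxes, harvest = harvest, grid = grid)
}

#' Aggregate ditch capture into catchment discharge and loads
#'
#' Converts per-cell ditch capture (mm and kg ha-1) into catchment totals:
#' discharge in m3 d-1 and nutrient loads in kg per catchment per day.
#' Field drains (layer-3 drainage and the nitrate and phosphorus it
#' carries) are included when the routing parameter
#' `field_drains_to_ditch` is set.
#'
#' @param grid grid state (areas and ditch designations)
#' @param fluxes daily flux table from [run_simulation()]
#' @param params model parameters
#' @return data.frame: date, discharge_m3, nitrate_kg, p_kg
#' @export
aggregate_catchment <- function(grid, fluxes, params = landsim_params()) {
  has_ditch <- any(vapply(grid$cells, function(cl)
    any(cl$edges == "ditch"), TRUE))
  if (!has_ditch) warning("no ditch edges in grid; discharge will be zero ",
                          "unless field drains are connected")
  areas <- vapply(grid$cells, `[[`, 0, "area")
  names(areas) <- vapply(grid$cells, function(cl) as.character(cl$id), "")
  a <- areas[as.character(fluxes$cell)]
  drains <- isTRUE(params$routing$field_drains_to_ditch)
  w_mm <- fluxes$ditch_water + if (drains) fluxes$drainage else 0
  n_kgha <- fluxes$n_ditch + if (drains) fluxes$n_leached else 0
  p_kgha <- fluxes$p_ditch + if (drains) fluxes$p_leached else 0
  agg <- stats::aggregate(
    cbind(discharge_m3 = w_mm * a / 1000,
          nitrate_kg = n_kgha * a / 10000,
          p_kg = p_kgha * a / 10000),
    by = list(date = fluxes$date), FUN = sum)
  agg
}
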
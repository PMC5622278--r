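#' Read a daily weather series
#'
#' Expects a comma-separated file with header
#' `date,tmin,tmax,rain,rad,vp,wind`; ISO dates, one row per day with no
#' gaps.  Rows violating the physical invariants (tmax >= tmin, rain >= 0,
#' rad >= 0) are rejected with the offending date named.
#'
#' @param path CSV file path
#' @return data.frame with one row per day (class `Date` in column `date`)
#' @export
read_weather <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("date", "tmin", "tmax", "rain", "rad", "vp", "wind")
  missing <- setdiff(needed, names(w))
  if (length(missing) > 0) {
    stop("weather file missing column(s): ", paste(missing, collapse = ", "))
  }
  w$date <- as.Date(w$date)
  if (anyNA(w$date)) stop("unparseable date at row ",
                          which(is.na(w$date))[1])
  num_cols <- setdiff(needed, "date")
  for (cc in num_cols) {
    w[[cc]] <- suppressWarnings(as.numeric(w[[cc]]))
    if (anyNA(w[[cc]])) {
      stop("unparseable value in column '", cc, "' at row ",
           which(is.na(w[[cc]]))[1])
    }
  }
  gaps <- which(diff(as.integer(w$date)) != 1)
  if (length(gaps) > 0) {
    stop("gap in dates after ", format(w$date[gaps[1]]))
  }
  bad <- which(w$tmax < w$tmin)
  if (length(bad) > 0) {
    stop("tmax < tmin on ", format(w$date[bad[1]]))
  }
  bad <- which(w$rain < 0 | w$rad < 0)
  if (length(bad) > 0) {
    stop("negative rain or radiation on ", format(w$date[bad[1]]))
  }
  w[needed]
}

# daily extraterrestrial radiation, MJ m-2 d-1 (FAO-56)
extraterrestrial_radiation <- function(lat_deg, doy) {
  phi <- lat_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(dec)
  ws <- acos(pmin(pmax(x, -1), 1))
  118.08 / pi * dr * (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}

#' Generate synthetic daily weather
#'
#' A seasonal stand-in for temperate maritime (SE England style) station
#' records: sinusoidal annual cycles in temperature with autocorrelated
#' daily anomalies, radiation as a cloud-modulated fraction of the
#' extraterrestrial flux, rainfall occurrence from a two-state (wet/dry)
#' Markov chain with exponentially distributed wet-day amounts, vapour
#' pressure near saturation at the daily minimum, and log-normal windspeed.
#' Reproducible for a given seed.
#'
#' @param years number of years (starting 1 January of `start_year`)
#' @param latitude degrees north
#' @param seed integer RNG seed
#' @param start_year first calendar year
#' @param annual_rain target mean annual rainfall, mm
#' @param t_mean,t_amp annual mean temperature and seasonal amplitude, deg C
#' @return weather data.frame as from [read_weather()]
#' @export
synth_weather <- function(years, latitude = 51.8, seed = 1,
                          start_year = 2000, annual_rain = 700,
                          t_mean = 9.8, t_amp = 6.3) {
  stopifnot(years >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1)), by = 1)
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  # temperature: annual wave peaking around 20 July (doy 201) + AR(1) anomaly
  base_t <- t_mean + t_amp * cos(2 * pi * (doy - 201) / 365.25)
  anom <- as.numeric(stats::filter(stats::rnorm(n, 0, 1.8), 0.7,
                                   method = "recursive"))
  tmean <- base_t + anom
  drange <- pmax(1, stats::rnorm(n, 7, 1.8))
  tmin <- tmean - drange / 2
  tmax <- tmean + drange / 2
  # rainfall: two-state Markov occurrence, exponential amounts
  p_wd <- 0.30  # dry -> wet
  p_ww <- 0.60  # wet -> wet
  wet_freq <- p_wd / (1 + p_wd - p_ww)
  mean_amount <- annual_rain / (365.25 * wet_freq)
  wet <- logical(n)
  wet[1] <- stats::runif(1) < wet_freq
  u <- stats::runif(n)
  for (i in 2:n) wet[i] <- u[i] < (if (wet[i - 1]) p_ww else p_wd)
  rain <- ifelse(wet, stats::rexp(n, 1 / mean_amount), 0)
  # radiation: clearness index lower on wet days
  ra <- extraterrestrial_radiation(latitude, doy)
  kt <- pmin(pmax(stats::rnorm(n, ifelse(wet, 0.30, 0.48), 0.08), 0.10), 0.75)
  rad <- ra * kt
  # vapour pressure ~ 95% of saturation at tmin; windspeed log-normal
  svp <- function(t) 0.611 * exp(17.4 * t / (t + 239))
  vp <- 0.95 * svp(tmin)
  wind <- stats::rlnorm(n, log(3.5), 0.4)
  data.frame(date = dates, tmin = tmin, tmax = tmax, rain = rain,
             rad = rad, vp = vp, wind = wind)
}

#' Write a weather series
#' @param weather weather data.frame
#' @param path output CSV path
#' @export
write_weather <- function(weather, path) {
  w <- weather
  w$date <- format(w$date, "%Y-%m-%d")
  utils::write.csv(w, path, row.names = FALSE, quote = FALSE)
}

#' Read a management schedule
#'
#' CSV with columns `date,kind,amount,n_form,animal,stocking`.  `kind` is
#' one of sow, fertilise_N, fertilise_P, apply_FYM, cut, graze_start,
#' graze_stop, harvest, fallow; `amount` is kg N ha-1, kg P ha-1 or t fresh
#' FYM ha-1 according to kind; `n_form` (ammonium, nitrate,
#' ammonium_nitrate) is required exactly for fertilise_N rows.
#'
#' @param path CSV file path
#' @return validated data.frame ordered by date
#' @export
read_management <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_management(m)
}

validate_management <- function(m) {
  kinds <- c("sow", "fertilise_N", "fertilise_P", "apply_FYM", "cut",
             "graze_start", "graze_stop", "harvest", "fallow")
  needed <- c("date", "kind")
  missing <- setdiff(needed, names(m))
  if (length(missing) > 0) {
    stop("management missing column(s): ", paste(missing, collapse = ", "))
  }
  nr <- nrow(m)
  if (!"amount" %in% names(m)) m$amount <- rep(0, nr)
  if (!"n_form" %in% names(m)) m$n_form <- rep(NA_character_, nr)
  if (!"animal" %in% names(m)) m$animal <- rep(NA_character_, nr)
  if (!"stocking" %in% names(m)) m$stocking <- rep(NA_real_, nr)
  if (!"crop" %in% names(m)) m$crop <- rep(NA_character_, nr)
  m$date <- as.Date(m$date)
  if (anyNA(m$date)) stop("unparseable management date")
  bad <- setdiff(unique(m$kind), kinds)
  if (length(bad) > 0) stop("unknown management kind: ",
                            paste(bad, collapse = ", "))
  m$amount[is.na(m$amount)] <- 0
  if (any(m$amount < 0)) stop("management amounts must be >= 0")
  fn <- m$kind == "fertilise_N"
  if (any(fn & (is.na(m$n_form) | !m$n_form %in%
                c("ammonium", "nitrate", "ammonium_nitrate")))) {
    stop("fertilise_N events need n_form in ",
         "{ammonium, nitrate, ammonium_nitrate}")
  }
  if (any(!fn & !is.na(m$n_form))) {
    stop("n_form present on a non-fertilise_N event")
  }
  m[order(m$date), ]
}

#' Write / read a run-output flux table
#'
#' Plain CSV round trip for the per-cell per-day output of
#' [run_simulation()]; numeric columns survive to better than 1e-9 relative.
#'
#' @param fluxes data.frame of daily outputs
#' @param path CSV path
#' @export
write_fluxes <- function(fluxes, path) {
  f <- fluxes
  if ("date" %in% names(f)) f$date <- format(f$date, "%Y-%m-%d")
  utils::write.csv(format(f, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_fluxes
#' @return data.frame
#' @export
read_fluxes <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(f)) f$date <- as.Date(f$date)
  f
}

# annual management template for one cell, replicated over simulation years
schedule_events <- function(years, template) {
  out <- do.call(rbind, lapply(years, function(y) {
    tm <- template
    tm$date <- as.Date(sprintf("%d-%s", y + tm$year_offset, tm$md))
    tm$year_offset <- NULL
    tm$md <- NULL
    tm
  }))
  validate_management(out)
}

#' Ready-to-run fixture farms
#'
#' Synthetic single-plot and small-catchment configurations patterned on
#' classical long-term experiment layouts:
#' \describe{
#'   \item{broadbalk_like_plot}{one cell of continuous winter wheat on a
#'     silty clay loam; an annual spring N dressing from the ladder
#'     0/48/96/144/192/240/288 kg N ha-1 (argument `n_rate`), 35 kg P ha-1
#'     in autumn, or FYM at 35 t ha-1 fresh (`fym = TRUE`).}
#'   \item{park_grass_like_plot}{one cell of permanent grassland, cut
#'     mid-June and early November, 96 kg N ha-1 as nitrate each spring and
#'     35 kg P ha-1 each autumn.}
#'   \item{two_cell_slope}{two grass cells on a slope; the upper drains into
#'     the lower, whose downhill edge is a ditch.}
#'   \item{catchment_3x3}{a 3 x 3 inclined plane of grassland draining to a
#'     ditch along the lowest edge, with field drains connected.}
#' }
#'
#' @param preset preset name
#' @param n_rate annual fertiliser N, kg N ha-1 (broadbalk_like_plot)
#' @param fym logical: replace mineral N with 35 t ha-1 FYM
#' @param years integer vector of calendar years to schedule
#' @param params model parameters
#' @return list(grid, management, params) ready for [run_simulation()]
#' @export
build_fixture_farm <- function(preset = c("broadbalk_like_plot",
                                          "park_grass_like_plot",
                                          "two_cell_slope",
                                          "catchment_3x3"),
                               n_rate = 144, fym = FALSE,
                               years = 2001:2005,
                               params = landsim_params()) {
  preset <- match.arg(preset)
  scl_profile <- function() list(
    new_soil_layer(230, clay = 25, silt = 55, ph = 7, bulk_density = 1.30,
                   toc_pct = 1.1, n_nh4 = 1, n_no3 = 8, p_av = 120,
                   p_nonav = 1000, topsoil = TRUE),
    new_soil_layer(230, clay = 28, silt = 54, ph = 7, bulk_density = 1.45,
                   toc_pct = 0.5, n_nh4 = 0.5, n_no3 = 4, p_av = 40,
                   p_nonav = 600),
    new_soil_layer(230, clay = 30, silt = 52, ph = 7, bulk_density = 1.50,
                   toc_pct = 0.3, n_nh4 = 0.2, n_no3 = 2, p_av = 20,
                   p_nonav = 400))
  # plant-material pool stoichiometry near the long-run residue input
  # (C:N ~ 30, C:P ~ 300) so the pools neither flush nor lock up mineral N
  wheat_pools <- new_organic_pools(
    c_stocks = c(DPM = 0.4, RPM = 4.5, BIO = 0.9, HUM = 24), iom = 2.7,
    cn_dpm = 30, cn_rpm = 30, cp_dpm = 300, cp_rpm = 300)
  grass_pools <- new_organic_pools(
    c_stocks = c(DPM = 0.8, RPM = 9, BIO = 1.8, HUM = 55), iom = 4,
    cn_dpm = 25, cn_rpm = 25, cp_dpm = 250, cp_rpm = 250)

  if (preset == "broadbalk_like_plot") {
    events <- data.frame(
      md = c("10-15", "04-15", "09-20", "08-15"),
      year_offset = c(0, 1, 0, 1),
      kind = c("sow", if (fym) "apply_FYM" else "fertilise_N",
               "fertilise_P", "harvest"),
      amount = c(0, if (fym) 35 else n_rate, 35, 0),
      n_form = c(NA, if (fym) NA else "ammonium_nitrate", NA, NA),
      crop = c("wheat", NA, NA, NA))
    if (!fym && n_rate == 0) events <- events[events$kind != "fertilise_N", ]
    mgmt <- schedule_events(years, events)
    grid <- new_grid(list(new_cell(id = 1, area = 10000, elevation = 100,
                                   profile = scl_profile(),
                                   pools = wheat_pools)))
  } else if (preset == "park_grass_like_plot") {
    events <- data.frame(
      md = c("04-01", "06-15", "11-05", "09-20"),
      year_offset = 0,
      kind = c("fertilise_N", "cut", "cut", "fertilise_P"),
      amount = c(96, 0, 0, 35),
      n_form = c("nitrate", NA, NA, NA),
      crop = NA)
    mgmt <- schedule_events(years, events)
    cell <- new_cell(id = 1, area = 10000, elevation = 100,
                     profile = scl_profile(), pools = grass_pools,
                     crop = new_crop_state(crop_params("grass")))
    cell$crop$dvs <- 0.5
    cell$crop$age <- 400
    grid <- new_grid(list(cell))
  } else if (preset == "two_cell_slope") {
    mgmt <- schedule_events(years, data.frame(
      md = "04-01", year_offset = 0, kind = "fertilise_N", amount = 50,
      n_form = "ammonium_nitrate", crop = NA))
    upper <- new_cell(id = 1, area = 10000, elevation = 105,
                      profile = scl_profile(), pools = grass_pools,
                      crop = new_crop_state(crop_params("grass")))
    lower <- new_cell(id = 2, area = 10000, elevation = 100,
                      profile = scl_profile(), pools = grass_pools,
                      crop = new_crop_state(crop_params("grass")))
    upper$neighbours <- c(S = 2)
    lower$neighbours <- c(N = 1)
    lower$edges["S"] <- "ditch"
    grid <- new_grid(list(upper, lower), cell_size = 100)
  } else { # catchment_3x3
    cells <- list()
    id <- 0
    for (r in 1:3) for (cc in 1:3) {
      id <- id + 1
      cell <- new_cell(id = id, area = 21 * 10000 / 9,
                       elevation = 100 + (3 - r) * 3,
                       profile = scl_profile(), pools = grass_pools,
                       crop = new_crop_state(crop_params("grass")))
      nb <- c()
      if (r > 1) nb["N"] <- id - 3
      if (r < 3) nb["S"] <- id + 3
      if (cc > 1) nb["W"] <- id - 1
      if (cc < 3) nb["E"] <- id + 1
      cell$neighbours <- nb
      if (r == 3) cell$edges["S"] <- "ditch"
      cells[[id]] <- cell
    }
    mgmt <- schedule_events(years, data.frame(
      md = c("04-01", "06-15"), year_offset = 0,
      kind = c("fertilise_N", "cut"), amount = c(80, 0),
      n_form = c("ammonium_nitrate", NA), crop = NA))
    for (i in seq_along(cells)) {
      cells[[i]]$crop$dvs <- 0.5
      cells[[i]]$crop$age <- 400
    }
    grid <- new_grid(cells, cell_size = sqrt(21 * 10000 / 9))
  }
  list(grid = grid, management = mgmt, params = params)
}

#' Read or write a full run configuration
#'
#' A single structured YAML document holding the model constants (any
#' subset of [landsim_params()] to override), per-layer soil initial state,
#' grid topology and elevations.  Validated on load.
#'
#' @param path YAML file
#' @return list(params, grid)
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  params <- do.call(landsim_params, cfg$params %||% list())
  cells <- lapply(cfg$cells, function(cl) {
    profile <- lapply(seq_along(cl$layers), function(i) {
      do.call(new_soil_layer, c(cl$layers[[i]], list(topsoil = (i == 1))))
    })
    pools <- if (!is.null(cl$pools)) do.call(new_organic_pools,
      c(list(c_stocks = unlist(cl$pools$c_stocks)), cl$pools[-1])) else
      new_organic_pools()
    crop <- if (!is.null(cl$crop)) new_crop_state(crop_params(cl$crop)) else NULL
    cell <- new_cell(id = cl$id, area = cl$area %||% 10000,
                     elevation = cl$elevation %||% 100,
                     profile = profile, pools = pools, crop = crop)
    if (!is.null(cl$neighbours)) cell$neighbours <- unlist(cl$neighbours)
    if (!is.null(cl$edges)) cell$edges[names(cl$edges)] <- unlist(cl$edges)
    cell
  })
  list(params = params, grid = new_grid(cells))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
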
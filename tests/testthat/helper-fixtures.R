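# shared builders for small in-code fixtures

mk_layer <- function(...) new_soil_layer(...)

# a single calm weather day
mk_day <- function(date = as.Date("2001-06-01"), tmin = 8, tmax = 18,
                   rain = 0, rad = 15, vp = 1.0, wind = 3) {
  data.frame(date = date, tmin = tmin, tmax = tmax, rain = rain, rad = rad,
             vp = vp, wind = wind)
}

# n days of constant weather starting at `start`
mk_weather_run <- function(n, start = as.Date("2001-01-01"), ...) {
  out <- do.call(rbind, lapply(seq_len(n) - 1, function(i) {
    mk_day(date = start + i, ...)
  }))
  out
}

# per-cell audit of the daily closure of a conserved quantity.
# fluxes: one cell's rows in date order; returns max abs daily error.
max_daily_closure <- function(fc, initial_store, store_col, in_cols,
                              out_cols) {
  store <- c(initial_store, fc[[store_col]])
  d_store <- diff(store)
  inp <- rowSums(fc[, in_cols, drop = FALSE])
  out <- rowSums(fc[, out_cols, drop = FALSE])
  max(abs(inp - out - d_store))
}

water_closure <- function(fc, w0) {
  max_daily_closure(fc, w0, "w_store", c("rain", "lat_in"),
                    c("runoff", "drainage", "evaporation", "transpiration"))
}

minn_closure <- function(fc, n0) {
  max_daily_closure(fc, n0, "min_n_store",
                    c("fert_n", "dep_n", "net_min_n", "n_lat_in"),
                    c("n_runoff", "n_leached", "n2o", "n2", "uptake_n"))
}

minp_closure <- function(fc, p0) {
  max_daily_closure(fc, p0, "min_p_store",
                    c("fert_p", "net_min_p", "p_lat_in"),
                    c("p_runoff", "p_leached", "uptake_p"))
}

carbon_closure <- function(fc, toc0) {
  max_daily_closure(fc, toc0, "toc", "c_in", "co2")
}

initial_stores <- function(cell) {
  list(w = profile_water(cell$profile),
       n = sum(vapply(cell$profile, function(x) x$N_NH4 + x$N_NO3, 0)),
       p = sum(vapply(cell$profile, function(x) x$P_Av + x$P_NonAv, 0)),
       toc = total_toc(cell$pools))
}
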
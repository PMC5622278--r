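#' Construct the organic matter pools
#'
#' Four active RothC-style pools (DPM, RPM, BIO, HUM) plus inert organic
#' matter (IOM), each carrying carbon with paired nitrogen and phosphorus
#' stocks.  BIO and HUM hold fixed stoichiometry (C:N 8.5; C:P 50 and 100);
#' DPM and RPM ratios float with the stored stocks.
#'
#' @param c_stocks named numeric, t C ha-1 for DPM, RPM, BIO, HUM
#' @param iom inert organic matter, t C ha-1
#' @param cn_dpm,cn_rpm initial C:N of the plant-material pools
#' @param cp_dpm,cp_rpm initial C:P of the plant-material pools
#' @param params model parameters
#' @return organic pools list: matrices-free named numerics `C`, `N`, `P`
#'   and scalar `IOM`
#' @export
new_organic_pools <- function(c_stocks = c(DPM = 0.5, RPM = 5, BIO = 1,
                                           HUM = 30),
                              iom = 2.5, cn_dpm = 40, cn_rpm = 100,
                              cp_dpm = 200, cp_rpm = 500,
                              params = landsim_params()) {
  stopifnot(all(c_stocks >= 0), iom >= 0)
  po <- params$organic
  C <- c_stocks[c("DPM", "RPM", "BIO", "HUM")]
  N <- c(DPM = unname(C["DPM"]) / cn_dpm, RPM = unname(C["RPM"]) / cn_rpm,
         BIO = unname(C["BIO"]) / po$cn_bio, HUM = unname(C["HUM"]) / po$cn_hum)
  P <- c(DPM = unname(C["DPM"]) / cp_dpm, RPM = unname(C["RPM"]) / cp_rpm,
         BIO = unname(C["BIO"]) / po$cp_bio, HUM = unname(C["HUM"]) / po$cp_hum)
  list(C = C, N = N, P = P, IOM = iom)
}

#' Total organic carbon of a pool set (active pools plus IOM), t C ha-1
#' @param pools organic pools
#' @return t C ha-1
#' @export
total_toc <- function(pools) sum(pools$C) + pools$IOM

#' RothC rate-modifying factors
#'
#' Temperature factor `47.91 / (1 + exp(106.06 / (T + 18.27)))` (zero at or
#' below -18.27 deg C), the topsoil moisture-deficit factor ranging 0.2-1,
#' and the plant-retainment (soil cover) factor: 0.6 under vegetation, 1.0
#' for bare soil.
#'
#' @param temp air temperature, deg C
#' @param smd topsoil moisture deficit below field capacity, mm (>= 0)
#' @param max_smd maximum attainable deficit for this soil, mm
#' @param covered logical, is the soil vegetated
#' @param params model parameters
#' @return named numeric (f_T, f_M, f_cover)
#' @export
rate_modifiers <- function(temp, smd, max_smd, covered,
                           params = landsim_params()) {
  f_t <- if (temp <= -18.27) 0 else 47.91 / (1 + exp(106.06 / (temp + 18.27)))
  smd <- max(0, min(smd, max_smd))
  thresh <- 0.444 * max_smd
  f_m <- if (smd <= thresh || max_smd <= 0) 1
         else 0.2 + 0.8 * (max_smd - smd) / (max_smd - thresh)
  f_c <- if (covered) params$organic$fcov_vegetated else params$organic$fcov_bare
  c(f_T = f_t, f_M = f_m, f_cover = f_c)
}

# maximum topsoil moisture deficit (mm) from clay content and layer depth,
# following the RothC convention for a 230 mm topsoil; halved exposure for
# bare soil is handled by the caller via f_cover, not here.
max_tsmd <- function(clay, delta = 230) {
  (20 + 1.3 * clay - 0.01 * clay^2) * delta / 230
}

# RothC clay response: ratio x of CO2 to (BIO+HUM) -> CO2 share = x/(x+1)
rothc_clay_x <- function(clay) 1.67 * (1.85 + 1.60 * exp(-0.0786 * clay))

#' One day of first-order decomposition
#'
#' Each active pool decomposes as
#' `C_i (1 - exp(-k_i f_T f_M f_cover / 365))`; the decomposed carbon is
#' split between CO2 and (BIO + HUM) by the clay response, with the
#' BIO:HUM share fixed at 46:54.
#'
#' @param pools organic pools
#' @param modifiers output of [rate_modifiers()]
#' @param clay topsoil clay percent
#' @param dt days
#' @param params model parameters
#' @return decomposition step: per-pool `delta` (C decomposed), `bio`, `hum`,
#'   `co2` (its fates), all t C ha-1
#' @export
decompose_pools <- function(pools, modifiers, clay, dt = 1,
                      params = landsim_params()) {
  po <- params$organic
  f <- modifiers["f_T"] * modifiers["f_M"] * modifiers["f_cover"]
  delta <- pools$C * (1 - exp(-po$k[names(pools$C)] * f * dt / 365))
  x <- rothc_clay_x(clay)
  co2_share <- x / (x + 1)
  co2 <- delta * co2_share
  formed <- delta - co2
  list(delta = delta,
       bio = formed * po$bio_hum_split["BIO"],
       hum = formed * po$bio_hum_split["HUM"],
       co2 = co2,
       modifiers = modifiers)
}

#' Apply a decomposition step: mineralisation or immobilisation
#'
#' The N mineralised from pool i is `delta_i / rho_i - B_i / rho_BIO -
#' U_i / rho_HUM` (and identically for P with C:P ratios).  A positive sum
#' adds mineral N as ammonium; a negative sum immobilises, drawing ammonium
#' before nitrate.  If the required immobilisation exceeds the mineral N
#' available, the whole day's decomposition is cancelled.  P immobilisation
#' draws available then non-available P and never halts decomposition.
#'
#' @param step output of [decompose_pools()]
#' @param pools organic pools
#' @param mineral_n_available total NH4 + NO3, kg N ha-1
#' @param params model parameters
#' @return list(pools, net_n, net_p, co2, performed); `net_n`/`net_p` in
#'   kg ha-1 d-1 (positive = mineralisation), `co2` in t C ha-1
#' @export
mineralise <- function(step, pools, mineral_n_available,
                       params = landsim_params()) {
  po <- params$organic
  rho_n <- pools$C / pools$N
  rho_p <- pools$C / pools$P
  rho_n[!is.finite(rho_n)] <- Inf   # empty pool decomposes nothing anyway
  rho_p[!is.finite(rho_p)] <- Inf

  n_out <- step$delta / rho_n              # N leaving each pool (t ha-1)
  n_out[step$delta == 0] <- 0
  p_out <- step$delta / rho_p
  p_out[step$delta == 0] <- 0
  bio_n_in <- sum(step$bio) / po$cn_bio
  hum_n_in <- sum(step$hum) / po$cn_hum
  bio_p_in <- sum(step$bio) / po$cp_bio
  hum_p_in <- sum(step$hum) / po$cp_hum

  net_n_t <- sum(n_out) - bio_n_in - hum_n_in   # t N ha-1
  net_p_t <- sum(p_out) - bio_p_in - hum_p_in
  net_n <- net_n_t * 1000                        # kg
  net_p <- net_p_t * 1000

  if (net_n < 0 && -net_n > mineral_n_available) {
    return(list(pools = pools, net_n = 0, net_p = 0, co2 = 0,
                performed = FALSE))
  }

  pools$C <- pools$C - step$delta
  pools$C["BIO"] <- pools$C["BIO"] + sum(step$bio)
  pools$C["HUM"] <- pools$C["HUM"] + sum(step$hum)
  pools$N <- pools$N - n_out
  pools$N["BIO"] <- pools$N["BIO"] + bio_n_in
  pools$N["HUM"] <- pools$N["HUM"] + hum_n_in
  pools$P <- pools$P - p_out
  pools$P["BIO"] <- pools$P["BIO"] + bio_p_in
  pools$P["HUM"] <- pools$P["HUM"] + hum_p_in

  list(pools = pools, net_n = net_n, net_p = net_p,
       co2 = sum(step$co2), performed = TRUE)
}

#' Add fresh organic carbon (residue or farmyard manure)
#'
#' Residue carbon splits DPM:RPM 59:41; FYM splits DPM:RPM:HUM 49:49:2.
#' Because HUM stoichiometry is fixed, the HUM share of an FYM addition
#' carries N and P at the HUM ratios and the remainder of the input N and P
#' goes to DPM and RPM in proportion to their carbon shares, so each
#' receiving pool ends at the stock-weighted mixture of old and new
#' material.
#'
#' @param pools organic pools
#' @param c_amount t C ha-1 added
#' @param source "residue" or "fym"
#' @param cn,cp C:N and C:P ratio of the input material
#' @param params model parameters
#' @return updated pools
#' @export
add_organic_input <- function(pools, c_amount, source = c("residue", "fym"),
                              cn, cp, params = landsim_params()) {
  source <- match.arg(source)
  stopifnot(c_amount >= 0)
  if (c_amount == 0) return(pools)
  if (cn <= 0 || cp <= 0) stop("input C:N and C:P ratios must be positive")
  po <- params$organic
  if (source == "residue") {
    split <- c(po$dpm_rpm_residue, HUM = 0)
  } else {
    split <- po$fym_split[c("DPM", "RPM", "HUM")]
  }
  c_in <- c_amount * split
  n_in_total <- c_amount / cn
  p_in_total <- c_amount / cp
  hum_n <- unname(c_in["HUM"]) / po$cn_hum
  hum_p <- unname(c_in["HUM"]) / po$cp_hum
  if (hum_n > n_in_total || hum_p > p_in_total) {
    stop("input stoichiometry too wide to satisfy the humus share")
  }
  rest <- c_in[c("DPM", "RPM")] / sum(c_in[c("DPM", "RPM")])
  n_in <- c((n_in_total - hum_n) * rest, HUM = hum_n)
  p_in <- c((p_in_total - hum_p) * rest, HUM = hum_p)
  for (pool in c("DPM", "RPM", "HUM")) {
    pools$C[pool] <- pools$C[pool] + c_in[pool]
    pools$N[pool] <- pools$N[pool] + n_in[pool]
    pools$P[pool] <- pools$P[pool] + p_in[pool]
  }
  pools
}

# Build the affine one-year map C -> A C + s*b of the active pools under a
# repeating daily modifier series and a daily C input pattern (t C ha-1 d-1
# at unit scale, split DPM:RPM by `split`).  Used by the spin-up.
annual_pool_map <- function(modifier_series, clay, input_pattern, split,
                            params = landsim_params()) {
  po <- params$organic
  x <- rothc_clay_x(clay)
  co2_share <- x / (x + 1)
  form <- 1 - co2_share
  step1 <- function(C, day) {
    f <- modifier_series[day, "f_T"] * modifier_series[day, "f_M"] *
      modifier_series[day, "f_cover"]
    delta <- C * (1 - exp(-po$k * f / 365))
    formed <- sum(delta) * form
    C <- C - delta
    C["BIO"] <- C["BIO"] + formed * po$bio_hum_split["BIO"]
    C["HUM"] <- C["HUM"] + formed * po$bio_hum_split["HUM"]
    C["DPM"] <- C["DPM"] + input_pattern[day] * split["DPM"]
    C["RPM"] <- C["RPM"] + input_pattern[day] * split["RPM"]
    C
  }
  run_year <- function(C) {
    for (d in seq_len(nrow(modifier_series))) C <- step1(C, d)
    C
  }
  zero <- c(DPM = 0, RPM = 0, BIO = 0, HUM = 0)
  b <- run_year(zero)
  A <- matrix(0, 4, 4, dimnames = list(names(zero), names(zero)))
  for (j in 1:4) {
    e <- zero; e[j] <- 1
    # inputs are affine: column j of A is run(e) - b
    A[, j] <- run_year(e) - b
  }
  list(A = A, b = b)
}

#' Spin the organic pools up to an equilibrium matching a target TOC
#'
#' Scales the magnitude of the annual plant-carbon input (bisection) until
#' the steady state of the active pools plus IOM matches the target total
#' organic carbon within 0.1 percent.  The steady state for a candidate
#' input scale is the fixed point of the affine one-year pool map built from
#' a repeating year of rate modifiers.  N and P pools are then set from the
#' equilibrium carbon and the pool stoichiometry.
#'
#' @param target_toc t C ha-1 (must exceed `iom`)
#' @param modifier_series matrix with columns f_T, f_M, f_cover; one row per
#'   day of a representative year
#' @param input_pattern daily relative C-input pattern (length = rows of the
#'   modifier series; internally normalised to sum to 1)
#' @param clay topsoil clay percent
#' @param iom inert organic matter t C ha-1
#' @param cn_input,cp_input stoichiometry of the plant input
#' @param params model parameters
#' @return list(pools, annual_input) where `annual_input` is t C ha-1 yr-1
#' @export
spinup_to_equilibrium <- function(target_toc, modifier_series, input_pattern,
                                  clay, iom, cn_input = 40, cp_input = 200,
                                  params = landsim_params()) {
  if (target_toc <= iom) stop("target TOC must exceed the inert pool")
  split <- c(params$organic$dpm_rpm_residue, HUM = 0)
  input_pattern <- input_pattern / sum(input_pattern)
  map <- annual_pool_map(modifier_series, clay, input_pattern, split, params)
  steady_active <- function(scale) {
    solve(diag(4) - map$A, scale * map$b)
  }
  f <- function(scale) sum(steady_active(scale)) + iom - target_toc
  lo <- 0; hi <- 1
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e6) stop("equilibrium target unreachable")
  }
  scale <- hi
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm < 0) lo <- mid else hi <- mid
    scale <- mid
    if (abs(fm) < 1e-5 * target_toc) break
  }
  Cs <- steady_active(scale)
  names(Cs) <- c("DPM", "RPM", "BIO", "HUM")
  pools <- new_organic_pools(c_stocks = Cs, iom = iom,
                             cn_dpm = cn_input, cn_rpm = cn_input,
                             cp_dpm = cp_input, cp_rpm = cp_input,
                             params = params)
  list(pools = pools, annual_input = scale)
}
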
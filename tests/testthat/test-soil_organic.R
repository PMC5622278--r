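test_that("rate modifiers reproduce the published functional forms", {
  m <- rate_modifiers(9.25, smd = 0, max_smd = 48, covered = FALSE)
  expect_equal(unname(m["f_T"]), 0.9944404731497349, tolerance = 1e-9)
  expect_equal(unname(m["f_M"]), 1)
  expect_equal(unname(m["f_cover"]), 1.0)
  expect_equal(unname(rate_modifiers(10, 0, 48, TRUE)["f_cover"]), 0.6)
  expect_equal(unname(rate_modifiers(-20, 0, 48, TRUE)["f_T"]), 0)
  # moisture factor bottoms out at 0.2 at the maximum deficit
  expect_equal(unname(rate_modifiers(10, 48, 48, TRUE)["f_M"]), 0.2)
})

test_that("first-order decay and the clay split follow the pool model", {
  pools <- new_organic_pools(c_stocks = c(DPM = 1, RPM = 0, BIO = 0, HUM = 0),
                             iom = 0)
  mods <- c(f_T = 1, f_M = 1, f_cover = 1)
  for (i in 1:365) {
    stp <- decompose_pools(pools, mods, clay = 25)
    pools <- mineralise(stp, pools, 1e6)$pools
  }
  # daily exp(-k/365) compounds to exactly exp(-k) over a year
  expect_equal(unname(pools$C["DPM"]), exp(-10), tolerance = 1e-9)

  zero <- decompose_pools(new_organic_pools(), c(f_T = 0, f_M = 1,
                                                 f_cover = 1), 25)
  expect_true(all(zero$delta == 0))

  # CO2 share x/(x+1) from the clay response, approaching the high-clay limit
  stp <- decompose_pools(new_organic_pools(), mods, clay = 23)
  x <- 1.67 * (1.85 + 1.60 * exp(-0.0786 * 23))
  expect_equal(sum(stp$co2) / sum(stp$delta), x / (x + 1), tolerance = 1e-9)
  stp_hi <- decompose_pools(new_organic_pools(), mods, clay = 1e6)
  x_inf <- 1.67 * 1.85
  expect_equal(sum(stp_hi$co2) / sum(stp_hi$delta), x_inf / (x_inf + 1),
               tolerance = 1e-9)
})

test_that("net mineralisation follows pool stoichiometry and halts when
           immobilisation exceeds mineral N", {
  # hand-constructed decomposition step: 10 t C leaves DPM, 2 t to BIO,
  # 2 t to HUM, remainder CO2
  mk_step <- function() list(
    delta = c(DPM = 10, RPM = 0, BIO = 0, HUM = 0),
    bio = c(DPM = 2, RPM = 0, BIO = 0, HUM = 0),
    hum = c(DPM = 2, RPM = 0, BIO = 0, HUM = 0),
    co2 = c(DPM = 6, RPM = 0, BIO = 0, HUM = 0))
  pools <- new_organic_pools(c_stocks = c(DPM = 20, RPM = 0, BIO = 0,
                                          HUM = 0), iom = 0, cn_dpm = 10)
  out <- mineralise(mk_step(), pools, mineral_n_available = 1e6)
  expect_true(out$performed)
  expect_equal(out$net_n, (10 / 10 - 2 / 8.5 - 2 / 8.5) * 1000,
               tolerance = 1e-9)

  wide <- new_organic_pools(c_stocks = c(DPM = 20, RPM = 0, BIO = 0,
                                         HUM = 0), iom = 0, cn_dpm = 80)
  out2 <- mineralise(mk_step(), wide, mineral_n_available = 1e6)
  expect_equal(out2$net_n, (10 / 80 - 4 / 8.5) * 1000, tolerance = 1e-9)
  expect_lt(out2$net_n, 0)
  halted <- mineralise(mk_step(), wide, mineral_n_available = 0.1)
  expect_false(halted$performed)
  expect_equal(halted$pools, wide)
  expect_equal(halted$net_n, 0)

  none <- mineralise(list(delta = c(DPM = 0, RPM = 0, BIO = 0, HUM = 0),
                          bio = c(DPM = 0, RPM = 0, BIO = 0, HUM = 0),
                          hum = c(DPM = 0, RPM = 0, BIO = 0, HUM = 0),
                          co2 = c(DPM = 0, RPM = 0, BIO = 0, HUM = 0)),
                     pools, 1e6)
  expect_equal(none$net_n, 0)
  expect_equal(none$net_p, 0)
})

test_that("organic inputs mix into pool stoichiometry harmonically", {
  empty <- new_organic_pools(c_stocks = c(DPM = 0, RPM = 0, BIO = 0,
                                          HUM = 0), iom = 0)
  same <- add_organic_input(empty, 0, "residue", cn = 40, cp = 200)
  expect_equal(same, empty)

  one <- add_organic_input(empty, 1, "residue", cn = 40, cp = 200)
  expect_equal(unname(one$C["DPM"] / one$N["DPM"]), 40, tolerance = 1e-9)
  expect_equal(unname(one$C["RPM"] / one$N["RPM"]), 40, tolerance = 1e-9)

  two <- add_organic_input(empty, 1, "residue", cn = 20, cp = 200)
  two <- add_organic_input(two, 1, "residue", cn = 60, cp = 200)
  # N stocks add as C/ratio: pooled C:N = 2 / (1/20 + 1/60) = 30
  expect_equal(unname(sum(two$C[c("DPM", "RPM")]) /
                        sum(two$N[c("DPM", "RPM")])), 30, tolerance = 1e-9)

  expect_error(add_organic_input(empty, 1, "residue", cn = 0, cp = 200))
})

test_that("BIO and HUM stoichiometry never drifts under turnover", {
  pools <- new_organic_pools()
  set.seed(11)
  for (i in 1:150) {
    mods <- c(f_T = runif(1, 0, 3), f_M = runif(1, 0.2, 1),
              f_cover = sample(c(0.6, 1), 1))
    stp <- decompose_pools(pools, mods, clay = 25)
    pools <- mineralise(stp, pools, 1e6)$pools
    if (i %% 10 == 0) {
      pools <- add_organic_input(pools, runif(1, 0, 0.05),
                                 sample(c("residue", "fym"), 1),
                                 cn = runif(1, 15, 60), cp = runif(1, 80, 400))
    }
    expect_equal(unname(pools$C["BIO"] / pools$N["BIO"]), 8.5,
                 tolerance = 1e-9)
    expect_equal(unname(pools$C["HUM"] / pools$N["HUM"]), 8.5,
                 tolerance = 1e-9)
    expect_equal(unname(pools$C["BIO"] / pools$P["BIO"]), 50,
                 tolerance = 1e-9)
    expect_equal(unname(pools$C["HUM"] / pools$P["HUM"]), 100,
                 tolerance = 1e-9)
  }
})

test_that("daily carbon balance closes to 1e-9", {
  pools <- new_organic_pools()
  mods <- c(f_T = 1.2, f_M = 0.8, f_cover = 0.6)
  for (i in 1:200) {
    before <- total_toc(pools)
    stp <- decompose_pools(pools, mods, clay = 25)
    out <- mineralise(stp, pools, 1e6)
    pools <- out$pools
    input <- if (i %% 7 == 0) 0.02 else 0
    if (input > 0) pools <- add_organic_input(pools, input, "residue",
                                              cn = 35, cp = 250)
    expect_lt(abs(input - out$co2 - (total_toc(pools) - before)), 1e-9)
  }
})

test_that("spin-up recovers a known input and sits at a fixed point", {
  w <- synth_weather(1, seed = 2, start_year = 2001)
  tmean <- (w$tmin + w$tmax) / 2
  mods <- t(vapply(seq_len(365), function(i)
    rate_modifiers(tmean[i], smd = 10, max_smd = 48, covered = TRUE),
    c(f_T = 0, f_M = 0, f_cover = 0)))
  pattern <- rep(1, 365)

  # forward-run oracle: steady state of a known input, used as the target
  known <- 2.0
  map <- landsim:::annual_pool_map(mods, 25, pattern / sum(pattern),
                                   c(DPM = 0.59, RPM = 0.41, HUM = 0))
  steady <- solve(diag(4) - map$A, known * map$b)
  target <- sum(steady) + 2.7

  sp <- spinup_to_equilibrium(target, mods, pattern, clay = 25, iom = 2.7)
  expect_lt(abs(sp$annual_input - known) / known, 0.01)
  expect_lt(abs(total_toc(sp$pools) - target) / target, 0.001)

  # doubling inputs from equilibrium raises TOC monotonically
  pools <- sp$pools
  toc_path <- numeric(0)
  for (y in 1:3) {
    for (d in 1:365) {
      stp <- decompose_pools(pools, mods[d, ], 25)
      pools <- mineralise(stp, pools, 1e6)$pools
      pools <- add_organic_input(pools, 2 * sp$annual_input / 365, "residue",
                                 cn = 40, cp = 200)
    }
    toc_path <- c(toc_path, total_toc(pools))
  }
  expect_true(all(diff(c(total_toc(sp$pools), toc_path)) > 0))
  expect_error(spinup_to_equilibrium(2.0, mods, pattern, clay = 25,
                                     iom = 2.7))
})
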
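test_that("development accumulates thermal time and grass never flowers", {
  cp <- crop_params("wheat")
  cp$vern_days <- 0
  cp$tsum1 <- 1000
  st <- new_crop_state(cp)
  cold <- mk_day(tmin = -6, tmax = -2)
  expect_equal(develop(st, cold)$dvs, 0)

  # fixed 20 degree days: anthesis exactly at tsum1 / 20 days
  warm <- mk_day(tmin = 15, tmax = 25)
  for (i in 1:49) st <- develop(st, warm)
  expect_lt(st$dvs, 1)
  st <- develop(st, warm)
  expect_gte(st$dvs, 1)

  gr <- new_crop_state(crop_params("grass"))
  gr$dvs <- 0.999
  for (i in 1:30) gr <- develop(gr, warm)
  expect_lt(gr$dvs, 1)
})

test_that("vernalisation delays pre-anthesis development", {
  cp <- crop_params("wheat")
  st_v <- new_crop_state(cp)
  cp0 <- cp; cp0$vern_days <- 0
  st_0 <- new_crop_state(cp0)
  warm <- mk_day(tmin = 8, tmax = 16)
  for (i in 1:40) { st_v <- develop(st_v, warm); st_0 <- develop(st_0, warm) }
  expect_lt(st_v$dvs, st_0$dvs)
})

test_that("root distribution matches the exponential profile", {
  b <- c(0, 230, 460, 690)
  expect_equal(root_distribution(100, b), c(1, 0, 0))
  got <- root_distribution(690, b)
  expect_equal(got, c(0.7434267738168462, 0.2017970731496765,
                      0.054776153033477305), tolerance = 1e-9)
  for (d in c(150, 400, 690, 1200)) {
    f <- root_distribution(d, b)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(diff(f) <= 1e-12))
  }
})

test_that("water stress follows the four-branch retention response", {
  cp_w <- crop_params("wheat")
  cp_g <- crop_params("grass")
  prof <- list(mk_layer(topsoil = TRUE), mk_layer(), mk_layer())
  set_theta <- function(prof, th) {
    for (l in 1:3) prof[[l]]$W <- th * prof[[l]]$delta
    prof
  }
  l1 <- prof[[1]]
  plateau <- set_theta(prof, (l1$theta_a + l1$theta_d) / 2)
  expect_equal(water_stress(plateau, 3, c(1, 0, 0), cp_w)$w_rf, 1)

  mid <- set_theta(prof, (l1$theta_d + l1$theta_wp) / 2)
  # single rooted layer: w_rf = W_S^2 / W_S = W_S = 0.5
  expect_equal(water_stress(mid, 1, c(1, 0, 0), cp_w)$w_rf, 0.5,
               tolerance = 1e-9)

  # grass floor: stress bottoms out at 0.4 approaching wilting point
  # (a tiny potential demand keeps the extractable-water cap inactive)
  wilt <- set_theta(prof, l1$theta_wp + 1e-6)
  expect_equal(water_stress(wilt, 1e-6, c(1, 0, 0), cp_g)$w_rf, 0.4,
               tolerance = 1e-4)
  grass_mid <- water_stress(mid, 1e-4, c(1, 0, 0), cp_g)$w_rf
  expect_equal(grass_mid, 0.7, tolerance = 1e-9)

  sat <- set_theta(prof, l1$theta_sat)
  expect_equal(water_stress(sat, 1, c(1, 0, 0), cp_g)$w_rf, 1)  # no sat stress
  expect_lt(water_stress(sat, 1, c(1, 0, 0), cp_w)$w_rf, 1e-9)

  expect_equal(water_stress(mid, 0, c(1, 0, 0), cp_w)$w_rf, 1)
  # actual transpiration never exceeds potential
  a <- water_stress(mid, 2.5, c(0.6, 0.3, 0.1), cp_w)
  expect_lte(sum(a$atran), 2.5 + 1e-12)
})

test_that("nutrition indices scale linearly between residual and maximum", {
  cp <- crop_params("wheat")
  expect_equal(cp$n_max_leaf(0), 0.060, tolerance = 1e-9)

  st <- new_crop_state(cp)
  st$dvs <- 0.5
  st$mass <- c(root = 50, stem = 100, leaf = 100, storage = 0)
  nmax_l <- cp$n_max_leaf(0.5)
  nmax_s <- 0.5 * nmax_l
  # at exactly the maxima the index is 1
  st$n <- c(root = 0, stem = 100 * nmax_s, leaf = 100 * nmax_l, storage = 0)
  st$p <- c(root = 0, stem = 100 * 0.5 * 0.0051, leaf = 100 * 0.0051,
            storage = 0)
  ni <- nutrition_indices(st)
  expect_equal(unname(ni["n_ni"]), 1)

  # at half the headroom above residual the N index is 0.5
  half_n <- 200 * (cp$n_res + 0.5 * ((100 * nmax_l + 100 * nmax_s) / 200 -
                                       cp$n_res))
  st$n <- c(root = 0, stem = 0, leaf = half_n, storage = 0)
  ni2 <- nutrition_indices(st)
  expect_equal(unname(ni2["n_ni"]), 0.5, tolerance = 1e-9)

  empty <- new_crop_state(cp)
  empty$mass <- c(root = 0, stem = 0, leaf = 0, storage = 0)
  expect_equal(unname(nutrition_indices(empty)["n_ni"]), 1)
})

test_that("biomass production is multiplicative in the stress factors", {
  cp <- crop_params("wheat")
  st <- new_crop_state(cp)
  st$dvs <- 0.5                        # past the juvenile phase
  st$mass[["leaf"]] <- 1000            # closed canopy
  day <- mk_day(rad = 20)
  # interception ~ 1, PAR = 10 MJ, LUE 3 -> 30 g
  full <- daily_growth(st, day, 1, 1, 1)
  expect_equal(full$db, 0.5 * 20 *
                 (1 - exp(-cp$extinction_k * cp$sla * 1000)) * 3,
               tolerance = 1e-9)
  expect_equal(daily_growth(st, day, 0, 1, 1)$db, 0)
  expect_equal(daily_growth(st, day, 1, 0, 1)$db, 0)
  expect_equal(daily_growth(st, day, 1, 1, 0)$db, 0)

  # grass LUE ramps: radiation 40 scales epsilon by 0.33 (warm day)
  expect_equal(landsim:::grass_lue_factors(crop_params("grass"), 40, 15),
               0.33, tolerance = 1e-9)
  expect_equal(landsim:::grass_lue_factors(crop_params("grass"), 10, 15), 1)
  expect_equal(landsim:::grass_lue_factors(crop_params("grass"), 10, 6), 0)
})

test_that("nutrient demand vanishes after anthesis and at the maxima", {
  cp <- crop_params("wheat")
  st <- new_crop_state(cp)
  st$dvs <- 1.2
  post <- nutrient_demand(st)
  expect_equal(post$n_demand, 0)
  expect_equal(post$p_demand, 0)

  st$dvs <- 0.4
  nmax_l <- cp$n_max_leaf(0.4)
  pmax_l <- landsim:::interp_table(cp$p_max_leaf_knots, 0.4)
  st$mass <- c(root = 100, stem = 100, leaf = 100, storage = 0)
  st$n <- c(root = 100 * 0.5 * nmax_l, stem = 100 * 0.5 * nmax_l,
            leaf = 100 * nmax_l, storage = 0)
  st$p <- c(root = 100 * 0.5 * pmax_l, stem = 100 * 0.5 * pmax_l,
            leaf = 100 * pmax_l, storage = 0)
  expect_equal(nutrient_demand(st)$n_demand, 0)
  st$n <- st$n / 2
  expect_gt(nutrient_demand(st)$n_demand, 0)
})

test_that("senescence returns dead material to the soil without loss", {
  cp <- crop_params("wheat")
  st <- new_crop_state(cp)
  st$dvs <- 1.0
  st$mass <- c(root = 100, stem = 50, leaf = 0, storage = 0)
  st$n <- c(root = 1, stem = 0.3, leaf = 0, storage = 0)
  st$p <- c(root = 0.1, stem = 0.03, leaf = 0, storage = 0)
  none <- senesce_and_return(st, mk_day(), n_ni = 1)
  expect_equal(none$state$mass[["root"]], 100)   # below the DVS threshold

  st$dvs <- 1.6
  out <- senesce_and_return(st, mk_day(), n_ni = 1)
  expect_equal(st$mass[["root"]] - out$state$mass[["root"]], 2,
               tolerance = 1e-9)                 # 0.02 x 100
  # plant loss equals soil organic input, exactly
  n_before <- sum(st$n) + st$dead_leaf_n
  n_after <- sum(out$state$n) + out$state$dead_leaf_n
  expect_equal((n_before - n_after) * 10, out$litter$n, tolerance = 1e-12)
  m_before <- sum(st$mass) + st$dead_leaf
  m_after <- sum(out$state$mass) + out$state$dead_leaf
  expect_equal((m_before - m_after) * cp$c_frac_dm * 0.01, out$litter$c,
               tolerance = 1e-12)
})

test_that("cutting and grazing respect the standing-biomass floor", {
  gr <- new_crop_state(crop_params("grass"))
  gr$mass <- c(root = 100, stem = 60, leaf = 240, storage = 0)
  gr$n <- c(root = 1, stem = 0.6, leaf = 7, storage = 0)
  gr$p <- c(root = 0.1, stem = 0.06, leaf = 0.7, storage = 0)
  cutout <- cut_or_graze(gr, "cut")
  expect_equal(cutout$removed_dm, 2.5, tolerance = 1e-9)  # 250 g m-2
  left <- cutout$state
  expect_equal(left$mass[["leaf"]] + left$mass[["stem"]] + left$dead_leaf,
               50, tolerance = 1e-9)

  small <- gr
  small$mass <- c(root = 100, stem = 10, leaf = 30, storage = 0)
  expect_equal(cut_or_graze(small, "cut")$removed_dm, 0)

  grz <- cut_or_graze(gr, "graze", animal = "beef", stocking = 2)
  expect_equal(grz$manure_c, 8.06, tolerance = 1e-9)
  expect_equal(grz$manure_n, 0.44, tolerance = 1e-9)

  wheat <- new_crop_state(crop_params("wheat"))
  expect_error(cut_or_graze(wheat, "cut"), "grass")
})

test_that("harvest expresses yield at 85 percent dry matter", {
  st <- new_crop_state(crop_params("wheat"))
  st$mass[["storage"]] <- 510
  st$n[["storage"]] <- 10
  h <- harvest_crop(st)
  expect_equal(h$yield, 6.0, tolerance = 1e-9)
  expect_equal(h$grain_n, 100)
  expect_warning(h0 <- harvest_crop(new_crop_state(crop_params("wheat"))),
                 "zero yield")
  expect_equal(h0$yield, 0)
})
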
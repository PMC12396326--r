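test_that("mineral stock arithmetic matches the closed form", {
  d <- toy_domain(1e4) # 1e10 m^2
  tf <- toy_tf(c(tundra = 30, boreal_forest = 15))
  bm <- toy_biomes(tundra = 0.6, boreal_forest = 0.4)
  base <- mineral_stock(bm, tf, continuous = mat1(FALSE),
                        peat_fraction = mat1(0), slope_fraction = mat1(0),
                        domain = d, land = mat1(TRUE), shelf = mat1(FALSE))
  expect_equal(base$cell_stock[1, 1], 0.24)
  expect_equal(unname(base$pools["land"]), 0.24)
  expect_equal(unname(base$pools["shelf"]), 0)

  # a 10% steep-slope share: mineral part scaled by 0.9 plus alpine density
  sl <- mineral_stock(bm, tf, mat1(FALSE), mat1(0), mat1(0.1), d,
                      mat1(TRUE), mat1(FALSE))
  expect_equal(sl$cell_stock[1, 1], 1e10 * (0.9 * 24 + 0.1 * 3) * 1e-12)

  # full peat cover with no slope leaves no mineral stock
  pt <- mineral_stock(bm, tf, mat1(FALSE), mat1(1), mat1(0), d,
                      mat1(TRUE), mat1(FALSE))
  expect_equal(pt$cell_stock[1, 1], 0)

  expect_error(mineral_stock(bm, tf, mat1(FALSE), mat1(0.8), mat1(0.3), d,
                             mat1(TRUE), mat1(FALSE)), "exceeds 1")
})

test_that("permafrost state selects the transfer function", {
  d <- toy_domain(1e4)
  tf <- toy_tf(c(tundra = 10))
  tf$table$mean_kg_m2[tf$table$class == "tundra" & tf$table$permafrost] <- 40
  bm <- toy_biomes(tundra = 1)
  pf <- mineral_stock(bm, tf, mat1(TRUE), mat1(0), mat1(0), d, mat1(TRUE),
                      mat1(FALSE))
  nopf <- mineral_stock(bm, tf, mat1(FALSE), mat1(0), mat1(0), d,
                        mat1(TRUE), mat1(FALSE))
  expect_equal(pf$cell_stock[1, 1] / nopf$cell_stock[1, 1], 4)
})

test_that("model averaging is exact and tracks the inter-model gap", {
  d <- toy_domain(1e4)
  tf <- toy_tf(c(tundra = 30), sds = c(tundra = 10))
  bm <- toy_biomes(tundra = 1)
  s1 <- mineral_stock(bm, tf, mat1(FALSE), mat1(0), mat1(0), d, mat1(TRUE),
                      mat1(FALSE))
  avg_same <- average_models(list(s1, s1))
  expect_equal(avg_same$pools, s1$pools)
  expect_equal(unname(avg_same$intermodel_gap["land"]), 0)

  tf2 <- toy_tf(c(tundra = 32), sds = c(tundra = 10))
  s2 <- mineral_stock(bm, tf2, mat1(FALSE), mat1(0), mat1(0), d,
                      mat1(TRUE), mat1(FALSE))
  avg <- average_models(list(s1, s2))
  delta <- (s2$pools["land"] - s1$pools["land"]) / 2
  expect_equal(unname(avg$pools["land"] - s1$pools["land"]), unname(delta))
  expect_equal(unname(avg$intermodel_gap["land"]), unname(delta))
  expect_true(is.finite(avg$intermodel_gap_pct_of_sd["land"]))

  s_small <- s1
  s_small$cell_stock <- matrix(0, 2, 2)
  expect_error(average_models(list(s1, s_small)), "mismatched")
})

test_that("loess bookkeeping: deposition era, thaw losses, frozen stasis", {
  d <- test_domain()
  spec <- default_loess_spec()[1, ]
  # one region: 8 equal-area cells in a single latitude row, 100 Pg C
  spec$lat0 <- 43; spec$lat1 <- 48; spec$lon0 <- 0; spec$lon1 <- 40
  spec$area_km2 <- 1e6; spec$depth_below_2m <- 10
  spec$c_density_frozen <- 10; spec$c_density_thawed <- 1
  spec$deposition_pg_per_ka <- 0
  lo <- make_loess_regions(d, spec)
  expect_equal(lo$total_stock_21ka_pg, 100)
  expect_equal(sum(!is.na(lo$id)), 8)

  st <- loess_init(lo, d)
  all_frozen <- matrix(TRUE, d$nlat, d$nlon)
  cont <- list(pseudo_hadcm3 = all_frozen, pseudo_trace = all_frozen)
  st <- loess_step(st, cont, 20)
  expect_equal(st$stock_pg, 100) # fully frozen, no deposition: unchanged
  expect_equal(st$loss_pg, 0)

  # half the region (by area) leaves the continuous mask
  half <- all_frozen
  cells <- which(!is.na(lo$id))[1:4]
  half[cells] <- FALSE
  st <- loess_step(st, list(pseudo_hadcm3 = half, pseudo_trace = half), 19,
                   retention = 0.1)
  expect_equal(st$loss_pg, 45) # 100 * 0.5 * (1 - 0.1)
  expect_equal(st$stock_pg, 55)

  # thawed cells stay thawed; the frozen half is untouched next step
  st <- loess_step(st, list(pseudo_hadcm3 = half, pseudo_trace = half), 18)
  expect_equal(st$loss_pg, 0)
  expect_equal(st$stock_pg, 55)

  expect_error(loess_step(st, cont, 15), "one millennium")
})

test_that("loess deposition accrues only during the depositional era", {
  d <- test_domain()
  lo <- make_loess_regions(d, default_loess_spec())
  st <- loess_init(lo, d)
  all_frozen <- matrix(TRUE, d$nlat, d$nlon)
  cont <- list(pseudo_hadcm3 = all_frozen, pseudo_trace = all_frozen)
  for (t in 20:17) st <- loess_step(st, cont, t)
  expect_equal(st$stock_pg, 398) # 363 + 4 x 8.75
  st <- loess_step(st, cont, 16)
  expect_equal(st$stock_pg, 398) # era over, nothing thawed
})

test_that("peat distribution hits the curve totals and the PI stock", {
  w <- test_world()
  p0 <- peat_step(w$peat, w, 0)
  expect_equal(p0$total_pg, 450)
  expect_equal(sum(p0$stock_map), 450, tolerance = 1e-9)
  expect_equal(sum(p0$area_map), w$peat$pi_total_area, tolerance = 1e-6)
  expect_equal(p0$sd_pg, 450 * sqrt(0.36^2 + 0.10^2), tolerance = 1e-9)

  p16 <- peat_step(w$peat, w, 16)
  expect_equal(p16$total_pg, 0)

  totals <- vapply(21:0, function(t) peat_step(w$peat, w, t)$total_pg,
                   numeric(1))
  expect_true(all(diff(totals) >= 0)) # non-decreasing toward the present

  # the relative uncertainty ramp: +/-50% share at 16 ka, 0 at PI
  p8 <- peat_step(w$peat, w, 8)
  expect_equal(p8$sd_pg / p8$total_pg,
               sqrt(0.36^2 + 0.10^2 + (0.5 * 8 / 16)^2), tolerance = 1e-9)
})

test_that("post-glacial accrual follows the exponential saturation design", {
  expect_equal(postglacial_accrual(0, "boreal_forest"), 0)
  Ce <- default_accrual_equilibria()
  ce_bor <- sum(Ce[Ce$class == "boreal_forest", c("ce_0_1", "ce_1_2")])
  expect_equal(postglacial_accrual(50, "boreal_forest"), ce_bor,
               tolerance = 1e-9)
  expect_gte(postglacial_accrual(3, "boreal_forest"), 0.95 * ce_bor)
  ce_tun <- sum(Ce[Ce$class == "tundra", c("ce_0_1", "ce_1_2")])
  expect_gte(postglacial_accrual(3, "tundra"), 0.95 * ce_tun)
  ce_gr <- sum(Ce[Ce$class == "grassland_dry_shrubland",
                  c("ce_0_1", "ce_1_2")])
  expect_lt(postglacial_accrual(3, "grassland_dry_shrubland"), 0.95 * ce_gr)
  expect_error(postglacial_accrual(1, "steppe"), "unknown")
})

test_that("subglacial stock and release arithmetic", {
  d <- test_domain()
  mask <- matrix(FALSE, d$nlat, d$nlon)
  mask[10, 1:4] <- TRUE
  a <- sum(d$area[mask]) * 1e6
  s <- subglacial_stock(mask, d, tundra_density = 35,
                        peat1m_density = 50, peat_share = 0.01)
  expect_equal(s, (a * 35 + 0.01 * a * 50) * 1e-12)

  none <- matrix(FALSE, d$nlat, d$nlon)
  same <- subglacial_step(mask, mask, d)
  expect_equal(same$release_pg, 0)
  full <- subglacial_step(mask, none, d)
  expect_equal(full$release_pg, s)
  expect_error(subglacial_step(none, mask, d), "readvance")
  expect_equal(subglacial_step(none, mask, d,
                               allow_readvance = TRUE)$release_pg, -s)
})

test_that("subglacial release ends once the ice sheets are gone", {
  w <- test_world()
  i5 <- match(5, w$times)
  expect_equal(sum(w$masks$cold_based[, , i5]), 0)
  r <- subglacial_step(w$masks$cold_based[, , i5],
                       w$masks$cold_based[, , i5 + 1], w$domain)
  expect_equal(r$release_pg, 0)
})

test_that("shelf transfers conserve the combined pools and cycle 30%", {
  d <- test_domain()
  land_old <- matrix(FALSE, d$nlat, d$nlon); land_old[5, 1:3] <- TRUE
  land_young <- land_old; land_young[5, 1] <- FALSE # one cell inundated
  stock <- matrix(0, d$nlat, d$nlon); stock[5, 1] <- 40
  tr <- shelf_transfer(land_old, land_young, stock,
                       cycling_fraction = 0.30, exposed_pool = 100,
                       inundated_pool = 7)
  expect_equal(tr$transferred_pg, 40)
  expect_equal(tr$cycled_pg, 12)
  expect_equal(tr$exposed_pool + tr$inundated_pool, 107, tolerance = 1e-9)

  none <- shelf_transfer(land_old, land_old, stock)
  expect_equal(none$transferred_pg, 0)
  expect_equal(none$cycled_pg, 0)

  expect_error(shelf_transfer(land_young, land_old, stock),
               "re-emergence")
  ice_old <- matrix(FALSE, d$nlat, d$nlon); ice_old[5, 1] <- TRUE
  ok <- shelf_transfer(land_young, land_old, stock, ice_old = ice_old)
  expect_equal(ok$transferred_pg, 0)
  expect_error(shelf_transfer(land_old, land_young, stock,
                              cycling_fraction = 0.9), "0, 0.66")
})

test_that("net change decomposes exactly and validates its inputs", {
  pools <- stats::setNames(c(100, 20, 10, 50, 60, 5, 2),
                           paleocarb:::POOL_NAMES)
  sds <- pools * 0.2
  s_old <- carbon_state(12, pools, sds)
  s_same <- carbon_state(11, pools, sds)
  z <- net_change(s_old, s_same)
  expect_true(all(z$deltas == 0))
  expect_equal(z$net_pg, 0)
  expect_equal(z$net_sd_pg, 0)

  pools2 <- pools + stats::setNames(c(10, -4, 0, 0, 0, 0, 0),
                                    paleocarb:::POOL_NAMES)
  s_young <- carbon_state(11, pools2, sds)
  r <- net_change(s_old, s_young, cycled_flux = 3)
  expect_equal(sum(r$deltas), 6)
  expect_equal(r$net_pg, 6 - 3)
  # per-pool uncertainties follow the dispersion-index rule
  V_old <- sds["mineral_land"]^2 / pools["mineral_land"]
  V_young <- (0.2 * 100)^2 / pools2["mineral_land"]
  expect_equal(unname(r$E["mineral_land"]),
               unname((V_old + V_young) / 2 * 10))
  expect_error(net_change(s_old, s_old), "consecutive")
})

test_that("gross changes split the net exactly", {
  a <- matrix(0, 3, 3)
  b <- a; b[1, 1] <- 5; b[2, 2] <- -3
  g <- gross_changes(a, b)
  expect_equal(g$gains_pg, 5)
  expect_equal(g$losses_pg, -3)
  expect_equal(g$net_pg, 2)
  expect_equal(gross_changes(a, a)$gains_pg, 0)
  set.seed(2)
  x <- matrix(rnorm(100), 10, 10)
  y <- matrix(rnorm(100), 10, 10)
  g2 <- gross_changes(x, y)
  expect_gte(abs(g2$gains_pg) + abs(g2$losses_pg), abs(g2$net_pg) - 1e-12)
  expect_equal(g2$gains_pg + g2$losses_pg, sum(y - x))
  expect_error(gross_changes(a, matrix(0, 2, 2)), "co-registered")
})
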
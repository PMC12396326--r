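test_that("climate slices satisfy the variable constraints everywhere", {
  w <- test_world()
  for (m in model_labels()) {
    cl <- w$climate$models[[m]]
    expect_true(all(cl$t_cold <= cl$maat & cl$maat <= cl$t_warm))
    expect_equal(cl$t_range, cl$t_warm - cl$t_cold)
    expect_true(all(cl$precip_annual >= 0))
    expect_true(all(cl$precip_gs >= 0 &
                      cl$precip_gs <= cl$precip_annual + 1e-12))
  }
})

test_that("climate generation is deterministic given a seed and requires one", {
  d <- test_domain()
  a <- simulate_climate(d, default_scenario(), seed = 5)
  b <- simulate_climate(d, default_scenario(), seed = 5)
  expect_identical(a, b)
  c2 <- simulate_climate(d, default_scenario(), seed = 6)
  expect_false(identical(a$models$pseudo_hadcm3$maat,
                         c2$models$pseudo_hadcm3$maat))
  expect_error(simulate_climate(d, default_scenario()), "seed")
})

test_that("inter-model MAAT difference is the configured constant bias", {
  w <- test_world()
  diff <- w$climate$models$pseudo_trace$maat -
    w$climate$models$pseudo_hadcm3$maat
  expect_true(all(abs(diff - w$scenario$model_bias_trace) < 1e-12))
})

test_that("the domain warms from the LGM to preindustrial", {
  w <- test_world()
  maat <- w$climate$models$pseudo_hadcm3$maat
  expect_lt(mean(maat[, , 1]), mean(maat[, , 22]))
})

test_that("ice retreat is monotone and complete by the residual date", {
  w <- test_world()
  area <- w$domain$area
  ice_area <- vapply(seq_along(w$times), function(i)
    sum(area[w$masks$ice[, , i]]), numeric(1))
  expect_true(all(diff(ice_area) <= 1e-9))
  expect_equal(ice_area[w$times == 4], 0)
  expect_gt(ice_area[1], 0)
})

test_that("cold-based ice is a subset of the ice mask", {
  w <- test_world()
  expect_true(all(w$masks$ice[w$masks$cold_based]))
})

test_that("land, ice and ocean partition the domain at every slice", {
  w <- test_world()
  for (i in c(1, 10, 22)) {
    land <- w$masks$land[, , i]
    ice <- w$masks$ice[, , i]
    expect_false(any(land & ice))
    ocean <- !land & !ice
    expect_equal(sum(land) + sum(ice) + sum(ocean),
                 w$domain$nlat * w$domain$nlon)
  }
})

test_that("present land is within LGM land outside formerly glaciated cells", {
  w <- test_world()
  land0 <- w$masks$land[, , 22]
  land21 <- w$masks$land[, , 1]
  glaciated <- w$masks$ice[, , 1]
  expect_true(all(land21[land0 & !glaciated]))
})

test_that("land-area bookkeeping closes: shelf loss and deglacial gain", {
  w <- test_world()
  a <- w$domain$area
  land21 <- sum(a[w$masks$land[, , 1]])
  land0 <- sum(a[w$masks$land[, , 22]])
  shelf21 <- sum(a[w$masks$land[, , 1] & !w$masks$land[, , 22]])
  ice_gain <- sum(a[w$masks$ice[, , 1]]) # all LGM ice becomes land by 0 ka
  expect_equal(land21 - land0, shelf21 - ice_gain, tolerance = 1e-9)
})

test_that("invalid retreat schedules are rejected", {
  sc <- default_scenario(retreat_start_ka = 5, retreat_end_ka = 17)
  expect_error(simulate_ice_and_sea(test_domain(), sc), "monotone|retreat")
})

test_that("biome truth obeys the rule table and masks", {
  w <- test_world()
  cl <- w$climate$models$pseudo_hadcm3
  for (i in c(1, 22)) {
    lab <- w$truth[, , i]
    land <- w$masks$land[, , i]
    expect_true(all(!is.na(lab[land])))
    expect_true(all(is.na(lab[!land])))
    # cold-summer moist land cells must be tundra (rule threshold)
    cold <- land & cl$t_warm[, , i] < 10 & cl$precip_annual[, , i] >= 150
    expect_true(all(lab[cold] == match("tundra", biome_classes())))
    # hyper-arid land cells are desert
    arid <- land & cl$precip_annual[, , i] < 150
    expect_true(all(lab[arid] == match("desert", biome_classes())))
  }
})

test_that("truth assignment is deterministic and incompleteness is an error", {
  w <- test_world()
  t1 <- simulate_true_biomes(w$climate, w$masks)
  t2 <- simulate_true_biomes(w$climate, w$masks)
  expect_identical(t1, t2)
  only_desert <- default_biome_rules()[1, ]
  expect_error(simulate_true_biomes(w$climate, w$masks, only_desert),
               "incomplete")
})

test_that("pollen sampling copies truth at zero noise and honours counts", {
  w <- test_world()
  tr <- sample_pollen_sites(w, 100, label_noise = 0, protected_rate = 0.5,
                            seed = 3, times = 9:0)
  expect_equal(nrow(tr), 1000)
  expect_identical(tr$biome, tr$true_biome)
  expect_true(all(tr$time_ka %in% 9:0))
  expect_true(any(duplicated(tr$cell))) # duplicates are permitted
})

test_that("label corruption rate matches the binomial expectation", {
  w <- test_world()
  n <- 10000
  tr <- sample_pollen_sites(w, n, label_noise = 0.2, protected_rate = 0,
                            seed = 4, times = 0)
  rate <- mean(tr$biome != tr$true_biome)
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(rate - 0.2), 3 * se)
})

test_that("loess spec reproduces its configured stocks and scales linearly", {
  d <- test_domain()
  lo <- make_loess_regions(d, default_loess_spec())
  expect_equal(lo$total_stock_21ka_pg, 363)
  spec2 <- default_loess_spec()
  spec2$area_km2 <- spec2$area_km2 * 2
  expect_equal(make_loess_regions(d, spec2)$total_stock_21ka_pg, 726)
  empty <- default_loess_spec()[0, ]
  expect_equal(make_loess_regions(d, empty)$total_stock_21ka_pg, 0)
  bad <- default_loess_spec()
  bad$c_density_thawed <- bad$c_density_frozen
  expect_error(make_loess_regions(d, bad), "thawed")
})

test_that("peat curves are monotone with the right boundary values", {
  w <- test_world()
  cv <- w$peat$curves
  expect_equal(cv$stock_fraction[cv$time_ka == 0], 1)
  expect_equal(cv$area_fraction[cv$time_ka == 0], 1)
  expect_true(all(cv$stock_fraction[cv$time_ka >= 16] == 0))
  # non-decreasing toward the present (rows run 21 -> 0)
  expect_true(all(diff(cv$stock_fraction) >= 0))
  expect_true(all(diff(cv$area_fraction) >= 0))
})

test_that("missing southern initiation ages default to 12 ka", {
  d <- test_domain()
  pi_ext <- matrix(0, d$nlat, d$nlon)
  init <- matrix(NA_real_, d$nlat, d$nlon)
  south <- which(d$lat_centers < 38)[1]
  north <- which(d$lat_centers > 50)[1]
  pi_ext[south, 1] <- 0.2
  pi_ext[north, 1] <- 0.2
  pc <- make_peat_curves(450, pi_ext, init, d, pi_total_area = 1e6)
  expect_equal(pc$initiation[south, 1], 12)
  expect_true(is.na(pc$initiation[north, 1])) # rule applies only in the south
  expect_error(make_peat_curves(450, pi_ext, init, d, 1e6,
                                stock_width_ka = -1), "monotone")
  expect_error(make_peat_curves(0, pi_ext, init, d, 1e6), "positive")
})

test_that("the full world build is deterministic given seed and scenario", {
  d <- test_domain()
  w1 <- build_world(d, default_scenario(), seed = 55)
  w2 <- build_world(d, default_scenario(), seed = 55)
  expect_identical(w1$climate, w2$climate)
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$peat$pi_extent, w2$peat$pi_extent)
  expect_identical(w1$elevation, w2$elevation)
})
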
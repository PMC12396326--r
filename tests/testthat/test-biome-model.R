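test_that("implausibly warm tundra rows are filtered unless protected", {
  w <- test_world()
  # a southern land cell, warm at 0 ka
  i0 <- match(0, w$times)
  maat0 <- w$climate$models$pseudo_hadcm3$maat[, , i0]
  warm_cell <- which(w$masks$land[, , i0] & maat0 > 6)[1]
  cool_cell <- which(w$masks$land[, , i0] & maat0 < 4.9 & maat0 > 0)[1]
  tr <- data.frame(site_id = 1:3, lon = 0, lat = 0, time_ka = 0,
                   biome = "tundra", protected = c(FALSE, TRUE, FALSE),
                   cell = c(warm_cell, warm_cell, cool_cell),
                   true_biome = "tundra")
  out <- filter_training(tr, w)
  expect_equal(out$site_id, c(2L, 3L)) # protected kept, cool kept
  # non-tundra rows at the same warm site are untouched
  tr$biome <- "boreal_forest"
  expect_equal(nrow(filter_training(tr, w)), 3)
  # unresolvable site climate is an error naming the site
  tr_bad <- tr
  tr_bad$cell[1] <- NA
  expect_error(filter_training(tr_bad, w), "site 1")
})

test_that("desert augmentation adds the configured counts", {
  w <- test_world()
  tr <- test_bundles()$train_h
  aug <- augment_deserts(tr, w, "holocene", seed = 9)
  expect_equal(nrow(aug), nrow(tr) + 242)
  added <- aug[(nrow(tr) + 1):nrow(aug), ]
  expect_true(all(added$biome == "desert" & added$time_ka == 0))

  trd <- test_bundles()$train_d
  # plant identifiable 6-ka desert rows in the Holocene set
  h6 <- tr[tr$time_ka == 6, ][1:3, ]
  h6$biome <- "desert"
  aug_d <- augment_deserts(trd, w, "deglacial", seed = 9,
                           holocene_train = h6)
  expect_equal(nrow(aug_d), nrow(trd) + 3 + 40)
  expect_equal(sum(aug_d$time_ka == 21 & aug_d$biome == "desert") -
                 sum(trd$time_ka == 21 & trd$biome == "desert"), 40)
})

test_that("augmentation fails loudly when the world has no deserts", {
  w <- test_world()
  w2 <- w
  i0 <- match(0, w$times)
  tb <- w2$truth
  slice <- tb[, , i0]
  slice[slice == match("desert", biome_classes())] <-
    match("grassland_dry_shrubland", biome_classes())
  tb[, , i0] <- slice
  w2$truth <- tb
  expect_error(augment_deserts(test_bundles()$train_h, w2, "holocene",
                               seed = 9), "no desert cells")
})

test_that("a single-class training set predicts that class everywhere", {
  w <- test_world()
  tr <- test_bundles()$train_h
  tr$biome <- "boreal_forest"
  expect_warning(
    b <- fit_biome_classifier(tr, "holocene", w, num_trees = 30, seed = 2),
    "absent")
  expect_true("tundra" %in% b$metadata$missing_classes)
  bm <- predict_biome_fractions(b, w, 0)
  land <- w$masks$land[, , match(0, w$times)]
  k <- match("boreal_forest", biome_classes())
  expect_true(all(bm$fractions[, , k][land] == 1))
})

test_that("fitting and prediction are deterministic given the seed", {
  w <- test_world()
  tr <- test_bundles()$train_h
  b1 <- fit_biome_classifier(tr, "holocene", w, num_trees = 50, seed = 31)
  b2 <- fit_biome_classifier(tr, "holocene", w, num_trees = 50, seed = 31)
  p1 <- predict_biome_fractions(b1, w, 4)
  p2 <- predict_biome_fractions(b2, w, 4)
  expect_identical(p1$fractions, p2$fractions)
})

test_that("predicted fractions sum to 1 on land and vanish off land", {
  w <- test_world()
  b <- test_bundles()$holocene
  bm <- predict_biome_fractions(b, w, 0)
  i0 <- match(0, w$times)
  land <- w$masks$land[, , i0]
  sums <- apply(bm$fractions, c(1, 2), sum)
  expect_true(all(abs(sums[land] - 1) < 1e-9))
  expect_true(all(sums[!land] == 0))
  expect_true(all(bm$fractions >= 0))
})

test_that("slices outside a model's period are rejected", {
  w <- test_world()
  expect_error(predict_biome_fractions(test_bundles()$holocene, w, 15),
               "outside")
  expect_error(fit_biome_classifier(test_bundles()$train_h[0, ],
                                    "holocene", w, seed = 1), "empty")
})

test_that("vote-fraction argmax agrees with the hard majority vote", {
  w <- test_world()
  tr <- test_bundles()$train_h
  soft <- test_bundles()$holocene
  hard <- fit_biome_classifier(tr, "holocene", w, num_trees = 150,
                               seed = 21, vote = "hard")
  i0 <- match(0, w$times)
  land_cells <- which(w$masks$land[, , i0])
  x <- paleocarb:::covariates_at(w, "pseudo_hadcm3", 0, land_cells)
  ps <- paleocarb:::predict_fractions_frame(soft, x)
  ph <- paleocarb:::predict_fractions_frame(hard, x)
  soft_lab <- max.col(ps, ties.method = "first")
  hard_lab <- max.col(ph, ties.method = "first")
  expect_gte(mean(soft_lab == hard_lab), 0.99)
})

test_that("accuracy bookkeeping: perfect agreement scores 1 and is
           order-invariant", {
  w <- test_world()
  b <- test_bundles()$holocene
  hold <- sample_pollen_sites(w, 60, label_noise = 0, protected_rate = 0,
                              seed = 77, times = 9:0)
  acc <- evaluate_accuracy(b, hold, w)
  # relabel the holdout with the model's own argmax: accuracy must be 1
  x <- paleocarb:::covariates_at(w, "pseudo_hadcm3", 0,
                                 hold$cell[hold$time_ka == 0])
  p <- paleocarb:::predict_fractions_frame(b, x)
  hold0 <- hold[hold$time_ka == 0, ]
  hold0$biome <- biome_classes()[max.col(p, ties.method = "first")]
  acc0 <- suppressWarnings(evaluate_accuracy(b, hold0, w))
  expect_equal(acc0$accuracy[acc0$time_ka == 0], 1)
  # permutation of rows changes nothing
  perm <- hold[sample(nrow(hold)), ]
  expect_equal(evaluate_accuracy(b, perm, w)$accuracy, acc$accuracy)
})

test_that("uniform-random labels score near 1/8", {
  w <- test_world()
  b <- test_bundles()$holocene
  hold <- sample_pollen_sites(w, 400, label_noise = 0, protected_rate = 0,
                              seed = 78, times = 2)
  set.seed(1)
  hold$biome <- sample(biome_classes(), nrow(hold), replace = TRUE)
  acc <- suppressWarnings(evaluate_accuracy(b, hold, w))
  n <- nrow(hold)
  expect_lt(abs(acc$accuracy - 1 / 8), 3 * sqrt(1 / 8 * 7 / 8 / n))
})

test_that("empty holdout slices are omitted with a warning", {
  w <- test_world()
  b <- test_bundles()$holocene
  hold <- sample_pollen_sites(w, 50, label_noise = 0, protected_rate = 0,
                              seed = 79, times = c(9, 8))
  expect_warning(acc <- evaluate_accuracy(b, hold, w), "omitted")
  expect_setequal(acc$time_ka, c(9, 8))
})

test_that("calibration sanity: within-class mean fraction beats the base rate", {
  w <- test_world()
  b <- test_bundles()$holocene
  bm <- predict_biome_fractions(b, w, 0)
  i0 <- match(0, w$times)
  land <- w$masks$land[, , i0]
  truth <- w$truth[, , i0]
  for (k in seq_along(biome_classes())) {
    in_class <- land & !is.na(truth) & truth == k
    if (sum(in_class) < 5) next
    frac_k <- bm$fractions[, , k]
    expect_gt(mean(frac_k[in_class]), mean(frac_k[land]))
  }
})

test_that("duplicate rows of a class pull predictions toward it", {
  w <- test_world()
  tr <- test_bundles()$train_h
  # weight one climate neighbourhood: duplicate boreal rows near a site
  target <- tr[tr$biome == "boreal_forest" & tr$time_ka == 5, ][1, ]
  stacked <- rbind(tr, target[rep(1, 200), ])
  b0 <- test_bundles()$holocene
  b1 <- suppressWarnings(
    fit_biome_classifier(stacked, "holocene", w, num_trees = 150,
                         seed = 21))
  x <- paleocarb:::covariates_at(w, "pseudo_hadcm3", 5, target$cell)
  k <- match("boreal_forest", biome_classes())
  p0 <- paleocarb:::predict_fractions_frame(b0, x)[, k]
  p1 <- paleocarb:::predict_fractions_frame(b1, x)[, k]
  expect_gte(p1, p0)
})
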
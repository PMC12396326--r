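# Shared fixtures, built once per test run. The quick (5 degree) world and
# one full pipeline run are cached because several suites probe different
# facets of the same objects.

.cache <- new.env(parent = emptyenv())

test_domain <- function() {
  if (is.null(.cache$domain)) .cache$domain <- make_domain(5)
  .cache$domain
}

test_world <- function() {
  if (is.null(.cache$world)) {
    .cache$world <- build_world(test_domain(), default_scenario(),
                                seed = 101)
  }
  .cache$world
}

# a fine-grid, low-noise world for tests needing latitudinal precision
# (permafrost calibration recovery, the prescribed loess trajectory);
# classifier stages are never run on it
test_world_fine <- function() {
  if (is.null(.cache$world_fine)) {
    sc <- default_scenario(noise_spatial_sd = 0.2, noise_slice_sd = 0.1)
    .cache$world_fine <- build_world(make_domain(1), sc, seed = 101)
  }
  .cache$world_fine
}

test_loess_fine <- function() {
  if (is.null(.cache$loess_fine)) {
    .cache$loess_fine <- loess_trajectory(test_world_fine())
  }
  .cache$loess_fine
}

# lightweight classifier bundles for unit tests (fewer sites and trees than
# the pipeline defaults)
test_bundles <- function() {
  if (is.null(.cache$bundles)) {
    w <- test_world()
    train_h <- sample_pollen_sites(w, 300, label_noise = 0.1,
                                   protected_rate = 0.5, seed = 11,
                                   times = 9:0)
    train_d <- sample_pollen_sites(w, 300, label_noise = 0.1,
                                   protected_rate = 0.5, seed = 12,
                                   times = 21:10)
    .cache$bundles <- suppressWarnings(list(
      holocene = fit_biome_classifier(train_h, "holocene", w,
                                      num_trees = 150, seed = 21),
      deglacial = fit_biome_classifier(train_d, "deglacial", w,
                                       num_trees = 150, seed = 21),
      train_h = train_h, train_d = train_d))
  }
  .cache$bundles
}

test_recon <- function() {
  if (is.null(.cache$recon)) {
    .cache$recon <- run_reconstruction(default_config(seed = 7,
                                                      quick = TRUE))
  }
  .cache$recon
}

# single-cell grid stand-in for arithmetic unit tests (area in km^2)
toy_domain <- function(area_km2 = 1e4) {
  structure(list(lat_edges = c(60, 61), lon_edges = c(0, 1),
                 lat_centers = 60.5, lon_centers = 0.5,
                 area = matrix(area_km2, 1, 1), nlat = 1, nlon = 1,
                 resolution = 1, radius_km = 6371),
            class = "grid_domain")
}

# biome map with given named fractions in a 1 x 1 grid
toy_biomes <- function(...) {
  fr <- c(...)
  arr <- array(0, c(1, 1, 8))
  arr[1, 1, match(names(fr), biome_classes())] <- fr
  structure(list(time = 0, model_label = "pseudo_hadcm3", fractions = arr),
            class = "biome_map")
}

# transfer functions with one density per class, identical in both states
toy_tf <- function(means, sds = means * 0) {
  cls <- biome_classes()
  m <- rep(0, 8); names(m) <- cls
  s <- rep(0, 8); names(s) <- cls
  m[names(means)] <- means
  s[names(sds)] <- sds
  list(table = data.frame(class = rep(cls, 2),
                          permafrost = rep(c(TRUE, FALSE), each = 8),
                          mean_kg_m2 = rep(unname(m), 2),
                          sd_kg_m2 = rep(unname(s), 2)),
       slope_density = 3, slope_sd = 0, slope_threshold_deg = 4)
}

mat1 <- function(x) matrix(x, 1, 1)
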
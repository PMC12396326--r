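# Synthetic-world generator: seeded stand-ins for the climate-model fields,
# ice-sheet and shoreline chronologies, loess regions, peat curves and
# pollen-style training samples that drive the reconstruction.

RECON_TIMES <- 21:0 # ka BP, oldest first

# evaluate expr under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed)) {
    stop("a single integer `seed` is required for reproducibility",
         call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# derive a stage-specific sub-seed (< 2^31) from the run seed
sub_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483587L
}

# smooth zero-mean spatial noise: coarse iid normals, bilinearly interpolated
# to cell centres; uses the current RNG stream
smooth_noise <- function(domain, scale_deg, sd) {
  if (sd == 0) return(matrix(0, domain$nlat, domain$nlon))
  glat <- seq(LAT_MIN - scale_deg, LAT_MAX + scale_deg, by = scale_deg)
  glon <- seq(-180 - scale_deg, 180 + scale_deg, by = scale_deg)
  z <- matrix(stats::rnorm(length(glat) * length(glon), sd = sd),
              length(glat), length(glon))
  li <- findInterval(domain$lat_centers, glat)
  lj <- findInterval(domain$lon_centers, glon)
  wy <- (domain$lat_centers - glat[li]) / scale_deg
  wx <- (domain$lon_centers - glon[lj]) / scale_deg
  out <- matrix(0, domain$nlat, domain$nlon)
  for (i in seq_len(domain$nlat)) {
    a <- z[li[i], lj] * (1 - wx) + z[li[i], lj + 1] * wx
    b <- z[li[i] + 1, lj] * (1 - wx) + z[li[i] + 1, lj + 1] * wx
    out[i, ] <- a * (1 - wy[i]) + b * wy[i]
  }
  out
}

#' Simulate the two pseudo climate-model ensembles
#'
#' Produces the six climate variables (mean annual air temperature, warmest
#' and coldest month temperature, annual range, annual and growing-season
#' precipitation) on the grid for every millennium 21-0 ka, for two model
#' labels that share the same warming trajectory and spatial noise but differ
#' by a constant MAAT bias (default -5 C on `pseudo_trace`).
#'
#' @param domain A [make_domain()] grid.
#' @param scenario A [default_scenario()] parameter list.
#' @param seed Integer seed; required (runs must be reproducible).
#' @return A list of class `climate_ensemble` with `times`, and `models`, a
#'   named list per model label of arrays `[nlat, nlon, ntime]` for `maat`,
#'   `t_warm`, `t_cold`, `t_range`, `precip_annual`, `precip_gs`.
#' @export
simulate_climate <- function(domain, scenario = default_scenario(), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  sc <- scenario
  times <- RECON_TIMES
  nt <- length(times)
  lat <- lat_matrix(domain)
  lon <- lon_matrix(domain)
  dims <- c(domain$nlat, domain$nlon, nt)

  with_seed(seed, {
    spat <- smooth_noise(domain, sc$noise_scale_deg, sc$noise_spatial_sd)
    slice_noise <- lapply(seq_len(nt), function(i)
      smooth_noise(domain, sc$noise_scale_deg, sc$noise_slice_sd))
    precip_noise <- smooth_noise(domain, sc$noise_scale_deg, sc$precip_noise_sd)

    amp <- sc$seasonal_amp_base + sc$seasonal_amp_gradient * (lat - LAT_MIN)
    base_maat <- sc$pi_maat_at_23N - sc$maat_lat_gradient * (lat - LAT_MIN)

    # dry-sector precipitation factor
    dry <- matrix(1, domain$nlat, domain$nlon)
    in_sector <- lon >= sc$dry_sector_lon[1] & lon < sc$dry_sector_lon[2] &
      lat < sc$dry_sector_lat_max
    edge <- in_sector &
      (lon < sc$dry_sector_lon[1] + sc$dry_edge_width |
       lon >= sc$dry_sector_lon[2] - sc$dry_edge_width)
    dry[in_sector] <- sc$dry_core_factor
    dry[edge] <- sc$dry_edge_factor
    base_precip <- pmax(0, sc$precip_base -
                          sc$precip_lat_gradient * abs(lat - sc$precip_lat_peak)) *
      dry * exp(precip_noise)

    maat <- array(NA_real_, dims)
    pa <- array(NA_real_, dims)
    pg <- array(NA_real_, dims)
    for (i in seq_len(nt)) {
      w <- warming_weight(times[i], sc)
      maat[, , i] <- base_maat - sc$lgm_cooling * w + spat + slice_noise[[i]]
      pa[, , i] <- base_precip * (1 - (1 - sc$glacial_precip_factor) * w)
    }
    t_warm <- sweep_array(maat, amp / 2, `+`)
    t_cold <- sweep_array(maat, amp / 2, `-`)
    gs_frac <- pmin(0.95, pmax(0.05, sc$gs_frac_base +
                                 sc$gs_frac_per_degC * t_warm))
    pg <- pa * gs_frac

    had <- list(maat = maat, t_warm = t_warm, t_cold = t_cold,
                t_range = t_warm - t_cold, precip_annual = pa, precip_gs = pg)
    b <- sc$model_bias_trace
    trc <- had
    trc$maat <- had$maat + b
    trc$t_warm <- had$t_warm + b
    trc$t_cold <- had$t_cold + b
    # annual range and precipitation are unaffected by a uniform bias
    structure(list(times = times,
                   models = list(pseudo_hadcm3 = had, pseudo_trace = trc)),
              class = "climate_ensemble")
  })
}

# add a [nlat, nlon] matrix to every time slab of a 3-d array
sweep_array <- function(arr, mat, op) {
  out <- arr
  for (i in seq_len(dim(arr)[3])) out[, , i] <- op(arr[, , i], mat)
  out
}

#' Simulate ice-sheet, cold-based-ice and land/shoreline chronologies
#'
#' Ice sheets cover the high-latitude parts of both continental sectors at
#' the LGM and retreat monotonically between `retreat_start_ka` and
#' `retreat_end_ka`; cold-based ice is the high-latitude subset of the ice
#' mask. Continental shelves exposed at the LGM (longitude margins on each
#' sector) are inundated by rising seas between `inundation_start_ka` and
#' `inundation_end_ka`, so all shelf land exposed at 21 ka is ocean again at
#' 0 ka.
#'
#' @inheritParams simulate_climate
#' @param seed Unused (the chronology is deterministic); accepted for
#'   interface symmetry.
#' @return A list of class `world_masks` with logical arrays
#'   `[nlat, nlon, ntime]` `ice`, `cold_based`, `land`, plus
#'   `deglaciation_ka` (matrix; millennium a cell first became ice-free, NA
#'   if never glaciated) and `times`.
#' @export
simulate_ice_and_sea <- function(domain, scenario = default_scenario(),
                                 seed = NULL) {
  sc <- scenario
  if (sc$retreat_start_ka <= sc$retreat_end_ka) {
    stop("invalid scenario: ice retreat schedule must run from an older to a ",
         "younger millennium", call. = FALSE)
  }
  if (sc$inundation_start_ka <= sc$inundation_end_ka) {
    stop("invalid scenario: inundation schedule must be monotone",
         call. = FALSE)
  }
  times <- RECON_TIMES
  nt <- length(times)
  lat <- lat_matrix(domain)
  lon <- lon_matrix(domain)
  in_band <- lat < sc$land_lat_max

  core <- in_band & (sector_mask(lon, sc$sector_nearctic) |
                     sector_mask(lon, sc$sector_palearctic))

  ice <- array(FALSE, c(domain$nlat, domain$nlon, nt))
  cold <- array(FALSE, c(domain$nlat, domain$nlon, nt))
  land <- array(FALSE, c(domain$nlat, domain$nlon, nt))
  for (i in seq_len(nt)) {
    t <- times[i]
    r <- pmin(1, pmax(0, (t - sc$retreat_end_ka) /
                        (sc$retreat_start_ka - sc$retreat_end_ka)))
    bnd_ne <- sc$ice_nearctic_lat +
      (sc$land_lat_max - sc$ice_nearctic_lat) * (1 - r)
    bnd_pa <- sc$ice_palearctic_lat +
      (sc$land_lat_max - sc$ice_palearctic_lat) * (1 - r)
    ice_t <- core & ((sector_mask(lon, sc$ice_nearctic_lon) & lat >= bnd_ne) |
                     (sector_mask(lon, sc$ice_palearctic_lon) & lat >= bnd_pa))
    cold_t <- ice_t &
      ((sector_mask(lon, sc$ice_nearctic_lon) &
          lat >= sc$cold_based_lat_nearctic) |
       (sector_mask(lon, sc$ice_palearctic_lon) &
          lat >= sc$cold_based_lat_palearctic))
    wsh <- sc$shelf_width_lgm *
      pmin(1, pmax(0, (t - sc$inundation_end_ka) /
                     (sc$inundation_start_ka - sc$inundation_end_ka)))
    shelf_t <- in_band & !core &
      (edge_margin(lon, sc$sector_nearctic, wsh) |
       edge_margin(lon, sc$sector_palearctic, wsh))
    ice[, , i] <- ice_t
    cold[, , i] <- cold_t
    land[, , i] <- (core | shelf_t) & !ice_t
  }
  deglac <- matrix(NA_real_, domain$nlat, domain$nlon)
  for (i in seq_len(nt)) {
    t <- times[i]
    if (i == 1) next
    newly_free <- ice[, , i - 1] & !ice[, , i]
    deglac[newly_free] <- t
  }
  structure(list(times = times, ice = ice, cold_based = cold, land = land,
                 deglaciation_ka = deglac),
            class = "world_masks")
}

sector_mask <- function(lon, range) lon >= range[1] & lon < range[2]

# longitude margins of width w outside each edge of a sector
edge_margin <- function(lon, range, w) {
  (lon >= range[1] - w & lon < range[1]) |
  (lon >= range[2] & lon < range[2] + w)
}

#' Assign true biome labels from climate via the threshold rule table
#'
#' Applies the ordered decision list in `rules` to each unglaciated land cell
#' of each time slice: the first rule whose thresholds are all satisfied
#' assigns its class. A cell matched by no rule raises a configuration error;
#' ice and ocean cells get `NA`.
#'
#' @param climate A `climate_ensemble` (the `pseudo_hadcm3` member is used as
#'   the unbiased "real" climate) or a single model's field list.
#' @param masks A `world_masks` object.
#' @param rules A [default_biome_rules()]-style data.frame.
#' @return Integer array `[nlat, nlon, ntime]` of class indices into
#'   [biome_classes()], NA off land.
#' @export
simulate_true_biomes <- function(climate, masks,
                                 rules = default_biome_rules()) {
  fields <- if (inherits(climate, "climate_ensemble")) {
    climate$models$pseudo_hadcm3
  } else climate
  if (!all(rules$class %in% biome_classes())) {
    stop("configuration error: rule table contains unknown class labels",
         call. = FALSE)
  }
  dims <- dim(fields$maat)
  out <- array(NA_integer_, dims)
  for (i in seq_len(dims[3])) {
    lab <- classify_cells(fields$t_warm[, , i], fields$t_cold[, , i],
                          fields$precip_annual[, , i], rules)
    land_t <- masks$land[, , i]
    if (anyNA(lab[land_t])) {
      stop("configuration error: rule table is incomplete (unmatched land ",
           "cells in slice ", masks$times[i], " ka)", call. = FALSE)
    }
    lab[!land_t] <- NA_integer_
    out[, , i] <- lab
  }
  out
}

classify_cells <- function(t_warm, t_cold, precip, rules) {
  lab <- matrix(NA_integer_, nrow(t_warm), ncol(t_warm))
  cls <- biome_classes()
  for (r in seq_len(nrow(rules))) {
    ok <- is.na(lab)
    if (!is.na(rules$t_warm_min[r])) ok <- ok & t_warm >= rules$t_warm_min[r]
    if (!is.na(rules$t_warm_max[r])) ok <- ok & t_warm < rules$t_warm_max[r]
    if (!is.na(rules$t_cold_min[r])) ok <- ok & t_cold >= rules$t_cold_min[r]
    if (!is.na(rules$t_cold_max[r])) ok <- ok & t_cold < rules$t_cold_max[r]
    if (!is.na(rules$precip_min[r])) ok <- ok & precip >= rules$precip_min[r]
    if (!is.na(rules$precip_max[r])) ok <- ok & precip < rules$precip_max[r]
    lab[ok] <- match(rules$class[r], cls)
  }
  lab
}

#' Place the deep-loess regions on the grid
#'
#' Marks the cells of each configured region and reports the implied frozen
#' stock at 21 ka (nominal area x depth x frozen density). Stocks are carried
#' at region level; the cell mask only determines, later, which fraction of a
#' region leaves the continuous-permafrost zone in a given millennium.
#'
#' @param domain A [make_domain()] grid.
#' @param spec A [default_loess_spec()]-style data.frame.
#' @return A list of class `loess_regions`: `spec` (with `stock_21ka_pg`
#'   added), `id` (matrix of region indices, NA outside loess), and
#'   `total_stock_21ka_pg`.
#' @export
make_loess_regions <- function(domain, spec = default_loess_spec()) {
  if (nrow(spec) > 0 &&
      any(spec$c_density_thawed >= spec$c_density_frozen)) {
    stop("invalid loess spec: thawed C density must be below frozen density",
         call. = FALSE)
  }
  id <- matrix(NA_integer_, domain$nlat, domain$nlon)
  lat <- lat_matrix(domain)
  lon <- lon_matrix(domain)
  if (nrow(spec) > 0) {
    for (r in seq_len(nrow(spec))) {
      inbox <- lat >= spec$lat0[r] & lat < spec$lat1[r] &
        lon >= spec$lon0[r] & lon < spec$lon1[r]
      id[inbox] <- r
    }
    spec$stock_21ka_pg <- spec$area_km2 * 1e6 * spec$depth_below_2m *
      spec$c_density_frozen * 1e-12
  } else {
    spec$stock_21ka_pg <- numeric(0)
  }
  structure(list(spec = spec, id = id,
                 total_stock_21ka_pg = sum(spec$stock_21ka_pg)),
            class = "loess_regions")
}

#' Peatland area and carbon-accumulation curves
#'
#' Builds monotone normalized curves of peatland area and carbon stock as
#' fractions of their preindustrial totals: both are ~0 at and before
#' `onset_ka` (peatlands were rare under glacial conditions), rise along a
#' bell-shaped increment schedule peaking in the early Holocene, and reach 1
#' exactly at 0 ka. Fills missing initiation ages: cells south of
#' `no_data_lat` with no initiation data are assigned `default_init_ka`.
#'
#' @param pi_total_stock Preindustrial peat C stock, Pg C.
#' @param pi_extent Matrix of preindustrial peat area fraction per cell.
#' @param initiation Matrix of peat initiation age (ka), NA where unknown.
#' @param domain A [make_domain()] grid (for latitudes and areas).
#' @param pi_total_area Preindustrial peat area, km^2.
#' @param stock_peak_ka,stock_width_ka,area_peak_ka,area_width_ka,onset_ka
#'   Shape parameters of the increment schedules (ka).
#' @param no_data_lat,default_init_ka The southern initiation-data limit and
#'   the age assumed south of it.
#' @return A list of class `peat_curves`: `curves` (data.frame `time_ka`,
#'   `area_fraction`, `stock_fraction`), `pi_total_stock`, `pi_total_area`,
#'   `pi_extent`, `initiation` (filled).
#' @export
make_peat_curves <- function(pi_total_stock, pi_extent, initiation, domain,
                             pi_total_area,
                             stock_peak_ka = 8, stock_width_ka = 3,
                             area_peak_ka = 9, area_width_ka = 3.5,
                             onset_ka = 16, no_data_lat = 38,
                             default_init_ka = 12) {
  if (pi_total_stock <= 0) stop("`pi_total_stock` must be positive",
                                call. = FALSE)
  if (stock_width_ka <= 0 || area_width_ka <= 0 || onset_ka <= 0) {
    stop("peat curve shape parameters must be positive (curves must be ",
         "monotone)", call. = FALSE)
  }
  frac_curve <- function(peak, width) {
    inc <- stats::dnorm(0:(onset_ka - 1), mean = peak, sd = width)
    inc <- inc / sum(inc)
    # fraction in place at slice t = everything accumulated at slices >= ...
    sapply(RECON_TIMES, function(t) {
      if (t >= onset_ka) 0 else sum(inc[(t + 1):onset_ka])
    })
  }
  curves <- data.frame(
    time_ka = RECON_TIMES,
    area_fraction = frac_curve(area_peak_ka, area_width_ka),
    stock_fraction = frac_curve(stock_peak_ka, stock_width_ka))
  lat <- lat_matrix(domain)
  init <- initiation
  fill <- is.na(init) & lat < no_data_lat & pi_extent > 0
  init[fill] <- default_init_ka
  structure(list(curves = curves, pi_total_stock = pi_total_stock,
                 pi_total_area = pi_total_area, pi_extent = pi_extent,
                 initiation = init),
            class = "peat_curves")
}

#' Sample pollen-style training sites from the true biome map
#'
#' Draws `n_per_slice` sites per requested millennium from unglaciated land
#' cells, copies the true biome label, then corrupts a fraction
#' `label_noise` of rows with a label drawn uniformly from the other seven
#' classes. A fraction `protected_rate` of rows is flagged as coming from the
#' exempted source database (their tundra labels are never filtered).
#' Duplicate sites are permitted.
#'
#' @param world A [build_world()] object (or a list with `truth`, `masks`,
#'   `domain`, `times`).
#' @param n_per_slice Sites per time slice (>= 1).
#' @param label_noise Probability a row's label is corrupted, in `[0, 1]`.
#' @param protected_rate Probability a row is flagged protected.
#' @param seed Integer seed; required.
#' @param times Millennia to sample (default all 21-0 ka).
#' @return A data.frame: `site_id`, `lon`, `lat`, `time_ka`, `biome`,
#'   `protected`, plus bookkeeping columns `cell` (grid cell index within a
#'   slice) and `true_biome`.
#' @export
sample_pollen_sites <- function(world, n_per_slice, label_noise = 0.1,
                                protected_rate = 0.5, seed,
                                times = RECON_TIMES) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_per_slice >= 1, label_noise >= 0, label_noise <= 1)
  cls <- biome_classes()
  domain <- world$domain
  res <- domain$resolution
  with_seed(seed, {
    rows <- lapply(times, function(t) {
      i <- match(t, world$times)
      eligible <- which(world$masks$land[, , i] &
                          !is.na(world$truth[, , i]))
      if (length(eligible) == 0) {
        stop("no eligible land cells to sample at slice ", t, " ka",
             call. = FALSE)
      }
      cells <- sample(eligible, n_per_slice, replace = TRUE)
      ij <- arrayInd(cells, c(domain$nlat, domain$nlon))
      truth <- world$truth[, , i][cells]
      lab <- truth
      flip <- stats::runif(n_per_slice) < label_noise
      if (any(flip)) {
        lab[flip] <- vapply(truth[flip], function(k)
          sample(setdiff(seq_along(cls), k), 1L), integer(1))
      }
      data.frame(
        lon = domain$lon_centers[ij[, 2]] + stats::runif(n_per_slice, -res / 2, res / 2),
        lat = domain$lat_centers[ij[, 1]] + stats::runif(n_per_slice, -res / 2, res / 2),
        time_ka = t,
        biome = cls[lab],
        protected = stats::runif(n_per_slice) < protected_rate,
        cell = cells,
        true_biome = cls[truth])
    })
    out <- do.call(rbind, rows)
    out <- cbind(site_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

#' Build the complete synthetic world
#'
#' Orchestrates [simulate_climate()], [simulate_ice_and_sea()],
#' [simulate_true_biomes()], [make_loess_regions()] and [make_peat_curves()],
#' and generates the fixed surface fields (steep-slope fraction, elevation
#' surrogate, preindustrial peat extent and initiation ages). Deterministic
#' given `seed` and `scenario`.
#'
#' @inheritParams simulate_climate
#' @return A list of class `synthetic_world` with elements `domain`, `times`,
#'   `scenario`, `climate`, `masks`, `truth`, `loess`, `peat`,
#'   `slope_fraction`, `elevation`.
#' @export
build_world <- function(domain, scenario = default_scenario(), seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  sc <- scenario
  climate <- simulate_climate(domain, sc, seed = sub_seed(seed, 1))
  masks <- simulate_ice_and_sea(domain, sc)
  truth <- simulate_true_biomes(climate, masks)
  loess <- make_loess_regions(domain, sc$loess)

  lat <- lat_matrix(domain)
  lon <- lon_matrix(domain)
  land0 <- masks$land[, , length(masks$times)]

  slope <- matrix(sc$base_slope_fraction, domain$nlat, domain$nlon)
  mb <- sc$mountain_boxes
  for (r in seq_len(nrow(mb))) {
    inbox <- lat >= mb$lat0[r] & lat < mb$lat1[r] &
      lon >= mb$lon0[r] & lon < mb$lon1[r]
    slope[inbox] <- mb$slope_fraction[r]
  }

  world <- with_seed(sub_seed(seed, 2), {
    elev <- sc$elev_base + sc$elev_per_slope * slope +
      smooth_noise(domain, sc$noise_scale_deg, sc$elev_noise_sd)

    # preindustrial peat extent: a boreal band plus a smaller southern patch
    peat_frac <- matrix(0, domain$nlat, domain$nlon)
    band <- land0 & lat >= sc$peat_band_lat[1] & lat < sc$peat_band_lat[2]
    mid <- mean(sc$peat_band_lat)
    half <- diff(sc$peat_band_lat) / 2
    peat_frac[band] <- 0.35 * cos((lat[band] - mid) / half * pi / 2)^2 *
      exp(smooth_noise(domain, sc$noise_scale_deg, 0.3)[band])
    south <- land0 & lat >= sc$peat_south_lat[1] & lat < sc$peat_south_lat[2] &
      lon >= sc$peat_south_lon[1] & lon < sc$peat_south_lon[2]
    peat_frac[south] <- 0.15
    # normalize each component to its configured area target
    north_target <- sc$peat_pi_total_area - sc$peat_south_area
    a_band <- sum(peat_frac[band] * domain$area[band])
    a_south <- sum(peat_frac[south] * domain$area[south])
    if (a_band > 0) peat_frac[band] <- peat_frac[band] * north_target / a_band
    if (a_south > 0) peat_frac[south] <- peat_frac[south] * sc$peat_south_area / a_south
    peat_frac <- pmin(peat_frac, 0.9)

    # initiation ages: deglaciated cells start one millennium after ice-free;
    # other northern cells 12-9 ka; the southern patch has no data (NA)
    init <- matrix(NA_real_, domain$nlat, domain$nlon)
    north <- band & peat_frac > 0
    raw <- 11 + smooth_noise(domain, sc$noise_scale_deg, 2.5)
    dg <- masks$deglaciation_ka
    # pioneer peatlands sit on the never-glaciated southern fringe of the
    # band and initiate earliest, back to the glacial onset of peat growth
    pioneer <- north & is.na(dg) & lat < 58
    raw[pioneer] <- raw[pioneer] + 4
    init[north] <- pmin(16, pmax(8, round(raw)))[north]
    has_dg <- north & !is.na(dg)
    init[has_dg] <- pmin(init[has_dg], pmax(1, dg[has_dg] - 1))
    list(elev = elev, peat_frac = peat_frac, init = init)
  })

  peat <- make_peat_curves(
    pi_total_stock = sc$peat_pi_total_stock,
    pi_extent = world$peat_frac, initiation = world$init, domain = domain,
    pi_total_area = sc$peat_pi_total_area,
    stock_peak_ka = sc$peat_stock_peak_ka,
    stock_width_ka = sc$peat_stock_width_ka,
    area_peak_ka = sc$peat_area_peak_ka,
    area_width_ka = sc$peat_area_width_ka,
    onset_ka = sc$peat_onset_ka, no_data_lat = sc$peat_no_data_lat,
    default_init_ka = sc$peat_default_init_ka)

  structure(list(domain = domain, times = RECON_TIMES, scenario = sc,
                 seed = seed, climate = climate, masks = masks, truth = truth,
                 loess = loess, peat = peat, slope_fraction = slope,
                 elevation = world$elev),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_world> %d x %d grid at %g deg, %d millennial slices\n",
    "  loess stock at 21 ka: %.1f Pg C | PI peat stock: %.0f Pg C\n"),
    x$domain$nlat, x$domain$nlon, x$domain$resolution, length(x$times),
    x$loess$total_stock_21ka_pg, x$peat$pi_total_stock))
  invisible(x)
}
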
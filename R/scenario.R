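# Scenario parameters for the synthetic world.
#
# The defaults encode the study conditions the downstream stages are designed
# for: a glacial-to-interglacial warming of ~15 degrees C, two pseudo
# climate-model ensembles separated by a constant -5 C bias, ice sheets that
# retreat between 17 and 5 ka, continental shelves exposed at the LGM and
# inundated by 7 ka, four deep-loess regions holding 363 Pg C at 21 ka
# (398 Pg C at the 17 ka depositional peak), and a preindustrial peatland
# stock of 450 Pg C that accumulates over the Holocene.

#' Canonical biome class labels
#'
#' The eight mega-biome classes, in the fixed ordering used throughout the
#' package (argmax tie-breaks resolve to the lowest index).
#' @return Character vector of length 8.
#' @export
biome_classes <- function() {
  c("tundra", "boreal_forest", "temperate_forest", "warm_temperate_forest",
    "tropical_forest", "grassland_dry_shrubland", "savanna_dry_woodland",
    "desert")
}

#' Pseudo climate-model labels
#' @return Character vector of length 2.
#' @export
model_labels <- function() c("pseudo_hadcm3", "pseudo_trace")

#' Default synthetic-world scenario
#'
#' Returns the full parameter set consumed by [simulate_climate()],
#' [simulate_ice_and_sea()] and [build_world()]. Any element can be
#' overridden via `...`.
#'
#' @param ... Named overrides merged over the defaults.
#' @return A named list of scenario parameters.
#' @export
default_scenario <- function(...) {
  sc <- list(
    # -- climate ------------------------------------------------------------
    pi_maat_at_23N     = 27,      # degC, preindustrial MAAT at the southern edge
    maat_lat_gradient  = 0.7653,  # degC per degree latitude
    lgm_cooling        = 15,      # degC amplitude of the glacial anomaly
    # warming trajectory weights: 1 at >=17 ka, 0.3 at 10 ka, 0 at 0 ka
    warming_mid_ka     = 17,
    warming_knee_ka    = 10,
    warming_knee_level = 0.3,
    seasonal_amp_base  = 14,      # degC annual range at 23 N
    seasonal_amp_gradient = 0.35, # degC per degree latitude
    precip_base        = 900,     # mm at the latitude of peak precipitation
    precip_lat_peak    = 55,
    precip_lat_gradient = 8,      # mm per degree away from the peak
    glacial_precip_factor = 0.75, # multiplier at full glacial conditions
    gs_frac_base       = 0.35,    # growing-season share of annual precip
    gs_frac_per_degC   = 0.02,
    dry_sector_lon     = c(30, 70),
    dry_sector_lat_max = 45,
    dry_core_factor    = 0.15,
    dry_edge_factor    = 0.45,
    dry_edge_width     = 10,      # degrees of longitude
    model_bias_trace   = -5,      # degC added to pseudo-TraCE MAAT
    noise_spatial_sd   = 1.0,     # degC, time-constant smooth field
    noise_slice_sd     = 0.3,     # degC, per-slice smooth field
    noise_scale_deg    = 15,      # correlation scale of the noise
    precip_noise_sd    = 0.10,    # lognormal sd on precipitation
    # -- geography ----------------------------------------------------------
    land_lat_max       = 78,
    sector_nearctic    = c(-170, -50),
    sector_palearctic  = c(-10, 140),
    shelf_width_lgm    = 11,      # degrees of longitude on each sector edge
    inundation_start_ka = 16,
    inundation_end_ka  = 7,
    ice_nearctic_lon   = c(-170, -50),
    ice_nearctic_lat   = 56,
    ice_palearctic_lon = c(-10, 40),
    ice_palearctic_lat = 60,
    cold_based_lat_nearctic   = 66,
    cold_based_lat_palearctic = 68,
    retreat_start_ka   = 17,
    retreat_end_ka     = 5,
    # -- surface fields -----------------------------------------------------
    base_slope_fraction = 0.02,
    mountain_boxes = data.frame(
      lat0 = c(35, 43, 28), lat1 = c(60, 48, 38),
      lon0 = c(-130, 5, 75), lon1 = c(-115, 20, 95),
      slope_fraction = c(0.45, 0.50, 0.55)),
    elev_base  = 300,
    elev_per_slope = 3500,
    elev_noise_sd  = 150,
    # -- peatlands ----------------------------------------------------------
    peat_pi_total_stock = 450,    # Pg C
    peat_pi_total_area  = 3.7e6,  # km^2
    peat_south_area     = 0.7e6,  # km^2 south of the initiation-data limit
    peat_band_lat       = c(50, 70),
    peat_south_lat      = c(30, 38),
    peat_south_lon      = c(-10, 30),
    peat_stock_peak_ka  = 8,      # millennium of fastest C accumulation
    peat_stock_width_ka = 3,
    peat_area_peak_ka   = 9,
    peat_area_width_ka  = 3.5,
    peat_onset_ka       = 16,
    peat_no_data_lat    = 38,     # south of this, initiation data are absent
    peat_default_init_ka = 12,
    peat_stock_rel_sd   = 0.36,
    peat_extent_rel_sd  = 0.10,
    peat_ramp_rel_sd_16ka = 0.50,
    # -- pollen-style training samples --------------------------------------
    holocene_n_per_slice = 1561,  # ~15,610 points over 9-0 ka
    deglacial_n_per_slice = 597,  # ~7,164 points over 21-10 ka
    label_noise        = 0.10,
    protected_rate     = 0.50,    # share of rows from the exempted source
    desert_aug_holocene = 242,
    desert_aug_deglacial = 40,
    # -- loess, shelf cycling, subglacial ------------------------------------
    loess = NULL,                 # filled with default_loess_spec() below
    retention_on_thaw  = 0.10,    # fraction of deep-loess C surviving thaw
    cycling_fraction   = 0.30,    # inundated C cycled via the atmosphere
    cycling_fraction_sd = 0.15,
    subglacial_tundra_density = 35, # kg C m^-2, 0-2 m
    subglacial_peat1m_density = 50, # kg C m^-2, upper metre of peat
    subglacial_peat_share = 0.01,
    subglacial_rel_sd  = 0.5,
    accrual_ka_to_transfer = 3)
  sc$loess <- default_loess_spec()
  override <- list(...)
  if (length(override)) {
    stopifnot(!is.null(names(override)), all(nzchar(names(override))))
    unknown <- setdiff(names(override), names(sc))
    if (length(unknown)) {
      stop("unknown scenario parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    sc[names(override)] <- override
  }
  sc
}

#' Default deep-loess region specification
#'
#' Four regions (Central Europe, Central Siberia, United States, China) whose
#' configured areas sum to 2.3 million km^2 and whose frozen stocks at 21 ka
#' sum to 363 Pg C; syn-depositional accumulation between 21 and 17 ka adds a
#' further 35 Pg C (peak 398 Pg C). Thawed carbon densities are one tenth of
#' the frozen densities.
#'
#' @return A data.frame with one row per region: the bounding box used to
#'   place its cells, nominal `area_km2`, `depth_below_2m` (m, includes the
#'   extra metre of original deposit so stocks below 2 m are fully counted),
#'   frozen/thawed C densities (kg C m^-3), relative SDs for area and depth,
#'   and `deposition_pg_per_ka` (Pg C per millennium during 21-17 ka).
#' @export
default_loess_spec <- function() {
  stock <- c(95, 120, 88, 60) # Pg C at 21 ka, sums to 363
  area <- c(0.6e6, 0.8e6, 0.5e6, 0.4e6) # km^2, sums to 2.3e6
  depth <- c(10, 15, 12, 10)  # m below 2 m
  dens_frozen <- stock / (area * 1e6 * depth) * 1e12 # kg C m^-3
  data.frame(
    region = c("central_europe", "central_siberia", "united_states", "china"),
    lat0 = c(49, 63, 49, 49), lat1 = c(55, 78, 55, 55),
    lon0 = c(0, 75, -110, 100), lon1 = c(13, 88, -100, 108),
    area_km2 = area,
    depth_below_2m = depth,
    c_density_frozen = dens_frozen,
    c_density_thawed = dens_frozen * 0.1,
    rel_sd_area = 0.076,
    rel_sd_depth = 0.076,
    deposition_pg_per_ka = stock / sum(stock) * 35 / 4)
}

#' Default biome-classification rule table
#'
#' An ordered decision list mapping climate space to the eight mega-biome
#' classes; the first matching rule wins and a catch-all guarantees
#' completeness. Thresholds are in degrees C and mm per year. `NA` means
#' unconstrained.
#'
#' @return A data.frame with columns `class`, `t_warm_min`, `t_warm_max`,
#'   `t_cold_min`, `t_cold_max`, `precip_min`, `precip_max`.
#' @export
default_biome_rules <- function() {
  data.frame(
    class = c("desert", "tundra", "tropical_forest", "warm_temperate_forest",
              "savanna_dry_woodland", "grassland_dry_shrubland",
              "temperate_forest", "boreal_forest"),
    t_warm_min = c(NA, NA, NA, NA, NA, NA, 15, NA),
    t_warm_max = c(NA, 10, NA, NA, NA, NA, NA, NA),
    t_cold_min = c(NA, NA, 18, 2, 10, NA, -18, NA),
    t_cold_max = c(NA, NA, NA, NA, NA, NA, NA, NA),
    precip_min = c(NA, NA, 700, 600, NA, NA, NA, NA),
    precip_max = c(150, NA, NA, NA, NA, 400, NA, NA))
}

#' Default carbon transfer-function table
#'
#' Typical mineral-soil carbon densities (kg C m^-2 over 0-2 m) per biome
#' class and permafrost state, with standard deviations, plus the alpine
#' slope density applied to steep-slope fractions.
#'
#' @return A list with `table` (data.frame: class, permafrost, mean_kg_m2,
#'   sd_kg_m2), `slope_density` (kg C m^-2), `slope_sd` and
#'   `slope_threshold_deg`.
#' @export
default_transfer_functions <- function() {
  cls <- biome_classes()
  mean_pf   <- c(35, 25, 13, 10, 9, 18, 7, 2)
  mean_nopf <- c(22, 16, 13, 10, 9, 10, 7, 2)
  sd_pf     <- c(15, 12, 6, 5, 5, 9, 4, 1.5)
  sd_nopf   <- c(10, 8, 6, 5, 5, 5, 4, 1.5)
  list(
    table = data.frame(
      class = rep(cls, 2),
      permafrost = rep(c(TRUE, FALSE), each = length(cls)),
      mean_kg_m2 = c(mean_pf, mean_nopf),
      sd_kg_m2 = c(sd_pf, sd_nopf)),
    slope_density = 3,
    slope_sd = 1.5,
    slope_threshold_deg = 4)
}

#' Default soil-development constants for deglaciated terrain
#'
#' Exponential accrual rates (per millennium) towards the biome-specific
#' carbon equilibrium. Boreal forest and tundra reach at least 95% of their
#' equilibrium after three millennia; grassland does not.
#'
#' @return Named numeric vector of rates `k` per biome class.
#' @export
default_accrual_rates <- function() {
  k <- rep(1.0, 8)
  names(k) <- biome_classes()
  k["grassland_dry_shrubland"] <- 0.5
  k
}

# deglacial warming weight: 1 at/before warming_mid_ka, knee at warming_knee_ka,
# 0 at 0 ka; piecewise linear in t (ka)
warming_weight <- function(t, scenario) {
  mid <- scenario$warming_mid_ka
  knee <- scenario$warming_knee_ka
  lvl <- scenario$warming_knee_level
  w <- ifelse(t >= mid, 1,
       ifelse(t >= knee, lvl + (1 - lvl) * (t - knee) / (mid - knee),
              lvl * t / knee))
  w
}
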
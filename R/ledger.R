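# Multi-pool carbon ledger: mineral soil stocks from biome fractions and
# transfer functions, deep-loess bookkeeping, peat distribution, post-glacial
# accrual, subglacial stocks, shelf transfers, and millennial net/gross
# changes.

POOL_NAMES <- c("mineral_land", "mineral_exposed_shelf", "mineral_inundated",
                "peat", "loess_deep", "subglacial", "postglacial_accruing")

#' Mineral soil carbon stock for one model and millennium
#'
#' Per-cell stock (0-2 m) from predicted biome area fractions and the
#' carbon transfer functions:
#' `area * [(1 - peat_frac - slope_frac) * sum_c frac_c * tf(c, state) +
#' slope_frac * slope_density]`, where `state` is permafrost/no-permafrost
#' from the continuous mask. The pool is split into land and exposed-shelf
#' parts by the preindustrial shoreline. Pool SDs treat each transfer
#' function's error as fully correlated across the cells it applies to and
#' independent between (class, state) combinations.
#'
#' @param biomes A [predict_biome_fractions()] map.
#' @param tf A [default_transfer_functions()] list.
#' @param continuous Logical matrix: continuous-permafrost state per cell.
#' @param peat_fraction Matrix: fraction of each cell occupied by peat.
#' @param slope_fraction Matrix: fraction of each cell that is steep slope.
#' @param domain A [make_domain()] grid.
#' @param land Logical matrix: land mask at this millennium.
#' @param shelf Logical matrix: cells of `land` that are ocean at 0 ka.
#' @param exclude Optional logical matrix of cells handled elsewhere (e.g.
#'   accruing post-glacial soils); their mineral stock is zero here.
#' @return A list of class `mineral_stock`: `cell_stock` (Pg C per cell),
#'   `pools` and `sd` (named: land, shelf).
#' @export
mineral_stock <- function(biomes, tf, continuous, peat_fraction,
                          slope_fraction, domain, land, shelf,
                          exclude = NULL) {
  over <- land & (peat_fraction + slope_fraction > 1 + 1e-9)
  if (any(over)) {
    ij <- which(over, arr.ind = TRUE)[1, ]
    stop("peat + slope fraction exceeds 1 in cell [", ij[1], ", ", ij[2],
         "]", call. = FALSE)
  }
  cls <- biome_classes()
  tft <- tf$table
  mean_of <- function(c, pf) tft$mean_kg_m2[tft$class == c &
                                              tft$permafrost == pf]
  sd_of <- function(c, pf) tft$sd_kg_m2[tft$class == c &
                                          tft$permafrost == pf]
  active <- land
  if (!is.null(exclude)) active <- active & !exclude
  area_m2 <- domain$area * 1e6
  open <- pmax(0, 1 - peat_fraction - slope_fraction)

  dens <- matrix(0, domain$nlat, domain$nlon)
  var_pool <- c(land = 0, shelf = 0)
  a_slope <- c(land = 0, shelf = 0)
  pool_of <- list(land = active & !shelf, shelf = active & shelf)
  for (k in seq_along(cls)) {
    frac_k <- biomes$fractions[, , k]
    for (pf in c(TRUE, FALSE)) {
      state <- if (pf) continuous else !continuous
      w <- frac_k * open * area_m2 * (active & state)
      dens <- dens + frac_k * mean_of(cls[k], pf) * state
      for (p in names(pool_of)) {
        A <- sum(w[pool_of[[p]]])
        var_pool[p] <- var_pool[p] + (A * sd_of(cls[k], pf) * 1e-12)^2
      }
    }
  }
  cell <- area_m2 * (open * dens + slope_fraction * tf$slope_density) *
    1e-12
  cell[!active] <- 0
  for (p in names(pool_of)) {
    A <- sum((slope_fraction * area_m2)[pool_of[[p]]])
    var_pool[p] <- var_pool[p] + (A * tf$slope_sd * 1e-12)^2
  }
  pools <- c(land = sum(cell[pool_of$land]),
             shelf = sum(cell[pool_of$shelf]))
  structure(list(cell_stock = cell, pools = pools, sd = sqrt(var_pool)),
            class = "mineral_stock")
}

#' Average per-model carbon stocks
#'
#' Arithmetic mean of two (or more) model runs' cell maps and pool totals,
#' with the inter-model spread retained as a diagnostic (reported as a
#' percentage of the mean pool SD).
#'
#' @param stocks List of [mineral_stock()] results on identical grids.
#' @return A `mineral_stock`-like list with an extra `intermodel_gap`
#'   element: per pool, half the max-min spread, and its percentage of the
#'   pool SD.
#' @export
average_models <- function(stocks) {
  dims <- lapply(stocks, function(s) dim(s$cell_stock))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("model runs are on mismatched grids", call. = FALSE)
  }
  cell <- Reduce(`+`, lapply(stocks, `[[`, "cell_stock")) / length(stocks)
  pools <- Reduce(`+`, lapply(stocks, `[[`, "pools")) / length(stocks)
  sd <- Reduce(`+`, lapply(stocks, `[[`, "sd")) / length(stocks)
  pmat <- do.call(rbind, lapply(stocks, `[[`, "pools"))
  gap <- (apply(pmat, 2, max) - apply(pmat, 2, min)) / 2
  structure(list(cell_stock = cell, pools = pools, sd = sd,
                 intermodel_gap = gap,
                 intermodel_gap_pct_of_sd =
                   ifelse(sd > 0, 100 * gap / sd, 0)),
            class = "mineral_stock")
}

#' Initialize the deep-loess bookkeeping state
#'
#' All region stock starts frozen; each model carries its own frozen-cell
#' set (initially every region cell) so the two permafrost delineations can
#' diverge.
#'
#' @param loess A [make_loess_regions()] object.
#' @param domain A [make_domain()] grid.
#' @return A list of class `loess_state` with per-model frozen stocks `F`,
#'   retained (post-thaw) stocks `R` and frozen-cell masks.
#' @export
loess_init <- function(loess, domain) {
  nr <- nrow(loess$spec)
  frozen_cells <- lapply(seq_len(nr), function(r)
    !is.na(loess$id) & loess$id == r)
  per_model <- lapply(model_labels(), function(m) {
    list(F = loess$spec$stock_21ka_pg, R = rep(0, nr),
         frozen = frozen_cells)
  })
  names(per_model) <- model_labels()
  structure(list(spec = loess$spec, domain = domain,
                 per_model = per_model, time = 21),
            class = "loess_state")
}

#' Advance the deep-loess ledger by one millennium
#'
#' During the depositional era (by default while the young millennium is at
#' or older than 17 ka) each region gains its configured syngenetic
#' deposition. Cells leaving the continuous-permafrost mask thaw their share
#' of the region's frozen stock within that millennium; a fraction
#' `retention` survives as a passive pool, the rest is released. Bookkeeping
#' runs per climate model and the reported stock is the model mean; the
#' half-spread between models enters the SD.
#'
#' @param state A [loess_init()] state at the old millennium.
#' @param continuous_by_model Named list (per model label) of logical
#'   continuous-permafrost masks at the young millennium.
#' @param t_young The young millennium (ka); must be `state$time - 1`.
#' @param retention Fraction of thawed C retained (default 0.1: more than
#'   90% is lost within the millennium of thaw).
#' @param deposition_until_ka Depositional era lasts while
#'   `t_young >= deposition_until_ka`.
#' @return Updated `loess_state` with elements `loss_pg` (release to the
#'   atmosphere this step, model mean), `stock_pg`, `sd_pg`, and per-region
#'   breakdown `region_stocks`.
#' @export
loess_step <- function(state, continuous_by_model, t_young,
                       retention = 0.1, deposition_until_ka = 17) {
  if (t_young != state$time - 1) {
    stop("loess_step must advance by exactly one millennium", call. = FALSE)
  }
  spec <- state$spec
  nr <- nrow(spec)
  if (nr == 0) {
    state$time <- t_young
    state$loss_pg <- 0
    state$stock_pg <- 0
    state$sd_pg <- 0
    state$region_stocks <- data.frame(region = character(0),
                                      stock_pg = numeric(0),
                                      sd_pg = numeric(0))
    return(state)
  }
  area <- state$domain$area
  losses <- matrix(0, length(state$per_model), nr)
  for (mi in seq_along(state$per_model)) {
    m <- names(state$per_model)[mi]
    ms <- state$per_model[[mi]]
    cont <- continuous_by_model[[m]]
    for (r in seq_len(nr)) {
      if (t_young >= deposition_until_ka) {
        ms$F[r] <- ms$F[r] + spec$deposition_pg_per_ka[r]
      }
      frozen <- ms$frozen[[r]]
      a_frozen <- sum(area[frozen])
      if (a_frozen > 0) {
        leaving <- frozen & !cont
        frac <- sum(area[leaving]) / a_frozen
        thawed_stock <- ms$F[r] * frac
        losses[mi, r] <- thawed_stock * (1 - retention)
        ms$R[r] <- ms$R[r] + thawed_stock * retention
        ms$F[r] <- ms$F[r] - thawed_stock
        ms$frozen[[r]] <- frozen & cont
      }
      if (ms$F[r] < -1e-9) stop("negative loess stock: bookkeeping bug",
                                call. = FALSE)
    }
    state$per_model[[mi]] <- ms
  }
  tot <- vapply(state$per_model, function(ms) ms$F + ms$R, numeric(nr))
  tot <- matrix(tot, nrow = nr)
  region_mean <- rowMeans(tot)
  model_gap <- (apply(tot, 1, max) - apply(tot, 1, min)) / 2
  rel <- sqrt(spec$rel_sd_area^2 + spec$rel_sd_depth^2)
  region_var <- (region_mean * rel)^2 + model_gap^2
  state$time <- t_young
  state$loss_pg <- mean(rowSums(losses))
  state$stock_pg <- sum(region_mean)
  state$sd_pg <- sqrt(sum(region_var))
  state$region_stocks <- data.frame(region = spec$region,
                                    stock_pg = region_mean,
                                    sd_pg = sqrt(region_var))
  state
}

# summary of a loess state without stepping (for the 21 ka slice)
loess_summary <- function(state) {
  spec <- state$spec
  nr <- nrow(spec)
  tot <- vapply(state$per_model, function(ms) ms$F + ms$R, numeric(nr))
  tot <- matrix(tot, nrow = nr)
  region_mean <- rowMeans(tot)
  rel <- sqrt(spec$rel_sd_area^2 + spec$rel_sd_depth^2)
  list(stock_pg = sum(region_mean),
       sd_pg = sqrt(sum((region_mean * rel)^2)))
}

#' Peatland stock and extent for one millennium
#'
#' The pool total is `pi_total_stock * stock_fraction(t)`; it is distributed
#' over cells with peat initiated by `t`, proportionally to each cell's
#' preindustrial peat area, and scaled so the total peat area equals
#' `pi_total_area * area_fraction(t)` (full preindustrial extent is reached
#' only at the final step). The SD combines the preindustrial extent
#' (+/-10%) and stock (+/-36%) uncertainties with a back-in-time ramp
#' (+/-50% at 16 ka falling linearly to 0 at 0 ka) by root-sum-of-variances.
#'
#' @param peat A [make_peat_curves()] object.
#' @param world A [build_world()] object.
#' @param t Millennium, ka.
#' @param stock_rel_sd,extent_rel_sd,ramp_rel_sd_16ka Relative SD
#'   components.
#' @return A list of class `peat_state`: `time`, `total_pg`, `sd_pg`,
#'   `stock_map` (Pg C per cell), `area_map` (km^2), `peat_fraction`
#'   (of cell area).
#' @export
peat_step <- function(peat, world, t, stock_rel_sd = 0.36,
                      extent_rel_sd = 0.10, ramp_rel_sd_16ka = 0.50) {
  cv <- peat$curves
  row <- cv[cv$time_ka == t, ]
  if (nrow(row) != 1) stop("no peat curve value at ", t, " ka",
                           call. = FALSE)
  domain <- world$domain
  i <- match(t, world$times)
  i0 <- match(0, world$times)
  eligible <- world$masks$land[, , i] & world$masks$land[, , i0] &
    peat$pi_extent > 0 & !is.na(peat$initiation) & peat$initiation >= t
  total <- peat$pi_total_stock * row$stock_fraction
  area_total <- peat$pi_total_area * row$area_fraction
  stock_map <- matrix(0, domain$nlat, domain$nlon)
  area_map <- matrix(0, domain$nlat, domain$nlon)
  if (area_total > 0 || total > 0) {
    w <- peat$pi_extent * domain$area
    w[!eligible] <- 0
    sw <- sum(w)
    if (sw <= 0) {
      stop("no eligible peat cells at ", t,
           " ka while the area curve is positive", call. = FALSE)
    }
    stock_map <- total * w / sw
    area_map <- area_total * w / sw
  }
  ramp <- ramp_rel_sd_16ka * min(t, 16) / 16
  sd <- total * sqrt(stock_rel_sd^2 + extent_rel_sd^2 + ramp^2)
  structure(list(time = t, total_pg = total, sd_pg = sd,
                 stock_map = stock_map, area_map = area_map,
                 peat_fraction = pmin(area_map / domain$area, 0.95)),
            class = "peat_state")
}

#' Carbon density of soils developing on deglaciated terrain
#'
#' Exponential approach to the biome-specific equilibrium:
#' `C(t) = (Ce_0_1 + Ce_1_2) * (1 - exp(-k t))` with `t` in millennia since
#' deglaciation. With default rates, boreal forest and tundra reach at least
#' 95% of equilibrium after three millennia; grassland does not. After
#' three millennia such cells transfer to the biome-based mineral stocks.
#'
#' @param time_since_deglaciation Millennia since the cell became ice-free
#'   (0-3).
#' @param biome_class One of [biome_classes()].
#' @param Ce Named list or data.frame of per-class equilibrium densities
#'   with components `ce_0_1` and `ce_1_2` (kg C m^-2).
#' @param k Named vector of per-class rates (per millennium).
#' @return Carbon density, kg C m^-2.
#' @export
postglacial_accrual <- function(time_since_deglaciation, biome_class,
                                Ce = default_accrual_equilibria(),
                                k = default_accrual_rates()) {
  if (!biome_class %in% biome_classes() || !biome_class %in% Ce$class) {
    stop("unknown biome class: ", biome_class, call. = FALSE)
  }
  row <- match(biome_class, Ce$class)
  ce <- Ce$ce_0_1[row] + Ce$ce_1_2[row]
  ce * (1 - exp(-k[[biome_class]] * time_since_deglaciation))
}

#' Equilibrium densities for post-glacial soil development
#'
#' Derived from the (non-permafrost) transfer functions, split between the
#' 0-1 m and 1-2 m intervals.
#'
#' @param tf A [default_transfer_functions()] list.
#' @param split_0_1 Share of the 0-2 m equilibrium in the upper metre.
#' @return data.frame `class`, `ce_0_1`, `ce_1_2` (kg C m^-2).
#' @export
default_accrual_equilibria <- function(tf = default_transfer_functions(),
                                       split_0_1 = 0.6) {
  tab <- tf$table[!tf$table$permafrost, ]
  data.frame(class = tab$class,
             ce_0_1 = tab$mean_kg_m2 * split_0_1,
             ce_1_2 = tab$mean_kg_m2 * (1 - split_0_1))
}

#' Carbon stock preserved beneath cold-based ice
#'
#' High-arctic tundra soil (0-2 m) across the cold-based area, plus peat
#' down to 1 m across a small share of it.
#'
#' @param mask Logical matrix of cold-based ice.
#' @param domain A [make_domain()] grid.
#' @param tundra_density kg C m^-2 over 0-2 m.
#' @param peat1m_density kg C m^-2 in the upper metre of peat.
#' @param peat_share Fraction of the area carrying that peat (default 1%).
#' @return Stock, Pg C.
#' @export
subglacial_stock <- function(mask, domain, tundra_density = 35,
                             peat1m_density = 50, peat_share = 0.01) {
  a <- sum(domain$area[mask]) * 1e6 # m^2
  (a * tundra_density + peat_share * a * peat1m_density) * 1e-12
}

#' Subglacial carbon release over one millennium of ice retreat
#'
#' The stock beneath cold-based ice shrinks with the cold-based area; the
#' difference is released to the atmosphere upon retreat (rapid oxidation).
#' Ice advance (a negative release) is rejected unless the scenario permits
#' readvance.
#'
#' @param mask_old,mask_young Cold-based masks at the two millennia.
#' @param domain A [make_domain()] grid.
#' @inheritParams subglacial_stock
#' @param allow_readvance Permit a negative release.
#' @return A list: `stock_old_pg`, `stock_young_pg`, `release_pg`.
#' @export
subglacial_step <- function(mask_old, mask_young, domain,
                            tundra_density = 35, peat1m_density = 50,
                            peat_share = 0.01, allow_readvance = FALSE) {
  s_old <- subglacial_stock(mask_old, domain, tundra_density,
                            peat1m_density, peat_share)
  s_young <- subglacial_stock(mask_young, domain, tundra_density,
                              peat1m_density, peat_share)
  release <- s_old - s_young
  if (release < -1e-9 && !allow_readvance) {
    stop("cold-based ice advance encountered but the scenario does not ",
         "permit readvance", call. = FALSE)
  }
  list(stock_old_pg = s_old, stock_young_pg = s_young,
       release_pg = release)
}

#' Transfer soil carbon from newly inundated shelf cells
#'
#' Soil C present on cells that are land at the old millennium but ocean at
#' the young one moves from the exposed-shelf pool to the inundated pool;
#' the total of the two pools is conserved exactly. A fraction
#' `cycling_fraction` of the transferred stock is assumed to cycle via the
#' atmosphere; that flux is recorded in net changes only, never in stocks.
#'
#' @param land_old,land_young Land masks at the two millennia.
#' @param stock_map_old Per-cell mineral stock (Pg C) at the old
#'   millennium.
#' @param cycling_fraction Fraction cycled via the atmosphere, in
#'   `[0, 0.66]` (default 0.30).
#' @param exposed_pool,inundated_pool Pool totals (Pg C) before the
#'   transfer.
#' @param ice_old Optional ice mask at the old millennium: cells gaining
#'   land are only legal where ice retreated; otherwise an error (no shelf
#'   re-emergence in the scenario).
#' @param cycling_sd_fraction SD of the cycling fraction (default half of
#'   it, matching the quoted 0-66% range).
#' @return A list: `transferred_pg`, `cycled_pg`, `cycled_sd_pg`,
#'   `exposed_pool`, `inundated_pool` (updated), `newly_inundated` mask.
#' @export
shelf_transfer <- function(land_old, land_young, stock_map_old,
                           cycling_fraction = 0.30,
                           exposed_pool = NULL, inundated_pool = 0,
                           ice_old = NULL, cycling_sd_fraction = 0.15) {
  if (cycling_fraction < 0 || cycling_fraction > 0.66) {
    stop("`cycling_fraction` must be in [0, 0.66]", call. = FALSE)
  }
  new_land <- land_young & !land_old
  if (any(new_land)) {
    legal <- if (is.null(ice_old)) matrix(FALSE, nrow(land_old),
                                          ncol(land_old)) else ice_old
    if (any(new_land & !legal)) {
      stop("land mask gains non-deglaciated cells: shelf re-emergence is ",
           "not permitted", call. = FALSE)
    }
  }
  newly_inundated <- land_old & !land_young
  transferred <- sum(stock_map_old[newly_inundated])
  out <- list(transferred_pg = transferred,
              cycled_pg = cycling_fraction * transferred,
              cycled_sd_pg = cycling_sd_fraction * transferred,
              newly_inundated = newly_inundated)
  if (!is.null(exposed_pool)) {
    out$exposed_pool <- exposed_pool - transferred
    out$inundated_pool <- inundated_pool + transferred
  }
  out
}

#' Construct a per-millennium carbon state
#'
#' @param time Millennium, ka.
#' @param pools,sds Named numeric vectors over the seven pools
#'   (`r paste(POOL_NAMES, collapse = ", ")`).
#' @param maps Optional list of per-cell maps (e.g. `mineral`, `peat`).
#' @return An object of class `carbon_state`.
#' @export
carbon_state <- function(time, pools, sds, maps = list()) {
  stopifnot(all(POOL_NAMES %in% names(pools)),
            all(POOL_NAMES %in% names(sds)))
  if (any(pools[POOL_NAMES] < -1e-9)) {
    stop("negative pool mean in carbon state at ", time, " ka",
         call. = FALSE)
  }
  structure(list(time = time, pools = pools[POOL_NAMES],
                 sds = sds[POOL_NAMES], maps = maps),
            class = "carbon_state")
}

#' @export
print.carbon_state <- function(x, ...) {
  cat(sprintf("<carbon_state> %d ka, total %.1f Pg C\n", x$time,
              sum(x$pools)))
  df <- data.frame(pool = names(x$pools), mean_pg = unname(x$pools),
                   sd_pg = unname(x$sds))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Net change between two consecutive carbon states
#'
#' Per-pool stock deltas plus the inundation cycling flux (counted in net
#' changes but never in stocks). The net transfer to (positive) or from
#' (negative) land is the total stock delta minus the cycled flux. Each
#' pool's change uncertainty comes from the dispersion index of its stock
#' at both millennia ([stock_cov()], [change_uncertainty()]); components
#' combine by root-sum-of-variances.
#'
#' @param state_old,state_young [carbon_state()]s at consecutive millennia
#'   (`state_old$time == state_young$time + 1`).
#' @param cycled_flux Inundation-cycled carbon this interval, Pg C (>= 0).
#' @param cycled_sd Its uncertainty, Pg C.
#' @return An object of class `flux_record`: `t_old`, `t_young`, `deltas`
#'   and `E` (named per pool), `cycled_pg`, `net_pg`, `net_sd_pg`.
#' @export
net_change <- function(state_old, state_young, cycled_flux = 0,
                       cycled_sd = 0) {
  if (state_old$time != state_young$time + 1) {
    stop("states must be at consecutive millennia (old = young + 1)",
         call. = FALSE)
  }
  deltas <- state_young$pools - state_old$pools
  V <- function(st) {
    ifelse(st$pools > 1e-12, stock_cov(st$sds^2, pmax(st$pools, 1e-12)), 0)
  }
  v_old <- V(state_old)
  v_young <- V(state_young)
  E <- change_uncertainty(v_old, v_young, deltas)
  net <- sum(deltas) - cycled_flux
  structure(list(t_old = state_old$time, t_young = state_young$time,
                 deltas = deltas, E = E, cycled_pg = cycled_flux,
                 cycled_sd_pg = cycled_sd, net_pg = net,
                 net_sd_pg = combine_errors(c(E, cycled_sd))),
            class = "flux_record")
}

#' @export
print.flux_record <- function(x, ...) {
  cat(sprintf("<flux_record> %d -> %d ka: net %+.1f +/- %.1f Pg C (cycled %.1f)\n",
              x$t_old, x$t_young, x$net_pg, x$net_sd_pg, x$cycled_pg))
  invisible(x)
}

#' Gross carbon gains and losses between two millennia
#'
#' Compares per-cell stock maps and sums positive and negative deltas
#' separately; gains + losses equal the net delta exactly.
#'
#' @param map_old,map_young Co-registered per-cell stock maps (Pg C).
#' @return A list: `gains_pg` (>= 0), `losses_pg` (<= 0), `net_pg`.
#' @export
gross_changes <- function(map_old, map_young) {
  if (!all(dim(map_old) == dim(map_young))) {
    stop("maps are not co-registered", call. = FALSE)
  }
  d <- map_young - map_old
  gains <- sum(d[d > 0])
  losses <- sum(d[d < 0])
  list(gains_pg = gains, losses_pg = losses, net_pg = gains + losses)
}
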
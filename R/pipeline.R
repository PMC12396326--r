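# End-to-end orchestration: world generation -> biome classifiers ->
# permafrost -> carbon ledger -> atmospheric translation, from a single
# serializable run configuration.

#' Default run configuration
#'
#' @param seed Integer seed driving every random stage.
#' @param resolution Grid resolution in degrees (1 for full runs; 5 for
#'   quick runs).
#' @param quick If TRUE, use the coarse 5-degree grid.
#' @param ... Scenario overrides forwarded to [default_scenario()].
#' @return A named list of class `run_config`.
#' @export
default_config <- function(seed = 1, resolution = if (quick) 5 else 1,
                           quick = FALSE, ...) {
  structure(list(
    seed = seed,
    resolution = resolution,
    scenario = default_scenario(...),
    classifier = list(num_trees = 500, min_node_size = 1),
    permafrost = default_permafrost_params(),
    transfer_functions = default_transfer_functions(),
    constants = default_constants(),
    ppm_mode = "per_millennium"),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Statically checks every stage precondition; each violation names the
#' offending field and rule.
#'
#' @param config A [default_config()]-style list.
#' @return Character vector of violations (empty when valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  bad <- function(msg) v <<- c(v, msg)
  sc <- config$scenario
  if (is.null(config$seed) || !is.finite(config$seed)) {
    bad("seed: a finite integer seed is required")
  }
  if (is.null(config$resolution) || config$resolution <= 0 ||
      abs(360 / config$resolution - round(360 / config$resolution)) > 1e-9) {
    bad("resolution: must be positive and divide 360 evenly")
  }
  if (!is.null(config$classifier$num_trees) &&
      config$classifier$num_trees < 1) {
    bad("classifier$num_trees: ensemble size must be >= 1")
  }
  if (sc$cycling_fraction < 0 || sc$cycling_fraction > 0.66) {
    bad("scenario$cycling_fraction: must lie in [0, 0.66]")
  }
  if (sc$retention_on_thaw < 0 || sc$retention_on_thaw > 1) {
    bad("scenario$retention_on_thaw: must lie in [0, 1]")
  }
  if (sc$label_noise < 0 || sc$label_noise > 1) {
    bad("scenario$label_noise: must lie in [0, 1]")
  }
  if (sc$retreat_start_ka <= sc$retreat_end_ka) {
    bad("scenario$retreat_start_ka: ice retreat schedule must be monotone")
  }
  if (sc$inundation_start_ka <= sc$inundation_end_ka) {
    bad("scenario$inundation_start_ka: inundation schedule must be monotone")
  }
  if (sc$peat_pi_total_stock <= 0) {
    bad("scenario$peat_pi_total_stock: must be positive")
  }
  pf <- config$permafrost
  if (pf$s <= 0) bad("permafrost$s: logistic scale must be positive")
  if (pf$continuous_threshold <= 0 || pf$continuous_threshold > 1) {
    bad("permafrost$continuous_threshold: must lie in (0, 1]")
  }
  cn <- config$constants
  if (cn$airborne_fraction <= 0 || cn$airborne_fraction > 1) {
    bad("constants$airborne_fraction: must lie in (0, 1]")
  }
  if (cn$uptake_response <= 0 || cn$uptake_response > 1) {
    bad("constants$uptake_response: must lie in (0, 1]")
  }
  ls <- sc$loess
  if (nrow(ls) > 0 && any(ls$c_density_thawed >= ls$c_density_frozen)) {
    bad("scenario$loess: thawed C density must be below frozen density")
  }
  v
}

#' Run the full carbon-stock reconstruction
#'
#' Executes every stage for both pseudo climate models, averages the mineral
#' stocks across models, and assembles per-millennium pool totals, flux
#' records, gross changes, the atmospheric CO2 series and the classifier
#' accuracy table.
#'
#' @param config A [default_config()] list.
#' @param verbose Log stage progress to the console.
#' @return An object of class `carbon_reconstruction`.
#' @export
run_reconstruction <- function(config = default_config(), verbose = FALSE) {
  viol <- validate_config(config)
  if (length(viol)) {
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  sc <- config$scenario
  tf <- config$transfer_functions
  pfp <- config$permafrost

  say("stage world: building synthetic world at %g deg", config$resolution)
  domain <- make_domain(config$resolution)
  world <- build_world(domain, sc, seed = seed)
  times <- world$times
  nt <- length(times)

  say("stage biomes: sampling training data and fitting classifiers")
  train_h <- sample_pollen_sites(world, sc$holocene_n_per_slice,
                                 sc$label_noise, sc$protected_rate,
                                 seed = sub_seed(seed, 10), times = 9:0)
  train_d <- sample_pollen_sites(world, sc$deglacial_n_per_slice,
                                 sc$label_noise, sc$protected_rate,
                                 seed = sub_seed(seed, 11), times = 21:10)
  aug_h <- augment_deserts(train_h, world, "holocene",
                           seed = sub_seed(seed, 12),
                           n_holocene = sc$desert_aug_holocene)
  aug_d <- augment_deserts(train_d, world, "deglacial",
                           seed = sub_seed(seed, 13),
                           n_deglacial = sc$desert_aug_deglacial,
                           holocene_train = train_h)
  hold_h <- sample_pollen_sites(world, max(50, sc$holocene_n_per_slice %/% 4),
                                sc$label_noise, sc$protected_rate,
                                seed = sub_seed(seed, 14), times = 9:0)
  hold_d <- sample_pollen_sites(world, max(50, sc$deglacial_n_per_slice %/% 4),
                                sc$label_noise, sc$protected_rate,
                                seed = sub_seed(seed, 15), times = 21:10)

  bundles <- list()
  accuracy <- list()
  warnings_log <- character(0)
  for (m in model_labels()) {
    withCallingHandlers({
      fh <- filter_training(aug_h, world, m)
      fd <- filter_training(aug_d, world, m)
      bundles[[m]] <- list(
        holocene = fit_biome_classifier(
          fh, "holocene", world, m, num_trees = config$classifier$num_trees,
          min_node_size = config$classifier$min_node_size,
          seed = sub_seed(seed, 20)),
        deglacial = fit_biome_classifier(
          fd, "deglacial", world, m, num_trees = config$classifier$num_trees,
          min_node_size = config$classifier$min_node_size,
          seed = sub_seed(seed, 21)))
      acc <- rbind(evaluate_accuracy(bundles[[m]]$deglacial, hold_d, world),
                   evaluate_accuracy(bundles[[m]]$holocene, hold_h, world))
      acc$model <- m
      accuracy[[m]] <- acc
    }, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  accuracy_df <- do.call(rbind, accuracy)
  rownames(accuracy_df) <- NULL

  say("stage ledger: %d slices x %d models", nt, length(model_labels()))
  loess_state <- loess_init(world$loess, domain)
  i0 <- match(0, times)
  land0 <- world$masks$land[, , i0]
  states <- vector("list", nt)
  pf_extent <- list()
  inundated_pool <- 0
  inundated_var <- 0
  cycled <- numeric(nt - 1)
  cycled_sd <- numeric(nt - 1)
  prev_total_map <- NULL
  prev_land <- NULL
  prev_ice <- NULL
  gross <- list()
  total_maps <- vector("list", nt)

  for (i in seq_len(nt)) {
    t <- times[i]
    land_t <- world$masks$land[, , i]
    shelf_t <- land_t & !land0
    ice_t <- world$masks$ice[, , i]
    dg_age <- world$masks$deglaciation_ka - t
    accruing <- !is.na(dg_age) & dg_age >= 0 &
      dg_age <= sc$accrual_ka_to_transfer & land_t

    peat_t <- peat_step(world$peat, world, t,
                        stock_rel_sd = sc$peat_stock_rel_sd,
                        extent_rel_sd = sc$peat_extent_rel_sd,
                        ramp_rel_sd_16ka = sc$peat_ramp_rel_sd_16ka)

    per_model <- list()
    cont_by_model <- list()
    for (m in model_labels()) {
      pm <- permafrost_map(world, m, t, pfp)
      cont_by_model[[m]] <- pm$continuous
      pf_extent[[length(pf_extent) + 1]] <-
        data.frame(time_ka = t, model = m, area_km2 = pm$area_km2)
      bundle <- bundles[[m]][[period_for_slice(t)]]
      bm <- predict_biome_fractions(bundle, world, t)
      ms <- mineral_stock(bm, tf, pm$continuous, peat_t$peat_fraction,
                          world$slope_fraction, domain, land_t, shelf_t,
                          exclude = accruing)
      acr <- accrual_stock(bm, tf, dg_age, accruing, peat_t$peat_fraction,
                           world$slope_fraction, domain)
      per_model[[m]] <- list(mineral = ms, accrual = acr)
    }
    ms_avg <- average_models(lapply(per_model, `[[`, "mineral"))
    acr_pool <- mean(vapply(per_model, function(x) x$accrual$pool,
                            numeric(1)))
    acr_sd <- mean(vapply(per_model, function(x) x$accrual$sd, numeric(1)))
    acr_map <- Reduce(`+`, lapply(per_model, function(x) x$accrual$cell)) /
      length(per_model)

    if (i > 1) {
      loess_state <- loess_step(loess_state, cont_by_model, t,
                                retention = sc$retention_on_thaw)
      loess_pool <- loess_state$stock_pg
      loess_sd <- loess_state$sd_pg
      loess_loss <- loess_state$loss_pg
    } else {
      ls0 <- loess_summary(loess_state)
      loess_pool <- ls0$stock_pg
      loess_sd <- ls0$sd_pg
      loess_loss <- 0
    }

    cb_t <- world$masks$cold_based[, , i]
    sub_pool <- subglacial_stock(cb_t, domain, sc$subglacial_tundra_density,
                                 sc$subglacial_peat1m_density,
                                 sc$subglacial_peat_share)
    sub_sd <- sub_pool * sc$subglacial_rel_sd

    if (i > 1) {
      tr <- shelf_transfer(prev_land, land_t, prev_mineral_map,
                           cycling_fraction = sc$cycling_fraction,
                           ice_old = prev_ice,
                           cycling_sd_fraction = sc$cycling_fraction_sd)
      cycled[i - 1] <- tr$cycled_pg
      cycled_sd[i - 1] <- tr$cycled_sd_pg
      inundated_pool <- inundated_pool + tr$transferred_pg
      rel <- prev_shelf_rel_sd
      inundated_var <- inundated_var + (tr$transferred_pg * rel)^2
    }

    pools <- c(mineral_land = unname(ms_avg$pools["land"]),
               mineral_exposed_shelf = unname(ms_avg$pools["shelf"]),
               mineral_inundated = inundated_pool,
               peat = peat_t$total_pg,
               loess_deep = loess_pool,
               subglacial = sub_pool,
               postglacial_accruing = acr_pool)
    sds <- c(mineral_land = unname(ms_avg$sd["land"]),
             mineral_exposed_shelf = unname(ms_avg$sd["shelf"]),
             mineral_inundated = sqrt(inundated_var),
             peat = peat_t$sd_pg,
             loess_deep = loess_sd,
             subglacial = sub_sd,
             postglacial_accruing = acr_sd)
    total_map <- ms_avg$cell_stock + peat_t$stock_map + acr_map
    states[[i]] <- carbon_state(t, pools, sds,
                                maps = list(mineral = ms_avg$cell_stock,
                                            peat = peat_t$stock_map,
                                            accrual = acr_map))
    total_maps[[i]] <- total_map
    if (i > 1) {
      g <- gross_changes(prev_total_map, total_map)
      gross[[i - 1]] <- data.frame(t_old = times[i - 1], t_young = t,
                                   gains_pg = g$gains_pg,
                                   losses_pg = g$losses_pg)
    }
    prev_total_map <- total_map
    prev_mineral_map <- ms_avg$cell_stock
    prev_land <- land_t
    prev_ice <- ice_t
    prev_shelf_rel_sd <- if (ms_avg$pools["shelf"] > 1e-9) {
      unname(ms_avg$sd["shelf"] / ms_avg$pools["shelf"])
    } else 0
  }

  say("stage atmosphere: flux records and ppm series")
  records <- vector("list", nt - 1)
  for (i in seq_len(nt - 1)) {
    records[[i]] <- net_change(states[[i]], states[[i + 1]],
                               cycled_flux = cycled[i],
                               cycled_sd = cycled_sd[i])
  }
  fluxes <- do.call(rbind, lapply(records, function(r) {
    data.frame(t_old = r$t_old, t_young = r$t_young,
               as.list(stats::setNames(r$deltas,
                                       paste0("d_", names(r$deltas)))),
               cycled_pg = r$cycled_pg, net_pg = r$net_pg,
               net_sd_pg = r$net_sd_pg)
  }))
  ppm <- ppm_series(fluxes, config$constants, mode = config$ppm_mode)

  pools_df <- do.call(rbind, lapply(states, function(s) {
    data.frame(time_ka = s$time, pool = names(s$pools),
               mean_pg = unname(s$pools), sd_pg = unname(s$sds))
  }))
  rownames(pools_df) <- NULL

  deglacial <- fluxes$t_young >= 10
  holocene <- fluxes$t_young <= 8
  cum_deglacial <- sum(fluxes$net_pg[deglacial])
  cum_holocene <- sum(fluxes$net_pg[holocene])
  totals <- vapply(states, function(s) sum(s$pools), numeric(1))
  summaries <- list(
    cumulative_deglacial_net_pg = cum_deglacial,
    cumulative_holocene_net_pg = cum_holocene,
    deglacial_ppm = pgc_to_ppm(-cum_deglacial,
                               config$constants$airborne_fraction,
                               config$constants),
    holocene_ppm = -pgc_to_ppm(cum_holocene,
                               config$constants$uptake_response,
                               config$constants),
    lgm_to_pi_stock_change_pg = totals[nt] - totals[1],
    stock_minimum_ka = times[which.min(totals)],
    stock_minimum_rel_lgm_pg = min(totals) - totals[1],
    mean_accuracy = mean(accuracy_df$accuracy),
    loess_remaining_pg = states[[nt]]$pools[["loess_deep"]],
    loess_peak_pg = max(vapply(states, function(s)
      s$pools[["loess_deep"]], numeric(1))))

  structure(list(config = config, world = world, states = states,
                 pools = pools_df, fluxes = fluxes, flux_records = records,
                 ppm = ppm, gross = do.call(rbind, gross),
                 accuracy = accuracy_df,
                 permafrost_extent = do.call(rbind, pf_extent),
                 summaries = summaries, warnings = warnings_log,
                 provenance = list(config_hash = config_hash(config),
                                   package_version =
                                     as.character(utils::packageVersion("paleocarb")))),
            class = "carbon_reconstruction")
}

# per-cell stock of accruing post-glacial soils (kg m^-2 -> Pg)
accrual_stock <- function(biomes, tf, dg_age, accruing, peat_fraction,
                          slope_fraction, domain) {
  cls <- biome_classes()
  k <- default_accrual_rates()
  Ce <- default_accrual_equilibria(tf)
  area_m2 <- domain$area * 1e6
  open <- pmax(0, 1 - peat_fraction - slope_fraction)
  dens <- matrix(0, domain$nlat, domain$nlon)
  var_pool <- 0
  tab <- tf$table[!tf$table$permafrost, ]
  age <- dg_age
  age[!accruing | is.na(age)] <- 0
  for (kk in seq_along(cls)) {
    ce <- Ce$ce_0_1[Ce$class == cls[kk]] + Ce$ce_1_2[Ce$class == cls[kk]]
    gain <- (1 - exp(-k[[cls[kk]]] * age)) * accruing
    dens_k <- biomes$fractions[, , kk] * ce * gain
    dens <- dens + dens_k
    A <- sum((biomes$fractions[, , kk] * gain * open * area_m2)[accruing])
    sd_k <- tab$sd_kg_m2[tab$class == cls[kk]]
    var_pool <- var_pool + (A * sd_k * 1e-12)^2
  }
  cell <- area_m2 * open * dens * 1e-12
  cell[!accruing] <- 0
  list(cell = cell, pool = sum(cell), sd = sqrt(var_pool))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' @export
print.carbon_reconstruction <- function(x, ...) {
  s <- x$summaries
  cat("<carbon_reconstruction>\n")
  cat(sprintf("  grid: %g deg, %d millennial slices, seed %s\n",
              x$config$resolution, length(x$states),
              format(x$config$seed)))
  cat(sprintf("  LGM -> PI total stock change: %+.0f Pg C (minimum %+.0f Pg C at %d ka)\n",
              s$lgm_to_pi_stock_change_pg, s$stock_minimum_rel_lgm_pg,
              s$stock_minimum_ka))
  cat(sprintf("  cumulative net 21-10 ka: %+.0f Pg C (%.1f ppm at %.0f%% airborne)\n",
              s$cumulative_deglacial_net_pg, s$deglacial_ppm,
              100 * x$config$constants$airborne_fraction))
  cat(sprintf("  cumulative net 9-0 ka:  %+.0f Pg C (%.1f ppm at %.0f%% uptake response)\n",
              s$cumulative_holocene_net_pg, s$holocene_ppm,
              100 * x$config$constants$uptake_response))
  cat(sprintf("  classifier mean held-out accuracy: %.3f\n", s$mean_accuracy))
  invisible(x)
}

#' @export
summary.carbon_reconstruction <- function(object, ...) {
  print(object)
  cat("\nPool totals (Pg C):\n")
  wide <- stats::reshape(object$pools, idvar = "time_ka",
                         timevar = "pool", direction = "wide",
                         drop = "sd_pg")
  names(wide) <- sub("^mean_pg\\.", "", names(wide))
  wide$total <- rowSums(wide[, -1])
  print(wide, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Plot a reconstruction
#'
#' Two panels: stacked pool trajectories (Pg C per millennium) and the net
#' millennial transfers with their propagated uncertainties.
#'
#' @param x A `carbon_reconstruction`.
#' @param ... Unused.
#' @export
plot.carbon_reconstruction <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  wide <- stats::reshape(x$pools, idvar = "time_ka", timevar = "pool",
                         direction = "wide", drop = "sd_pg")
  names(wide) <- sub("^mean_pg\\.", "", names(wide))
  t <- wide$time_ka
  total <- rowSums(wide[, -1])
  graphics::plot(t, total, type = "l", lwd = 2, xlim = rev(range(t)),
                 xlab = "ka BP", ylab = "Pg C",
                 main = "Land carbon stocks by pool")
  cols <- grDevices::hcl.colors(length(POOL_NAMES), "Dark 3")
  for (j in seq_along(POOL_NAMES)) {
    graphics::lines(t, wide[[POOL_NAMES[j]]], col = cols[j])
  }
  graphics::legend("topleft", c("total", POOL_NAMES), lwd = c(2, rep(1, 7)),
                   col = c("black", cols), cex = 0.6, bty = "n")
  f <- x$fluxes
  graphics::plot(f$t_young, f$net_pg, type = "h", lwd = 3,
                 xlim = rev(range(f$t_young)),
                 ylim = range(c(f$net_pg - f$net_sd_pg,
                                f$net_pg + f$net_sd_pg)),
                 xlab = "ka BP", ylab = "net transfer (Pg C)",
                 main = "Millennial net land-C transfers")
  graphics::arrows(f$t_young, f$net_pg - f$net_sd_pg, f$t_young,
                   f$net_pg + f$net_sd_pg, angle = 90, code = 3,
                   length = 0.02, col = "grey50")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
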
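# Serialization: run configuration to/from YAML, and CSV writers for the
# gridded and tabular artifacts.

df_fields <- list(c("scenario", "mountain_boxes"),
                  c("scenario", "loess"),
                  c("transfer_functions", "table"))

#' Write a run configuration to a YAML file
#'
#' The configuration (scenario, classifier, permafrost, transfer functions,
#' constants, seed) fully determines a run; a reconstruction regenerates
#' bit-identically from it.
#'
#' @param config A [default_config()] list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  for (f in df_fields) {
    x[[f]] <- lapply(as.data.frame(x[[f]]), identity)
  }
  x$permafrost$base_offset <- as.list(x$permafrost$base_offset)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file written by [write_config()].
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  x <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("cannot parse config file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  for (f in df_fields) {
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]])
  }
  if (!is.null(x$permafrost$base_offset)) {
    x$permafrost$base_offset <- unlist(x$permafrost$base_offset)
  }
  structure(x, class = "run_config")
}

#' Write a gridded field to long-format CSV
#'
#' One row per cell (and per time slice for 3-d arrays), columns `time_ka`
#' (if applicable), `lat`, `lon`, `value`.
#'
#' @param field Matrix `[nlat, nlon]` or array `[nlat, nlon, nslab]` (the
#'   third axis may be time or, e.g., the biome classes of a fraction map).
#' @param domain The [make_domain()] grid.
#' @param path Output file.
#' @param times Third-axis labels for 3-d arrays.
#' @param name Column name for the values.
#' @param slab_name Column name for the third axis (default `time_ka`).
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(field, domain, path, times = NULL,
                           name = "value", slab_name = "time_ka") {
  grid <- expand.grid(lat = domain$lat_centers, lon = domain$lon_centers)
  if (length(dim(field)) == 3) {
    stopifnot(!is.null(times))
    out <- do.call(rbind, lapply(seq_along(times), function(i) {
      cbind(slab = times[i], grid, v = c(field[, , i]))
    }))
    names(out)[names(out) == "slab"] <- slab_name
  } else {
    out <- cbind(grid, v = c(field))
  }
  names(out)[names(out) == "v"] <- name
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the tabular artifacts of a reconstruction
#'
#' Emits `pools.csv`, `fluxes.csv`, `ppm.csv`, `gross.csv`,
#' `accuracy.csv`, `permafrost_extent.csv` and `config.yaml` under `dir`.
#'
#' @param recon A [run_reconstruction()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reconstruction <- function(recon, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE)
  w(recon$pools, "pools.csv")
  w(recon$fluxes, "fluxes.csv")
  w(recon$ppm, "ppm.csv")
  w(recon$gross, "gross.csv")
  w(recon$accuracy, "accuracy.csv")
  w(recon$permafrost_extent, "permafrost_extent.csv")
  write_config(recon$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write training samples to CSV
#'
#' Columns `site_id`, `lon`, `lat`, `time_ka`, `biome`, `protected`.
#'
#' @param train A [sample_pollen_sites()] data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_training_csv <- function(train, path) {
  utils::write.csv(train[, c("site_id", "lon", "lat", "time_ka", "biome",
                             "protected")], path, row.names = FALSE)
  invisible(path)
}

#' Write peat curves to CSV
#'
#' Columns `time_ka`, `area_fraction`, `stock_fraction`.
#'
#' @param peat A [make_peat_curves()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peat_curves_csv <- function(peat, path) {
  utils::write.csv(peat$curves, path, row.names = FALSE)
  invisible(path)
}
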
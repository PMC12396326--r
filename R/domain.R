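# Grid domain for the northern (>23 degrees N) cap.

EARTH_RADIUS_KM <- 6371.0
LAT_MIN <- 23
LAT_MAX <- 90

#' Build the latitude-longitude grid domain
#'
#' Constructs a regular grid over the northern cap (23-90 degrees N, all
#' longitudes) with per-cell areas from the spherical band formula
#' \eqn{A = R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)}. Cell centres sit at
#' half-resolution offsets; latitude edges are inclusive-lower /
#' exclusive-upper. If the resolution does not divide the 67-degree band
#' evenly, the northernmost row is a partial row reaching exactly 90 N, so
#' the cap is always covered in full.
#'
#' @param resolution Cell size in degrees. Must be positive and divide 360
#'   evenly (longitude rows must tile the circle).
#' @param radius_km Planetary radius in km used for areas.
#' @return An object of class `grid_domain`: a list with `lat_edges`,
#'   `lon_edges`, `lat_centers`, `lon_centers`, `area` (nlat x nlon matrix,
#'   km^2), `nlat`, `nlon`, `resolution`.
#' @examples
#' d <- make_domain(5)
#' sum(d$area) # spherical cap area north of 23 N
#' @export
make_domain <- function(resolution = 1, radius_km = EARTH_RADIUS_KM) {
  if (!is.numeric(resolution) || length(resolution) != 1 ||
      !is.finite(resolution) || resolution <= 0) {
    stop("`resolution` must be a single positive number", call. = FALSE)
  }
  if (abs(360 / resolution - round(360 / resolution)) > 1e-9) {
    stop("`resolution` must divide 360 degrees of longitude evenly",
         call. = FALSE)
  }
  band <- LAT_MAX - LAT_MIN
  n_full <- floor(band / resolution + 1e-9)
  lat_edges <- LAT_MIN + resolution * seq(0, n_full)
  if (lat_edges[length(lat_edges)] < LAT_MAX - 1e-9) {
    lat_edges <- c(lat_edges, LAT_MAX) # partial top row
  }
  lon_edges <- seq(-180, 180, by = resolution)
  nlat <- length(lat_edges) - 1
  nlon <- length(lon_edges) - 1
  lat_centers <- (lat_edges[-1] + lat_edges[-(nlat + 1)]) / 2
  lon_centers <- (lon_edges[-1] + lon_edges[-(nlon + 1)]) / 2
  # band area per row, split over nlon equal longitude steps
  phi1 <- lat_edges[-(nlat + 1)] * pi / 180
  phi2 <- lat_edges[-1] * pi / 180
  row_area <- radius_km^2 * (sin(phi2) - sin(phi1)) *
    (resolution * pi / 180)
  area <- matrix(row_area, nrow = nlat, ncol = nlon)
  structure(
    list(lat_edges = lat_edges, lon_edges = lon_edges,
         lat_centers = lat_centers, lon_centers = lon_centers,
         area = area, nlat = nlat, nlon = nlon,
         resolution = resolution, radius_km = radius_km),
    class = "grid_domain")
}

#' @export
print.grid_domain <- function(x, ...) {
  cat(sprintf("<grid_domain> %d x %d cells at %g deg, %.4g km^2 total\n",
              x$nlat, x$nlon, x$resolution, sum(x$area)))
  invisible(x)
}

# matrix of cell-centre latitudes (same shape as domain$area)
lat_matrix <- function(domain) {
  matrix(domain$lat_centers, nrow = domain$nlat, ncol = domain$nlon)
}

lon_matrix <- function(domain) {
  matrix(domain$lon_centers, nrow = domain$nlat, ncol = domain$nlon,
         byrow = TRUE)
}
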
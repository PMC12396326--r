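# Uncertainty propagation for stock changes and translation of net land-C
# transfers into atmospheric CO2 (ppm), plus ice-core millennial differencing.

#' Atmospheric constants
#'
#' @param atmosphere_mass Mass of the atmosphere, g (constant over time).
#' @param airborne_fraction Share of released C remaining airborne on
#'   millennial scales.
#' @param uptake_response Linear atmospheric CO2 response to peatland C
#'   uptake.
#' @param molar_mass_air,molar_mass_C g/mol.
#' @return Named list of constants.
#' @export
default_constants <- function(atmosphere_mass = 5.15e21,
                              airborne_fraction = 0.25,
                              uptake_response = 0.13,
                              molar_mass_air = 28.966,
                              molar_mass_C = 12.011) {
  stopifnot(airborne_fraction > 0, airborne_fraction <= 1,
            uptake_response > 0, uptake_response <= 1)
  list(atmosphere_mass = atmosphere_mass,
       airborne_fraction = airborne_fraction,
       uptake_response = uptake_response,
       molar_mass_air = molar_mass_air,
       molar_mass_C = molar_mass_C)
}

#' Variance-to-mean ratio of a stock
#'
#' `V = sigma^2 / mu`, the dispersion index used to scale change
#' uncertainties. Note this is the variance (not the SD) over the mean, so
#' it is not the conventional dimensionless coefficient of variation; it is
#' implemented in this form deliberately.
#'
#' @param sigma2 Stock variance, (Pg C)^2.
#' @param mu Mean stock, Pg C, > 0.
#' @return V (Pg C).
#' @export
stock_cov <- function(sigma2, mu) {
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  if (any(sigma2 < 0)) stop("`sigma2` must be non-negative", call. = FALSE)
  sigma2 / mu
}

#' Uncertainty of a millennial stock change
#'
#' `E = mean(V_t, V_t1) * |delta|`: the stock dispersion index averaged over
#' the two consecutive millennia, scaled by the magnitude of the change.
#' Zero change has zero uncertainty.
#'
#' @param V_t,V_t1 Dispersion indices ([stock_cov()]) at the two millennia.
#' @param delta Stock change, Pg C (sign irrelevant).
#' @return Uncertainty, Pg C.
#' @export
change_uncertainty <- function(V_t, V_t1, delta) {
  if (any(V_t < 0) || any(V_t1 < 0)) {
    stop("V must be non-negative", call. = FALSE)
  }
  (V_t + V_t1) / 2 * abs(delta)
}

#' Combine independent uncertainties
#'
#' Root of summed variances.
#'
#' @param components Numeric vector of uncertainties (Pg C), all >= 0.
#' @return Combined uncertainty, Pg C.
#' @export
combine_errors <- function(components) {
  if (any(components < 0)) stop("components must be non-negative",
                                call. = FALSE)
  sqrt(sum(components^2))
}

#' Convert a carbon transfer to an atmospheric CO2 change
#'
#' `ppm = (delta_C * response * 1e15 / M_C) / (m_atm / M_air) * 1e6`: moles
#' of carbon reaching the atmosphere over moles of air, in parts per
#' million. With the default constants 1 ppm corresponds to about 2.13 Pg C.
#' The sign of `delta_C` is preserved: pass a release as positive to obtain
#' a positive ppm contribution.
#'
#' @param delta_C Carbon transfer, Pg C.
#' @param response_fraction Share of the transfer expressed in the
#'   atmosphere (airborne fraction for releases, uptake response for
#'   peat-driven gains).
#' @param constants A [default_constants()] list.
#' @return CO2 change, ppm.
#' @export
pgc_to_ppm <- function(delta_C, response_fraction,
                       constants = default_constants()) {
  mol_air <- constants$atmosphere_mass / constants$molar_mass_air
  mol_c <- delta_C * response_fraction * 1e15 / constants$molar_mass_C
  mol_c / mol_air * 1e6
}

#' Inverse of [pgc_to_ppm()]
#' @param ppm CO2 change, ppm.
#' @inheritParams pgc_to_ppm
#' @return Carbon transfer, Pg C.
#' @export
ppm_to_pgc <- function(ppm, response_fraction,
                       constants = default_constants()) {
  mol_air <- constants$atmosphere_mass / constants$molar_mass_air
  ppm / 1e6 * mol_air * constants$molar_mass_C / 1e15 / response_fraction
}

#' Millennial CO2 changes from an ice-core record
#'
#' Bins the record by millennium (ages in `[t, t+1)` ka fall in bin `t`) and
#' sums consecutive-point differences within each bin, which telescopes to
#' the last-minus-first point of the bin (ordered old to young). Millennia
#' with fewer than two points are reported as missing, not zero.
#'
#' @param series data.frame with columns `age_ka` and `co2_ppm`, sorted by
#'   age.
#' @return data.frame `time_ka`, `n`, `delta_ppm` (NA for empty bins).
#' @export
icecore_millennial_delta <- function(series) {
  if (is.unsorted(series$age_ka) && is.unsorted(rev(series$age_ka))) {
    stop("`series` must be sorted by age", call. = FALSE)
  }
  bins <- floor(series$age_ka)
  out <- lapply(sort(unique(bins), decreasing = TRUE), function(b) {
    pts <- series[bins == b, , drop = FALSE]
    pts <- pts[order(pts$age_ka, decreasing = TRUE), ] # old to young
    delta <- if (nrow(pts) >= 2) {
      sum(diff(pts$co2_ppm)) # telescopes to last - first
    } else NA_real_
    data.frame(time_ka = b, n = nrow(pts), delta_ppm = delta)
  })
  do.call(rbind, out)
}

#' Modeled atmospheric CO2 contributions from net land-C transfers
#'
#' Translates flux records into per-millennium ppm contributions, applying
#' the airborne fraction to net releases and the (weaker) uptake response to
#' net uptakes, which in this reconstruction are peat-dominated. By the
#' output sign convention, land C losses appear as positive ppm
#' contributions. Error bars span the transfer +/- its propagated
#' uncertainty.
#'
#' @param fluxes data.frame of flux records with columns `t_young`,
#'   `net_pg` (signed, losses negative) and `net_sd_pg`.
#' @param constants A [default_constants()] list.
#' @param mode `"per_millennium"` (each interval converted separately) or
#'   `"cumulative"` (the response factors applied to running cumulative
#'   sums, then differenced; this is how summary deglacial/Holocene totals
#'   are quoted).
#' @return data.frame `time_ka`, `net_pg`, `E_pg`, `ppm`, `ppm_lo`,
#'   `ppm_hi`.
#' @export
ppm_series <- function(fluxes, constants = default_constants(),
                       mode = c("per_millennium", "cumulative")) {
  mode <- match.arg(mode)
  resp <- ifelse(fluxes$net_pg < 0, constants$airborne_fraction,
                 constants$uptake_response)
  ppm <- -pgc_to_ppm(fluxes$net_pg, resp, constants)
  if (mode == "cumulative") {
    # convert cumulative signed transfers, then difference back
    cum <- cumsum(fluxes$net_pg)
    cresp <- ifelse(cum < 0, constants$airborne_fraction,
                    constants$uptake_response)
    cppm <- -pgc_to_ppm(cum, cresp, constants)
    ppm <- diff(c(0, cppm))
  }
  lo_net <- fluxes$net_pg - fluxes$net_sd_pg
  hi_net <- fluxes$net_pg + fluxes$net_sd_pg
  bound <- function(x) {
    r <- ifelse(x < 0, constants$airborne_fraction,
                constants$uptake_response)
    -pgc_to_ppm(x, r, constants)
  }
  b1 <- bound(lo_net)
  b2 <- bound(hi_net)
  data.frame(time_ka = fluxes$t_young, net_pg = fluxes$net_pg,
             E_pg = fluxes$net_sd_pg, ppm = ppm,
             ppm_lo = pmin(b1, b2), ppm_hi = pmax(b1, b2))
}
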
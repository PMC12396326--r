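# Permafrost extent from mean annual air temperature: logistic fraction,
# per-model bias adjustments, continuous-zone delineation and offset
# calibration.

#' Default permafrost model parameters
#' @return A list: logistic midpoint `T0` (degC), scale `s` (degC),
#'   `continuous_threshold` (fraction standing in for "100% coverage"),
#'   per-model `base_offset` (degC) and the deglacial `ramp` settings
#'   (degC per millennium over the ramp window).
#' @export
default_permafrost_params <- function() {
  list(T0 = -6, s = 1.5, continuous_threshold = 0.99,
       base_offset = c(pseudo_hadcm3 = 0, pseudo_trace = 5),
       ramp_per_ka = -1, ramp_start_ka = 10, ramp_end_ka = 17,
       ramp_anchoring = "zero_at_start")
}

#' Permafrost fraction from adjusted mean annual air temperature
#'
#' Two-parameter logistic: `1 / (1 + exp((T - T0) / s))`. Strictly
#' decreasing in temperature, saturating to 1 in deep cold and 0 in warmth.
#'
#' @param maat_adjusted Temperature(s), degrees C, after model adjustments.
#' @param T0 Logistic midpoint (fraction = 0.5), degrees C.
#' @param s Logistic scale, degrees C, > 0.
#' @return Fraction in `[0, 1]`, same shape as the input.
#' @export
permafrost_fraction <- function(maat_adjusted, T0 = -6, s = 1.5) {
  if (s <= 0) stop("`s` must be positive", call. = FALSE)
  if (any(!is.finite(maat_adjusted))) {
    stop("non-finite temperature passed to permafrost_fraction",
         call. = FALSE)
  }
  1 / (1 + exp((maat_adjusted - T0) / s))
}

#' Adjust modeled MAAT for permafrost delineation
#'
#' Applies the per-model base offset (default +5 degC for `pseudo_trace`,
#' 0 for `pseudo_hadcm3`) and the deglacial cooling ramp: 0 at and after
#' (younger than) `ramp_start_ka`, growing by `ramp_per_ka` degC per
#' millennium back to `ramp_end_ka`, constant for older slices. With the
#' defaults the adjustment is 0 at 10 ka, -4 degC at 14 ka and -7 degC at
#' 17 ka and beyond; the total adjustment is piecewise linear and continuous
#' in time. The alternative anchoring (`"step_at_start"`, one full increment
#' already at the first ramp millennium) is selectable.
#'
#' @param maat MAAT value(s), degrees C.
#' @param model_label One of [model_labels()].
#' @param time Millennium, ka (0-21).
#' @param params A [default_permafrost_params()] list.
#' @return Adjusted temperature(s).
#' @export
adjust_maat <- function(maat, model_label, time,
                        params = default_permafrost_params()) {
  if (!model_label %in% names(params$base_offset)) {
    stop("unknown model label: ", model_label, call. = FALSE)
  }
  if (time < 0 || time > 21) stop("`time` must be in 0..21 ka",
                                  call. = FALSE)
  shift <- if (identical(params$ramp_anchoring, "step_at_start")) 1 else 0
  ramp <- params$ramp_per_ka *
    (pmin(time, params$ramp_end_ka) - params$ramp_start_ka + shift)
  ramp <- if (time <= params$ramp_start_ka - shift) 0 else ramp
  maat + params$base_offset[[model_label]] + ramp
}

#' Delineate continuous permafrost from a fraction map
#'
#' Cells where the modeled fraction reaches the saturation threshold
#' (default 0.99, the numerical stand-in for full coverage) form the
#' continuous-permafrost zone.
#'
#' @param fraction Matrix of permafrost fractions.
#' @param threshold Delineation threshold in `(0, 1]`.
#' @param area Optional matrix of cell areas (km^2); if given, the mask
#'   carries its total area as attribute `area_km2`.
#' @return Logical matrix (`TRUE` = continuous permafrost).
#' @export
delineate_continuous <- function(fraction, threshold = 0.99, area = NULL) {
  if (threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  }
  mask <- fraction >= threshold
  if (!is.null(area)) attr(mask, "area_km2") <- sum(area[mask])
  mask
}

#' Permafrost map for one model and millennium
#'
#' Convenience wrapper: adjusts the model's MAAT field, evaluates the
#' logistic fraction and delineates the continuous zone. Fractions are
#' reported on all cells; the continuous mask is restricted to land.
#'
#' @param world A [build_world()] object.
#' @param model_label One of [model_labels()].
#' @param t Millennium, ka.
#' @param params A [default_permafrost_params()] list.
#' @return A list of class `permafrost_map`: `time`, `model_label`,
#'   `fraction` (matrix), `continuous` (logical matrix, land only),
#'   `area_km2` (continuous extent).
#' @export
permafrost_map <- function(world, model_label, t,
                           params = default_permafrost_params()) {
  i <- match(t, world$times)
  if (is.na(i)) stop("no slice at ", t, " ka", call. = FALSE)
  maat <- world$climate$models[[model_label]]$maat[, , i]
  adj <- adjust_maat(maat, model_label, t, params)
  fr <- permafrost_fraction(adj, params$T0, params$s)
  cont <- delineate_continuous(fr, params$continuous_threshold) &
    world$masks$land[, , i]
  structure(list(time = t, model_label = model_label, fraction = fr,
                 continuous = cont,
                 area_km2 = sum(world$domain$area[cont])),
            class = "permafrost_map")
}

#' Calibrate the per-model MAAT offset against a reference extent
#'
#' Grid-searches the base offset (0.5 degC steps) minimizing the
#' symmetric-difference area between the modeled continuous-permafrost mask
#' and a reference mask at 0 ka, then reports the residual misfit at 6 and
#' 21 ka. The deglacial ramp is fixed, not tuned. Misfit can be scored on a
#' sub-mask (e.g. one continental sector) via `score_mask`.
#'
#' @param world A [build_world()] object.
#' @param model_label Model to calibrate.
#' @param reference Named list of logical reference masks; must contain
#'   `"0"`, optionally `"6"` and `"21"`.
#' @param params Permafrost parameters (the found offset replaces
#'   `base_offset[model_label]` in the returned copy).
#' @param offsets Candidate offsets (degC).
#' @param score_mask Optional logical matrix restricting where misfit is
#'   scored.
#' @return A list: `offset` (degC), `misfit_km2` (named vector at the
#'   reference times), `params` (updated parameter list).
#' @export
calibrate_offsets <- function(world, model_label, reference,
                              params = default_permafrost_params(),
                              offsets = seq(-10, 10, by = 0.5),
                              score_mask = NULL) {
  ref0 <- reference[["0"]]
  if (is.null(ref0) || !any(ref0)) {
    stop("reference mask at 0 ka is empty", call. = FALSE)
  }
  area <- world$domain$area
  if (is.null(score_mask)) score_mask <- matrix(TRUE, nrow(area), ncol(area))
  misfit <- function(mask, ref) {
    sum(area[(mask != ref) & score_mask])
  }
  mask_at <- function(t, offset) {
    p <- params
    p$base_offset[[model_label]] <- offset
    permafrost_map(world, model_label, t, p)$continuous
  }
  scores <- vapply(offsets, function(o) misfit(mask_at(0, o), ref0),
                   numeric(1))
  best <- offsets[which.min(scores)]
  out_params <- params
  out_params$base_offset[[model_label]] <- best
  mis <- c("0" = min(scores))
  for (t in c(6, 21)) {
    key <- as.character(t)
    if (!is.null(reference[[key]])) {
      mis[key] <- misfit(mask_at(t, best), reference[[key]])
    }
  }
  list(offset = best, misfit_km2 = mis, params = out_params)
}
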
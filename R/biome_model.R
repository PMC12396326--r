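# Vote-fraction biome classifier: training hygiene (tundra filter, desert
# augmentation, two training periods), ensemble fitting, per-cell biome area
# fractions, and held-out accuracy evaluation.

PERIOD_SLICES <- list(holocene = 9:0, deglacial = 21:10)

CLIMATE_FEATURES <- c("maat", "t_warm", "t_cold", "t_range",
                      "precip_annual", "precip_gs")

# which fitted period predicts slice t: the deglacial model covers 21-10 ka,
# the Holocene model 9-0 ka
period_for_slice <- function(t) {
  if (t >= 10 && t <= 21) "deglacial" else if (t >= 0 && t < 10) "holocene"
  else stop("slice ", t, " ka is outside both training periods",
            call. = FALSE)
}

# covariate frame (6 climate variables + elevation surrogate) for cells of a
# slice, from one model's fields
covariates_at <- function(world, model_label, t, cells) {
  fields <- world$climate$models[[model_label]]
  if (is.null(fields)) stop("unknown model label: ", model_label,
                            call. = FALSE)
  i <- match(t, world$times)
  if (is.na(i)) stop("no climate slice at ", t, " ka", call. = FALSE)
  out <- lapply(CLIMATE_FEATURES, function(v) fields[[v]][, , i][cells])
  names(out) <- CLIMATE_FEATURES
  out$elevation <- world$elevation[cells]
  as.data.frame(out)
}

# covariates for training rows (per-row slice lookup)
training_covariates <- function(train, world, model_label) {
  parts <- lapply(split(seq_len(nrow(train)), train$time_ka), function(idx) {
    t <- train$time_ka[idx[1]]
    cbind(row = idx,
          covariates_at(world, model_label, t, train$cell[idx]))
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$row), ]
  out$row <- NULL
  rownames(out) <- NULL
  out
}

#' Filter implausible tundra interpretations from a training set
#'
#' Removes rows labelled tundra whose site mean annual air temperature
#' exceeds 5 degrees C, unless the row is flagged `protected` (rows from the
#' exempted source database are always retained). All other rows pass
#' through unchanged.
#'
#' @param train A [sample_pollen_sites()] data.frame.
#' @param world The [build_world()] object used to resolve site climate.
#' @param model_label Which pseudo-model's MAAT to use (default the unbiased
#'   `pseudo_hadcm3`).
#' @param maat_threshold Removal threshold in degrees C.
#' @return The filtered training data.frame.
#' @export
filter_training <- function(train, world, model_label = "pseudo_hadcm3",
                            maat_threshold = 5) {
  if (nrow(train) == 0) return(train)
  bad_cell <- is.na(train$cell) | train$cell < 1 |
    train$cell > world$domain$nlat * world$domain$nlon
  if (any(bad_cell)) {
    i <- which(bad_cell)[1]
    stop("missing climate for site ", train$site_id[i], " at slice ",
         train$time_ka[i], " ka", call. = FALSE)
  }
  maat <- training_covariates(train, world, model_label)$maat
  drop <- train$biome == "tundra" & maat > maat_threshold & !train$protected
  train[!drop, , drop = FALSE]
}

#' Augment a training set with modern and paleo desert sites
#'
#' Desert evidence is sparse in pollen-style data, so known desert areas are
#' added directly: `n_holocene` sites at 0 ka for the Holocene set;
#' for the deglacial set, all 6-ka desert rows already present in the
#' Holocene-period samples are copied in and `n_deglacial` random desert
#' sites at 21 ka are added.
#'
#' @param train Training data.frame for the given `period`.
#' @param world The [build_world()] object.
#' @param period `"holocene"` or `"deglacial"`.
#' @param seed Integer seed for the random site draws.
#' @param n_holocene,n_deglacial Numbers of added sites (defaults as used in
#'   the reconstruction: 242 and 40).
#' @param holocene_train For `period = "deglacial"`, the Holocene-period
#'   training set whose 6-ka desert rows are copied in (optional).
#' @return The augmented training data.frame.
#' @export
augment_deserts <- function(train, world, period, seed,
                            n_holocene = 242, n_deglacial = 40,
                            holocene_train = NULL) {
  period <- match.arg(period, c("holocene", "deglacial"))
  draw <- function(t, n) {
    i <- match(t, world$times)
    eligible <- which(world$masks$land[, , i] &
                        !is.na(world$truth[, , i]) &
                        world$truth[, , i] == match("desert", biome_classes()))
    if (length(eligible) == 0) {
      stop("no desert cells at ", t, " ka: cannot augment training set",
           call. = FALSE)
    }
    domain <- world$domain
    res <- domain$resolution
    cells <- sample(eligible, n, replace = TRUE)
    ij <- arrayInd(cells, c(domain$nlat, domain$nlon))
    data.frame(
      site_id = NA_integer_,
      lon = domain$lon_centers[ij[, 2]] + stats::runif(n, -res / 2, res / 2),
      lat = domain$lat_centers[ij[, 1]] + stats::runif(n, -res / 2, res / 2),
      time_ka = t, biome = "desert", protected = FALSE,
      cell = cells, true_biome = "desert")
  }
  with_seed(seed, {
    if (period == "holocene") {
      out <- rbind(train, draw(0, n_holocene))
    } else {
      extra <- draw(21, n_deglacial)
      copied <- NULL
      if (!is.null(holocene_train)) {
        copied <- holocene_train[holocene_train$time_ka == 6 &
                                   holocene_train$biome == "desert", ,
                                 drop = FALSE]
      }
      out <- rbind(train, copied, extra)
    }
    out$site_id <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
  })
}

#' Fit the vote-fraction biome ensemble for one period and model
#'
#' Trains a random-forest ensemble on the period's training rows, using the
#' six climate covariates plus the elevation surrogate. Per-class
#' probabilities are the fraction of trees voting for each class.
#' Deterministic given `seed`.
#'
#' @param train Training data.frame (already filtered/augmented).
#' @param period `"holocene"` (9-0 ka) or `"deglacial"` (21-10 ka); rows are
#'   restricted to the period's slices.
#' @param world The [build_world()] object used to resolve covariates.
#' @param model_label Pseudo-model whose fields supply the covariates.
#' @param num_trees,min_node_size Ensemble hyperparameters (defaults: 500
#'   trees, fully grown).
#' @param seed Integer seed; required.
#' @param vote `"fraction"` (probability forest, the default used for area
#'   fractions) or `"hard"` (majority-vote classifier, used for consistency
#'   checks).
#' @return An object of class `classifier_bundle`.
#' @export
fit_biome_classifier <- function(train, period, world,
                                 model_label = "pseudo_hadcm3",
                                 num_trees = 500, min_node_size = 1,
                                 seed, vote = c("fraction", "hard")) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  vote <- match.arg(vote)
  period <- match.arg(period, c("holocene", "deglacial"))
  slices <- PERIOD_SLICES[[period]]
  rows <- train[train$time_ka %in% slices, , drop = FALSE]
  if (nrow(rows) == 0) stop("empty training set for period ", period,
                            call. = FALSE)
  cls <- biome_classes()
  present <- intersect(cls, unique(rows$biome))
  missing_classes <- setdiff(cls, present)
  if (length(missing_classes)) {
    warning("classes absent from ", period, " training: ",
            paste(missing_classes, collapse = ", "), call. = FALSE)
  }
  x <- training_covariates(rows, world, model_label)
  y <- factor(rows$biome, levels = present)
  fit <- ranger::ranger(
    x = x, y = y, num.trees = num_trees, min.node.size = min_node_size,
    probability = (vote == "fraction"), seed = sub_seed(seed, 7),
    num.threads = 1, verbose = FALSE)
  structure(list(fit = fit, period = period, slices = slices,
                 features = c(CLIMATE_FEATURES, "elevation"),
                 classes = cls, present_classes = present,
                 model_label = model_label, vote = vote,
                 metadata = list(n_rows = nrow(rows), seed = seed,
                                 num_trees = num_trees,
                                 missing_classes = missing_classes)),
            class = "classifier_bundle")
}

#' @export
print.classifier_bundle <- function(x, ...) {
  cat(sprintf("<classifier_bundle> %s / %s: %d rows, %d trees (%s vote)\n",
              x$period, x$model_label, x$metadata$n_rows,
              x$metadata$num_trees, x$vote))
  invisible(x)
}

# predict class probabilities (n x 8, full class set, zero-padded for
# classes absent from training) for a covariate frame
predict_fractions_frame <- function(bundle, newdata) {
  pred <- stats::predict(bundle$fit, data = newdata, num.threads = 1)
  out <- matrix(0, nrow(newdata), length(bundle$classes),
                dimnames = list(NULL, bundle$classes))
  if (bundle$vote == "fraction") {
    p <- pred$predictions
    out[, colnames(p)] <- p
  } else {
    lab <- as.character(pred$predictions)
    out[cbind(seq_along(lab), match(lab, bundle$classes))] <- 1
  }
  out
}

#' Predict per-cell biome area fractions for one millennium
#'
#' Applies the fitted ensemble to every grid cell of the slice and returns
#' vote fractions as biome area fractions. Fractions sum to 1 on unglaciated
#' land cells and are zero on ice and ocean.
#'
#' @param bundle A [fit_biome_classifier()] bundle.
#' @param world The [build_world()] object.
#' @param t Millennium (ka); must lie in the bundle's period.
#' @return A list of class `biome_map`: `time`, `model_label`, `fractions`
#'   (array `[nlat, nlon, 8]`).
#' @export
predict_biome_fractions <- function(bundle, world, t) {
  if (!(t %in% bundle$slices)) {
    stop("slice ", t, " ka is outside the ", bundle$period,
         " model's period", call. = FALSE)
  }
  domain <- world$domain
  ncell <- domain$nlat * domain$nlon
  i <- match(t, world$times)
  land <- world$masks$land[, , i]
  x <- covariates_at(world, bundle$model_label, t, seq_len(ncell))
  p <- predict_fractions_frame(bundle, x)
  p <- p / pmax(rowSums(p), .Machine$double.eps)
  p[!c(land), ] <- 0
  fr <- array(p, c(domain$nlat, domain$nlon, length(bundle$classes)))
  structure(list(time = t, model_label = bundle$model_label, fractions = fr),
            class = "biome_map")
}

#' Held-out accuracy of a fitted biome classifier
#'
#' Fraction of holdout rows whose argmax predicted class equals the recorded
#' label, per slice and averaged. Ties in the argmax resolve to the lowest
#' class index. Empty holdout slices are omitted with a warning.
#'
#' @param bundle A [fit_biome_classifier()] bundle.
#' @param holdout Holdout data.frame (disjoint from training).
#' @param world The [build_world()] object.
#' @return A data.frame `time_ka`, `n`, `accuracy`, with attribute
#'   `mean_accuracy` (unweighted mean over slices).
#' @export
evaluate_accuracy <- function(bundle, holdout, world) {
  slices <- intersect(bundle$slices, sort(unique(holdout$time_ka),
                                          decreasing = TRUE))
  empty <- setdiff(bundle$slices, slices)
  if (length(empty)) {
    warning("no holdout rows for slice(s) ",
            paste(empty, collapse = ", "), " ka; omitted", call. = FALSE)
  }
  res <- lapply(slices, function(t) {
    rows <- holdout[holdout$time_ka == t, , drop = FALSE]
    x <- covariates_at(world, bundle$model_label, t, rows$cell)
    p <- predict_fractions_frame(bundle, x)
    pred <- bundle$classes[max.col(p, ties.method = "first")]
    data.frame(time_ka = t, n = nrow(rows),
               accuracy = mean(pred == rows$biome))
  })
  out <- do.call(rbind, res)
  attr(out, "mean_accuracy") <- mean(out$accuracy)
  out
}
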
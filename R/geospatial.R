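#' The 18-configuration hyperparameter grid
#'
#' Random-forest hyperparameter grid used for the model ensemble: variables
#' per split 2-7 crossed with minimum leaf population 3-5.
#'
#' @return data.frame with 18 rows: \code{variables_per_split},
#'   \code{min_leaf_population}, \code{config_id}.
#' @export
modelConfigGrid <- function() {
  g <- expand.grid(variables_per_split = 2:7, min_leaf_population = 3:5)
  g$config_id <- sprintf("m%d_l%d", g$variables_per_split,
                         g$min_leaf_population)
  g
}

# Fit one regression engine on (train[, covariates], train[[response]]).
# Engines: "ranger" (default random forest) and "lm" (fast linear baseline,
# useful in simulations where forest flexibility is not the point).
fitModel <- function(train, response, covariates, config, engine = "ranger",
                     num_trees = 100, seed = 1) {
  engine <- match.arg(engine, c("ranger", "lm"))
  if (engine == "ranger") {
    f <- stats::as.formula(paste(response, "~",
                                 paste(covariates, collapse = "+")))
    ranger::ranger(f, data = train,
                   num.trees = num_trees,
                   mtry = min(config$variables_per_split, length(covariates)),
                   min.node.size = config$min_leaf_population,
                   seed = seed, num.threads = 1)
  } else {
    f <- stats::as.formula(paste(response, "~",
                                 paste(covariates, collapse = "+")))
    stats::lm(f, data = train)
  }
}

predictModel <- function(fit, newdata) {
  if (inherits(fit, "ranger"))
    stats::predict(fit, data = newdata, num.threads = 1)$predictions
  else as.numeric(stats::predict(fit, newdata = newdata))
}

#' Cross-validated performance of the model grid
#'
#' Trains every hyperparameter configuration under k-fold cross validation
#' (folds assigned randomly given \code{seed}, identical across
#' configurations) and scores each by out-of-fold coefficient of
#' determination \eqn{R^2 = 1 - SSE/SST}. A constant response makes
#' \eqn{R^2} undefined and is an error.
#'
#' @param train data.frame of training sites.
#' @param response name of the response column (conventionally already on
#'   the log10 scale, see [log10Metric()]).
#' @param covariates character vector of covariate column names.
#' @param configs hyperparameter grid (default [modelConfigGrid()]).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed controlling fold assignment and forests.
#' @param engine \code{"ranger"} (default) or \code{"lm"}.
#' @param num_trees trees per forest (default 100).
#' @return \code{configs} with a \code{cv_r2} column, sorted decreasing.
#' @export
trainModelGrid <- function(train, response, covariates,
                           configs = modelConfigGrid(), folds = 10,
                           seed = 1, engine = "ranger", num_trees = 100) {
  stopIfNot(nrow(train) >= folds, "need at least `folds` training sites")
  y <- train[[response]]
  stopIfNot(all(is.finite(y)), "response must be finite")
  if (stats::var(y) == 0)
    stop("constant response: cross-validated R^2 is undefined", call. = FALSE)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), nrow(train)))
  configs$cv_r2 <- vapply(seq_len(nrow(configs)), function(i) {
    pred <- numeric(nrow(train))
    for (f in seq_len(folds)) {
      hold <- fold == f
      fit <- fitModel(train[!hold, , drop = FALSE], response, covariates,
                      configs[i, ], engine, num_trees, seed = seed + f)
      pred[hold] <- predictModel(fit, train[hold, , drop = FALSE])
    }
    1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  configs[order(configs$cv_r2, decreasing = TRUE), , drop = FALSE]
}

#' Ensemble prediction over a pixel grid
#'
#' Refits the \code{top} best configurations (by cross-validated R^2) on the
#' full training set and predicts each grid pixel as the unweighted mean of
#' the member predictions. Predictions stay on the modelling (log10) scale
#' unless \code{back_transform = TRUE}, which applies \code{10^x} without a
#' smearing correction. Pixels with any missing covariate get \code{NA}.
#'
#' @inheritParams trainModelGrid
#' @param grid data.frame of pixels carrying the covariate columns.
#' @param ranking output of [trainModelGrid()].
#' @param top ensemble size (default 10).
#' @param back_transform back-transform predictions with \code{10^x}.
#' @return list with \code{prediction} (numeric per pixel), \code{members}
#'   (the configurations used), \code{scale} (\code{"log10"} or
#'   \code{"response"}).
#' @export
ensemblePredict <- function(train, grid, response, covariates, ranking,
                            top = 10, seed = 1, engine = "ranger",
                            num_trees = 100, back_transform = FALSE) {
  members <- utils::head(ranking, top)
  complete <- stats::complete.cases(grid[, covariates, drop = FALSE])
  preds <- matrix(NA_real_, nrow(grid), nrow(members))
  for (i in seq_len(nrow(members))) {
    fit <- fitModel(train, response, covariates, members[i, ], engine,
                    num_trees, seed = seed + i)
    preds[complete, i] <- predictModel(fit, grid[complete, , drop = FALSE])
  }
  p <- rowMeans(preds)
  if (back_transform) p <- 10^p
  list(prediction = p, members = members,
       scale = if (back_transform) "response" else "log10")
}

# Closed point-in-convex-polygon test by cross-product orientation: a point
# is inside iff it is on the same side of (or exactly on) every edge of the
# counter-clockwise hull.
pointsInHull <- function(px, py, hx, hy) {
  n <- length(hx)
  inside <- rep(TRUE, length(px))
  eps <- 1e-12
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & (cross >= -eps)
  }
  inside
}

#' Build the interpolation/extrapolation mask
#'
#' Quantifies, per pixel, how far the grid's environmental conditions sit
#' outside the training data's coverage. The training covariates are
#' transformed by centred, scaled PCA; the leading axes jointly explaining
#' at least \code{variance_target} of the variance are retained; a convex
#' hull is drawn around the training points in every bivariate axis pair;
#' and each pixel's outside-fraction is the share of axis pairs whose hull
#' excludes it (hulls are closed: boundary points are inside). Pixels with
#' outside-fraction above \code{outside_threshold} are masked.
#'
#' @param train data.frame of training sites with the covariate columns.
#' @param grid data.frame of pixels with the same covariate columns.
#' @param covariates character vector of covariate names.
#' @param variance_target cumulative variance the retained axes must reach
#'   (default 0.90).
#' @param outside_threshold outside-fraction above which a pixel is masked
#'   (default 0.90).
#' @return list with \code{outside_fraction} (per pixel), \code{masked}
#'   (logical per pixel), \code{n_axes}, \code{n_pairs}, \code{pca}.
#' @export
buildExtrapolationMask <- function(train, grid, covariates,
                                   variance_target = 0.90,
                                   outside_threshold = 0.90) {
  X <- as.matrix(train[, covariates, drop = FALSE])
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  pca <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  nAxes <- which(cum >= variance_target)[1]
  if (is.na(nAxes) || nAxes < 2) nAxes <- min(2L, ncol(pca$x))
  stopIfNot(nAxes >= 2, "need at least 2 principal components for hulls")
  trainScores <- pca$x[, seq_len(nAxes), drop = FALSE]
  G <- as.matrix(grid[, covariates, drop = FALSE])[, keep, drop = FALSE]
  gridScores <- scale(G, center = pca$center, scale = pca$scale) %*%
    pca$rotation[, seq_len(nAxes), drop = FALSE]
  pairs <- utils::combn(nAxes, 2)
  outside <- matrix(FALSE, nrow(grid), ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    hx <- trainScores[, a]; hy <- trainScores[, b]
    hull <- grDevices::chull(hx, hy)   # chull returns clockwise; reverse
    hull <- rev(hull)
    stopIfNot(length(hull) >= 3, "degenerate convex hull (collinear training points)")
    outside[, p] <- !pointsInHull(gridScores[, a], gridScores[, b],
                                  hx[hull], hy[hull])
  }
  frac <- rowMeans(outside)
  bad <- !stats::complete.cases(G)
  frac[bad] <- 1
  list(outside_fraction = frac, masked = frac > outside_threshold,
       n_axes = nAxes, n_pairs = ncol(pairs), pca = pca)
}

# Largest-remainder apportionment of n draws to strata with weights w.
apportion <- function(w, n) {
  w <- w / sum(w)
  raw <- w * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Spatially stratified bootstrap prediction maps
#'
#' Resamples the training sites with replacement, with per-region draw
#' counts proportional to each region's relative land area (so densely
#' sampled regions do not dominate the uncertainty estimate), refits the
#' model on each resample, predicts the grid, and reduces the \code{B} maps
#' pixelwise to mean, standard deviation, empirical 95\% confidence interval
#' (2.5/97.5 percentiles) and coefficient of variation.
#'
#' @inheritParams ensemblePredict
#' @param regions character vector assigning every training site to a
#'   stratum (e.g. the four IPBES regions).
#' @param region_areas named numeric vector of relative region areas,
#'   summing to 1, covering every region present.
#' @param B number of bootstrap resamples (default 100).
#' @param config single model configuration for the per-resample fits
#'   (default: first row of [modelConfigGrid()]).
#' @param keep_maps return the B x pixels matrix of resample maps.
#' @return list with \code{mean}, \code{sd}, \code{ci_lo}, \code{ci_hi},
#'   \code{cv} (each per pixel), \code{B}, and optionally \code{maps}.
#' @export
stratifiedBootstrapMaps <- function(train, grid, response, covariates,
                                    regions, region_areas, B = 100,
                                    seed = 1, engine = "ranger",
                                    num_trees = 100,
                                    config = modelConfigGrid()[1, ],
                                    keep_maps = FALSE) {
  stopIfNot(length(regions) == nrow(train),
            "one region label per training site required")
  stopIfNot(abs(sum(region_areas) - 1) < 1e-6, "region areas must sum to 1")
  present <- unique(regions)
  miss <- setdiff(names(region_areas)[region_areas > 0], present)
  if (length(miss))
    stop("region(s) with positive area but no sites: ",
         paste(miss, collapse = ", "), call. = FALSE)
  region_areas <- region_areas[names(region_areas) %in% present]
  region_areas <- region_areas / sum(region_areas)
  counts <- apportion(region_areas, nrow(train))
  idxByRegion <- split(seq_len(nrow(train)), regions)

  set.seed(seed)
  maps <- matrix(NA_real_, B, nrow(grid))
  for (b in seq_len(B)) {
    take <- unlist(lapply(names(region_areas), function(r) {
      pool <- idxByRegion[[r]]
      sample(pool, counts[[r]], replace = TRUE)
    }))
    fit <- fitModel(train[take, , drop = FALSE], response, covariates,
                    config, engine, num_trees, seed = seed + b)
    maps[b, ] <- predictModel(fit, grid)
  }
  m <- colMeans(maps)
  sdv <- apply(maps, 2, stats::sd)
  ci <- apply(maps, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- list(mean = m, sd = sdv, ci_lo = ci[1, ], ci_hi = ci[2, ],
              cv = sdv / m, B = B)
  if (keep_maps) out$maps <- maps
  out
}

#' Spherical pixel areas for a latitude/longitude grid
#'
#' Area in m^2 of a pixel of \code{dlat} x \code{dlon} degrees centred at
#' \code{lat}, on a sphere of Earth radius 6,371,000 m:
#' \eqn{A = R^2 \Delta\lambda (\sin\phi_2 - \sin\phi_1)}.
#'
#' @param lat pixel-centre latitudes, degrees.
#' @param dlat,dlon pixel height and width, degrees.
#' @return areas in m^2.
#' @export
pixelAreaM2 <- function(lat, dlat, dlon) {
  phi1 <- (lat - dlat / 2) * pi / 180
  phi2 <- (lat + dlat / 2) * pi / 180
  EARTH_RADIUS_M^2 * (dlon * pi / 180) * (sin(phi2) - sin(phi1))
}

#' Global totals from a prediction map
#'
#' Sums \code{value * area} over unmasked pixels. Values must be per-m^2 on
#' the response (not log) scale. For community metabolism
#' (J h^-1 m^-2), \code{as_carbon = TRUE} converts the total to kg C per
#' month using 730.5 hours per month and [energyToCarbon()].
#'
#' @param values per-pixel metric, per m^2 units.
#' @param area_m2 per-pixel areas in m^2.
#' @param masked logical per-pixel extrapolation mask (TRUE = excluded).
#' @param as_carbon convert a J h^-1 m^-2 metabolism total to kg C month^-1.
#' @param constants [carbonConstants()] for the conversion.
#' @return scalar total (metric units x m^2, or kg C month^-1).
#' @export
globalTotals <- function(values, area_m2, masked = NULL, as_carbon = FALSE,
                         constants = carbonConstants()) {
  stopIfNot(length(values) == length(area_m2),
            "values and area_m2 lengths differ")
  if (is.null(masked)) masked <- rep(FALSE, length(values))
  keep <- !masked & is.finite(values)
  total <- sum(values[keep] * area_m2[keep])
  if (as_carbon) total <- energyToCarbon(total * HOURS_PER_MONTH, constants)
  total
}

#' Moran's I with distance-band weights
#'
#' Standard Moran's I of site values under binary spatial weights: pairs
#' closer than \code{band_km} (great-circle, haversine) get weight 1, all
#' others 0. Under spatial randomness the expectation is \eqn{-1/(n-1)}.
#'
#' @param values numeric vector of site values (e.g. model residuals).
#' @param latitude,longitude site coordinates in degrees.
#' @param band_km distance band in km (default 150).
#' @return list with \code{observed}, \code{expected}, \code{sd},
#'   \code{p_value}, \code{n_pairs}.
#' @export
moransI <- function(values, latitude, longitude, band_km = 150) {
  n <- length(values)
  stopIfNot(n >= 10, "need at least 10 sites")
  d <- geosphere::distm(cbind(longitude, latitude),
                        fun = geosphere::distHaversine) / 1000
  W <- (d > 0 & d <= band_km) * 1
  nPairs <- sum(W) / 2
  if (nPairs < 1)
    return(list(observed = NA_real_, expected = -1 / (n - 1), sd = NA_real_,
                p_value = NA_real_, n_pairs = 0))
  mi <- ape::Moran.I(values, W)
  list(observed = mi$observed, expected = mi$expected, sd = mi$sd,
       p_value = mi$p.value, n_pairs = nPairs)
}
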
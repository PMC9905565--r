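gridFixture <- function(seed = 7, n_lon = 20, n_lat = 10) {
  cfg <- generatorConfig(n_sites = 50, seed = seed)
  generateCovariateGrid(cfg, n_lon = n_lon, n_lat = n_lat)
}

test_that("the hyperparameter grid has the 18 expected configurations", {
  g <- modelConfigGrid()
  expect_equal(nrow(g), 18)
  expect_setequal(unique(g$variables_per_split), 2:7)
  expect_setequal(unique(g$min_leaf_population), 3:5)
})

test_that("cross-validated R2 hits the perfect-signal and null limits", {
  set.seed(43)
  n <- 120
  train <- data.frame(x1 = runif(n), x2 = runif(n))
  train$y <- 2 + 3 * train$x1           # deterministic, no noise
  rk <- trainModelGrid(train, "y", c("x1", "x2"),
                       configs = modelConfigGrid()[c(1, 18), ], folds = 5,
                       seed = 1, engine = "lm")
  expect_true(all(rk$cv_r2 > 0.999))
  train$y <- rnorm(n)                   # pure noise
  rk0 <- trainModelGrid(train, "y", c("x1", "x2"),
                        configs = modelConfigGrid()[1, ], folds = 5,
                        seed = 1, engine = "ranger", num_trees = 100)
  expect_lt(rk0$cv_r2, 0.15)
  train$y <- 1
  expect_error(trainModelGrid(train, "y", c("x1", "x2")), "constant response")
})

test_that("config ranking is stable across seeds on a nonlinear signal", {
  go <- gridFixture()
  tr <- sampleTrainingSites(go, 100, noise_sd = 0.15, seed = 5)
  cfgs <- modelConfigGrid()[c(1, 4, 6, 13, 18), ]
  r1 <- trainModelGrid(tr, "response", go$covariates, cfgs, folds = 5,
                       seed = 11, num_trees = 100)
  r2 <- trainModelGrid(tr, "response", go$covariates, cfgs, folds = 5,
                       seed = 77, num_trees = 100)
  common <- intersect(r1$config_id, r2$config_id)
  expect_gt(cor(match(common, r1$config_id), match(common, r2$config_id),
                method = "spearman"), 0.5)
  # deterministic given the seed
  r1b <- trainModelGrid(tr, "response", go$covariates, cfgs, folds = 5,
                        seed = 11, num_trees = 100)
  expect_equal(r1$cv_r2, r1b$cv_r2)
})

test_that("ensemble prediction is the unweighted member mean", {
  go <- gridFixture()
  tr <- sampleTrainingSites(go, 60, seed = 3)
  rk <- trainModelGrid(tr, "response", go$covariates,
                       configs = modelConfigGrid()[1:3, ], folds = 5,
                       seed = 2, num_trees = 50)
  # one member: ensemble equals that model's prediction
  e1 <- ensemblePredict(tr, go$grid, "response", go$covariates, rk, top = 1,
                        seed = 9, num_trees = 50)
  fit <- springtailMetrics:::fitModel(tr, "response", go$covariates,
                                      rk[1, ], "ranger", 50, seed = 10)
  expect_equal(e1$prediction,
               springtailMetrics:::predictModel(fit, go$grid))
  # missing covariate at a pixel -> NA prediction
  g2 <- go$grid
  g2$cov1[5] <- NA
  e2 <- ensemblePredict(tr, g2, "response", go$covariates, rk, top = 2,
                        num_trees = 50)
  expect_true(is.na(e2$prediction[5]))
  expect_false(anyNA(e2$prediction[-5]))
  # back-transformation is 10^x
  e3 <- ensemblePredict(tr, go$grid, "response", go$covariates, rk, top = 2,
                        seed = 9, num_trees = 50, back_transform = TRUE)
  e4 <- ensemblePredict(tr, go$grid, "response", go$covariates, rk, top = 2,
                        seed = 9, num_trees = 50)
  expect_equal(e3$prediction, 10^e4$prediction)
})

test_that("ensemble RMSE does not exceed the median member RMSE", {
  go <- gridFixture(seed = 15)
  tr <- sampleTrainingSites(go, 120, noise_sd = 0.25, seed = 8)
  cfgs <- modelConfigGrid()[c(1, 6, 13, 18), ]
  rk <- trainModelGrid(tr, "response", go$covariates, cfgs, folds = 5,
                       seed = 4, num_trees = 80)
  memberRmse <- vapply(seq_len(nrow(rk)), function(i) {
    e <- ensemblePredict(tr, go$grid, "response", go$covariates, rk[i, ],
                         top = 1, seed = 30, num_trees = 80)
    sqrt(mean((e$prediction - go$true_log10)^2))
  }, numeric(1))
  ens <- ensemblePredict(tr, go$grid, "response", go$covariates, rk, top = 4,
                         seed = 30, num_trees = 80)
  ensRmse <- sqrt(mean((ens$prediction - go$true_log10)^2))
  expect_lte(ensRmse, median(memberRmse) * 1.05)
})

test_that("convex-hull membership is closed and exact on a triangle", {
  # 2 covariates -> 2 PCs -> one axis pair
  train <- data.frame(a = c(0, 1, 0.5, 0.5), b = c(0, 0, 1, 0.4))
  grid <- data.frame(a = c(0.5, 0.5, 5), b = c(0.2, 0.0, 5))
  mask <- buildExtrapolationMask(train, grid, c("a", "b"),
                                 variance_target = 0.99)
  expect_equal(mask$outside_fraction[1], 0)  # interior
  expect_equal(mask$outside_fraction[2], 0)  # on an edge: closed hull
  expect_equal(mask$outside_fraction[3], 1)  # far outside
  expect_equal(mask$masked, c(FALSE, FALSE, TRUE))
})

test_that("training points are never masked; distant pixels are", {
  go <- gridFixture(seed = 33)
  tr <- sampleTrainingSites(go, 40, seed = 12)
  mask <- buildExtrapolationMask(tr, tr, go$covariates)
  expect_true(all(!mask$masked))
  far <- tr[1, ]
  for (cv in go$covariates) far[[cv]] <- far[[cv]] + 1e3
  m2 <- buildExtrapolationMask(tr, far, go$covariates)
  expect_equal(m2$outside_fraction, 1)
  expect_true(m2$masked)
})

test_that("raising the outside threshold never masks additional pixels", {
  go <- gridFixture(seed = 51)
  tr <- sampleTrainingSites(go, 30, seed = 2)
  thresholds <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  masked <- lapply(thresholds, function(th)
    buildExtrapolationMask(tr, go$grid, go$covariates,
                           outside_threshold = th)$masked)
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(masked[[i + 1]] <= masked[[i]]))
  }
})

test_that("stratified bootstrap honours region quotas and its summary oracle", {
  go <- gridFixture(seed = 61)
  tr <- sampleTrainingSites(go, 80, seed = 6)
  areas <- c(americas = 0.25, europe_central_asia = 0.25, africa = 0.25,
             asia_pacific = 0.25)
  areas <- areas[names(areas) %in% unique(tr$region)]
  areas <- areas / sum(areas)
  bs <- stratifiedBootstrapMaps(tr, go$grid[1:40, ], "response",
                                go$covariates, tr$region, areas, B = 20,
                                seed = 14, engine = "lm", keep_maps = TRUE)
  # summaries equal brute-force recomputation from the stored maps
  expect_identical(bs$mean, colMeans(bs$maps))
  expect_identical(bs$sd, apply(bs$maps, 2, sd))
  expect_identical(bs$ci_lo, apply(bs$maps, 2, quantile, 0.025, names = FALSE))
  expect_identical(bs$ci_hi, apply(bs$maps, 2, quantile, 0.975, names = FALSE))
  expect_identical(bs$cv, bs$sd / bs$mean)
  # empty region with positive area is an error
  expect_error(
    stratifiedBootstrapMaps(tr, go$grid[1:5, ], "response", go$covariates,
                            tr$region, c(areas, atlantis = 0.5) /
                              (1 + 0.5), B = 2, engine = "lm"),
    "no sites")
})

test_that("equal-area stratification draws near-uniform region composition", {
  # resample composition is fixed by largest-remainder apportionment
  w <- c(a = 0.25, b = 0.25, c = 0.25, d = 0.25)
  expect_equal(unname(springtailMetrics:::apportion(w, 101)),
               c(26, 25, 25, 25))
  expect_equal(sum(springtailMetrics:::apportion(c(0.6, 0.3, 0.1), 7)), 7)
})

test_that("global totals sum value x area over unmasked pixels", {
  vals <- rep(1, 10)
  areas <- rep(2, 10)
  expect_equal(globalTotals(vals, areas), 20)
  mask <- rep(c(TRUE, FALSE), 5)
  expect_equal(globalTotals(vals, areas, mask), 10)
  # linearity
  expect_equal(globalTotals(2 * vals, areas), 2 * globalTotals(vals, areas))
  # carbon conversion for a metabolism map: J/h/m2 -> kg C / month
  expect_equal(globalTotals(1, 1, as_carbon = TRUE),
               energyToCarbon(730.5))
})

test_that("pixel areas follow the spherical formula and sum to the zone area", {
  lat <- seq(-89.5, 89.5, by = 1)
  total <- sum(pixelAreaM2(lat, 1, 1)) * 360
  expect_equal(total, 4 * pi * 6371000^2, tolerance = 1e-6)
})

test_that("Moran's I matches its null expectation and detects structure", {
  set.seed(71)
  n <- 40
  lat <- runif(n, 30, 60)
  lon <- runif(n, -10, 30)
  # random values: observed I close to -1/(n-1)
  mi <- moransI(rnorm(n), lat, lon, band_km = 800)
  expect_equal(mi$expected, -1 / (n - 1))
  expect_lt(abs(mi$observed - mi$expected), 3 * mi$sd)
  # strong gradient: positive autocorrelation
  mi2 <- moransI(lat * 2, lat, lon, band_km = 1000)
  expect_gt(mi2$observed, 0.3)
  # alternating pattern along a line: negative autocorrelation
  latLine <- seq(40, 41.95, by = 0.05)
  mi3 <- moransI(rep(c(1, -1), length.out = length(latLine)), latLine,
                 rep(0, length(latLine)), band_km = 7)
  expect_lt(mi3$observed, 0)
  # no pairs in band: undefined, reported as NA
  mi4 <- moransI(rnorm(12), seq(0, 55, by = 5), rep(0, 12), band_km = 1)
  expect_true(is.na(mi4$observed))
})
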
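test_that("a 3x3 wet block is one wetland of 8100 m2", {
  st <- toy_stack()
  wl <- delineate_wetlands(st)
  expect_equal(nrow(wl$table), 2) # block plus the single transient pixel
  expect_setequal(wl$table$area_m2, c(8100, 900))
  expect_equal(sort(unique(as.vector(wl$labels))), c(0L, 1L, 2L))
})

test_that("diagonal adjacency merges under 8- but not 4-connectivity", {
  water <- array(0L, dim = c(16, 16, 2))
  water[5, 5, ] <- 1L
  water[6, 6, ] <- 1L
  st <- raster_stack(water, array(10, dim = c(16, 16, 2)),
                     array(0, dim = c(16, 16, 2)), matrix(1L, 16, 16),
                     window = frost_free_window(80, 107))
  expect_equal(nrow(delineate_wetlands(st, connectivity = 8)$table), 1)
  expect_equal(nrow(delineate_wetlands(st, connectivity = 4)$table), 2)
})

test_that("delineation recovers the generating wetlands exactly", {
  ls <- generate_wetlandscape(landscape_config(nrow = 192, ncol = 192,
                                               n_wetlands = 150, seed = 9,
                                               max_retries = 1000))
  wl <- delineate_wetlands(ls$rasters)
  expect_equal(nrow(wl$table), 150)
  expect_equal(sort(wl$table$area_m2), sort(ls$wetland_table$max_area_m2))
  # repeated delineation is identical; empty masks warn and return no wetlands
  expect_identical(wl$labels, delineate_wetlands(ls$rasters)$labels)
})

test_that("delineation is invariant to raster translation", {
  st <- toy_stack()
  wl <- delineate_wetlands(st)
  water2 <- array(0L, dim = dim(st$water_mask))
  water2[4:16, 4:16, ] <- st$water_mask[1:13, 1:13, ]
  st2 <- raster_stack(water2, st$temperature, st$ndvi, st$land_cover,
                      window = st$window)
  wl2 <- delineate_wetlands(st2)
  expect_equal(sort(wl2$table$area_m2), sort(wl$table$area_m2))
})

test_that("empty water masks warn and produce an empty table", {
  water <- array(0L, dim = c(16, 16, 2))
  st <- raster_stack(water, array(1, dim = c(16, 16, 2)),
                     array(0, dim = c(16, 16, 2)), matrix(1L, 16, 16),
                     window = frost_free_window(80, 107))
  expect_warning(wl <- delineate_wetlands(st), "empty")
  expect_equal(nrow(wl$table), 0)
})

test_that("predictor stack encodes wetness, hydroperiod, size, season, and lags", {
  # 26 steps x 14 days; one pixel wet 9 steps, the block wet all steps
  st <- toy_stack(ns = 26, window = frost_free_window(1, 364))
  st$water_mask[10, 10, ] <- 0L
  st$water_mask[10, 10, 1:9] <- 1L
  wl <- delineate_wetlands(st)
  pred <- derive_predictor_stack(st, wl)
  rows1010 <- pred[pred$row == 10 & pred$col == 10, ]
  expect_equal(unique(rows1010$hydroperiod), 9 * 14) # 126 days
  expect_equal(unique(rows1010$wetland_size), 900)
  expect_equal(rows1010$wfps[rows1010$step <= 9], rep(100, 9))
  expect_equal(rows1010$wfps[rows1010$step > 9], rep(50, 17))
  # upland pixels contribute no records
  expect_true(all(wl$labels[cbind(pred$row, pred$col)] > 0))
  expect_equal(nrow(pred), (9 + 1) * 26)
  # step-1 lags equal step-1 values; later lags reference step - 1
  s1 <- pred[pred$step == 1, ]
  expect_equal(s1$wfps_lag, s1$wfps)
  s2 <- pred[pred$step == 2, ]
  expect_equal(s2$wfps_lag, s1$wfps[match(s2$pixel, s1$pixel)])
  # early/late split at the window midpoint
  expect_equal(unique(pred$season_interval[pred$step <= 13]), "early")
  expect_equal(unique(pred$season_interval[pred$step > 13]), "late")
})

test_that("predictor derivation rejects an inconsistent window", {
  st <- toy_stack(ns = 2)
  wl <- delineate_wetlands(st)
  expect_error(derive_predictor_stack(st, wl, frost_free_window(1, 364)),
               "window")
})

test_that("a noise-free single-predictor response is learned almost perfectly", {
  set.seed(5)
  df <- data.frame(x = runif(2000))
  df$flux <- exp(1.5 * df$x)
  fo <- fit_landscape_model(df, ensemble_config(seed = 2), covariates = "x")
  expect_gte(fo$oob_variance_explained, 0.95)
})

test_that("a response independent of the predictors explains nothing out of bag", {
  d <- generate_chamber_dataset(chamber_config(n_wetlands = 20,
                                               chambers_per_wetland = 3,
                                               years = 2, seed = 17))
  obs <- d$observations
  set.seed(17)
  obs$flux <- exp(rnorm(nrow(obs))) # permutation-null response
  fo <- fit_landscape_model(obs, ensemble_config(n_trees = 300, seed = 3))
  expect_lte(fo$oob_variance_explained, 0.05)
})

test_that("prediction is deterministic, tile-invariant, and constant on constant input", {
  d <- generate_chamber_dataset(chamber_config(n_wetlands = 20,
                                               chambers_per_wetland = 3,
                                               years = 2, seed = 23))
  fo <- fit_landscape_model(d$observations, ensemble_config(n_trees = 100, seed = 4))
  newx <- d$observations[1:500, ]
  p1 <- predict_pixel_flux(fo, newx, tiles = 1)
  p4 <- predict_pixel_flux(fo, newx, tiles = 4)
  expect_identical(p1$flux, p4$flux)
  same <- newx[rep(1, 50), ]
  expect_equal(length(unique(predict_pixel_flux(fo, same)$flux)), 1)
  expect_true(all(p1$flux > 0))
})

test_that("ensemble prediction variance across seeds shrinks with more trees", {
  d <- generate_chamber_dataset(chamber_config(n_wetlands = 15,
                                               chambers_per_wetland = 2,
                                               years = 2, seed = 29))
  obs <- d$observations
  test_rows <- obs[1:50, ]
  pred_sd <- function(n_trees) {
    preds <- sapply(1:5, function(s) {
      fo <- fit_landscape_model(obs, ensemble_config(n_trees = n_trees, seed = s))
      predict_pixel_flux(fo, test_rows)$flux
    })
    mean(apply(log(preds), 1, stats::sd))
  }
  expect_lt(pred_sd(500), pred_sd(50))
})

test_that("schema violations and degenerate training sets are rejected", {
  d <- generate_chamber_dataset(chamber_config(n_wetlands = 20,
                                               chambers_per_wetland = 3,
                                               years = 1, seed = 31))
  obs <- d$observations
  fo <- fit_landscape_model(obs, ensemble_config(n_trees = 50, seed = 1))
  bad <- obs[1:10, setdiff(names(obs), "wfps")]
  expect_error(predict_pixel_flux(fo, bad), "schema")
  bad2 <- obs[1:10, ]; bad2$land_cover <- "forest"
  expect_error(predict_pixel_flux(fo, bad2), "schema")
  const <- obs; const$flux <- 2
  expect_error(fit_landscape_model(const), "degenerate")
  expect_error(fit_landscape_model(obs[1:50, ]), "100")
})
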
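test_that("one 14-day step on one 900-m2 pixel at 1 mg/m2/h yields 302.4 g", {
  # 26 steps cover day 1-364; winter hours are charged at boundary rates,
  # which are zero here, so the annual total is the single step's share
  st <- toy_stack(ns = 26, window = frost_free_window(1, 364))
  wl <- delineate_wetlands(st)
  pred <- derive_predictor_stack(st, wl)
  fx <- data.frame(pixel = pred$pixel, step = pred$step, flux = 0)
  one_pixel <- fx$pixel[1]
  fx$flux[fx$pixel == one_pixel & fx$step == 5] <- 1
  annual <- integrate_annual(fx, st)
  expect_equal(sum(annual), 302.4)
  expect_equal(annual[one_pixel], 302.4)
})

test_that("zero rates integrate to zero and constants to r x area x 8760 h", {
  st <- toy_stack(ns = 19, window = frost_free_window(80, 345))
  wl <- delineate_wetlands(st)
  pred <- derive_predictor_stack(st, wl)
  fx0 <- data.frame(pixel = pred$pixel, step = pred$step, flux = 0)
  expect_equal(sum(integrate_annual(fx0, st)), 0)
  for (r in c(0.3, 1, 2.7)) {
    fxr <- data.frame(pixel = pred$pixel, step = pred$step, flux = r)
    annual <- integrate_annual(fxr, st)
    expect_equal(annual[annual > 0],
                 rep(r * 900 * 8760 / 1000, length(unique(pred$pixel))))
  }
})

test_that("integration is linear in the rates", {
  st <- toy_stack(ns = 19, window = frost_free_window(80, 345))
  wl <- delineate_wetlands(st)
  pred <- derive_predictor_stack(st, wl)
  set.seed(12)
  F <- data.frame(pixel = pred$pixel, step = pred$step,
                  flux = runif(nrow(pred)))
  G <- F; G$flux <- runif(nrow(pred), 0, 2)
  comb <- F; comb$flux <- 2 * F$flux + 3 * G$flux
  expect_equal(integrate_annual(comb, st),
               2 * integrate_annual(F, st) + 3 * integrate_annual(G, st))
})

test_that("regional totals equal the brute-force pixel-step oracle", {
  ls <- generate_wetlandscape(small_landscape_config(seed = 14))
  st <- ls$rasters
  wl <- delineate_wetlands(st)
  pred <- derive_predictor_stack(st, wl)
  tr <- true_response()
  fx <- predict_pixel_flux(function(df) evaluate_true_response(tr, df), pred)
  annual <- integrate_annual(fx, st)
  oracle <- brute_force_annual(fx, st)
  expect_lt(max(abs(annual - oracle)) / max(annual), 1e-9)
  s <- summarize_region(annual, fx, wl, st)
  expect_equal(s$total_emission_Gg, sum(oracle) / 1e9, tolerance = 1e-9)
})

test_that("a single always-wet pixel at 1 mg/m2/h summarizes correctly", {
  st <- toy_stack(ns = 19, window = frost_free_window(80, 345))
  st$water_mask[, , ] <- 0L
  st$water_mask[10, 10, ] <- 1L
  wl <- delineate_wetlands(st)
  pred <- derive_predictor_stack(st, wl)
  fx <- data.frame(pixel = pred$pixel, step = pred$step, flux = 1)
  annual <- integrate_annual(fx, st)
  s <- summarize_region(annual, fx, wl, st)
  expect_equal(s$mean_flux_rate, 1)
  expect_equal(s$inundated_area_km2, 0.0009)
  expect_equal(s$wetland_count, 1)
})

test_that("emissions are conserved across pixel, wetland, and size-class sums", {
  ls <- generate_wetlandscape(small_landscape_config(seed = 15))
  st <- ls$rasters
  wl <- delineate_wetlands(st)
  pred <- derive_predictor_stack(st, wl)
  tr <- true_response()
  fx <- predict_pixel_flux(function(df) evaluate_true_response(tr, df), pred)
  annual <- integrate_annual(fx, st)
  sc <- size_class_decomposition(annual, wl)
  total <- sum(annual)
  expect_equal(sum(sc$emission_Gg) * 1e9, total, tolerance = 1e-12)
  expect_equal(sum(sc$emission_share_pct), 100, tolerance = 1e-6)
  expect_equal(sum(sc$extent_share_pct), 100, tolerance = 1e-6)
  per_wetland <- rowsum(annual[wl$labels > 0], wl$labels[wl$labels > 0])
  expect_equal(sum(per_wetland), total, tolerance = 1e-12)
})

test_that("equal per-area rates split shares proportionally to extent", {
  # 10-pixel (0.9 ha) and 90-pixel (8.1 ha) wetlands at the same rate
  water <- array(0L, dim = c(32, 32, 2))
  water[2, 2:11, ] <- 1L
  water[10:18, 14:23, ] <- 1L
  st <- raster_stack(water, array(10, dim = c(32, 32, 2)),
                     array(0, dim = c(32, 32, 2)), matrix(1L, 32, 32),
                     window = frost_free_window(100, 127))
  wl <- delineate_wetlands(st)
  pred <- derive_predictor_stack(st, wl)
  fx <- data.frame(pixel = pred$pixel, step = pred$step, flux = 1.4)
  annual <- integrate_annual(fx, st)
  sc <- size_class_decomposition(annual, wl)
  expect_equal(sc$extent_share_pct[sc$size_class == "[0,1) ha"], 10)
  expect_equal(sc$emission_share_pct[sc$size_class == "[0,1) ha"], 10)
  expect_equal(sc$extent_share_pct[sc$size_class == "[8,9) ha"], 90)
  # single wetland degenerates to 100% shares
  st1 <- st; st1$water_mask[2, 2:11, ] <- 0L
  wl1 <- delineate_wetlands(st1)
  pred1 <- derive_predictor_stack(st1, wl1)
  fx1 <- data.frame(pixel = pred1$pixel, step = pred1$step, flux = 1)
  sc1 <- size_class_decomposition(integrate_annual(fx1, st1), wl1)
  expect_equal(max(sc1$emission_share_pct), 100)
  expect_equal(max(sc1$extent_share_pct), 100)
})

test_that("doubling the wet extent at identical rates doubles the total", {
  water <- array(0L, dim = c(64, 64, 2))
  water[5:7, 5:7, ] <- 1L
  st1 <- raster_stack(water, array(12, dim = c(64, 64, 2)),
                      array(0, dim = c(64, 64, 2)), matrix(1L, 64, 64),
                      window = frost_free_window(100, 127))
  water2 <- water
  water2[25:27, 25:27, ] <- 1L # identical twin wetland
  st2 <- raster_stack(water2, st1$temperature, st1$ndvi, st1$land_cover,
                      window = st1$window)
  rate <- 0.8
  mk_fx <- function(st) {
    wl <- delineate_wetlands(st)
    pred <- derive_predictor_stack(st, wl)
    data.frame(pixel = pred$pixel, step = pred$step, flux = rate)
  }
  expect_equal(sum(integrate_annual(mk_fx(st2), st2)),
               2 * sum(integrate_annual(mk_fx(st1), st1)))
})

test_that("inconsistent inputs are rejected", {
  st <- toy_stack(ns = 2)
  wl <- delineate_wetlands(st)
  pred <- derive_predictor_stack(st, wl)
  fx <- data.frame(pixel = pred$pixel, step = pred$step, flux = 1)
  expect_error(integrate_annual(fx, st, frost_free_window(1, 200)), "window")
  annual <- integrate_annual(fx, st)
  bad <- annual; bad[1, 1] <- 5 # emission on an unlabeled pixel
  expect_error(size_class_decomposition(bad, wl), "consistency")
})
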
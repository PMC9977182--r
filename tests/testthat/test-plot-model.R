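test_that("a flat generating truth yields near-zero deviance explained and flat effects", {
  tr <- noise_free_truth(wfps_amplitude = 0, ndvi_amplitude = 0,
                         size_curvature = 0, hydro_amplitude = 0, q10 = 1,
                         lc_offset = c(grassland = 0, cropland = 0),
                         season_offset = c(early = 0, late = 0),
                         lag_weights = c(wfps = 0, soil_temp = 0, ndvi = 0))
  d <- generate_chamber_dataset(chamber_config(n_wetlands = 15,
                                               chambers_per_wetland = 2,
                                               years = 2, seed = 2, truth = tr))
  m <- fit_plot_model(d$observations)
  expect_lt(deviance_explained(m), 0.01)
  pe <- partial_effect(m, "wfps")
  expect_lt(max(abs(pe$effect)), 0.02)
})

test_that("fitted partial effects recover the generating shapes", {
  d <- generate_chamber_dataset(recovery_chamber_config(seed = 101))
  m <- fit_plot_model(d$observations)

  # size peak within [1, 6] ha, bracketing the generating 3-ha peak
  r <- m$covariate_ranges$wetland_size
  ha_grid <- exp(seq(log(r[1]), log(r[2]), length.out = 200))
  ps <- partial_effect(m, "wetland_size", grid = ha_grid)
  peak_ha <- ha_grid[which.max(ps$effect)] / 1e4
  expect_gte(peak_ha, 1); expect_lte(peak_ha, 6)

  # temperature effect monotone increasing
  pt <- partial_effect(m, "soil_temp", grid = seq(5, 22, length.out = 50))
  expect_true(all(diff(pt$effect) > -0.01))

  # WFPS: steep decline below the 80% inflection
  pw <- partial_effect(m, "wfps")
  f <- stats::approxfun(pw$grid, pw$effect)
  expect_gt(f(100) - f(60), 0)
  expect_gt(f(100) - f(60), f(100) - f(90))

  # NDVI step at 0
  pn <- partial_effect(m, "ndvi")
  g <- stats::approxfun(pn$grid, pn$effect)
  expect_gt(g(0.15) - g(-0.15), 0)

  # temperature curve close to the generating line (centered comparison)
  truth_line <- log(d$truth$q10) / 10 * (pt$grid - 15)
  rmse <- sqrt(mean(((pt$effect - mean(pt$effect)) -
                     (truth_line - mean(truth_line)))^2))
  expect_lt(rmse, 0.15)

  # fit quality lands where the generator was designed to put it
  expect_gte(deviance_explained(m), 0.5)
  expect_lte(deviance_explained(m), 0.7)
})

test_that("the selection penalty removes a pure-noise smooth but keeps signal terms", {
  d <- generate_chamber_dataset(recovery_chamber_config(seed = 55))
  obs <- d$observations
  set.seed(55)
  obs$noise_cov <- rnorm(nrow(obs))
  cfg <- plot_model_config(smooth_terms = c("wfps", "soil_temp", "ndvi",
                                            "wetland_size", "hydroperiod",
                                            "noise_cov"))
  m <- fit_plot_model(obs, cfg)
  expect_lt(m$term_edf[["noise_cov"]], 0.5)
  expect_gt(m$term_edf[["wfps"]], 0.5)
  expect_gt(m$term_edf[["soil_temp"]], 0.5)
  expect_error(partial_effect(m, "land_cover"), "smooth")
})

test_that("noise-free training fluxes are reproduced within 1%", {
  d <- generate_chamber_dataset(chamber_config(n_wetlands = 20,
                                               chambers_per_wetland = 3,
                                               years = 3, seed = 77,
                                               truth = noise_free_truth()))
  m <- fit_plot_model(d$observations, plot_model_config(basis_dim = 12))
  p <- predict_plot_flux(m, d$observations, include_random = TRUE)
  expect_lt(max(abs(p$flux / d$observations$flux - 1)), 0.01)
  expect_true(all(p$flux > 0))
  expect_true(all(p$lwr <= p$flux & p$flux <= p$upr))
})

test_that("land-cover contrast matches the generating offset direction", {
  d <- generate_chamber_dataset(recovery_chamber_config(seed = 13))
  m <- fit_plot_model(d$observations)
  rec <- reference_record(d$truth)
  rec$hydroperiod <- 150 # inside the training range
  g <- rec; g$land_cover <- "grassland"
  c_ <- rec; c_$land_cover <- "cropland"
  expect_gte(predict_plot_flux(m, g)$flux, predict_plot_flux(m, c_)$flux)
})

test_that("partial effects are centered over the training distribution", {
  d <- generate_chamber_dataset(chamber_config(n_wetlands = 25,
                                               chambers_per_wetland = 3,
                                               years = 2, seed = 3))
  m <- fit_plot_model(d$observations)
  obs <- d$observations
  set.seed(4)
  sub <- obs[sample(nrow(obs), 400), ]
  pe <- partial_effect(m, "soil_temp", grid = sub$soil_temp)
  expect_lt(abs(mean(pe$effect)), 0.05)
})

test_that("fits are invariant to row order and ID relabeling", {
  d <- generate_chamber_dataset(chamber_config(n_wetlands = 15,
                                               chambers_per_wetland = 2,
                                               years = 2, seed = 19))
  obs <- d$observations
  set.seed(6)
  perm <- sample(nrow(obs))
  m1 <- fit_plot_model(obs)
  m2 <- fit_plot_model(obs[perm, ])
  relab <- obs
  relab$wetland_id <- paste0("Z", relab$wetland_id)
  relab$chamber_id <- paste0("Z", relab$chamber_id)
  m3 <- fit_plot_model(relab)
  newx <- obs[1:50, ]
  p1 <- predict_plot_flux(m1, newx)$flux
  expect_equal(predict_plot_flux(m2, newx)$flux, p1, tolerance = 1e-6)
  expect_equal(predict_plot_flux(m3, newx)$flux, p1, tolerance = 1e-6)
})

test_that("random effects improve held-out log-likelihood when wetlands differ", {
  diffs <- vapply(1:5, function(s) {
    tr <- true_response(sigma_wetland = 0.5, sigma_chamber = 0.2)
    d <- generate_chamber_dataset(chamber_config(n_wetlands = 25,
                                                 chambers_per_wetland = 3,
                                                 years = 2, seed = 400 + s,
                                                 truth = tr))
    obs <- d$observations
    set.seed(s)
    hold <- sample(nrow(obs), round(0.3 * nrow(obs)))
    train <- obs[-hold, ]; test <- obs[hold, ]
    ll <- function(cfg, include_random) {
      m <- fit_plot_model(train, cfg)
      p <- suppressMessages(
        predict_plot_flux(m, test, include_random = include_random))
      sig <- sqrt(mean((log(predict_plot_flux(m, train,
                                              include_random = include_random)$flux) -
                          log(train$flux))^2))
      sum(stats::dnorm(log(test$flux), log(p$flux), sig, log = TRUE))
    }
    ll(plot_model_config(), TRUE) -
      ll(plot_model_config(random_effects = FALSE), FALSE)
  }, numeric(1))
  expect_gt(stats::median(diffs), 0)
})

test_that("schema and sizing errors are reported", {
  d <- generate_chamber_dataset(chamber_config(n_wetlands = 15,
                                               chambers_per_wetland = 2,
                                               years = 1, seed = 9))
  obs <- d$observations
  expect_error(fit_plot_model(obs[, setdiff(names(obs), "ndvi")]), "missing")
  expect_error(fit_plot_model(obs[1:40, ]), "under-determined")
  m <- fit_plot_model(obs)
  bad <- obs[1:2, ]; bad$season_interval <- "winter"
  expect_error(predict_plot_flux(m, bad), "level")
  expect_error(partial_effect(m, "nonexistent"), "smooth")
})

test_that("non-positive fluxes are dropped with a message before fitting", {
  d <- generate_chamber_dataset(chamber_config(n_wetlands = 15,
                                               chambers_per_wetland = 2,
                                               years = 2, seed = 10))
  obs <- d$observations
  obs$flux[1:25] <- -0.01
  expect_message(m <- fit_plot_model(obs), "25 non-positive")
  expect_equal(m$n_dropped, 25)
})
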
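# shared fixtures: small configs kept cheap; sizes chosen for test runtime

# chamber dataset of ~10,400 rows matching the recovery-test problem size
recovery_chamber_config <- function(seed, truth = true_response()) {
  chamber_config(n_wetlands = 40, chambers_per_wetland = 4, years = 5,
                 steps_per_year = 13, seed = seed, truth = truth)
}

# small landscape for pipeline-stage tests
small_landscape_config <- function(seed = 5, ...) {
  landscape_config(nrow = 96, ncol = 96, n_wetlands = 40, seed = seed,
                   max_retries = 500, ...)
}

# a noiseless generating truth
noise_free_truth <- function(...) {
  true_response(sigma_wetland = 0, sigma_chamber = 0, sigma_resid = 0, ...)
}

# hand-built two-wetland raster stack: wetland A = pixels (3:5, 3:5) wet all
# steps, wetland B = pixel (10, 10) wet in step 1 only
toy_stack <- function(ns = 2, nr = 16, nc = 16,
                      window = frost_free_window(80, 80 + 14 * ns - 1)) {
  water <- array(0L, dim = c(nr, nc, ns))
  water[3:5, 3:5, ] <- 1L
  water[10, 10, 1] <- 1L
  raster_stack(water_mask = water,
               temperature = array(15, dim = c(nr, nc, ns)),
               ndvi = array(0.2, dim = c(nr, nc, ns)),
               land_cover = matrix(1L, nr, nc),
               window = window)
}

# independent brute-force annual integration oracle: plain loops, separate
# arithmetic from integrate_annual()
brute_force_annual <- function(fluxes, stack, window = stack$window) {
  fx <- as.data.frame(fluxes)
  ns <- dim(stack$water_mask)[3]
  nr <- dim(stack$water_mask)[1]; nc <- dim(stack$water_mask)[2]
  area <- stack$pixel_size^2
  step_h <- stack$step_length * 24
  winter_h <- max(0, 8760 - ns * step_h)
  pre_d <- window$start_day - 1; post_d <- 365 - window$end_day
  pre_f <- if (pre_d + post_d > 0) pre_d / (pre_d + post_d) else 0.5
  annual <- matrix(0, nr, nc)
  for (p in unique(fx$pixel)) {
    rows <- fx[fx$pixel == p, ]
    rows <- rows[order(rows$step), ]
    total_mg <- 0
    for (i in seq_len(nrow(rows))) total_mg <- total_mg + rows$flux[i] * area * step_h
    total_mg <- total_mg + rows$flux[1] * pre_f * winter_h * area
    total_mg <- total_mg + rows$flux[nrow(rows)] * (1 - pre_f) * winter_h * area
    annual[p] <- total_mg / 1000
  }
  annual
}
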
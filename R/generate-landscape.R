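#' Configuration for the synthetic wetlandscape generator
#'
#' Defaults emulate a 30-m resolution prairie-pothole scene: many small
#' depressional wetlands with a log-normal size distribution (majority under
#' 1 ha), biweekly surface-water dynamics over a 266-day frost-free season
#' (19 steps of 14 days), seasonal temperature, an NDVI field with negative
#' values over open water and elevated values in an emergent-vegetation ring,
#' and a two-class grassland/cropland mosaic.
#'
#' @param nrow,ncol Grid shape in pixels (>= 64 each).
#' @param n_wetlands Number of wetlands to place.
#' @param pixel_size Pixel edge (m), default 30.
#' @param step_length Step length (days), default 14.
#' @param window [frost_free_window()] spanned by the time steps; the step
#'   count is `ceiling(length / step_length)` unless `n_steps` is given.
#' @param n_steps Optional explicit step count; must match the window.
#' @param area_meanlog,area_sdlog Log-normal parameters of wetland area in
#'   pixels (defaults: median 6 pixels = 0.54 ha, right-skewed so roughly 2%
#'   of wetlands exceed 10 ha).
#' @param area_max_px Upper truncation of wetland area (pixels); the default
#'   250 (22.5 ha) keeps the rare lake-sized waterbodies out of the default
#'   scene while preserving a heavy >10-ha extent share.
#' @param areas_px Optional explicit integer vector of wetland areas in
#'   pixels, overriding the distribution (length = `n_wetlands`).
#' @param wetness Multiplier in `(0, 1]` on every wetland's wetted-fraction
#'   trajectory; lowering it (with the same seed) produces a drier bookend of
#'   the same landscape whose wet extents are subsets of the wetter one.
#' @param max_retries Placement attempts per wetland before a placement error.
#' @param seed Integer RNG seed.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 128, ncol = 128, n_wetlands = 60,
                             pixel_size = 30, step_length = 14,
                             window = frost_free_window(80, 345),
                             n_steps = NULL,
                             area_meanlog = log(6), area_sdlog = 1.4,
                             area_max_px = 250, areas_px = NULL, wetness = 1,
                             max_retries = 200, seed = 1L) {
  if (nrow < 64 || ncol < 64) stop_domain("grid must be at least 64 x 64")
  derived <- as.integer(ceiling(window$length / step_length))
  if (is.null(n_steps)) n_steps <- derived
  if (n_steps != derived)
    stop_domain("window error: %d steps of %g days do not cover a %d-day window",
                n_steps, step_length, window$length)
  if (n_steps < 2) stop_domain("need at least 2 time steps")
  if (wetness <= 0 || wetness > 1) stop_domain("wetness must be in (0, 1]")
  if (!is.null(areas_px) && length(areas_px) != n_wetlands)
    stop_domain("areas_px must have length n_wetlands")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 n_wetlands = as.integer(n_wetlands),
                 pixel_size = pixel_size, step_length = step_length,
                 window = window, n_steps = as.integer(n_steps),
                 area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                 area_max_px = as.integer(area_max_px),
                 areas_px = areas_px, wetness = wetness,
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "landscape_config")
}

#' Generate a synthetic wetlandscape with known truth
#'
#' Places disjoint, roughly elliptical depressional wetlands on the grid
#' (largest first, with a one-pixel moat so components never touch), assigns
#' each a monotone seasonal drawdown trajectory of wetted fraction, and builds
#' the co-registered raster time series: binary water masks (pixels wet in
#' order of depth, so masks are nested across steps), temperature (seasonal
#' sinusoid plus a latitudinal gradient and a smooth spatial field), NDVI
#' (negative over open water, elevated in the emergent ring, moderate upland),
#' and a static blocky grassland/cropland mosaic.
#'
#' @param config A [landscape_config()].
#' @return A list of class `wetlandscape`: `wetland_table` (per-wetland id,
#'   centroid, pixel count, max area m^2, minimum wetted fraction, hydroperiod
#'   days, mean NDVI, land cover), `rasters` (a [raster_stack()]),
#'   `truth_labels` (integer matrix of generating wetland ids, 0 = upland),
#'   and `config`.
#' @export
generate_wetlandscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  nr <- config$nrow; nc <- config$ncol; ns <- config$n_steps
  nw <- config$n_wetlands

  areas <- config$areas_px
  if (is.null(areas)) {
    areas <- pmax(1L, as.integer(round(
      stats::rlnorm(nw, config$area_meanlog, config$area_sdlog))))
    areas <- pmin(areas, config$area_max_px, as.integer(floor(0.05 * nr * nc)))
  }
  ord <- order(areas, decreasing = TRUE)

  occ <- matrix(0L, nr, nc)
  footprints <- vector("list", nw) # pixel indices, sorted by depth rank
  aspect <- stats::runif(nw, 0.55, 1)
  theta <- stats::runif(nw, 0, pi)
  f_min <- clamp(0.10 + 0.10 * log(areas) + stats::rnorm(nw, 0, 0.08), 0.05, 0.90)

  for (k in ord) {
    a <- areas[k]
    rx <- sqrt(a * aspect[k] / pi); ry <- a / (pi * rx)
    m <- ceiling(max(rx, ry)) + 2L
    placed <- FALSE
    for (try_i in seq_len(config$max_retries)) {
      if (2L * m + 2L >= min(nr, nc)) break
      r0 <- sample((m + 2L):(nr - m - 1L), 1L)
      c0 <- sample((m + 2L):(nc - m - 1L), 1L)
      dr <- rep(-m:m, times = 2L * m + 1L)
      dc <- rep(-m:m, each = 2L * m + 1L)
      u <- (dr * cos(theta[k]) + dc * sin(theta[k])) / rx
      v <- (-dr * sin(theta[k]) + dc * cos(theta[k])) / ry
      depth <- u^2 + v^2
      sel <- order(depth)[seq_len(a)] # exactly `a` deepest-first pixels
      rows <- r0 + dr[sel]; cols <- c0 + dc[sel]
      # 1-pixel dilation: wetland plus moat must be unoccupied
      nbr_r <- rep(rows, each = 9L) + rep(c(-1L, 0L, 1L), times = 3L)
      nbr_c <- rep(cols, each = 9L) + rep(c(-1L, 0L, 1L), each = 3L)
      if (any(occ[cbind(nbr_r, nbr_c)] != 0L)) next
      occ[cbind(rows, cols)] <- k
      footprints[[k]] <- cbind(row = rows, col = cols) # depth order
      placed <- TRUE
      break
    }
    if (!placed)
      stop_domain("placement error: could not place wetland of %d pixels after %d retries",
                  a, config$max_retries)
  }

  # seasonal wetted fractions: monotone drawdown from step 1 (wettest)
  water <- array(0L, dim = c(nr, nc, ns))
  wet_counts <- matrix(0L, nw, ns)
  for (k in seq_len(nw)) {
    fp <- footprints[[k]]
    frac <- config$wetness *
      (f_min[k] + (1 - f_min[k]) * ((ns - seq_len(ns)) / (ns - 1))^2)
    n_wet <- pmax(1L, as.integer(round(frac * areas[k])))
    n_wet <- pmin(n_wet, areas[k])
    wet_counts[k, ] <- n_wet
    for (t in seq_len(ns)) {
      idx <- fp[seq_len(n_wet[t]), , drop = FALSE]
      water[cbind(idx[, 1], idx[, 2], t)] <- 1L
    }
  }

  # temperature: seasonal sinusoid + latitude gradient + smooth spatial field
  g_season <- 8 + 12 * sin(pi * (seq_len(ns) - 0.5) / ns)
  lat <- matrix((nr / 2 - seq_len(nr)) / nr * 2.0, nr, nc)
  ph <- stats::runif(4, 0, 2 * pi); fr <- sample(1:3, 4, replace = TRUE)
  rowg <- seq_len(nr) / nr; colg <- seq_len(nc) / nc
  field <- 0.6 * (outer(sin(2 * pi * fr[1] * rowg + ph[1]),
                        cos(2 * pi * fr[2] * colg + ph[2])) +
                  outer(cos(2 * pi * fr[3] * rowg + ph[3]),
                        sin(2 * pi * fr[4] * colg + ph[4]))) / 2
  temperature <- array(0, dim = c(nr, nc, ns))
  for (t in seq_len(ns))
    temperature[, , t] <- g_season[t] + lat + field +
      matrix(stats::rnorm(nr * nc, 0, 0.3), nr, nc)

  # land cover: blocky two-class mosaic
  block <- 16L
  br <- ceiling(nr / block); bc <- ceiling(nc / block)
  blocks <- matrix(sample(1:2, br * bc, replace = TRUE), br, bc)
  land_cover <- blocks[cbind(rep(ceiling(seq_len(nr) / block), times = nc),
                             rep(ceiling(seq_len(nc) / block), each = nr))]
  dim(land_cover) <- c(nr, nc)

  # NDVI: open-water core negative, emergent ring and drawn-down margin high
  green <- stats::plogis((seq_len(ns) - ns / 2.8) / (ns / 8))
  base_noise <- matrix(stats::rnorm(nr * nc, 0, 0.05), nr, nc)
  ndvi <- array(0, dim = c(nr, nc, ns))
  ring_start <- vapply(seq_len(nw), function(k) # deepest 60% of wet area = open water
    as.integer(ceiling(0.6 * wet_counts[k, 1])), integer(1))
  for (t in seq_len(ns)) {
    g <- matrix(0.15 + 0.25 * green[t], nr, nc) + 0.04 * (land_cover == 2)
    for (k in seq_len(nw)) {
      fp <- footprints[[k]]
      n_open <- min(ring_start[k], wet_counts[k, t])
      if (n_open >= 1) {
        core <- fp[seq_len(n_open), , drop = FALSE]
        g[core] <- -0.18 + 0.05 * green[t]
      }
      if (areas[k] > n_open) {
        ring <- fp[(n_open + 1):areas[k], , drop = FALSE]
        g[ring] <- 0.25 + 0.5 * green[t]
      }
    }
    ndvi[, , t] <- clamp(g + base_noise, -0.5, 0.95)
  }

  stack <- raster_stack(water_mask = water, temperature = temperature,
                        ndvi = ndvi, land_cover = land_cover,
                        pixel_size = config$pixel_size,
                        step_length = config$step_length,
                        window = config$window)

  hydro_days <- vapply(seq_len(nw), function(k) {
    # mean per-pixel wet-step count over the footprint, in days
    config$step_length * sum(wet_counts[k, ]) / areas[k]
  }, numeric(1))
  mean_ndvi <- vapply(seq_len(nw), function(k) {
    fp <- footprints[[k]]
    mean(vapply(seq_len(ns), function(t) mean(ndvi[, , t][fp]), numeric(1)))
  }, numeric(1))
  lc_mode <- vapply(seq_len(nw), function(k) {
    tab <- tabulate(land_cover[footprints[[k]]], 2)
    stack$land_cover_levels[which.max(tab)]
  }, character(1))
  centroids <- t(vapply(footprints, function(fp) colMeans(fp), numeric(2)))

  wetland_table <- data.frame(
    wetland_id = seq_len(nw),
    centroid_row = centroids[, 1], centroid_col = centroids[, 2],
    n_pixels = areas,
    max_area_m2 = areas * config$pixel_size^2,
    min_wet_fraction = config$wetness * f_min,
    hydroperiod_days = clamp(hydro_days, 0, 365),
    mean_ndvi = mean_ndvi,
    land_cover = lc_mode,
    stringsAsFactors = FALSE
  )

  structure(list(wetland_table = wetland_table, rasters = stack,
                 truth_labels = occ, config = config),
            class = "wetlandscape")
}

#' @export
print.wetlandscape <- function(x, ...) {
  wt <- x$wetland_table
  cat(sprintf("wetlandscape: %d wetlands on a %d x %d grid (%g m pixels)\n",
              nrow(wt), x$config$nrow, x$config$ncol, x$config$pixel_size))
  cat(sprintf("  area: median %.2f ha, %.0f%% under 1 ha, max %.1f ha\n",
              stats::median(wt$max_area_m2) / 1e4,
              100 * mean(wt$max_area_m2 < 1e4), max(wt$max_area_m2) / 1e4))
  invisible(x)
}
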
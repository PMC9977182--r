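#' Delineate wetlands from a water-mask time series
#'
#' Connected components of the union (wet at any step) water mask. The union
#' mask defines the wetland object and its size; per-step masks define
#' inundated extent. Components are labelled 1..K in order of their first
#' pixel (column-major), so labels are stable under translation of the scene.
#'
#' @param stack A [raster_stack()].
#' @param connectivity 8 (default; queen) or 4 (rook) pixel adjacency.
#' @return An object of class `labeled_wetlands`: `labels` (integer matrix,
#'   0 = upland), `table` (per-wetland `wetland_id`, `n_pixels`, `area_m2`,
#'   `size_class`), `connectivity`, `pixel_size`.
#' @export
delineate_wetlands <- function(stack, connectivity = 8) {
  stopifnot(inherits(stack, "raster_stack"))
  if (!connectivity %in% c(4, 8)) stop_domain("connectivity must be 4 or 8")
  nr <- dim(stack$water_mask)[1]; nc <- dim(stack$water_mask)[2]
  ns <- n_steps(stack)
  u <- matrix(rowSums(matrix(stack$water_mask, nr * nc, ns)) > 0, nr, nc)

  wet <- which(u)
  labels <- matrix(0L, nr, nc)
  if (length(wet) == 0L) {
    warning("empty water mask: no wetlands delineated", call. = FALSE)
    tab <- data.frame(wetland_id = integer(), n_pixels = integer(),
                      area_m2 = numeric(), size_class = character(),
                      stringsAsFactors = FALSE)
    return(structure(list(labels = labels, table = tab,
                          connectivity = connectivity,
                          pixel_size = stack$pixel_size),
                     class = "labeled_wetlands"))
  }

  row_i <- (wet - 1L) %% nr + 1L
  col_i <- (wet - 1L) %/% nr + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  for (o in offs) {
    ok <- row_i + o[1] >= 1L & row_i + o[1] <= nr & col_i + o[2] <= nc
    nb <- (col_i[ok] + o[2] - 1L) * nr + (row_i[ok] + o[1])
    j <- match(nb, wet)
    keep <- !is.na(j)
    edges[[length(edges) + 1L]] <- cbind(which(ok)[keep], j[keep])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(wet), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel components by first (column-major) pixel for translation stability
  first_pix <- tapply(wet, memb, min)
  relab <- match(memb, as.integer(names(sort(first_pix))))
  labels[wet] <- relab

  npx <- tabulate(relab)
  area <- npx * stack$pixel_size^2
  tab <- data.frame(wetland_id = seq_along(npx), n_pixels = npx,
                    area_m2 = area,
                    size_class = size_class_label(area / 1e4),
                    stringsAsFactors = FALSE)
  structure(list(labels = labels, table = tab, connectivity = connectivity,
                 pixel_size = stack$pixel_size),
            class = "labeled_wetlands")
}

# 1-ha size classes up to 10 ha, then ">= 10 ha" (left-closed, right-open)
size_class_label <- function(area_ha, width = 1, max_class = 10) {
  edges <- seq(0, max_class, by = width)
  lab <- ifelse(area_ha >= max_class, sprintf(">=%g ha", max_class),
                sprintf("[%g,%g) ha", edges[findInterval(area_ha, edges)],
                        edges[findInterval(area_ha, edges) + 1L]))
  lab
}

#' @export
print.labeled_wetlands <- function(x, ...) {
  cat(sprintf("labeled_wetlands: %d components (%d-connectivity), %.2f km2 total\n",
              nrow(x$table), x$connectivity, sum(x$table$area_m2) / 1e6))
  invisible(x)
}

#' Derive the per-pixel, per-step predictor table
#'
#' Translates the raster stack into the chamber model's covariate schema for
#' every pixel belonging to a delineated wetland: a WFPS surrogate (100% when
#' the pixel is wet, a configurable dry-pixel value otherwise), hydroperiod as
#' the pixel's wet-step count times the step length, wetland size from the
#' component area, NDVI and temperature sampled from the grids, land cover,
#' the early/late growing-season interval split at the midpoint of the
#' frost-free window, and first-order lags (step 1 lags equal step-1 values).
#'
#' @param stack A [raster_stack()].
#' @param wetlands A [delineate_wetlands()] result for the same stack.
#' @param window A [frost_free_window()]; defaults to the stack's. Must be
#'   covered by the stack's steps.
#' @param dry_wfps WFPS surrogate (%) for currently-dry wetland pixels.
#' @return Data frame of class `predictor_stack`, step-major, with columns
#'   `pixel`, `row`, `col`, `step`, `wetland_id`, `wfps`, `soil_temp`,
#'   `ndvi`, `wetland_size`, `hydroperiod`, `land_cover`, `season_interval`,
#'   `wfps_lag`, `soil_temp_lag`, `ndvi_lag`.
#' @export
derive_predictor_stack <- function(stack, wetlands, window = stack$window,
                                   dry_wfps = 50) {
  stopifnot(inherits(stack, "raster_stack"), inherits(wetlands, "labeled_wetlands"))
  ns <- n_steps(stack)
  if (as.integer(ceiling(window$length / stack$step_length)) != ns)
    stop_domain("window error: %d steps of %g days do not cover the %d-day window",
                ns, stack$step_length, window$length)
  nr <- dim(stack$water_mask)[1]; nc <- dim(stack$water_mask)[2]
  idx <- which(wetlands$labels > 0L)
  if (length(idx) == 0L) stop_domain("no labeled wetland pixels")
  lab <- wetlands$labels[idx]
  area <- wetlands$table$area_m2[lab]
  wet_steps <- rowSums(matrix(stack$water_mask, nr * nc, ns)[idx, , drop = FALSE])
  hydro <- pmin(wet_steps * stack$step_length, 365)
  lc <- stack$land_cover_levels[stack$land_cover[idx]]
  half <- (window$start_day + window$end_day) / 2

  np <- length(idx)
  step_of <- rep(seq_len(ns), each = np)
  flat <- rep(idx, ns) + (step_of - 1L) * (nr * nc)
  wet_now <- stack$water_mask[flat] == 1L
  mid_day <- window$start_day - 1 + (step_of - 0.5) * stack$step_length

  out <- data.frame(
    pixel = rep(idx, ns),
    row = rep((idx - 1L) %% nr + 1L, ns),
    col = rep((idx - 1L) %/% nr + 1L, ns),
    step = step_of,
    wetland_id = rep(lab, ns),
    wfps = ifelse(wet_now, 100, dry_wfps),
    soil_temp = stack$temperature[flat],
    ndvi = stack$ndvi[flat],
    wetland_size = rep(area, ns),
    hydroperiod = rep(hydro, ns),
    land_cover = rep(lc, ns),
    season_interval = ifelse(mid_day <= half, "early", "late"),
    stringsAsFactors = FALSE
  )
  lag1 <- function(x) c(x[seq_len(np)], x[seq_len(np * (ns - 1L))])
  out$wfps_lag <- lag1(out$wfps)
  out$soil_temp_lag <- lag1(out$soil_temp)
  out$ndvi_lag <- lag1(out$ndvi)
  class(out) <- c("predictor_stack", "data.frame")
  out
}

#' Configuration of the bootstrap tree-ensemble flux model
#'
#' @param n_trees Number of regression trees.
#' @param feature_subset Predictors tried at each split; default
#'   `ceiling(p / 3)` (regression convention).
#' @param bootstrap_fraction Fraction of rows sampled (without replacement)
#'   per tree; the remaining ~1/3 are that tree's out-of-bag rows.
#' @param seed Integer seed; fits are single-threaded and reproducible.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_trees = 500, feature_subset = NULL,
                            bootstrap_fraction = 2 / 3, seed = 1L) {
  if (n_trees < 1) stop_domain("n_trees must be >= 1")
  if (bootstrap_fraction <= 0 || bootstrap_fraction >= 1)
    stop_domain("bootstrap_fraction must be in (0, 1)")
  structure(list(n_trees = as.integer(n_trees), feature_subset = feature_subset,
                 bootstrap_fraction = bootstrap_fraction, seed = as.integer(seed)),
            class = "ensemble_config")
}

ls_default_covariates <- c("wfps", "soil_temp", "ndvi", "wetland_size",
                           "hydroperiod", "land_cover", "season_interval",
                           "wfps_lag", "soil_temp_lag", "ndvi_lag")

#' Fit the landscape tree-ensemble flux model
#'
#' Random-forest regression of `log(flux)` on the landscape predictor schema:
#' each tree is grown on a random ~2/3 subsample of the training rows with a
#' random subset of predictors at each split, and evaluated on its out-of-bag
#' rows. Out-of-bag variance explained and mean squared residual are reported
#' on the training-response (log-flux) scale.
#'
#' @param training Data frame with a positive `flux` column (mg m^-2 h^-1)
#'   and the predictor columns (chamber rows or chamber rows joined to
#'   co-located pixel predictors).
#' @param config An [ensemble_config()].
#' @param covariates Predictor columns to use; defaults to the chamber
#'   covariate schema intersected with the available columns.
#' @return An object of class `ensemble_model` with the fitted forest,
#'   `oob_variance_explained`, `oob_mean_squared_residual`, and the training
#'   schema.
#' @export
fit_landscape_model <- function(training, config = ensemble_config(),
                                covariates = NULL) {
  stopifnot(inherits(config, "ensemble_config"))
  tr <- as.data.frame(training)
  if (!"flux" %in% names(tr)) stop_domain("training data must have a `flux` column")
  if (is.null(covariates))
    covariates <- intersect(ls_default_covariates, names(tr))
  miss <- setdiff(covariates, names(tr))
  if (length(miss)) stop_domain("missing covariates: %s", paste(miss, collapse = ", "))
  tr <- tr[is.finite(tr$flux) & tr$flux > 0, c("flux", covariates)]
  if (nrow(tr) < 100) stop_domain("need >= 100 positive-flux training rows")
  if (stats::var(log(tr$flux)) < 1e-12)
    stop_domain("degenerate fit: single-valued response")
  tr$log_flux <- log(tr$flux)
  for (cv in intersect(c("land_cover", "season_interval"), covariates))
    tr[[cv]] <- factor(tr[[cv]])

  mtry <- config$feature_subset %||% ceiling(length(covariates) / 3)
  form <- stats::as.formula(paste("log_flux ~", paste(covariates, collapse = " + ")))
  rf <- ranger::ranger(form, data = tr, num.trees = config$n_trees,
                       mtry = mtry, replace = FALSE,
                       sample.fraction = config$bootstrap_fraction,
                       seed = config$seed, num.threads = 1,
                       oob.error = TRUE)
  factor_levels <- lapply(tr[intersect(c("land_cover", "season_interval"),
                                       covariates)], levels)
  structure(list(forest = rf, covariates = covariates, config = config,
                 factor_levels = factor_levels,
                 oob_variance_explained = rf$r.squared,
                 oob_mean_squared_residual = rf$prediction.error),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("Landscape tree-ensemble flux model: %d trees, mtry %d\n",
              x$forest$num.trees, x$forest$mtry))
  cat(sprintf("  OOB variance explained: %.1f%%; OOB MSE (log scale): %.3f\n",
              100 * x$oob_variance_explained, x$oob_mean_squared_residual))
  invisible(x)
}

#' Predict per-pixel, per-step fluxes
#'
#' Applies the fitted ensemble (or any flux-predictor function, e.g. the
#' generating-truth oracle [evaluate_true_response()] wrapped in a closure) to
#' a predictor table. Evaluation is streamed over `tiles` consecutive row
#' chunks; the output is identical regardless of the partitioning.
#'
#' @param model An [fit_landscape_model()] result, or a function taking the
#'   predictor data frame and returning a flux vector (mg m^-2 h^-1).
#' @param predictors A [derive_predictor_stack()] table (or any data frame
#'   with the training schema).
#' @param tiles Number of row chunks to stream over.
#' @return Data frame of class `pixel_flux` with columns `pixel`, `step`,
#'   `flux` (mg m^-2 h^-1, non-negative).
#' @export
predict_pixel_flux <- function(model, predictors, tiles = 1) {
  pred_df <- as.data.frame(predictors)
  n <- nrow(pred_df)
  bounds <- unique(round(seq(0, n, length.out = tiles + 1)))
  fx <- numeric(n)
  for (i in seq_len(length(bounds) - 1L)) {
    rows <- (bounds[i] + 1L):bounds[i + 1L]
    chunk <- pred_df[rows, , drop = FALSE]
    if (is.function(model)) {
      fx[rows] <- model(chunk)
    } else {
      stopifnot(inherits(model, "ensemble_model"))
      miss <- setdiff(model$covariates, names(chunk))
      if (length(miss))
        stop_domain("schema error: predictor table missing %s",
                    paste(miss, collapse = ", "))
      for (cv in names(model$factor_levels)) {
        bad <- setdiff(unique(as.character(chunk[[cv]])), model$factor_levels[[cv]])
        if (length(bad))
          stop_domain("schema error: unknown %s level(s) %s", cv,
                      paste(bad, collapse = ", "))
        chunk[[cv]] <- factor(as.character(chunk[[cv]]),
                              levels = model$factor_levels[[cv]])
      }
      fx[rows] <- exp(stats::predict(model$forest, data = chunk,
                                     num.threads = 1)$predictions)
    }
  }
  if (any(fx < 0)) stop_domain("negative flux prediction")
  out <- data.frame(pixel = pred_df$pixel %||% seq_len(n),
                    step = pred_df$step %||% 1L, flux = fx)
  class(out) <- c("pixel_flux", "data.frame")
  out
}
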
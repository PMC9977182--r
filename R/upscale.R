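#' Frost-free (growing-season) window
#'
#' @param start_day,end_day Day-of-year bounds, `1 <= start < end <= 365`.
#' @return List of class `frost_free_window` with `start_day`, `end_day`,
#'   `length` (days, inclusive).
#' @export
frost_free_window <- function(start_day, end_day) {
  if (start_day < 1 || end_day > 365 || start_day >= end_day)
    stop_domain("window error: need 1 <= start_day < end_day <= 365")
  structure(list(start_day = as.integer(start_day),
                 end_day = as.integer(end_day),
                 length = as.integer(end_day - start_day + 1L)),
            class = "frost_free_window")
}

#' Integrate biweekly flux rates to annual per-pixel emissions
#'
#' Within the frost-free window each step contributes
#' `rate x pixel_area x step_hours`. Winter is charged at boundary rates: the
#' hours before the window at the first-step rate and the hours after it at
#' the last-step rate, so the 365-day (8760-hour) year is covered seamlessly —
#' a constant rate `r` integrates to exactly `r x area x 8760` regardless of
#' the window.
#'
#' @param fluxes A [predict_pixel_flux()] table (`pixel`, `step`, `flux` in
#'   mg m^-2 h^-1); every pixel must have a record for every step.
#' @param stack The [raster_stack()] the fluxes were predicted on.
#' @param window A [frost_free_window()]; defaults to the stack's.
#' @return Numeric matrix (grid shape) of annual emissions, g CH4 per pixel
#'   per year; 0 for pixels without flux records.
#' @export
integrate_annual <- function(fluxes, stack, window = stack$window) {
  stopifnot(inherits(stack, "raster_stack"))
  fx <- as.data.frame(fluxes)
  ns <- n_steps(stack)
  if (as.integer(ceiling(window$length / stack$step_length)) != ns)
    stop_domain("window error: steps do not cover the window")
  if (max(fx$step) > ns) stop_domain("window error: flux steps beyond stack steps")
  px_area <- stack$pixel_size^2
  step_hours <- stack$step_length * 24
  winter_hours <- max(0, 365 * 24 - ns * step_hours)
  pre_days <- window$start_day - 1
  post_days <- 365 - window$end_day
  pre_frac <- if (pre_days + post_days > 0) pre_days / (pre_days + post_days) else 0.5

  ord <- order(fx$pixel, fx$step)
  fx <- fx[ord, ]
  counts <- tabulate(factor(fx$pixel))
  if (any(counts[counts > 0] != ns))
    stop_domain("every pixel must have one flux record per step")
  pix <- unique(fx$pixel)
  m <- matrix(fx$flux, nrow = ns) # columns = pixels (sorted), rows = steps
  season_mg <- colSums(m) * px_area * step_hours
  winter_mg <- (m[1, ] * pre_frac + m[ns, ] * (1 - pre_frac)) *
    winter_hours * px_area
  nr <- dim(stack$water_mask)[1]; nc <- dim(stack$water_mask)[2]
  annual <- matrix(0, nr, nc)
  annual[pix] <- (season_mg + winter_mg) / 1000 # mg -> g
  annual
}

#' Summarize annual emissions over a region
#'
#' Table-style regional summary: total emission in Gg CH4, inundated area as
#' the maximum per-step wet extent (km^2; the per-step mean is also reported),
#' the pixel-hour-weighted mean flux rate over inundated pixel-steps, wetland
#' count, and means of NDVI, soil temperature (over inundated pixel-steps) and
#' per-pixel hydroperiod (over wetland pixels).
#'
#' @param annual Annual emission grid from [integrate_annual()] (g/pixel/yr).
#' @param fluxes The [predict_pixel_flux()] table used to build it.
#' @param wetlands A [delineate_wetlands()] result.
#' @param stack The [raster_stack()].
#' @param region_id,scenario_id Identifier strings carried into the output.
#' @return One-row data frame of class `emission_summary`.
#' @export
summarize_region <- function(annual, fluxes, wetlands, stack,
                             region_id = "region", scenario_id = "historical") {
  stopifnot(inherits(stack, "raster_stack"), inherits(wetlands, "labeled_wetlands"))
  fx <- as.data.frame(fluxes)
  nr <- dim(stack$water_mask)[1]; nc <- dim(stack$water_mask)[2]
  ns <- n_steps(stack)
  km2_per_px <- stack$pixel_size^2 / 1e6

  wet_per_step <- colSums(matrix(stack$water_mask, nr * nc, ns))
  flat <- fx$pixel + (fx$step - 1L) * (nr * nc)
  wet_now <- stack$water_mask[flat] == 1L

  labeled <- which(wetlands$labels > 0L)
  wet_steps_px <- rowSums(matrix(stack$water_mask, nr * nc, ns)[labeled, , drop = FALSE])

  out <- data.frame(
    region_id = region_id, scenario_id = scenario_id,
    total_emission_Gg = sum(annual) / 1e9,
    mean_flux_rate = if (any(wet_now)) mean(fx$flux[wet_now]) else 0,
    growing_season_days = stack$window$length,
    inundated_area_km2 = max(wet_per_step) * km2_per_px,
    mean_inundated_area_km2 = mean(wet_per_step) * km2_per_px,
    wetland_count = nrow(wetlands$table),
    mean_ndvi = if (any(wet_now)) mean(fx$ndvi[wet_now] %||% stack$ndvi[flat][wet_now]) else NA_real_,
    mean_soil_temp = if (any(wet_now)) mean(stack$temperature[flat][wet_now]) else NA_real_,
    mean_hydroperiod_days = mean(pmin(wet_steps_px * stack$step_length, 365)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("emission_summary", "data.frame")
  out
}

#' Decompose annual emissions by wetland size class
#'
#' Sums annual emissions per wetland, bins wetlands by maximum (union-mask)
#' area into left-closed right-open classes of `class_width_ha` up to
#' `max_class_ha` plus a final open class, and reports each class's share of
#' total emission and of total wetland extent, its area-weighted mean flux
#' rate, and its wetland count. Shares sum to 100 exactly.
#'
#' @param annual Annual emission grid (g/pixel/yr) from [integrate_annual()].
#' @param wetlands A [delineate_wetlands()] result; every pixel with non-zero
#'   annual emission must be labeled.
#' @param class_width_ha Class width (ha), default 1.
#' @param max_class_ha Lower edge of the open top class (ha), default 10.
#' @return Data frame of class `size_class_table`: `size_class`,
#'   `wetland_count`, `extent_km2`, `extent_share_pct`, `emission_Gg`,
#'   `emission_share_pct`, `mean_flux_mg_m2_h` (per-area annualized rate).
#' @export
size_class_decomposition <- function(annual, wetlands, class_width_ha = 1,
                                     max_class_ha = 10) {
  stopifnot(inherits(wetlands, "labeled_wetlands"))
  if (any(annual[wetlands$labels == 0L] != 0))
    stop_domain("consistency error: non-zero emission on unlabeled pixel")
  lab <- wetlands$labels[wetlands$labels > 0L]
  em_g <- as.numeric(rowsum(annual[wetlands$labels > 0L], lab)) # per wetland
  tab <- wetlands$table
  cls <- size_class_label(tab$area_m2 / 1e4, class_width_ha, max_class_ha)
  edges <- seq(0, max_class_ha, by = class_width_ha)
  all_cls <- c(sprintf("[%g,%g) ha", edges[-length(edges)], edges[-1]),
               sprintf(">=%g ha", max_class_ha))
  cls <- factor(cls, levels = all_cls)

  em_cls <- tapply(em_g, cls, sum, default = 0)
  area_cls <- tapply(tab$area_m2, cls, sum, default = 0)
  cnt_cls <- tapply(rep(1L, nrow(tab)), cls, sum, default = 0L)
  tot_em <- sum(em_cls); tot_area <- sum(area_cls)
  out <- data.frame(
    size_class = all_cls,
    wetland_count = as.integer(cnt_cls),
    extent_km2 = as.numeric(area_cls) / 1e6,
    extent_share_pct = if (tot_area > 0) 100 * as.numeric(area_cls) / tot_area else 0,
    emission_Gg = as.numeric(em_cls) / 1e9,
    emission_share_pct = if (tot_em > 0) 100 * as.numeric(em_cls) / tot_em else 0,
    mean_flux_mg_m2_h = ifelse(area_cls > 0,
                               as.numeric(em_cls) * 1000 / (as.numeric(area_cls) * 8760),
                               0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("size_class_table", "data.frame")
  out
}
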
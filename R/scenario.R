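#' Scenario specification: extent bookend x warming pathway x members
#'
#' A scenario pairs one historical wetland-extent bookend ("dry" or "wet")
#' with a warming pathway represented by an ensemble of members, each carrying
#' twelve monthly temperature deltas (degC) and a frost-free-window length
#' (days, at least the historical length).
#'
#' @param id Scenario identifier string.
#' @param extent_bookend `"dry"` or `"wet"` — names the source extent rasters.
#' @param pathway `"moderate"` or `"severe"` (bookkeeping label).
#' @param members List of members, each `list(deltas = <12 numeric degC>,
#'   window_length = <days>)`.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(id, extent_bookend = c("dry", "wet"),
                          pathway = c("moderate", "severe"), members) {
  extent_bookend <- match.arg(extent_bookend)
  pathway <- match.arg(pathway)
  if (!is.list(members) || length(members) < 1L)
    stop_domain("need at least one ensemble member")
  for (m in members) {
    if (!is.numeric(m$deltas) || length(m$deltas) != 12L || any(!is.finite(m$deltas)))
      stop_domain("each member needs 12 finite monthly deltas")
    if (is.null(m$window_length) || m$window_length < 1 || m$window_length > 365)
      stop_domain("each member needs a window_length in [1, 365]")
  }
  structure(list(id = id, extent_bookend = extent_bookend, pathway = pathway,
                 members = members),
            class = "scenario_spec")
}

#' Draw an ensemble of warming members
#'
#' Emulates a multi-model temperature-projection ensemble: each member has a
#' mean regional warming drawn around the pathway mean, a seasonal cycle
#' (stronger warming in the cold months), small monthly noise, and a
#' frost-free-window length drawn around the pathway's season length and
#' clamped to at least the historical length.
#'
#' @param n Number of members (13 mirrors a CMIP6-style ensemble).
#' @param mean_warming Pathway mean warming (degC); ~1.7 moderate, ~2.7 severe.
#' @param member_sd SD of member mean warming across the ensemble (degC).
#' @param seasonal_amplitude Amplitude of the monthly cycle (degC).
#' @param window_length Mean future frost-free-window length (days).
#' @param window_sd SD of member window lengths (days).
#' @param historical_length Historical window length (days); member windows
#'   never fall below it.
#' @param seed Integer seed.
#' @return List of members suitable for [scenario_spec()].
#' @export
make_ensemble_members <- function(n = 13, mean_warming = 1.7, member_sd = 0.5,
                                  seasonal_amplitude = 0.6,
                                  window_length = 323, window_sd = 6,
                                  historical_length = 266, seed = 1L) {
  set.seed(seed, kind = "Mersenne-Twister")
  lapply(seq_len(n), function(i) {
    base <- stats::rnorm(1, mean_warming, member_sd)
    deltas <- base + seasonal_amplitude * cos(2 * pi * (1:12 - 1) / 12) +
      stats::rnorm(12, 0, 0.15)
    wl <- max(historical_length,
              round(stats::rnorm(1, window_length, window_sd)))
    list(deltas = deltas, window_length = min(365L, as.integer(wl)))
  })
}

#' Apply one scenario member to a raster stack
#'
#' Shifts every temperature grid by the member's monthly delta (the month
#' containing each step's midpoint day) and extends the frost-free window to
#' the member's length. Extension days are placed after the historical window
#' where the calendar allows, then before it; new shoulder steps replicate the
#' boundary step's water mask and NDVI (consistent with the winter
#' boundary-rate assumption) and its pre-delta temperature. Water and NDVI
#' otherwise remain those of the bookend year.
#'
#' @param stack Historical bookend [raster_stack()].
#' @param spec A [scenario_spec()].
#' @param member Member index in `spec$members`.
#' @return A new [raster_stack()] with the shifted temperatures and extended
#'   window. With all-zero deltas and an unchanged window the output equals
#'   the input.
#' @export
apply_scenario <- function(stack, spec, member = 1L) {
  stopifnot(inherits(stack, "raster_stack"), inherits(spec, "scenario_spec"))
  if (member < 1 || member > length(spec$members))
    stop_domain("configuration error: member %d not in spec `%s`", member, spec$id)
  mb <- spec$members[[member]]
  w <- stack$window
  if (mb$window_length < w$length)
    stop_domain("member window (%d days) shorter than historical (%d days)",
                mb$window_length, w$length)

  extra <- mb$window_length - w$length
  ext_end <- min(extra, 365L - w$end_day)
  ext_start <- extra - ext_end
  if (w$start_day - ext_start < 1L)
    stop_domain("window error: extension does not fit in the calendar year")
  new_win <- frost_free_window(w$start_day - ext_start, w$end_day + ext_end)

  ns_old <- n_steps(stack)
  ns_new <- as.integer(ceiling(new_win$length / stack$step_length))
  n_add <- ns_new - ns_old
  n_pre <- if (extra > 0) as.integer(round(n_add * ext_start / extra)) else 0L
  n_post <- n_add - n_pre

  idx_old <- c(rep(1L, n_pre), seq_len(ns_old), rep(ns_old, n_post))
  water <- stack$water_mask[, , idx_old, drop = FALSE]
  ndvi <- stack$ndvi[, , idx_old, drop = FALSE]
  temp <- stack$temperature[, , idx_old, drop = FALSE]

  mid_day <- clamp(new_win$start_day - 1 + (seq_len(ns_new) - 0.5) * stack$step_length,
                   1, 365)
  months <- month_of_day(mid_day)
  for (t in seq_len(ns_new))
    temp[, , t] <- temp[, , t] + mb$deltas[months[t]]

  raster_stack(water_mask = water, temperature = temp, ndvi = ndvi,
               land_cover = stack$land_cover, pixel_size = stack$pixel_size,
               step_length = stack$step_length, window = new_win,
               origin = stack$origin, crs = stack$crs,
               land_cover_levels = stack$land_cover_levels)
}

#' Run a scenario ensemble through the landscape pipeline
#'
#' For every spec and member: apply the member to the bookend stack, derive
#' predictors, predict per-pixel fluxes, integrate to annual emissions, and
#' summarize; then compute ensemble statistics (mean total, CV as
#' `100 x sd / mean`, min/max range) across members. Any member failure
#' aborts with the scenario and member identified — no silent partial
#' ensembles. Deterministic given a fitted model.
#'
#' @param model An [fit_landscape_model()] result or a flux-predictor
#'   function (see [predict_pixel_flux()]).
#' @param stacks Named list of historical bookend stacks; names must cover
#'   the bookends used by `specs` (e.g. `list(dry = ..., wet = ...)`).
#' @param specs List of [scenario_spec()] objects.
#' @param dry_wfps Dry-pixel WFPS surrogate passed to the predictor stage.
#' @return List of `scenario_result` objects: per-member summaries plus
#'   `total_mean_Gg`, `total_cv_pct`, `total_range_Gg`.
#' @export
run_ensemble <- function(model, stacks, specs, dry_wfps = 50) {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  if (length(specs) < 1L) stop_domain("specs must be non-empty")
  wetlands_cache <- list()
  lapply(specs, function(spec) {
    bk <- spec$extent_bookend
    if (!bk %in% names(stacks))
      stop_domain("configuration error: missing `%s` bookend stack", bk)
    stack <- stacks[[bk]]
    if (is.null(wetlands_cache[[bk]]))
      wetlands_cache[[bk]] <<- delineate_wetlands(stack)
    wetlands <- wetlands_cache[[bk]]
    summaries <- vector("list", length(spec$members))
    for (m in seq_along(spec$members)) {
      summaries[[m]] <- tryCatch({
        st <- apply_scenario(stack, spec, m)
        pred <- derive_predictor_stack(st, wetlands, st$window, dry_wfps = dry_wfps)
        fx <- predict_pixel_flux(model, pred)
        annual <- integrate_annual(fx, st)
        summarize_region(annual, fx, wetlands, st,
                         scenario_id = sprintf("%s_m%02d", spec$id, m))
      }, error = function(e) {
        stop(sprintf("scenario `%s` member %d failed: %s",
                     spec$id, m, conditionMessage(e)), call. = FALSE)
      })
    }
    member_summaries <- do.call(rbind, summaries)
    tot <- member_summaries$total_emission_Gg
    structure(list(spec = spec, member_summaries = member_summaries,
                   total_mean_Gg = mean(tot),
                   total_cv_pct = if (length(tot) > 1 && mean(tot) > 0)
                     100 * stats::sd(tot) / mean(tot) else 0,
                   total_range_Gg = range(tot)),
              class = "scenario_result")
  })
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario `%s` (%s warming, %s bookend): %d member(s)\n",
              x$spec$id, x$spec$pathway, x$spec$extent_bookend,
              length(x$spec$members)))
  cat(sprintf("  total emission: %.3f Gg (CV %.1f%%, range %.3f-%.3f)\n",
              x$total_mean_Gg, x$total_cv_pct,
              x$total_range_Gg[1], x$total_range_Gg[2]))
  invisible(x)
}

#' Fold change of future versus historical emissions
#'
#' Ratio of the mean future total (across whatever future totals are passed,
#' typically the ensemble means of the dry and wet bookends of one pathway)
#' to the mean historical total (typically the dry and wet historical years).
#' Per-future ratios against the same baseline are also reported.
#'
#' @param future Numeric vector of future totals (Gg), or a list of
#'   `scenario_result` objects (their ensemble means are used).
#' @param historical Numeric vector of historical totals (Gg), or
#'   `emission_summary` rows.
#' @return List with `fold` (overall ratio) and `per_future` (each future
#'   total over the historical mean).
#' @examples
#' fold_change(c(710.4, 1270.9), c(351.8, 620.7)) # ~2.04
#' @export
fold_change <- function(future, historical) {
  if (is.list(future) && all(vapply(future, inherits, TRUE, "scenario_result")))
    future <- vapply(future, function(x) x$total_mean_Gg, numeric(1))
  if (inherits(historical, "emission_summary"))
    historical <- historical$total_emission_Gg
  if (is.list(historical))
    historical <- vapply(historical, function(x)
      if (inherits(x, "emission_summary")) x$total_emission_Gg else as.numeric(x),
      numeric(1))
  future <- as.numeric(future); historical <- as.numeric(historical)
  if (any(!is.finite(historical)) || mean(historical) <= 0)
    stop_domain("historical baseline totals must be positive")
  base <- mean(historical)
  list(fold = mean(future) / base, per_future = future / base)
}
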
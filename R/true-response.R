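#' Generating truth for synthetic chamber fluxes
#'
#' Defines the closed-form log-scale response surface used by the synthetic
#' chamber generator: additive terms in water-filled pore space (WFPS), soil
#' temperature, NDVI, wetland size, hydroperiod, plus land-cover and
#' season-interval offsets, first-order lag terms, and the variance components
#' of wetland and chamber random intercepts and residual noise. All terms are
#' centered so that a record with every covariate at its reference value has
#' log flux exactly equal to `intercept`.
#'
#' The term shapes mirror the qualitative behaviour expected of temperate
#' depressional wetlands: a logistic rise of flux with WFPS with its inflection
#' at 80% (flux collapses as surface soils aerate below that point), an
#' exponential (Arrhenius-like) temperature response with a fixed Q10, a smooth
#' step in NDVI at 0 (open water to emergent vegetation transition), a
#' log-quadratic wetland-size curve peaking at 3 ha (the "goldilocks" zone of
#' medium-sized wetlands), and a saturating hydroperiod effect.
#'
#' @param intercept Log-flux (log mg CH4 m^-2 h^-1) at the reference record.
#' @param q10 True multiplicative change in flux per +10 degC soil temperature.
#' @param wfps_amplitude,wfps_scale Height (log units) and logistic width (%)
#'   of the WFPS term; inflection fixed at 80% WFPS.
#' @param ndvi_amplitude,ndvi_scale Height and logistic width of the NDVI step
#'   centered at NDVI = 0.
#' @param size_curvature Curvature of the log-quadratic size term
#'   (log-units per squared log-ratio of area to the 3-ha peak).
#' @param hydro_amplitude,hydro_efold Height and e-folding scale (days) of the
#'   saturating hydroperiod term.
#' @param lc_offset Named additive offsets (log units) for land cover;
#'   reference level is `cropland` (offset 0).
#' @param season_offset Named additive offsets for growing-season interval;
#'   reference level is `early`.
#' @param lag_weights Weights applied to the parent response curves evaluated
#'   at the lagged WFPS, soil-temperature, and NDVI values.
#' @param sigma_wetland,sigma_chamber,sigma_resid Standard deviations (log
#'   units) of the wetland random intercept, chamber-within-wetland random
#'   intercept, and residual noise.
#' @param reference Named list of reference covariate values (wfps %,
#'   soil_temp degC, ndvi, wetland_size m^2, hydroperiod days).
#'
#' @return An object of class `true_response`.
#' @examples
#' tr <- true_response()
#' ref <- reference_record(tr)
#' evaluate_true_response(tr, ref) # exp(intercept)
#' @export
true_response <- function(intercept = -1.1,
                          q10 = 3,
                          wfps_amplitude = 1.9, wfps_scale = 6,
                          ndvi_amplitude = 1.1, ndvi_scale = 0.12,
                          size_curvature = 0.16,
                          hydro_amplitude = 0.8, hydro_efold = 90,
                          lc_offset = c(grassland = 0.25, cropland = 0),
                          season_offset = c(early = 0, late = -0.2),
                          lag_weights = c(wfps = 0.25, soil_temp = 0.25, ndvi = 0.25),
                          sigma_wetland = 0.15, sigma_chamber = 0.12,
                          sigma_resid = 1.15,
                          reference = list(wfps = 80, soil_temp = 15, ndvi = 0,
                                           wetland_size = 30000, hydroperiod = 180)) {
  for (nm in c("sigma_wetland", "sigma_chamber", "sigma_resid")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop_domain("`%s` must be a non-negative number", nm)
  }
  assert_scalar_number(q10, "q10", positive = TRUE)
  stopifnot(all(c("grassland", "cropland") %in% names(lc_offset)),
            all(c("early", "late") %in% names(season_offset)),
            all(c("wfps", "soil_temp", "ndvi") %in% names(lag_weights)))
  structure(list(
    intercept = intercept, q10 = q10,
    wfps_amplitude = wfps_amplitude, wfps_center = 80, wfps_scale = wfps_scale,
    ndvi_amplitude = ndvi_amplitude, ndvi_scale = ndvi_scale,
    size_curvature = size_curvature, size_peak_m2 = 30000,
    hydro_amplitude = hydro_amplitude, hydro_efold = hydro_efold,
    lc_offset = lc_offset, season_offset = season_offset,
    lag_weights = lag_weights,
    sigma_wetland = sigma_wetland, sigma_chamber = sigma_chamber,
    sigma_resid = sigma_resid,
    reference = reference
  ), class = "true_response")
}

#' @export
print.true_response <- function(x, ...) {
  cat("Generating truth for synthetic chamber CH4 fluxes\n")
  cat(sprintf("  intercept (log mg m-2 h-1): %.3f   Q10: %.2f\n", x$intercept, x$q10))
  cat(sprintf("  sigmas (wetland/chamber/resid): %.2f / %.2f / %.2f\n",
              x$sigma_wetland, x$sigma_chamber, x$sigma_resid))
  cat("  terms: logistic WFPS (inflection 80%), exponential soil T,",
      "NDVI step at 0,\n         log-quadratic size (peak 3 ha), saturating hydroperiod\n")
  invisible(x)
}

# individual centered term functions (log-flux scale) ------------------------

tr_f_wfps <- function(tr, wfps) {
  tr$wfps_amplitude *
    (stats::plogis((wfps - tr$wfps_center) / tr$wfps_scale) -
       stats::plogis((tr$reference$wfps - tr$wfps_center) / tr$wfps_scale))
}

tr_f_temp <- function(tr, soil_temp) {
  log(tr$q10) / 10 * (soil_temp - tr$reference$soil_temp)
}

tr_f_ndvi <- function(tr, ndvi) {
  tr$ndvi_amplitude *
    (stats::plogis(ndvi / tr$ndvi_scale) -
       stats::plogis(tr$reference$ndvi / tr$ndvi_scale))
}

tr_f_size <- function(tr, wetland_size) {
  -tr$size_curvature * (log(wetland_size / tr$size_peak_m2))^2 +
    tr$size_curvature * (log(tr$reference$wetland_size / tr$size_peak_m2))^2
}

tr_f_hydro <- function(tr, hydroperiod) {
  tr$hydro_amplitude *
    (-exp(-hydroperiod / tr$hydro_efold) +
       exp(-tr$reference$hydroperiod / tr$hydro_efold))
}

tr_check_domain <- function(records) {
  with(records, {
    if (any(wfps < 0 | wfps > 100)) stop_domain("wfps outside [0, 100]")
    if (any(ndvi < -1 | ndvi > 1)) stop_domain("ndvi outside [-1, 1]")
    if (any(wetland_size <= 0)) stop_domain("wetland_size must be > 0")
    if (any(hydroperiod < 0 | hydroperiod > 365)) stop_domain("hydroperiod outside [0, 365]")
    if (any(soil_temp < -30 | soil_temp > 50)) stop_domain("soil_temp outside [-30, 50] degC")
  })
  invisible(records)
}

#' Log-scale expected response of the generating truth
#'
#' Sum of all generating terms (no random effects, no noise) on the log-flux
#' scale for one or more covariate records.
#'
#' @param truth A [true_response()] object.
#' @param records Data frame with columns `wfps`, `soil_temp`, `ndvi`,
#'   `wetland_size`, `hydroperiod`, `land_cover`, `season_interval`,
#'   `wfps_lag`, `soil_temp_lag`, `ndvi_lag`. Missing lag columns default to
#'   the parent values.
#' @return Numeric vector of log expected fluxes.
#' @export
true_log_response <- function(truth, records) {
  stopifnot(inherits(truth, "true_response"))
  records <- as.data.frame(records)
  need <- c("wfps", "soil_temp", "ndvi", "wetland_size", "hydroperiod",
            "land_cover", "season_interval")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_domain("records missing columns: %s", paste(miss, collapse = ", "))
  for (lag in c("wfps", "soil_temp", "ndvi")) {
    lcol <- paste0(lag, "_lag")
    if (!lcol %in% names(records)) records[[lcol]] <- records[[lag]]
  }
  tr_check_domain(records)
  lc <- as.character(records$land_cover)
  si <- as.character(records$season_interval)
  if (!all(lc %in% names(truth$lc_offset))) stop_domain("unknown land_cover level")
  if (!all(si %in% names(truth$season_offset))) stop_domain("unknown season_interval level")
  w <- truth$lag_weights
  truth$intercept +
    tr_f_wfps(truth, records$wfps) +
    tr_f_temp(truth, records$soil_temp) +
    tr_f_ndvi(truth, records$ndvi) +
    tr_f_size(truth, records$wetland_size) +
    tr_f_hydro(truth, records$hydroperiod) +
    unname(truth$lc_offset[lc]) +
    unname(truth$season_offset[si]) +
    w[["wfps"]] * tr_f_wfps(truth, records$wfps_lag) +
    w[["soil_temp"]] * tr_f_temp(truth, records$soil_temp_lag) +
    w[["ndvi"]] * tr_f_ndvi(truth, records$ndvi_lag)
}

#' Expected flux under the generating truth
#'
#' Deterministic expected flux (mg CH4 m^-2 h^-1): the exponential of the sum
#' of all generating terms, without random effects or noise. Serves as the
#' oracle for model-recovery tests and as a drop-in pixel predictor for
#' scenario physics checks.
#'
#' @inheritParams true_log_response
#' @return Numeric vector of expected fluxes (mg m^-2 h^-1).
#' @export
evaluate_true_response <- function(truth, records) {
  exp(true_log_response(truth, records))
}

#' Reference covariate record of a generating truth
#'
#' @param truth A [true_response()] object.
#' @return One-row data frame at the reference values (cropland, early season,
#'   lags equal to parents).
#' @export
reference_record <- function(truth) {
  stopifnot(inherits(truth, "true_response"))
  r <- truth$reference
  data.frame(wfps = r$wfps, soil_temp = r$soil_temp, ndvi = r$ndvi,
             wetland_size = r$wetland_size, hydroperiod = r$hydroperiod,
             land_cover = "cropland", season_interval = "early",
             wfps_lag = r$wfps, soil_temp_lag = r$soil_temp, ndvi_lag = r$ndvi,
             stringsAsFactors = FALSE)
}
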
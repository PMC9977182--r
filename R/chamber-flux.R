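#' Static-chamber geometry
#'
#' @param height Chamber headspace height (m).
#' @param basal_area Basal area (m^2). For a circular chamber of diameter `d`,
#'   `pi * d^2 / 4`.
#' @param volume Headspace volume (m^3); defaults to `height * basal_area` and
#'   must agree with it to within 1e-9 relative tolerance.
#' @return A list of class `chamber_geometry`.
#' @examples
#' chamber_geometry(height = 0.20, basal_area = pi * 0.20^2 / 4)
#' @export
chamber_geometry <- function(height, basal_area, volume = height * basal_area) {
  assert_scalar_number(height, "height", positive = TRUE)
  assert_scalar_number(basal_area, "basal_area", positive = TRUE)
  assert_scalar_number(volume, "volume", positive = TRUE)
  if (abs(volume - height * basal_area) > 1e-9 * volume)
    stop_domain("volume (%g) inconsistent with height x basal_area (%g)",
                volume, height * basal_area)
  structure(list(height = height, basal_area = basal_area, volume = volume),
            class = "chamber_geometry")
}

# universal gas constant, J mol^-1 K^-1
R_GAS <- 8.31446261815324

#' Compute a static-chamber gas flux from a concentration series
#'
#' Fits the linear change of headspace concentration over deployment time by
#' ordinary least squares and converts the slope to a mass flux with the ideal
#' gas law: one ppm of a gas with molar mass M occupies
#' `M * P / (R * T) * 1e-6` g m^-3, and the areal flux is the volumetric rate
#' times the effective chamber height (`volume / basal_area`).
#'
#' @param times Minutes since chamber closure; strictly increasing, first
#'   element 0 (the ambient sample).
#' @param concentrations Mole fractions in ppm, same length as `times`.
#' @param geom A [chamber_geometry()].
#' @param temperature Air temperature (K).
#' @param pressure Air pressure (Pa); default standard atmosphere.
#' @param molar_mass Gas molar mass (g mol^-1); default CH4 (16.04).
#' @return A list of class `flux_result` with `flux` (mg m^-2 h^-1), `slope`
#'   (ppm h^-1), `r_squared`, and the `temperature_K` and `pressure_Pa` used.
#' @examples
#' geom <- chamber_geometry(height = 0.20, basal_area = pi * 0.1^2)
#' compute_flux(c(0, 30), c(1.9, 6.9), geom, temperature = 293.15)
#' @export
compute_flux <- function(times, concentrations, geom,
                         temperature, pressure = 101325,
                         molar_mass = 16.04) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (length(times) < 2L || length(times) != length(concentrations))
    stop_domain("need >= 2 (time, concentration) points of equal length")
  if (any(diff(times) <= 0)) stop_domain("times must be strictly increasing")
  if (times[1] != 0) stop_domain("first time must be 0 (ambient sample)")
  assert_scalar_number(temperature, "temperature", positive = TRUE)
  assert_scalar_number(pressure, "pressure", positive = TRUE)
  assert_scalar_number(molar_mass, "molar_mass", positive = TRUE)

  hours <- times / 60
  fit <- stats::lm.fit(cbind(1, hours), concentrations)
  slope <- unname(fit$coefficients[2]) # ppm h^-1
  ss_tot <- sum((concentrations - mean(concentrations))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1

  g_per_m3_per_ppm <- molar_mass * pressure / (R_GAS * temperature) * 1e-6
  flux_mg <- slope * g_per_m3_per_ppm * (geom$volume / geom$basal_area) * 1000
  structure(list(flux = flux_mg, slope = slope, r_squared = r2,
                 temperature_K = temperature, pressure_Pa = pressure),
            class = "flux_result")
}

#' Water-filled pore space from volumetric water content
#'
#' WFPS = VWC / porosity, as a percent, clamped to 100 (with a warning) when
#' the measured VWC exceeds the stated porosity.
#'
#' @param vwc Volumetric water content (%), in `[0, 100]`.
#' @param porosity Soil porosity as a fraction in `(0, 1]`.
#' @return WFPS (%), elementwise.
#' @examples
#' compute_wfps(40, 0.5) # 80
#' @export
compute_wfps <- function(vwc, porosity) {
  if (any(!is.finite(porosity)) || any(porosity <= 0) || any(porosity > 1))
    stop_domain("porosity must be in (0, 1]")
  if (any(!is.finite(vwc)) || any(vwc < 0) || any(vwc > 100))
    stop_domain("vwc must be in [0, 100]")
  wfps <- vwc / porosity
  if (any(wfps > 100)) {
    warning(sprintf("%d WFPS value(s) exceeded 100%% and were clamped",
                    sum(wfps > 100)), call. = FALSE)
    wfps <- pmin(wfps, 100)
  }
  wfps
}

#' Q10 temperature sensitivity from binned fluxes
#'
#' Bins paired (temperature, flux) records into 1 degC increments, averages
#' flux per bin, and fits `log(mean flux)` against bin midpoint temperature by
#' least squares; `Q10 = exp(10 * slope)`. With exactly two occupied bins this
#' reduces to the endpoint ratio `(F2/F1)^(10/(T2-T1))`.
#'
#' @param temperature Temperatures (degC), paired with `flux`.
#' @param flux Flux rates (any positive unit); Q10 is scale-invariant.
#' @param range Either `"all"` or a numeric `c(low, high)` in degC; records
#'   with `low <= T < high` are used (`"all"` keeps everything).
#' @return A list of class `q10_result` with `q10`, `temp_range`, `n_bins`.
#' @examples
#' T <- 0:30
#' compute_q10(T, 2^(T / 10))$q10 # 2
#' @export
compute_q10 <- function(temperature, flux, range = "all") {
  if (length(temperature) != length(flux) || length(flux) < 2L)
    stop_domain("temperature and flux must be equal-length vectors (n >= 2)")
  keep <- is.finite(temperature) & is.finite(flux)
  temperature <- temperature[keep]; flux <- flux[keep]
  if (identical(range, "all")) {
    lo <- -Inf; hi <- Inf
  } else {
    if (!is.numeric(range) || length(range) != 2L || range[1] >= range[2])
      stop_domain("range must be \"all\" or c(low, high) with low < high")
    lo <- range[1]; hi <- range[2]
    keep <- temperature >= lo & temperature < hi
    temperature <- temperature[keep]; flux <- flux[keep]
  }
  bins <- floor(temperature) # 1 degC increments
  if (length(bins) == 0L || length(unique(bins)) < 2L)
    stop_domain("need records in >= 2 distinct 1-degC bins within the range")
  mean_flux <- tapply(flux, bins, mean)
  if (any(mean_flux <= 0))
    stop_domain("non-positive bin mean flux: log-scale Q10 undefined")
  mid <- as.numeric(names(mean_flux)) + 0.5
  fit <- stats::lm.fit(cbind(1, mid), log(as.numeric(mean_flux)))
  q10 <- exp(10 * unname(fit$coefficients[2]))
  structure(list(q10 = q10,
                 temp_range = c(low = lo, high = hi),
                 n_bins = length(mean_flux)),
            class = "q10_result")
}
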
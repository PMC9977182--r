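#' Configuration for the synthetic chamber-flux generator
#'
#' Defaults emulate the structure of a large multi-year prairie-pothole
#' chamber campaign: ~143 wetlands sampled with five wetland-zone chambers
#' each, every two weeks through the growing season (13 biweekly steps,
#' May-November), over multiple years, yielding roughly 19,000 rows at two
#' years (143 x 5 x 13 x 2 = 18,590).
#'
#' @param n_wetlands Number of wetlands (>= 2).
#' @param chambers_per_wetland Chambers per wetland (>= 1).
#' @param years Number of sampling years.
#' @param steps_per_year Biweekly sampling steps per growing season.
#' @param seed Integer RNG seed; same config + seed gives byte-identical data.
#' @param truth A [true_response()] generating truth.
#' @param constant_covariates If `TRUE`, hold every covariate at its reference
#'   value (used for noise-free identity checks).
#' @param wfps_ndvi_cor Extra coupling in `[0, 1]` between the chamber-level
#'   WFPS and NDVI deviations, beyond their shared seasonality. The real
#'   campaign's covariate correlation structure is unknown; default 0.
#' @return A list of class `chamber_config`.
#' @export
chamber_config <- function(n_wetlands = 143, chambers_per_wetland = 5,
                           years = 2, steps_per_year = 13, seed = 1L,
                           truth = true_response(),
                           constant_covariates = FALSE,
                           wfps_ndvi_cor = 0) {
  if (n_wetlands < 2) stop_domain("n_wetlands must be >= 2")
  if (chambers_per_wetland < 1) stop_domain("chambers_per_wetland must be >= 1")
  if (years < 1 || steps_per_year < 1) stop_domain("years and steps_per_year must be >= 1")
  if (wfps_ndvi_cor < 0 || wfps_ndvi_cor > 1) stop_domain("wfps_ndvi_cor must be in [0, 1]")
  stopifnot(inherits(truth, "true_response"))
  structure(list(n_wetlands = as.integer(n_wetlands),
                 chambers_per_wetland = as.integer(chambers_per_wetland),
                 years = as.integer(years),
                 steps_per_year = as.integer(steps_per_year),
                 seed = as.integer(seed), truth = truth,
                 constant_covariates = isTRUE(constant_covariates),
                 wfps_ndvi_cor = wfps_ndvi_cor),
            class = "chamber_config")
}

#' Generate a synthetic chamber flux dataset
#'
#' Simulates one row per chamber x biweekly step x year. Covariate
#' trajectories follow a seasonal temperature sinusoid and wetland-specific
#' soil-moisture drawdown; wetland size is log-normal (majority < 1 ha) with
#' hydroperiod increasing in size; NDVI rises from open-water (negative)
#' values early in the season to emergent-vegetation values later. Fluxes are
#' `exp(log-mean + wetland effect + chamber effect + Gaussian noise)` with the
#' log-mean given by the generating [true_response()].
#'
#' First-step lags equal current values (no prior step exists); later lags are
#' the previous step's values within each chamber-year series.
#'
#' @param config A [chamber_config()].
#' @return List with `observations` (data frame, one row per deployment; the
#'   hidden column `log_mu` holds the generating log-mean for diagnostics) and
#'   `truth` (the generating [true_response()]).
#' @examples
#' d <- generate_chamber_dataset(chamber_config(n_wetlands = 4, years = 1, seed = 7))
#' head(d$observations)
#' @export
generate_chamber_dataset <- function(config = chamber_config()) {
  stopifnot(inherits(config, "chamber_config"))
  tr <- config$truth
  set.seed(config$seed, kind = "Mersenne-Twister")

  nw <- config$n_wetlands; nc <- config$chambers_per_wetland
  ny <- config$years; ns <- config$steps_per_year
  if (nw * nc * ny * ns < 1) stop_domain("empty design")

  # wetland-level attributes
  size <- clamp(stats::rlnorm(nw, meanlog = log(7000), sdlog = 1.35), 150, 2e6)
  hydro <- clamp(120 + 38 * (log(size) - log(7000)) + stats::rnorm(nw, 0, 25), 30, 365)
  land_cover <- sample(c("grassland", "cropland"), nw, replace = TRUE)
  b_wetland <- stats::rnorm(nw, 0, tr$sigma_wetland)
  drawdown <- clamp(stats::runif(nw, 0.5, 3.5) * (1.2 - hydro / 365), 0.1, 3.5)

  rows <- vector("list", nw)
  for (w in seq_len(nw)) {
    b_ch <- stats::rnorm(nc, 0, tr$sigma_chamber)
    pos <- seq_len(nc) / (nc + 1) # chamber position, edge (0) -> centre (1)
    out <- vector("list", nc * ny)
    k <- 0L
    for (ch in seq_len(nc)) {
      for (y in seq_len(ny)) {
        t <- seq_len(ns)
        year_off <- stats::rnorm(1, 0, 1)
        soil_temp <- 8 + 12 * sin(pi * (t - 0.5) / ns) + year_off +
          stats::rnorm(ns, 0, 1.5)
        e_w <- stats::rnorm(ns, 0, 4)
        base_wfps <- 68 + 28 * pos[ch] + 6 * (hydro[w] - 120) / 100
        wfps <- clamp(base_wfps - drawdown[w] * (t - 1) + e_w, 20, 100)
        green <- stats::plogis((t - ns / 2.8) / 1.6)
        e_n <- config$wfps_ndvi_cor * (e_w / 40) +
          sqrt(1 - config$wfps_ndvi_cor^2) * stats::rnorm(ns, 0, 0.08)
        ndvi <- clamp(-0.22 + 0.75 * green + 0.25 * (1 - pos[ch]) * green + e_n,
                      -0.5, 0.95)
        soil_temp <- clamp(soil_temp, -5, 35)
        rec <- data.frame(
          wetland_id = sprintf("W%03d", w),
          chamber_id = sprintf("W%03d_C%02d", w, ch),
          year = 2000L + y, step_index = t,
          wfps = wfps, soil_temp = soil_temp, ndvi = ndvi,
          wetland_size = size[w], hydroperiod = hydro[w],
          land_cover = land_cover[w],
          season_interval = ifelse(t <= ns / 2, "early", "late"),
          wfps_lag = c(wfps[1], wfps[-ns]),
          soil_temp_lag = c(soil_temp[1], soil_temp[-ns]),
          ndvi_lag = c(ndvi[1], ndvi[-ns]),
          stringsAsFactors = FALSE
        )
        rec$b_chamber <- b_ch[ch]
        k <- k + 1L
        out[[k]] <- rec
      }
    }
    rows[[w]] <- do.call(rbind, out)
    rows[[w]]$b_wetland <- b_wetland[w]
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL

  if (config$constant_covariates) {
    r <- tr$reference
    obs$wfps <- r$wfps; obs$soil_temp <- r$soil_temp; obs$ndvi <- r$ndvi
    obs$wetland_size <- r$wetland_size; obs$hydroperiod <- r$hydroperiod
    obs$land_cover <- "cropland"; obs$season_interval <- "early"
    obs$wfps_lag <- r$wfps; obs$soil_temp_lag <- r$soil_temp; obs$ndvi_lag <- r$ndvi
  }

  obs$log_mu <- true_log_response(tr, obs)
  eps <- stats::rnorm(nrow(obs), 0, tr$sigma_resid)
  obs$flux <- exp(obs$log_mu + obs$b_wetland + obs$b_chamber + eps)
  obs$b_wetland <- NULL
  obs$b_chamber <- NULL
  list(observations = obs, truth = tr)
}
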
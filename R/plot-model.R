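#' Configuration of the plot-scale additive flux model
#'
#' @param smooth_terms Continuous covariates to model with penalized smooths.
#'   `wetland_size` is smoothed on the log scale internally (areas span four
#'   orders of magnitude); every other term is smoothed on its native scale.
#' @param categorical_terms Categorical covariates entered as fixed effects;
#'   never subject to removal by the selection penalty.
#' @param basis_dim Basis dimension per smooth (>= 4).
#' @param selection_penalty If `TRUE`, use the double-penalty selection
#'   criterion that can shrink whole smooth terms to zero (effectively
#'   removing uninformative covariates).
#' @param random_effects If `TRUE`, add wetland and chamber-within-wetland
#'   random intercepts as ridge-penalized spline terms.
#' @return A list of class `plot_model_config`.
#' @export
plot_model_config <- function(smooth_terms = c("wfps", "soil_temp", "ndvi",
                                               "wetland_size", "hydroperiod",
                                               "wfps_lag", "soil_temp_lag",
                                               "ndvi_lag"),
                              categorical_terms = c("land_cover", "season_interval"),
                              basis_dim = 10, selection_penalty = TRUE,
                              random_effects = TRUE) {
  if (basis_dim < 4) stop_domain("basis_dim must be >= 4")
  structure(list(smooth_terms = smooth_terms,
                 categorical_terms = categorical_terms,
                 basis_dim = as.integer(basis_dim),
                 selection_penalty = isTRUE(selection_penalty),
                 random_effects = isTRUE(random_effects)),
            class = "plot_model_config")
}

# model-frame variable used for a covariate (log transform for size)
pm_var <- function(covariate) {
  ifelse(covariate == "wetland_size", "log_wetland_size", covariate)
}

pm_transform <- function(covariate, x) {
  if (covariate == "wetland_size") log(x) else x
}

#' Fit the plot-scale additive flux model
#'
#' Models positive chamber CH4 fluxes as log-normal: Gaussian penalized
#' additive regression of `log(flux)` on smooth terms for the continuous
#' covariates, fixed effects for land cover and growing-season interval, and
#' random intercepts for wetland and chamber within wetland. Rows with
#' `flux <= 0` are dropped (the count is reported via `message()`). Smoothness
#' is chosen by fast REML; with the selection penalty on, uninformative smooth
#' terms can be penalized out of the model entirely.
#'
#' @param observations Data frame of chamber observations (see
#'   [generate_chamber_dataset()] for the column dictionary); must contain
#'   `flux`, every configured covariate, and — when random effects are on —
#'   `wetland_id` and `chamber_id`.
#' @param config A [plot_model_config()].
#' @return An object of class `plot_model`: the fitted mgcv model plus
#'   training ranges, per-term effective degrees of freedom, the set of terms
#'   effectively removed by selection (EDF < 0.1), the random-effect standard
#'   deviations, `deviance_explained`, and `adjusted_r2`.
#' @export
fit_plot_model <- function(observations, config = plot_model_config()) {
  stopifnot(inherits(config, "plot_model_config"))
  obs <- as.data.frame(observations)
  need <- c("flux", config$smooth_terms, config$categorical_terms,
            if (config$random_effects) c("wetland_id", "chamber_id"))
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop_domain("observations missing columns: %s", paste(miss, collapse = ", "))

  n0 <- nrow(obs)
  obs <- obs[is.finite(obs$flux) & obs$flux > 0, , drop = FALSE]
  n_dropped <- n0 - nrow(obs)
  if (n_dropped > 0)
    message(sprintf("dropped %d non-positive flux rows before fitting", n_dropped))

  total_basis <- length(config$smooth_terms) * config$basis_dim
  if (nrow(obs) <= total_basis)
    stop_domain("under-determined fit: %d rows for %d basis functions",
                nrow(obs), total_basis)

  obs$log_flux <- log(obs$flux)
  for (cv in config$smooth_terms) obs[[pm_var(cv)]] <- pm_transform(cv, obs[[cv]])
  for (cv in config$categorical_terms) obs[[cv]] <- factor(obs[[cv]])
  if (config$random_effects) {
    obs$wetland_id <- factor(obs$wetland_id)
    obs$chamber_id <- factor(obs$chamber_id)
  }

  sm <- sprintf("s(%s, bs = \"tp\", k = %d)", vapply(config$smooth_terms, pm_var, ""),
                config$basis_dim)
  re <- if (config$random_effects)
    c("s(wetland_id, bs = \"re\")", "s(chamber_id, bs = \"re\")") else character()
  rhs <- paste(c(sm, config$categorical_terms, re), collapse = " + ")
  form <- stats::as.formula(paste("log_flux ~", rhs))

  if (stats::var(obs$log_flux) < 1e-12) {
    # degenerate constant response: REML smoothness selection is unstable at
    # zero residual variance, so pin every penalty at a large fixed value
    fit <- mgcv::bam(form, data = obs, method = "GCV.Cp", discrete = FALSE,
                     select = FALSE, nthreads = 1,
                     sp = rep(1e8, length(sm) + length(re)))
  } else {
    fit <- mgcv::bam(form, data = obs, method = "fREML", discrete = TRUE,
                     select = config$selection_penalty, nthreads = 1)
  }

  edf <- pm_term_edf(fit)
  smooth_labels <- sprintf("s(%s)", vapply(config$smooth_terms, pm_var, ""))
  term_edf <- stats::setNames(edf[smooth_labels], config$smooth_terms)
  terms_removed <- names(term_edf)[!is.na(term_edf) & term_edf < 0.1]

  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((obs$log_flux - mean(obs$log_flux))^2)
  dev_expl <- if (tss > 1e-12) 1 - rss / tss else 0
  n <- nrow(obs); edf_total <- sum(fit$edf)
  adj_r2 <- if (tss > 1e-12)
    1 - (rss / max(n - edf_total, 1)) / (tss / (n - 1)) else 0

  re_sd <- c(wetland = NA_real_, chamber = NA_real_)
  if (config$random_effects) {
    vc <- try({
      tmp <- utils::capture.output(
        v <- suppressWarnings(mgcv::gam.vcomp(fit, rescale = TRUE)))
      v
    }, silent = TRUE)
    if (!inherits(vc, "try-error") && is.matrix(vc)) {
      rn <- rownames(vc)
      if ("s(wetland_id)" %in% rn) re_sd["wetland"] <- vc["s(wetland_id)", 1]
      if ("s(chamber_id)" %in% rn) re_sd["chamber"] <- vc["s(chamber_id)", 1]
    }
  }

  ranges <- lapply(config$smooth_terms, function(cv) range(obs[[cv]]))
  names(ranges) <- config$smooth_terms
  cat_levels <- lapply(config$categorical_terms, function(cv) levels(obs[[cv]]))
  names(cat_levels) <- config$categorical_terms

  structure(list(fit = fit, config = config,
                 covariate_ranges = ranges, categorical_levels = cat_levels,
                 term_edf = term_edf, terms_removed = terms_removed,
                 deviance_explained = max(0, min(1, dev_expl)),
                 adjusted_r2 = adj_r2,
                 random_effect_sd = re_sd,
                 n_train = n, n_dropped = n_dropped,
                 re_levels = if (config$random_effects)
                   list(wetland_id = levels(obs$wetland_id),
                        chamber_id = levels(obs$chamber_id)) else NULL),
            class = "plot_model")
}

# per-term effective degrees of freedom without the cost of summary.gam
pm_term_edf <- function(fit) {
  vapply(fit$smooth, function(s) {
    sum(fit$edf[s$first.para:s$last.para])
  }, numeric(1)) |>
    stats::setNames(vapply(fit$smooth, function(s) s$label, character(1)))
}

#' @export
print.plot_model <- function(x, ...) {
  cat("Plot-scale additive CH4 flux model (log-normal positive fluxes)\n")
  cat(sprintf("  n = %d training rows (%d non-positive dropped)\n",
              x$n_train, x$n_dropped))
  cat(sprintf("  deviance explained = %.1f%%, adjusted r2 = %.2f\n",
              100 * x$deviance_explained, x$adjusted_r2))
  if (length(x$terms_removed))
    cat("  terms removed by selection:", paste(x$terms_removed, collapse = ", "), "\n")
  cat("  smooth EDF:\n")
  print(round(x$term_edf, 2))
  invisible(x)
}

#' Deviance explained by a fitted plot model
#'
#' One minus the ratio of residual to null deviance on the log-flux scale.
#'
#' @param model A fitted [fit_plot_model()] object.
#' @return Fraction in `[0, 1]`.
#' @export
deviance_explained <- function(model) {
  stopifnot(inherits(model, "plot_model"))
  model$deviance_explained
}

# build a prediction frame: transform, clamp to training range, fill factors
pm_newdata <- function(model, records, clamp_range = TRUE, use_ids = FALSE) {
  cfg <- model$config
  rec <- as.data.frame(records)
  miss <- setdiff(c(cfg$smooth_terms, cfg$categorical_terms), names(rec))
  if (length(miss)) stop_domain("records missing columns: %s", paste(miss, collapse = ", "))
  n_clamped <- 0L
  for (cv in cfg$smooth_terms) {
    x <- rec[[cv]]
    r <- model$covariate_ranges[[cv]]
    if (clamp_range) {
      out <- x < r[1] | x > r[2]
      n_clamped <- n_clamped + sum(out)
      x <- clamp(x, r[1], r[2])
    }
    rec[[pm_var(cv)]] <- pm_transform(cv, x)
  }
  for (cv in cfg$categorical_terms) {
    lv <- model$categorical_levels[[cv]]
    bad <- setdiff(unique(as.character(rec[[cv]])), lv)
    if (length(bad))
      stop_domain("unknown %s level(s): %s", cv, paste(bad, collapse = ", "))
    rec[[cv]] <- factor(as.character(rec[[cv]]), levels = lv)
  }
  if (!is.null(model$re_levels)) {
    for (id in c("wetland_id", "chamber_id")) {
      lv <- model$re_levels[[id]]
      if (!use_ids || !id %in% names(rec)) rec[[id]] <- lv[1]
      rec[[id]] <- factor(as.character(rec[[id]]), levels = lv)
      if (anyNA(rec[[id]])) stop_domain("unknown %s level in records", id)
    }
  }
  attr(rec, "n_clamped") <- n_clamped
  rec
}

#' Predict plot-scale fluxes
#'
#' Predictions are strictly positive (exponential of the fitted log-scale
#' mean). Covariates beyond the training range are clamped to the range
#' boundary (smooths are held at their boundary values) and the number of
#' clamped values is reported via `message()` and the `extrapolated`
#' attribute — extrapolation is flagged, not refused.
#'
#' @param model A fitted [fit_plot_model()] object.
#' @param records Covariate table.
#' @param include_random If `FALSE` (default), population-level predictions:
#'   random-effect terms are excluded. If `TRUE`, `records` must carry known
#'   `wetland_id`/`chamber_id` levels.
#' @param level Confidence level for the pointwise interval.
#' @return Data frame with `flux`, `lwr`, `upr` (mg m^-2 h^-1).
#' @export
predict_plot_flux <- function(model, records, include_random = FALSE,
                              level = 0.95) {
  stopifnot(inherits(model, "plot_model"))
  nd <- pm_newdata(model, records, use_ids = include_random)
  if (attr(nd, "n_clamped") > 0)
    message(sprintf("%d covariate value(s) beyond the training range were clamped",
                    attr(nd, "n_clamped")))
  excl <- if (!include_random && !is.null(model$re_levels))
    c("s(wetland_id)", "s(chamber_id)") else NULL
  pr <- mgcv::predict.bam(model$fit, newdata = nd, se.fit = TRUE,
                          exclude = excl, discrete = FALSE,
                          newdata.guaranteed = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(flux = exp(as.numeric(pr$fit)),
                    lwr = exp(as.numeric(pr$fit) - z * as.numeric(pr$se.fit)),
                    upr = exp(as.numeric(pr$fit) + z * as.numeric(pr$se.fit)))
  attr(out, "extrapolated") <- attr(nd, "n_clamped")
  out
}

#' Partial effect of a smooth term
#'
#' Centered effect of one smooth covariate on the log-flux scale over an
#' evaluation grid, with a pointwise confidence interval from the coefficient
#' covariance. mgcv smooths carry sum-to-zero constraints over the training
#' covariate distribution, so the effect is centered by construction.
#'
#' @param model A fitted [fit_plot_model()] object.
#' @param covariate Name of a fitted smooth term.
#' @param grid Evaluation values (native units); default is an equally spaced
#'   grid of 100 points across the training range.
#' @param level Confidence level.
#' @return Data frame of class `partial_effect` with columns `covariate`,
#'   `grid`, `effect`, `lwr`, `upr` (log-flux scale).
#' @export
partial_effect <- function(model, covariate, grid = NULL, level = 0.95) {
  stopifnot(inherits(model, "plot_model"))
  if (!covariate %in% model$config$smooth_terms)
    stop_domain("`%s` is not a fitted smooth term", covariate)
  if (covariate %in% model$terms_removed)
    stop_domain("`%s` was removed by the selection penalty", covariate)
  r <- model$covariate_ranges[[covariate]]
  if (is.null(grid)) grid <- seq(r[1], r[2], length.out = 100)
  if (any(grid < r[1] - 1e-9) || any(grid > r[2] + 1e-9))
    stop_domain("grid extends beyond the training range [%g, %g]", r[1], r[2])

  base <- lapply(model$config$smooth_terms, function(cv) mean(model$covariate_ranges[[cv]]))
  names(base) <- model$config$smooth_terms
  nd <- as.data.frame(base)[rep(1, length(grid)), , drop = FALSE]
  nd[[covariate]] <- grid
  for (cv in model$config$categorical_terms)
    nd[[cv]] <- model$categorical_levels[[cv]][1]
  nd <- pm_newdata(model, nd, clamp_range = FALSE)

  label <- sprintf("s(%s)", pm_var(covariate))
  pr <- mgcv::predict.bam(model$fit, newdata = nd, type = "terms",
                          terms = label, se.fit = TRUE, discrete = FALSE,
                          newdata.guaranteed = TRUE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  eff <- as.numeric(pr$fit[, label])
  se <- as.numeric(pr$se.fit[, label])
  structure(data.frame(covariate = covariate, grid = grid, effect = eff,
                       lwr = eff - z * se, upr = eff + z * se),
            class = c("partial_effect", "data.frame"))
}
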
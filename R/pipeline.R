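#' End-to-end pipeline configuration
#'
#' All randomness in the pipeline flows from `seed`: each stage derives its
#' own sub-seed from it, so a rerun with the same config reproduces every
#' numeric output.
#'
#' @param seed Global integer seed.
#' @param chamber A [chamber_config()] for the plot-scale training data; its
#'   seed is overridden by the derived stage seed.
#' @param landscape A [landscape_config()] for the wet-bookend landscape;
#'   seed overridden likewise. The dry bookend reuses the same landscape with
#'   `dry_wetness` applied, so dry wet-extents are subsets of wet ones.
#' @param dry_wetness Wetted-fraction multiplier for the dry bookend.
#' @param n_members Ensemble members per warming pathway.
#' @param moderate_warming,severe_warming Pathway mean warmings (degC).
#' @param moderate_season,severe_season Future frost-free-season lengths
#'   (days) for the two pathways.
#' @param plot_config A [plot_model_config()].
#' @param forest_config An [ensemble_config()]; seed overridden.
#' @param dry_wfps Dry-pixel WFPS surrogate (%).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            chamber = chamber_config(n_wetlands = 60,
                                                     chambers_per_wetland = 4,
                                                     years = 3),
                            landscape = landscape_config(nrow = 128, ncol = 128,
                                                         n_wetlands = 200,
                                                         max_retries = 500),
                            dry_wetness = 0.55,
                            n_members = 13,
                            moderate_warming = 1.7, severe_warming = 2.7,
                            moderate_season = 323, severe_season = 337,
                            plot_config = plot_model_config(),
                            forest_config = ensemble_config(),
                            dry_wfps = 50) {
  stopifnot(inherits(chamber, "chamber_config"),
            inherits(landscape, "landscape_config"),
            inherits(plot_config, "plot_model_config"),
            inherits(forest_config, "ensemble_config"))
  if (dry_wetness <= 0 || dry_wetness > 1) stop_domain("dry_wetness must be in (0, 1]")
  structure(list(seed = as.integer(seed), chamber = chamber,
                 landscape = landscape, dry_wetness = dry_wetness,
                 n_members = as.integer(n_members),
                 moderate_warming = moderate_warming,
                 severe_warming = severe_warming,
                 moderate_season = moderate_season,
                 severe_season = severe_season,
                 plot_config = plot_config, forest_config = forest_config,
                 dry_wfps = dry_wfps),
            class = "pipeline_config")
}

#' Run the chamber-to-landscape-to-scenario pipeline
#'
#' Executes, in order: synthetic chamber simulation; Q10 estimation from the
#' simulated fluxes; plot-scale additive model fit; wet- and dry-bookend
#' landscape simulation (same landscape, reduced wetness for the dry year);
#' tree-ensemble fit on the chamber rows; per-pixel prediction, annual
#' integration and regional/size-class summaries for both bookends; and the
#' four warming-by-extent scenario ensembles with fold changes against the
#' historical bookend mean.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, summaries, size-class
#'   tables, and the manifest are written there as CSV/JSON.
#' @param quiet Suppress per-stage messages.
#' @return A list of class `pipeline_result`: `chamber`, `q10`, `plot_model`,
#'   `landscape` (wet/dry `wetlandscape`s), `forest`, `historical`
#'   (summaries + size-class tables per bookend), `scenarios` (list of
#'   `scenario_result`), `fold_changes`, and `manifest` (stage seeds,
#'   runtimes, artifact hashes).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- Sys.time()
  stage_times <- c()
  say <- function(...) if (!quiet) message(sprintf(...))
  timed <- function(name, expr) {
    t0 <- Sys.time()
    v <- force(expr)
    stage_times[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    v
  }

  # 1. simulate chambers
  ch_cfg <- config$chamber
  ch_cfg$seed <- derive_seed(config$seed, 1L)
  say("stage simulate-chambers (seed %d)", ch_cfg$seed)
  chamber <- timed("simulate_chambers", generate_chamber_dataset(ch_cfg))
  obs <- chamber$observations

  # 2. flux-derived temperature sensitivity
  say("stage q10")
  q10 <- timed("q10", {
    sat <- obs[obs$wfps >= 99, ]
    list(all = compute_q10(obs$soil_temp, obs$flux, "all"),
         saturated = if (nrow(sat) >= 50)
           compute_q10(sat$soil_temp, sat$flux, "all") else NULL)
  })

  # 3. plot-scale additive model
  say("stage fit-plot")
  plot_model <- timed("fit_plot", suppressMessages(
    fit_plot_model(obs, config$plot_config)))

  # 4. landscapes: wet bookend, then the same landscape drier
  ls_wet_cfg <- config$landscape
  ls_wet_cfg$seed <- derive_seed(config$seed, 2L)
  ls_dry_cfg <- ls_wet_cfg
  ls_dry_cfg$wetness <- ls_wet_cfg$wetness * config$dry_wetness
  say("stage simulate-landscape (seed %d)", ls_wet_cfg$seed)
  land_wet <- timed("simulate_landscape_wet", generate_wetlandscape(ls_wet_cfg))
  land_dry <- timed("simulate_landscape_dry", generate_wetlandscape(ls_dry_cfg))
  stacks <- list(wet = land_wet$rasters, dry = land_dry$rasters)

  # 5. landscape ensemble model trained on chamber rows
  fo_cfg <- config$forest_config
  fo_cfg$seed <- derive_seed(config$seed, 3L)
  say("stage fit-landscape (seed %d)", fo_cfg$seed)
  forest <- timed("fit_landscape", fit_landscape_model(obs, fo_cfg))

  # 6. historical upscaling per bookend
  say("stage upscale")
  historical <- timed("upscale", {
    lapply(stacks, function(st) {
      wl <- delineate_wetlands(st)
      pred <- derive_predictor_stack(st, wl, dry_wfps = config$dry_wfps)
      fx <- predict_pixel_flux(forest, pred)
      annual <- integrate_annual(fx, st)
      list(summary = summarize_region(annual, fx, wl, st),
           size_classes = size_class_decomposition(annual, wl),
           wetlands = wl)
    })
  })
  hist_totals <- vapply(historical, function(h) h$summary$total_emission_Gg,
                        numeric(1))

  # 7. scenarios: {moderate, severe} x {dry, wet}
  say("stage scenario")
  scen <- timed("scenario", {
    mk <- function(pathway, warming, season, offset) {
      members <- make_ensemble_members(
        n = config$n_members, mean_warming = warming,
        window_length = season,
        historical_length = stacks$wet$window$length,
        seed = derive_seed(config$seed, offset))
      lapply(c("dry", "wet"), function(bk)
        scenario_spec(sprintf("%s_%s", pathway, bk), extent_bookend = bk,
                      pathway = pathway, members = members))
    }
    specs <- c(mk("moderate", config$moderate_warming, config$moderate_season, 4L),
               mk("severe", config$severe_warming, config$severe_season, 5L))
    run_ensemble(forest, stacks, specs, dry_wfps = config$dry_wfps)
  })
  names(scen) <- vapply(scen, function(s) s$spec$id, character(1))

  fold_changes <- list(
    moderate = fold_change(scen[c("moderate_dry", "moderate_wet")], hist_totals),
    severe = fold_change(scen[c("severe_dry", "severe_wet")], hist_totals))

  manifest <- list(
    package_version = as.character(utils::packageVersion("prairieCH4")),
    seed = config$seed,
    stage_seeds = list(chambers = ch_cfg$seed, landscape = ls_wet_cfg$seed,
                       forest = fo_cfg$seed),
    stage_runtimes_s = as.list(stage_times),
    n_chamber_rows = nrow(obs),
    n_wetlands_wet = nrow(historical$wet$wetlands$table),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    total_runtime_s = round(as.numeric(Sys.time() - t_all, units = "secs"), 2)
  )

  result <- structure(list(chamber = chamber, q10 = q10,
                           plot_model = plot_model,
                           landscape = list(wet = land_wet, dry = land_dry),
                           forest = forest, historical = historical,
                           scenarios = scen, fold_changes = fold_changes,
                           manifest = manifest),
                      class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      historical_summaries = file.path(out_dir, "historical_summaries.csv"),
      size_classes_wet = file.path(out_dir, "size_classes_wet.csv"),
      scenario_members = file.path(out_dir, "scenario_member_summaries.csv"))
    utils::write.csv(do.call(rbind, lapply(historical, `[[`, "summary")),
                     paths["historical_summaries"], row.names = FALSE)
    utils::write.csv(historical$wet$size_classes, paths["size_classes_wet"],
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, lapply(scen, `[[`, "member_summaries")),
                     paths["scenario_members"], row.names = FALSE)
    manifest$artifacts <- lapply(as.list(paths), function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("prairieCH4 pipeline result\n")
  cat(sprintf("  chamber rows: %d; plot-model deviance explained: %.1f%%\n",
              nrow(x$chamber$observations), 100 * deviance_explained(x$plot_model)))
  cat(sprintf("  forest OOB variance explained: %.1f%%\n",
              100 * x$forest$oob_variance_explained))
  h <- vapply(x$historical, function(h) h$summary$total_emission_Gg, numeric(1))
  cat(sprintf("  historical totals (Gg): dry %.4f, wet %.4f\n", h["dry"], h["wet"]))
  cat(sprintf("  fold change: moderate %.2f, severe %.2f\n",
              x$fold_changes$moderate$fold, x$fold_changes$severe$fold))
  invisible(x)
}
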
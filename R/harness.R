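#' Experiment run configuration
#'
#' One declarative object holding every knob of an experiment: trial design,
#' scene archetypes, per-layer threshold parameters, calibration
#' hyperparameters, input regime and seeds. No hidden defaults exist outside
#' it — the constructor materialises all defaults so the stored config is a
#' complete audit trail. `read_run_config()` loads the same structure from a
#' YAML file.
#'
#' @param regime input regime: `"stream"` (activation-space synthetic
#'   streams; default), or the pixel-space regimes `"full_frame"`, `"gaze"`,
#'   `"shuffled"`, `"pixel_baseline"` driven by synthetic video.
#' @param durations,repetitions,scene_types trial design, see
#'   [trial_design()].
#' @param scenes named list of [scene_spec()].
#' @param params named list of [threshold_params()] per layer.
#' @param calibration a [calibration_spec()].
#' @param attention_C global attention factor applied to the thresholds.
#' @param noiseless run zero-noise threshold dynamics.
#' @param static_threshold use the constant-threshold control variant.
#' @param frame_rate frames per second.
#' @param frame_size `c(height, width)` for synthetic video regimes.
#' @param crop_full,crop_gaze patch sizes (px) for the centre-crop and
#'   gaze-patch regimes; defaults scale the 720/400 px patches of a
#'   1280 x 720 source down to the synthetic frame.
#' @param seed master integer seed; all per-trial streams derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(regime = "stream",
                       durations = standard_durations(),
                       repetitions = 20,
                       scene_types = c("city", "campus_outside",
                                       "office_cafe"),
                       scenes = default_scenes(),
                       params = default_threshold_params(),
                       calibration = calibration_spec(),
                       attention_C = 1,
                       noiseless = FALSE,
                       static_threshold = FALSE,
                       frame_rate = 30,
                       frame_size = c(64, 64),
                       crop_full = NULL,
                       crop_gaze = NULL,
                       seed = 1L) {
  regime <- match.arg(regime, c("stream", "full_frame", "gaze", "shuffled",
                                "pixel_baseline"))
  # default patches keep the reference area ratios: 0.75^2 = 56% of a square
  # frame for the full-frame patch, a half-width patch for the gaze spotlight
  if (is.null(crop_full)) crop_full <- round(min(frame_size) * 0.75)
  if (is.null(crop_gaze)) crop_gaze <- round(min(frame_size) * 0.5)
  if (static_threshold)
    params <- lapply(params, function(p) { p$static_mode <- TRUE; p })
  cfg <- list(regime = regime, durations = durations,
              repetitions = repetitions, scene_types = scene_types,
              scenes = scenes, params = params, calibration = calibration,
              attention_C = attention_C, noiseless = noiseless,
              static_threshold = static_threshold, frame_rate = frame_rate,
              frame_size = frame_size, crop_full = crop_full[1],
              crop_gaze = crop_gaze[1], seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file; top-level keys mirror the `run_config()`
#'   arguments, with `scenes` as `name: {change_rate, noise_floor}` maps and
#'   `params` as `layer: {T_max, T_min, tau, alpha}` maps.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("scenes", "params", "calibration"))]
  if (!is.null(y$scenes))
    args$scenes <- stats::setNames(lapply(names(y$scenes), function(nm)
      do.call(scene_spec, c(list(scene_type = nm), y$scenes[[nm]]))),
      names(y$scenes))
  if (!is.null(y$params))
    args$params <- lapply(y$params, function(p) do.call(threshold_params, p))
  if (!is.null(y$calibration))
    args$calibration <- do.call(calibration_spec, y$calibration)
  do.call(run_config, args)
}

# distance streams for a config: either direct synthetic streams or
# synthetic video passed through the configured gating + extractor
config_streams <- function(config, design) {
  if (config$regime == "stream")
    return(synth_streams(design, config$scenes, config$params,
                         config$frame_rate, config$seed))
  videos <- lapply(seq_len(nrow(design)), function(i)
    synth_video(design$duration_s[i],
                config$scenes[[design$scene_type[i]]],
                config$frame_size, config$frame_rate,
                seed = trial_seed(config$seed, design$trial_id[i]),
                trial_id = design$trial_id[i]))
  names(videos) <- design$trial_id
  gated <- switch(config$regime,
    full_frame = , pixel_baseline = lapply(videos, centre_crop,
                                           width = config$crop_full,
                                           height = config$crop_full),
    gaze = lapply(videos, function(v)
      gaze_crop(v, synth_gaze(v, "tracking_object"),
                width = config$crop_gaze, height = config$crop_gaze)),
    shuffled = {
      donors <- shuffle_gaze(design$trial_id, config$seed)
      traces <- lapply(videos, synth_gaze, mode = "tracking_object")
      lapply(design$trial_id, function(id)
        gaze_crop(videos[[id]], traces[[donors[[id]]]],
                  width = config$crop_gaze, height = config$crop_gaze))
    })
  names(gated) <- design$trial_id
  if (config$regime == "pixel_baseline")
    return(lapply(gated, pixel_change_series))
  # project gated pixels through a seeded random hierarchy sized to the
  # configured layers' relative widths, at desk scale
  layers <- layer_spec(names(config$params),
                       pmax(8L, 2L^(seq_along(config$params) + 3L)))
  patch <- if (config$regime == "full_frame") config$crop_full else
    config$crop_gaze
  extractor <- random_projection_extractor(config$seed, c(patch, patch),
                                           layers)
  lapply(gated, function(fr) layer_distances(
    extract_activations(fr, extractor)))
}

# threshold params a pixel-baseline stream needs: scale-free, derived from
# the observed distance range of the run itself
pixel_params <- function(streams, template = default_threshold_params()[[1]]) {
  all_d <- unlist(lapply(streams, function(s) s$pixels))
  hi <- stats::quantile(all_d, 0.95, names = FALSE)
  if (hi <= 0) hi <- 1
  list(pixels = threshold_params(T_max = hi, T_min = hi * 0.29,
                                 tau = template$tau, alpha = template$alpha,
                                 attention_C = template$attention_C,
                                 static_mode = template$static_mode))
}

#' Run a full experiment
#'
#' Orchestrates the pipeline end to end for one configuration: generate (or
#' gate and featurise) the inputs, detect and accumulate salient changes,
#' calibrate counts to seconds under cross-validation, and compute the
#' summary metrics. Fully reproducible from `(config, seed)`.
#'
#' @param config a [run_config()].
#' @return A `results bundle` (list): `design`, `accumulators`, `curves`
#'   (per-timestep cumulative counts), `estimates` (out-of-fold
#'   `estimate_set`), `metrics` (NME, RMSE, scene bias, variance by
#'   duration), `manifest` (config echo + hash) and `config`.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  design <- trial_design(config$durations, config$repetitions,
                         config$scene_types, config$seed)
  streams <- config_streams(config, design)
  params <- if (config$regime == "pixel_baseline")
    pixel_params(streams) else config$params
  params <- scale_attention(params, config$attention_C)
  acc <- run_accumulators(streams, params, design, seed = config$seed,
                          noiseless = config$noiseless, keep_curves = TRUE)
  estimates <- calibrate_durations(acc, config$calibration,
                                   regime = config$regime)
  metrics <- list(nme = compute_nme(estimates),
                  rmse_vs_truth = compute_rmse(estimates),
                  scene_bias = scene_bias(estimates),
                  variance = variance_by_duration(estimates))
  list(design = design, accumulators = acc,
       curves = attr(acc, "curves"), estimates = estimates,
       metrics = metrics, manifest = run_manifest(config), config = config)
}

#' Attention sweep
#'
#' Repeats change detection over a list of attention factors `C` on shared
#' input streams with shared per-trial seeds, converting counts to seconds
#' with the calibration fixed at the reference condition `C = 1` (fitted
#' out-of-fold once and then applied unchanged). Holding the mapping fixed
#' is what lets attention shift the estimates: raised thresholds register
#' fewer changes and produce shorter estimates, lowered thresholds the
#' opposite.
#'
#' @param config a [run_config()] (its `attention_C` is ignored; the
#'   reference condition is `C = 1`).
#' @param C_values at least two positive attention factors.
#' @return List: `estimates` (one `estimate_set` per C, named),
#'   `per_duration` (data frame `attention_C`, `duration_s`, `mean_est`),
#'   `mean_by_C` (data frame `attention_C`, `mean_est`, `slope_loglog`).
#' @export
attention_sweep <- function(config = run_config(),
                            C_values = c(0.5, 1, 2)) {
  if (length(C_values) < 2) stopf("need >= 2 attention factors")
  if (any(C_values <= 0)) stopf("attention factors must be > 0")
  design <- trial_design(config$durations, config$repetitions,
                         config$scene_types, config$seed)
  streams <- config_streams(config, design)
  base_params <- if (config$regime == "pixel_baseline")
    pixel_params(streams) else config$params
  acc_ref <- run_accumulators(streams, base_params, design,
                              seed = config$seed,
                              noiseless = config$noiseless)
  calib <- calibrate_durations(acc_ref, config$calibration,
                               regime = config$regime)
  estimates <- lapply(C_values, function(C) {
    if (C == 1) return(calib)
    acc_c <- run_accumulators(streams, scale_attention(base_params, C),
                              design, seed = config$seed,
                              noiseless = config$noiseless)
    predict_durations(calib, acc_c, regime = config$regime)
  })
  names(estimates) <- paste0("C_", C_values)
  per_duration <- do.call(rbind, lapply(seq_along(C_values), function(i) {
    agg <- aggregate(estimates[[i]]$predicted_s,
                     list(duration_s = estimates[[i]]$true_s), mean)
    data.frame(attention_C = C_values[i], duration_s = agg$duration_s,
               mean_est = agg$x)
  }))
  mean_by_C <- do.call(rbind, lapply(seq_along(C_values), function(i) {
    pd <- per_duration[per_duration$attention_C == C_values[i], ]
    data.frame(attention_C = C_values[i],
               mean_est = mean(estimates[[i]]$predicted_s),
               slope_loglog = unname(coef(
                 lm(log(pmax(pd$mean_est, 1e-9)) ~ log(pd$duration_s)))[2]))
  }))
  list(estimates = estimates, per_duration = per_duration,
       mean_by_C = mean_by_C)
}

run_manifest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_as_list(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  list(package = "perceptime",
       version = as.character(utils::packageVersion("perceptime")),
       r_version = as.character(getRversion()),
       seed = config$seed,
       config = config_as_list(config),
       config_hash = unname(tools::md5sum(tmp)))
}

# strip all S3 classes recursively so the config serialises as plain JSON
config_as_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}

#' Export a results bundle to disk
#'
#' Writes `estimates.csv`, `accumulators.csv`, `curves.csv`, `metrics.json`
#' and `manifest.json` under `dir`.
#'
#' @param bundle result of [run_experiment()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(estimates = file.path(dir, "estimates.csv"),
             accumulators = file.path(dir, "accumulators.csv"),
             curves = file.path(dir, "curves.csv"),
             metrics = file.path(dir, "metrics.json"),
             manifest = file.path(dir, "manifest.json"))
  write.csv(as.data.frame(bundle$estimates), paths["estimates"],
            row.names = FALSE)
  write.csv(as.data.frame(bundle$accumulators), paths["accumulators"],
            row.names = FALSE)
  write.csv(bundle$curves, paths["curves"], row.names = FALSE)
  m <- bundle$metrics
  jsonlite::write_json(
    list(nme_per_duration = m$nme$per_duration,
         nme_overall = m$nme$overall,
         rmse_vs_truth = m$rmse_vs_truth,
         scene_deviations = m$scene_bias$per_scene,
         scene_ordering = m$scene_bias$ordering,
         sd_per_duration = m$variance$per_duration,
         sd_vs_mean_slope = m$variance$slope),
    paths["metrics"], auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(bundle$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
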
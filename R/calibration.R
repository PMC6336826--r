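#' Calibration specification for the counts-to-seconds regression
#'
#' Accumulated salient-change counts are abstract duration units; an epsilon
#' support vector regression (RBF kernel) maps the per-layer count vector of
#' each trial to seconds. The regression is trained on the *physical*
#' durations of the trials, never on reported estimates. Defaults follow the
#' reference configuration: kernel coefficient (gamma) `1e-4`, error penalty
#' (cost) `1e-3`, 10-fold cross-validation. The insensitivity width
#' `epsilon` defaults to the common library default 0.1. Features enter
#' unstandardised by default; `standardize = TRUE` is available for
#' sensitivity analysis.
#'
#' @param gamma RBF kernel coefficient.
#' @param cost penalty parameter for the error term.
#' @param epsilon insensitivity width of the epsilon-SVR loss.
#' @param n_folds number of cross-validation folds (>= 2). Folds are
#'   stratified by duration level: every fold sees (as nearly as possible)
#'   the same mix of durations, which keeps the weakly regularised SVR's
#'   intercept stable across folds.
#' @param fold_seed integer seed controlling the fold partition.
#' @param standardize standardise feature columns before fitting.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(gamma = 1e-4, cost = 1e-3, epsilon = 0.1,
                             n_folds = 10, fold_seed = 1L,
                             standardize = FALSE) {
  check_scalar_num(gamma, "gamma", positive = TRUE)
  check_scalar_num(cost, "cost", positive = TRUE)
  check_scalar_num(epsilon, "epsilon", positive = TRUE)
  if (n_folds < 2) stopf("`n_folds` must be >= 2")
  structure(list(gamma = gamma, cost = cost, epsilon = epsilon,
                 n_folds = as.integer(n_folds),
                 fold_seed = as.integer(fold_seed),
                 standardize = isTRUE(standardize)),
            class = "calibration_spec")
}

# Seeded fold assignment, stratified by duration level: each level's trials
# spread as evenly as possible over folds, remainders rotated across levels
# so overall fold sizes still differ by at most 1. Stratification keeps the
# training sets compositionally alike across folds, which matters for a
# weakly regularised SVR whose intercept is sensitive to fold composition.
assign_folds <- function(y, n_folds, fold_seed) {
  n <- length(y)
  fold <- integer(n)
  with_seed(fold_seed, {
    offset <- 0L
    for (lev in sample(unique(y))) {
      idx <- which(y == lev)
      m <- length(idx)
      f <- (offset + seq_len(m) - 1L) %% n_folds + 1L
      fold[idx] <- sample(f)
      offset <- (offset + m) %% n_folds
    }
  })
  fold
}

fit_svr <- function(X, y, spec) {
  if (var(y) == 0)
    warnf("constant training targets; predictions will sit at that constant")
  e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
             gamma = spec$gamma, cost = spec$cost, epsilon = spec$epsilon,
             scale = spec$standardize)
}

#' Calibrate accumulated counts to seconds under cross-validation
#'
#' Fits the epsilon-SVR counts-to-seconds mapping with k-fold
#' cross-validation: each fold's trials are predicted by a model trained on
#' the other folds only, so every trial receives exactly one out-of-fold
#' prediction. All scene types are pooled into a single regression — the
#' mapping is never fit per scene, so scene-wise estimate differences
#' reflect differences in accumulated perceptual change only.
#'
#' Optionally the training set (but not the predicted set) is restricted to
#' a duration subset via `train_durations`, which reproduces block-range
#' regression effects: predictions for durations outside the trained range
#' are pulled toward it.
#'
#' @param acc an `accumulator_set` from [run_accumulators()] carrying
#'   `duration_s` (and `scene_type`), or a wide data frame from
#'   [accumulator_matrix()].
#' @param spec a [calibration_spec()].
#' @param regime label recorded with the estimates (e.g. `"full_frame"`,
#'   `"gaze"`, `"shuffled"`, `"pixel_baseline"`, `"stream"`).
#' @param train_durations optional numeric vector; only trials with these
#'   true durations are used for training (all trials are still predicted).
#' @return An `estimate_set` data frame: `trial_id`, `regime`, `scene_type`,
#'   `true_s`, `predicted_s`, `predicted_clamped_s` (negatives clamped at
#'   0), `fold`. The fitted fold models and feature layout are attached as
#'   attributes `models`, `feature_names` and `spec` so the calibration can
#'   be re-applied to other counts via [predict_durations()].
#' @export
calibrate_durations <- function(acc, spec = calibration_spec(),
                                regime = "stream", train_durations = NULL) {
  wide <- if ("layer" %in% names(acc)) accumulator_matrix(acc) else acc
  if (!"duration_s" %in% names(wide))
    stopf("accumulators carry no `duration_s`; pass a design to run_accumulators()")
  n <- nrow(wide)
  if (n < spec$n_folds)
    stopf("%d trials but %d folds requested", n, spec$n_folds)
  feat_cols <- grep("^count_", names(wide), value = TRUE)
  X <- as.matrix(wide[, feat_cols, drop = FALSE])
  y <- wide$duration_s
  # partition over trial ids, not row order, so estimates are invariant to
  # the ordering of the input rows; stratified by duration level
  ord <- order(wide$trial_id)
  fold <- integer(n)
  fold[ord] <- assign_folds(y[ord], spec$n_folds, spec$fold_seed)
  trainable <- if (is.null(train_durations)) rep(TRUE, n) else
    y %in% train_durations
  if (!any(trainable)) stopf("`train_durations` excludes every trial")
  models <- vector("list", spec$n_folds)
  pred <- numeric(n)
  for (k in seq_len(spec$n_folds)) {
    tr <- fold != k & trainable
    if (!any(tr)) stopf("fold %d has an empty training set", k)
    models[[k]] <- fit_svr(X[tr, , drop = FALSE], y[tr], spec)
    te <- fold == k
    pred[te] <- predict(models[[k]], X[te, , drop = FALSE])
  }
  est <- data.frame(
    trial_id = wide$trial_id, regime = regime,
    scene_type = if ("scene_type" %in% names(wide)) wide$scene_type else
      NA_character_,
    true_s = y, predicted_s = pred, predicted_clamped_s = pmax(pred, 0),
    fold = fold, stringsAsFactors = FALSE)
  structure(est, class = c("estimate_set", "data.frame"),
            models = models, feature_names = feat_cols, spec = spec)
}

#' Apply a fitted calibration to new counts
#'
#' Predicts durations for new accumulator counts using the fold models of an
#' existing calibration: each trial is predicted by the model of its own
#' fold, i.e. by a model that never saw that trial during training. This is
#' how attention-modulated counts are converted to seconds with the mapping
#' held fixed at the reference condition.
#'
#' @param calibration an `estimate_set` from [calibrate_durations()].
#' @param acc accumulators for the same trials (long or wide form).
#' @param regime label for the returned estimates.
#' @return An `estimate_set` for the new counts (no attached models).
#' @export
predict_durations <- function(calibration, acc, regime = "stream") {
  models <- attr(calibration, "models")
  feat_cols <- attr(calibration, "feature_names")
  if (is.null(models)) stopf("`calibration` carries no fitted models")
  wide <- if ("layer" %in% names(acc)) accumulator_matrix(acc) else acc
  idx <- match(wide$trial_id, calibration$trial_id)
  if (any(is.na(idx)))
    stopf("counts contain trial ids absent from the calibration")
  X <- as.matrix(wide[, feat_cols, drop = FALSE])
  fold <- calibration$fold[idx]
  pred <- numeric(nrow(wide))
  for (k in unique(fold)) {
    sel <- fold == k
    pred[sel] <- predict(models[[k]], X[sel, , drop = FALSE])
  }
  data.frame(
    trial_id = wide$trial_id, regime = regime,
    scene_type = if ("scene_type" %in% names(wide)) wide$scene_type else
      calibration$scene_type[idx],
    true_s = if ("duration_s" %in% names(wide)) wide$duration_s else
      calibration$true_s[idx],
    predicted_s = pred, predicted_clamped_s = pmax(pred, 0),
    fold = fold, stringsAsFactors = FALSE) -> est
  class(est) <- c("estimate_set", "data.frame")
  est
}

#' Normalised mean error of duration estimates
#'
#' Per-trial error is `(predicted - true) / true`. The per-duration NME is
#' the mean of these over the trials of each duration level; the overall
#' NME averages the duration levels with equal weight (not trial-weighted),
#' matching a per-duration summary across the presented durations.
#'
#' @param estimates an `estimate_set`.
#' @return List with `per_duration` (data frame `duration_s`, `nme`, `n`)
#'   and `overall` (scalar).
#' @export
compute_nme <- function(estimates) {
  if (!nrow(estimates)) stopf("empty estimate set")
  if (any(estimates$true_s == 0))
    stopf("zero true duration: normalised error undefined")
  err <- (estimates$predicted_s - estimates$true_s) / estimates$true_s
  per <- aggregate(err, list(duration_s = estimates$true_s), mean)
  names(per)[2] <- "nme"
  per$n <- as.integer(table(estimates$true_s)[as.character(per$duration_s)])
  list(per_duration = per, overall = mean(per$nme))
}

#' Root-mean-squared error of duration estimates
#'
#' RMSE of the out-of-fold predictions against a reference series: the
#' physical durations by default, or an external per-trial reference (e.g.
#' human duration reports for the same trials) supplied as `reference`.
#' Human reports never enter the fitting; they are only ever a comparison
#' series here.
#'
#' @param estimates an `estimate_set`.
#' @param reference optional numeric vector, one value per row of
#'   `estimates`, replacing the physical durations as the comparison series.
#' @return RMSE in seconds.
#' @export
compute_rmse <- function(estimates, reference = NULL) {
  if (!nrow(estimates)) stopf("empty estimate set")
  ref <- if (is.null(reference)) estimates$true_s else reference
  if (length(ref) != nrow(estimates))
    stopf("reference has %d values for %d trials", length(ref),
          nrow(estimates))
  sqrt(mean((estimates$predicted_s - ref)^2))
}

#' Scene-type bias of duration estimates
#'
#' Quantifies content-driven estimation bias: for each duration level, each
#' scene's mean estimate is expressed as a percentage deviation from that
#' duration's grand-mean estimate; a scene's score is the mean of its
#' per-duration deviations (`method = "per_duration"`, default). The pooled
#' alternative compares scene means over all trials at once. Cells with no
#' trials are omitted with a warning.
#'
#' @param estimates an `estimate_set` with scene labels.
#' @param method `"per_duration"` (average of per-duration deviations) or
#'   `"pooled"`.
#' @return List with `per_scene` (data frame `scene_type`,
#'   `deviation_pct`, `n`, ordered by decreasing deviation), `per_cell`
#'   (duration x scene deviations, per_duration method) and `ordering`
#'   (scene labels from most over- to most under-estimated).
#' @export
scene_bias <- function(estimates, method = c("per_duration", "pooled")) {
  method <- match.arg(method)
  if (all(is.na(estimates$scene_type)))
    stopf("estimates carry no scene labels")
  scenes <- unique(estimates$scene_type)
  if (length(scenes) < 2) stopf("need >= 2 scene types")
  if (method == "pooled") {
    grand <- mean(estimates$predicted_s)
    per <- aggregate(estimates$predicted_s,
                     list(scene_type = estimates$scene_type), mean)
    names(per)[2] <- "mean_est"
    per$deviation_pct <- 100 * (per$mean_est - grand) / grand
    cells <- NULL
  } else {
    cells <- do.call(rbind, lapply(split(estimates, estimates$true_s),
                                   function(d) {
      grand <- mean(d$predicted_s)
      sc <- aggregate(d$predicted_s, list(scene_type = d$scene_type), mean)
      names(sc)[2] <- "mean_est"
      absent <- setdiff(scenes, sc$scene_type)
      if (length(absent))
        warnf("no trials for scene(s) %s at duration %g s; cell omitted",
              paste(absent, collapse = ", "), d$true_s[1])
      data.frame(duration_s = d$true_s[1], scene_type = sc$scene_type,
                 deviation_pct = 100 * (sc$mean_est - grand) / grand,
                 stringsAsFactors = FALSE)
    }))
    rownames(cells) <- NULL
    per <- aggregate(cells$deviation_pct,
                     list(scene_type = cells$scene_type), mean)
    names(per)[2] <- "deviation_pct"
  }
  per$n <- as.integer(table(estimates$scene_type)[per$scene_type])
  per <- per[order(-per$deviation_pct), ]
  rownames(per) <- NULL
  list(per_scene = per, per_cell = cells, ordering = per$scene_type)
}

#' Estimate variability by duration (scalar-variability summary)
#'
#' Per-duration mean and standard deviation of the estimates, plus the
#' fitted slope of SD against mean estimate. Under scalar variability
#' (Weber-like timing) the SD grows proportionally with the estimated
#' duration, so the slope approximates the coefficient of variation.
#' Durations with a single trial have no SD and are omitted.
#'
#' @param estimates an `estimate_set`.
#' @return List with `per_duration` (data frame `duration_s`, `mean_est`,
#'   `sd_est`, `n`), `slope`, and `slope_se` from the linear fit of SD on
#'   mean.
#' @export
variance_by_duration <- function(estimates) {
  spl <- split(estimates$predicted_s, estimates$true_s)
  per <- data.frame(
    duration_s = as.numeric(names(spl)),
    mean_est = vapply(spl, mean, 1),
    sd_est = vapply(spl, function(v) if (length(v) > 1) sd(v) else NA_real_,
                    1),
    n = lengths(spl), row.names = NULL)
  per <- per[order(per$duration_s), ]
  keep <- !is.na(per$sd_est)
  if (sum(keep) < 2)
    return(list(per_duration = per, slope = NA_real_, slope_se = NA_real_))
  # under scalar variability the sampling error of each SD estimate scales
  # with the mean, so the line is fit with constant-CV weights
  fit <- lm(sd_est ~ mean_est, data = per[keep, ],
            weights = 1 / per$mean_est[keep]^2)
  list(per_duration = per,
       slope = unname(coef(fit)["mean_est"]),
       slope_se = unname(summary(fit)$coefficients["mean_est", "Std. Error"]))
}
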
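#' Threshold parameters for salient-change detection
#'
#' Each layer carries a dynamic threshold on its activation-change distance.
#' Between crossings the threshold decays from its ceiling `T_max` towards a
#' floor governed by `T_min` with time constant `tau` (timesteps), corrupted
#' each step by zero-mean Gaussian noise of scale `(T_max - T_min) / alpha`.
#' A crossing (distance strictly above the threshold) registers one salient
#' perceptual change — the model's unit of subjective time — and resets the
#' threshold to `T_max`.
#'
#' The noise term is interpreted as a standard deviation by default; set
#' `noise_as_variance = TRUE` to read it as a variance instead (the scale is
#' then its square root). `attention_C` is the global attention factor
#' multiplying both `T_min` and `T_max` (see [scale_attention()]). With
#' `static_mode = TRUE` the threshold is the constant `attention_C * T_max`
#' with no decay and no noise — the static control variant.
#'
#' `default_threshold_params()` returns the standard per-layer table: conv2
#' (340, 100), pool5 (400, 100), fc7 (355, 100) and output (0.55, 0.15),
#' all with `tau = 100` timesteps and `alpha = 50`. The published fc7 row
#' omits one value; `tau = 100` is adopted there, matching every other
#' layer (flagged here so users can override it).
#'
#' @param T_max threshold ceiling (activation-distance units).
#' @param T_min threshold floor parameter; `0 < T_min < T_max`.
#' @param tau decay time constant in timesteps.
#' @param alpha noise divisor (dimensionless).
#' @param attention_C global attention scaling factor, `> 0`.
#' @param static_mode if `TRUE`, constant threshold at `attention_C * T_max`.
#' @param noise_as_variance read `(T_max - T_min)/alpha` as a variance.
#' @param clamp_zero if `TRUE`, noise-driven negative thresholds are clamped
#'   at zero (off by default: the update rule is applied as published).
#' @return `threshold_params()`: a validated parameter object.
#' @export
threshold_params <- function(T_max, T_min, tau, alpha, attention_C = 1,
                             static_mode = FALSE, noise_as_variance = FALSE,
                             clamp_zero = FALSE) {
  check_scalar_num(T_max, "T_max", positive = TRUE)
  check_scalar_num(T_min, "T_min", positive = TRUE)
  check_scalar_num(tau, "tau", positive = TRUE)
  check_scalar_num(alpha, "alpha", positive = TRUE)
  check_scalar_num(attention_C, "attention_C", positive = TRUE)
  if (T_min >= T_max)
    stopf("need 0 < T_min < T_max (got T_min = %g, T_max = %g)", T_min, T_max)
  structure(
    list(T_max = T_max, T_min = T_min, tau = tau, alpha = alpha,
         attention_C = attention_C, static_mode = isTRUE(static_mode),
         noise_as_variance = isTRUE(noise_as_variance),
         clamp_zero = isTRUE(clamp_zero)),
    class = "threshold_params")
}

#' @rdname threshold_params
#' @param ... arguments passed on to every layer's [threshold_params()]
#'   (e.g. `attention_C`, `static_mode`).
#' @export
default_threshold_params <- function(...) {
  list(
    conv2  = threshold_params(T_max = 340,  T_min = 100,  tau = 100,
                              alpha = 50, ...),
    pool5  = threshold_params(T_max = 400,  T_min = 100,  tau = 100,
                              alpha = 50, ...),
    fc7    = threshold_params(T_max = 355,  T_min = 100,  tau = 100,
                              alpha = 50, ...),
    output = threshold_params(T_max = 0.55, T_min = 0.15, tau = 100,
                              alpha = 50, ...))
}

#' @export
print.threshold_params <- function(x, ...) {
  cat(sprintf(
    "<threshold_params> T_max %g, T_min %g, tau %g, alpha %g, C %g%s\n",
    x$T_max, x$T_min, x$tau, x$alpha, x$attention_C,
    if (x$static_mode) " [static]" else ""))
  invisible(x)
}

# attention-scaled ceiling/floor; noise scale derives from their difference
scaled_bounds <- function(params) {
  list(T_max = params$attention_C * params$T_max,
       T_min = params$attention_C * params$T_min)
}

#' Apply attention scaling to threshold parameters
#'
#' Attention is modelled as a single global factor `C > 0` multiplying the
#' threshold ceiling and floor: `T_min <- C * T_min`, `T_max <- C * T_max`.
#' High thresholds (`C > 1`, low attention to change) register fewer salient
#' changes and shorten duration estimates; low thresholds (`C < 1`) register
#' more and lengthen them. The noise scale and decay floor follow, since
#' both derive from `T_max - T_min`.
#'
#' @param params a [threshold_params()] object, or a named list of them.
#' @param C positive scaling factor.
#' @return Parameters with `attention_C` multiplied by `C`.
#' @export
scale_attention <- function(params, C) {
  check_scalar_num(C, "C", positive = TRUE)
  if (is.list(params) && !inherits(params, "threshold_params"))
    return(lapply(params, scale_attention, C = C))
  stopifnot(inherits(params, "threshold_params"))
  params$attention_C <- params$attention_C * C
  params
}

#' One step of the threshold update rule
#'
#' Advances the (attention-scaled) threshold one timestep:
#' `T' = T - ((T_max - T_min)/tau) * exp(-D/tau) + N(0, (T_max - T_min)/alpha)`
#' and increments `D`, the number of timesteps since the last reset. With
#' `noiseless = TRUE` the Gaussian term is dropped exactly (the
#' `alpha -> Inf` limit).
#'
#' @param state list with `T_current` (threshold value) and `D`
#'   (non-negative integer timesteps since reset).
#' @param params a [threshold_params()] object.
#' @param noiseless drop the noise term.
#' @return Updated state list.
#' @export
threshold_step <- function(state, params, noiseless = FALSE) {
  stopifnot(inherits(params, "threshold_params"))
  if (state$D < 0) stopf("D must be >= 0")
  b <- scaled_bounds(params)
  range <- b$T_max - b$T_min
  decr <- (range / params$tau) * exp(-state$D / params$tau)
  noise <- if (noiseless || params$static_mode) 0 else {
    scale <- range / params$alpha
    rnorm(1, 0, if (params$noise_as_variance) sqrt(scale) else scale)
  }
  T_new <- if (params$static_mode) state$T_current else
    state$T_current - decr + noise
  if (params$clamp_zero && T_new < 0) T_new <- 0
  list(T_current = T_new, D = state$D + 1L)
}

#' Asymptotic floor of the noiseless threshold decay
#'
#' Between resets the noiseless threshold follows a geometric series:
#' starting from `T_max`, after `n` steps
#' `T = T_max - (dT/tau) * (1 - exp(-n/tau)) / (1 - exp(-1/tau))` with
#' `dT = T_max - T_min`, which converges to
#' `T_max - dT / (tau * (1 - exp(-1/tau)))`. For the conv2 defaults this
#' floor is about 98.8 — slightly below `T_min`, since `T_min` enters only
#' through the decrement scale.
#'
#' @param params a [threshold_params()] object (attention scaling applies).
#' @return The asymptotic threshold value.
#' @export
threshold_floor <- function(params) {
  stopifnot(inherits(params, "threshold_params"))
  b <- scaled_bounds(params)
  b$T_max - (b$T_max - b$T_min) / (params$tau * (1 - exp(-1 / params$tau)))
}

#' Detect salient perceptual changes in a distance series
#'
#' Runs the dynamic-threshold mechanism over each layer of a
#' [layer_distances()] series. Per timestep the distance is compared with the
#' current threshold first; a strict crossing records an event, resets the
#' threshold to the attention-scaled `T_max` and `D` to 0, and otherwise the
#' threshold advances via the update rule ([threshold_step()]). Thresholds
#' are initialised at the scaled `T_max` with `D = 0`. Deterministic given
#' `seed`.
#'
#' @param distances a `distance_series` (one numeric vector per layer).
#' @param params a named list of [threshold_params()], one per layer of
#'   `distances` (a single object is recycled to all layers).
#' @param seed integer RNG seed for the threshold noise.
#' @param noiseless run the exact zero-noise dynamics.
#' @param keep_trace also return the per-timestep threshold trace.
#' @return An `event_train`: named list (per layer) of strictly increasing
#'   1-based timestep indices; with `keep_trace`, a `trace` attribute holds
#'   the threshold trajectories.
#' @export
detect_salient_events <- function(distances, params, seed = 1L,
                                  noiseless = FALSE, keep_trace = FALSE) {
  if (inherits(params, "threshold_params"))
    params <- stats::setNames(rep(list(params), length(distances)),
                              names(distances))
  missing <- setdiff(names(distances), names(params))
  if (length(missing))
    stopf("no threshold parameters for layer(s): %s",
          paste(missing, collapse = ", "))
  res <- with_seed(as.integer(seed), {
    lapply(names(distances), function(ly) {
      p <- params[[ly]]
      b <- scaled_bounds(p)
      detect_core(as.numeric(distances[[ly]]), b$T_max, b$T_min, p$tau,
                  p$alpha, isTRUE(noiseless), p$static_mode,
                  p$noise_as_variance, p$clamp_zero, isTRUE(keep_trace))
    })
  })
  events <- lapply(res, function(r) as.integer(r$events))
  names(events) <- names(distances)
  out <- structure(events, class = "event_train",
                   trial_id = attr(distances, "trial_id"))
  if (keep_trace) {
    traces <- lapply(res, `[[`, "trace")
    names(traces) <- names(distances)
    attr(out, "trace") <- traces
  }
  out
}

#' Run the accumulators over a set of trials
#'
#' Applies [detect_salient_events()] independently to every trial: thresholds
#' and accumulators are re-initialised per trial and each trial draws its
#' noise from its own RNG stream derived from `seed` and the trial id, so
#' results do not depend on trial order and no state leaks between trials.
#'
#' @param streams named list of `distance_series`, one per trial (names are
#'   trial ids), e.g. from [synth_streams()].
#' @param params named list of [threshold_params()] per layer.
#' @param design optional [trial_design()] data frame supplying
#'   `duration_s` and `scene_type` per trial id.
#' @param seed integer RNG seed.
#' @param noiseless run zero-noise dynamics.
#' @param keep_curves also return cumulative-count-versus-time curves.
#' @return An `accumulator_set`: data frame with columns `trial_id`, `layer`,
#'   `count` (plus `duration_s`, `scene_type` when `design` is given). With
#'   `keep_curves`, a `curves` attribute holds a long data frame
#'   `trial_id, layer, t, cumulative_count`.
#' @export
run_accumulators <- function(streams, params, design = NULL, seed = 1L,
                             noiseless = FALSE, keep_curves = FALSE) {
  stopifnot(is.list(streams), length(streams) >= 1L)
  ids <- names(streams)
  if (is.null(ids)) stopf("`streams` must be a named list (trial ids)")
  rows <- vector("list", length(ids))
  curves <- if (keep_curves) vector("list", length(ids)) else NULL
  for (i in seq_along(ids)) {
    ev <- detect_salient_events(streams[[i]], params,
                                seed = trial_seed(seed, ids[i]),
                                noiseless = noiseless)
    rows[[i]] <- data.frame(trial_id = ids[i], layer = names(ev),
                            count = vapply(ev, length, 1L),
                            stringsAsFactors = FALSE)
    if (keep_curves) {
      n_t <- length(streams[[i]][[1]])
      curves[[i]] <- do.call(rbind, lapply(names(ev), function(ly) {
        cc <- cumsum(tabulate(ev[[ly]], nbins = n_t))
        data.frame(trial_id = ids[i], layer = ly, t = seq_len(n_t),
                   cumulative_count = cc, stringsAsFactors = FALSE)
      }))
    }
  }
  acc <- do.call(rbind, rows)
  rownames(acc) <- NULL
  if (!is.null(design)) {
    meta <- design[match(acc$trial_id, design$trial_id),
                   c("duration_s", "scene_type")]
    acc <- cbind(acc, meta)
    rownames(acc) <- NULL
  }
  class(acc) <- c("accumulator_set", "data.frame")
  if (keep_curves) attr(acc, "curves") <- do.call(rbind, curves)
  acc
}

#' Reshape accumulator counts to one row per trial
#'
#' @param acc an `accumulator_set` from [run_accumulators()].
#' @return Data frame with one row per trial: `trial_id`, optional
#'   `duration_s` / `scene_type`, and one `count_<layer>` column per layer
#'   in a fixed layer order.
#' @export
accumulator_matrix <- function(acc) {
  layers <- unique(acc$layer)
  ids <- unique(acc$trial_id)
  m <- matrix(NA_real_, length(ids), length(layers),
              dimnames = list(ids, paste0("count_", layers)))
  m[cbind(match(acc$trial_id, ids), match(acc$layer, layers))] <- acc$count
  out <- data.frame(trial_id = ids, m, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  for (col in c("duration_s", "scene_type")) {
    if (col %in% names(acc))
      out[[col]] <- acc[[col]][match(ids, acc$trial_id)]
  }
  out
}

#' @rdname run_accumulators
#' @param acc an `accumulator_set`.
#' @param path output CSV path.
#' @export
write_accumulator_csv <- function(acc, path) {
  write.csv(as.data.frame(acc), path, row.names = FALSE)
  invisible(path)
}
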
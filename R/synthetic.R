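#' The standard duration set
#'
#' Thirteen trial durations spanning 1-64 s, log-spaced by roughly powers of
#' two with intermediate values at the short end.
#'
#' @return Numeric vector of 13 durations in seconds.
#' @export
standard_durations <- function() {
  c(1, 1.5, 2, 3, 4, 6, 8, 12, 16, 24, 32, 48, 64)
}

#' Generate a trial design
#'
#' Builds a pseudo-random trial list: every duration appears exactly
#' `repetitions` times, scene types are cycled evenly across the repetitions
#' of each duration, and the order is shuffled deterministically from `seed`.
#' The full-scale design (330 repetitions of the 13 standard durations,
#' 4290 trials) is used for reference experiments; desk-scale runs default
#' to 20 repetitions (260 trials).
#'
#' @param durations vector of trial durations in seconds.
#' @param repetitions repetitions per duration (>= 1).
#' @param scene_types character vector of scene labels to cycle over.
#' @param seed integer RNG seed for the shuffle.
#' @return A `trial_design` data frame: `trial_id`, `duration_s`,
#'   `scene_type`.
#' @export
trial_design <- function(durations = standard_durations(), repetitions = 20,
                         scene_types = c("city", "campus_outside",
                                         "office_cafe"),
                         seed = 1L) {
  if (!length(durations)) stopf("`durations` must be non-empty")
  if (repetitions < 1) stopf("`repetitions` must be >= 1")
  df <- expand.grid(rep = seq_len(repetitions), duration_s = durations,
                    KEEP.OUT.ATTRS = FALSE)
  df$scene_type <- scene_types[(df$rep - 1L) %% length(scene_types) + 1L]
  df <- with_seed(as.integer(seed), df[sample.int(nrow(df)), ])
  df$trial_id <- sprintf("trial_%04d", seq_len(nrow(df)))
  rownames(df) <- NULL
  out <- df[, c("trial_id", "duration_s", "scene_type")]
  class(out) <- c("trial_design", "data.frame")
  out
}

#' Scene archetypes for the synthetic generators
#'
#' A scene specification controls the change statistics of generated input:
#' `change_rate` is the expected rate (Hz) of candidate salient changes
#' (bursts in stream mode; object speed/count scale with it in video mode)
#' and `noise_floor` sets the baseline inter-frame change as a fraction of
#' each layer's `T_min`. `default_scenes()` provides three archetypes with
#' ordered perceptual-change richness, mirroring the busy-city >
#' campus/outside > office/cafe ordering of natural scenes: city scenes
#' (walking through traffic and crowds) change fastest, indoor static
#' viewpoints slowest.
#'
#' @param scene_type label.
#' @param change_rate expected candidate-change rate in Hz (>= 0).
#' @param noise_floor baseline change magnitude as a fraction of `T_min`
#'   (>= 0).
#' @return `scene_spec()`: a list of class `scene_spec`;
#'   `default_scenes()`: a named list of them.
#' @export
scene_spec <- function(scene_type, change_rate, noise_floor = 0.5) {
  check_scalar_num(change_rate, "change_rate")
  check_scalar_num(noise_floor, "noise_floor")
  if (change_rate < 0 || noise_floor < 0)
    stopf("`change_rate` and `noise_floor` must be >= 0")
  structure(list(scene_type = scene_type, change_rate = change_rate,
                 noise_floor = noise_floor),
            class = "scene_spec")
}

#' @rdname scene_spec
#' @export
default_scenes <- function() {
  list(city          = scene_spec("city",          change_rate = 1.2),
       campus_outside = scene_spec("campus_outside", change_rate = 0.7),
       office_cafe   = scene_spec("office_cafe",   change_rate = 0.35))
}

# burst magnitudes span T_min + U(0.3, 1.15) * (T_max - T_min): early in the
# decay (high threshold) many bursts miss, late most hit, so the effective
# event rate reflects both the scene and the threshold dynamics
burst_lo <- 0.3
burst_hi <- 1.15

#' Expected mean of a generated distance stream
#'
#' Closed-form mean of the marginal distance distribution produced by
#' [synth_streams()] for one layer: baseline plus burst occupancy times the
#' mean burst magnitude.
#'
#' @param scene a [scene_spec()].
#' @param params the layer's [threshold_params()].
#' @param frame_rate frames per second.
#' @return Expected per-timestep distance.
#' @export
expected_stream_mean <- function(scene, params, frame_rate = 30) {
  base <- scene$noise_floor * params$T_min
  p_burst <- min(scene$change_rate / frame_rate, 1)
  burst_mean <- params$T_min +
    (burst_lo + burst_hi) / 2 * (params$T_max - params$T_min)
  base + p_burst * burst_mean
}

#' Generate synthetic activation-distance streams
#'
#' Emulates the per-layer Euclidean change series that natural video would
#' drive through a feature hierarchy, without any video or network: each
#' layer's series is a low-amplitude baseline (Gaussian magnitudes around
#' `noise_floor * T_min`) plus sparse bursts (per-frame Bernoulli at
#' `change_rate / frame_rate`) whose magnitudes span the layer's threshold
#' range. Higher `change_rate` therefore yields stochastically larger and
#' more frequent changes — the knob that makes a busy scene "busy". Each
#' trial draws from its own RNG stream derived from `seed` and its trial id.
#'
#' @param design a [trial_design()].
#' @param scenes named list of [scene_spec()] covering every scene in
#'   `design`.
#' @param params named list of [threshold_params()] per layer; the streams
#'   are expressed on each layer's (unscaled, `C = 1`) threshold scale.
#' @param frame_rate frames per second (default 30).
#' @param seed integer RNG seed.
#' @return Named list of `distance_series`, one per trial, each layer of
#'   length `round(duration_s * frame_rate) - 1`.
#' @export
synth_streams <- function(design, scenes = default_scenes(),
                          params = default_threshold_params(),
                          frame_rate = 30, seed = 1L) {
  check_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  missing <- setdiff(unique(design$scene_type), names(scenes))
  if (length(missing))
    stopf("no scene_spec for scene type(s): %s",
          paste(missing, collapse = ", "))
  out <- vector("list", nrow(design))
  names(out) <- design$trial_id
  for (i in seq_len(nrow(design))) {
    sc <- scenes[[design$scene_type[i]]]
    n <- round(design$duration_s[i] * frame_rate) - 1L
    series <- with_seed(trial_seed(seed, design$trial_id[i]), {
      lapply(params, function(p) {
        base_mu <- sc$noise_floor * p$T_min
        base <- abs(rnorm(n, base_mu, 0.25 * base_mu))
        bursts <- runif(n) < sc$change_rate / frame_rate
        mag <- p$T_min + runif(n, burst_lo, burst_hi) * (p$T_max - p$T_min)
        base + ifelse(bursts, mag, 0)
      })
    })
    out[[i]] <- new_distance_series(series, frame_rate,
                                    design$trial_id[i],
                                    design$scene_type[i])
  }
  out
}

#' Generate a synthetic video trial
#'
#' Pixel-space fixture: a constant grey background with moving square
#' objects bouncing off the frame edges. Object count and speed scale with
#' the scene's `change_rate`. Trajectories are attached (attribute
#' `trajectories`: list of `n_frames x 2` matrices of x, y centres) so gaze
#' generators can track an object.
#'
#' @param duration_s trial duration in seconds.
#' @param scene a [scene_spec()]; `change_rate` sets object count/speed.
#' @param frame_size `c(height, width)` in pixels.
#' @param frame_rate frames per second.
#' @param seed integer RNG seed.
#' @param trial_id identifier.
#' @param n_objects,speed_px override the scene-derived object count and
#'   per-frame speed (pixels/frame).
#' @return A [frame_sequence()] with a `trajectories` attribute.
#' @export
synth_video <- function(duration_s, scene = default_scenes()$city,
                        frame_size = c(64, 64), frame_rate = 30, seed = 1L,
                        trial_id = "trial_1",
                        n_objects = NULL, speed_px = NULL) {
  n_frames <- max(1L, round(duration_s * frame_rate))
  h <- frame_size[1]; w <- frame_size[2]
  if (is.null(n_objects)) n_objects <- max(0L, round(scene$change_rate * 2))
  if (is.null(speed_px)) speed_px <- max(0.5, scene$change_rate)
  size <- max(2L, round(min(h, w) / 8))
  state <- with_seed(as.integer(seed), {
    lapply(seq_len(n_objects), function(o) {
      list(x = runif(1, size, w - size), y = runif(1, size, h - size),
           th = runif(1, 0, 2 * pi),
           col = runif(3, 0.1, 1))
    })
  })
  frames <- vector("list", n_frames)
  traj <- lapply(seq_len(n_objects), function(o)
    matrix(NA_real_, n_frames, 2, dimnames = list(NULL, c("x", "y"))))
  for (t in seq_len(n_frames)) {
    f <- array(0.5, dim = c(h, w, 3))
    for (o in seq_along(state)) {
      s <- state[[o]]
      rows <- max(1, round(s$y - size / 2)):min(h, round(s$y + size / 2))
      cols <- max(1, round(s$x - size / 2)):min(w, round(s$x + size / 2))
      for (ch in 1:3) f[rows, cols, ch] <- s$col[ch]
      traj[[o]][t, ] <- c(s$x, s$y)
      # advance with edge bounce
      nx <- s$x + speed_px * cos(s$th)
      ny <- s$y + speed_px * sin(s$th)
      if (nx < size / 2 || nx > w - size / 2) s$th <- pi - s$th
      if (ny < size / 2 || ny > h - size / 2) s$th <- -s$th
      s$x <- s$x + speed_px * cos(s$th)
      s$y <- s$y + speed_px * sin(s$th)
      state[[o]] <- s
    }
    frames[[t]] <- f
  }
  out <- frame_sequence(frames, frame_rate, trial_id, scene$scene_type)
  attr(out, "trajectories") <- traj
  out
}

#' Generate a synthetic gaze trace for a frame sequence
#'
#' Three modes: `centre` fixates the frame centre throughout;
#' `random_walk` performs a reflected Gaussian walk within the frame;
#' `tracking_object` follows the first generated object's trajectory (the
#' sequence must carry a `trajectories` attribute, as [synth_video()]
#' produces).
#'
#' @param frames a [frame_sequence()].
#' @param mode one of `"centre"`, `"tracking_object"`, `"random_walk"`.
#' @param seed integer RNG seed (random_walk mode).
#' @param step_sd random-walk step standard deviation in pixels.
#' @return A [gaze_trace()] with one sample per frame, inside frame bounds.
#' @export
synth_gaze <- function(frames, mode = c("centre", "tracking_object",
                                        "random_walk"),
                       seed = 1L, step_sd = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(frames, "frame_sequence"))
  d <- frame_dims(frames)
  n <- length(frames)
  xy <- switch(mode,
    centre = cbind(rep(d[2] / 2, n), rep(d[1] / 2, n)),
    tracking_object = {
      traj <- attr(frames, "trajectories")
      if (is.null(traj) || !length(traj))
        stopf("frames carry no object trajectories to track")
      traj[[1]]
    },
    random_walk = with_seed(as.integer(seed), {
      x <- numeric(n); y <- numeric(n)
      x[1] <- d[2] / 2; y[1] <- d[1] / 2
      for (t in seq_len(n)[-1]) {
        x[t] <- min(max(x[t - 1] + rnorm(1, 0, step_sd), 1), d[2])
        y[t] <- min(max(y[t - 1] + rnorm(1, 0, step_sd), 1), d[1])
      }
      cbind(x, y)
    }))
  gaze_trace(pmin(pmax(xy[, 1], 1), d[2]), pmin(pmax(xy[, 2], 1), d[1]),
             trial_id = frames$trial_id)
}
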
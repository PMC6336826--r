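# shared fixture builders: everything is generated in code, nothing on disk

# tiny layer hierarchy for the random-projection extractor
small_layers <- function() layer_spec(c("low", "mid", "top"), c(16, 8, 4))

# n identical or per-frame-varying frames of size h x w
make_frames <- function(n, h = 8, w = 8, value = 0.5, frame_rate = 30,
                        trial_id = "t1", scene_type = "synthetic") {
  vals <- if (length(value) == 1) rep(value, n) else value
  frame_sequence(lapply(vals, function(v) array(v, dim = c(h, w, 3))),
                 frame_rate, trial_id, scene_type)
}

random_frames <- function(n, h = 6, w = 6, seed = 42) {
  set.seed(seed)
  frame_sequence(lapply(seq_len(n), function(i)
    array(runif(h * w * 3), dim = c(h, w, 3))), 30, "rnd", "synthetic")
}

# hand-built activation stream: one matrix (timesteps x n) per layer
as_activation_stream <- function(mats, frame_rate = 30, trial_id = "t1") {
  structure(mats, class = "activation_stream", frame_rate = frame_rate,
            trial_id = trial_id, scene_type = "synthetic",
            extractor_id = "handmade")
}

as_distance_series <- function(series, trial_id = "t1") {
  structure(series, class = "distance_series", frame_rate = 30,
            trial_id = trial_id, scene_type = "synthetic")
}

conv2_params <- function(...) threshold_params(340, 100, 100, 50, ...)

# independent pure-R reference for the detection loop (the C++ path's
# oracle); draws noise in the same per-step order
r_detect_oracle <- function(d, p, seed = NULL, noiseless = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  b <- p$attention_C
  t_max <- b * p$T_max; t_min <- b * p$T_min
  sdv <- (t_max - t_min) / p$alpha
  if (p$noise_as_variance) sdv <- sqrt(sdv)
  T_cur <- t_max; D <- 0
  ev <- integer(0)
  for (t in seq_along(d)) {
    if (d[t] > T_cur) {
      ev <- c(ev, t); T_cur <- t_max; D <- 0
    } else if (!p$static_mode) {
      noise <- if (noiseless) 0 else rnorm(1, 0, sdv)
      T_cur <- T_cur - (t_max - t_min) / p$tau * exp(-D / p$tau) + noise
      D <- D + 1
    }
  }
  ev
}

# wide count table with counts exactly proportional to duration
proportional_counts <- function(repetitions = 20, rates = c(2, 1, 0.5, 0.1),
                                seed = 3) {
  d <- trial_design(standard_durations(), repetitions,
                    scene_types = "synthetic", seed = seed)
  w <- data.frame(trial_id = d$trial_id, check.names = FALSE)
  for (i in seq_along(rates))
    w[[paste0("count_l", i)]] <- round(rates[i] * d$duration_s)
  w$duration_s <- d$duration_s
  w$scene_type <- d$scene_type
  w
}
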
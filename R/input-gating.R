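#' Centre crop a frame sequence
#'
#' The full-frame input regime: every frame is cropped to a centred patch.
#' The default 720 x 720 patch of a 1280 x 720 source retains 56% of pixels
#' (about 18 degrees of visual angle for a seated observer).
#' Offsets are `floor((source - patch) / 2)` on each axis.
#'
#' @param frames a [frame_sequence()].
#' @param width,height patch size in pixels (defaults 720 x 720).
#' @return A [frame_sequence()] of cropped frames.
#' @export
centre_crop <- function(frames, width = 720, height = 720) {
  stopifnot(inherits(frames, "frame_sequence"))
  d <- frame_dims(frames) # c(height, width)
  if (height > d[1] || width > d[2])
    stopf("patch %dx%d exceeds frame %dx%d", width, height, d[2], d[1])
  top <- floor((d[1] - height) / 2)
  left <- floor((d[2] - width) / 2)
  out <- lapply(frames$frames, function(f)
    f[(top + 1):(top + height), (left + 1):(left + width), , drop = FALSE])
  frame_sequence(out, frames$frame_rate, frames$trial_id, frames$scene_type)
}

#' Fraction of source pixels retained by a crop
#'
#' @param frame_width,frame_height source frame size in pixels.
#' @param patch_width,patch_height crop size in pixels.
#' @return Retained fraction in `[0, 1]`.
#' @examples
#' crop_pixel_fraction(1280, 720, 720, 720) # 0.5625: the centre-crop regime
#' crop_pixel_fraction(1280, 720, 400, 400) # ~0.174: the gaze-patch regime
#' @export
crop_pixel_fraction <- function(frame_width, frame_height,
                                patch_width, patch_height) {
  check_scalar_num(frame_width, "frame_width", positive = TRUE)
  check_scalar_num(frame_height, "frame_height", positive = TRUE)
  (patch_width * patch_height) / (frame_width * frame_height)
}

#' Gaze traces
#'
#' A gaze trace is a data frame with per-frame fixation coordinates in
#' source-frame pixel space: columns `frame_index`, `x_px`, `y_px`, `valid`
#' (logical). `read_gaze_csv()` reads a multi-trial file with an additional
#' `trial_id` column and returns a named list of traces.
#'
#' @param x_px,y_px numeric fixation coordinates per frame.
#' @param valid logical vector flagging usable samples.
#' @param trial_id identifier.
#' @return `gaze_trace()`: a data frame of class `gaze_trace`.
#' @export
gaze_trace <- function(x_px, y_px, valid = rep(TRUE, length(x_px)),
                       trial_id = "trial_1") {
  if (length(x_px) != length(y_px) || length(x_px) != length(valid))
    stopf("x_px, y_px and valid must have equal length")
  if (any(!is.finite(x_px[valid])) || any(!is.finite(y_px[valid])))
    stopf("valid gaze samples must have finite coordinates")
  g <- data.frame(frame_index = seq_along(x_px), x_px = x_px, y_px = y_px,
                  valid = as.logical(valid), stringsAsFactors = FALSE)
  attr(g, "trial_id") <- trial_id
  class(g) <- c("gaze_trace", "data.frame")
  g
}

#' @rdname gaze_trace
#' @param path CSV path with columns `trial_id, frame_index, x_px, y_px,
#'   valid`.
#' @export
read_gaze_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "frame_index", "x_px", "y_px", "valid")
  if (!all(need %in% names(df)))
    stopf("gaze CSV must have columns %s", paste(need, collapse = ", "))
  lapply(split(df, df$trial_id), function(tr) {
    tr <- tr[order(tr$frame_index), ]
    gaze_trace(tr$x_px, tr$y_px, as.logical(tr$valid), tr$trial_id[1])
  })
}

#' @rdname gaze_trace
#' @param traces named list of `gaze_trace` objects.
#' @export
write_gaze_csv <- function(traces, path) {
  if (inherits(traces, "gaze_trace")) traces <- list(traces)
  rows <- lapply(traces, function(g)
    data.frame(trial_id = attr(g, "trial_id"), frame_index = g$frame_index,
               x_px = g$x_px, y_px = g$y_px, valid = g$valid))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Align a high-rate gaze recording to frame timestamps
#'
#' Eye trackers commonly sample far faster than the video frame rate (e.g.
#' 1000 Hz gaze against 30 Hz frames). For each frame timestamp the nearest
#' gaze sample in time is taken.
#'
#' @param gaze a [gaze_trace()] sampled at `sample_rate` Hz.
#' @param n_frames number of video frames to align to.
#' @param frame_rate video frame rate (Hz).
#' @param sample_rate gaze sampling rate (Hz).
#' @return A [gaze_trace()] with exactly `n_frames` rows.
#' @export
align_gaze <- function(gaze, n_frames, frame_rate, sample_rate) {
  stopifnot(inherits(gaze, "gaze_trace"))
  check_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  check_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  frame_time <- (seq_len(n_frames) - 1) / frame_rate
  sample_time <- (seq_len(nrow(gaze)) - 1) / sample_rate
  idx <- vapply(frame_time, function(tt) which.min(abs(sample_time - tt)), 1L)
  gaze_trace(gaze$x_px[idx], gaze$y_px[idx], gaze$valid[idx],
             attr(gaze, "trial_id"))
}

# fill invalid samples: hold last valid; leading invalids take first valid
fill_gaze <- function(gaze) {
  if (!any(gaze$valid))
    stopf("gaze trace for trial %s has no valid samples",
          attr(gaze, "trial_id"))
  first_valid <- which(gaze$valid)[1]
  x <- gaze$x_px; y <- gaze$y_px
  if (first_valid > 1L) {
    x[seq_len(first_valid - 1L)] <- x[first_valid]
    y[seq_len(first_valid - 1L)] <- y[first_valid]
  }
  for (i in seq_len(nrow(gaze))[-1]) {
    if (!gaze$valid[i] && i > first_valid) {
      x[i] <- x[i - 1L]; y[i] <- y[i - 1L]
    }
  }
  data.frame(x_px = x, y_px = y)
}

# pad (hold final sample) or truncate a trace to n_frames rows;
# needed when donor gaze is applied to a different-length trial
conform_gaze <- function(gaze, n_frames) {
  n <- nrow(gaze)
  if (n == n_frames) return(gaze)
  if (n > n_frames) {
    g <- gaze[seq_len(n_frames), ]
  } else {
    pad <- gaze[rep(n, n_frames - n), ]
    g <- rbind(gaze, pad)
  }
  out <- gaze_trace(g$x_px, g$y_px, g$valid, attr(gaze, "trial_id"))
  out
}

#' Gaze-contingent crop
#'
#' The attention-spotlight input regime: each frame is reduced to a patch
#' centred on that frame's fixation (default 400 x 400, about 17% of a
#' 1280 x 720 frame and roughly 10 degrees of visual angle). Patch windows
#' are clamped to lie fully inside the frame, so output dimensions are
#' constant and no artificial padding edges are introduced. Invalid gaze
#' samples are filled by the most recent valid sample (leading invalids by
#' the first valid one); a trace with no valid samples is an error. Donor
#' traces shorter or longer than the trial are held at their final sample or
#' truncated, respectively.
#'
#' @param frames a [frame_sequence()].
#' @param gaze a [gaze_trace()] aligned to `frames` (see [align_gaze()]).
#' @param width,height patch size in pixels (defaults 400 x 400).
#' @return A [frame_sequence()] of `height x width` patches.
#' @export
gaze_crop <- function(frames, gaze, width = 400, height = 400) {
  stopifnot(inherits(frames, "frame_sequence"), inherits(gaze, "gaze_trace"))
  d <- frame_dims(frames)
  if (height > d[1] || width > d[2])
    stopf("patch %dx%d exceeds frame %dx%d", width, height, d[2], d[1])
  gaze <- conform_gaze(gaze, length(frames))
  xy <- fill_gaze(gaze)
  lefts <- pmin(pmax(floor(xy$x_px - width / 2), 0), d[2] - width)
  tops <- pmin(pmax(floor(xy$y_px - height / 2), 0), d[1] - height)
  out <- lapply(seq_along(frames$frames), function(i) {
    frames$frames[[i]][(tops[i] + 1):(tops[i] + height),
                       (lefts[i] + 1):(lefts[i] + width), , drop = FALSE]
  })
  frame_sequence(out, frames$frame_rate, frames$trial_id, frames$scene_type)
}

#' Shuffled-gaze assignment
#'
#' The control regime that dissociates patch movement from patch content:
#' each trial receives the gaze trace recorded on a *different* trial. The
#' assignment is a seeded derangement — a permutation with no fixed point —
#' so no trial ever keeps its own gaze.
#'
#' @param trial_ids character vector of at least two trial identifiers.
#' @param seed integer RNG seed; the mapping is deterministic given it.
#' @return Named character vector: `result[trial]` is the donor trial whose
#'   gaze `trial` receives.
#' @export
shuffle_gaze <- function(trial_ids, seed) {
  trial_ids <- as.character(trial_ids)
  n <- length(trial_ids)
  if (n < 2L)
    stopf("need at least 2 trials to derange gaze assignments (got %d)", n)
  perm <- with_seed(as.integer(seed), {
    repeat {
      p <- sample.int(n)
      if (!any(p == seq_len(n))) break
    }
    p
  })
  stats::setNames(trial_ids[perm], trial_ids)
}
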
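#' Construct a frame sequence
#'
#' Bundles an ordered set of RGB frames with its frame rate and trial
#' metadata. Frames are `height x width x 3` numeric arrays sharing identical
#' dimensions; intensities are on whatever scale the downstream extractor
#' expects (the synthetic generator uses `[0, 1]`).
#'
#' @param frames list of `height x width x 3` numeric arrays.
#' @param frame_rate frames per second (default 30, the native video rate).
#' @param trial_id identifier for the trial this sequence belongs to.
#' @param scene_type categorical scene label (e.g. `"city"`,
#'   `"campus_outside"`, `"office_cafe"`), carried through to the metrics.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate = 30, trial_id = "trial_1",
                           scene_type = "unlabelled") {
  if (!is.list(frames) || length(frames) < 1L)
    stopf("`frames` must be a non-empty list of arrays")
  dims <- lapply(frames, dim)
  if (any(vapply(dims, length, 1L) != 3L) ||
      any(vapply(dims, function(d) d[3], 1L) != 3L))
    stopf("each frame must be a height x width x 3 array")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stopf("all frames must share identical dimensions")
  check_scalar_num(frame_rate, "frame_rate", positive = TRUE)
  structure(
    list(frames = frames, frame_rate = frame_rate, trial_id = trial_id,
         scene_type = scene_type),
    class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_sequence> trial %s (%s): %d frames, %dx%d px @ %g Hz\n",
              x$trial_id, x$scene_type, length(x$frames), d[2], d[1],
              x$frame_rate))
  invisible(x)
}

frame_dims <- function(frames) dim(frames$frames[[1]])[1:2]

#' Layer specifications for the feature hierarchy
#'
#' A layer specification is a data frame with columns `name` and `n_neurons`.
#' `default_layers()` returns the four read-out stages of the canonical
#' image-classification hierarchy used throughout: conv2 (290,400 units),
#' pool5 (9,216), fc7 (4,096) and the 1,000-way class-probability output.
#' Layer identity is configurable; smaller hierarchies are routinely used
#' with the random-projection extractor.
#'
#' @param name character vector of unique layer names.
#' @param n_neurons positive integer vector, activation vector length per
#'   layer.
#' @return data frame with columns `name`, `n_neurons`.
#' @export
layer_spec <- function(name, n_neurons) {
  if (length(name) != length(n_neurons) || length(name) < 1L)
    stopf("`name` and `n_neurons` must be non-empty and the same length")
  if (anyDuplicated(name))
    stopf("layer names must be unique")
  n_neurons <- as.integer(n_neurons)
  if (any(is.na(n_neurons)) || any(n_neurons < 1L))
    stopf("`n_neurons` must be positive integers")
  data.frame(name = as.character(name), n_neurons = n_neurons,
             stringsAsFactors = FALSE)
}

#' @rdname layer_spec
#' @export
default_layers <- function() {
  layer_spec(c("conv2", "pool5", "fc7", "output"),
             c(290400L, 9216L, 4096L, 1000L))
}

#' Feature extractors
#'
#' An extractor is a deterministic map from one RGB frame to one activation
#' vector per layer. Any object honouring this contract can drive the
#' pipeline; three are provided:
#'
#' * `pixel_extractor()` — the identity map: one "layer" holding the
#'   flattened frame (channel-major order: all of channel 1, then 2, then 3).
#'   The change-detection path fed by this extractor is exactly the
#'   pixel-difference control that bypasses the classification hierarchy.
#' * `random_projection_extractor()` — a seeded, frozen hierarchy of random
#'   linear maps with a pointwise nonlinearity, layer `k + 1` reading layer
#'   `k`. A desk-scale stand-in for a pretrained network: deterministic,
#'   download-free, and hierarchical so higher layers respond to transformed
#'   lower-layer features.
#' * any user-supplied object of class `feature_extractor` with fields `id`,
#'   `layers` (a [layer_spec()] table) and `fun(frame) -> named list of
#'   numeric vectors` — e.g. an adapter around a pretrained classification
#'   network. No such adapter is bundled.
#'
#' @param seed integer seed from which the projection matrices are drawn once
#'   and then frozen.
#' @param input_dim frame dimensions `c(height, width)` the extractor will
#'   accept (channels fixed at 3).
#' @param layers a [layer_spec()] table; layer sizes of the hierarchy, in
#'   order from lowest to highest.
#' @param nonlinearity pointwise nonlinearity between layers: `"relu"`
#'   (default), `"tanh"` or `"identity"`.
#' @return An object of class `feature_extractor`.
#' @export
random_projection_extractor <- function(seed, input_dim, layers,
                                        nonlinearity = c("relu", "tanh",
                                                         "identity")) {
  nonlinearity <- match.arg(nonlinearity)
  if (length(input_dim) != 2L || any(input_dim < 1))
    stopf("`input_dim` must be c(height, width)")
  stopifnot(is.data.frame(layers), all(c("name", "n_neurons") %in%
                                         names(layers)))
  d_in <- prod(input_dim) * 3L
  sizes <- c(d_in, layers$n_neurons)
  mats <- with_seed(as.integer(seed), {
    lapply(seq_len(nrow(layers)), function(k) {
      # variance-preserving scale so activations stay O(1) across depth
      matrix(rnorm(sizes[k + 1] * sizes[k], sd = 1 / sqrt(sizes[k])),
             nrow = sizes[k + 1], ncol = sizes[k])
    })
  })
  nl <- switch(nonlinearity,
               relu = function(x) pmax(x, 0),
               tanh = tanh,
               identity = identity)
  fun <- function(frame) {
    if (!identical(dim(frame)[1:2], as.integer(input_dim)))
      stopf("frame is %s but extractor expects %dx%d",
            paste(dim(frame)[1:2], collapse = "x"),
            input_dim[1], input_dim[2])
    x <- as.numeric(frame) # column-major within channel, channel-major blocks
    out <- vector("list", nrow(layers))
    for (k in seq_along(mats)) {
      x <- nl(drop(mats[[k]] %*% x))
      out[[k]] <- x
    }
    names(out) <- layers$name
    out
  }
  structure(
    list(id = sprintf("random_projection(seed=%d,%s)", as.integer(seed),
                      nonlinearity),
         layers = layers, fun = fun),
    class = "feature_extractor")
}

#' @rdname random_projection_extractor
#' @export
pixel_extractor <- function() {
  structure(
    list(id = "pixel_identity",
         layers = NULL, # resolved from the first frame
         fun = function(frame) list(pixels = as.numeric(frame))),
    class = "feature_extractor")
}

#' Extract per-layer activation streams from a frame sequence
#'
#' Feeds every frame through the extractor and collects one activation vector
#' per frame per layer. Deterministic given the frames and the extractor's
#' frozen state.
#'
#' @param frames a [frame_sequence()].
#' @param extractor a `feature_extractor` (see
#'   [random_projection_extractor()]).
#' @return An `activation_stream`: a named list of `timesteps x n_neurons`
#'   matrices, one per layer, carrying `frame_rate`, `trial_id`,
#'   `scene_type` and `extractor_id` attributes.
#' @export
extract_activations <- function(frames, extractor) {
  stopifnot(inherits(frames, "frame_sequence"),
            inherits(extractor, "feature_extractor"))
  acts <- lapply(frames$frames, extractor$fun)
  layer_names <- names(acts[[1]])
  if (is.null(layer_names))
    stopf("extractor must return a named list of vectors")
  if (!is.null(extractor$layers)) {
    missing <- setdiff(extractor$layers$name, layer_names)
    if (length(missing))
      stopf("extractor did not produce configured layer(s): %s",
            paste(missing, collapse = ", "))
    lens <- vapply(acts[[1]], length, 1L)[extractor$layers$name]
    bad <- which(lens != extractor$layers$n_neurons)
    if (length(bad))
      stopf("layer %s returned %d values, spec says %d",
            extractor$layers$name[bad[1]], lens[bad[1]],
            extractor$layers$n_neurons[bad[1]])
  }
  stream <- lapply(layer_names, function(nm) {
    do.call(rbind, lapply(acts, function(a) a[[nm]]))
  })
  names(stream) <- layer_names
  structure(stream,
            class = "activation_stream",
            frame_rate = frames$frame_rate,
            trial_id = frames$trial_id,
            scene_type = frames$scene_type,
            extractor_id = extractor$id)
}

new_distance_series <- function(series, frame_rate, trial_id, scene_type) {
  structure(series, class = "distance_series", frame_rate = frame_rate,
            trial_id = trial_id, scene_type = scene_type)
}

#' Euclidean distances between successive activations
#'
#' For each layer, entry `t` is the L2 norm of the difference between the
#' activation vectors at timesteps `t + 1` and `t`, so a stream of `T`
#' timesteps yields `T - 1` distances. Computed in double precision.
#'
#' @param stream an `activation_stream` from [extract_activations()].
#' @return A `distance_series`: a named list of non-negative numeric vectors,
#'   one per layer, each of length `timesteps - 1`.
#' @export
layer_distances <- function(stream) {
  stopifnot(inherits(stream, "activation_stream"))
  n_t <- nrow(stream[[1]])
  if (n_t < 2L) {
    warnf("activation stream has %d timestep(s); distance series is empty",
          n_t)
    series <- lapply(stream, function(m) numeric(0))
  } else {
    series <- lapply(unclass(stream), function(m) {
      d <- m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
      sqrt(rowSums(d * d))
    })
  }
  new_distance_series(series,
                      frame_rate = attr(stream, "frame_rate"),
                      trial_id = attr(stream, "trial_id"),
                      scene_type = attr(stream, "scene_type"))
}

#' Pixel-wise frame-change series
#'
#' The stimulus-difference control: Euclidean distance between flattened
#' successive frames, bypassing any feature hierarchy. The result is a
#' single-layer `distance_series` (layer `"pixels"`) usable as a drop-in
#' stream for [detect_salient_events()].
#'
#' @param frames a [frame_sequence()] with at least two frames.
#' @return A `distance_series` with one layer, `pixels`.
#' @export
pixel_change_series <- function(frames) {
  stopifnot(inherits(frames, "frame_sequence"))
  if (length(frames) < 2L)
    stopf("need at least 2 frames to compute a change series")
  f <- frames$frames
  d <- vapply(seq_len(length(f) - 1L), function(t) {
    sqrt(sum((as.numeric(f[[t + 1L]]) - as.numeric(f[[t]]))^2))
  }, numeric(1))
  new_distance_series(list(pixels = d),
                      frame_rate = frames$frame_rate,
                      trial_id = frames$trial_id,
                      scene_type = frames$scene_type)
}

#' Persist and reload streams
#'
#' Activation streams are stored as a keyed array container (one array per
#' layer name, RDS serialisation); distance series travel as plain CSV with
#' columns `trial_id, layer, t, distance`.
#'
#' @param stream an `activation_stream`.
#' @param series a `distance_series`, or a list of them for multi-trial CSV.
#' @param path file path.
#' @name stream-io
#' @export
write_activations <- function(stream, path) {
  stopifnot(inherits(stream, "activation_stream"))
  saveRDS(stream, path)
  invisible(path)
}

#' @rdname stream-io
#' @export
read_activations <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "activation_stream"))
  x
}

#' @rdname stream-io
#' @export
write_distance_csv <- function(series, path) {
  if (inherits(series, "distance_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    do.call(rbind, lapply(names(s), function(ly) {
      v <- s[[ly]]
      if (!length(v)) return(NULL)
      data.frame(trial_id = attr(s, "trial_id"), layer = ly,
                 t = seq_along(v), distance = v, stringsAsFactors = FALSE)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname stream-io
#' @export
read_distance_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "layer", "t", "distance")
  if (!all(need %in% names(df)))
    stopf("distance CSV must have columns %s", paste(need, collapse = ", "))
  lapply(split(df, df$trial_id), function(tr) {
    series <- lapply(split(tr, tr$layer), function(ly)
      ly$distance[order(ly$t)])
    new_distance_series(series, frame_rate = NA_real_,
                        trial_id = tr$trial_id[1], scene_type = NA_character_)
  })
}
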
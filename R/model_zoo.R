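# The seven convolution weight-sharing variants and their recurrent heads.
#
# "1-dimensional" variants convolve each signal row alone (filter height 1);
# "2-dimensional" variants convolve a sensor triad together (height 3, one
# aligned position per triad) or the whole array at once (full height).
# Sharing modes: one filter bank for all rows/triads (share), an independent
# bank per triad (per_sensor), or the concatenation of the constituent
# variants' feature maps stacked along the spatial axis (combined). A sensor
# group is one modality triad (3 axes), giving 10 groups with gyroscopes and
# 5 without. All convolutions are valid (no padding) with ReLU.

.scaleWidth <- function(w, s) max(1L, as.integer(round(w * s)))

# the two-stage conv trunk of one elementary variant
.convTrunk <- function(variant, ws, prefix) {
  f1_1d <- .scaleWidth(16L, ws); f2_1d <- .scaleWidth(32L, ws)
  f1_2d <- .scaleWidth(32L, ws); f2_2d <- .scaleWidth(64L, ws)
  id <- function(k) paste0(prefix, "L", k)
  switch(variant,
    c1d_share = list(
      list(type = "conv", id = id(1), f = f1_1d, h = 1L, m = 5L, strideH = 1L),
      list(type = "maxpool", id = id(2), pw = 4L),
      list(type = "conv", id = id(3), f = f2_1d, h = 1L, m = 5L, strideH = 1L),
      list(type = "maxpool", id = id(4), pw = 4L)),
    c1d_per_sensor = list(
      list(type = "gconv", id = id(1), f = f1_1d, h = 1L, m = 5L, groupSize = 3L),
      list(type = "maxpool", id = id(2), pw = 4L),
      list(type = "gconv", id = id(3), f = f2_1d, h = 1L, m = 5L, groupSize = 3L),
      list(type = "maxpool", id = id(4), pw = 4L)),
    c2d_share = list(
      list(type = "conv", id = id(1), f = f1_2d, h = 3L, m = 5L, strideH = 3L),
      list(type = "maxpool", id = id(2), pw = 4L),
      list(type = "conv", id = id(3), f = f2_2d, h = 1L, m = 5L, strideH = 1L),
      list(type = "maxpool", id = id(4), pw = 4L)),
    c2d_per_sensor = list(
      list(type = "gconv", id = id(1), f = f1_2d, h = 3L, m = 5L, groupSize = 3L),
      list(type = "maxpool", id = id(2), pw = 4L),
      list(type = "gconv", id = id(3), f = f2_2d, h = 1L, m = 5L, groupSize = 1L),
      list(type = "maxpool", id = id(4), pw = 4L)),
    c2d_all = list(
      list(type = "conv", id = id(1), f = f1_2d, h = NA, m = 5L, strideH = 1L),
      list(type = "maxpool", id = id(2), pw = 4L),
      list(type = "conv", id = id(3), f = f2_2d, h = 1L, m = 5L, strideH = 1L),
      list(type = "maxpool", id = id(4), pw = 4L)),
    stop("config error: unknown variant '", variant, "'", call. = FALSE))
}

#' Expand a ModelSpec into a concrete LayerPlan
#'
#' 1-dimensional trunks use Conv(16,(1,5)) / Conv(32,(1,5)) stages,
#' 2-dimensional ones Conv(32,(.,5)) / Conv(64,(1,5)), each stage followed
#' by MaxP(1,4). Combined variants run their constituent trunks in parallel
#' and stack the resulting feature maps one on top of the other along the
#' spatial axis. Models with a recurrent head append the full-height bridge
#' convolution Conv(128,(d,1),1), the (bi)LSTM of 128 units, then
#' dropout-FC(128,ReLU)-dropout-FC(5,softmax); head-less models flatten into
#' the same fully connected stack. Recurrent-only models feed the raw
#' channels as sequence features. All unit counts scale with the spec's
#' \code{widthScale}.
#'
#' @param spec a [modelSpec()].
#' @param window window length in timesteps (default 500).
#' @return A [LayerPlan-class].
#' @export
buildPlan <- function(spec, window = 500L) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  ws <- spec@widthScale
  nCh <- if (spec@useGyro) 30L else 15L
  layers <- list()
  if (spec@variant == "none") {
    layers <- list(list(type = "asseq", id = "A1"))
  } else if (spec@variant %in% c("c1d_combined", "c2d_combined")) {
    parts <- if (spec@variant == "c1d_combined")
      c("c1d_share", "c1d_per_sensor")
    else c("c2d_share", "c2d_per_sensor", "c2d_all")
    branches <- lapply(seq_along(parts), function(i)
      .convTrunk(parts[i], ws, sprintf("P1.b%d.", i)))
    layers <- list(list(type = "parallel", id = "P1", branches = branches))
  } else {
    layers <- .convTrunk(spec@variant, ws, "")
  }
  fcu <- .scaleWidth(128L, ws)
  if (spec@head == "none") {
    tailL <- list(
      list(type = "flatten", id = "F1"),
      list(type = "dropout", id = "D1", rate = spec@dropout),
      list(type = "dense", id = "FC1", units = fcu, act = "relu"),
      list(type = "dropout", id = "D2", rate = spec@dropout),
      list(type = "dense", id = "FC2", units = 5L, act = "linear"))
  } else {
    pre <- if (spec@variant == "none") list()
    else list(list(type = "bridge", id = "BR", f = fcu))
    tailL <- c(pre, list(
      list(type = "rnn", id = "R1", kind = spec@head, units = fcu),
      list(type = "dropout", id = "D1", rate = spec@dropout),
      list(type = "dense", id = "FC1", units = fcu, act = "relu"),
      list(type = "dropout", id = "D2", rate = spec@dropout),
      list(type = "dense", id = "FC2", units = 5L, act = "linear")))
  }
  plan <- new("LayerPlan", spec = spec, layers = c(layers, tailL),
              inputShape = c(nCh, as.integer(window)),
              classes = .ACTIVITY_CLASSES)
  .walk(plan@layers, c(nCh, as.integer(window), 1L))   # shape compatibility
  plan
}

#' Per-layer output shapes of a plan
#'
#' Shapes under valid convolution arithmetic: conv time out = t - m + 1,
#' max-pool time out = floor(t/4), spatial out = floor((h_in - h)/stride)+1.
#' The first element is the input shape (height x time x maps); matrix-stage
#' entries are single feature counts.
#'
#' @param plan a [LayerPlan-class].
#' @param inputShape c(channels, timesteps); defaults to the plan's.
#' @return List of shape vectors, one per layer plus the input.
#' @export
outputShape <- function(plan, inputShape = plan@inputShape) {
  .walk(plan@layers, c(inputShape[1], inputShape[2], 1L))$shapes
}

#' Exact learnable parameter count of a plan
#'
#' Per-group banks count once per group; shared banks once; a bidirectional
#' recurrent layer counts twice its unidirectional size.
#'
#' @param plan a [LayerPlan-class].
#' @param inputShape c(channels, timesteps); defaults to the plan's.
#' @return Integer parameter count.
#' @export
weightCount <- function(plan, inputShape = plan@inputShape) {
  .walk(plan@layers, c(inputShape[1], inputShape[2], 1L), count = TRUE)$count
}

#' Initialize a model from a plan
#'
#' Glorot-uniform weights (LSTM forget-gate biases at 1), deterministic
#' under \code{seed}.
#'
#' @param plan a [LayerPlan-class].
#' @param seed RNG seed.
#' @param scaled whether the model will consume max-abs-scaled windows
#'   (recorded on the model; affects the training learning rate).
#' @return A [TrainedModel-class] with untrained parameters.
#' @export
buildModel <- function(plan, seed = 1, scaled = TRUE) {
  set.seed(seed %% 2147483647)
  params <- .walk(plan@layers, c(plan@inputShape[1], plan@inputShape[2], 1L),
                  params = list())$params
  new("TrainedModel", plan = plan, params = params,
      classes = plan@classes, scaled = scaled)
}

# windows (WindowSet or channels x time x n array) -> (1, H, W, N) input
# in the engine's maps-first layout (a single input map)
.asInput <- function(windows) {
  a <- if (is(windows, "WindowSet")) windowData(windows) else windows
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  d <- dim(a)
  dim(a) <- c(1L, d[1], d[2], d[3])
  a
}

#' Class probabilities for a batch of windows
#'
#' Forward pass (dropout inactive) followed by softmax; each row is a
#' probability vector over the five movement classes, summing to one.
#'
#' @param model a [TrainedModel-class].
#' @param windows a [WindowSet-class] (or channels x time x n array) whose
#'   channel count matches the model input; the scaling regime must match
#'   the model's.
#' @param batch mini-batch size used internally (memory control).
#' @return n x 5 matrix of probabilities, columns named by class.
#' @export
predictProba <- function(model, windows, batch = 64L) {
  X <- .asInput(windows)
  if (dim(X)[2] != model@plan@inputShape[1] ||
      dim(X)[3] != model@plan@inputShape[2])
    stop("incompatible input: model expects ",
         model@plan@inputShape[1], "x", model@plan@inputShape[2],
         " windows, got ", dim(X)[2], "x", dim(X)[3], call. = FALSE)
  if (is(windows, "WindowSet") && windows@scaled != model@scaled)
    warning("window scaling state does not match the model's training regime",
            call. = FALSE)
  n <- dim(X)[4]
  P <- matrix(0, n, 5L, dimnames = list(NULL, model@classes))
  for (s in seq(1L, n, by = batch)) {
    e <- min(n, s + batch - 1L)
    out <- .forwardLayers(model@plan@layers, X[, , , s:e, drop = FALSE],
                          model@params, training = FALSE)$out
    z <- sweep(out, 2L, apply(out, 2L, max))
    ez <- exp(z)
    P[s:e, ] <- t(sweep(ez, 2L, colSums(ez), "/"))
  }
  P
}

#' Realized per-layer activation shapes on a concrete batch
#'
#' Runs a forward pass and records the actual tensor dimensions after every
#' layer (per sample, batch axis dropped) — the runtime counterpart of
#' [outputShape()].
#'
#' @param model a [TrainedModel-class].
#' @param n batch size of the probe input.
#' @return List of shape vectors, one per layer plus the input.
#' @export
realizedShapes <- function(model, n = 2L) {
  shp <- model@plan@inputShape
  X <- array(rnorm(shp[1] * shp[2] * n), c(1L, shp[1], shp[2], n))
  shapes <- list(c(shp[1], shp[2], 1L))
  cur <- X
  layers <- model@plan@layers
  for (i in seq_along(layers)) {
    cur <- .forwardLayers(layers[i], cur, model@params, training = FALSE)$out
    d <- dim(cur)
    # engine layout is maps-first; report (height, time, maps)
    shapes[[i + 1L]] <- if (length(d) == 4L) d[c(2, 3, 1)] else d[1]
  }
  shapes
}

#' Total parameters actually allocated in a model
#'
#' Runtime counterpart of [weightCount()].
#' @param model a [TrainedModel-class].
#' @return Integer.
#' @export
realizedWeightCount <- function(model)
  sum(vapply(model@params, function(p) sum(lengths(p)), 1))
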
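# Central S4 containers for the pipeline.

#' Recording: fixed-rate multi-channel inertial time series
#'
#' Columns of \code{series} follow the canonical channel order
#' (location-major, accelerometer triad before gyroscope triad, axes X, Y, Z;
#' see [canonicalChannels()]). Accelerometer values are in g and must lie in
#' \eqn{[-16, 16]}; gyroscope values are in degrees/second within
#' \eqn{[-2000, 2000]}.
#'
#' @slot id recording identifier; subject identity is encoded here by the
#'   corpus generator as \code{"subject/recording"}.
#' @slot sampleRate sampling frequency in Hz (500 for the supported sensors).
#' @slot series numeric matrix, timesteps x channels, canonical column names.
#' @exportClass Recording
setClass("Recording",
  representation(id = "character", sampleRate = "numeric", series = "matrix"),
  prototype(id = "", sampleRate = 500))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (nrow(object@series) < 1L)
    msg <- c(msg, "recording must have at least one timestep")
  cn <- colnames(object@series)
  full <- canonicalChannels(TRUE); acc <- canonicalChannels(FALSE)
  if (!(identical(cn, full) || identical(cn, acc)))
    msg <- c(msg, "series columns must be the canonical 30- or 15-channel layout")
  else {
    accCols <- .accelColumns(cn)
    a <- object@series[, accCols, drop = FALSE]
    if (any(abs(a) > .ACCEL_RANGE, na.rm = TRUE))
      msg <- c(msg, sprintf("accelerometer values outside +/-%d g", .ACCEL_RANGE))
    gyrCols <- setdiff(cn, accCols)
    if (length(gyrCols)) {
      g <- object@series[, gyrCols, drop = FALSE]
      if (any(abs(g) > .GYRO_RANGE, na.rm = TRUE))
        msg <- c(msg, sprintf("gyroscope values outside +/-%d deg/s", .GYRO_RANGE))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param series timesteps x channels numeric matrix with canonical column
#'   names (any column order is accepted and reordered canonically).
#' @param sampleRate Hz, default 500.
#' @param id recording identifier.
#' @return A [Recording-class] object.
#' @export
Recording <- function(series, sampleRate = 500, id = "") {
  cn <- colnames(series)
  if (is.null(cn)) stop("series must have channel column names", call. = FALSE)
  full <- canonicalChannels(TRUE); acc <- canonicalChannels(FALSE)
  want <- if (all(full %in% cn)) full else acc
  missing <- setdiff(want, cn)
  if (length(missing))
    stop("missing channels: ", paste(missing, collapse = ", "), call. = FALSE)
  new("Recording", id = id, sampleRate = sampleRate,
      series = series[, want, drop = FALSE])
}

#' @describeIn Recording number of timesteps
#' @param x,object a \code{Recording}
#' @export
setMethod("length", "Recording", function(x) nrow(x@series))

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s': %d timesteps (%.1f s) x %d channels @ %g Hz\n",
              object@id, nrow(object@series),
              nrow(object@series) / object@sampleRate,
              ncol(object@series), object@sampleRate))
})

#' @rdname Recording-accessors
#' @param x a \code{Recording}
#' @return \code{recordingSeries}: the timesteps x channels matrix;
#'   \code{sampleRate}: Hz; \code{recordingId}: identifier; \code{hasGyro}:
#'   logical.
#' @export
recordingSeries <- function(x) x@series

#' Recording accessors
#' @name Recording-accessors
#' @rdname Recording-accessors
#' @export
sampleRate <- function(x) x@sampleRate

#' @rdname Recording-accessors
#' @export
recordingId <- function(x) x@id

#' @rdname Recording-accessors
#' @export
hasGyro <- function(x) ncol(x@series) == 30L

#' WindowSet: a batch of 1-second window samples
#'
#' @slot data array channels x window x n, canonical channel order.
#' @slot label character vector of length n.
#' @slot sourceId recording of origin per window.
#' @slot sourceStart 0-based start timestep in the source recording.
#' @slot scaled whether max-abs scaling has been applied.
#' @slot channels channel names (rows of each window matrix).
#' @exportClass WindowSet
setClass("WindowSet",
  representation(data = "array", label = "character", sourceId = "character",
                 sourceStart = "integer", scaled = "logical",
                 channels = "character"))

setValidity("WindowSet", function(object) {
  d <- dim(object@data)
  n <- if (length(d) == 3L) d[3] else NA_integer_
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array (channels x time x n)")
  else {
    if (d[1] != length(object@channels)) msg <- c(msg, "channel dimension mismatch")
    if (length(object@label) != n || length(object@sourceId) != n ||
        length(object@sourceStart) != n)
      msg <- c(msg, "per-window metadata must have length n")
  }
  if (length(object@scaled) != 1L) msg <- c(msg, "scaled must be a single flag")
  if (length(msg)) msg else TRUE
})

WindowSet <- function(data, label, sourceId, sourceStart, scaled, channels) {
  new("WindowSet", data = data, label = as.character(label),
      sourceId = as.character(sourceId), sourceStart = as.integer(sourceStart),
      scaled = scaled, channels = channels)
}

#' @describeIn WindowSet number of windows
#' @param x,object a \code{WindowSet}
#' @export
setMethod("length", "WindowSet", function(x) dim(x@data)[3])

setMethod("show", "WindowSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("WindowSet: %d windows of %d channels x %d timesteps%s\n",
              d[3], d[1], d[2], if (object@scaled) " (scaled)" else ""))
  if (d[3] > 0) print(table(object@label))
})

#' @rdname WindowSet-accessors
#' @param x a \code{WindowSet}
#' @param i index vector
#' @return \code{windowData}: the channels x time x n array;
#'   \code{windowLabels}: labels; \code{windowSource}: provenance data.frame;
#'   \code{subsetWindows}: a new \code{WindowSet}.
#' @export
windowData <- function(x) x@data

#' WindowSet accessors
#' @name WindowSet-accessors
#' @rdname WindowSet-accessors
#' @export
windowLabels <- function(x) x@label

#' @rdname WindowSet-accessors
#' @export
windowSource <- function(x)
  data.frame(sourceId = x@sourceId, sourceStart = x@sourceStart,
             stringsAsFactors = FALSE)

#' @rdname WindowSet-accessors
#' @export
subsetWindows <- function(x, i) {
  WindowSet(x@data[, , i, drop = FALSE], x@label[i], x@sourceId[i],
            x@sourceStart[i], x@scaled, x@channels)
}

#' Combine WindowSets
#' @param windowSets list of \code{WindowSet}s with identical channel layout
#'   and scaling state.
#' @return A single \code{WindowSet}.
#' @export
bindWindows <- function(windowSets) {
  windowSets <- Filter(function(w) length(w) > 0L, windowSets)
  if (!length(windowSets)) stop("no non-empty window sets to bind", call. = FALSE)
  ch <- windowSets[[1]]@channels
  sc <- windowSets[[1]]@scaled
  stopifnot(all(vapply(windowSets, function(w) identical(w@channels, ch), TRUE)),
            all(vapply(windowSets, function(w) identical(w@scaled, sc), TRUE)))
  dat <- array(unlist(lapply(windowSets, windowData), use.names = FALSE),
               dim = c(length(ch), dim(windowSets[[1]]@data)[2],
                       sum(vapply(windowSets, length, 1L))))
  WindowSet(dat,
            unlist(lapply(windowSets, windowLabels)),
            unlist(lapply(windowSets, function(w) w@sourceId)),
            unlist(lapply(windowSets, function(w) w@sourceStart)),
            sc, ch)
}

#' ModelSpec: declarative description of one classifier architecture
#'
#' @slot variant one of \code{c1d_share, c1d_per_sensor, c1d_combined,
#'   c2d_share, c2d_per_sensor, c2d_all, c2d_combined, none}.
#' @slot head recurrent head: \code{none}, \code{lstm} or \code{blstm}.
#' @slot useGyro include gyroscope channels (30-row input) or not (15).
#' @slot dropout dropout rate before each fully connected layer.
#' @slot widthScale multiplier on all filter/unit counts (1 = published
#'   widths; 0.25 = reduced desk widths).
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(variant = "character", head = "character",
                 useGyro = "logical", dropout = "numeric",
                 widthScale = "numeric"))

.VARIANTS <- c("c1d_share", "c1d_per_sensor", "c1d_combined",
               "c2d_share", "c2d_per_sensor", "c2d_all", "c2d_combined", "none")

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!(object@variant %in% .VARIANTS))
    msg <- c(msg, paste("unknown variant:", object@variant))
  if (!(object@head %in% c("none", "lstm", "blstm")))
    msg <- c(msg, paste("unknown head:", object@head))
  if (object@variant == "none" && object@head == "none")
    msg <- c(msg, "a model needs at least a convolutional part or a recurrent head")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (object@widthScale <= 0) msg <- c(msg, "widthScale must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelSpec
#'
#' @param variant convolution variant (see [ModelSpec-class]).
#' @param head recurrent head.
#' @param useGyro include gyroscope channels.
#' @param dropout dropout rate (default 0.5).
#' @param widthScale width multiplier; \code{desk = TRUE} sets 0.25.
#' @param desk convenience flag for reduced widths.
#' @return A [ModelSpec-class].
#' @export
modelSpec <- function(variant, head = "none", useGyro = TRUE, dropout = 0.5,
                      widthScale = if (desk) 0.25 else 1, desk = FALSE) {
  new("ModelSpec", variant = variant, head = head, useGyro = useGyro,
      dropout = dropout, widthScale = widthScale)
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s + head '%s', %s, dropout %.2f, width x%.2g\n",
              object@variant, object@head,
              if (object@useGyro) "acc+gyro (30 ch)" else "acc only (15 ch)",
              object@dropout, object@widthScale))
})

#' LayerPlan: concrete layer arithmetic for a ModelSpec
#'
#' Produced by [buildPlan()]; a list of layer records with all filter
#' heights/widths, strides, sharing modes and unit counts resolved.
#'
#' @slot spec the originating [ModelSpec-class].
#' @slot layers list of layer records.
#' @slot inputShape c(channels, timesteps).
#' @slot classes output class labels.
#' @exportClass LayerPlan
setClass("LayerPlan",
  representation(spec = "ModelSpec", layers = "list", inputShape = "numeric",
                 classes = "character"))

setMethod("show", "LayerPlan", function(object) {
  cat(sprintf("LayerPlan for %s+%s on %dx%d input; %d layers, %d parameters\n",
              object@spec@variant, object@spec@head, object@inputShape[1],
              object@inputShape[2], length(object@layers), weightCount(object)))
  sh <- outputShape(object)
  for (i in seq_along(object@layers)) {
    l <- object@layers[[i]]
    cat(sprintf("  %2d %-12s -> %s\n", i, l$type,
                paste(sh[[i + 1L]], collapse = "x")))
  }
})

#' TrainedModel: a LayerPlan plus fitted parameters
#'
#' @slot plan the [LayerPlan-class].
#' @slot params named list of numeric parameter arrays.
#' @slot classes class labels in output order.
#' @slot scaled whether the model was trained on max-abs-scaled windows.
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(plan = "LayerPlan", params = "list", classes = "character",
                 scaled = "logical"))

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel (%s+%s): %d parameters, classes: %s%s\n",
              object@plan@spec@variant, object@plan@spec@head,
              sum(vapply(object@params, length, 1L)),
              paste(object@classes, collapse = ", "),
              if (object@scaled) " [expects scaled windows]" else ""))
})

#' GateModel: binary low/high activity gate
#'
#' A threshold on a statistic of the per-timestep accelerometer-norm of a
#' window. Windows with metric value strictly above the threshold are routed
#' to the movement classifier; others are labeled low activity.
#'
#' @slot metric one of \code{mean, std, cv, iqr, range}.
#' @slot threshold decision threshold, in the metric's units (g).
#' @slot f1 F1 score attained on the fitting data.
#' @exportClass GateModel
setClass("GateModel",
  representation(metric = "character", threshold = "numeric", f1 = "numeric"))

setValidity("GateModel", function(object) {
  if (!(object@metric %in% c("mean", "std", "cv", "iqr", "range")))
    return("unknown gate metric")
  if (length(object@threshold) != 1L || object@threshold <= 0)
    return("threshold must be a single positive number")
  TRUE
})

#' Construct a GateModel directly
#'
#' Usually produced by [fitGate()]; direct construction supports documented
#' presets.
#' @param metric gate statistic (default \code{"std"}).
#' @param threshold decision threshold (> 0).
#' @param f1 optional F1 attained when the threshold was chosen.
#' @return A [GateModel-class].
#' @export
gateModel <- function(metric = "std", threshold, f1 = NA_real_)
  new("GateModel", metric = metric, threshold = threshold, f1 = f1)

setMethod("show", "GateModel", function(object) {
  cat(sprintf("GateModel: %s of accel-norm > %.4g => high activity (fit F1 %s)\n",
              object@metric, object@threshold,
              ifelse(is.na(object@f1), "NA", sprintf("%.3f", object@f1))))
})

#' Timeline: per-timestep label and confidence
#'
#' Working state of the sliding-window evaluator: one label and one
#' confidence per timestep of a recording.
#'
#' @slot label character vector, one of the activity classes, \code{low} or
#'   \code{other_high}.
#' @slot confidence numeric vector in [0, 1].
#' @slot sampleRate Hz.
#' @exportClass Timeline
setClass("Timeline",
  representation(label = "character", confidence = "numeric",
                 sampleRate = "numeric"))

setValidity("Timeline", function(object) {
  if (length(object@label) != length(object@confidence))
    return("label and confidence must have the same length")
  if (any(object@confidence < 0 | object@confidence > 1))
    return("confidences must lie in [0, 1]")
  TRUE
})

#' Construct a Timeline
#'
#' @param label per-timestep labels.
#' @param confidence per-timestep confidences in [0, 1].
#' @param sampleRate Hz (default 500).
#' @return A [Timeline-class].
#' @export
Timeline <- function(label, confidence, sampleRate = 500)
  new("Timeline", label = label, confidence = confidence, sampleRate = sampleRate)

#' @describeIn Timeline number of timesteps
#' @param x,object a \code{Timeline}
#' @export
setMethod("length", "Timeline", function(x) length(x@label))

setMethod("show", "Timeline", function(object) {
  cat(sprintf("Timeline: %d timesteps @ %g Hz\n", length(object@label),
              object@sampleRate))
  print(table(object@label))
})

#' @rdname Timeline-accessors
#' @param x a \code{Timeline}
#' @return \code{timelineLabels}: character vector; \code{timelineConfidence}:
#'   numeric vector.
#' @export
timelineLabels <- function(x) x@label

#' Timeline accessors
#' @name Timeline-accessors
#' @rdname Timeline-accessors
#' @export
timelineConfidence <- function(x) x@confidence
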
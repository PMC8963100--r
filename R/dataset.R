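# Windowed dataset construction: segmentation, max-abs scaling,
# undersampling balance, random-subsampling splits, handcrafted features.

#' Segmentation parameters
#'
#' @param window window length in timesteps (500 = 1 s at 500 Hz).
#' @param overlap fractional overlap between consecutive training windows
#'   (default 0.75, i.e. a new window every 125 timesteps).
#' @return List with \code{window}, \code{overlap} and integer \code{step}.
#' @export
segmentationParams <- function(window = 500L, overlap = 0.75) {
  stopifnot(overlap >= 0, overlap < 1)
  step <- as.integer(round(window * (1 - overlap)))
  stopifnot(step >= 1)
  list(window = as.integer(window), overlap = overlap, step = step)
}

#' Cut 1-second windows from a labeled interval
#'
#' Windows start at \code{interval$start}, advancing by \code{params$step}
#' while the window still fits inside the interval; for an interval of
#' length L this yields \code{floor((L - window)/step) + 1} windows (zero,
#' with a note, when L < window).
#'
#' @param recording a [Recording-class].
#' @param interval one-row data.frame (or list) with \code{start}/\code{end}.
#' @param label label attached to every produced window.
#' @param params a [segmentationParams()] list.
#' @return A [WindowSet-class] (possibly empty).
#' @export
segmentWindows <- function(recording, interval, label,
                           params = segmentationParams()) {
  L <- interval$end - interval$start
  ch <- colnames(recording@series)
  if (L < params$window) {
    message("interval shorter than window (", L, " < ", params$window,
            "); no windows produced")
    return(WindowSet(array(0, c(length(ch), params$window, 0L)),
                     character(), character(), integer(), FALSE, ch))
  }
  starts <- seq(interval$start, interval$end - params$window, by = params$step)
  dat <- array(0, c(length(ch), params$window, length(starts)))
  for (i in seq_along(starts))
    dat[, , i] <- t(recording@series[(starts[i] + 1L):(starts[i] + params$window), ,
                                     drop = FALSE])
  WindowSet(dat, rep(label, length(starts)),
            rep(recordingId(recording), length(starts)),
            as.integer(starts), FALSE, ch)
}

#' Max-abs scaling
#'
#' Divides each channel by the maximum absolute value of the corresponding
#' reference channel, mapping values into \eqn{[-1, 1]} (when the reference
#' contains the input) without shifting zero. An all-zero reference channel
#' leaves the channel at zero. With no explicit reference each window is its
#' own reference; in deployment the reference is a calibration recording.
#'
#' @param x a [WindowSet-class], or a channels x time numeric matrix.
#' @param reference \code{NULL} for self-scaling, a channels x time matrix,
#'   or a [Recording-class] whose series provides per-channel maxima.
#' @return Object of the same type as \code{x}, scaled.
#' @export
maxAbsScale <- function(x, reference = NULL) {
  refMax <- function(m) apply(abs(m), 1L, max)   # channels x time
  scaleMat <- function(m, f) {
    f[f == 0] <- 1                               # defined division: 0 -> 0
    m / f
  }
  if (is(x, "WindowSet")) {
    f <- if (is.null(reference)) NULL
    else if (is(reference, "Recording"))
      refMax(t(reference@series[, x@channels, drop = FALSE]))
    else refMax(reference)
    dat <- x@data
    for (i in seq_len(dim(dat)[3])) {
      mi <- dat[, , i, drop = FALSE]
      dim(mi) <- dim(dat)[1:2]
      fi <- if (is.null(f)) refMax(mi) else f
      dat[, , i] <- scaleMat(mi, fi)
    }
    return(WindowSet(dat, x@label, x@sourceId, x@sourceStart, TRUE, x@channels))
  }
  if (is.matrix(x)) {
    f <- refMax(if (is.null(reference)) x else reference)
    return(scaleMat(x, f))
  }
  # plain numeric series
  r <- if (is.null(reference)) x else reference
  f <- max(abs(r)); if (f == 0) f <- 1
  x / f
}

#' Balance a window set by undersampling
#'
#' Every class present is downsampled, without replacement, to the minority
#' class count; the result is shuffled.
#'
#' @param windows a [WindowSet-class] with at least one window per class.
#' @param seed RNG seed.
#' @return A balanced, shuffled [WindowSet-class].
#' @export
balanceWindows <- function(windows, seed = 1) {
  set.seed(seed %% 2147483647)
  counts <- table(windows@label)
  k <- min(counts)
  keep <- unlist(lapply(names(counts), function(cl) {
    idx <- which(windows@label == cl)
    if (length(idx) > k) sample(idx, k) else idx
  }))
  subsetWindows(windows, sample(keep))
}

#' Split plan for random-subsampling cross-validation
#'
#' @param trainFraction fraction of samples (or recordings) in the train
#'   partition (default 0.70).
#' @param folds number of independent random splits (default 5).
#' @param granularity \code{"recording"} keeps all windows of one source
#'   recording on the same side (no leakage between overlapping windows);
#'   \code{"window"} samples windows directly.
#' @param seed master seed; each fold uses a seed derived from it.
#' @return Validated plan list.
#' @export
splitPlan <- function(trainFraction = 0.7, folds = 5L,
                      granularity = c("recording", "window"), seed = 1) {
  granularity <- match.arg(granularity)
  stopifnot(trainFraction > 0, trainFraction < 1, folds >= 1)
  list(trainFraction = trainFraction, folds = as.integer(folds),
       granularity = granularity, seed = seed)
}

#' Draw one train/test partition
#'
#' Disjoint, exhaustive partition of the windows. At recording granularity
#' the sampled unit is the source recording id.
#'
#' @param windows a [WindowSet-class].
#' @param plan a [splitPlan()].
#' @param fold 0-based fold index, \code{fold < plan$folds}.
#' @return \code{list(train =, test =)} of [WindowSet-class] objects.
#' @export
splitWindows <- function(windows, plan = splitPlan(), fold = 0L) {
  stopifnot(fold >= 0, fold < plan$folds)
  set.seed(.subSeed(plan$seed, fold + 1L))
  n <- length(windows)
  if (plan$granularity == "recording") {
    ids <- unique(windows@sourceId)
    if (length(ids) < 2L)
      stop("split impossible: recording granularity needs >= 2 recordings",
           call. = FALSE)
    k <- max(1L, min(length(ids) - 1L, round(plan$trainFraction * length(ids))))
    trainIds <- sample(ids, k)
    trainIdx <- which(windows@sourceId %in% trainIds)
  } else {
    k <- max(1L, min(n - 1L, round(plan$trainFraction * n)))
    trainIdx <- sample.int(n, k)
  }
  list(train = subsetWindows(windows, sort(trainIdx)),
       test = subsetWindows(windows, sort(setdiff(seq_len(n), trainIdx))))
}

# population central moments based statistics; zero variance -> 0
.skewness <- function(x) {
  m <- mean(x); m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}
.kurtosis <- function(x) {
  m <- mean(x); m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2 - 3
}

#' Handcrafted per-channel window features
#'
#' The nine summary statistics used by the traditional-classifier baselines:
#' mean, median, standard deviation, maximum, minimum, skewness, kurtosis,
#' sum of the real parts of the discrete Fourier coefficients, and their
#' maximum — computed per channel and concatenated in canonical channel
#' order (9 x channels values per window). Skewness and kurtosis of a
#' zero-variance channel are defined as 0.
#'
#' @param x a channels x time matrix, or a [WindowSet-class].
#' @return Named numeric vector (matrix n x features for a WindowSet).
#' @export
handcraftedFeatures <- function(x) {
  if (is(x, "WindowSet")) {
    out <- t(vapply(seq_len(length(x)),
                    function(i) handcraftedFeatures(x@data[, , i]),
                    numeric(9L * length(x@channels))))
    return(out)
  }
  stopifnot(is.matrix(x))
  statNames <- c("mean", "median", "std", "max", "min", "skew", "kurt",
                 "fft_re_sum", "fft_re_max")
  feats <- apply(x, 1L, function(ch) {
    re <- Re(fft(ch))
    c(mean(ch), median(ch), sd(ch), max(ch), min(ch),
      .skewness(ch), .kurtosis(ch), sum(re), max(re))
  })  # 9 x channels
  v <- as.numeric(feats)
  names(v) <- as.vector(outer(statNames, seq_len(nrow(x)),
                              function(s, c) paste0("ch", c, ".", s)))
  v
}

#' Build a labeled window dataset from a synthetic corpus
#'
#' Cuts windows from the ground-truth activity intervals of every recording
#' (low intervals too when \code{"low"} is in \code{labels}), with optional
#' max-abs scaling against the recording itself as calibration reference or
#' against each window.
#'
#' @param corpus list of \code{list(recording, intervals)} as produced by
#'   [synthesizeCorpus()].
#' @param labels which interval labels to keep (default the five activity
#'   classes).
#' @param params [segmentationParams()].
#' @param scale \code{"calibration"} (per-recording reference),
#'   \code{"window"} (self) or \code{"none"}.
#' @param useGyro keep the gyroscope channels (default \code{TRUE}).
#' @return A [WindowSet-class].
#' @export
buildDataset <- function(corpus, labels = activityClasses(),
                         params = segmentationParams(),
                         scale = c("calibration", "window", "none"),
                         useGyro = TRUE) {
  scale <- match.arg(scale)
  sets <- list()
  for (item in corpus) {
    rec <- item$recording
    iv <- item$intervals
    iv <- iv[iv$label %in% labels & (iv$end - iv$start) >= params$window, ,
             drop = FALSE]
    if (nrow(iv) == 0L) next
    ws <- lapply(seq_len(nrow(iv)), function(i)
      segmentWindows(rec, iv[i, ], iv$label[i], params))
    ws <- Filter(function(w) length(w) > 0L, ws)
    if (!length(ws)) next
    w <- bindWindows(ws)
    if (scale == "calibration") w <- maxAbsScale(w, rec)
    else if (scale == "window") w <- maxAbsScale(w)
    sets[[length(sets) + 1L]] <- w
  }
  if (!length(sets)) stop("no windows produced from corpus", call. = FALSE)
  out <- bindWindows(sets)
  if (!useGyro) {
    keep <- grep("\\.accel\\.", out@channels)
    out <- WindowSet(out@data[keep, , , drop = FALSE], out@label,
                     out@sourceId, out@sourceStart, out@scaled,
                     out@channels[keep])
  }
  out
}
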
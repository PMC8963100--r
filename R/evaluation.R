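# Whole-recording inference: a binary low/high gate on a statistic of the
# window's accelerometer norm routes windows either to "low activity" or to
# the movement classifier; sliding-window predictions are reduced to a
# per-timestep timeline by best-score postprocessing, cleaned by
# duration-based outlier removal, and summarized into labeled events.

#' Evaluation configuration
#'
#' @param window window length in timesteps (500, must equal the training
#'   window).
#' @param step sliding step in timesteps; 5--50 (10--100 ms at 500 Hz) is
#'   the recommended range (default 25 = 50 ms).
#' @param confidence softmax confidence below which a high-activity window
#'   is relabeled \code{other_high} (default 0.95).
#' @param tauMs minimum credible event duration in milliseconds for outlier
#'   removal; 100--300 ms is sensible (default 200).
#' @return Validated configuration list.
#' @export
evalConfig <- function(window = 500L, step = 25L, confidence = 0.95,
                       tauMs = 200) {
  stopifnot(step >= 1, step <= window, confidence > 0, confidence < 1,
            tauMs > 0)
  list(window = as.integer(window), step = as.integer(step),
       confidence = confidence, tauMs = tauMs)
}

#' Statistic of a window's accelerometer norm
#'
#' Computes the chosen statistic (mean, standard deviation, coefficient of
#' variation, interquartile range, or range) of the per-timestep Euclidean
#' norm over all accelerometer channels of the window. The coefficient of
#' variation of a zero-mean norm is degenerate and reported as 0.
#'
#' @param window channels x time matrix with canonical channel names, or a
#'   [WindowSet-class] (vectorized over windows).
#' @param metric one of \code{"mean"}, \code{"std"}, \code{"cv"},
#'   \code{"iqr"}, \code{"range"}.
#' @return Numeric value (vector for a WindowSet).
#' @export
windowMetric <- function(window, metric = "std") {
  if (is(window, "WindowSet")) {
    return(vapply(seq_len(length(window)), function(i) {
      m <- window@data[, , i, drop = FALSE]; dim(m) <- dim(window@data)[1:2]
      rownames(m) <- window@channels
      windowMetric(m, metric)
    }, 0))
  }
  acc <- grep("\\.accel\\.", rownames(window))
  if (!length(acc)) stop("window has no accelerometer channels", call. = FALSE)
  n <- sqrt(colSums(window[acc, , drop = FALSE]^2))
  switch(metric,
    mean = mean(n),
    std = sd(n),
    cv = {
      if (mean(n) == 0) { message("zero-mean norm; CV degenerate, returning 0"); 0 }
      else sd(n) / mean(n)
    },
    iqr = .iqr(n),
    range = diff(range(n)),
    stop("unknown gate metric '", metric, "'", call. = FALSE))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum of the absolute difference between the two empirical CDFs;
#' tie-safe.
#'
#' @param a,b non-empty numeric samples.
#' @return Value in [0, 1].
#' @export
ksStatistic <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(p) mean(a <= p), 0)
  Fb <- vapply(pts, function(p) mean(b <= p), 0)
  max(abs(Fa - Fb))
}

#' Fit the binary low/high activity gate
#'
#' Sweeps a fixed grid of candidate thresholds over the observed range of
#' the metric, classifying a window as high activity when its metric value
#' is strictly above the threshold, and returns the threshold maximizing
#' the F1 score (high = positive class); ties break toward the larger
#' threshold.
#'
#' @param highValues,lowValues metric values of high- and low-activity
#'   windows (both non-empty).
#' @param metric the statistic the values were computed with (stored on the
#'   gate; default \code{"std"}).
#' @param gridSize number of candidate thresholds (default 512).
#' @return A [GateModel-class].
#' @export
fitGate <- function(highValues, lowValues, metric = "std", gridSize = 512L) {
  if (!length(highValues) || !length(lowValues))
    stop("fit error: both classes must be represented", call. = FALSE)
  v <- c(highValues, lowValues)
  grid <- seq(min(v), max(v), length.out = gridSize)
  f1 <- vapply(grid, function(thr) {
    tp <- sum(highValues > thr)
    fp <- sum(lowValues > thr)
    fn <- sum(highValues <= thr)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, 0)
  best <- max(f1)
  thr <- grid[max(which(f1 == best))]    # ties -> larger threshold
  gateModel(metric = metric, threshold = thr, f1 = best)
}

# align a channels x time matrix with a model's expected channel count;
# a 15-channel model on a 30-channel window keeps the accelerometer rows
.matchChannels <- function(w, keep) {
  if (nrow(w) == keep) return(w)
  if (keep == 15L && nrow(w) == 30L && !is.null(rownames(w)))
    return(w[grep("\\.accel\\.", rownames(w)), , drop = FALSE])
  stop("incompatible input: window has ", nrow(w), " channels, model expects ",
       keep, call. = FALSE)
}

#' Classify one window through gate and model
#'
#' Gate metric at or below the gate threshold gives \code{low} (confidence
#' 1 by convention, so gate decisions dominate postprocessing). Otherwise
#' the model's softmax is computed; a maximum probability below the
#' confidence threshold yields \code{other_high} carrying that probability,
#' else the argmax class with its probability.
#'
#' @param window channels x time matrix (canonical row names).
#' @param gate a [GateModel-class].
#' @param model a [TrainedModel-class].
#' @param config an [evalConfig()].
#' @param scaler optional function applied to the window before the model
#'   (e.g. calibration max-abs scaling); the gate always sees raw signals.
#' @return List with \code{label} and \code{confidence}.
#' @export
classifyWindow <- function(window, gate, model, config = evalConfig(),
                           scaler = identity) {
  if (windowMetric(window, gate@metric) <= gate@threshold)
    return(list(label = "low", confidence = 1))
  x <- .matchChannels(scaler(window), model@plan@inputShape[1])
  P <- predictProba(model, array(x, c(nrow(x), ncol(x), 1L)))
  p <- max(P)
  if (p < config$confidence) list(label = "other_high", confidence = p)
  else list(label = colnames(P)[which.max(P)], confidence = p)
}

#' Sliding-window prediction over a whole recording
#'
#' Windows start at 0, advancing by \code{config$step} while they fit;
#' each is gated and classified. For efficiency all high-gated windows are
#' batched through the model.
#'
#' @param recording a [Recording-class] with at least \code{window}
#'   timesteps.
#' @param gate a [GateModel-class].
#' @param model a [TrainedModel-class].
#' @param config an [evalConfig()].
#' @param scaler optional function matrix -> matrix applied to windows
#'   before the model (the gate sees raw signals). Use
#'   [calibrationScaler()] for the deployment regime.
#' @return data.frame of window predictions: \code{start}, \code{label},
#'   \code{confidence}, sorted by start.
#' @export
slidingPredict <- function(recording, gate, model, config = evalConfig(),
                           scaler = identity) {
  T <- length(recording)
  if (T < config$window)
    stop("input too short: ", T, " < window ", config$window, call. = FALSE)
  starts <- seq(0L, T - config$window, by = config$step)
  S <- t(recording@series)               # channels x T
  metric <- vapply(starts, function(s)
    windowMetric(S[, (s + 1L):(s + config$window), drop = FALSE],
                 gate@metric), 0)
  label <- rep("low", length(starts))
  conf <- rep(1, length(starts))
  hi <- which(metric > gate@threshold)
  if (length(hi)) {
    keep <- model@plan@inputShape[1]
    arr <- array(0, c(keep, config$window, length(hi)))
    for (k in seq_along(hi)) {
      w <- scaler(S[, (starts[hi[k]] + 1L):(starts[hi[k]] + config$window),
                    drop = FALSE])
      arr[, , k] <- .matchChannels(w, keep)
    }
    P <- predictProba(model, arr)
    pmax_ <- apply(P, 1L, max)
    lab <- colnames(P)[max.col(P)]
    lab[pmax_ < config$confidence] <- "other_high"
    label[hi] <- lab
    conf[hi] <- pmax_
  }
  data.frame(start = starts, label = label, confidence = conf,
             stringsAsFactors = FALSE)
}

#' Per-channel calibration scaler
#'
#' Returns a function that max-abs-scales a channels x time matrix with the
#' per-channel maxima of a calibration recording.
#'
#' @param recording calibration [Recording-class].
#' @return Function matrix -> matrix.
#' @export
calibrationScaler <- function(recording) {
  f <- apply(abs(recording@series), 2L, max)
  f[f == 0] <- 1
  function(w) w / f[rownames(w)]
}

#' Best-score postprocessing: reduce window predictions to a timeline
#'
#' Every timestep takes the (label, confidence) of the highest-confidence
#' window covering it; ties break toward the later-starting window.
#' Timesteps covered by no window (an uncovered tail when the step does not
#' divide the recording length) are labeled \code{low} with confidence 0.
#'
#' @param predictions data.frame from [slidingPredict()], sorted by start.
#' @param T recording length in timesteps.
#' @param window window length.
#' @param sampleRate Hz, recorded on the timeline.
#' @return A [Timeline-class] of length \code{T}.
#' @export
bestScorePostprocess <- function(predictions, T, window = 500L,
                                 sampleRate = 500) {
  stopifnot(!is.unsorted(predictions$start))
  label <- rep("low", T)
  conf <- rep(-1, T)
  for (i in seq_len(nrow(predictions))) {
    s <- predictions$start[i]
    idx <- (s + 1L):min(T, s + window)
    upd <- idx[conf[idx] <= predictions$confidence[i]]  # later window wins ties
    label[upd] <- predictions$label[i]
    conf[upd] <- predictions$confidence[i]
  }
  conf[conf < 0] <- 0                    # uncovered timesteps
  Timeline(label, conf, sampleRate)
}

#' Remove implausibly short predicted runs
#'
#' Maximal constant-label runs shorter than \eqn{\tau} (converted to
#' timesteps) adopt the label of the nearest following run of length at
#' least \eqn{\tau}; with no qualifying successor, the nearest preceding
#' qualifying run. Replaced timesteps take the adopting run's mean
#' confidence. Applied left to right until no sub-threshold run remains; a
#' timeline with no qualifying run at all is returned unchanged with a
#' warning.
#'
#' @param timeline a [Timeline-class].
#' @param tauMs minimum credible duration in milliseconds (default 200).
#' @return A cleaned [Timeline-class].
#' @export
removeOutliers <- function(timeline, tauMs = 200) {
  tau <- as.integer(round(tauMs * timeline@sampleRate / 1000))
  label <- timeline@label
  conf <- timeline@confidence
  maxIter <- 2L * nrow(.runs(label)) + 10L
  for (iter in seq_len(maxIter)) {
    runs <- .runs(label)
    len <- runs$end - runs$start
    if (all(len >= tau) || nrow(runs) == 1L)
      return(Timeline(label, conf, timeline@sampleRate))
    if (!any(len >= tau)) {
      warning("no run reaches tau; timeline returned unchanged", call. = FALSE)
      return(timeline)
    }
    # apply the first replacement that changes a label; a short run already
    # carrying its adopting run's label (with short runs in between) waits
    # for those to be absorbed first
    ok <- which(len >= tau)
    changed <- FALSE
    for (i in which(len < tau)) {
      j <- if (any(ok > i)) min(ok[ok > i]) else max(ok[ok < i])
      if (runs$label[j] == runs$label[i]) next
      span <- (runs$start[i] + 1L):runs$end[i]
      adopt <- (runs$start[j] + 1L):runs$end[j]
      label[span] <- runs$label[j]
      conf[span] <- mean(conf[adopt])
      changed <- TRUE
      break
    }
    if (!changed) break    # every short run already matches its adopter
  }
  Timeline(label, conf, timeline@sampleRate)
}

#' Summarize a timeline into labeled events
#'
#' Maximal constant-label runs become intervals carrying their mean
#' confidence; per-class counts exclude \code{low}.
#'
#' @param timeline a [Timeline-class].
#' @return List with \code{events} (interval table with confidence) and
#'   \code{counts} (named integer vector over non-low labels).
#' @export
summarizeEvents <- function(timeline) {
  runs <- .runs(timeline@label)
  runs$confidence <- vapply(seq_len(nrow(runs)), function(i)
    mean(timeline@confidence[(runs$start[i] + 1L):runs$end[i]]), 0)
  events <- intervalTable(runs$start, runs$end, runs$label, runs$confidence)
  hi <- events$label[events$label != "low"]
  counts <- table(factor(hi, levels = setdiff(.ALL_LABELS, "low")))
  list(events = events, counts = counts)
}

#' Build gate-fitting window metric samples from a corpus
#'
#' Cuts non-overlapping windows from the ground-truth high-activity and
#' low-activity intervals of a corpus and returns the chosen metric values
#' for both groups (raw, unscaled signals).
#'
#' @param corpus list of \code{list(recording, intervals)}.
#' @param metric gate statistic.
#' @param window window length in timesteps.
#' @return List with numeric vectors \code{high} and \code{low}.
#' @export
gateSamples <- function(corpus, metric = "std", window = 500L) {
  params <- segmentationParams(window = window, overlap = 0)
  high <- numeric(); low <- numeric()
  for (item in corpus) {
    iv <- item$intervals
    iv <- iv[(iv$end - iv$start) >= window, , drop = FALSE]
    if (nrow(iv) == 0L) next
    for (i in seq_len(nrow(iv))) {
      w <- segmentWindows(item$recording, iv[i, ], iv$label[i], params)
      if (length(w) == 0L) next
      vals <- windowMetric(w, metric)
      if (iv$label[i] == "low") low <- c(low, vals) else high <- c(high, vals)
    }
  }
  list(high = high, low = low)
}

#' Evaluate a whole recording end to end
#'
#' Sliding-window classification, best-score postprocessing and outlier
#' removal in one call.
#'
#' @param recording a [Recording-class].
#' @param gate a [GateModel-class].
#' @param model a [TrainedModel-class].
#' @param config an [evalConfig()].
#' @param scaler window scaler for the model (see [slidingPredict()]).
#' @return List with \code{predictions} (raw window trace),
#'   \code{postprocessed} ([Timeline-class]), \code{final}
#'   ([Timeline-class]) and \code{summary} (events + counts).
#' @export
evaluateRecording <- function(recording, gate, model, config = evalConfig(),
                              scaler = identity) {
  preds <- slidingPredict(recording, gate, model, config, scaler)
  post <- bestScorePostprocess(preds, length(recording), config$window,
                               sampleRate = recording@sampleRate)
  final <- removeOutliers(post, config$tauMs)
  list(predictions = preds, postprocessed = post, final = final,
       summary = summarizeEvents(final))
}
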
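# Threshold-based activity isolation.
#
# High-activity stretches are found per sensor location from the Euclidean
# norm of the accelerometer triad: a stretch qualifies where the norm stays
# strictly above a mean-based threshold for at least one full block
# (50 timesteps = 0.1 s at 500 Hz). The threshold multiplier depends on the
# recording's movement kind: periodic recordings (jog, sprint) use the mean
# itself, explosive ones (pass, shoot, jump) 1.5 times the mean. The kind is
# decided by the interquartile range of the min-max-normalized global
# accelerometer norm (periodic iff IQR > 0.12). Per-sensor detections are
# combined by interval union.

#' Isolation parameters
#'
#' @param block minimum qualifying run, in timesteps (default 50 = 0.1 s).
#' @param periodicCoef threshold multiplier for periodic recordings (1.0).
#' @param explosiveCoef threshold multiplier for explosive recordings (1.5).
#' @param iqrThreshold IQR cut separating periodic from explosive (0.12).
#' @return List of validated parameters.
#' @export
isolationParams <- function(block = 50L, periodicCoef = 1.0,
                            explosiveCoef = 1.5, iqrThreshold = 0.12) {
  stopifnot(block >= 1, periodicCoef > 0, explosiveCoef > 0,
            iqrThreshold > 0, iqrThreshold < 1)
  list(block = as.integer(block), periodicCoef = periodicCoef,
       explosiveCoef = explosiveCoef, iqrThreshold = iqrThreshold)
}

#' Per-location accelerometer norm
#'
#' Per-timestep Euclidean norm \eqn{\sqrt{x^2+y^2+z^2}} of one location's
#' accelerometer triad.
#'
#' @param recording a [Recording-class].
#' @param location one of \code{pelvis, right_thigh, left_thigh, right_shank,
#'   left_shank}.
#' @return Non-negative numeric vector of length \code{length(recording)}.
#' @export
accelNorm <- function(recording, location) {
  cols <- paste0(location, ".accel.", .AXES)
  miss <- setdiff(cols, colnames(recording@series))
  if (length(miss))
    stop("missing channel: ", miss[1], call. = FALSE)
  sqrt(rowSums(recording@series[, cols, drop = FALSE]^2))
}

#' Global accelerometer norm
#'
#' Per-timestep Euclidean norm of the stacked 15-dimensional accelerometer
#' vector over all five locations.
#'
#' @param recording a [Recording-class].
#' @return Non-negative numeric vector.
#' @export
globalAccelNorm <- function(recording) {
  cols <- .accelColumns(colnames(recording@series))
  sqrt(rowSums(recording@series[, cols, drop = FALSE]^2))
}

#' Classify a recording as periodic or explosive movement
#'
#' Min-max normalizes the global accelerometer norm to [0, 1] and compares
#' its interquartile range against \code{iqrThreshold}: sustained repetitive
#' movement keeps the norm elevated for a sizable fraction of the recording
#' (large IQR), a one-shot burst does not. A constant norm (zero range) is
#' degenerate and reported as explosive.
#'
#' @param recording a [Recording-class].
#' @param iqrThreshold decision threshold on the normalized IQR (default 0.12).
#' @return \code{"periodic"} or \code{"explosive"}.
#' @export
movementKind <- function(recording, iqrThreshold = 0.12) {
  n <- globalAccelNorm(recording)
  rng <- range(n)
  if (diff(rng) == 0) {
    message("constant global norm; movement kind degenerate, returning explosive")
    return("explosive")
  }
  z <- (n - rng[1]) / diff(rng)
  if (.iqr(z) > iqrThreshold) "periodic" else "explosive"
}

# maximal TRUE-runs of length >= block in a logical vector -> (start, end)
.qualifyingRuns <- function(above, block) {
  r <- rle(above)
  end <- cumsum(r$lengths)
  start <- c(0L, head(end, -1L))
  keep <- r$values & r$lengths >= block
  data.frame(start = start[keep], end = end[keep])
}

# union of possibly overlapping intervals; merges adjacency (end == start)
.mergeIntervals <- function(df) {
  if (nrow(df) <= 1L) return(df[order(df$start), , drop = FALSE])
  df <- df[order(df$start, df$end), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in 2:nrow(df)) {
    j <- nrow(out)
    if (df$start[i] <= out$end[j]) out$end[j] <- max(out$end[j], df$end[i])
    else out <- rbind(out, df[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Isolate high-activity intervals in a recording
#'
#' For each sensor location, the accelerometer-norm threshold is
#' \code{coef * mean(norm)} where \code{coef} follows the recording's
#' movement kind. A detection is a maximal run of timesteps with norm
#' strictly above the threshold lasting at least \code{block} timesteps (the
#' run's first timestep is the onset found by the forward block scan; its
#' last is the offset found by the mirrored backward scan). Ties at exactly
#' the threshold count as low activity. Per-location detections are combined
#' by union, merging overlapping or adjacent intervals.
#'
#' @param recording a [Recording-class] of length at least \code{block}.
#' @param params an [isolationParams()] list.
#' @param kind optional override of [movementKind()] (\code{"periodic"} or
#'   \code{"explosive"}); by default the kind is computed once per recording.
#' @return data.frame with 0-based half-open \code{start}/\code{end} columns,
#'   sorted and non-overlapping; zero rows when nothing qualifies.
#' @export
isolateActivities <- function(recording, params = isolationParams(),
                              kind = NULL) {
  T <- length(recording)
  if (T < params$block)
    stop("input too short: ", T, " timesteps < block ", params$block,
         call. = FALSE)
  if (is.null(kind)) kind <- movementKind(recording, params$iqrThreshold)
  coef <- if (kind == "periodic") params$periodicCoef else params$explosiveCoef
  pieces <- lapply(.LOCATIONS, function(loc) {
    n <- accelNorm(recording, loc)
    .qualifyingRuns(n > coef * mean(n), params$block)
  })
  all <- do.call(rbind, pieces)
  if (nrow(all) == 0L)
    return(data.frame(start = integer(), end = integer()))
  .mergeIntervals(all)
}

#' Fraction of ground-truth intervals recovered by detections
#'
#' A ground-truth interval counts as recovered when some detected interval
#' matches both its boundaries within \code{tol} timesteps.
#'
#' @param detected data.frame of detected \code{start}/\code{end}.
#' @param truth data.frame of injected high-activity intervals.
#' @param tol boundary tolerance in timesteps (default 50 = 0.1 s).
#' @return Fraction in [0, 1] (1 for an empty truth set).
#' @export
intervalRecovery <- function(detected, truth, tol = 50L) {
  if (nrow(truth) == 0L) return(1)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(abs(detected$start - truth$start[i]) <= tol &
        abs(detected$end - truth$end[i]) <= tol)
  }, TRUE)
  mean(hit)
}
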
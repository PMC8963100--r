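#' @import methods
#' @importFrom stats quantile rnorm runif sd fft median
#' @importFrom utils head tail
NULL

# Canonical sensor layout ------------------------------------------------

#' Sensor locations, modalities and axes
#'
#' The array carries five body-worn inertial units. The canonical channel
#' order is location-major (in the order below), accelerometer triad before
#' gyroscope triad, axes X, Y, Z — 30 channels with gyroscopes, 15 without.
#'
#' @name channel-layout
#' @keywords internal
NULL

.LOCATIONS <- c("pelvis", "right_thigh", "left_thigh", "right_shank", "left_shank")
.MODALITIES <- c("accel", "gyro")
.AXES <- c("X", "Y", "Z")

.ACTIVITY_CLASSES <- c("jog", "sprint", "pass", "shoot", "jump")
.PERIODIC <- c("jog", "sprint")
.EXPLOSIVE <- c("pass", "shoot", "jump")
.ALL_LABELS <- c(.ACTIVITY_CLASSES, "low", "other_high")

.ACCEL_RANGE <- 16     # g
.GYRO_RANGE <- 2000    # deg/s

#' Canonical channel names
#'
#' @param useGyro include the gyroscope triads (default \code{TRUE}).
#' @return Character vector of channel names of the form
#'   \code{"location.modality.axis"}, in canonical order.
#' @examples
#' canonicalChannels(FALSE)
#' @export
canonicalChannels <- function(useGyro = TRUE) {
  mods <- if (useGyro) .MODALITIES else "accel"
  unlist(lapply(.LOCATIONS, function(loc)
    unlist(lapply(mods, function(m) paste(loc, m, .AXES, sep = ".")))))
}

#' Activity class labels
#'
#' The five trainable movement classes, in the fixed order used by the
#' classifier output layer. \code{"low"} and \code{"other_high"} are
#' pipeline-level labels, not classifier outputs.
#'
#' @return Character vector of length 5.
#' @export
activityClasses <- function() .ACTIVITY_CLASSES

# Channel-name helpers ---------------------------------------------------

.parseChannel <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 3L || !(parts[1] %in% .LOCATIONS) ||
      !(parts[2] %in% .MODALITIES) || !(parts[3] %in% .AXES))
    stop("malformed channel column: '", name, "'", call. = FALSE)
  parts
}

.accelColumns <- function(channels) grep("\\.accel\\.", channels, value = TRUE)

# Interval-table helpers -------------------------------------------------

#' Construct a labeled interval table
#'
#' Intervals are 0-based half-open \code{[start, end)} in timesteps. A table
#' must be sorted by start and non-overlapping.
#'
#' @param start,end integer timestep bounds, \code{0 <= start < end}.
#' @param label activity labels (one of \code{jog, sprint, pass, shoot, jump,
#'   low, other_high}).
#' @param confidence optional per-interval confidence in \code{[0, 1]}.
#' @return \code{data.frame} with columns \code{start}, \code{end},
#'   \code{label} and optionally \code{confidence}.
#' @export
intervalTable <- function(start = integer(), end = integer(),
                          label = character(), confidence = NULL) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   label = as.character(label), stringsAsFactors = FALSE)
  if (!is.null(confidence)) df$confidence <- as.numeric(confidence)
  validateIntervals(df)
  df
}

#' Validate a labeled interval table
#'
#' @param df interval table as from [intervalTable()].
#' @param T optional recording length; when given, checks \code{end <= T}.
#' @return The table, invisibly, or an error.
#' @export
validateIntervals <- function(df, T = NULL) {
  stopifnot(is.data.frame(df), all(c("start", "end", "label") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L) || any(df$end <= df$start))
    stop("intervals must satisfy 0 <= start < end", call. = FALSE)
  if (!is.null(T) && any(df$end > T))
    stop("interval end exceeds recording length ", T, call. = FALSE)
  if (is.unsorted(df$start))
    stop("intervals must be sorted by start", call. = FALSE)
  if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)]))
    stop("intervals must be non-overlapping", call. = FALSE)
  bad <- setdiff(unique(df$label), .ALL_LABELS)
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(df)
}

# Misc -------------------------------------------------------------------

# sub-seed derivation: cheap splitting of a master seed; kept below 2^31
.subSeed <- function(seed, i) (as.numeric(seed) * 48271 + i * 7919) %% 2147483647

.iqr <- function(x) unname(diff(quantile(x, c(0.25, 0.75), names = FALSE, type = 7)))

# run-length encoding of a label vector: data.frame(start, end, label), 0-based
.runs <- function(labels) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  data.frame(start = c(0L, head(end, -1L)), end = end,
             label = r$values, stringsAsFactors = FALSE)
}
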
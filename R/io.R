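# Text I/O for recordings, interval tables and event outputs.
#
# Recording file: comma-separated values, "." decimal. First line is a
# metadata comment "#sample_rate_hz=500"; second line the channel names
# "pelvis.accel.X,...". Event/interval file: CSV with header
# "start_s,end_s,label,confidence".

#' Read a recording from delimited text
#'
#' The file must start with a metadata line \code{#sample_rate_hz=<Hz>}
#' followed by a comma-separated header naming one column per channel as
#' \code{location.modality.axis}. Columns may appear in any order; they are
#' returned in canonical order. Files with only the 15 accelerometer columns
#' yield an accelerometer-only [Recording-class].
#'
#' @param path file path.
#' @param id recording identifier; defaults to the file name.
#' @return A [Recording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- readLines(path, n = 1L)
  if (!grepl("^#sample_rate_hz=", meta))
    stop("format error: first line must be '#sample_rate_hz=<Hz>', got '",
         meta, "'", call. = FALSE)
  rate <- as.numeric(sub("^#sample_rate_hz=", "", meta))
  if (!is.finite(rate) || rate <= 0)
    stop("format error: invalid sample rate in '", meta, "'", call. = FALSE)
  # ragged rows surface as fread errors or discarded-line warnings; both are
  # length errors here (other fread warnings are irrelevant bookkeeping)
  dt <- withCallingHandlers(
    tryCatch(
      data.table::fread(path, skip = 1L, header = TRUE, sep = ",",
                        fill = FALSE, data.table = FALSE),
      error = function(e) stop("length error reading '", path, "': ",
                               conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      if (grepl("[Dd]iscard|[Ss]topped early|fewer|too many", conditionMessage(w)))
        stop("length error reading '", path, "': ", conditionMessage(w),
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  for (nm in names(dt)) .parseChannel(nm)   # format error names the column
  full <- canonicalChannels(TRUE); acc <- canonicalChannels(FALSE)
  want <- if (all(full %in% names(dt))) full else acc
  missing <- setdiff(want, names(dt))
  if (length(missing))
    stop("format error: missing channel column '", missing[1], "'",
         call. = FALSE)
  m <- as.matrix(dt[, want, drop = FALSE])
  .checkRanges(m, path)
  Recording(m, sampleRate = rate, id = id)
}

.checkRanges <- function(m, path) {
  for (nm in colnames(m)) {
    lim <- if (grepl(".accel.", nm, fixed = TRUE)) .ACCEL_RANGE else .GYRO_RANGE
    bad <- which(!is.finite(m[, nm]) | abs(m[, nm]) > lim)
    if (length(bad))
      stop(sprintf("range error in '%s': channel %s, timestep %d (value %s)",
                   path, nm, bad[1] - 1L, format(m[bad[1], nm])),
           call. = FALSE)
  }
}

#' Write a recording to delimited text
#'
#' @param recording a [Recording-class].
#' @param path output file path.
#' @param digits significant digits written (default 7; round-trip agreement
#'   is within this text precision).
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(recording, path, digits = 7) {
  stopifnot(is(recording, "Recording"))
  writeLines(sprintf("#sample_rate_hz=%g", recording@sampleRate), path)
  df <- as.data.frame(signif(recording@series, digits))
  data.table::fwrite(df, path, sep = ",", col.names = TRUE, append = TRUE)
  invisible(path)
}

#' Write labeled intervals / events to CSV
#'
#' Serializes a labeled interval table (timesteps, half-open) as seconds:
#' columns \code{start_s}, \code{end_s}, \code{label}, \code{confidence}.
#'
#' @param intervals interval table from [intervalTable()]; a missing
#'   \code{confidence} column is written as \code{NA}.
#' @param sampleRate Hz used to convert timesteps to seconds.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @seealso [readEvents()]
#' @export
writeEvents <- function(intervals, sampleRate, path) {
  validateIntervals(intervals)
  df <- data.frame(
    start_s = intervals$start / sampleRate,
    end_s = intervals$end / sampleRate,
    label = intervals$label,
    confidence = if ("confidence" %in% names(intervals))
      intervals$confidence else rep(NA_real_, nrow(intervals)))
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

#' Read labeled intervals / events from CSV
#'
#' Inverse of [writeEvents()]: converts seconds back to integer timesteps at
#' \code{sampleRate}.
#'
#' @param path file with header \code{start_s,end_s,label,confidence}.
#' @param sampleRate Hz.
#' @return Interval table (see [intervalTable()]).
#' @export
readEvents <- function(path, sampleRate) {
  df <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    stop("format error: event file needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) return(intervalTable())
  intervalTable(round(df$start_s * sampleRate), round(df$end_s * sampleRate),
                df$label,
                confidence = if ("confidence" %in% names(df))
                  df$confidence else NULL)
}
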
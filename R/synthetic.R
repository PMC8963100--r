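# Synthetic scripted-session generator.
#
# The study's corpus is not public, so training and evaluation run on
# synthetic recordings with the statistical structure the pipeline assumes:
# a low-activity baseline (gravity offset plus small Gaussian noise),
# sustained quasi-sinusoidal gait oscillation for periodic activities (jog,
# sprint) and short high-amplitude bursts localized to class-specific limbs
# for explosive ones (pass, shoot, jump). Oscillations are laid out in
# quadrature on the two horizontal axes so the accelerometer norm stays
# smoothly elevated for the whole labeled interval, as it does over a real
# gait cycle where the limb never stops accelerating.

#' Built-in activity templates
#'
#' One template per movement class: kind (periodic/explosive), duration
#' range in seconds, fundamental frequency in Hz, per-location accelerometer
#' amplitude in g and gyroscope amplitude in deg/s, and the envelope ramp
#' time. Dominant locations are the names of the amplitude vectors: jumps
#' load both shanks and the pelvis; passes and shots one thigh + shank with
#' the shot the stronger and faster of the two.
#'
#' @return Named list of templates.
#' @export
activityTemplates <- function() {
  t <- list(
    jog = list(kind = "periodic", duration = c(5.0, 8.0), freq = 2.5,
               accelAmp = c(pelvis = 0.4, right_thigh = 0.8, left_thigh = 0.8,
                            right_shank = 1.2, left_shank = 1.2),
               gyroAmp = c(pelvis = 40, right_thigh = 90, left_thigh = 90,
                           right_shank = 150, left_shank = 150)),
    sprint = list(kind = "periodic", duration = c(4.0, 7.0), freq = 3.5,
                  accelAmp = c(pelvis = 0.8, right_thigh = 1.6, left_thigh = 1.6,
                               right_shank = 2.5, left_shank = 2.5),
                  gyroAmp = c(pelvis = 80, right_thigh = 180, left_thigh = 180,
                              right_shank = 300, left_shank = 300)),
    pass = list(kind = "explosive", duration = c(1.0, 1.4), freq = 8,
                accelAmp = c(right_thigh = 2.5, right_shank = 3.5),
                gyroAmp = c(right_thigh = 150, right_shank = 250)),
    shoot = list(kind = "explosive", duration = c(1.0, 1.4), freq = 11,
                 accelAmp = c(right_thigh = 5, right_shank = 7),
                 gyroAmp = c(right_thigh = 300, right_shank = 450)),
    jump = list(kind = "explosive", duration = c(1.2, 1.6), freq = 5,
                accelAmp = c(pelvis = 3, right_shank = 5, left_shank = 5),
                gyroAmp = c(pelvis = 120, right_shank = 260, left_shank = 260)))
  for (nm in names(t)) { t[[nm]]$label <- nm; t[[nm]]$ramp <- 0.1 }
  t
}

#' Specify a synthetic corpus
#'
#' The defaults are the package's standard study corpus: 6 subjects with 2
#' scripted sessions each, every session containing each periodic activity
#' once and each explosive activity twice (explosive events are short and
#' yield few windows, so they are scripted more often).
#'
#' @param nSubjects number of simulated subjects.
#' @param recordingsPerSubject recordings per subject.
#' @param grammar character vector of activity labels making up one scripted
#'   session (each preceded and followed by a low-activity gap).
#' @param noiseSd accelerometer noise standard deviation in g (default 0.05).
#' @param gravity gravity offset in g on the vertical (X) accelerometer axis
#'   of every location (default 1).
#' @param lowGapRange range, in seconds, of the low-activity gaps.
#' @param sampleRate Hz (default 500).
#' @param seed master seed; every derived recording seed is a deterministic
#'   function of it and the recording counter.
#' @return A \code{corpusSpec} list.
#' @export
corpusSpec <- function(nSubjects = 6, recordingsPerSubject = 2,
                       grammar = c("jog", "pass", "sprint", "shoot", "jump",
                                   "pass", "shoot", "jump"),
                       noiseSd = 0.05, gravity = 1, lowGapRange = c(3, 5),
                       sampleRate = 500, seed = 1) {
  templates <- activityTemplates()
  bad <- setdiff(grammar, names(templates))
  if (length(bad))
    stop("config error: unknown activity label(s) in grammar: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!length(grammar)) stop("config error: empty grammar", call. = FALSE)
  stopifnot(noiseSd >= 0, sampleRate > 0, lowGapRange[1] >= 1,
            diff(lowGapRange) >= 0)
  structure(list(nSubjects = nSubjects,
                 recordingsPerSubject = recordingsPerSubject,
                 grammar = grammar, noiseSd = noiseSd, gravity = gravity,
                 lowGapRange = lowGapRange, sampleRate = sampleRate,
                 seed = seed, templates = templates),
            class = "corpusSpec")
}

#' Draw a scripted session: alternating low/high intervals
#'
#' Produces the ground-truth interval table of one session: a low-activity
#' gap, then each grammar activity followed by another gap. Activity
#' durations are drawn uniformly from the template's range, gaps from the
#' spec's \code{lowGapRange}; the result exactly tiles \code{[0, T)}.
#'
#' @param spec a [corpusSpec()].
#' @param seed RNG seed (defaults to the spec's).
#' @param subjectFreqMult per-subject frequency multiplier (affects only
#'   durations indirectly; kept for interface symmetry, default 1).
#' @return Interval table with labels \code{low} and the grammar activities.
#' @export
makeScript <- function(spec, seed = spec$seed, subjectFreqMult = 1) {
  set.seed(seed %% 2147483647)
  rate <- spec$sampleRate
  gap <- function() as.integer(round(runif(1, spec$lowGapRange[1],
                                           spec$lowGapRange[2]) * rate))
  starts <- integer(); ends <- integer(); labels <- character()
  cur <- 0L
  push <- function(len, lab) {
    starts <<- c(starts, cur); ends <<- c(ends, cur + len)
    labels <<- c(labels, lab); cur <<- cur + len
  }
  push(gap(), "low")
  for (lab in spec$grammar) {
    tpl <- spec$templates[[lab]]
    dur <- as.integer(round(runif(1, tpl$duration[1], tpl$duration[2]) * rate))
    push(dur, lab)
    push(gap(), "low")
  }
  intervalTable(starts, ends, labels)
}

# envelope over an interval: cosine ramps at both ends, flat plateau between
.envelope <- function(len, rampSteps) {
  e <- rep(1, len)
  r <- min(rampSteps, floor(len / 2))
  if (r > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    e[seq_len(r)] <- up
    e[len + 1L - seq_len(r)] <- up
  }
  e
}

#' Synthesize one recording from a script
#'
#' Low intervals carry the gravity offset plus Gaussian noise. Activity
#' intervals add, on each dominant location, an oscillation in quadrature on
#' the two horizontal accelerometer axes (amplitude-enveloped, with slow
#' amplitude modulation and phase jitter) plus a second-harmonic vertical
#' component; gyroscope channels receive the analogous structure in deg/s.
#' Values beyond the sensor ranges are clipped with a warning.
#'
#' @param script interval table from [makeScript()].
#' @param spec the [corpusSpec()].
#' @param seed RNG seed.
#' @param subjectFactors optional list with \code{ampMult} and
#'   \code{freqMult}; per-subject variability multipliers (default 1).
#' @param id recording identifier.
#' @return A [Recording-class] with 30 channels.
#' @export
synthesizeRecording <- function(script, spec, seed = spec$seed,
                                subjectFactors = list(ampMult = 1, freqMult = 1),
                                id = "synthetic") {
  validateIntervals(script)
  set.seed(seed %% 2147483647)
  T <- max(script$end)
  rate <- spec$sampleRate
  ch <- canonicalChannels(TRUE)
  m <- matrix(rnorm(T * 30L, 0, spec$noiseSd), T, 30L, dimnames = list(NULL, ch))
  gyroNoise <- 40 * spec$noiseSd              # deg/s-scale baseline jitter
  gyrAll <- grep("\\.gyro\\.", ch)
  m[, gyrAll] <- matrix(rnorm(T * length(gyrAll), 0, gyroNoise), T)
  for (loc in .LOCATIONS)
    m[, paste0(loc, ".accel.X")] <- m[, paste0(loc, ".accel.X")] + spec$gravity
  acts <- script[script$label != "low", , drop = FALSE]
  for (k in seq_len(nrow(acts))) {
    tpl <- spec$templates[[acts$label[k]]]
    i0 <- acts$start[k] + 1L; i1 <- acts$end[k]
    len <- i1 - i0 + 1L
    env <- .envelope(len, as.integer(round(tpl$ramp * rate)))
    f <- tpl$freq * subjectFactors$freqMult * runif(1, 0.96, 1.04)
    tt <- seq_len(len) / rate
    # slow phase jitter (random walk, low amplitude) and ~0.7 Hz amp modulation
    phase <- 2 * pi * f * tt + cumsum(rnorm(len, 0, 0.015))
    amod <- 1 + 0.05 * sin(2 * pi * 0.7 * tt + runif(1, 0, 2 * pi))
    for (loc in names(tpl$accelAmp)) {
      A <- tpl$accelAmp[[loc]] * subjectFactors$ampMult * runif(1, 0.95, 1.05)
      ph <- runif(1, 0, 2 * pi)
      ax <- paste0(loc, ".accel.", c("X", "Y", "Z"))
      m[i0:i1, ax[2]] <- m[i0:i1, ax[2]] + A * env * amod * sin(phase + ph)
      m[i0:i1, ax[3]] <- m[i0:i1, ax[3]] + A * env * amod * cos(phase + ph)
      m[i0:i1, ax[1]] <- m[i0:i1, ax[1]] +
        0.3 * A * env * amod * sin(2 * phase + ph)
      G <- tpl$gyroAmp[[loc]] * subjectFactors$ampMult
      gx <- paste0(loc, ".gyro.", c("X", "Y", "Z"))
      m[i0:i1, gx[2]] <- m[i0:i1, gx[2]] + G * env * sin(phase + ph + pi / 3)
      m[i0:i1, gx[3]] <- m[i0:i1, gx[3]] + G * env * cos(phase + ph + pi / 3)
      m[i0:i1, gx[1]] <- m[i0:i1, gx[1]] + 0.3 * G * env * sin(phase + ph)
    }
  }
  accCols <- .accelColumns(ch); gyrCols <- setdiff(ch, accCols)
  nClip <- sum(abs(m[, accCols]) > .ACCEL_RANGE) +
    sum(abs(m[, gyrCols]) > .GYRO_RANGE)
  if (nClip > 0) {
    warning("clipped ", nClip, " sample(s) to sensor range", call. = FALSE)
    m[, accCols] <- pmin(pmax(m[, accCols], -.ACCEL_RANGE), .ACCEL_RANGE)
    m[, gyrCols] <- pmin(pmax(m[, gyrCols], -.GYRO_RANGE), .GYRO_RANGE)
  }
  Recording(m, sampleRate = rate, id = id)
}

#' Synthesize a labeled corpus
#'
#' Draws per-subject amplitude and frequency multipliers once per subject
#' (inter-subject variability), then generates each subject's scripted
#' recordings. Each recording's seed is derived deterministically from the
#' spec seed and a global recording counter, so regeneration with the same
#' spec is bit-identical.
#'
#' @param spec a [corpusSpec()].
#' @return List of \code{list(recording, intervals)} pairs; recording ids
#'   are \code{"S<subject>/R<recording>"}.
#' @export
synthesizeCorpus <- function(spec) {
  out <- vector("list", spec$nSubjects * spec$recordingsPerSubject)
  counter <- 0L
  for (s in seq_len(spec$nSubjects)) {
    set.seed(.subSeed(spec$seed, 1e6 + s))
    factors <- list(ampMult = runif(1, 0.85, 1.15),
                    freqMult = runif(1, 0.92, 1.08))
    for (r in seq_len(spec$recordingsPerSubject)) {
      counter <- counter + 1L
      sd1 <- .subSeed(spec$seed, 2L * counter)
      sd2 <- .subSeed(spec$seed, 2L * counter + 1L)
      script <- makeScript(spec, seed = sd1)
      rec <- synthesizeRecording(script, spec, seed = sd2,
                                 subjectFactors = factors,
                                 id = sprintf("S%d/R%d", s, r))
      out[[counter]] <- list(recording = rec, intervals = script)
    }
  }
  out
}
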
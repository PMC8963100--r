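# Shared fixtures: everything is generated in code at test time.

# a recording whose accelerometer triads are set explicitly; remaining
# channels (and gyros) default to zero
fixtureRecording <- function(T = 1000L, rate = 500, id = "fix",
                             fill = function(m) m) {
  ch <- canonicalChannels(TRUE)
  m <- matrix(0, T, length(ch), dimnames = list(NULL, ch))
  Recording(fill(m), sampleRate = rate, id = id)
}

# recording with a given per-timestep norm on one location (X carries it)
normRecording <- function(values, location = "pelvis", rate = 500) {
  fixtureRecording(length(values), rate, fill = function(m) {
    m[, paste0(location, ".accel.X")] <- values
    m
  })
}

# single-activity corpus spec used across isolation / kind tests
singleActivitySpec <- function(label, seed)
  corpusSpec(nSubjects = 1, recordingsPerSubject = 1, grammar = label,
             seed = seed)

# small labeled corpus for training-flavored tests
smallCorpus <- function(seed = 4, nSubjects = 4, recordingsPerSubject = 2,
                        grammar = c("jog", "pass", "sprint", "shoot", "jump",
                                    "pass", "shoot", "jump")) {
  synthesizeCorpus(corpusSpec(nSubjects = nSubjects,
                              recordingsPerSubject = recordingsPerSubject,
                              grammar = grammar, seed = seed))
}

# brute-force best-score oracle: literal per-timestep maximization
bruteBestScore <- function(predictions, T, window) {
  label <- rep("low", T); conf <- rep(0, T)
  for (t in seq_len(T)) {
    cover <- which(predictions$start < t & t <= predictions$start + window)
    if (!length(cover)) next
    best <- -Inf; pick <- NA
    for (i in cover) {   # later windows listed later; >= keeps the last max
      if (predictions$confidence[i] >= best) { best <- predictions$confidence[i]; pick <- i }
    }
    label[t] <- predictions$label[pick]
    conf[t] <- predictions$confidence[pick]
  }
  list(label = label, confidence = conf)
}

randomPredictions <- function(T, window, step, labels = c("jog", "low", "pass")) {
  starts <- seq(0L, T - window, by = step)
  data.frame(start = starts,
             label = sample(labels, length(starts), replace = TRUE),
             confidence = round(runif(length(starts)), 3),
             stringsAsFactors = FALSE)
}

randomTimeline <- function(T, rate = 500, labels = c("jog", "low", "pass")) {
  # random run-length structure with many short runs
  lab <- character(0)
  while (length(lab) < T)
    lab <- c(lab, rep(sample(labels, 1), sample(c(5, 20, 60, 150, 400), 1)))
  Timeline(lab[seq_len(T)], runif(T), rate)
}
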
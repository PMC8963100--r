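test_that("segment counts match the closed form over an (L, step) grid", {
  spec <- corpusSpec(grammar = "jog", seed = 61)
  rec <- synthesizeRecording(intervalTable(0L, 4000L, "low"), spec, seed = 1)
  for (L in c(499L, 500L, 501L, 999L, 1000L, 1500L, 3210L))
    for (overlap in c(0, 0.5, 0.75, 0.9)) {
      params <- segmentationParams(500L, overlap)
      iv <- list(start = 0L, end = L)
      w <- suppressMessages(segmentWindows(rec, iv, "jog", params))
      expected <- if (L < 500L) 0L else (L - 500L) %/% params$step + 1L
      expect_equal(length(w), expected,
                   info = sprintf("L=%d step=%d", L, params$step))
    }
})

test_that("window matrices carry the right slice and provenance", {
  spec <- corpusSpec(grammar = "jog", seed = 62)
  rec <- synthesizeRecording(intervalTable(0L, 2000L, "low"), spec, seed = 3)
  w <- segmentWindows(rec, list(start = 250L, end = 1500L), "sprint")
  expect_equal(windowLabels(w), rep("sprint", length(w)))
  expect_equal(windowSource(w)$sourceStart, c(250L, 375L, 500L, 625L, 750L,
                                              875L, 1000L))
  expect_equal(windowData(w)[, , 3],
               t(recordingSeries(rec)[501:1000, ]), ignore_attr = TRUE)
})

test_that("maxAbsScale maps extrema to +/-1, fixes zeros, is idempotent", {
  expect_equal(maxAbsScale(c(-4, 2, 0)), c(-1, 0.5, 0))
  expect_equal(maxAbsScale(c(0, 0, 0)), c(0, 0, 0))
  m <- rbind(a = c(-4, 2, 0), b = c(0, 0, 0), c = c(1, -0.5, 0.25))
  s <- maxAbsScale(m)
  expect_equal(s["a", ], c(-1, 0.5, 0), ignore_attr = TRUE)
  expect_equal(s["b", ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(max(abs(s["c", ])), 1)
  # sign pattern preserved
  expect_equal(sign(s), sign(m), ignore_attr = TRUE)
  # idempotent on the already-scaled series
  expect_equal(maxAbsScale(s), s)
})

test_that("maxAbsScale with an external reference bounds values it contains", {
  ref <- matrix(c(-8, 4, 2, -1), 2, 2)
  x <- matrix(c(-4, 2, 8, -0.5), 2, 2)
  s <- maxAbsScale(x, ref)
  expect_equal(s[1, 1], -0.5)
  expect_true(all(abs(s[, 1]) <= 1))
})

test_that("balancing undersamples to the minority class and is seeded", {
  spec <- corpusSpec(grammar = "jog", seed = 63)
  rec <- synthesizeRecording(intervalTable(0L, 3000L, "low"), spec, seed = 5)
  w1 <- segmentWindows(rec, list(start = 0L, end = 1750L), "jog")    # 11
  w2 <- segmentWindows(rec, list(start = 2000L, end = 2999L), "pass") # 4
  w <- bindWindows(list(w1, w2))
  b <- balanceWindows(w, seed = 4)
  expect_equal(unname(table(windowLabels(b))["jog"]),
               unname(table(windowLabels(b))["pass"]))
  expect_equal(length(b), 8L)
  b2 <- balanceWindows(w, seed = 4)
  expect_identical(windowData(b), windowData(b2))
  # already balanced input keeps the multiset
  bb <- balanceWindows(b, seed = 9)
  expect_equal(sort(windowSource(bb)$sourceStart),
               sort(windowSource(b)$sourceStart))
})

test_that("splits are disjoint, exhaustive and leak-free by recording", {
  corpus <- smallCorpus(seed = 64, nSubjects = 3, recordingsPerSubject = 3,
                        grammar = c("jog", "sprint"))
  w <- buildDataset(corpus, scale = "none")
  plan <- splitPlan(0.7, folds = 3, granularity = "recording", seed = 5)
  for (fold in 0:2) {
    sp <- splitWindows(w, plan, fold)
    expect_equal(length(sp$train) + length(sp$test), length(w))
    expect_length(intersect(unique(windowSource(sp$train)$sourceId),
                            unique(windowSource(sp$test)$sourceId)), 0L)
  }
  # distinct folds draw distinct partitions
  s0 <- sort(unique(windowSource(splitWindows(w, plan, 0)$train)$sourceId))
  s1 <- sort(unique(windowSource(splitWindows(w, plan, 1)$train)$sourceId))
  s2 <- sort(unique(windowSource(splitWindows(w, plan, 2)$train)$sourceId))
  expect_false(identical(s0, s1) && identical(s1, s2))
  # window granularity honors the 70/30 count
  wp <- splitPlan(0.7, folds = 1, granularity = "window", seed = 6)
  sp <- splitWindows(w, wp, 0)
  expect_equal(length(sp$train), round(0.7 * length(w)))
})

test_that("a single recording cannot be split at recording granularity", {
  corpus <- smallCorpus(seed = 65, nSubjects = 1, recordingsPerSubject = 1,
                        grammar = "jog")
  w <- buildDataset(corpus, scale = "none")
  expect_error(splitWindows(w, splitPlan(granularity = "recording"), 0),
               "split impossible")
})

test_that("handcrafted features match direct moment computations", {
  m <- matrix(0, 2, 4, dimnames = list(c("pelvis.accel.X", "pelvis.accel.Y"),
                                       NULL))
  m[1, ] <- c(1, 2, 3, 4)
  m[2, ] <- 5                    # constant channel
  f <- handcraftedFeatures(m)
  expect_length(f, 18L)
  expect_equal(unname(f["ch1.mean"]), 2.5)
  expect_equal(unname(f["ch1.median"]), 2.5)
  expect_equal(unname(f["ch1.std"]), sd(1:4))
  expect_equal(unname(f["ch1.max"]), 4)
  expect_equal(unname(f["ch1.min"]), 1)
  x <- 1:4; mu <- mean(x)
  expect_equal(unname(f["ch1.skew"]),
               mean((x - mu)^3) / mean((x - mu)^2)^1.5)
  expect_equal(unname(f["ch1.kurt"]),
               mean((x - mu)^4) / mean((x - mu)^2)^2 - 3)
  expect_equal(unname(f["ch1.fft_re_sum"]), sum(Re(fft(x))))
  expect_equal(unname(f["ch1.fft_re_max"]), max(Re(fft(x))))
  # degenerate constant channel
  expect_equal(unname(f["ch2.mean"]), 5)
  expect_equal(unname(f["ch2.std"]), 0)
  expect_equal(unname(f["ch2.skew"]), 0)
  expect_equal(unname(f["ch2.kurt"]), 0)
})

test_that("handcrafted moments agree with the e1071 oracle", {
  skip_if_not_installed("e1071")
  set.seed(8)
  x <- rnorm(128)
  m <- matrix(x, 1, 128, dimnames = list("pelvis.accel.X", NULL))
  f <- handcraftedFeatures(m)
  expect_equal(unname(f["ch1.skew"]), e1071::skewness(x, type = 1))
  expect_equal(unname(f["ch1.kurt"]), e1071::kurtosis(x, type = 1))
})

test_that("feature vectors have 9 x channel-count entries", {
  corpus <- smallCorpus(seed = 66, nSubjects = 1, recordingsPerSubject = 1,
                        grammar = "jog")
  w <- buildDataset(corpus, scale = "none")
  F <- handcraftedFeatures(subsetWindows(w, 1:2))
  expect_equal(dim(F), c(2L, 9L * 30L))
})

test_that("calibration-scaled datasets stay within [-1, 1]", {
  corpus <- smallCorpus(seed = 67, nSubjects = 1, recordingsPerSubject = 2,
                        grammar = c("jog", "shoot"))
  w <- buildDataset(corpus, scale = "calibration")
  expect_true(w@scaled)
  expect_lte(max(abs(windowData(w))), 1)
  wn <- buildDataset(corpus, scale = "none", useGyro = FALSE)
  expect_equal(dim(windowData(wn))[1], 15L)
})
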
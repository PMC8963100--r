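test_that("window metrics match direct formulas on the accel norm", {
  m <- matrix(0, 30, 5, dimnames = list(canonicalChannels(TRUE), NULL))
  m["pelvis.accel.X", ] <- c(1, 2, 3, 4, 5)
  expect_equal(windowMetric(m, "mean"), 3)
  expect_equal(windowMetric(m, "std"), sd(1:5))
  expect_equal(windowMetric(m, "cv"), sd(1:5) / 3)
  expect_equal(windowMetric(m, "iqr"),
               unname(diff(quantile(1:5, c(.25, .75)))))
  expect_equal(windowMetric(m, "range"), 4)
  # degenerate cases
  z <- matrix(0, 30, 4, dimnames = list(canonicalChannels(TRUE), NULL))
  expect_equal(windowMetric(z, "std"), 0)
  expect_equal(windowMetric(z, "range"), 0)
  expect_message(cv <- windowMetric(z, "cv"), "degenerate")
  expect_equal(cv, 0)
  alt <- z; alt["pelvis.accel.X", ] <- c(0, 10, 0, 10)
  expect_equal(windowMetric(alt, "range"), 10)
})

test_that("the KS statistic matches hand counts and the stats oracle", {
  expect_equal(ksStatistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ksStatistic(c(1, 2), c(10, 11)), 1)
  expect_equal(ksStatistic(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  expect_error(ksStatistic(numeric(), 1), "empty")
  set.seed(10)
  a <- rnorm(40); b <- rnorm(35, 0.6)
  expect_equal(ksStatistic(a, b),
               unname(suppressWarnings(stats::ks.test(a, b)$statistic)))
})

test_that("the gate threshold maximizes F1 with ties toward the larger value", {
  g <- fitGate(c(5, 6, 7), c(1, 1.5, 2), metric = "std")
  expect_equal(g@f1, 1)
  expect_gte(g@threshold, 2)   # perfectly separable: largest F1=1 threshold
  expect_lt(g@threshold, 5)
  # swapping the roles changes the fitted threshold/F1 accordingly
  g2 <- fitGate(c(1, 1.5, 2), c(5, 6, 7), metric = "std")
  expect_lt(g2@f1, 1)          # high class no longer separable from above
  expect_error(fitGate(numeric(), c(1, 2)), "fit error")
  # brute-force F1 check on an overlapping fixture
  set.seed(11)
  hi <- rnorm(50, 3); lo <- rnorm(50, 1)
  g3 <- fitGate(hi, lo)
  f1At <- function(thr) {
    tp <- sum(hi > thr); fp <- sum(lo > thr); fn <- sum(hi <= thr)
    if (tp == 0) 0 else {
      p <- tp / (tp + fp); r <- tp / (tp + fn); 2 * p * r / (p + r)
    }
  }
  grid <- seq(min(c(hi, lo)), max(c(hi, lo)), length.out = 512)
  expect_equal(g3@f1, max(vapply(grid, f1At, 0)))
})

test_that("classifyWindow follows the gate/confidence routing rules", {
  gate <- gateModel("std", threshold = 0.5)
  model <- buildModel(buildPlan(modelSpec("c1d_share", "none",
                                          useGyro = FALSE,
                                          widthScale = 0.25)), seed = 1)
  zero <- matrix(0, 15, 500, dimnames = list(canonicalChannels(FALSE), NULL))
  expect_equal(classifyWindow(zero, gate, model)$label, "low")
  expect_equal(classifyWindow(zero, gate, model)$confidence, 1)
  # an untrained model is diffuse -> confident-threshold rejection
  set.seed(2)
  noisy <- matrix(rnorm(15 * 500, 0, 3), 15, 500,
                  dimnames = list(canonicalChannels(FALSE), NULL))
  out <- classifyWindow(noisy, gate, model, evalConfig(confidence = 0.95))
  expect_equal(out$label, "other_high")
  expect_lt(out$confidence, 0.95)
  # with a permissive confidence threshold the argmax class is returned
  out2 <- classifyWindow(noisy, gate, model, evalConfig(confidence = 1e-6))
  expect_true(out2$label %in% activityClasses())
})

test_that("sliding predictions cover the recording at the configured step", {
  spec <- corpusSpec(grammar = "jog", seed = 101)
  rec <- synthesizeRecording(intervalTable(0L, 1000L, "low"), spec, seed = 1)
  gate <- gateModel("std", threshold = 1e6)  # everything low
  model <- buildModel(buildPlan(modelSpec("c1d_share", "none",
                                          widthScale = 0.25)), seed = 1)
  preds <- slidingPredict(rec, gate, model, evalConfig(step = 50L))
  expect_equal(nrow(preds), (1000 - 500) %/% 50 + 1)
  expect_equal(preds$start, seq(0L, 500L, by = 50L))
  expect_true(all(preds$label == "low"))
  expect_true(all(diff(preds$start) == 50L))
  expect_error(slidingPredict(
    synthesizeRecording(intervalTable(0L, 300L, "low"), spec, seed = 2),
    gate, model, evalConfig()), "too short")
})

test_that("best-score postprocessing equals the brute-force oracle", {
  # worked two-window example
  preds <- data.frame(start = c(0L, 2L), label = c("jog", "pass"),
                      confidence = c(0.7, 0.9))
  tl <- bestScorePostprocess(preds, 6L, window = 4L)
  expect_equal(timelineLabels(tl), c("jog", "jog", "pass", "pass", "pass", "pass"))
  expect_equal(timelineConfidence(tl), c(.7, .7, .9, .9, .9, .9))
  # a single window labels exactly its span
  one <- data.frame(start = 2L, label = "jump", confidence = 0.8)
  tl1 <- bestScorePostprocess(one, 8L, window = 3L)
  expect_equal(timelineLabels(tl1), c("low", "low", "jump", "jump", "jump",
                                      "low", "low", "low"))
  expect_equal(timelineConfidence(tl1)[1], 0)
  # randomized equivalence against the literal per-timestep maximization
  set.seed(12)
  for (rep in 1:25) {
    T <- sample(40:120, 1); window <- sample(5:20, 1)
    step <- sample(1:window, 1)
    preds <- randomPredictions(T, window, step)
    tl <- bestScorePostprocess(preds, T, window)
    oracle <- bruteBestScore(preds, T, window)
    expect_identical(timelineLabels(tl), oracle$label)
    expect_equal(timelineConfidence(tl), oracle$confidence)
  }
})

test_that("outlier removal adopts the next long run and reaches a fixpoint", {
  rate <- 500
  # 50 A then 200 B, tau = 150 ms (75 steps): A adopts B
  tl <- Timeline(c(rep("jog", 50), rep("pass", 200)),
                 c(rep(0.6, 50), rep(0.9, 200)), rate)
  out <- removeOutliers(tl, 150)
  expect_equal(unique(timelineLabels(out)), "pass")
  expect_equal(timelineConfidence(out)[1], 0.9)
  # all runs long: identity
  tl2 <- Timeline(rep(c("jog", "low"), each = 150), runif(300), rate)
  expect_identical(timelineLabels(removeOutliers(tl2, 200)),
                   timelineLabels(tl2))
  # trailing short run with no successor adopts its predecessor
  tl3 <- Timeline(c(rep("low", 300), rep("shoot", 30)), runif(330), rate)
  out3 <- removeOutliers(tl3, 200)
  expect_equal(unique(timelineLabels(out3)), "low")
  # no qualifying run at all: unchanged with a warning
  tl4 <- Timeline(rep(c("jog", "low"), each = 20), runif(40), rate)
  expect_warning(out4 <- removeOutliers(tl4, 200), "unchanged")
  expect_identical(timelineLabels(out4), timelineLabels(tl4))
})

test_that("no sub-tau run survives outlier removal on random timelines", {
  set.seed(13)
  for (rep in 1:40) {
    tauMs <- sample(c(100, 200, 300), 1)
    tl <- randomTimeline(sample(800:2000, 1))
    out <- suppressWarnings(removeOutliers(tl, tauMs))
    runs <- kinegram:::.runs(timelineLabels(out))
    tau <- round(tauMs * 500 / 1000)
    if (nrow(runs) > 1L) expect_true(all(runs$end - runs$start >= tau))
  }
})

test_that("summarized events tile the timeline and count non-low runs", {
  tl <- Timeline(c(rep("low", 100), rep("jog", 200), rep("low", 50),
                   rep("jog", 80)), runif(430), 500)
  s <- summarizeEvents(tl)
  expect_equal(unname(s$counts["jog"]), 2L)
  expect_equal(sum(s$counts), 2L)
  expect_equal(s$events$start[1], 0L)
  expect_equal(max(s$events$end), 430L)
  expect_equal(s$events$start[-1], s$events$end[-nrow(s$events)])
  # all-low timeline: zero counts
  s0 <- summarizeEvents(Timeline(rep("low", 100), runif(100), 500))
  expect_equal(sum(s0$counts), 0L)
})

test_that("raising the gate threshold never converts low to high", {
  spec <- corpusSpec(grammar = "jog", seed = 102)
  rec <- synthesizeRecording(makeScript(spec, seed = 4), spec, seed = 5)
  model <- buildModel(buildPlan(modelSpec("c1d_share", "none",
                                          widthScale = 0.25)), seed = 1)
  cfg <- evalConfig(step = 125L)
  lowAt <- function(thr) {
    p <- slidingPredict(rec, gateModel("std", thr), model, cfg)
    p$label == "low"
  }
  l1 <- lowAt(0.1); l2 <- lowAt(0.4); l3 <- lowAt(2)
  expect_true(all(l2[l1]))   # low stays low as the threshold rises
  expect_true(all(l3[l2]))
})
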
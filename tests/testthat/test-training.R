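test_that("learning-rate schedules follow a0 * r^floor(epoch/10)", {
  expect_equal(lrSchedule("cnn_only", 0), 1e-3)
  expect_equal(lrSchedule("cnn_only", 9), 1e-3)
  expect_equal(lrSchedule("cnn_only", 10), 7.5e-4)
  expect_equal(lrSchedule("cnn_only", 20), 5.625e-4)
  expect_equal(lrSchedule("rnn_only", 0), 1e-4)
  expect_equal(lrSchedule("rnn_only", 10), 5e-5)
  expect_equal(lrSchedule("cnn_rnn", 0), 5e-5)
  expect_equal(lrSchedule("cnn_rnn", 10), 3.75e-5)
  # scaled inputs raise the initial rate tenfold
  expect_equal(lrSchedule("cnn_only", 0, normalized = TRUE), 1e-2)
  expect_error(lrSchedule("bogus", 0), "config error")
  # piecewise constant, non-increasing
  for (fam in c("cnn_only", "rnn_only", "cnn_rnn")) {
    lrs <- vapply(0:60, function(e) lrSchedule(fam, e), 0)
    expect_true(all(diff(lrs) <= 0))
    expect_equal(length(unique(lrs)), 7L)
  }
})

test_that("schedule family follows the model composition", {
  expect_equal(scheduleFamily(modelSpec("c1d_share", "none")), "cnn_only")
  expect_equal(scheduleFamily(modelSpec("none", "blstm")), "rnn_only")
  expect_equal(scheduleFamily(modelSpec("c2d_all", "lstm")), "cnn_rnn")
})

test_that("early stopping halts exactly at the first 5-epoch stale streak", {
  expect_equal(earlyStopEpoch(c(1.0, .9, .91, .92, .93, .94, .95)), 7L)
  # strictly decreasing: never triggers
  expect_equal(earlyStopEpoch(seq(1, 0.01, length.out = 200)), 200L)
  # improvement resets the streak: 5 stale epochs after the reset
  expect_equal(earlyStopEpoch(c(1, 1.1, 1.1, 1.1, 0.5, 1, 1, 1, 1, 1)), 10L)
  # sub-tolerance decreases do not count as improvement
  expect_equal(earlyStopEpoch(c(1, 1 - 1e-9, 1 - 2e-9, 1 - 3e-9, 1 - 4e-9,
                                1 - 5e-9)), 6L)
})

test_that("a separable two-class toy problem trains to high accuracy", {
  # two classes distinguished by a strong low- vs high-frequency signature
  set.seed(90)
  mk <- function(freq, n, label) {
    dat <- array(0, c(15, 500, n))
    tt <- (1:500) / 500
    for (i in seq_len(n))
      dat[, , i] <- matrix(rep(sin(2 * pi * freq * tt + runif(1, 0, 6)), each = 15),
                           15) + rnorm(15 * 500, 0, 0.3)
    kinegram:::WindowSet(dat, rep(label, n), rep(paste0("r", label), n),
                         integer(n), TRUE, canonicalChannels(FALSE))
  }
  train <- bindWindows(list(mk(2, 16, "jog"), mk(12, 16, "shoot")))
  test <- bindWindows(list(mk(2, 8, "jog"), mk(12, 8, "shoot")))
  fit <- trainModel(modelSpec("c1d_share", "none", useGyro = FALSE,
                              widthScale = 0.25, dropout = 0.2),
                    train, test,
                    trainConfig(batch = 8, maxEpochs = 25, seed = 1))
  expect_gte(fit$testAcc, 0.95)
  expect_lte(fit$stoppedEpoch, 25L)
  expect_equal(nrow(fit$history), fit$stoppedEpoch)
})

test_that("training is deterministic for identical seeds and data", {
  set.seed(91)
  dat <- array(rnorm(15 * 500 * 16), c(15, 500, 16))
  w <- kinegram:::WindowSet(dat, rep(c("jog", "pass"), 8), rep(c("a", "b"), 8),
                            integer(16), TRUE, canonicalChannels(FALSE))
  cfg <- trainConfig(batch = 8, maxEpochs = 3, seed = 5)
  spec <- modelSpec("c2d_share", "lstm", useGyro = FALSE, widthScale = 0.125)
  f1 <- trainModel(spec, w, w, cfg)
  f2 <- trainModel(spec, w, w, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@params, f2$model@params)
})

test_that("single-fold protocols report zero spread", {
  corpus <- smallCorpus(seed = 92, nSubjects = 3, recordingsPerSubject = 2,
                        grammar = c("jog", "shoot"))
  w <- buildDataset(corpus, scale = "calibration")
  r <- runProtocol(modelSpec("c1d_share", "none", widthScale = 0.125),
                   w, splitPlan(folds = 1, seed = 2),
                   trainConfig(maxEpochs = 3, seed = 3))
  expect_equal(r$sdTestAcc, 0)
  expect_equal(nrow(r$folds), 1L)
  expect_equal(sum(r$confusion), length(balanceWindows(
    splitWindows(w, splitPlan(folds = 1, seed = 2), 0)$test, 1)))
})

test_that("confusion kinds are partitioned correctly", {
  cm <- matrix(0, 5, 5, dimnames = list(activityClasses(), activityClasses()))
  cm["jog", "sprint"] <- 3     # within periodic
  cm["pass", "jump"] <- 2      # within explosive
  cm["jog", "shoot"] <- 1      # cross
  diag(cm) <- 10
  ck <- confusionKinds(cm)
  expect_equal(ck$within, 5)
  expect_equal(ck$cross, 1)
})

test_that("empty partitions are a data error", {
  set.seed(93)
  dat <- array(rnorm(15 * 500 * 4), c(15, 500, 4))
  w <- kinegram:::WindowSet(dat, rep("jog", 4), rep("a", 4), integer(4),
                            TRUE, canonicalChannels(FALSE))
  empty <- subsetWindows(w, integer(0))
  expect_error(trainModel(modelSpec("c1d_share", "none"), empty, w), "data error")
})
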
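# Optimization protocol: ADAM (beta1 0.9, beta2 0.999, eps 1e-8) on
# categorical cross-entropy, batches of 32, at most 200 epochs, early
# stopping when the validation loss fails to decrease for 5 consecutive
# epochs, with a staged learning-rate schedule per model family.

#' Training configuration
#'
#' @param batch mini-batch size (default 32).
#' @param maxEpochs epoch cap (default 200).
#' @param patience consecutive non-improving epochs tolerated before the
#'   halt (default 5).
#' @param tol improvement tolerance: a validation loss counts as improved
#'   when it decreases by more than \code{tol} (default 1e-6).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return Validated configuration list.
#' @export
trainConfig <- function(batch = 32L, maxEpochs = 200L, patience = 5L,
                        tol = 1e-6, seed = 1) {
  stopifnot(batch >= 1, patience >= 1, maxEpochs >= 1)
  list(batch = as.integer(batch), maxEpochs = as.integer(maxEpochs),
       patience = as.integer(patience), tol = tol, seed = seed)
}

#' Staged learning-rate schedule
#'
#' Convolution-only models start at 1e-3 and decay to 75\% every 10 epochs;
#' recurrent-only models start at 1e-4 with 50\% decay; combined
#' convolution+recurrent models start at 5e-5 with 75\% decay. When the
#' inputs are max-abs scaled the initial rate is multiplied by 10 (the
#' signals' absolute values are an order of magnitude smaller).
#'
#' @param family \code{"cnn_only"}, \code{"rnn_only"} or \code{"cnn_rnn"}.
#' @param epoch 0-based epoch index.
#' @param normalized whether inputs are scaled (multiplies the initial rate
#'   by 10).
#' @return Learning rate \eqn{\alpha_0 r^{\lfloor epoch/10 \rfloor}}.
#' @export
lrSchedule <- function(family, epoch, normalized = FALSE) {
  stopifnot(epoch >= 0)
  sched <- switch(family,
    cnn_only = c(1e-3, 0.75),
    rnn_only = c(1e-4, 0.50),
    cnn_rnn = c(5e-5, 0.75),
    stop("config error: unknown schedule family '", family, "'", call. = FALSE))
  a0 <- sched[1] * if (normalized) 10 else 1
  a0 * sched[2]^(epoch %/% 10)
}

#' Schedule family implied by a model spec
#' @param spec a [modelSpec()].
#' @return \code{"cnn_only"}, \code{"rnn_only"} or \code{"cnn_rnn"}.
#' @export
scheduleFamily <- function(spec) {
  if (spec@variant == "none") "rnn_only"
  else if (spec@head == "none") "cnn_only"
  else "cnn_rnn"
}

#' Epoch at which early stopping halts
#'
#' Scans a validation-loss sequence and returns how many epochs training
#' runs before the first streak of \code{patience} consecutive epochs
#' without improvement (a loss improves when it is more than \code{tol}
#' below the best seen so far), or \code{length(valLosses)} if the streak
#' never occurs.
#'
#' @param valLosses per-epoch validation losses.
#' @param patience streak length (default 5).
#' @param tol improvement tolerance (default 1e-6).
#' @return Number of epochs run.
#' @export
earlyStopEpoch <- function(valLosses, patience = 5L, tol = 1e-6) {
  best <- Inf; streak <- 0L
  for (e in seq_along(valLosses)) {
    if (valLosses[e] < best - tol) { best <- valLosses[e]; streak <- 0L }
    else {
      streak <- streak + 1L
      if (streak >= patience) return(e)
    }
  }
  length(valLosses)
}

.labelsToIdx <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx))
    stop("data error: labels outside model classes: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  idx
}

.datasetLoss <- function(layers, params, X, y, batch) {
  n <- dim(X)[4]
  loss <- 0; correct <- 0L
  for (s in seq(1L, n, by = batch)) {
    e <- min(n, s + batch - 1L)
    out <- .forwardLayers(layers, X[, , , s:e, drop = FALSE], params,
                          training = FALSE)$out
    r <- .softmaxCE(out, y[s:e])
    loss <- loss + r$loss * (e - s + 1L)
    correct <- correct + sum(max.col(t(r$P)) == y[s:e])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train a model on a train/test partition
#'
#' Minimizes categorical cross-entropy with ADAM under the staged
#' learning-rate schedule of the model's family; monitors the loss on the
#' \code{test} partition and halts at the first \code{patience}-epoch
#' non-improving streak or at \code{maxEpochs}. The test partition doubles
#' as the early-stopping validation set (no third split); last-epoch
#' weights are returned. Identical seeds and data give identical results on
#' one platform.
#'
#' @param spec a [modelSpec()] (a fresh model is initialized from it).
#' @param train,test [WindowSet-class] partitions.
#' @param config a [trainConfig()].
#' @param window window length in timesteps.
#' @return List with \code{model} ([TrainedModel-class]), \code{history}
#'   (per-epoch train/validation loss and validation accuracy),
#'   \code{stoppedEpoch}, \code{trainAcc}, \code{testAcc}.
#' @export
trainModel <- function(spec, train, test, config = trainConfig(),
                       window = dim(windowData(train))[2]) {
  if (length(train) == 0L || length(test) == 0L)
    stop("data error: empty train or test partition", call. = FALSE)
  if (any(table(windowLabels(train)) == 0L))
    stop("data error: empty class in train set", call. = FALSE)
  plan <- buildPlan(spec, window = window)
  model <- buildModel(plan, seed = config$seed, scaled = train@scaled)
  family <- scheduleFamily(spec)
  layers <- plan@layers
  params <- model@params
  Xtr <- .asInput(train); ytr <- .labelsToIdx(windowLabels(train), plan@classes)
  Xte <- .asInput(test); yte <- .labelsToIdx(windowLabels(test), plan@classes)
  if (dim(Xtr)[2] != plan@inputShape[1])
    stop("incompatible input: windows have ", dim(Xtr)[2],
         " channels, model expects ", plan@inputShape[1], call. = FALSE)
  n <- dim(Xtr)[4]
  state <- .adamInit(params)
  set.seed(.subSeed(config$seed, 17L))
  hist <- data.frame(epoch = integer(), trainLoss = numeric(),
                     valLoss = numeric(), valAcc = numeric())
  best <- Inf; streak <- 0L
  for (epoch in seq_len(config$maxEpochs)) {
    lr <- lrSchedule(family, epoch - 1L, normalized = model@scaled)
    ord <- sample.int(n)
    epochLoss <- 0
    for (s in seq(1L, n, by = config$batch)) {
      idx <- ord[s:min(n, s + config$batch - 1L)]
      fw <- .forwardLayers(layers, Xtr[, , , idx, drop = FALSE], params,
                           training = TRUE)
      r <- .softmaxCE(fw$out, ytr[idx])
      epochLoss <- epochLoss + r$loss * length(idx)
      bw <- .backwardLayers(layers, fw$caches, r$dZ, params)
      upd <- .adamStep(params, bw$grads, state, lr)
      params <- upd$params; state <- upd$state
    }
    val <- .datasetLoss(layers, params, Xte, yte, config$batch)
    hist <- rbind(hist, data.frame(epoch = epoch, trainLoss = epochLoss / n,
                                   valLoss = val$loss, valAcc = val$acc))
    if (val$loss < best - config$tol) { best <- val$loss; streak <- 0L }
    else {
      streak <- streak + 1L
      if (streak >= config$patience) break
    }
  }
  model@params <- params
  tr <- .datasetLoss(layers, params, Xtr, ytr, config$batch)
  te <- .datasetLoss(layers, params, Xte, yte, config$batch)
  list(model = model, history = hist, stoppedEpoch = nrow(hist),
       trainAcc = tr$acc, testAcc = te$acc)
}

#' Run the repeated random-subsampling protocol
#'
#' Draws \code{plan$folds} independent 70/30 partitions, balances each side
#' by undersampling, trains a fresh model per fold and reports per-fold and
#' aggregate accuracies plus the pooled test confusion matrix.
#'
#' @param spec a [modelSpec()].
#' @param windows full labeled [WindowSet-class].
#' @param plan a [splitPlan()].
#' @param config a [trainConfig()]; per-fold seeds derive from its seed.
#' @return List with \code{folds} (data.frame of per-fold accuracies),
#'   \code{meanTrainAcc}, \code{meanTestAcc}, \code{sdTestAcc},
#'   \code{confusion} (true x predicted counts), \code{models}.
#' @export
runProtocol <- function(spec, windows, plan = splitPlan(),
                        config = trainConfig()) {
  res <- data.frame(fold = integer(), stoppedEpoch = integer(),
                    trainAcc = numeric(), testAcc = numeric())
  classes <- .ACTIVITY_CLASSES
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  models <- vector("list", plan$folds)
  for (fold in seq_len(plan$folds) - 1L) {
    sp <- splitWindows(windows, plan, fold)
    foldSeed <- .subSeed(config$seed, 100L + fold)
    train <- balanceWindows(sp$train, seed = .subSeed(foldSeed, 1L))
    test <- balanceWindows(sp$test, seed = .subSeed(foldSeed, 2L))
    cfg <- config; cfg$seed <- foldSeed
    fit <- trainModel(spec, train, test, cfg)
    P <- predictProba(fit$model, test)
    pred <- classes[max.col(P)]
    tab <- table(factor(windowLabels(test), classes), factor(pred, classes))
    confusion <- confusion + unclass(tab)
    res <- rbind(res, data.frame(fold = fold, stoppedEpoch = fit$stoppedEpoch,
                                 trainAcc = fit$trainAcc,
                                 testAcc = fit$testAcc))
    models[[fold + 1L]] <- fit$model
  }
  list(folds = res,
       meanTrainAcc = mean(res$trainAcc),
       meanTestAcc = mean(res$testAcc),
       sdTestAcc = if (nrow(res) > 1L) sd(res$testAcc) else 0,
       confusion = confusion, models = models)
}

#' Within- vs cross-kind confusion rates
#'
#' Splits classification errors into confusions inside one movement kind
#' (jog with sprint; pass, shoot, jump among themselves) and across kinds.
#'
#' @param confusion true x predicted count matrix over the five classes.
#' @return List with \code{withinRate} and \code{crossRate} (errors per
#'   off-diagonal opportunity of each type).
#' @export
confusionKinds <- function(confusion) {
  classes <- rownames(confusion)
  kind <- ifelse(classes %in% .PERIODIC, "periodic", "explosive")
  within <- 0; cross <- 0
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (i == j) next
    if (kind[i] == kind[j]) { within <- within + confusion[i, j] }
    else { cross <- cross + confusion[i, j] }
  }
  total <- sum(confusion)
  list(within = within, cross = cross,
       withinRate = within / total, crossRate = cross / total)
}
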
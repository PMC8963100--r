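# Architecture construction, shape arithmetic and sharing semantics.

test_that("plan structure follows the published trunk layouts", {
  p <- buildPlan(modelSpec("c1d_share", "none", useGyro = TRUE))
  types <- vapply(p@layers, `[[`, "", "type")
  expect_equal(types, c("conv", "maxpool", "conv", "maxpool", "flatten",
                        "dropout", "dense", "dropout", "dense"))
  expect_equal(p@layers[[1]]$f, 16L)
  expect_equal(p@layers[[1]]$h, 1L)
  expect_equal(p@layers[[1]]$m, 5L)
  expect_equal(p@layers[[3]]$f, 32L)

  pc <- buildPlan(modelSpec("c2d_combined", "blstm"))
  expect_equal(vapply(pc@layers, `[[`, "", "type")[1], "parallel")
  expect_length(pc@layers[[1]]$branches, 3L)
  expect_true(any(vapply(pc@layers, `[[`, "", "type") == "bridge"))

  pr <- buildPlan(modelSpec("none", "blstm"))
  expect_false(any(vapply(pr@layers, `[[`, "", "type") %in%
                     c("conv", "gconv", "bridge")))
})

test_that("a model needs a convolutional part or a recurrent head", {
  expect_error(modelSpec("none", "none"), "at least")
})

test_that("declared shapes match hand-derived valid-convolution arithmetic", {
  p <- buildPlan(modelSpec("c2d_share", "blstm", useGyro = TRUE))
  sh <- outputShape(p)
  expect_equal(sh[[1]], c(30, 500, 1))
  expect_equal(sh[[2]], c(10, 496, 32))  # conv(32,(3,5),stride 3)
  expect_equal(sh[[3]], c(10, 124, 32))  # maxpool(1,4)
  expect_equal(sh[[4]], c(10, 120, 64))  # conv(64,(1,5))
  expect_equal(sh[[5]], c(10, 30, 64))   # maxpool(1,4)
  expect_equal(sh[[6]], c(1, 30, 128))   # bridge conv(128,(10,1))
  expect_equal(sh[[7]], 256)             # blstm: 2 x 128
  p2 <- buildPlan(modelSpec("c2d_all", "none", useGyro = FALSE))
  expect_equal(outputShape(p2)[[2]], c(1, 496, 32))  # full-height filter
})

test_that("weight counts follow the sharing semantics", {
  ke <- asNamespace("kinegram")
  # conv(16,(1,5)) on one input map: 16*5+16 = 96; per-group over 5: 480
  shared <- list(list(type = "conv", id = "c", f = 16L, h = 1L, m = 5L,
                      strideH = 1L))
  expect_equal(ke$.walk(shared, c(15, 500, 1), count = TRUE)$count, 96)
  pg <- list(list(type = "gconv", id = "g", f = 16L, h = 1L, m = 5L,
                  groupSize = 3L))
  expect_equal(ke$.walk(pg, c(15, 500, 1), count = TRUE)$count, 480)
  # combined first stage = shared + per-group counts
  c1s <- buildPlan(modelSpec("c1d_share", "lstm"))
  c1p <- buildPlan(modelSpec("c1d_per_sensor", "lstm"))
  comb <- buildPlan(modelSpec("c1d_combined", "lstm"))
  stage1 <- function(p) ke$.walk(p@layers[1], c(30, 500, 1), count = TRUE)$count
  expect_equal(ke$.walk(comb@layers[[1]]$branches[[1]][1], c(30, 500, 1),
                        count = TRUE)$count +
               ke$.walk(comb@layers[[1]]$branches[[2]][1], c(30, 500, 1),
                        count = TRUE)$count,
               stage1(c1s) + stage1(c1p))
})

test_that("a bidirectional head doubles the recurrent parameter count", {
  countRnn <- function(head) {
    p <- buildPlan(modelSpec("c2d_share", head))
    m <- buildModel(p, seed = 1)
    sum(lengths(m@params[grep("^R1", names(m@params))]) * 0 +
          vapply(m@params[grep("^R1", names(m@params))],
                 function(x) sum(lengths(x)), 1))
  }
  expect_equal(countRnn("blstm"), 2 * countRnn("lstm"))
})

test_that("probabilities are a proper softmax and inference is deterministic", {
  spec <- modelSpec("c1d_share", "none", useGyro = FALSE, widthScale = 0.25)
  model <- buildModel(buildPlan(spec), seed = 3)
  x <- array(rnorm(15 * 500 * 4), c(15, 500, 4))
  P <- predictProba(model, x)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-6)
  expect_true(all(P >= 0))
  # duplicated inputs give identical rows
  xd <- x; xd[, , 2] <- x[, , 1]
  Pd <- predictProba(model, xd)
  expect_equal(Pd[1, ], Pd[2, ])
  # zeroed final layer: uniform distribution
  m0 <- model
  m0@params$FC2.bank$W[] <- 0
  m0@params$FC2.bank$b[] <- 0
  P0 <- predictProba(m0, x)
  expect_equal(unname(P0[1, ]), rep(0.2, 5), tolerance = 1e-12)
})

test_that("shared trunks are equivariant to sensor-group permutation, per-sensor ones are not", {
  ke <- asNamespace("kinegram")
  set.seed(77)
  X <- array(rnorm(1 * 30 * 120 * 2), c(1, 30, 120, 2))
  perm <- c(4, 1, 3, 2, 6, 5, 8, 7, 10, 9)          # permute the 10 triads
  rowPerm <- as.vector(outer(1:3, (perm - 1) * 3, "+"))
  Xp <- X[, rowPerm, , , drop = FALSE]
  trunkOut <- function(variant) {
    p <- buildPlan(modelSpec(variant, "lstm", useGyro = TRUE), window = 120)
    m <- buildModel(p, seed = 5)
    trunk <- p@layers[vapply(p@layers, function(l)
      l$type %in% c("conv", "gconv", "maxpool"), TRUE)]
    function(x) ke$.forwardLayers(trunk, x, m@params, FALSE)$out
  }
  # c2d_share: output row g corresponds to triad g -> rows permute with perm
  f <- trunkOut("c2d_share")
  expect_equal(f(Xp), f(X)[, perm, , , drop = FALSE])
  # c1d_share: output rows are signals -> permute with rowPerm
  f1 <- trunkOut("c1d_share")
  expect_equal(f1(Xp), f1(X)[, rowPerm, , , drop = FALSE])
  # per-sensor banks break the equivariance
  fp <- trunkOut("c2d_per_sensor")
  expect_gt(max(abs(fp(Xp) - fp(X)[, perm, , , drop = FALSE])), 1e-4)
})

test_that("incompatible inputs are rejected", {
  model <- buildModel(buildPlan(modelSpec("c1d_share", "none",
                                          useGyro = TRUE,
                                          widthScale = 0.25)), seed = 2)
  expect_error(predictProba(model, array(0, c(15, 500, 1))), "incompatible")
  expect_error(buildPlan(modelSpec("c1d_share", "none"), window = 10),
               "incompatible")
})
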
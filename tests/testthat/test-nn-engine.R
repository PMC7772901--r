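# The engine is the package's own implementation; its gradients are checked
# against central finite differences on small graphs of every layer type.

ns <- asNamespace("wearnet")

lossAt <- function(plan, skel, wflat, X, y, loss) {
  w <- ns$unflattenParams(skel, wflat)
  fwd <- ns$nnForward(plan, w, X, keepCache = FALSE)
  ns$nnLoss(fwd$out, y, loss)$loss
}

maxGradMismatch <- function(graph, X, y, loss, nProbe = 50, seed = 42) {
  plan <- ns$planGraph(graph)
  weights <- ns$withSeed(seed, ns$initWeights(plan))
  wflat <- ns$flattenParams(weights)
  fwd <- ns$nnForward(plan, weights, X, keepCache = TRUE)
  ls <- ns$nnLoss(fwd$out, y, loss)
  g <- ns$flattenParams(ns$nnBackward(plan, weights, fwd, ls$dZ))
  set.seed(7)
  probes <- sample(length(wflat), min(nProbe, length(wflat)))
  eps <- 1e-6
  num <- vapply(probes, function(i) {
    wp <- wflat; wp[i] <- wp[i] + eps
    wm <- wflat; wm[i] <- wm[i] - eps
    (lossAt(plan, weights, wp, X, y, loss) -
       lossAt(plan, weights, wm, X, y, loss)) / (2 * eps)
  }, numeric(1))
  max(abs(num - g[probes]) / pmax(1e-6, abs(num) + abs(g[probes])))
}

tinyConvGraph <- function(task, inputLen = 40L) {
  layers <- list(
    list(type = "conv", nFilters = 3L, kernel = 5L, stride = 2L,
         activation = "relu"),
    list(type = "maxpool", pool = 2L, poolStride = 2L),
    list(type = "conv", nFilters = 4L, kernel = 3L, stride = 1L,
         activation = "relu"),
    list(type = "maxpool", pool = 3L, poolStride = 2L))  # overlapping pool
  len <- inputLen
  for (ly in layers)
    len <- if (ly$type == "conv") layerOutLen(len, ly$kernel, ly$stride)
           else layerOutLen(len, ly$pool, ly$poolStride)
  br <- list(channels = "A", inputLen = inputLen, layers = layers,
             outWidth = as.integer(len * 4))
  head <- list(list(width = 6L, activation = "relu"),
               if (task == "binary") list(width = 1L, activation = "sigmoid")
               else list(width = 3L, activation = "softmax"))
  new("ModelGraph", branches = list(A = br, B = br), head = head,
      task = task, parameterCount = 0, metadata = list())
}

test_that("backprop matches finite differences for conv/pool/dense stacks", {
  set.seed(1)
  B <- 7
  X <- list(A = matrix(rnorm(40 * B), 40), B = matrix(rnorm(40 * B), 40))
  y3 <- sample(0:2, B, replace = TRUE)
  expect_lt(maxGradMismatch(tinyConvGraph("three_class"), X, y3,
                            "categorical_cross_entropy"), 1e-5)
  yb <- sample(0:1, B, replace = TRUE)
  expect_lt(maxGradMismatch(tinyConvGraph("binary"), X, yb,
                            "binary_cross_entropy"), 1e-5)
  # dense-only graph with raw pass-through branches (wrist shape)
  gw <- buildWristMlp(task = "three_class", windowS = 1)
  Xw <- list(BVP = matrix(rnorm(64 * B), 64),
             ACC = matrix(rnorm(96 * B), 96),
             EDA = matrix(rnorm(4 * B), 4), TEMP = matrix(rnorm(4 * B), 4))
  expect_lt(maxGradMismatch(gw, Xw, y3, "categorical_cross_entropy"), 1e-5)
})

test_that("a trivially separable constant dataset is memorized", {
  # 10 identical windows per class, far apart: loss must shrink and
  # training accuracy reach 1 well within the epoch budget
  n <- 4
  mk <- function(level) matrix(level, nrow = 4, ncol = 10)
  ws <- new("WindowSet",
            signals = list(EDA = cbind(mk(0), mk(5))),
            rates = c(EDA = 4), site = "wrist", windowS = 1,
            subject = rep("S", 20), tStart = seq_len(20) - 1,
            condition = rep(c(1L, 2L), each = 10), task = "binary",
            labels = rep(c(0L, 1L), each = 10), metadata = list())
  g <- new("ModelGraph",
           branches = list(EDA = list(channels = "EDA", inputLen = 4L,
                                      layers = list(), outWidth = 4L)),
           head = list(list(width = 4L, activation = "relu"),
                       list(width = 1L, activation = "sigmoid")),
           task = "binary", parameterCount = 0, metadata = list())
  fit <- trainModel(g, ws, trainConfig("binary", epochs = 60, seed = 3,
                                       batchSize = 5))
  expect_identical(tail(fit@history$accuracy, 1), 1)
  expect_lt(tail(fit@history$loss, 1), head(fit@history$loss, 1))
})

test_that("training is bit-for-bit deterministic per seed", {
  ws <- mapTaskLabels(segmentRecord(tinyRecord(seconds = 10),
                                    site = "wrist"), "three_class")
  g <- buildWristMlp(task = "three_class")
  cfg <- trainConfig("three_class", epochs = 3, seed = 11)
  f1 <- trainModel(g, ws, cfg)
  f2 <- trainModel(g, ws, cfg)
  expect_identical(f1@history, f2@history)
  expect_identical(f1@weights, f2@weights)
  f3 <- trainModel(g, ws, trainConfig("three_class", epochs = 3, seed = 12))
  expect_false(identical(f3@weights, f1@weights))
})

test_that("shape and task mismatches fail with useful messages", {
  ws <- mapTaskLabels(segmentRecord(tinyRecord(seconds = 10),
                                    site = "wrist"), "three_class")
  g <- buildWristMlp(task = "binary")
  expect_error(trainModel(g, ws), "does not match")
  g2 <- buildWristMlp(task = "three_class", windowS = 10)
  expect_error(trainModel(g2, ws, trainConfig("three_class", epochs = 1)),
               "branch")
  gc <- buildChestCnn(task = "three_class")
  expect_error(trainModel(gc, ws, trainConfig("three_class", epochs = 1)),
               "lacks channel")
})

test_that("branch order in the forward pass follows the declared order", {
  # permuting the branch declaration (with matching weights) permutes only
  # the concatenation order; with symmetric head weights outputs are equal
  set.seed(2)
  B <- 5
  g <- buildWristMlp(task = "three_class", windowS = 1)
  plan <- ns$planGraph(g)
  w <- ns$withSeed(9, ns$initWeights(plan))
  X <- list(BVP = matrix(rnorm(64 * B), 64),
            ACC = matrix(rnorm(96 * B), 96),
            EDA = matrix(rnorm(4 * B), 4), TEMP = matrix(rnorm(4 * B), 4))
  out1 <- ns$nnForward(plan, w, X)$out
  # reorder branches everywhere consistently
  ord <- c("TEMP", "BVP", "EDA", "ACC")
  g2 <- g; g2@branches <- g@branches[ord]
  plan2 <- ns$planGraph(g2)
  w2 <- w; w2$branches <- w$branches[ord]
  # head weight rows must be permuted to match the new concatenation order
  widths <- vapply(g@branches, function(b) b$outWidth, integer(1))
  offs <- c(0L, cumsum(widths))
  rowIdx <- unlist(lapply(ord, function(nm) {
    k <- match(nm, names(widths))
    (offs[k] + 1L):offs[k + 1L]
  }))
  w2$head[[1]]$W <- w$head[[1]]$W[rowIdx, ]
  out2 <- ns$nnForward(plan2, w2, X)$out
  expect_equal(out2, out1, tolerance = 1e-12)
})
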
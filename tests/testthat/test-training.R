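test_that("binary confusion metrics follow the four defining formulas", {
  # TP = 4, TN = 4, FP = 1, FN = 1 (positive class = 1, second row/col)
  C <- matrix(c(4, 1, 1, 4), 2, 2)
  m <- metricsFromConfusion(C)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
})

test_that("F1 equals precision and recall whenever the two are equal", {
  set.seed(12)
  for (i in 1:50) {
    tp <- sample(0:30, 1); fp <- sample(0:30, 1)
    C <- matrix(c(sample(0:30, 1), fp, fp, tp), 2, 2)  # FP == FN
    m <- metricsFromConfusion(C)
    expect_equal(m$precision, m$recall)
    expect_equal(m$f1, m$precision)
  }
})

test_that("metrics agree with prediction-list recomputation on random cases", {
  set.seed(99)
  for (i in 1:300) {
    k <- sample(2:4, 1)
    n <- sample(5:60, 1)
    truth <- sample(0:(k - 1), n, replace = TRUE)
    pred <- sample(0:(k - 1), n, replace = TRUE)
    C <- as.matrix(table(factor(truth, levels = 0:(k - 1)),
                         factor(pred, levels = 0:(k - 1))))
    m <- metricsFromConfusion(C)
    o <- bruteMetrics(truth, pred, 0:(k - 1))
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$perClass$precision, unname(o$perClass[, "precision"]))
    expect_equal(m$perClass$recall, unname(o$perClass[, "recall"]))
    expect_equal(m$macro$f1, o$macroF1)
    if (k > 2) expect_equal(m$f1, o$macroF1)
  }
  expect_error(metricsFromConfusion(matrix(1, 2, 3)), "square")
})

test_that("zero-denominator conventions give 0, never NaN", {
  m <- metricsFromConfusion(matrix(c(5, 0, 0, 0), 2, 2))
  expect_identical(m$precision, 0)
  expect_identical(m$recall, 0)
  expect_identical(m$f1, 0)
  expect_false(anyNA(unlist(m[c("accuracy", "precision", "recall", "f1")])))
})

mkLabelled <- function(labels, task, nFeat = 4L) {
  n <- length(labels)
  new("WindowSet",
      signals = list(EDA = matrix(rnorm(nFeat * n), nFeat)),
      rates = c(EDA = nFeat), site = "wrist", windowS = 1,
      subject = rep("S", n), tStart = seq_len(n) - 1,
      condition = rep(2L, n), task = task, labels = labels,
      metadata = list())
}

constantModel <- function(task, cls, nFeat = 4L) {
  # hand-set weights: zero hidden, bias pushes the output to class `cls`
  g <- new("ModelGraph",
           branches = list(EDA = list(channels = "EDA", inputLen = nFeat,
                                      layers = list(), outWidth = nFeat)),
           head = if (task == "binary")
             list(list(width = 1L, activation = "sigmoid"))
           else list(list(width = 3L, activation = "softmax")),
           task = task, parameterCount = 0, metadata = list())
  fit <- trainModel(g, mkLabelled(rep(0L, 4), task, nFeat),
                    trainConfig(task, epochs = 1, seed = 1,
                                normalize = FALSE))
  W <- fit@weights$head[[1]]$W * 0
  b <- fit@weights$head[[1]]$b * 0
  if (task == "binary") b[1] <- if (cls == 1L) 10 else -10
  else b[cls + 1L] <- 10
  fit@weights$head[[1]]$W <- W
  fit@weights$head[[1]]$b <- b
  fit
}

test_that("a perfect predictor scores accuracy and F1 of 1", {
  set.seed(5)
  labels <- rep(0:2, each = 6)
  ws <- mkLabelled(labels, "three_class")
  # separable by construction: encode the class in the signal mean
  ws@signals$EDA <- ws@signals$EDA * 0.01 + rep(labels * 5, each = 4)
  # train a tiny dense net until it is perfect
  fit <- trainModel(
    new("ModelGraph",
        branches = list(EDA = list(channels = "EDA", inputLen = 4L,
                                   layers = list(), outWidth = 4L)),
        head = list(list(width = 8L, activation = "relu"),
                    list(width = 3L, activation = "softmax")),
        task = "three_class", parameterCount = 0, metadata = list()),
    ws, trainConfig("three_class", epochs = 80, seed = 2, batchSize = 6))
  rep <- evaluateModel(fit, ws)
  expect_equal(accuracy(rep), 1)
  expect_equal(f1Score(rep), 1)
  expect_identical(sum(confusionMatrix(rep)), 18L)
})

test_that("a constant predictor scores 1/3 on a balanced 3-class set", {
  ws <- mkLabelled(rep(0:2, each = 5), "three_class")
  rep <- evaluateModel(constantModel("three_class", 1L), ws)
  expect_equal(accuracy(rep), 1 / 3)
  expect_equal(unname(colSums(confusionMatrix(rep))), c(0, 15, 0))
  expect_error(evaluateModel(constantModel("three_class", 1L), ws[0]),
               "empty")
})

test_that("EvalReport metrics equal recomputation from its prediction list", {
  set.seed(21)
  for (task in c("binary", "three_class")) {
    k <- if (task == "binary") 2L else 3L
    labels <- sample(0:(k - 1), 40, replace = TRUE)
    ws <- mkLabelled(labels, task)
    fit <- trainModel(
      new("ModelGraph",
          branches = list(EDA = list(channels = "EDA", inputLen = 4L,
                                     layers = list(), outWidth = 4L)),
          head = headList <- c(list(list(width = 4L, activation = "relu")),
                               if (task == "binary")
                                 list(list(width = 1L,
                                           activation = "sigmoid"))
                               else list(list(width = 3L,
                                              activation = "softmax"))),
          task = task, parameterCount = 0, metadata = list()),
      ws, trainConfig(task, epochs = 3, seed = 8))
    rep <- evaluateModel(fit, ws)
    pred <- predictModel(fit, ws)$labels
    o <- bruteMetrics(labels, pred, 0:(k - 1))
    expect_equal(accuracy(rep), o$accuracy)
    if (task == "three_class") expect_equal(f1Score(rep), o$macroF1)
    expect_identical(as.integer(sum(confusionMatrix(rep))), 40L)
  }
})

test_that("runProtocol produces fold telemetry and a hold-out report", {
  ws <- mapTaskLabels(
    segmentRecords(generateDataset(tinySpec(seconds = 15, nSubjects = 2)),
                   site = "wrist"), "three_class")
  cfg <- trainConfig("three_class", epochs = 2, seed = 4, cvFolds = 5L)
  res <- runProtocol(ws, function(task) buildWristMlp(task = task), cfg)
  expect_length(res$folds, 5)
  expect_s4_class(res$holdout, "EvalReport")
  expect_true(res$cvAccuracy >= 0 && res$cvAccuracy <= 1)
  expect_identical(res$manifest$nTrain + res$manifest$nTest, length(ws))
  expect_identical(res$manifest$seed, 4L)
  expect_error(runProtocol(ws[1:4], buildWristMlp(task = "three_class"),
                           cfg), "folds")
})

test_that("including ACC never hurts much on the default benchmark", {
  # soft regression check: the ACC ablation may not cost more than noise
  ws <- segmentRecords(generateDataset(tinySpec(seconds = 20,
                                                nSubjects = 2, seed = 3)),
                      site = "wrist")
  cfg <- trainConfig("three_class", epochs = 15, seed = 1, cvFolds = 0L)
  accWith <- accuracy(runProtocol(mapTaskLabels(ws, "three_class"),
                                  buildWristMlp(task = "three_class"),
                                  cfg)$holdout)
  wsNo <- ws; wsNo@signals <- ws@signals[c("BVP", "EDA", "TEMP")]
  accWithout <- accuracy(runProtocol(
    mapTaskLabels(wsNo, "three_class"),
    buildWristMlp(task = "three_class", includeAcc = FALSE), cfg)$holdout)
  expect_gte(accWith, accWithout - 0.15)
})
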
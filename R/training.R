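## Training protocol (Adam, cross-entropy, scrambled 7:3 split, tenfold CV)
## and confusion-matrix metrics.

## Stack a WindowSet's channels into per-branch input matrices, applying the
## stored per-channel z-scoring. Multi-channel branches (wrist ACC) are
## flattened axis-major: the full X axis window, then Y, then Z.
assembleBranchInputs <- function(ws, graph, norm = NULL) {
  X <- list()
  for (nm in names(graph@branches)) {
    br <- graph@branches[[nm]]
    missing <- setdiff(br$channels, names(ws@signals))
    if (length(missing))
      stop(sprintf("branch %s: WindowSet lacks channel(s) %s", nm,
                   paste(missing, collapse = ", ")))
    mats <- lapply(br$channels, function(ch) {
      m <- ws@signals[[ch]]
      if (!is.null(norm)) (m - norm$mean[[ch]]) / norm$sd[[ch]] else m
    })
    m <- if (length(mats) == 1L) mats[[1]] else do.call(rbind, mats)
    if (nrow(m) != br$inputLen)
      stop(sprintf(
        "branch %s: window length %d does not match graph input length %d",
        nm, nrow(m), br$inputLen))
    X[[nm]] <- m
  }
  X
}

channelNorms <- function(ws, channels) {
  mean <- list(); sd <- list()
  for (ch in channels) {
    v <- ws@signals[[ch]]
    if (is.null(v))
      stop(sprintf("WindowSet lacks channel(s) %s required by the graph",
                   ch))
    mu <- mean(v)
    s <- stats::sd(as.vector(v))
    if (!is.finite(s) || s < 1e-8) s <- 1
    mean[[ch]] <- mu; sd[[ch]] <- s
  }
  list(mean = mean, sd = sd)
}

checkTaskMatch <- function(graph, ws) {
  if (ws@task == "none")
    stop("WindowSet is unmapped; call mapTaskLabels() first")
  if (graph@task != ws@task)
    stop(sprintf("graph task '%s' does not match WindowSet task '%s'",
                 graph@task, ws@task))
}

#' Train a network on a mapped WindowSet
#'
#' Seeded minibatch training with the Adam optimizer and the task-bound
#' cross-entropy loss (binary cross-entropy for stress detection,
#' categorical cross-entropy for the 3-class task). Inputs are z-scored per
#' channel with statistics taken from the training windows (disable with
#' `normalize = FALSE` in the config). Two runs with the same graph, data
#' and config are bit-for-bit identical.
#'
#' @param graph a [ModelGraph-class] whose task matches `train`.
#' @param train a mapped, non-empty [WindowSet-class].
#' @param cfg a [TrainConfig-class]; see [trainConfig()].
#' @return a [FittedModel-class] with per-epoch loss/accuracy history.
#' @export
trainModel <- function(graph, train, cfg = trainConfig(graph@task)) {
  checkTaskMatch(graph, train)
  expectedLoss <- if (graph@task == "binary") "binary_cross_entropy"
                  else "categorical_cross_entropy"
  if (cfg@loss != expectedLoss)
    stop(sprintf("loss '%s' does not match task '%s'", cfg@loss, graph@task))
  n <- length(train)
  if (n < 1L) stop("training set is empty")
  chans <- unique(unlist(lapply(graph@branches, function(b) b$channels)))
  norm <- if (cfg@normalize) channelNorms(train, chans) else NULL
  X <- assembleBranchInputs(train, graph, norm)
  y <- train@labels
  plan <- planGraph(graph)

  withSeed(cfg@seed, {
    weights <- initWeights(plan)
    skel <- weights
    wflat <- flattenParams(weights)
    opt <- adamInit(length(wflat))
    history <- data.frame(epoch = integer(), loss = numeric(),
                          accuracy = numeric())
    for (epoch in seq_len(cfg@epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg@batchSize))
      totLoss <- 0; totCorrect <- 0L
      for (idx in batches) {
        Xb <- lapply(X, function(m) m[, idx, drop = FALSE])
        fwd <- nnForward(plan, weights, Xb, keepCache = TRUE)
        ls <- nnLoss(fwd$out, y[idx], cfg@loss)
        if (!is.finite(ls$loss))
          stop(sprintf(
            "NaN/Inf loss at epoch %d; try a smaller learning rate", epoch))
        grads <- nnBackward(plan, weights, fwd, ls$dZ)
        step <- adamStep(opt, wflat, flattenParams(grads), cfg@learningRate)
        wflat <- step$w; opt <- step$state
        weights <- unflattenParams(skel, wflat)
        pred <- decodePredictions(fwd$out, graph@task)
        totCorrect <- totCorrect + sum(pred == y[idx])
        totLoss <- totLoss + ls$loss * length(idx)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, loss = totLoss / n, accuracy = totCorrect / n))
    }
    new("FittedModel", graph = graph, weights = weights,
        norm = norm %||% list(), history = history, config = cfg)
  })
}

decodePredictions <- function(out, task) {
  if (task == "binary") as.integer(out[1L, ] > 0.5)
  else max.col(t(out), ties.method = "first") - 1L
}

#' Predict task labels (and class probabilities) for a WindowSet
#'
#' Uses argmax decoding for the 3-class softmax output and a 0.5 threshold
#' on the sigmoid output for binary stress detection.
#'
#' @param model a [FittedModel-class].
#' @param ws a mapped [WindowSet-class] with matching channels.
#' @return list with `labels` (integer predictions) and `prob`
#'   (classes x windows probability matrix).
#' @export
predictModel <- function(model, ws) {
  if (!length(ws)) stop("cannot predict on an empty WindowSet")
  norm <- if (length(model@norm)) model@norm else NULL
  X <- assembleBranchInputs(ws, model@graph, norm)
  plan <- planGraph(model@graph)
  out <- nnForward(plan, model@weights, X)$out
  list(labels = decodePredictions(out, model@graph@task), prob = out)
}

#' Compute classification metrics from a confusion matrix
#'
#' Accuracy is the fraction of correct predictions; in the binary case
#' (positive class = stress, the second row/column) precision is
#' TP / (TP + FP), recall TP / (TP + FN) and F1 their harmonic mean. For
#' more than two classes, per-class one-vs-rest precision/recall/F1 are
#' computed and aggregated as macro (unweighted mean), micro (pooled
#' counts) and support-weighted averages. Undefined ratios (zero
#' denominators) are taken as 0, and F1 is 0 when precision + recall = 0.
#'
#' @param confusion square non-negative count matrix, rows = true class,
#'   columns = predicted class.
#' @return list with `accuracy`, headline `precision`/`recall`/`f1`
#'   (positive-class for 2x2, macro otherwise), a `perClass` data.frame,
#'   and `macro`/`micro`/`weighted` aggregate lists.
#' @export
#' @examples
#' metricsFromConfusion(matrix(c(4, 1, 1, 4), 2, 2))  # all 0.8
metricsFromConfusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square")
  if (any(confusion < 0)) stop("confusion entries must be non-negative")
  total <- sum(confusion)
  k <- nrow(confusion)
  acc <- if (total > 0) sum(diag(confusion)) / total else 0
  safeDiv <- function(a, b) if (b > 0) a / b else 0
  per <- data.frame(class = seq_len(k) - 1L, precision = 0, recall = 0,
                    f1 = 0, support = rowSums(confusion))
  for (i in seq_len(k)) {
    tp <- confusion[i, i]
    per$precision[i] <- safeDiv(tp, sum(confusion[, i]))
    per$recall[i] <- safeDiv(tp, sum(confusion[i, ]))
    pr <- per$precision[i] + per$recall[i]
    per$f1[i] <- if (pr > 0) 2 * per$precision[i] * per$recall[i] / pr else 0
  }
  macro <- list(precision = mean(per$precision), recall = mean(per$recall),
                f1 = mean(per$f1))
  ## micro-averaged one-vs-rest precision == recall == accuracy
  micro <- list(precision = acc, recall = acc, f1 = acc)
  wts <- if (total > 0) per$support / total else rep(1 / k, k)
  weighted <- list(precision = sum(wts * per$precision),
                   recall = sum(wts * per$recall), f1 = sum(wts * per$f1))
  headline <- if (k == 2L)
    list(precision = per$precision[2], recall = per$recall[2],
         f1 = per$f1[2])
  else macro
  list(accuracy = acc, precision = headline$precision,
       recall = headline$recall, f1 = headline$f1, perClass = per,
       macro = macro, micro = micro, weighted = weighted)
}

#' Evaluate a fitted model on a test WindowSet
#'
#' @param model a [FittedModel-class].
#' @param test a non-empty mapped [WindowSet-class] with the same task.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(model, test) {
  checkTaskMatch(model@graph, test)
  if (!length(test)) stop("test set is empty")
  pred <- predictModel(model, test)$labels
  k <- if (model@graph@task == "binary") 2L else 3L
  lev <- 0:(k - 1)
  confusion <- table(factor(test@labels, levels = lev),
                     factor(pred, levels = lev))
  confusion <- matrix(as.integer(confusion), k, k,
                      dimnames = list(true = lev, predicted = lev))
  m <- metricsFromConfusion(confusion)
  new("EvalReport", confusion = confusion, accuracy = m$accuracy,
      precision = m$precision, recall = m$recall, f1 = m$f1,
      perClass = m$perClass, nTest = length(test),
      metadata = list(task = model@graph@task, macro = m$macro,
                      micro = m$micro, weighted = m$weighted,
                      seed = model@config@seed))
}

#' Run the full training protocol
#'
#' Scrambles the windows into a 7:3 train/hold-out split, optionally runs
#' k-fold cross-validation on the training portion (model-selection
#' telemetry), then fits on the full training portion and reports metrics
#' on the 30% hold-out.
#'
#' @param ws a mapped [WindowSet-class].
#' @param graph a [ModelGraph-class], or a function of `task` returning one.
#' @param cfg a [TrainConfig-class]; `cfg@cvFolds = 0` skips the CV stage.
#' @param bySubject split at subject level instead of window level.
#' @return list with `holdout` ([EvalReport-class]), `folds` (list of
#'   per-fold [EvalReport-class]), `cvAccuracy` (mean fold accuracy, `NA`
#'   if skipped), `model` (the final [FittedModel-class]) and `manifest`
#'   (seeds and sizes).
#' @export
runProtocol <- function(ws, graph, cfg = trainConfig(taskType(ws)),
                        bySubject = FALSE) {
  if (is.function(graph)) graph <- graph(taskType(ws))
  checkTaskMatch(graph, ws)
  if (cfg@cvFolds > 0L && length(ws) < cfg@cvFolds)
    stop(sprintf("fewer windows (%d) than folds (%d)", length(ws),
                 cfg@cvFolds))
  split <- scrambleSplit(ws, cfg@trainFraction, cfg@seed,
                         bySubject = bySubject)
  foldReports <- list()
  if (cfg@cvFolds > 0L) {
    n <- length(split$train)
    folds <- foldIndices(n, cfg@cvFolds, cfg@seed + 1L)
    for (f in seq_along(folds)) {
      testIdx <- sort(folds[[f]])
      fit <- trainModel(graph, split$train[setdiff(seq_len(n), testIdx)],
                        cfg)
      foldReports[[f]] <- evaluateModel(fit, split$train[testIdx])
    }
  }
  model <- trainModel(graph, split$train, cfg)
  holdout <- evaluateModel(model, split$test)
  list(holdout = holdout, folds = foldReports,
       cvAccuracy = if (length(foldReports))
         mean(vapply(foldReports, accuracy, numeric(1))) else NA_real_,
       model = model,
       manifest = list(seed = cfg@seed, nTrain = length(split$train),
                       nTest = length(split$test), cvFolds = cfg@cvFolds,
                       epochs = cfg@epochs, batchSize = cfg@batchSize,
                       learningRate = cfg@learningRate,
                       trainFraction = cfg@trainFraction,
                       task = taskType(ws), bySubject = bySubject))
}

#' Serialize an EvalReport to JSON
#'
#' @param report an [EvalReport-class].
#' @param path output file; `NULL` returns the JSON string.
#' @return the JSON string, invisibly when written to a file.
#' @export
evalReportToJson <- function(report, path = NULL) {
  obj <- list(confusion = unclass(report@confusion),
              accuracy = report@accuracy, precision = report@precision,
              recall = report@recall, f1 = report@f1,
              perClass = report@perClass, nTest = report@nTest,
              metadata = report@metadata)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
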
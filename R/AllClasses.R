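#' @import methods
#' @importFrom stats rnorm runif rpois sd quantile
#' @importFrom utils head tail read.table write.table modifyList
NULL

## ---- channel / condition vocabulary --------------------------------------

#' Chest and wrist channel sets
#'
#' Channel identifiers used throughout the package. Chest-worn sensors are all
#' sampled at 700 Hz: ECG, EDA (electrodermal activity), EMG, RESP
#' (respiration), TEMP (skin temperature) and the three accelerometer axes
#' ACC_X/ACC_Y/ACC_Z, each axis treated as a separate input. Wrist-worn
#' sensors are sampled at heterogeneous rates: BVP 64 Hz, ACC axes 32 Hz,
#' EDA 4 Hz, TEMP 4 Hz.
#'
#' @param includeAcc logical; include the three accelerometer axes.
#' @return character vector of channel names.
#' @export
#' @examples
#' chestChannels()
#' wristChannels(includeAcc = FALSE)
chestChannels <- function(includeAcc = TRUE) {
  ch <- c("ECG", "EDA", "EMG", "RESP", "TEMP")
  if (includeAcc) ch <- c(ch, "ACC_X", "ACC_Y", "ACC_Z")
  ch
}

#' @rdname chestChannels
#' @export
wristChannels <- function(includeAcc = TRUE) {
  ch <- "BVP"
  if (includeAcc) ch <- c(ch, "ACC_X", "ACC_Y", "ACC_Z")
  c(ch, "EDA", "TEMP")
}

#' @rdname chestChannels
#' @export
chestRate <- function() 700

#' @rdname chestChannels
#' @export
wristRates <- function() {
  c(BVP = 64, ACC_X = 32, ACC_Y = 32, ACC_Z = 32, EDA = 4, TEMP = 4)
}

#' Condition label codes
#'
#' Integer condition codes carried by the 700 Hz label track, following the
#' dataset's documentation: 0 = undefined/transient, 1 = baseline, 2 = stress,
#' 3 = amusement, 4 = meditation, 5-7 = ignored. Modelling uses the three
#' study conditions baseline/stress/amusement by default.
#'
#' @return named integer vector.
#' @export
#' @examples
#' studyConditions()
conditionCodes <- function() {
  c(transient = 0L, baseline = 1L, stress = 2L, amusement = 3L,
    meditation = 4L, ignored5 = 5L, ignored6 = 6L, ignored7 = 7L)
}

#' @rdname conditionCodes
#' @export
studyConditions <- function() {
  c(baseline = 1L, stress = 2L, amusement = 3L)
}

## ---- ChannelSeries --------------------------------------------------------

#' ChannelSeries: one sensor stream at its native rate
#'
#' A single ordered series of real-valued samples from one sensor channel,
#' together with its sampling rate in Hz.
#'
#' @slot name character(1), channel identifier (e.g. "ECG", "ACC_X").
#' @slot rate numeric(1), sampling frequency in Hz; strictly positive.
#' @slot values numeric vector of samples; all finite.
#' @export
setClass("ChannelSeries",
  representation(name = "character", rate = "numeric", values = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a single non-empty string")
    if (length(object@rate) != 1L || !is.finite(object@rate) ||
        object@rate <= 0)
      msg <- c(msg, "rate must be a single positive finite number")
    if (anyNA(object@values) || any(!is.finite(object@values)))
      msg <- c(msg, "values must all be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a ChannelSeries
#'
#' @param name channel identifier.
#' @param rate sampling frequency in Hz.
#' @param values numeric samples.
#' @return a [ChannelSeries-class] object.
#' @export
ChannelSeries <- function(name, rate, values) {
  new("ChannelSeries", name = as.character(name), rate = as.numeric(rate),
      values = as.numeric(values))
}

#' @describeIn ChannelSeries-class number of samples.
#' @param x a ChannelSeries.
#' @export
setMethod("length", "ChannelSeries", function(x) length(x@values))

setMethod("show", "ChannelSeries", function(object) {
  cat(sprintf("ChannelSeries '%s': %d samples @ %g Hz (%.2f s)\n",
              object@name, length(object@values), object@rate,
              length(object@values) / object@rate))
})

#' Accessors for wearnet classes
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "ChannelSeries", function(object) object@rate)

#' @rdname accessors
#' @export
setGeneric("channelValues", function(object) standardGeneric("channelValues"))
#' @rdname accessors
#' @export
setMethod("channelValues", "ChannelSeries", function(object) object@values)

## ---- SubjectRecord --------------------------------------------------------

#' SubjectRecord: one participant's multi-rate signal set
#'
#' All chest channels (700 Hz), all wrist channels (64/32/4/4 Hz) and the
#' 700 Hz integer condition-label track for one study participant. Structural
#' slot checks live in the class validity; the full cross-channel invariants
#' (shared chest length, wrist length vs. duration, label code set) are
#' reported by [validateRecord()], which returns diagnostics rather than
#' throwing, so that deliberately inconsistent records can be constructed and
#' examined.
#'
#' @slot subjectId character(1).
#' @slot chest named list of [ChannelSeries-class], all at 700 Hz.
#' @slot wrist named list of [ChannelSeries-class] at native rates.
#' @slot labels [ChannelSeries-class] of integer condition codes at 700 Hz.
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", chest = "list", wrist = "list",
                 labels = "ChannelSeries"),
  validity = function(object) {
    msg <- character()
    if (length(object@subjectId) != 1L)
      msg <- c(msg, "subjectId must be a single string")
    for (site in c("chest", "wrist")) {
      chans <- slot(object, site)
      if (length(chans) &&
          (is.null(names(chans)) || any(!nzchar(names(chans)))))
        msg <- c(msg, sprintf("%s channels must be named", site))
      if (!all(vapply(chans, is, logical(1), "ChannelSeries")))
        msg <- c(msg, sprintf("%s entries must be ChannelSeries", site))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SubjectRecord
#'
#' @param subjectId subject identifier.
#' @param chest named list of chest [ChannelSeries-class].
#' @param wrist named list of wrist [ChannelSeries-class].
#' @param labels [ChannelSeries-class] with the 700 Hz condition-code track.
#' @return a [SubjectRecord-class] object.
#' @export
SubjectRecord <- function(subjectId, chest, wrist, labels) {
  new("SubjectRecord", subjectId = as.character(subjectId), chest = chest,
      wrist = wrist, labels = labels)
}

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "SubjectRecord", function(object) object@subjectId)

#' @rdname accessors
#' @param site "chest" or "wrist".
#' @export
setGeneric("channels", function(object, site = "chest")
  standardGeneric("channels"))
#' @rdname accessors
#' @export
setMethod("channels", "SubjectRecord", function(object, site = "chest") {
  site <- match.arg(site, c("chest", "wrist"))
  slot(object, site)
})

#' @rdname accessors
#' @export
setGeneric("labelTrack", function(object) standardGeneric("labelTrack"))
#' @rdname accessors
#' @export
setMethod("labelTrack", "SubjectRecord", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("recordDuration", function(object)
  standardGeneric("recordDuration"))
#' @rdname accessors
#' @export
setMethod("recordDuration", "SubjectRecord", function(object)
  length(object@labels@values) / object@labels@rate)

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord '%s' (%.1f s)\n", object@subjectId,
              recordDuration(object)))
  cat(sprintf("  chest: %s\n", paste(names(object@chest), collapse = ", ")))
  cat(sprintf("  wrist: %s\n", paste(names(object@wrist), collapse = ", ")))
  tab <- table(object@labels@values)
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                    collapse = " ")))
})

## ---- WindowSet ------------------------------------------------------------

#' WindowSet: fixed-duration windows with one condition each
#'
#' Windows cut from one or more [SubjectRecord-class] objects. Each channel is
#' stored as a samples-by-windows matrix at its native rate, so a 5 s chest
#' window contributes a 3500-row column per channel while wrist channels
#' contribute 320 (BVP), 160 (each ACC axis) or 20 (EDA, TEMP) rows.
#'
#' @slot signals named list, channel name -> numeric matrix
#'   (rate x window seconds) rows by n windows columns.
#' @slot rates named numeric, Hz per channel.
#' @slot site "chest" or "wrist".
#' @slot windowS numeric(1), window duration in seconds.
#' @slot subject character, per-window subject id.
#' @slot tStart numeric, per-window start time in seconds from record start.
#' @slot condition integer, per-window condition code.
#' @slot task "none", "binary" or "three_class".
#' @slot labels integer, per-window task label once mapped (length 0 before).
#' @slot metadata list: mapping, seed, purity, stride, dropped-window counts.
#' @export
setClass("WindowSet",
  representation(signals = "list", rates = "numeric", site = "character",
                 windowS = "numeric", subject = "character",
                 tStart = "numeric", condition = "integer",
                 task = "character", labels = "integer", metadata = "list"),
  validity = function(object) {
    msg <- character()
    n <- length(object@condition)
    if (!object@task %in% c("none", "binary", "three_class"))
      msg <- c(msg, "task must be none, binary or three_class")
    if (length(object@signals)) {
      if (is.null(names(object@signals)))
        msg <- c(msg, "signals must be a named list")
      ncols <- vapply(object@signals, ncol, integer(1))
      if (any(ncols != n))
        msg <- c(msg, "all channel matrices must have one column per window")
      for (ch in names(object@signals)) {
        expect <- round(object@rates[[ch]] * object@windowS)
        if (nrow(object@signals[[ch]]) != expect)
          msg <- c(msg, sprintf(
            "channel %s has %d rows, expected rate x window = %d",
            ch, nrow(object@signals[[ch]]), expect))
      }
    }
    if (length(object@subject) != n || length(object@tStart) != n)
      msg <- c(msg, "subject and tStart must have one entry per window")
    if (object@task == "none") {
      if (length(object@labels) != 0L)
        msg <- c(msg, "unmapped WindowSet must have empty labels")
    } else {
      if (length(object@labels) != n)
        msg <- c(msg, "mapped WindowSet needs one label per window")
      ok <- if (object@task == "binary") 0:1 else 0:2
      if (n && !all(object@labels %in% ok))
        msg <- c(msg, sprintf("labels must lie in {%s}",
                              paste(ok, collapse = ",")))
    }
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn WindowSet-class number of windows.
#' @param x a WindowSet.
#' @export
setMethod("length", "WindowSet", function(x) length(x@condition))

#' @describeIn WindowSet-class subset windows by index.
#' @param i integer or logical index over windows.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "WindowSet", function(x, i, j, ..., drop = FALSE) {
  idx <- seq_len(length(x))[i]
  initialize(x,
    signals = lapply(x@signals, function(m) m[, idx, drop = FALSE]),
    subject = x@subject[idx], tStart = x@tStart[idx],
    condition = x@condition[idx],
    labels = if (length(x@labels)) x@labels[idx] else x@labels)
})

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d windows of %g s (%s), task = %s\n",
              length(object), object@windowS, object@site, object@task))
  cat(sprintf("  channels: %s\n",
              paste(sprintf("%s[%d]", names(object@signals),
                            vapply(object@signals, nrow, integer(1))),
                    collapse = " ")))
  if (length(object)) {
    tab <- table(object@condition)
    cat(sprintf("  conditions: %s\n",
                paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                      collapse = " ")))
  }
})

#' @rdname accessors
#' @export
setGeneric("windowLabels", function(object) standardGeneric("windowLabels"))
#' @rdname accessors
#' @export
setMethod("windowLabels", "WindowSet", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("windowConditions", function(object)
  standardGeneric("windowConditions"))
#' @rdname accessors
#' @export
setMethod("windowConditions", "WindowSet", function(object) object@condition)

#' @rdname accessors
#' @export
setGeneric("taskType", function(object) standardGeneric("taskType"))
#' @rdname accessors
#' @export
setMethod("taskType", "WindowSet", function(object) object@task)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "WindowSet", function(object)
  names(object@signals))

#' Combine WindowSets from several subjects
#'
#' @param ... WindowSet objects sharing channel schema, site, window length
#'   and task.
#' @return a single [WindowSet-class].
#' @export
combineWindowSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "WindowSet"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, is, logical(1), "WindowSet")))
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(names(s@signals), names(ref@signals)) ||
        !identical(s@site, ref@site) || !identical(s@task, ref@task) ||
        !identical(s@windowS, ref@windowS))
      stop("WindowSets have incompatible schema and cannot be combined")
  }
  sig <- lapply(names(ref@signals), function(ch)
    do.call(cbind, lapply(sets, function(s) s@signals[[ch]])))
  names(sig) <- names(ref@signals)
  initialize(ref,
    signals = sig,
    subject = unlist(lapply(sets, function(s) s@subject)),
    tStart = unlist(lapply(sets, function(s) s@tStart)),
    condition = unlist(lapply(sets, function(s) s@condition)),
    labels = if (ref@task == "none") integer()
             else unlist(lapply(sets, function(s) s@labels)),
    metadata = ref@metadata)
}

## ---- model / training / evaluation classes --------------------------------

#' ConvLayerSpec: one 1D convolution + max-pooling stage
#'
#' @slot nFilters number of 1D filters.
#' @slot kernel filter length in samples.
#' @slot stride convolution stride in samples.
#' @slot pool max-pooling window in samples.
#' @slot poolStride max-pooling stride in samples.
#' @slot activation activation name; "relu".
#' @export
setClass("ConvLayerSpec",
  representation(nFilters = "integer", kernel = "integer", stride = "integer",
                 pool = "integer", poolStride = "integer",
                 activation = "character"),
  validity = function(object) {
    v <- c(object@nFilters, object@kernel, object@stride, object@pool,
           object@poolStride)
    if (any(v < 1L)) return("all layer sizes/strides must be positive")
    if (!object@activation %in% "relu")
      return("conv layer activation must be 'relu'")
    TRUE
  }
)

#' Construct a ConvLayerSpec
#'
#' @param nFilters,kernel,stride,pool,poolStride positive integers.
#' @param activation activation function name.
#' @return a [ConvLayerSpec-class].
#' @export
convLayerSpec <- function(nFilters, kernel, stride, pool, poolStride,
                          activation = "relu") {
  new("ConvLayerSpec", nFilters = as.integer(nFilters),
      kernel = as.integer(kernel), stride = as.integer(stride),
      pool = as.integer(pool), poolStride = as.integer(poolStride),
      activation = activation)
}

#' ConvBlockSpec: the 3-stage 1D convolutional block
#'
#' @slot layers list of three [ConvLayerSpec-class].
#' @slot inputLen input vector length in samples.
#' @export
setClass("ConvBlockSpec",
  representation(layers = "list", inputLen = "integer"),
  validity = function(object) {
    if (length(object@layers) != 3L ||
        !all(vapply(object@layers, is, logical(1), "ConvLayerSpec")))
      return("a conv block has exactly 3 ConvLayerSpec stages")
    if (object@inputLen < 1L) return("inputLen must be positive")
    TRUE
  }
)

#' ModelGraph: declarative description of a built network
#'
#' Produced by [buildChestCnn()] and [buildWristMlp()]; consumed by
#' [trainModel()]. Branches are per-sensor subgraphs; the fused head is a
#' stack of dense layers ending in a 1-unit sigmoid (binary) or 3-unit
#' softmax (three_class) output.
#'
#' @slot branches named list of branch descriptions (channels, input length,
#'   layer list).
#' @slot head list of dense-layer descriptions (width, activation).
#' @slot task "binary" or "three_class".
#' @slot parameterCount closed-form count of trainable parameters.
#' @slot metadata list (site, concatenation width, block variant, ...).
#' @export
setClass("ModelGraph",
  representation(branches = "list", head = "list", task = "character",
                 parameterCount = "numeric", metadata = "list"),
  validity = function(object) {
    if (!object@task %in% c("binary", "three_class"))
      return("task must be binary or three_class")
    last <- object@head[[length(object@head)]]
    if (object@task == "binary" &&
        !(last$width == 1L && last$activation == "sigmoid"))
      return("binary head must end in width 1 with sigmoid")
    if (object@task == "three_class" &&
        !(last$width == 3L && last$activation == "softmax"))
      return("three_class head must end in width 3 with softmax")
    TRUE
  }
)

#' @rdname accessors
#' @export
setGeneric("parameterCount", function(object)
  standardGeneric("parameterCount"))
#' @rdname accessors
#' @export
setMethod("parameterCount", "ModelGraph", function(object)
  object@parameterCount)

setMethod("show", "ModelGraph", function(object) {
  cat(sprintf("ModelGraph (%s, %s): %d branches, %s parameters\n",
              object@metadata$site %||% "?", object@task,
              length(object@branches),
              format(object@parameterCount, big.mark = ",")))
  for (nm in names(object@branches)) {
    br <- object@branches[[nm]]
    cat(sprintf("  branch %-6s <- %-22s out %d\n", nm,
                paste(br$channels, collapse = "+"), br$outWidth))
  }
  cat(sprintf("  head: %s\n",
              paste(vapply(object@head, function(l)
                sprintf("%d(%s)", l$width, l$activation), character(1)),
                collapse = " -> ")))
})

#' TrainConfig: the training protocol
#'
#' Defaults follow the training protocol: Adam optimization, 100 epochs,
#' batch size 40, binary or categorical cross-entropy bound to the task,
#' a 7:3 scrambled train/test split and tenfold cross-validation.
#'
#' @slot optimizer "adam".
#' @slot learningRate Adam step size.
#' @slot epochs training epochs.
#' @slot batchSize minibatch size.
#' @slot loss "binary_cross_entropy" or "categorical_cross_entropy".
#' @slot seed integer RNG seed for init and shuffling.
#' @slot cvFolds cross-validation folds for [runProtocol()] (0 skips CV).
#' @slot trainFraction hold-out training fraction.
#' @slot normalize apply per-channel z-scoring fit on the training split.
#' @export
setClass("TrainConfig",
  representation(optimizer = "character", learningRate = "numeric",
                 epochs = "integer", batchSize = "integer", loss = "character",
                 seed = "integer", cvFolds = "integer",
                 trainFraction = "numeric", normalize = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@optimizer != "adam") msg <- c(msg, "optimizer must be 'adam'")
    if (object@epochs < 1L || object@batchSize < 1L)
      msg <- c(msg, "epochs and batchSize must be >= 1")
    if (!object@loss %in% c("binary_cross_entropy",
                            "categorical_cross_entropy"))
      msg <- c(msg, "unknown loss")
    if (object@trainFraction <= 0 || object@trainFraction >= 1)
      msg <- c(msg, "trainFraction must be in (0, 1)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a TrainConfig
#'
#' @param task "binary" or "three_class"; binds the loss.
#' @param learningRate Adam learning rate.
#' @param epochs number of epochs.
#' @param batchSize minibatch size.
#' @param seed RNG seed.
#' @param cvFolds folds for [runProtocol()]; 0 skips the CV stage.
#' @param trainFraction scrambled hold-out training fraction.
#' @param normalize z-score channels using training-split statistics.
#' @return a [TrainConfig-class].
#' @export
#' @examples
#' trainConfig("three_class", epochs = 5, seed = 1)
trainConfig <- function(task = c("three_class", "binary"),
                        learningRate = 0.001, epochs = 100L, batchSize = 40L,
                        seed = 1L, cvFolds = 10L, trainFraction = 0.7,
                        normalize = TRUE) {
  task <- match.arg(task)
  new("TrainConfig", optimizer = "adam",
      learningRate = as.numeric(learningRate), epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      loss = if (task == "binary") "binary_cross_entropy"
             else "categorical_cross_entropy",
      seed = as.integer(seed), cvFolds = as.integer(cvFolds),
      trainFraction = as.numeric(trainFraction),
      normalize = as.logical(normalize))
}

#' FittedModel: a trained network with its preprocessing state
#'
#' @slot graph the [ModelGraph-class] that was instantiated.
#' @slot weights list of branch/head weight matrices and biases.
#' @slot norm per-channel means and sds used for input z-scoring.
#' @slot history data.frame with per-epoch loss and training accuracy.
#' @slot config the [TrainConfig-class] used.
#' @export
setClass("FittedModel",
  representation(graph = "ModelGraph", weights = "list", norm = "list",
                 history = "data.frame", config = "TrainConfig"))

setMethod("show", "FittedModel", function(object) {
  h <- object@history
  cat(sprintf("FittedModel (%s): %d epochs, final loss %.4f, train acc %.3f\n",
              object@graph@task, nrow(h), tail(h$loss, 1),
              tail(h$accuracy, 1)))
})

#' EvalReport: confusion matrix and classification metrics
#'
#' Accuracy is the fraction of correct predictions,
#' (TP + TN) / total population in the binary case. Precision is
#' TP / (TP + FP), recall TP / (TP + FN), and F1 the harmonic mean
#' 2 * precision * recall / (precision + recall). For the 3-class task the
#' headline precision/recall/F1 are macro averages over per-class
#' one-vs-rest values; micro and weighted variants are kept in
#' \code{metadata}.
#'
#' @slot confusion square count matrix, rows = true, cols = predicted.
#' @slot accuracy,precision,recall,f1 headline metrics in [0, 1].
#' @slot perClass data.frame of per-class one-vs-rest metrics.
#' @slot nTest number of evaluated windows.
#' @slot metadata list (seeds, averaging variants, config hash...).
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 precision = "numeric", recall = "numeric", f1 = "numeric",
                 perClass = "data.frame", nTest = "integer",
                 metadata = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@confusion) != ncol(object@confusion))
      msg <- c(msg, "confusion matrix must be square")
    if (any(object@confusion < 0))
      msg <- c(msg, "confusion entries must be non-negative")
    if (sum(object@confusion) != object@nTest)
      msg <- c(msg, "confusion entries must sum to nTest")
    m <- c(object@accuracy, object@precision, object@recall, object@f1)
    if (any(m < 0 | m > 1)) msg <- c(msg, "metrics must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname accessors
#' @export
setGeneric("confusionMatrix", function(object)
  standardGeneric("confusionMatrix"))
#' @rdname accessors
#' @export
setMethod("confusionMatrix", "EvalReport", function(object) object@confusion)

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setMethod("accuracy", "EvalReport", function(object) object@accuracy)

#' @rdname accessors
#' @export
setGeneric("f1Score", function(object) standardGeneric("f1Score"))
#' @rdname accessors
#' @export
setMethod("f1Score", "EvalReport", function(object) object@f1)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf(
    "EvalReport: n = %d | accuracy %.4f precision %.4f recall %.4f F1 %.4f\n",
    object@nTest, object@accuracy, object@precision, object@recall,
    object@f1))
  print(object@confusion)
})

## ---- SyntheticSpec --------------------------------------------------------

#' SyntheticSpec: parameters of the synthetic multimodal generator
#'
#' Describes a simulated study session: an ordered condition schedule and,
#' per condition, the signal statistics that drive each channel (pulse rate
#' for ECG/BVP, tonic level and phasic event rate for EDA, breathing rate for
#' respiration, temperature baseline and drift, accelerometer activity,
#' EMG amplitude), plus per-channel additive noise and a master seed.
#'
#' @slot nSubjects number of subjects to simulate.
#' @slot schedule data.frame with columns condition (character) and
#'   seconds (numeric), in session order.
#' @slot conditionParams named list: condition -> named numeric parameters
#'   (pulseBpm, edaTonic, edaEventsPerMin, respPerMin, tempC, tempDriftC,
#'   accSd, emgSd).
#' @slot noiseSd named numeric, additive Gaussian noise sd per channel family
#'   (ECG, BVP, EDA, RESP, TEMP, ACC, EMG).
#' @slot subjectVariability relative sd of per-subject parameter jitter.
#' @slot seed master integer seed.
#' @export
setClass("SyntheticSpec",
  representation(nSubjects = "integer", schedule = "data.frame",
                 conditionParams = "list", noiseSd = "numeric",
                 subjectVariability = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
    if (!all(c("condition", "seconds") %in% names(object@schedule)))
      msg <- c(msg, "schedule needs 'condition' and 'seconds' columns")
    else if (any(object@schedule$seconds <= 0))
      msg <- c(msg, "schedule durations must be positive")
    known <- names(object@conditionParams)
    miss <- setdiff(unique(object@schedule$condition),
                    c(known, "transient", "meditation"))
    if (length(miss))
      msg <- c(msg, sprintf("no parameters for condition(s): %s",
                            paste(miss, collapse = ", ")))
    if (object@subjectVariability < 0)
      msg <- c(msg, "subjectVariability must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d subject(s), seed %d\n", object@nSubjects,
              object@seed))
  cat(sprintf("  schedule: %s (total %.0f s)\n",
              paste(sprintf("%s %gs", object@schedule$condition,
                            object@schedule$seconds), collapse = ", "),
              sum(object@schedule$seconds)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
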
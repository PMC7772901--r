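## Declarative network construction: the chest multi-branch 1D CNN and the
## wrist multilayer perceptron, with exact valid-convolution arithmetic.

#' Output length of a valid 1D convolution or pooling stage
#'
#' Valid (no padding) sliding-window arithmetic with floor rounding:
#' floor((inputLen - kernel) / stride) + 1. Used for both convolution and
#' max pooling.
#'
#' @param inputLen input length in samples; must be at least `kernel`.
#' @param kernel window length in samples.
#' @param stride hop in samples.
#' @return number of valid window positions.
#' @export
#' @examples
#' layerOutLen(3500, 15, 2)  # 1743
#' layerOutLen(435, 4, 4)    # 108
layerOutLen <- function(inputLen, kernel, stride) {
  stopifnot(kernel >= 1, stride >= 1)
  if (inputLen < kernel)
    stop(sprintf("input of %d samples is shorter than the %d-sample kernel",
                 inputLen, kernel))
  as.integer((inputLen - kernel) %/% stride + 1L)
}

#' The default 3-stage chest convolutional block
#'
#' Stage 1: 8 filters of length 15, stride 2, then 4/4 max pooling.
#' Stage 2: 16 filters of length 7, stride 2, then 4/4 max pooling.
#' Stage 3: 32 filters of length 3, stride 1, then 2/2 max pooling.
#' All stages use ReLU. On a 3500-sample (5 s at 700 Hz) input the default
#' chain gives 32 maps of length 25 (3500 -> 1743 -> 435 -> 215 -> 53 -> 51
#' -> 25). `variant = "finalPool3"` replaces the last pooling stage with
#' size/stride 3, the single-change configuration whose output maps have
#' length 17 instead.
#'
#' @param inputLen samples per window (3500 for 5 s chest windows).
#' @param variant "default" or "finalPool3".
#' @return a [ConvBlockSpec-class].
#' @export
chestConvBlock <- function(inputLen = 3500L,
                           variant = c("default", "finalPool3")) {
  variant <- match.arg(variant)
  lastPool <- if (variant == "finalPool3") 3L else 2L
  new("ConvBlockSpec", inputLen = as.integer(inputLen), layers = list(
    convLayerSpec(8L, 15L, 2L, 4L, 4L),
    convLayerSpec(16L, 7L, 2L, 4L, 4L),
    convLayerSpec(32L, 3L, 1L, lastPool, lastPool)))
}

#' Output shape of a convolutional block
#'
#' Chains [layerOutLen()] through convolution and pooling of all three
#' stages.
#'
#' @param spec a [ConvBlockSpec-class].
#' @return integer vector `c(nMaps, mapLen)`.
#' @export
#' @examples
#' convBlockOutputShape(chestConvBlock())               # 32 25
#' convBlockOutputShape(chestConvBlock(variant = "finalPool3"))  # 32 17
convBlockOutputShape <- function(spec) {
  stopifnot(is(spec, "ConvBlockSpec"))
  len <- spec@inputLen
  for (i in seq_along(spec@layers)) {
    ly <- spec@layers[[i]]
    len <- tryCatch(layerOutLen(len, ly@kernel, ly@stride),
                    error = function(e) stop(sprintf(
                      "block infeasible at stage %d convolution: %s",
                      i, conditionMessage(e))))
    len <- tryCatch(layerOutLen(len, ly@pool, ly@poolStride),
                    error = function(e) stop(sprintf(
                      "block infeasible at stage %d pooling: %s",
                      i, conditionMessage(e))))
  }
  c(nMaps = spec@layers[[length(spec@layers)]]@nFilters, mapLen = len)
}

convBlockLayers <- function(block) {
  layers <- list()
  for (ly in block@layers) {
    layers[[length(layers) + 1L]] <-
      list(type = "conv", nFilters = ly@nFilters, kernel = ly@kernel,
           stride = ly@stride, activation = ly@activation)
    layers[[length(layers) + 1L]] <-
      list(type = "maxpool", pool = ly@pool, poolStride = ly@poolStride)
  }
  layers
}

denseParams <- function(inWidth, outWidth) (inWidth + 1) * outWidth

headLayers <- function(widths, task) {
  head <- lapply(widths, function(w) list(width = as.integer(w),
                                          activation = "relu"))
  out <- if (task == "binary") list(width = 1L, activation = "sigmoid")
         else list(width = 3L, activation = "softmax")
  c(head, list(out))
}

#' Build the chest multi-branch deep 1D convolutional network
#'
#' One identical convolutional block per chest input signal (5 physiological
#' channels plus the 3 accelerometer axes, each axis a separate input, for 8
#' branches; 5 branches when the accelerometer is excluded). All block
#' outputs are flattened, concatenated into one vector and passed through
#' fully connected layers of 32 and 16 ReLU units; the output layer is one
#' sigmoid unit for binary stress detection or three softmax units for
#' 3-class affect classification.
#'
#' @param block the shared [ConvBlockSpec-class]; window length per channel
#'   must equal `block@inputLen`.
#' @param channels ordered channel names, one branch each.
#' @param task "binary" or "three_class".
#' @param headWidths widths of the two hidden dense layers.
#' @return a [ModelGraph-class].
#' @export
#' @examples
#' g <- buildChestCnn(task = "three_class")
#' parameterCount(g)
buildChestCnn <- function(block = chestConvBlock(),
                          channels = chestChannels(),
                          task = c("three_class", "binary"),
                          headWidths = c(32L, 16L)) {
  task <- match.arg(task)
  if (!length(channels)) stop("channel list must not be empty")
  shape <- convBlockOutputShape(block)
  outWidth <- as.integer(shape[["nMaps"]] * shape[["mapLen"]])
  layers <- convBlockLayers(block)
  branches <- lapply(channels, function(ch)
    list(channels = ch, inputLen = block@inputLen, layers = layers,
         outWidth = outWidth))
  names(branches) <- channels

  nParams <- 0
  chIn <- 1L
  for (ly in block@layers) {
    nParams <- nParams + (ly@kernel * chIn + 1) * ly@nFilters
    chIn <- ly@nFilters
  }
  nParams <- nParams * length(channels)
  inW <- outWidth * length(channels)
  head <- headLayers(headWidths, task)
  for (l in head) {
    nParams <- nParams + denseParams(inW, l$width)
    inW <- l$width
  }
  new("ModelGraph", branches = branches, head = head, task = task,
      parameterCount = nParams,
      metadata = list(site = "chest", concatWidth = outWidth *
                        length(channels), block = block))
}

#' Build the wrist multilayer perceptron
#'
#' The BVP window (320 samples at 5 s) passes through two dense ReLU layers
#' of 64 and 32 units; the three accelerometer axes are flattened axis-major
#' into one 480-sample vector and pass through one dense ReLU layer of 32
#' units. Both branch outputs are concatenated with the raw EDA and
#' temperature windows (20 samples each), a 104-wide vector under the
#' defaults, and fed through three fully connected layers: `headWidth` ReLU
#' units, 8 ReLU units, and the task output (8 -> 1 sigmoid for binary,
#' 8 -> 3 softmax for 3-class).
#'
#' @param task "binary" or "three_class".
#' @param includeAcc include the accelerometer branch.
#' @param windowS window duration in seconds (fixes input lengths).
#' @param headWidth width of the first fused dense layer.
#' @return a [ModelGraph-class].
#' @export
#' @examples
#' buildWristMlp(task = "binary")
buildWristMlp <- function(task = c("three_class", "binary"),
                          includeAcc = TRUE, windowS = 5,
                          headWidth = 64L) {
  task <- match.arg(task)
  rates <- wristRates()
  nBvp <- as.integer(round(rates[["BVP"]] * windowS))
  nAcc <- as.integer(round(rates[["ACC_X"]] * windowS))
  nEda <- as.integer(round(rates[["EDA"]] * windowS))
  nTemp <- as.integer(round(rates[["TEMP"]] * windowS))
  dense <- function(w) list(type = "dense", width = as.integer(w),
                            activation = "relu")
  branches <- list(
    BVP = list(channels = "BVP", inputLen = nBvp,
               layers = list(dense(64), dense(32)), outWidth = 32L))
  if (includeAcc)
    branches$ACC <- list(channels = c("ACC_X", "ACC_Y", "ACC_Z"),
                         inputLen = 3L * nAcc, layers = list(dense(32)),
                         outWidth = 32L)
  branches$EDA <- list(channels = "EDA", inputLen = nEda, layers = list(),
                       outWidth = nEda)
  branches$TEMP <- list(channels = "TEMP", inputLen = nTemp, layers = list(),
                        outWidth = nTemp)

  nParams <- denseParams(nBvp, 64) + denseParams(64, 32)
  if (includeAcc) nParams <- nParams + denseParams(3L * nAcc, 32)
  inW <- sum(vapply(branches, function(b) b$outWidth, integer(1)))
  concatWidth <- inW
  head <- headLayers(c(headWidth, 8L), task)
  for (l in head) {
    nParams <- nParams + denseParams(inW, l$width)
    inW <- l$width
  }
  new("ModelGraph", branches = branches, head = head, task = task,
      parameterCount = nParams,
      metadata = list(site = "wrist", concatWidth = concatWidth,
                      includeAcc = includeAcc))
}

#' Apply an activation function
#'
#' ReLU is elementwise max(0, z); sigmoid is 1 / (1 + exp(-z)); softmax is
#' the normalized exponential exp(z_j) / sum_k exp(z_k), computed with a
#' max shift for numerical stability so its output is non-negative and sums
#' to one.
#'
#' @param name "relu", "sigmoid", "softmax" or "linear".
#' @param v numeric vector (softmax normalizes over the whole vector).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' applyActivation("relu", c(-2, 0, 3))
#' applyActivation("softmax", c(1, 1, 1))
applyActivation <- function(name, v) {
  switch(name,
    relu = pmax(0, v),
    sigmoid = 1 / (1 + exp(-v)),
    softmax = { e <- exp(v - max(v)); e / sum(e) },
    linear = v,
    stop("unknown activation '", name, "'"))
}

#' Structural difference between two model graphs
#'
#' Compares two [ModelGraph-class] objects component by component and
#' returns the paths that differ (branch layer fields, head layer fields,
#' task, parameter count). Binary and 3-class variants of the same
#' architecture differ only in the final head layer (and consequently the
#' task and parameter count).
#'
#' @param a,b [ModelGraph-class] objects.
#' @return character vector of differing component paths; empty if
#'   structurally identical.
#' @export
#' @examples
#' graphDiff(buildChestCnn(task = "binary"),
#'           buildChestCnn(task = "three_class"))
graphDiff <- function(a, b) {
  diffs <- character()
  if (!identical(names(a@branches), names(b@branches)))
    diffs <- c(diffs, "branches/names")
  for (nm in intersect(names(a@branches), names(b@branches)))
    if (!identical(a@branches[[nm]], b@branches[[nm]]))
      diffs <- c(diffs, sprintf("branches/%s", nm))
  nh <- max(length(a@head), length(b@head))
  for (i in seq_len(nh)) {
    la <- if (i <= length(a@head)) a@head[[i]] else NULL
    lb <- if (i <= length(b@head)) b@head[[i]] else NULL
    if (!identical(la, lb)) diffs <- c(diffs, sprintf("head/%d", i))
  }
  if (!identical(a@task, b@task)) diffs <- c(diffs, "task")
  if (!identical(a@parameterCount, b@parameterCount))
    diffs <- c(diffs, "parameterCount")
  diffs
}
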
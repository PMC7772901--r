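## Fixed-duration windowing of multi-rate records, window-label assignment,
## task-label mapping, scrambled splits and cross-validation folds.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Assign a single condition to a window's label slice
#'
#' Returns the modal condition code of the slice provided its share of the
#' slice is at least `purity` and it belongs to the allowed condition set;
#' otherwise the window is rejected (`NA`). At the default purity of 1 only
#' single-condition windows are accepted, so windows straddling a condition
#' transition are dropped. Ties between equally frequent codes are broken
#' towards the smallest code.
#'
#' @param labelSlice non-empty integer vector of condition codes.
#' @param purity minimum modal share in (0, 1].
#' @param conditions integer codes eligible to label a window.
#' @return the winning condition code, or `NA_integer_` for a rejected
#'   window.
#' @export
#' @examples
#' assignWindowCondition(rep(2L, 10))                   # stress
#' assignWindowCondition(c(rep(2L, 6), rep(1L, 4)))     # rejected at purity 1
#' assignWindowCondition(c(rep(2L, 6), rep(1L, 4)), purity = 0.5)
assignWindowCondition <- function(labelSlice, purity = 1.0,
                                  conditions = studyConditions()) {
  stopifnot(length(labelSlice) > 0, purity > 0, purity <= 1)
  tab <- table(labelSlice)
  modal <- as.integer(names(tab)[which.max(tab)])
  share <- max(tab) / length(labelSlice)
  if (share >= purity - 1e-12 && modal %in% conditions) modal
  else NA_integer_
}

#' Segment a record into fixed-duration windows
#'
#' Windows are taken at t = 0, strideS, 2 strideS, ... seconds. A window is
#' emitted only when every channel has a full-length slice (rate x windowS
#' samples at the channel's native rate) and the label rule of
#' [assignWindowCondition()] accepts its 700 Hz label slice. With the default
#' 5 s windows a chest channel contributes 3500 samples per window and the
#' wrist channels 320 (BVP) / 160 (each ACC axis) / 20 (EDA, TEMP).
#'
#' @param record a valid [SubjectRecord-class].
#' @param windowS window duration in seconds.
#' @param strideS hop between window starts in seconds (defaults to the
#'   window length, i.e. non-overlapping windows).
#' @param site which sensor site to segment, "chest" or "wrist".
#' @param includeAcc include the accelerometer axes.
#' @param purity minimum modal label share; see [assignWindowCondition()].
#' @param conditions condition codes eligible to label a window.
#' @return an unmapped [WindowSet-class] (task "none").
#' @export
segmentRecord <- function(record, windowS = 5, strideS = windowS,
                          site = c("chest", "wrist"), includeAcc = TRUE,
                          purity = 1.0, conditions = studyConditions()) {
  site <- match.arg(site)
  stopifnot(windowS > 0, strideS > 0)
  chans <- slot(record, site)
  if (!includeAcc)
    chans <- chans[!grepl("^ACC_", names(chans))]
  if (!length(chans)) stop("record has no channels at site ", site)
  rates <- vapply(chans, function(c) c@rate, numeric(1))
  if (windowS * min(rates) < 1)
    stop(sprintf(
      "configuration error: window of %g s holds < 1 sample at %g Hz",
      windowS, min(rates)))
  lb <- record@labels
  duration <- length(lb@values) / lb@rate
  nPerWin <- round(rates * windowS)
  nLab <- round(lb@rate * windowS)

  starts <- seq(0, by = strideS,
                length.out = max(0, floor((duration - windowS) / strideS +
                                            1e-9) + 1))
  keep <- logical(length(starts))
  cond <- integer(length(starts))
  for (i in seq_along(starts)) {
    t <- starts[i]
    full <- all(round(rates * t) + nPerWin <=
                  vapply(chans, length, integer(1)))
    i0 <- round(lb@rate * t)
    if (!full || i0 + nLab > length(lb@values)) next
    cc <- assignWindowCondition(lb@values[(i0 + 1):(i0 + nLab)], purity,
                                conditions)
    if (!is.na(cc)) { keep[i] <- TRUE; cond[i] <- cc }
  }
  starts <- starts[keep]; cond <- cond[keep]
  signals <- lapply(names(chans), function(nm) {
    r <- rates[[nm]]; n <- nPerWin[[nm]]; v <- chans[[nm]]@values
    idx <- outer(seq_len(n), round(r * starts), `+`)
    matrix(v[idx], nrow = n)
  })
  names(signals) <- names(chans)
  new("WindowSet", signals = signals, rates = rates, site = site,
      windowS = as.numeric(windowS),
      subject = rep(record@subjectId, length(starts)), tStart = starts,
      condition = cond, task = "none", labels = integer(),
      metadata = list(strideS = strideS, purity = purity,
                      includeAcc = includeAcc))
}

#' Segment several records and pool the windows
#'
#' @param records list of [SubjectRecord-class].
#' @param ... passed to [segmentRecord()].
#' @return one pooled [WindowSet-class].
#' @export
segmentRecords <- function(records, ...) {
  combineWindowSets(lapply(records, segmentRecord, ...))
}

#' Map window conditions to task labels
#'
#' For the 3-class affect task: baseline -> 0, stress -> 1, amusement -> 2.
#' For binary stress detection: stress -> 1, baseline and amusement -> 0
#' (non-stress). Windows carrying other documented codes (transient,
#' meditation, ...) are dropped and counted in the result's metadata; codes
#' outside the documented set raise an error naming the code.
#'
#' @param ws an unmapped [WindowSet-class].
#' @param task "binary" or "three_class".
#' @return a mapped [WindowSet-class] with per-window labels.
#' @export
mapTaskLabels <- function(ws, task = c("three_class", "binary")) {
  task <- match.arg(task)
  if (ws@task != "none")
    stop("WindowSet is already mapped to task ", ws@task)
  unknown <- setdiff(unique(ws@condition), conditionCodes())
  if (length(unknown))
    stop("unknown condition code(s): ", paste(unknown, collapse = ", "))
  sc <- studyConditions()
  keep <- ws@condition %in% sc
  dropped <- sum(!keep)
  kept <- ws[keep]
  labels <- if (task == "three_class") {
    c(0L, 1L, 2L)[match(kept@condition, sc)]
  } else {
    as.integer(kept@condition == sc[["stress"]])
  }
  mapping <- if (task == "three_class")
    c(baseline = 0L, stress = 1L, amusement = 2L)
  else c(baseline = 0L, stress = 1L, amusement = 0L)
  initialize(kept, task = task, labels = labels,
             metadata = c(kept@metadata,
                          list(mapping = mapping, droppedNonStudy = dropped)))
}

#' Scrambled train/test split
#'
#' Randomly scrambles the windows and partitions them into training and
#' testing sets, by default with a 7:3 ratio. The partition is disjoint and
#' exhaustive and identical for identical seeds. The default split is
#' window-level, which can place windows of one subject on both sides;
#' `bySubject = TRUE` instead splits whole subjects (the stricter,
#' subject-independent alternative).
#'
#' @param ws a mapped [WindowSet-class].
#' @param trainFraction fraction of windows (or subjects) to train on.
#' @param seed integer seed.
#' @param bySubject split at subject level instead of window level.
#' @return list with elements `train` and `test` ([WindowSet-class]).
#' @export
scrambleSplit <- function(ws, trainFraction = 0.7, seed = 1L,
                          bySubject = FALSE) {
  n <- length(ws)
  stopifnot(trainFraction > 0, trainFraction < 1)
  if (n < 2L) stop("need at least 2 windows to split")
  if (bySubject) {
    subj <- unique(ws@subject)
    if (length(subj) < 2L) stop("need at least 2 subjects for bySubject split")
    nTr <- max(1L, min(length(subj) - 1L,
                       round(trainFraction * length(subj))))
    trSubj <- withSeed(seed, sample(subj, nTr))
    trainIdx <- which(ws@subject %in% trSubj)
  } else {
    nTr <- max(1L, min(n - 1L, round(trainFraction * n)))
    perm <- withSeed(seed, sample.int(n))
    trainIdx <- sort(perm[seq_len(nTr)])
  }
  list(train = ws[trainIdx], test = ws[setdiff(seq_len(n), trainIdx)])
}

foldIndices <- function(n, k, seed) {
  if (n < k) stop(sprintf("need at least k = %d windows, have %d", k, n))
  perm <- withSeed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  split(perm, rep(seq_len(k), sizes))
}

#' k-fold cross-validation folds
#'
#' Builds `k` pairwise-disjoint, exhaustive test folds whose sizes differ by
#' at most one (tenfold by default), deterministically per seed.
#'
#' @param ws a mapped [WindowSet-class] with at least `k` windows.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` lists, each with `train` and `test`
#'   [WindowSet-class] elements.
#' @export
makeFolds <- function(ws, k = 10L, seed = 1L) {
  n <- length(ws)
  folds <- foldIndices(n, k, seed)
  lapply(folds, function(testIdx) {
    testIdx <- sort(testIdx)
    list(train = ws[setdiff(seq_len(n), testIdx)], test = ws[testIdx])
  })
}
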
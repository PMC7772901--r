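singleConditionRecord <- function(seconds, seed = 5L) {
  generateSubject(syntheticSpec(
    schedule = data.frame(condition = "stress", seconds = seconds),
    seed = seed), 1L)
}

test_that("5 s chest windows are 3500-sample vectors, 10 per 50 s record", {
  rec <- singleConditionRecord(50)   # 35,000 samples per chest channel
  expect_length(channelValues(channels(rec)$ECG), 35000)
  ws <- segmentRecord(rec, windowS = 5, site = "chest")
  expect_length(ws, 10)
  for (ch in channelNames(ws))
    expect_identical(nrow(ws@signals[[ch]]), 3500L)
  # windows start at t = 0, 5, 10, ...
  expect_equal(ws@tStart, seq(0, 45, by = 5))
  # slices are verbatim copies of the source signal
  expect_identical(ws@signals$ECG[, 3],
                   channelValues(channels(rec)$ECG)[(2 * 3500 + 1):(3 * 3500)])
})

test_that("wrist 5 s windows have native-rate lengths 320/160/20/20", {
  ws <- segmentRecord(tinyRecord(seconds = 10), site = "wrist")
  lens <- vapply(ws@signals, nrow, integer(1))
  expect_identical(lens[c("BVP", "ACC_X", "ACC_Y", "ACC_Z", "EDA", "TEMP")],
                   c(BVP = 320L, ACC_X = 160L, ACC_Y = 160L, ACC_Z = 160L,
                     EDA = 20L, TEMP = 20L))
})

test_that("window counts match a brute-force slicer on random records", {
  set.seed(31)
  for (i in 1:20) {
    seconds <- runif(1, 6, 40)
    windowS <- sample(2:6, 1)
    strideS <- sample(1:6, 1)
    rec <- singleConditionRecord(seconds, seed = i)
    ws <- segmentRecord(rec, windowS = windowS, strideS = strideS)
    nLab <- length(channelValues(labelTrack(rec)))
    expect_identical(length(ws),
                     bruteWindowCount(nLab, 700, windowS, strideS),
                     info = sprintf("seconds=%.2f w=%d s=%d", seconds,
                                    windowS, strideS))
  }
})

test_that("records shorter than one window give an empty WindowSet", {
  ws <- segmentRecord(tinyRecord(seconds = 1), windowS = 5)
  expect_length(ws, 0)
})

test_that("sub-sample windows are a configuration error", {
  expect_error(segmentRecord(tinyRecord(seconds = 2), windowS = 0.1,
                             site = "wrist"),
               "configuration error")
})

test_that("window-label rule follows modal share and purity", {
  expect_identical(assignWindowCondition(rep(2L, 10)), 2L)
  mixed <- c(rep(2L, 6), rep(1L, 4))
  expect_identical(assignWindowCondition(mixed, purity = 1.0), NA_integer_)
  expect_identical(assignWindowCondition(mixed, purity = 0.5), 2L)
  # modal code outside the study set is rejected even when pure
  expect_identical(assignWindowCondition(rep(4L, 10)), NA_integer_)
  expect_identical(assignWindowCondition(rep(4L, 10), conditions = 1:4), 4L)
})

test_that("default purity rejects windows straddling condition changes", {
  # 7 s + 8 s segments: the 5 s window starting at t = 5 mixes conditions
  rec <- generateSubject(syntheticSpec(schedule = data.frame(
    condition = c("baseline", "stress"), seconds = c(7, 8)), seed = 2), 1L)
  ws <- segmentRecord(rec, windowS = 5)
  expect_equal(ws@tStart, c(0, 10))
  expect_identical(windowConditions(ws), c(1L, 2L))
  # a majority rule keeps the straddling window
  ws2 <- segmentRecord(rec, windowS = 5, purity = 0.5)
  expect_equal(ws2@tStart, c(0, 5, 10))
  expect_identical(windowConditions(ws2)[2], 2L)  # 3 s stress vs 2 s baseline
})

test_that("task mapping encodes 3-class and binary labels per the tasks", {
  rec <- tinyRecord(seconds = 10)
  ws <- segmentRecord(rec)
  expect_identical(windowConditions(ws), rep(1:3, each = 2))
  ws3 <- mapTaskLabels(ws, "three_class")
  expect_identical(windowLabels(ws3), rep(0:2, each = 2))
  wsb <- mapTaskLabels(ws, "binary")
  expect_identical(windowLabels(wsb), rep(c(0L, 1L, 0L), each = 2))
  expect_error(mapTaskLabels(ws3, "binary"), "already mapped")
})

test_that("meditation windows are dropped with a count; unknown codes error", {
  rec <- generateSubject(syntheticSpec(schedule = data.frame(
    condition = c("baseline", "meditation", "stress"), seconds = 5),
    seed = 9), 1L)
  ws <- segmentRecord(rec, conditions = c(1:4))
  expect_identical(windowConditions(ws), c(1L, 4L, 2L))
  ws3 <- mapTaskLabels(ws, "three_class")
  expect_length(ws3, 2)
  expect_identical(ws3@metadata$droppedNonStudy, 1L)

  bad <- ws
  bad@condition[1] <- 9L
  expect_error(mapTaskLabels(bad, "binary"), "unknown condition code.*9")
})

test_that("scrambled split is a seeded disjoint exhaustive 7:3 partition", {
  ws <- mapTaskLabels(
    segmentRecords(generateDataset(tinySpec(seconds = 20, nSubjects = 2)),
                   site = "wrist"), "three_class")
  expect_length(ws, 24)
  for (seed in c(1L, 5L)) {
    sp <- scrambleSplit(ws, 0.7, seed)
    expect_length(sp$train, round(0.7 * 24))
    expect_length(sp$test, 24 - round(0.7 * 24))
    key <- function(s) paste(s@subject, s@tStart)
    expect_length(intersect(key(sp$train), key(sp$test)), 0)
    expect_setequal(c(key(sp$train), key(sp$test)), key(ws))
    sp2 <- scrambleSplit(ws, 0.7, seed)
    expect_identical(key(sp2$train), key(sp$train))
  }
  expect_error(scrambleSplit(ws[1], 0.7, 1), "at least 2")
})

test_that("subject-level split keeps each subject on one side", {
  ws <- mapTaskLabels(
    segmentRecords(generateDataset(tinySpec(seconds = 15, nSubjects = 4)),
                   site = "wrist"), "binary")
  sp <- scrambleSplit(ws, 0.7, 3, bySubject = TRUE)
  expect_length(intersect(unique(sp$train@subject),
                          unique(sp$test@subject)), 0)
  expect_setequal(c(unique(sp$train@subject), unique(sp$test@subject)),
                  unique(ws@subject))
})

test_that("tenfold CV folds are balanced, disjoint and exhaustive", {
  mkws <- function(n) {
    # bare WindowSet with n windows of one tiny channel
    new("WindowSet",
        signals = list(EDA = matrix(seq_len(4 * n), nrow = 4)),
        rates = c(EDA = 4), site = "wrist", windowS = 1,
        subject = rep("S", n), tStart = seq_len(n) - 1,
        condition = rep(2L, n), task = "binary",
        labels = rep(c(0L, 1L), length.out = n), metadata = list())
  }
  ws <- mkws(100)
  folds <- makeFolds(ws, k = 10, seed = 2)
  expect_length(folds, 10)
  sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_true(all(sizes == 10))
  ids <- unlist(lapply(folds, function(f) f$test@tStart))
  expect_setequal(ids, ws@tStart)   # every window in exactly one test fold
  expect_length(ids, 100)

  folds2 <- makeFolds(mkws(105), k = 10, seed = 2)
  sizes2 <- sort(unname(vapply(folds2, function(f) length(f$test),
                               integer(1))))
  expect_identical(sizes2, c(rep(10L, 5), rep(11L, 5)))

  expect_error(makeFolds(mkws(5), k = 10, seed = 1), "at least")
})
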
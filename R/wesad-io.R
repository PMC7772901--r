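## Record I/O: native per-subject records (Python pickles, converted through
## a bundled helper script) and a self-describing plain-text fixture format
## used by tests and the synthetic generator.

FIXTURE_MAGIC <- "# wearnet subject fixture v1"

#' Write a SubjectRecord as a plain-text columnar fixture
#'
#' The fixture is self-describing: a header block declares the subject id and
#' one `# channel:` line per column (site, name, rate in Hz, sample count),
#' followed by tab-separated data with one column per channel in header
#' order. Columns shorter than the longest channel are padded with `NA`.
#' Values are written with 17 significant digits, so a write/read round trip
#' reproduces every sample bit-for-bit.
#'
#' @param record a valid [SubjectRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readSubjectFixture()]
#' @export
writeSubjectFixture <- function(record, path) {
  stopifnot(is(record, "SubjectRecord"))
  validObject(record)
  cols <- list()
  hdr <- c(FIXTURE_MAGIC, sprintf("# subject: %s", record@subjectId))
  for (site in c("chest", "wrist")) {
    for (nm in names(slot(record, site))) {
      cs <- slot(record, site)[[nm]]
      hdr <- c(hdr, sprintf("# channel: %s %s %.10g %d", site, nm, cs@rate,
                            length(cs@values)))
      cols[[length(cols) + 1L]] <- formatC(cs@values, format = "g",
                                           digits = 17)
    }
  }
  lb <- record@labels
  hdr <- c(hdr, sprintf("# channel: label %s %.10g %d", lb@name, lb@rate,
                        length(lb@values)))
  cols[[length(cols) + 1L]] <- formatC(as.integer(lb@values), format = "d")
  nmax <- max(vapply(cols, length, integer(1)))
  padded <- vapply(cols, function(v) c(v, rep("NA", nmax - length(v))),
                   character(nmax))
  if (nmax == 1L) padded <- matrix(padded, nrow = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(do.call(paste, c(asplit(padded, 2), list(sep = "\t"))), con)
  invisible(path)
}

parseFixtureHeader <- function(lines, path) {
  if (length(lines) == 0L || lines[1] != FIXTURE_MAGIC)
    stop(sprintf("parse error in '%s' line 1: missing fixture magic header",
                 path))
  isHdr <- startsWith(lines, "#")
  nHdr <- match(FALSE, isHdr, nomatch = length(lines) + 1L) - 1L
  hdr <- lines[seq_len(nHdr)]
  subj <- sub("^# subject: *", "", grep("^# subject:", hdr, value = TRUE))
  if (length(subj) != 1L)
    stop(sprintf("parse error in '%s': exactly one '# subject:' line required",
                 path))
  chLines <- grep("^# channel:", hdr)
  if (!length(chLines))
    stop(sprintf("parse error in '%s': no '# channel:' declarations", path))
  decl <- lapply(chLines, function(i) {
    f <- strsplit(sub("^# channel: *", "", hdr[i]), " +")[[1]]
    if (length(f) != 4L)
      stop(sprintf(
        "parse error in '%s' line %d: channel declaration needs 'site name rate n'",
        path, i))
    list(site = f[1], name = f[2], rate = as.numeric(f[3]),
         n = as.integer(f[4]), line = i)
  })
  list(subject = subj, decl = decl, nHdr = nHdr)
}

#' Read a plain-text subject fixture
#'
#' Parses the columnar format written by [writeSubjectFixture()]. Malformed
#' headers and ragged data rows raise parse errors that name the offending
#' line; declared sample counts that disagree with the data, or rates that
#' disagree with the label-track duration, raise validation errors.
#'
#' @param path fixture file path.
#' @param check run [validateRecord()] and fail on any diagnostic.
#' @return a [SubjectRecord-class].
#' @export
readSubjectFixture <- function(path, check = TRUE) {
  if (!file.exists(path))
    stop(sprintf("I/O error: cannot open '%s': no such file", path))
  lines <- readLines(path)
  h <- parseFixtureHeader(lines, path)
  nCol <- length(h$decl)
  body <- lines[-seq_len(h$nHdr)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(parts)
  bad <- which(lens != nCol)
  if (length(bad))
    stop(sprintf(
      "parse error in '%s' line %d: %d fields, expected %d columns",
      path, h$nHdr + bad[1], lens[bad[1]], nCol))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts, use.names = FALSE))),
              nrow = nCol)
  chest <- list(); wrist <- list(); labels <- NULL
  for (j in seq_len(nCol)) {
    d <- h$decl[[j]]
    col <- m[j, ]
    if (d$n > length(col) || (d$n > 0 && anyNA(col[seq_len(d$n)])))
      stop(sprintf(
        "validation error in '%s': channel %s/%s declares %d samples but column has missing values",
        path, d$site, d$name, d$n))
    cs <- ChannelSeries(d$name, d$rate, col[seq_len(d$n)])
    switch(d$site,
      chest = { chest[[d$name]] <- cs },
      wrist = { wrist[[d$name]] <- cs },
      label = { labels <- cs },
      stop(sprintf("parse error in '%s' line %d: unknown site '%s'",
                   path, d$line, d$site)))
  }
  if (is.null(labels))
    stop(sprintf("parse error in '%s': no label channel declared", path))
  rec <- SubjectRecord(h$subject, chest, wrist, labels)
  if (check) {
    diag <- validateRecord(rec)
    if (length(diag))
      stop(sprintf("validation error in '%s':\n  %s", path,
                   paste(diag, collapse = "\n  ")))
  }
  rec
}

#' Validate a SubjectRecord's cross-channel invariants
#'
#' Checks, without throwing, that all chest channels share the label track's
#' rate and length, that each wrist channel's length matches rate x duration
#' within one sample (duration taken from the label track), and that every
#' label code belongs to the documented code set 0-7. Returns diagnostics
#' rather than raising so inconsistent records can be inspected.
#'
#' @param record a [SubjectRecord-class].
#' @param expectChannels also require the full standard channel sets
#'   (8 chest channels with ACC axes split, 6 wrist channels).
#' @return character vector of diagnostics; empty iff all invariants hold.
#' @export
#' @examples
#' spec <- syntheticSpec(schedule = data.frame(
#'   condition = "baseline", seconds = 2), seed = 1)
#' validateRecord(generateSubject(spec, 1))  # character(0)
validateRecord <- function(record, expectChannels = FALSE) {
  diag <- character()
  lb <- record@labels
  duration <- length(lb@values) / lb@rate
  if (expectChannels) {
    for (nm in setdiff(chestChannels(), names(record@chest)))
      diag <- c(diag, sprintf("schema: missing chest channel %s", nm))
    for (nm in setdiff(wristChannels(), names(record@wrist)))
      diag <- c(diag, sprintf("schema: missing wrist channel %s", nm))
  }
  for (nm in names(record@chest)) {
    cs <- record@chest[[nm]]
    if (cs@rate != lb@rate)
      diag <- c(diag, sprintf(
        "rate-mismatch: chest %s at %g Hz, label track at %g Hz",
        nm, cs@rate, lb@rate))
    if (length(cs@values) != length(lb@values))
      diag <- c(diag, sprintf(
        "length-mismatch: chest %s has %d samples, label track has %d",
        nm, length(cs@values), length(lb@values)))
  }
  for (nm in names(record@wrist)) {
    cs <- record@wrist[[nm]]
    expected <- cs@rate * duration
    if (abs(length(cs@values) - expected) > 1) {
      diag <- c(diag, sprintf(
        "length-mismatch: wrist %s has %d samples, expected %.1f (%g Hz x %.2f s)",
        nm, length(cs@values), expected, cs@rate, duration))
    }
  }
  badCodes <- setdiff(unique(lb@values), conditionCodes())
  if (length(badCodes))
    diag <- c(diag, sprintf("unknown-label: code(s) %s outside documented set",
                            paste(badCodes, collapse = ", ")))
  if (any(lb@values != round(lb@values)))
    diag <- c(diag, "unknown-label: non-integer codes in label track")
  diag
}

#' Read one subject's native serialized record
#'
#' Native per-subject records are Python pickles holding a nested dictionary
#' of chest/wrist signal arrays and a 700 Hz label array. A bundled Python
#' helper (run through the `python` on `PATH`) converts the pickle to the
#' package's plain-text fixture format, which is then parsed; `.txt`/`.tsv`
#' fixture files and directories containing a single `.pkl` are also
#' accepted. Three-axis accelerometer arrays (nested N x 3 or flat) are
#' normalized to separate ACC_X/ACC_Y/ACC_Z channels, and channel names to
#' ECG/EDA/EMG/RESP/TEMP/BVP.
#'
#' @param path a `.pkl` file, a directory holding one `.pkl`, or a fixture
#'   file.
#' @param python python interpreter used for pickle conversion.
#' @return a validated [SubjectRecord-class]; any failed invariant raises.
#' @export
readWesadSubject <- function(path, python = "python") {
  if (!file.exists(path))
    stop(sprintf("I/O error: cannot open '%s': no such file or directory",
                 path))
  if (dir.exists(path)) {
    pkls <- list.files(path, pattern = "\\.pkl$", full.names = TRUE)
    if (length(pkls) != 1L)
      stop(sprintf("I/O error: '%s' must contain exactly one .pkl file",
                   path))
    path <- pkls[1]
  }
  if (grepl("\\.pkl$", path)) {
    helper <- system.file("python", "wesad_pkl_to_fixture.py",
                          package = "wearnet", mustWork = TRUE)
    tmp <- tempfile(fileext = ".fixture.txt")
    on.exit(unlink(tmp))
    out <- suppressWarnings(
      system2(python, c(shQuote(helper), shQuote(path), shQuote(tmp)),
              stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status") %||% 0L
    if (status != 0L)
      stop(sprintf("schema error reading '%s': %s", path,
                   paste(out, collapse = "; ")))
    rec <- readSubjectFixture(tmp, check = FALSE)
  } else {
    rec <- readSubjectFixture(path, check = FALSE)
  }
  diag <- validateRecord(rec, expectChannels = TRUE)
  if (length(diag))
    stop(sprintf("validation error in '%s':\n  %s", path,
                 paste(diag, collapse = "\n  ")))
  rec
}
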
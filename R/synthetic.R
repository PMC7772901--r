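## Synthetic multimodal generator: study-shaped records (chest 700 Hz, wrist
## 64/32/4/4 Hz, 700 Hz label track) with condition-dependent statistics.
## Realism is deliberately minimal -- template pulses, tonic levels with
## exponentially decaying phasic events, sinusoidal respiration, drifting
## temperature, Gaussian movement -- the point is learnable class structure
## at the right shapes and rates, not biophysical fidelity.

defaultConditionParams <- function() {
  list(
    baseline   = c(pulseBpm = 70, edaTonic = 2.0, edaEventsPerMin = 2,
                   respPerMin = 14, tempC = 34.0, tempDriftC = 0.10,
                   accSd = 0.05, emgSd = 0.05),
    stress     = c(pulseBpm = 95, edaTonic = 8.0, edaEventsPerMin = 10,
                   respPerMin = 20, tempC = 34.3, tempDriftC = 0.10,
                   accSd = 0.15, emgSd = 0.15),
    amusement  = c(pulseBpm = 80, edaTonic = 4.0, edaEventsPerMin = 5,
                   respPerMin = 16, tempC = 34.3, tempDriftC = 0.10,
                   accSd = 0.25, emgSd = 0.08),
    meditation = c(pulseBpm = 65, edaTonic = 1.5, edaEventsPerMin = 1,
                   respPerMin = 10, tempC = 34.1, tempDriftC = 0.05,
                   accSd = 0.03, emgSd = 0.04))
}

defaultNoiseSd <- function() {
  c(ECG = 0.05, BVP = 0.05, EDA = 0.05, RESP = 0.10, TEMP = 0.01,
    ACC = 0.01, EMG = 0)
}

#' Construct a SyntheticSpec
#'
#' Defaults mirror a study session visiting baseline, stress and amusement
#' (60 s each here) for 15 subjects, with physiologically plausible
#' per-condition statistics: pulse 70/95/80 beats/min, EDA tonic level
#' 2/8/4 uS with 2/10/5 phasic events/min, respiration 14/20/16 breaths/min
#' and skin temperature 34.0/34.3/34.3 C -- stress and amusement differ on
#' EDA and pulse rate but deliberately overlap on temperature, so the
#' 3-class task is learnable but not trivial from one channel.
#'
#' @param nSubjects number of subjects.
#' @param schedule data.frame with `condition` and `seconds` columns, in
#'   session order.
#' @param conditionParams named list of per-condition parameter vectors; see
#'   [SyntheticSpec-class]. Partially overriding entries are merged over the
#'   defaults.
#' @param noiseSd named numeric of per-channel additive noise sds.
#' @param subjectVariability relative sd of the per-subject lognormal jitter
#'   applied to condition parameters.
#' @param seed master integer seed.
#' @return a [SyntheticSpec-class].
#' @export
#' @examples
#' spec <- syntheticSpec(nSubjects = 2, seed = 7)
#' spec
syntheticSpec <- function(nSubjects = 15L,
                          schedule = data.frame(
                            condition = c("baseline", "stress", "amusement"),
                            seconds = 60),
                          conditionParams = list(), noiseSd = c(),
                          subjectVariability = 0.05, seed = 1L) {
  params <- defaultConditionParams()
  for (nm in names(conditionParams)) {
    base <- params[[nm]] %||% params$baseline
    base[names(conditionParams[[nm]])] <- conditionParams[[nm]]
    params[[nm]] <- base
  }
  noise <- defaultNoiseSd()
  noise[names(noiseSd)] <- noiseSd
  new("SyntheticSpec", nSubjects = as.integer(nSubjects),
      schedule = schedule, conditionParams = params, noiseSd = noise,
      subjectVariability = as.numeric(subjectVariability),
      seed = as.integer(seed))
}

## Narrow periodic template centred at phase 0.2: one sharp pulse per beat.
pulseTemplate <- function(t, bpm) {
  phase <- (t * bpm / 60) %% 1
  exp(-0.5 * ((phase - 0.2) / 0.04)^2)
}

edaSegment <- function(n, rate, seconds, tonic, eventsPerMin, noise) {
  v <- rep(tonic, n)
  nEvents <- rpois(1, eventsPerMin * seconds / 60)
  if (nEvents > 0) {
    starts <- sort(runif(nEvents, 0, seconds))
    amps <- runif(nEvents, 0.3, 0.8)
    t <- (seq_len(n) - 1) / rate
    for (i in seq_len(nEvents)) {
      after <- t >= starts[i]
      v[after] <- v[after] + amps[i] * exp(-(t[after] - starts[i]) / 2)
    }
  }
  v + rnorm(n, 0, noise)
}

synthSegment <- function(channel, rate, seconds, n, p, noise) {
  t <- (seq_len(n) - 1) / rate
  switch(sub("_[XYZ]$", "", channel),
    ECG = pulseTemplate(t, p[["pulseBpm"]]) + rnorm(n, 0, noise[["ECG"]]),
    BVP = sin(2 * pi * p[["pulseBpm"]] / 60 * t) +
      0.3 * sin(4 * pi * p[["pulseBpm"]] / 60 * t) +
      rnorm(n, 0, noise[["BVP"]]),
    EDA = edaSegment(n, rate, seconds, p[["edaTonic"]],
                     p[["edaEventsPerMin"]], noise[["EDA"]]),
    RESP = sin(2 * pi * p[["respPerMin"]] / 60 * t) +
      rnorm(n, 0, noise[["RESP"]]),
    TEMP = p[["tempC"]] + p[["tempDriftC"]] * t / max(seconds, 1) +
      rnorm(n, 0, noise[["TEMP"]]),
    ACC = {
      g <- switch(substring(channel, 5), X = 0, Y = 0, Z = 1)
      g + rnorm(n, 0, p[["accSd"]]) + rnorm(n, 0, noise[["ACC"]])
    },
    EMG = rnorm(n, 0, p[["emgSd"]]) + rnorm(n, 0, noise[["EMG"]]),
    stop("no synthesis rule for channel ", channel))
}

segmentCounts <- function(rate, seconds) {
  bounds <- round(rate * cumsum(c(0, seconds)))
  diff(bounds)
}

#' Generate one synthetic subject record
#'
#' Deterministic per (spec seed, subject index). Chest channels are
#' synthesized at 700 Hz, wrist channels at 64/32/4/4 Hz, and the label
#' track at 700 Hz follows the schedule exactly. Per-subject parameter
#' jitter is lognormal with relative sd `spec@subjectVariability`.
#'
#' @param spec a [SyntheticSpec-class].
#' @param subjectIndex 1-based subject number (also names the record).
#' @return a [SubjectRecord-class] that passes [validateRecord()].
#' @export
#' @examples
#' spec <- syntheticSpec(nSubjects = 1, schedule = data.frame(
#'   condition = c("baseline", "stress"), seconds = 5), seed = 3)
#' generateSubject(spec, 1)
generateSubject <- function(spec, subjectIndex = 1L) {
  validObject(spec)
  subjectSeed <- spec@seed + 7919L * as.integer(subjectIndex)
  withSeed(subjectSeed, {
    params <- spec@conditionParams
    if (spec@subjectVariability > 0) {
      for (nm in names(params)) {
        jit <- exp(rnorm(length(params[[nm]]), 0, spec@subjectVariability))
        params[[nm]] <- params[[nm]] * jit
      }
    }
    sched <- spec@schedule
    condCodes <- conditionCodes()
    synthSite <- function(chans, rates) {
      out <- list()
      for (ch in chans) {
        r <- rates[[ch]]
        counts <- segmentCounts(r, sched$seconds)
        segs <- lapply(seq_len(nrow(sched)), function(i) {
          p <- params[[sched$condition[i]]] %||% params$baseline
          synthSegment(ch, r, sched$seconds[i], counts[i], p, spec@noiseSd)
        })
        out[[ch]] <- ChannelSeries(ch, r, unlist(segs))
      }
      out
    }
    chest <- synthSite(chestChannels(),
                       stats::setNames(rep(chestRate(),
                                           length(chestChannels())),
                                       chestChannels()))
    wrist <- synthSite(wristChannels(), as.list(wristRates()))
    labCounts <- segmentCounts(chestRate(), sched$seconds)
    labels <- unlist(lapply(seq_len(nrow(sched)), function(i) {
      if (!sched$condition[i] %in% names(condCodes))
        stop("unknown condition ", sched$condition[i])
      rep(condCodes[[sched$condition[i]]], labCounts[i])
    }))
    SubjectRecord(sprintf("SYN%02d", subjectIndex), chest, wrist,
                  ChannelSeries("labels", chestRate(), labels))
  })
}

#' Generate a full synthetic dataset
#'
#' Per-subject seeds are derived from the master seed, so the dataset is
#' reproducible as a whole and each subject individually.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list of `spec@nSubjects` [SubjectRecord-class] objects.
#' @export
generateDataset <- function(spec) {
  lapply(seq_len(spec@nSubjects), function(i) generateSubject(spec, i))
}
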
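#' @import methods
#' @importFrom stats fft rnorm runif sd var cor pt qt integrate optimize
#'   complete.cases
#' @importFrom utils read.table write.table head combn
NULL

#' Experimental condition labels, in fixed decoding order
#'
#' The three conditions of an imagery session. The order is load-bearing:
#' nearest-neighbour decoding breaks exact distance ties in favour of the
#' earlier condition.
#' @export
EEG_CONDITIONS <- c("audio", "visual", "rest")

# ---------------------------------------------------------------------------
# SyntheticConfig
# ---------------------------------------------------------------------------

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic EEG cohort generator. Defaults emulate the
#' study design this package models: 44 participants, 18 trials in each of 3
#' conditions (audio imagery, visual imagery, resting state), 64 sensors
#' sampled at 1024 Hz for 10 s per trial, a 1/f background spectrum with an
#' alpha (10 Hz) peak, occipitally weighted broad-band power reductions during
#' imagery, and per-participant vividness ratings coupled to band-limited
#' imagery-minus-rest log power.
#'
#' @slot nParticipants number of participants.
#' @slot nTrialsPerCondition trials per condition per participant.
#' @slot nSensors number of EEG sensors.
#' @slot sfreq sampling rate, Hz.
#' @slot trialDuration trial length, seconds; \code{trialDuration * sfreq}
#'   must be a whole number of samples.
#' @slot noiseExponent slope of the 1/f^exponent background power spectrum.
#' @slot backgroundPower background power density at 1 Hz, V^2 per 1 Hz bin.
#' @slot alphaPeakFreq,alphaPeakPower,alphaPeakWidth centre (Hz), peak power
#'   (V^2 per bin) and Gaussian width (Hz) of the alpha peak.
#' @slot conditionEffects list of multiplicative band-limited power effects,
#'   each \code{list(condition, band = c(lo, hi), factor, topography)} with
#'   \code{topography} either \code{"occipital"}, \code{"uniform"} or a
#'   numeric weight per sensor in [0, 1].
#' @slot vividnessCouplings list of
#'   \code{list(modality, band = c(lo, hi), slope, noiseSD)}: during imagery
#'   trials of \code{modality}, band power is multiplied by
#'   \code{exp(slope * (vividness - 3) + noise)}, so \code{slope} is the
#'   change in imagery-minus-rest log power per rating unit.
#' @slot vividnessCorrelation latent correlation between audio and visual
#'   vividness across participants.
#' @slot ratingNoiseSD standard deviation of per-trial rating noise before
#'   rounding to the 1-5 scale.
#' @slot artifactRate probability that a (trial, sensor) cell receives an
#'   injected out-of-range excursion.
#' @slot artifactAmplitude amplitude (V) of the injected excursion.
#' @slot seed integer seed; identical seeds give byte-identical cohorts.
#' @seealso [syntheticConfig()], [generateCohort()]
#' @export
setClass("SyntheticConfig", representation(
  nParticipants = "integer",
  nTrialsPerCondition = "integer",
  nSensors = "integer",
  sfreq = "numeric",
  trialDuration = "numeric",
  noiseExponent = "numeric",
  backgroundPower = "numeric",
  alphaPeakFreq = "numeric",
  alphaPeakPower = "numeric",
  alphaPeakWidth = "numeric",
  conditionEffects = "list",
  vividnessCouplings = "list",
  vividnessCorrelation = "numeric",
  ratingNoiseSD = "numeric",
  artifactRate = "numeric",
  artifactAmplitude = "numeric",
  seed = "integer"
))

validSyntheticConfig <- function(object) {
  msg <- character(0)
  if (object@nParticipants < 1L) msg <- c(msg, "nParticipants must be >= 1")
  if (object@nTrialsPerCondition < 1L) msg <- c(msg, "nTrialsPerCondition must be >= 1")
  if (object@nSensors < 1L) msg <- c(msg, "nSensors must be >= 1")
  if (object@sfreq <= 0) msg <- c(msg, "sfreq must be positive")
  ns <- object@trialDuration * object@sfreq
  if (abs(ns - round(ns)) > 1e-9)
    msg <- c(msg, "trialDuration * sfreq must be an integral number of samples")
  for (eff in c(object@conditionEffects, object@vividnessCouplings)) {
    b <- eff$band
    if (length(b) != 2L || b[1] > b[2] || b[1] < 1 || b[2] > 40)
      msg <- c(msg, "effect bands must lie within [1, 40] Hz")
  }
  for (eff in object@conditionEffects)
    if (!eff$condition %in% EEG_CONDITIONS)
      msg <- c(msg, sprintf("unknown condition '%s' in conditionEffects", eff$condition))
  for (cp in object@vividnessCouplings)
    if (!cp$modality %in% c("audio", "visual"))
      msg <- c(msg, sprintf("unknown modality '%s' in vividnessCouplings", cp$modality))
  if (object@artifactRate < 0 || object@artifactRate > 1)
    msg <- c(msg, "artifactRate must be in [0, 1]")
  if (length(msg)) msg else TRUE
}
setValidity("SyntheticConfig", validSyntheticConfig)

#' Build a synthetic cohort configuration
#'
#' Defaults are the emulated study conditions; see
#' \linkS4class{SyntheticConfig} for the meaning of each field. The default
#' condition effects reduce broad-band and alpha power during imagery,
#' maximally over occipital sensors, with audio and visual imagery differing
#' so that conditions are decodable; the default couplings tie audio
#' vividness to 6-9 Hz and visual vividness to 14-16 Hz imagery-minus-rest
#' log power.
#'
#' @param nParticipants,nTrialsPerCondition,nSensors,sfreq,trialDuration
#'   session design; see \linkS4class{SyntheticConfig}.
#' @param noiseExponent,backgroundPower,alphaPeakFreq,alphaPeakPower,alphaPeakWidth
#'   background spectrum.
#' @param conditionEffects,vividnessCouplings effect lists; see
#'   \linkS4class{SyntheticConfig}.
#' @param vividnessCorrelation,ratingNoiseSD rating model.
#' @param artifactRate,artifactAmplitude artifact injection.
#' @param seed integer seed.
#' @return a validated \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nParticipants = 2, nSensors = 4, sfreq = 256)
#' cfg
#' @export
syntheticConfig <- function(nParticipants = 44,
                            nTrialsPerCondition = 18,
                            nSensors = 64,
                            sfreq = 1024,
                            trialDuration = 10,
                            noiseExponent = 1,
                            backgroundPower = 1e-12,
                            alphaPeakFreq = 10,
                            alphaPeakPower = 2e-12,
                            alphaPeakWidth = 1.5,
                            conditionEffects = defaultConditionEffects(),
                            vividnessCouplings = defaultVividnessCouplings(),
                            vividnessCorrelation = 0.7,
                            ratingNoiseSD = 0.25,
                            artifactRate = 0,
                            artifactAmplitude = 5e-4,
                            seed = 1L) {
  new("SyntheticConfig",
      nParticipants = as.integer(nParticipants),
      nTrialsPerCondition = as.integer(nTrialsPerCondition),
      nSensors = as.integer(nSensors),
      sfreq = as.numeric(sfreq),
      trialDuration = as.numeric(trialDuration),
      noiseExponent = noiseExponent,
      backgroundPower = backgroundPower,
      alphaPeakFreq = alphaPeakFreq,
      alphaPeakPower = alphaPeakPower,
      alphaPeakWidth = alphaPeakWidth,
      conditionEffects = conditionEffects,
      vividnessCouplings = vividnessCouplings,
      vividnessCorrelation = vividnessCorrelation,
      ratingNoiseSD = ratingNoiseSD,
      artifactRate = artifactRate,
      artifactAmplitude = artifactAmplitude,
      seed = as.integer(seed))
}

#' Default condition effects of the synthetic generator
#'
#' Imagery reduces oscillatory power relative to rest across a broad band with
#' a stronger alpha-band reduction, maximal occipitally; the audio and visual
#' reductions span different bands so the three conditions carry distinct
#' spectral signatures.
#' @return list of condition-effect descriptors.
#' @export
defaultConditionEffects <- function() {
  list(
    list(condition = "audio",  band = c(1, 24), factor = 0.90, topography = "occipital"),
    list(condition = "audio",  band = c(8, 12), factor = 0.75, topography = "occipital"),
    list(condition = "visual", band = c(1, 10), factor = 0.88, topography = "occipital"),
    list(condition = "visual", band = c(8, 12), factor = 0.65, topography = "occipital")
  )
}

#' Default vividness couplings of the synthetic generator
#'
#' More vivid imagery produces larger band-limited power reductions: audio
#' vividness is coupled to 6-9 Hz (theta), visual vividness to 14-16 Hz (low
#' beta) imagery-minus-rest log power, with slope -0.12 per rating unit.
#' @return list of coupling descriptors.
#' @export
defaultVividnessCouplings <- function() {
  list(
    list(modality = "audio",  band = c(6, 9),   slope = -0.12, noiseSD = 0.05),
    list(modality = "visual", band = c(14, 16), slope = -0.12, noiseSD = 0.05)
  )
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nParticipants, "participants,",
      object@nTrialsPerCondition, "trials x", length(EEG_CONDITIONS),
      "conditions,", object@nSensors, "sensors @", object@sfreq, "Hz,",
      object@trialDuration, "s trials\n")
  cat("  background 1/f^", object@noiseExponent, ", alpha peak ",
      object@alphaPeakFreq, " Hz; ", length(object@conditionEffects),
      " condition effects, ", length(object@vividnessCouplings),
      " vividness couplings; seed ", object@seed, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# EpochSet
# ---------------------------------------------------------------------------

#' One participant's epoched multichannel EEG
#'
#' Trials share a common sensor count and sample count. Voltages are in volts.
#' The exclusion mask marks (trial, sensor) cells whose peak-to-peak amplitude
#' range exceeded the artifact threshold; masked cells propagate as NaN power
#' downstream.
#'
#' @slot signal numeric array \code{trial x sensor x time}.
#' @slot sfreq sampling rate, Hz.
#' @slot condition character vector, one of [EEG_CONDITIONS] per trial.
#' @slot rating numeric per-trial vividness rating (1-5), NA on rest trials.
#' @slot participant participant identifier.
#' @slot sensorNames sensor labels.
#' @slot exclusionMask logical \code{trial x sensor} matrix (may be empty
#'   before screening).
#' @export
setClass("EpochSet", representation(
  signal = "array",
  sfreq = "numeric",
  condition = "character",
  rating = "numeric",
  participant = "character",
  sensorNames = "character",
  exclusionMask = "matrix"
))

setValidity("EpochSet", function(object) {
  d <- dim(object@signal)
  msg <- character(0)
  if (length(d) != 3L) msg <- c(msg, "signal must be a trial x sensor x time array")
  else {
    if (length(object@condition) != d[1]) msg <- c(msg, "one condition label per trial required")
    if (length(object@rating) != d[1]) msg <- c(msg, "one rating per trial required")
    if (length(object@sensorNames) != d[2]) msg <- c(msg, "one name per sensor required")
    if (length(object@exclusionMask) &&
        !identical(dim(object@exclusionMask), d[1:2]))
      msg <- c(msg, "exclusionMask must be trial x sensor")
  }
  if (!all(object@condition %in% EEG_CONDITIONS))
    msg <- c(msg, "unknown condition label")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@signal)
  cat("EpochSet participant", object@participant, ":", d[1], "trials x",
      d[2], "sensors x", d[3], "samples @", object@sfreq, "Hz\n")
  print(table(factor(object@condition, EEG_CONDITIONS)))
  if (length(object@exclusionMask))
    cat("  excluded (trial, sensor) cells:", sum(object@exclusionMask), "\n")
})

#' @describeIn EpochSet-class number of trials
#' @param x an \code{EpochSet}
#' @export
nTrials <- function(x) dim(x@signal)[1]

# ---------------------------------------------------------------------------
# PSDArray
# ---------------------------------------------------------------------------

#' Cohort power spectral density features
#'
#' Binned power spectral density for every trial of every participant:
#' a \code{trial x sensor x frequency} array over integer frequencies
#' 1-40 Hz, with one metadata row per trial. Cells excluded by the amplitude
#' screen are NaN across all 40 bins.
#'
#' @slot power numeric array \code{trial x sensor x 40}, non-negative or NaN.
#' @slot freqs integer frequencies, always \code{1:40} Hz.
#' @slot meta data.frame with columns \code{participant}, \code{condition},
#'   \code{trialIndex}, \code{rating}; one row per trial (row order matches
#'   the first array dimension).
#' @slot sensorNames sensor labels.
#' @slot montage data.frame of sensor positions (\code{name,x,y,z}) or empty.
#' @export
setClass("PSDArray", representation(
  power = "array",
  freqs = "integer",
  meta = "data.frame",
  sensorNames = "character",
  montage = "data.frame"
))

setValidity("PSDArray", function(object) {
  d <- dim(object@power)
  msg <- character(0)
  if (length(d) != 3L) msg <- c(msg, "power must be trial x sensor x frequency")
  if (!identical(object@freqs, 1:40)) msg <- c(msg, "frequency axis must be the integers 1-40 Hz")
  if (length(d) == 3L) {
    if (d[3] != length(object@freqs)) msg <- c(msg, "third dim must match freqs")
    if (nrow(object@meta) != d[1]) msg <- c(msg, "one metadata row per trial required")
    if (length(object@sensorNames) != d[2]) msg <- c(msg, "one name per sensor required")
  }
  bad <- object@power[!is.na(object@power)]
  if (length(bad) && any(bad < 0)) msg <- c(msg, "power must be >= 0 or NaN")
  if (!all(c("participant", "condition", "trialIndex", "rating") %in% names(object@meta)))
    msg <- c(msg, "meta needs participant, condition, trialIndex, rating")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PSDArray", function(object) {
  d <- dim(object@power)
  cat("PSDArray:", d[1], "trials x", d[2], "sensors x", d[3], "frequency bins (1-40 Hz)\n")
  cat("  participants:", length(unique(object@meta$participant)),
      " NaN cells:", sum(is.na(object@power[, , 1])), "\n")
})

#' Accessors for PSDArray
#'
#' @param x a \linkS4class{PSDArray}
#' @return \code{psdPower}: the trial x sensor x frequency array;
#'   \code{psdMeta}: the per-trial metadata; \code{psdFreqs}: integer
#'   frequencies 1-40.
#' @export
psdPower <- function(x) x@power

#' @rdname psdPower
#' @export
psdMeta <- function(x) x@meta

#' @rdname psdPower
#' @export
psdFreqs <- function(x) x@freqs

# ---------------------------------------------------------------------------
# GroundTruth / SyntheticCohort
# ---------------------------------------------------------------------------

#' Latent ground truth of a synthetic cohort
#'
#' @slot vividness data.frame \code{participant, audio, visual}: latent
#'   (continuous) vividness per modality, within [1, 5].
#' @slot artifacts data.frame \code{participant, trialIndex, sensor}: injected
#'   out-of-range excursions.
#' @slot config the generating \linkS4class{SyntheticConfig}.
#' @export
setClass("GroundTruth", representation(
  vividness = "data.frame",
  artifacts = "data.frame",
  config = "SyntheticConfig"
))

setValidity("GroundTruth", function(object) {
  v <- c(object@vividness$audio, object@vividness$visual)
  if (length(v) && (any(v < 1) || any(v > 5))) "latent vividness must lie in [1, 5]" else TRUE
})

#' A generated synthetic cohort
#'
#' @slot epochs list of \linkS4class{EpochSet}, one per participant.
#' @slot meta data.frame, one row per trial
#'   (\code{participant, condition, trialIndex, rating}).
#' @slot montage data.frame of sensor positions.
#' @slot truth the \linkS4class{GroundTruth}.
#' @export
setClass("SyntheticCohort", representation(
  epochs = "list",
  meta = "data.frame",
  montage = "data.frame",
  truth = "GroundTruth"
))

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", length(object@epochs), "participants,",
      nrow(object@meta), "trials\n")
})

# ---------------------------------------------------------------------------
# Result classes
# ---------------------------------------------------------------------------

#' Leave-one-trial-out decoding results for a cohort
#'
#' @slot participants data.frame with per-participant \code{successRate},
#'   \code{shuffleP} (NA when the shuffle test was not run) and
#'   \code{nTrials} (decodable trials).
#' @slot confusion 3 x 3 decoded x actual proportion matrix, averaged across
#'   participants; columns sum to 1.
#' @slot groupT,groupDf,groupBF one-sample t statistic, degrees of freedom and
#'   JZS Bayes factor of participant success rates against chance (1/3).
#' @export
setClass("DecodingResult", representation(
  participants = "data.frame",
  confusion = "matrix",
  groupT = "numeric",
  groupDf = "numeric",
  groupBF = "numeric"
))

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult:", nrow(object@participants), "participants; mean success",
      round(mean(object@participants$successRate), 3), "(chance 1/3)\n")
  if (length(object@groupT) && is.finite(object@groupT))
    cat("  group test vs 1/3: t(", object@groupDf, ") = ",
        round(object@groupT, 2), ", BF10 = ", format(object@groupBF, digits = 3),
        "\n", sep = "")
  if (any(is.finite(object@participants$shuffleP)))
    cat("  participants with shuffle p < 0.05:",
        sum(object@participants$shuffleP < 0.05, na.rm = TRUE), "\n")
})

#' Cluster-based permutation test result
#'
#' @slot clusters list of clusters, each \code{list(cells, sign, mass, p)}
#'   where \code{cells} is a two-column (sensor, frequency) index matrix and
#'   \code{mass} the summed t statistic.
#' @slot tMap,pMap sensor x frequency paired-t and two-sided p maps.
#' @slot thresholdMap logical supra-threshold map at the cluster-forming alpha.
#' @slot nullMax permutation null distribution of the maximum absolute
#'   cluster mass.
#' @slot nPerm number of permutations used (equals the full enumeration size
#'   when exhaustive).
#' @slot exhaustive TRUE when all sign-flip patterns were enumerated.
#' @slot alpha cluster-forming threshold.
#' @export
setClass("ClusterResult", representation(
  clusters = "list",
  tMap = "matrix",
  pMap = "matrix",
  thresholdMap = "matrix",
  nullMax = "numeric",
  nPerm = "integer",
  exhaustive = "logical",
  alpha = "numeric"
))

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", length(object@clusters), "clusters;",
      object@nPerm, if (object@exhaustive) "exhaustive" else "random",
      "permutations\n")
  for (cl in head(object@clusters, 5)) {
    fr <- range(cl$cells[, 2])
    cat(sprintf("  %s cluster: %d points, %g-%g Hz, mass %.1f, p = %.4g\n",
                if (cl$sign > 0) "positive" else "negative",
                nrow(cl$cells), fr[1], fr[2], cl$mass, cl$p))
  }
})

#' Per-frequency support-vector-regression result
#'
#' @slot freqs integer frequencies 1-40 Hz.
#' @slot actualR,shuffledR matrices (values x frequency) of cross-validated
#'   fold R-values for the actual and shuffled-label analyses.
#' @slot bf10 per-frequency two-sample JZS Bayes factor comparing actual and
#'   shuffled R-values.
#' @slot bands data.frame of contiguous frequency runs (>= 2 successive Hz)
#'   with BF10 at or above the threshold.
#' @slot modality which imagery modality was analysed.
#' @export
setClass("SVRFrequencyResult", representation(
  freqs = "integer",
  actualR = "matrix",
  shuffledR = "matrix",
  bf10 = "numeric",
  bands = "data.frame",
  modality = "character"
))

setMethod("show", "SVRFrequencyResult", function(object) {
  cat("SVRFrequencyResult (", object@modality, "): ",
      nrow(object@actualR), " actual + ", nrow(object@shuffledR),
      " shuffled R-values per frequency\n", sep = "")
  if (nrow(object@bands)) {
    cat("  predictive bands (BF10 >= threshold):\n")
    print(object@bands)
  } else cat("  no predictive bands\n")
})

#' Jeffreys-Zellner-Siow Bayes-factor t-test result
#'
#' @slot bf10 Bayes factor for the alternative over the null (may be Inf for
#'   overwhelming evidence).
#' @slot t observed t statistic.
#' @slot df degrees of freedom.
#' @slot n1,n2 sample sizes (n2 = NA for one-sample tests).
#' @slot priorScale Cauchy prior scale on the standardized effect.
#' @export
setClass("BFResult", representation(
  bf10 = "numeric",
  t = "numeric",
  df = "numeric",
  n1 = "numeric",
  n2 = "numeric",
  priorScale = "numeric"
))

setMethod("show", "BFResult", function(object) {
  cat(sprintf("JZS Bayes factor t-test: t(%g) = %.3f, BF10 = %s (prior scale %.3f)\n",
              object@df, object@t, format(object@bf10, digits = 4),
              object@priorScale))
})
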
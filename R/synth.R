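# Synthetic EEG cohort generator. Signals are composed in the frequency
# domain: a 1/f^a background plus a Gaussian alpha peak define an expected
# one-sided per-bin power spectrum; condition effects and vividness couplings
# multiply band-limited power (amplitude of band-passed components), and the
# waveform is realized with independent random phases per sensor and trial.

# Expected one-sided power per FFT bin (freq x sensor) for one trial.
trialSpectrum <- function(config, condition, weightsByEffect, couplingGains, freqs) {
  bg <- config@backgroundPower * pmax(freqs, 0.5)^(-config@noiseExponent)
  alpha <- config@alphaPeakPower *
    exp(-(freqs - config@alphaPeakFreq)^2 / (2 * config@alphaPeakWidth^2))
  S <- matrix(bg + alpha, length(freqs), config@nSensors)
  for (i in seq_along(config@conditionEffects)) {
    eff <- config@conditionEffects[[i]]
    if (eff$condition != condition) next
    rows <- freqs >= eff$band[1] & freqs <= eff$band[2]
    fac <- 1 + (eff$factor - 1) * weightsByEffect[[i]]
    S[rows, ] <- S[rows, , drop = FALSE] * rep(fac, each = sum(rows))
  }
  for (j in seq_along(config@vividnessCouplings)) {
    cp <- config@vividnessCouplings[[j]]
    if (cp$modality != condition) next
    rows <- freqs >= cp$band[1] & freqs <= cp$band[2]
    S[rows, ] <- S[rows, , drop = FALSE] * couplingGains[j]
  }
  S
}

# Realize a multichannel waveform with expected spectrum S (freq x sensor).
# Consumes the global RNG stream.
realizeTrial <- function(S, n) {
  nf <- nrow(S)                  # n %/% 2 frequencies (k = 1 .. n/2)
  ns <- ncol(S)
  M <- n * sqrt(S / 2)
  eps <- matrix(complex(real = rnorm(nf * ns), imaginary = rnorm(nf * ns)) / sqrt(2),
                nf, ns)
  eps[nf, ] <- complex(real = sqrt(2) * Re(eps[nf, ]), imaginary = 0)  # Nyquist bin real
  Z <- matrix(0i, n, ns)
  Z[2:(nf + 1), ] <- M * eps
  Z[seq(n, n - nf + 2), ] <- Conj(Z[2:nf, ])
  t(Re(stats::mvfft(Z, inverse = TRUE)) / n)   # sensor x time
}

#' Generate one synthetic trial of multichannel EEG
#'
#' Draws a single trial for one participant and condition from the generative
#' model: 1/f^a background, Gaussian alpha peak, multiplicative band-limited
#' condition effects (occipitally weighted by default) and, on imagery trials,
#' the participant's vividness coupling gain. The signal is zero-mean per
#' sensor. Randomness is consumed from R's global generator; call
#' \code{set.seed()} first for reproducibility.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param participant participant identifier (labelling only).
#' @param condition one of [EEG_CONDITIONS].
#' @param vividness latent vividness of the trial's modality (1-5); used only
#'   for imagery conditions with a configured coupling.
#' @param montage optional montage (defaults to [defaultMontage()]).
#' @return numeric sensor x time matrix of voltages (V).
#' @export
generateTrialTimeseries <- function(config, participant, condition,
                                    vividness = 3, montage = NULL) {
  if (!condition %in% EEG_CONDITIONS)
    stop("unknown condition label '", condition, "'; expected one of: ",
         paste(EEG_CONDITIONS, collapse = ", "))
  if (is.null(montage)) montage <- defaultMontage(config@nSensors)
  n <- round(config@trialDuration * config@sfreq)
  freqs <- seq_len(n %/% 2) * config@sfreq / n
  w <- lapply(config@conditionEffects, function(eff)
    resolveTopography(eff$topography, montage, config@nSensors))
  gains <- vapply(config@vividnessCouplings, function(cp)
    exp(cp$slope * (vividness - 3)), numeric(1))
  S <- trialSpectrum(config, condition, w, gains, freqs)
  x <- realizeTrial(S, n)
  rownames(x) <- montage$name[seq_len(config@nSensors)]
  x
}

# Gaussian-windowed 5 Hz excursion, in-band so it survives filtering and sits
# inside the central epoch window.
artifactWave <- function(n, sfreq, amplitude) {
  t <- (seq_len(n) - 1) / sfreq
  mid <- (n - 1) / (2 * sfreq)
  amplitude * sin(2 * pi * 5 * (t - mid)) * exp(-(t - mid)^2 / (2 * 0.4^2))
}

# Core generator: one sequential RNG stream; `process` maps each participant's
# EpochSet to whatever the caller accumulates (NULL keeps the EpochSet).
generateCohortInternal <- function(config, process = NULL) {
  set.seed(config@seed)
  montage <- defaultMontage(config@nSensors)
  nP <- config@nParticipants
  nT <- config@nTrialsPerCondition
  n <- round(config@trialDuration * config@sfreq)
  freqs <- seq_len(n %/% 2) * config@sfreq / n
  w <- lapply(config@conditionEffects, function(eff)
    resolveTopography(eff$topography, montage, config@nSensors))

  # latent vividness: Gaussian copula with the configured correlation
  z1 <- rnorm(nP)
  z2 <- config@vividnessCorrelation * z1 +
    sqrt(1 - config@vividnessCorrelation^2) * rnorm(nP)
  vivid <- data.frame(participant = sprintf("P%02d", seq_len(nP)),
                      audio = 1 + 4 * stats::pnorm(z1),
                      visual = 1 + 4 * stats::pnorm(z2),
                      stringsAsFactors = FALSE)

  items <- vector("list", nP)
  metaList <- vector("list", nP)
  artList <- vector("list", nP)
  for (p in seq_len(nP)) {
    pid <- vivid$participant[p]
    gains <- vapply(config@vividnessCouplings, function(cp)
      exp(cp$slope * (vivid[[cp$modality]][p] - 3) + rnorm(1, 0, cp$noiseSD)),
      numeric(1))
    conditions <- sample(rep(EEG_CONDITIONS, each = nT))
    sig <- array(0, c(length(conditions), config@nSensors, n))
    rating <- rep(NA_real_, length(conditions))
    arts <- NULL
    for (tr in seq_along(conditions)) {
      cond <- conditions[tr]
      S <- trialSpectrum(config, cond, w, gains, freqs)
      x <- realizeTrial(S, n)
      if (config@artifactRate > 0) {
        hit <- which(runif(config@nSensors) < config@artifactRate)
        if (length(hit)) {
          wav <- artifactWave(n, config@sfreq, config@artifactAmplitude)
          x[hit, ] <- x[hit, , drop = FALSE] + rep(wav, each = length(hit))
          arts <- rbind(arts, data.frame(participant = pid, trialIndex = tr,
                                         sensor = hit))
        }
      }
      sig[tr, , ] <- x
      if (cond != "rest")
        rating[tr] <- min(5, max(1, round(vivid[[cond]][p] +
                                            rnorm(1, 0, config@ratingNoiseSD))))
    }
    es <- new("EpochSet", signal = sig, sfreq = config@sfreq,
              condition = conditions, rating = rating, participant = pid,
              sensorNames = montage$name[seq_len(config@nSensors)],
              exclusionMask = matrix(FALSE, 0, 0))
    metaList[[p]] <- data.frame(participant = pid, condition = conditions,
                                trialIndex = seq_along(conditions),
                                rating = rating, stringsAsFactors = FALSE)
    artList[[p]] <- arts
    items[[p]] <- if (is.null(process)) es else process(es)
  }
  arts <- do.call(rbind, artList[!vapply(artList, is.null, logical(1))])
  if (is.null(arts))
    arts <- data.frame(participant = character(0), trialIndex = integer(0),
                       sensor = integer(0))
  truth <- new("GroundTruth", vividness = vivid, artifacts = arts,
               config = config)
  list(items = items, meta = do.call(rbind, metaList), montage = montage,
       truth = truth)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Deterministic given \code{config@seed}. Every imagery trial carries a
#' reported rating (latent vividness plus rating noise, rounded onto 1-5);
#' rest trials carry NA. The returned ground truth records the latent
#' vividness, every injected artifact location and the generating
#' configuration, so downstream stages can be tested for recovery.
#'
#' Memory note: the full default configuration holds roughly 12 GB of raw
#' signal; use [simulateCohortPSD()] to stream participants straight to PSD
#' features, or reduce \code{nSensors}/\code{sfreq} for in-memory work.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{SyntheticCohort}.
#' @examples
#' cfg <- syntheticConfig(nParticipants = 2, nTrialsPerCondition = 2,
#'                        nSensors = 4, sfreq = 256, seed = 7)
#' coh <- generateCohort(cfg)
#' coh
#' @export
generateCohort <- function(config) {
  g <- generateCohortInternal(config)
  new("SyntheticCohort", epochs = g$items, meta = g$meta,
      montage = g$montage, truth = g$truth)
}

#' Simulate a cohort and stream it through preprocessing to PSD features
#'
#' Generates each participant in turn, filters (band-pass 1-100 Hz plus
#' 45-55 Hz notch, zero-phase), re-references to the sensor average, extracts
#' the centred epoch, screens amplitude ranges and computes 1 Hz-binned PSDs,
#' discarding raw signals as it goes. Identical seeds give identical output.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param epochDuration epoch length, s.
#' @param rangeThreshold peak-to-peak exclusion threshold, V.
#' @param applyFilter set FALSE to skip filtering (spectral tests on the raw
#'   generative process).
#' @return list with elements \code{psd} (a \linkS4class{PSDArray}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @export
simulateCohortPSD <- function(config, epochDuration = 9,
                              rangeThreshold = 250e-6, applyFilter = TRUE) {
  sos <- if (applyFilter) standardFilterSos(config@sfreq) else NULL
  g <- generateCohortInternal(config, process = function(es) {
    es <- preprocessEpochs(es, epochDuration = epochDuration,
                           rangeThreshold = rangeThreshold, sos = sos)
    participantPSD(es)
  })
  power <- do.call(abind1, g$items)
  psd <- new("PSDArray", power = power, freqs = 1:40, meta = g$meta,
             sensorNames = g$montage$name[seq_len(config@nSensors)],
             montage = g$montage)
  list(psd = psd, truth = g$truth)
}

# rbind for 3-D arrays along the first (trial) dimension
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))),
                           d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}
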
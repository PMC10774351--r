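# Periodogram PSD features: bare single-FFT power spectrum of the whole
# epoch (no taper, no segment averaging), then averaged into 1 Hz bins over
# 1-40 Hz. Absolute units cancel downstream (differences and regressions);
# the normalization is fixed so that Parseval-type checks are exact.

#' One-sided periodogram power spectrum
#'
#' Power of the full, un-windowed epoch: at frequency index k (0 < k <
#' Nyquist) the power is \code{|X_k|^2 * 2 / N^2}; the DC and Nyquist bins
#' are not doubled. With this scaling an on-bin sinusoid of amplitude A
#' carries power A^2/2 in its bin, and the total over all bins equals the
#' signal's mean square (variance plus squared mean).
#'
#' @param x numeric time series (finite values).
#' @param sfreq sampling rate, Hz.
#' @return list with \code{freq} (Hz, from 0 to Nyquist) and \code{power}.
#' @export
periodogramPower <- function(x, sfreq) {
  n <- length(x)
  if (n == 0) stop("empty input")
  if (!all(is.finite(x))) stop("input must be finite")
  X <- stats::fft(x)
  half <- floor(n / 2)
  idx <- 0:half
  p <- Mod(X[idx + 1])^2 * 2 / n^2
  p[1] <- p[1] / 2                      # DC
  if (n %% 2 == 0) p[half + 1] <- p[half + 1] / 2  # Nyquist
  list(freq = idx * sfreq / n, power = p)
}

#' Average spectral power into 1 Hz bins, 1-40 Hz
#'
#' Bin f (integer 1-40) is the mean of the power at FFT frequencies whose
#' round-half-up value equals f, i.e. frequencies in [f - 0.5, f + 0.5).
#'
#' @param freq FFT frequencies, Hz; resolution must be at most 1 Hz.
#' @param power matching power values.
#' @return numeric vector of 40 binned power values, named "1".."40".
#' @export
binPower1Hz <- function(freq, power) {
  if (length(freq) > 1 && min(diff(sort(freq))) > 1 + 1e-9)
    stop("frequency resolution must be at most 1 Hz")
  bin <- floor(freq + 0.5)              # round half up
  out <- vapply(1:40, function(f) {
    sel <- bin == f
    if (any(sel)) mean(power[sel]) else NA_real_
  }, numeric(1))
  names(out) <- as.character(1:40)
  out
}

# Binned PSD for every (trial, sensor) of one preprocessed EpochSet;
# masked cells are NaN across all 40 bins.
participantPSD <- function(epochs) {
  d <- dim(epochs@signal)
  n <- d[3]
  half <- floor(n / 2)
  freq <- (0:half) * epochs@sfreq / n
  bin <- floor(freq + 0.5)
  sel <- lapply(1:40, function(f) which(bin == f))
  out <- array(NA_real_, c(d[1], d[2], 40))
  mask <- if (length(epochs@exclusionMask)) epochs@exclusionMask else
    matrix(FALSE, d[1], d[2])
  for (tr in seq_len(d[1])) {
    xs <- matrix(epochs@signal[tr, , ], d[2], n)
    X <- stats::mvfft(t(xs))            # time x sensor
    P <- Mod(X[1:(half + 1), , drop = FALSE])^2 * 2 / n^2
    for (f in 1:40) {
      idx <- sel[[f]]
      out[tr, , f] <- if (length(idx)) colMeans(P[idx, , drop = FALSE]) else NaN
    }
    if (any(mask[tr, ])) out[tr, mask[tr, ], ] <- NaN
  }
  out
}

#' Compute the cohort PSD feature array
#'
#' Applies [periodogramPower()] plus [binPower1Hz()] to every (trial, sensor)
#' cell of every participant; cells flagged by the amplitude screen become
#' NaN across all 40 bins.
#'
#' @param epochsList an \linkS4class{EpochSet}, a list of them, or a
#'   \linkS4class{SyntheticCohort}.
#' @param montage optional montage to attach (taken from the cohort when one
#'   is supplied).
#' @return a \linkS4class{PSDArray}.
#' @export
computePSD <- function(epochsList, montage = NULL) {
  if (is(epochsList, "SyntheticCohort")) {
    montage <- epochsList@montage
    epochsList <- epochsList@epochs
  }
  if (is(epochsList, "EpochSet")) epochsList <- list(epochsList)
  mats <- lapply(epochsList, participantPSD)
  meta <- do.call(rbind, lapply(epochsList, function(es)
    data.frame(participant = es@participant, condition = es@condition,
               trialIndex = seq_along(es@condition), rating = es@rating,
               stringsAsFactors = FALSE)))
  if (is.null(montage)) montage <- data.frame()
  new("PSDArray", power = do.call(abind1, mats), freqs = 1:40, meta = meta,
      sensorNames = epochsList[[1]]@sensorNames, montage = montage)
}
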
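# Preprocessing: zero-phase Butterworth filtering, common-average reference,
# centred epoching, amplitude-range artifact screening. Pipeline order is
# fixed: filter -> reference -> epoch -> screen, so filter transients never
# touch epoch boundaries.

#' Second-order sections of the standard preprocessing filter
#'
#' Band-pass 1-100 Hz realized as cascaded 6th-order high-pass and low-pass
#' Butterworth sections, plus a 45-55 Hz 6th-order band-stop, all applied
#' forward-backward (two-pass, zero-phase) by [filterTimeseries()].
#'
#' @param sfreq sampling rate, Hz; must exceed 200 Hz so the 100 Hz edge is
#'   below Nyquist.
#' @param highPass,lowPass,notch band edges, Hz.
#' @param order Butterworth order of each section.
#' @return biquad coefficient matrix (see [butterSos()]).
#' @export
standardFilterSos <- function(sfreq, highPass = 1, lowPass = 100,
                              notch = c(45, 55), order = 6) {
  if (sfreq <= 200) stop("sfreq must exceed 200 Hz")
  nyq <- sfreq / 2
  rbind(butterSos(order, highPass / nyq, "high"),
        butterSos(order, lowPass / nyq, "low"),
        butterSos(order, notch / nyq, "stop"))
}

#' Zero-phase band-pass and notch filtering of multichannel EEG
#'
#' Applies the standard 1-100 Hz band-pass plus 45-55 Hz band-stop (6th-order
#' Butterworth, forward-backward) to each sensor independently.
#'
#' @param x sensor x time numeric matrix.
#' @param sfreq sampling rate, Hz (> 200).
#' @param sos optional precomputed sections from [standardFilterSos()]
#'   (passing them avoids redesigning the filter per trial).
#' @return filtered sensor x time matrix.
#' @export
filterTimeseries <- function(x, sfreq, sos = NULL) {
  if (is.null(sos)) sos <- standardFilterSos(sfreq)
  t(sosFiltFilt(sos, t(x)))
}

#' Re-reference to the across-sensor average
#'
#' Subtracts the instantaneous mean over all sensors from every sensor, so
#' the sensor mean is zero at every sample.
#'
#' @param x sensor x time numeric matrix (>= 2 sensors).
#' @return re-referenced matrix.
#' @export
averageReference <- function(x) {
  if (nrow(x) < 2) stop("average referencing requires at least 2 sensors")
  sweep(x, 2, colMeans(x))
}

#' Extract the centred epoch from a trial
#'
#' Drops \code{(trialDuration - epochDuration)/2} seconds from each end of
#' the trial (left offset floored to a whole sample when fractional), keeping
#' \code{round(epochDuration * sfreq)} samples.
#'
#' @param x sensor x time matrix (or a numeric vector).
#' @param sfreq sampling rate, Hz.
#' @param epochDuration epoch length, s; must not exceed the trial length.
#' @return the centred window, same type as the input.
#' @export
epochTrial <- function(x, sfreq, epochDuration) {
  vec <- is.null(dim(x))
  n <- if (vec) length(x) else ncol(x)
  nEpoch <- round(epochDuration * sfreq)
  if (nEpoch > n)
    stop("epoch duration (", epochDuration, " s) exceeds trial length (",
         n / sfreq, " s)")
  left <- floor((n - nEpoch) / 2)
  idx <- left + seq_len(nEpoch)
  if (vec) x[idx] else x[, idx, drop = FALSE]
}

#' Amplitude-range artifact screen
#'
#' Marks every (trial, sensor) cell whose within-epoch peak-to-peak amplitude
#' range (max minus min) exceeds the threshold. Downstream PSDs for masked
#' cells become NaN.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param rangeThreshold range threshold, V (> 0); the default reads the
#'   published 250 mV criterion as a 250 microvolt peak-to-peak range, the
#'   physiologically plausible scale for scalp EEG.
#' @return logical trial x sensor matrix.
#' @export
amplitudeExclusionMask <- function(epochs, rangeThreshold = 250e-6) {
  if (rangeThreshold <= 0) stop("rangeThreshold must be positive")
  d <- dim(epochs@signal)
  rng <- apply(epochs@signal, c(1, 2), function(v) max(v) - min(v))
  matrix(rng > rangeThreshold, d[1], d[2])
}

#' Preprocess one participant's trials
#'
#' Filter (zero-phase band-pass + notch), average-reference, epoch to the
#' centred window, then screen amplitude ranges. Order is fixed; filtering
#' and referencing are both linear and commute to numerical tolerance.
#'
#' @param epochs an \linkS4class{EpochSet} of raw trials.
#' @param epochDuration epoch length, s.
#' @param rangeThreshold peak-to-peak exclusion threshold, V.
#' @param sos optional precomputed filter sections; NULL designs the standard
#'   filter for \code{epochs@sfreq}, FALSE skips filtering.
#' @return an \linkS4class{EpochSet} of processed epochs with the exclusion
#'   mask filled in.
#' @export
preprocessEpochs <- function(epochs, epochDuration = 9,
                             rangeThreshold = 250e-6, sos = NULL) {
  doFilter <- !identical(sos, FALSE)
  if (doFilter && is.null(sos)) sos <- standardFilterSos(epochs@sfreq)
  d <- dim(epochs@signal)
  if (d[2] < 2) stop("average referencing requires at least 2 sensors")
  nEpoch <- round(epochDuration * epochs@sfreq)
  if (nEpoch > d[3])
    stop("epoch duration (", epochDuration, " s) exceeds trial length (",
         d[3] / epochs@sfreq, " s)")
  # filter every (trial, sensor) channel in one vectorized pass
  arr <- epochs@signal
  if (doFilter) {
    X <- matrix(aperm(arr, c(3, 1, 2)), d[3], d[1] * d[2])
    X <- sosFiltFilt(sos, X)
    arr <- aperm(array(X, c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  # common-average reference: subtract the per-(trial, sample) sensor mean
  m <- colMeans(aperm(arr, c(2, 1, 3)))          # trial x time
  for (s in seq_len(d[2])) arr[, s, ] <- arr[, s, ] - m
  left <- floor((d[3] - nEpoch) / 2)
  out <- arr[, , left + seq_len(nEpoch), drop = FALSE]
  res <- new("EpochSet", signal = out, sfreq = epochs@sfreq,
             condition = epochs@condition, rating = epochs@rating,
             participant = epochs@participant,
             sensorNames = epochs@sensorNames,
             exclusionMask = matrix(FALSE, 0, 0))
  res@exclusionMask <- amplitudeExclusionMask(res, rangeThreshold)
  res
}
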
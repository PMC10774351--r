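# Per-frequency prediction of participant vividness from global
# imagery-minus-rest PSD differences, via repeated fourfold cross-validated
# linear epsilon-insensitive support vector regression, with a shuffled-label
# chance distribution and per-frequency JZS Bayes-factor t-tests.

#' Imagery-minus-rest difference PSDs
#'
#' Per participant: mean PSD of the imagery condition minus mean PSD of the
#' resting state, per sensor and frequency; NaN where either operand is
#' missing.
#'
#' @param means named list of condition-mean arrays from [conditionMeans()]
#'   (optionally after [outlierInterpolate()]).
#' @param modality \code{"audio"} or \code{"visual"}.
#' @return participant x sensor x frequency difference array.
#' @export
differencePSD <- function(means, modality = c("audio", "visual")) {
  modality <- match.arg(modality)
  means[[modality]] - means[["rest"]]
}

#' Sensor-averaged global difference scores
#'
#' NaN-aware mean over sensors of the difference PSD, giving one value per
#' participant and frequency ("global" oscillatory power difference).
#' Participants missing a condition entirely (all-NaN difference) are dropped
#' with a warning.
#'
#' @param diffPsd participant x sensor x frequency array from
#'   [differencePSD()].
#' @return participant x frequency matrix, rownames = participant ids.
#' @export
computeGlobalDifference <- function(diffPsd) {
  d <- dim(diffPsd)
  out <- matrix(NA_real_, d[1], d[3], dimnames = list(dimnames(diffPsd)[[1]], NULL))
  for (f in seq_len(d[3])) {
    sl <- matrix(diffPsd[, , f], d[1], d[2])
    cnt <- rowSums(is.finite(sl))
    s <- rowSums(sl, na.rm = TRUE)
    out[, f] <- ifelse(cnt > 0, s / cnt, NaN)
  }
  empty <- rowSums(is.finite(out)) == 0
  if (any(empty)) {
    warning(sum(empty), " participant(s) missing a condition; dropped")
    out <- out[!empty, , drop = FALSE]
  }
  out
}

# One SVR fold: z-score x and y by training statistics, fit linear
# eps-insensitive SVR, return Pearson R between predicted and actual test
# ratings (0 for degenerate folds).
svrFoldR <- function(x, y, train, test, cost, epsilon) {
  mx <- mean(x[train]); sx <- stats::sd(x[train])
  my <- mean(y[train]); sy <- stats::sd(y[train])
  if (!is.finite(sx) || sx == 0 || !is.finite(sy) || sy == 0) return(0)
  xt <- (x - mx) / sx
  yt <- (y - my) / sy
  fit <- e1071::svm(x = matrix(xt[train], ncol = 1), y = yt[train],
                    type = "eps-regression", kernel = "linear",
                    cost = cost, epsilon = epsilon, scale = FALSE)
  pred <- as.numeric(stats::predict(fit, matrix(xt[test], ncol = 1)))
  if (stats::sd(pred) == 0 || stats::sd(y[test]) == 0) return(0)
  stats::cor(pred, y[test])
}

svrCvCore <- function(x, y, nIter, k, cost, epsilon, shuffle) {
  n <- length(x)
  if (n %% k != 0)
    stop("number of participants (", n, ") must be divisible by the fold ",
         "count (", k, "); drop participants to an even split")
  if (n < 2 * k) stop("need at least ", 2 * k, " participants")
  gsize <- n / k
  out <- numeric(nIter * k)
  # draw all label shuffles and partitions up front, so the randomization
  # sequence is a pure function of the RNG state at entry
  shuffles <- if (shuffle)
    lapply(seq_len(nIter), function(i) sample(n)) else NULL
  perms <- lapply(seq_len(nIter), function(i) sample(n))
  at <- 0L
  for (it in seq_len(nIter)) {
    yy <- if (shuffle) y[shuffles[[it]]] else y
    perm <- perms[[it]]
    for (fold in seq_len(k)) {
      test <- perm[(fold - 1) * gsize + seq_len(gsize)]
      train <- setdiff(perm, test)
      at <- at + 1L
      out[at] <- svrFoldR(x, yy, train, test, cost, epsilon)
    }
  }
  out
}

#' Cross-validated SVR R-values at one frequency
#'
#' Each iteration randomly partitions participants into \code{k} equal
#' groups; each fold trains a linear epsilon-insensitive support vector
#' regression of vividness on the global difference score (z-scored by
#' training-fold statistics) on \code{k - 1} groups and predicts the held-out
#' group, storing the Pearson correlation between predicted and actual
#' ratings. Degenerate folds (zero variance anywhere) record R = 0.
#'
#' @param x global difference scores at one frequency, one per participant.
#' @param y participant vividness ratings (means across imagery trials).
#' @param nIter partition iterations.
#' @param k folds per iteration; \code{length(x)} must be divisible by k.
#' @param cost,epsilon SVR hyperparameters (C and the insensitivity margin,
#'   on the z-scored scale).
#' @return numeric vector of \code{nIter * k} R-values in [-1, 1].
#' @export
svrCvRvalues <- function(x, y, nIter = 125, k = 4, cost = 1, epsilon = 0.1) {
  svrCvCore(x, y, nIter, k, cost, epsilon, shuffle = FALSE)
}

#' Shuffled-label chance R-values
#'
#' Identical procedure to [svrCvRvalues()] but the ratings are randomly
#' reassigned across participants afresh in every iteration before the
#' groups are formed, giving the empirical chance distribution.
#'
#' @inheritParams svrCvRvalues
#' @return numeric vector of \code{nIter * k} chance R-values.
#' @export
shuffledNullRvalues <- function(x, y, nIter = 125, k = 4, cost = 1,
                                epsilon = 0.1) {
  svrCvCore(x, y, nIter, k, cost, epsilon, shuffle = TRUE)
}

#' Contiguous frequency runs of extreme Bayes factors
#'
#' Maximal runs of at least two consecutive integer frequencies whose BF10
#' meets the threshold; isolated single frequencies are not reported as
#' bands.
#'
#' @param bf10 per-frequency Bayes factors (frequencies \code{freqs}).
#' @param threshold BF10 cut-off (default 100, conventionally "extreme"
#'   evidence).
#' @param freqs integer frequency axis.
#' @return data.frame with \code{lo}, \code{hi} (Hz) and \code{minBF} per
#'   run.
#' @export
frequencyBandClusters <- function(bf10, threshold = 100, freqs = 1:40) {
  above <- is.finite(bf10) & bf10 >= threshold
  out <- data.frame(lo = integer(0), hi = integer(0), minBF = numeric(0))
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      if (j > i)
        out <- rbind(out, data.frame(lo = freqs[i], hi = freqs[j],
                                     minBF = min(bf10[i:j])))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

#' Per-frequency SVR analysis of one imagery modality
#'
#' For every frequency 1-40 Hz: actual and shuffled-label cross-validated
#' R-value distributions, and a two-sample JZS Bayes-factor t-test for a
#' difference between them; contiguous frequency runs with BF10 at or above
#' the threshold are reported as predictive bands.
#'
#' @param globalDiff participant x frequency matrix from
#'   [computeGlobalDifference()].
#' @param ratings participant mean vividness ratings, aligned with the rows.
#' @param nIter,k,cost,epsilon cross-validation and SVR parameters.
#' @param bfThreshold band-forming BF10 threshold.
#' @param modality label carried through to the result.
#' @return an \linkS4class{SVRFrequencyResult}.
#' @export
svrFrequencyAnalysis <- function(globalDiff, ratings, nIter = 125, k = 4,
                                 cost = 1, epsilon = 0.1, bfThreshold = 100,
                                 modality = "audio") {
  ok <- complete.cases(globalDiff) & is.finite(ratings)
  if (!all(ok)) {
    warning(sum(!ok), " participant(s) with missing data dropped")
    globalDiff <- globalDiff[ok, , drop = FALSE]
    ratings <- ratings[ok]
  }
  nf <- ncol(globalDiff)
  nv <- nIter * k
  actual <- matrix(NA_real_, nv, nf)
  shuffled <- matrix(NA_real_, nv, nf)
  bf <- numeric(nf)
  for (f in seq_len(nf)) {
    actual[, f] <- svrCvRvalues(globalDiff[, f], ratings, nIter, k, cost, epsilon)
    shuffled[, f] <- shuffledNullRvalues(globalDiff[, f], ratings, nIter, k,
                                         cost, epsilon)
    bf[f] <- jzsBFTwoSample(actual[, f], shuffled[, f])@bf10
  }
  new("SVRFrequencyResult", freqs = seq_len(nf), actualR = actual,
      shuffledR = shuffled, bf10 = bf,
      bands = frequencyBandClusters(bf, bfThreshold, seq_len(nf)),
      modality = modality)
}

#' Participant mean vividness ratings for one modality
#'
#' @param psd a \linkS4class{PSDArray}.
#' @param modality \code{"audio"} or \code{"visual"}.
#' @return named numeric vector, one mean rating per participant (NaN when a
#'   participant has no rated trials of the modality).
#' @export
participantRatings <- function(psd, modality = c("audio", "visual")) {
  modality <- match.arg(modality)
  meta <- psd@meta
  ids <- unique(meta$participant)
  vapply(ids, function(pid) {
    r <- meta$rating[meta$participant == pid & meta$condition == modality]
    mean(r, na.rm = TRUE)
  }, numeric(1))
}
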
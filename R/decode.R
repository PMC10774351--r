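# Leave-one-trial-out nearest-neighbour condition decoding. Features are the
# sensor x frequency PSD values of a trial; the template ("conditional
# signature") is the per-condition mean over training trials, and a trial is
# assigned to the condition with the smallest sum of absolute differences
# (no rescaling, no Euclidean distance). Trials are only ever compared to
# other trials from the same participant.

#' Per-condition mean PSD signatures
#'
#' NaN-aware mean over all training trials of each condition, per feature
#' cell.
#'
#' @param power trial x feature numeric matrix (a participant's training
#'   set, flattened over sensor x frequency).
#' @param labels condition label per trial.
#' @param conditions condition set (fixed order).
#' @return condition x feature matrix of signatures.
#' @export
conditionSignatures <- function(power, labels, conditions = EEG_CONDITIONS) {
  sig <- matrix(NA_real_, length(conditions), ncol(power),
                dimnames = list(conditions, NULL))
  for (i in seq_along(conditions)) {
    rows <- which(labels == conditions[i])
    if (!length(rows))
      stop("condition '", conditions[i], "' has no trials in the training set")
    sub <- power[rows, , drop = FALSE]
    cnt <- colSums(is.finite(sub))
    s <- colSums(sub * is.finite(sub), na.rm = TRUE)
    sig[i, ] <- ifelse(cnt > 0, s / cnt, NaN)
  }
  sig
}

#' Decode one trial against condition signatures
#'
#' Assigns the condition whose signature has the smallest sum of absolute
#' differences over feature cells finite in both trial and signature. Exact
#' ties go to the earlier condition in \code{rownames(signatures)}.
#'
#' @param trial numeric feature vector.
#' @param signatures condition x feature matrix from [conditionSignatures()].
#' @return decoded condition label, or NA when the trial shares no finite
#'   cell with some signature (undecodable).
#' @export
decodeTrial <- function(trial, signatures) {
  conds <- rownames(signatures)
  d <- numeric(length(conds))
  for (i in seq_along(conds)) {
    ok <- is.finite(trial) & is.finite(signatures[i, ])
    if (!any(ok)) return(NA_character_)
    d[i] <- sum(abs(trial[ok] - signatures[i, ok]))
  }
  conds[which.min(d)]
}

# Vectorized leave-one-out decode of all trials of one participant.
# Returns decoded labels (NA = undecodable).
looDecodeLabels <- function(power, labels, conditions = EEG_CONDITIONS) {
  nT <- nrow(power)
  fin <- is.finite(power)
  P0 <- power
  P0[!fin] <- 0
  D <- matrix(NA_real_, nT, length(conditions))
  shared <- matrix(0L, nT, length(conditions))
  for (i in seq_along(conditions)) {
    inC <- labels == conditions[i]
    if (sum(inC) < 2)
      stop("condition '", conditions[i],
           "' needs at least 2 trials for leave-one-out decoding")
    S <- colSums(P0[inC, , drop = FALSE])
    N <- colSums(fin[inC, , drop = FALSE])
    # leave-one-out signature: subtract the trial's own contribution
    Sm <- matrix(S, nT, ncol(power), byrow = TRUE) - P0 * inC
    Nm <- matrix(N, nT, ncol(power), byrow = TRUE) - fin * inC
    sig <- Sm / Nm                     # 0/0 -> NaN where no training data
    diffs <- abs(power - sig)
    valid <- fin & is.finite(sig)
    diffs[!valid] <- 0
    D[, i] <- rowSums(diffs)
    shared[, i] <- rowSums(valid)
  }
  decodable <- rowSums(shared > 0) == length(conditions)
  pick <- max.col(-D, ties.method = "first")
  out <- conditions[pick]
  out[!decodable] <- NA_character_
  out
}

#' Leave-one-trial-out decoding for one participant
#'
#' Every trial is decoded against signatures built from all remaining trials
#' (circularity avoided by exclusion). Undecodable trials (no shared finite
#' features with some signature) are dropped from the success-rate
#' denominator.
#'
#' @param power trial x feature matrix (or trial x sensor x frequency array,
#'   flattened internally).
#' @param labels condition label per trial; each condition needs >= 2 trials.
#' @param conditions condition set in tie-break order.
#' @return list with \code{successRate}, \code{decoded} labels,
#'   \code{confusion} (decoded x actual proportion matrix, columns summing
#'   to 1) and \code{nTrials} (decodable count).
#' @export
leaveOneOutDecode <- function(power, labels, conditions = EEG_CONDITIONS) {
  if (length(dim(power)) == 3)
    power <- matrix(power, dim(power)[1], dim(power)[2] * dim(power)[3])
  decoded <- looDecodeLabels(power, labels, conditions)
  ok <- !is.na(decoded)
  conf <- matrix(0, length(conditions), length(conditions),
                 dimnames = list(decoded = conditions, actual = conditions))
  for (j in seq_along(conditions)) {
    sel <- ok & labels == conditions[j]
    if (any(sel))
      conf[, j] <- tabulate(match(decoded[sel], conditions),
                            length(conditions)) / sum(sel)
  }
  list(successRate = mean(decoded[ok] == labels[ok]),
       decoded = decoded, confusion = conf, nTrials = sum(ok))
}

#' Shuffle test for a participant's decoding success
#'
#' Permutes the condition labels over trials and re-runs the full
#' leave-one-out decode \code{nShuffles} times; the p-value is the add-one
#' proportion of shuffles whose success rate is at least the actual one,
#' p = (1 + #[shuffled >= actual]) / (nShuffles + 1).
#'
#' @param power trial x feature matrix.
#' @param labels condition label per trial.
#' @param nShuffles number of label permutations.
#' @param conditions condition set.
#' @return list with \code{p}, \code{actual} success rate and the vector of
#'   \code{shuffled} success rates.
#' @export
decodingShuffleTest <- function(power, labels, nShuffles = 1000,
                                conditions = EEG_CONDITIONS) {
  if (length(dim(power)) == 3)
    power <- matrix(power, dim(power)[1], dim(power)[2] * dim(power)[3])
  actual <- leaveOneOutDecode(power, labels, conditions)$successRate
  shuffled <- vapply(seq_len(nShuffles), function(i) {
    lab <- sample(labels)
    d <- looDecodeLabels(power, lab, conditions)
    ok <- !is.na(d)
    mean(d[ok] == lab[ok])
  }, numeric(1))
  list(p = (1 + sum(shuffled >= actual)) / (nShuffles + 1),
       actual = actual, shuffled = shuffled)
}

#' Decode every participant of a cohort
#'
#' Runs the leave-one-trial-out decoder per participant, optionally with the
#' label-shuffle significance test, and summarizes success rates against
#' chance (1/3) with a one-sample t-test and JZS Bayes factor.
#'
#' @param psd a \linkS4class{PSDArray}.
#' @param nShuffles shuffle-test permutations per participant (0 skips the
#'   test).
#' @return a \linkS4class{DecodingResult}.
#' @export
decodeCohort <- function(psd, nShuffles = 1000) {
  meta <- psd@meta
  ids <- unique(meta$participant)
  d <- dim(psd@power)
  flat <- matrix(psd@power, d[1], d[2] * d[3])
  rows <- lapply(ids, function(pid) {
    sel <- meta$participant == pid
    power <- flat[sel, , drop = FALSE]
    labels <- meta$condition[sel]
    res <- leaveOneOutDecode(power, labels)
    p <- if (nShuffles > 0)
      decodingShuffleTest(power, labels, nShuffles)$p else NA_real_
    list(row = data.frame(participant = pid, successRate = res$successRate,
                          shuffleP = p, nTrials = res$nTrials,
                          stringsAsFactors = FALSE),
         confusion = res$confusion)
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  conf <- Reduce(`+`, lapply(rows, `[[`, "confusion")) / length(rows)
  sr <- tab$successRate
  if (length(sr) >= 2 && stats::sd(sr) > 0) {
    tt <- (mean(sr) - 1 / 3) / (stats::sd(sr) / sqrt(length(sr)))
    bf <- jzsBFOneSample(sr, mu0 = 1 / 3)@bf10
  } else {
    tt <- NA_real_
    bf <- NA_real_
  }
  new("DecodingResult", participants = tab, confusion = conf,
      groupT = tt, groupDf = length(sr) - 1, groupBF = bf)
}
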
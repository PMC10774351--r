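# On-disk layout: one RDS container of trial voltage matrices (grouped by
# participant), CSV trial metadata, whitespace montage text, and long-form
# CSV export of PSD features.

#' Write a cohort to disk
#'
#' Writes \code{cohort.rds} (a list: participant -> list of sensor x time
#' trial matrices, plus sfreq), \code{metadata.csv}
#' (participant,condition,trial_index,rating) and \code{montage.txt}
#' (name x y z).
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  store <- list(sfreq = cohort@epochs[[1]]@sfreq,
                participants = lapply(cohort@epochs, function(es) {
                  d <- dim(es@signal)
                  lapply(seq_len(d[1]), function(tr)
                    matrix(es@signal[tr, , ], d[2], d[3]))
                }))
  names(store$participants) <- vapply(cohort@epochs, slot, character(1),
                                      "participant")
  saveRDS(store, file.path(dir, "cohort.rds"))
  meta <- cohort@meta
  names(meta) <- c("participant", "condition", "trial_index", "rating")
  utils::write.table(meta, file.path(dir, "metadata.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  writeMontage(cohort@montage, file.path(dir, "montage.txt"))
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing \code{cohort.rds}, \code{metadata.csv}
#'   and \code{montage.txt}.
#' @return a \linkS4class{SyntheticCohort} (with empty ground truth).
#' @export
readCohort <- function(dir) {
  store <- readRDS(file.path(dir, "cohort.rds"))
  meta <- utils::read.table(file.path(dir, "metadata.csv"), sep = ",",
                            header = TRUE, stringsAsFactors = FALSE)
  names(meta) <- c("participant", "condition", "trialIndex", "rating")
  montage <- readMontage(file.path(dir, "montage.txt"))
  epochs <- lapply(names(store$participants), function(pid) {
    trials <- store$participants[[pid]]
    d <- dim(trials[[1]])
    sig <- array(0, c(length(trials), d[1], d[2]))
    for (tr in seq_along(trials)) sig[tr, , ] <- trials[[tr]]
    sel <- meta$participant == pid
    new("EpochSet", signal = sig, sfreq = store$sfreq,
        condition = meta$condition[sel], rating = meta$rating[sel],
        participant = pid, sensorNames = montage$name[seq_len(d[1])],
        exclusionMask = matrix(FALSE, 0, 0))
  })
  truth <- new("GroundTruth",
               vividness = data.frame(participant = character(0),
                                      audio = numeric(0), visual = numeric(0)),
               artifacts = data.frame(participant = character(0),
                                      trialIndex = integer(0),
                                      sensor = integer(0)),
               config = syntheticConfig())
  new("SyntheticCohort", epochs = epochs, meta = meta, montage = montage,
      truth = truth)
}

#' Export PSD features as long-form CSV
#'
#' One row per (participant, trial, sensor, frequency):
#' \code{participant,trial,condition,sensor,freq,power}.
#'
#' @param psd a \linkS4class{PSDArray}.
#' @param path output file.
#' @export
exportPSDLongCSV <- function(psd, path) {
  d <- dim(psd@power)
  meta <- psd@meta
  df <- data.frame(
    participant = rep(meta$participant, times = d[2] * d[3]),
    trial = rep(meta$trialIndex, times = d[2] * d[3]),
    condition = rep(meta$condition, times = d[2] * d[3]),
    sensor = rep(rep(psd@sensorNames, each = d[1]), times = d[3]),
    freq = rep(psd@freqs, each = d[1] * d[2]),
    power = as.vector(psd@power))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
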
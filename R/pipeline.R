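# End-to-end orchestration: synthesis -> preprocessing -> PSD -> decoding,
# cluster tests, per-frequency SVR with Bayes factors; stage CSV outputs and
# a machine-readable JSON summary. Every stochastic stage consumes its own
# child seed derived from the master seed, so stages are individually
# reproducible.

#' Derive a stage-specific child seed
#'
#' Deterministic counter-based split of a master seed; stable under
#' reordering of other stages.
#'
#' @param master master integer seed.
#' @param stage stage index (1, 2, ...).
#' @return integer seed below 2^31.
#' @export
childSeed <- function(master, stage) {
  as.integer((as.numeric(master) + 104729 * as.numeric(stage)) %% 2147483647)
}

#' Assemble a pipeline configuration
#'
#' A plain, fully serializable list: the synthetic-cohort configuration plus
#' preprocessing, decoding, cluster and SVR parameters and the master seed.
#'
#' @param synth a \linkS4class{SyntheticConfig}.
#' @param epochDuration,rangeThreshold preprocessing parameters.
#' @param decodeShuffles decoding shuffle-test permutations (0 skips).
#' @param clusterPerm,clusterAlpha cluster-test parameters.
#' @param svrIter,svrFolds,bfThreshold SVR-stage parameters.
#' @param seed master seed.
#' @return config list for [runPipeline()].
#' @export
pipelineConfig <- function(synth = syntheticConfig(),
                           epochDuration = 9, rangeThreshold = 250e-6,
                           decodeShuffles = 1000,
                           clusterPerm = 1000, clusterAlpha = 0.05,
                           svrIter = 125, svrFolds = 4, bfThreshold = 100,
                           seed = 1L) {
  list(synth = synth, epochDuration = epochDuration,
       rangeThreshold = rangeThreshold, decodeShuffles = decodeShuffles,
       clusterPerm = clusterPerm, clusterAlpha = clusterAlpha,
       svrIter = svrIter, svrFolds = svrFolds, bfThreshold = bfThreshold,
       seed = as.integer(seed))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in fixed order on a synthetic cohort: generation
#' (streamed to PSD features), per-participant decoding with shuffle test,
#' the three pairwise cluster permutation tests, and the per-frequency SVR
#' analysis for both imagery modalities. When \code{outputDir} is given,
#' per-stage CSVs and a JSON summary are written there.
#'
#' @param config list from [pipelineConfig()].
#' @param outputDir optional output directory.
#' @return list with \code{psd}, \code{truth}, \code{decoding},
#'   \code{clusters} (one \linkS4class{ClusterResult} per contrast),
#'   \code{svr} (one \linkS4class{SVRFrequencyResult} per modality),
#'   \code{ratingCorrelation} and \code{summary}.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  synth <- config$synth
  synth@seed <- childSeed(config$seed, 1)

  sim <- tryCatch(
    simulateCohortPSD(synth, epochDuration = config$epochDuration,
                      rangeThreshold = config$rangeThreshold),
    error = function(e) stop("stage 'synth/preprocess/psd' failed: ",
                             conditionMessage(e)))
  psd <- sim$psd

  set.seed(childSeed(config$seed, 2))
  decoding <- tryCatch(decodeCohort(psd, nShuffles = config$decodeShuffles),
                       error = function(e) stop("stage 'decode' failed: ",
                                                conditionMessage(e)))

  adjacency <- delaunayAdjacency(psd@montage)
  means <- conditionMeans(psd)
  means <- lapply(means, outlierInterpolate, adjacency = adjacency)
  contrasts <- list(`audio-visual` = c("audio", "visual"),
                    `rest-visual` = c("rest", "visual"),
                    `rest-audio` = c("rest", "audio"))
  set.seed(childSeed(config$seed, 3))
  clusters <- lapply(contrasts, function(cc)
    tryCatch(clusterPermutationTest(means[[cc[1]]], means[[cc[2]]],
                                    adjacency, nPerm = config$clusterPerm,
                                    alpha = config$clusterAlpha),
             error = function(e) stop("stage 'cluster' (", cc[1], "-", cc[2],
                                      ") failed: ", conditionMessage(e))))

  set.seed(childSeed(config$seed, 4))
  svr <- lapply(c(audio = "audio", visual = "visual"), function(mod) {
    gd <- computeGlobalDifference(differencePSD(means, mod))
    ratings <- participantRatings(psd, mod)[rownames(gd)]
    tryCatch(svrFrequencyAnalysis(gd, ratings, nIter = config$svrIter,
                                  k = config$svrFolds,
                                  bfThreshold = config$bfThreshold,
                                  modality = mod),
             error = function(e) stop("stage 'svr' (", mod, ") failed: ",
                                      conditionMessage(e)))
  })

  rc <- ratingCorrelation(participantRatings(psd, "audio"),
                          participantRatings(psd, "visual"))

  summary <- list(
    seed = config$seed,
    nParticipants = length(unique(psd@meta$participant)),
    meanDecodingSuccess = mean(decoding@participants$successRate),
    decodableFraction = if (config$decodeShuffles > 0)
      mean(decoding@participants$shuffleP < 0.05) else NA,
    audioVisualRatingR = rc$r,
    significantClusters = lapply(clusters, function(cl) {
      sig <- Filter(function(x) x$p < 0.05, cl@clusters)
      lapply(sig, function(x)
        list(sign = x$sign, mass = x$mass, p = x$p,
             freqRange = as.numeric(range(x$cells[, 2])),
             nPoints = nrow(x$cells)))
    }),
    predictiveBands = lapply(svr, function(s) s@bands))

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(decoding@participants,
                       file.path(outputDir, "decoding.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(decoding@confusion),
                       file.path(outputDir, "confusion.csv"), sep = ",",
                       row.names = TRUE, quote = FALSE, col.names = NA)
    for (nm in names(clusters)) {
      cl <- clusters[[nm]]
      tab <- do.call(rbind, lapply(cl@clusters, function(x)
        data.frame(sign = x$sign, mass = x$mass, p = x$p,
                   freqLo = min(x$cells[, 2]), freqHi = max(x$cells[, 2]),
                   nPoints = nrow(x$cells))))
      if (is.null(tab)) tab <- data.frame()
      utils::write.table(tab, file.path(outputDir, paste0("clusters_", nm, ".csv")),
                         sep = ",", row.names = FALSE, quote = FALSE)
      utils::write.table(cl@tMap, file.path(outputDir, paste0("tmap_", nm, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
    for (nm in names(svr)) {
      s <- svr[[nm]]
      perFreq <- data.frame(freq = s@freqs,
                            mean_actual_R = colMeans(s@actualR),
                            mean_shuffled_R = colMeans(s@shuffledR),
                            bf10 = s@bf10)
      utils::write.table(perFreq, file.path(outputDir, paste0("svr_", nm, ".csv")),
                         sep = ",", row.names = FALSE, quote = FALSE)
      utils::write.table(s@bands, file.path(outputDir, paste0("svr_bands_", nm, ".csv")),
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(summary, file.path(outputDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    saveRDS(config, file.path(outputDir, "config.rds"))
  }

  list(psd = psd, truth = sim$truth, decoding = decoding, clusters = clusters,
       svr = svr, ratingCorrelation = rc, summary = summary)
}
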
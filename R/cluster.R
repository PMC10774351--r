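# Group-level analysis over sensor x frequency space: per-participant
# condition means, 3-SD outlier interpolation across neighbouring sensors,
# paired-t maps, clustering by spatio-frequency proximity, and a max-statistic
# sign-flip permutation test.

#' Per-participant condition-mean PSDs
#'
#' NaN-aware mean over trials, per participant, condition, sensor and
#' frequency.
#'
#' @param psd a \linkS4class{PSDArray}.
#' @param conditions condition set.
#' @return named list (one element per condition) of participant x sensor x
#'   frequency arrays; participant order is attached as dimnames.
#' @export
conditionMeans <- function(psd, conditions = EEG_CONDITIONS) {
  meta <- psd@meta
  ids <- unique(meta$participant)
  d <- dim(psd@power)
  out <- lapply(conditions, function(cond) {
    arr <- array(NA_real_, c(length(ids), d[2], d[3]),
                 dimnames = list(ids, NULL, NULL))
    for (p in seq_along(ids)) {
      sel <- meta$participant == ids[p] & meta$condition == cond
      if (!any(sel)) next
      sub <- psd@power[sel, , , drop = FALSE]
      cnt <- apply(is.finite(sub), c(2, 3), sum)
      s <- apply(sub, c(2, 3), function(v) sum(v[is.finite(v)]))
      arr[p, , ] <- ifelse(cnt > 0, s / cnt, NaN)
    }
    arr
  })
  names(out) <- conditions
  out
}

#' Interpolate group-level outliers across neighbouring sensors
#'
#' For each (sensor, frequency) cell, participants whose value lies more
#' than \code{sdLimit} standard deviations from the across-participant mean
#' are replaced by the mean of that participant's values at spatially
#' adjacent sensors (same frequency); when no neighbour is finite the value
#' becomes NaN. Detection statistics and neighbour values are taken from the
#' original (pre-replacement) data.
#'
#' @param means participant x sensor x frequency array (one condition).
#' @param adjacency symmetric logical sensor adjacency matrix.
#' @param sdLimit outlier threshold in standard deviations.
#' @return array of the same shape with outliers replaced.
#' @export
outlierInterpolate <- function(means, adjacency, sdLimit = 3) {
  d <- dim(means)
  out <- means
  for (f in seq_len(d[3])) {
    sl <- means[, , f, drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, d[1], d[2])
    m <- colMeans(sl, na.rm = TRUE)
    s <- apply(sl, 2, stats::sd, na.rm = TRUE)
    bad <- which(abs(sweep(sl, 2, m)) > sdLimit * rep(s, each = d[1]),
                 arr.ind = TRUE)
    for (r in seq_len(nrow(bad))) {
      p <- bad[r, 1]
      sens <- bad[r, 2]
      nb <- which(adjacency[sens, ])
      vals <- sl[p, nb]
      vals <- vals[is.finite(vals)]
      out[p, sens, f] <- if (length(vals)) mean(vals) else NaN
    }
  }
  out
}

#' Paired t-test map over sensor x frequency cells
#'
#' Per cell, a paired t-test of condition a against condition b across
#' participants, using pairwise-complete observations. Cells with fewer than
#' two complete pairs are NA; zero-variance nonzero differences give a
#' signed infinite t with p = 0.
#'
#' @param a,b participant x sensor x frequency arrays (same participants).
#' @return list with \code{t}, \code{p} (two-sided) and \code{n} matrices
#'   (sensor x frequency).
#' @export
pairedTMap <- function(a, b) {
  d <- dim(a)
  diffFlat <- matrix(a - b, d[1], d[2] * d[3])
  res <- tStatColumns(diffFlat)
  list(t = matrix(res$t, d[2], d[3]),
       p = matrix(res$p, d[2], d[3]),
       n = matrix(res$n, d[2], d[3]))
}

# Column-wise one-sample t statistics of a participant x cell matrix,
# NaN-aware. Shared by the observed map and the sign-flip permutations.
tStatColumns <- function(x) {
  fin <- is.finite(x)
  x0 <- x
  x0[!fin] <- 0
  n <- colSums(fin)
  s1 <- colSums(x0)
  s2 <- colSums(x0^2)
  m <- s1 / n
  v <- (s2 - n * m^2) / (n - 1)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  t[v == 0 & m == 0] <- 0
  t[v == 0 & m != 0] <- sign(m[v == 0 & m != 0]) * Inf
  t[n < 2] <- NA_real_
  p <- 2 * stats::pt(-abs(t), pmax(n - 1, 1))
  p[is.infinite(t)] <- 0
  p[n < 2] <- NA_real_
  list(t = t, p = p, n = n)
}

#' Cluster supra-threshold sensor x frequency points
#'
#' Connected components over points with an uncorrected p below the
#' cluster-forming threshold, positive and negative t clustered separately.
#' Two points are neighbours when their frequencies differ by at most 1 Hz
#' and they are at the same sensor or at spatially adjacent sensors.
#'
#' @param thresholdMap logical sensor x frequency supra-threshold map.
#' @param tMap matching t-statistic map.
#' @param adjacency symmetric logical sensor adjacency matrix.
#' @return list of clusters, each \code{list(cells, sign, mass)} with
#'   \code{cells} a (sensor, frequency) index matrix and \code{mass} the
#'   summed t; ordered by decreasing |mass|.
#' @export
formClusters <- function(thresholdMap, tMap, adjacency) {
  pts <- which(thresholdMap & is.finite(tMap), arr.ind = TRUE)
  if (!nrow(pts)) return(list())
  sgn <- sign(tMap[pts])
  key <- paste(pts[, 1], pts[, 2])
  lookup <- seq_len(nrow(pts))
  names(lookup) <- key
  visited <- rep(FALSE, nrow(pts))
  clusters <- list()
  for (start in seq_len(nrow(pts))) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      members <- c(members, i)
      s <- pts[i, 1]
      f <- pts[i, 2]
      nbSens <- c(s, which(adjacency[s, ]))
      nbFreq <- (f - 1):(f + 1)
      cand <- lookup[paste(rep(nbSens, each = 3), rep(nbFreq, length(nbSens)))]
      cand <- cand[!is.na(cand)]
      cand <- cand[!visited[cand] & sgn[cand] == sgn[start]]
      if (length(cand)) {
        visited[cand] <- TRUE
        queue <- c(queue, cand)
      }
    }
    cells <- pts[members, , drop = FALSE]
    clusters[[length(clusters) + 1]] <-
      list(cells = cells, sign = sgn[start],
           mass = sum(tMap[cells]))
  }
  clusters[order(-abs(vapply(clusters, `[[`, numeric(1), "mass")))]
}

# Observed or permuted max |cluster mass| for flattened differences.
maxClusterMass <- function(tFlat, pFlat, dims, adjacency, alpha) {
  tMap <- matrix(tFlat, dims[1], dims[2])
  thr <- matrix(pFlat < alpha, dims[1], dims[2])
  thr[is.na(thr)] <- FALSE
  cl <- formClusters(thr, tMap, adjacency)
  if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
}

#' Cluster-based permutation test between two paired conditions
#'
#' Observed clusters come from the paired-t map thresholded at the
#' cluster-forming alpha (two-sided, signs clustered separately). The null
#' distribution of the maximum absolute cluster mass is built by randomly
#' exchanging the two condition labels within each participant (sign-flips
#' of the paired differences) and re-running map, threshold and clustering.
#' When all \code{2^n} sign patterns number at most \code{nPerm} they are
#' enumerated exhaustively and p-values are exact proportions; otherwise
#' \code{nPerm} random flips are drawn and the add-one estimator
#' p = (1 + #[null >= |mass|]) / (nPerm + 1) is used.
#'
#' @param a,b participant x sensor x frequency condition-mean arrays.
#' @param adjacency symmetric logical sensor adjacency matrix.
#' @param nPerm number of permutations.
#' @param alpha cluster-forming (uncorrected, two-sided) threshold.
#' @return a \linkS4class{ClusterResult}.
#' @export
clusterPermutationTest <- function(a, b, adjacency, nPerm = 1000,
                                   alpha = 0.05) {
  d <- dim(a)
  nP <- d[1]
  diffFlat <- matrix(a - b, nP, d[2] * d[3])
  fin <- is.finite(diffFlat)
  obs <- tStatColumns(diffFlat)
  tMap <- matrix(obs$t, d[2], d[3])
  pMap <- matrix(obs$p, d[2], d[3])
  thr <- pMap < alpha
  thr[is.na(thr)] <- FALSE
  clusters <- formClusters(thr, tMap, adjacency)

  exhaustive <- nP <= 30 && 2^nP <= nPerm
  signs <- if (exhaustive) {
    m <- as.matrix(expand.grid(rep(list(c(1, -1)), nP)))
    dimnames(m) <- NULL
    m
  } else {
    matrix(sample(c(1, -1), nPerm * nP, replace = TRUE), nPerm, nP)
  }
  nullMax <- vapply(seq_len(nrow(signs)), function(i) {
    perm <- tStatColumns(diffFlat * signs[i, ])
    maxClusterMass(perm$t, perm$p, d[2:3], adjacency, alpha)
  }, numeric(1))

  for (i in seq_along(clusters)) {
    m <- abs(clusters[[i]]$mass)
    clusters[[i]]$p <- if (exhaustive) mean(nullMax >= m - 1e-10)
    else (1 + sum(nullMax >= m - 1e-10)) / (length(nullMax) + 1)
  }
  new("ClusterResult", clusters = clusters, tMap = tMap, pMap = pMap,
      thresholdMap = thr, nullMax = nullMax, nPerm = nrow(signs),
      exhaustive = exhaustive, alpha = alpha)
}

#' Pearson correlation between two per-participant rating vectors
#'
#' @param a,b numeric vectors (n >= 3, nonzero variance); pairwise-incomplete
#'   entries are dropped.
#' @return list with \code{r}, \code{p} (two-sided, t-based), \code{df}.
#' @export
ratingCorrelation <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in ratings; correlation undefined")
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value, df = unname(ct$parameter))
}
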
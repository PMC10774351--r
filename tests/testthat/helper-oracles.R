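# Independent oracle implementations used across the suite. Each one is a
# deliberately different route to the same quantity as the package code:
# plain loops, brute-force enumeration, penalty-method optimization, or a
# fixed-grid quadrature.

# --- tiny synthetic configs -------------------------------------------------

nullConfig <- function(nParticipants = 4, nTrials = 4, nSensors = 4,
                       sfreq = 256, trialDuration = 10, seed = 1, ...) {
  syntheticConfig(nParticipants = nParticipants,
                  nTrialsPerCondition = nTrials, nSensors = nSensors,
                  sfreq = sfreq, trialDuration = trialDuration,
                  conditionEffects = list(), vividnessCouplings = list(),
                  ratingNoiseSD = 0, seed = seed, ...)
}

# --- decoding ---------------------------------------------------------------

# Brute-force sum-of-absolute-differences decoding of one trial.
oracleDecodeTrial <- function(trial, signatures) {
  best <- NULL
  bestD <- Inf
  for (cond in rownames(signatures)) {
    d <- 0
    any_ok <- FALSE
    for (j in seq_along(trial)) {
      if (is.finite(trial[j]) && is.finite(signatures[cond, j])) {
        d <- d + abs(trial[j] - signatures[cond, j])
        any_ok <- TRUE
      }
    }
    if (!any_ok) return(NA_character_)
    if (d < bestD) {
      bestD <- d
      best <- cond
    }
  }
  best
}

# Full leave-one-out decode by explicit per-trial loops.
oracleLooDecode <- function(power, labels, conditions = EEG_CONDITIONS) {
  decoded <- character(nrow(power))
  for (i in seq_len(nrow(power))) {
    sig <- matrix(NA_real_, length(conditions), ncol(power),
                  dimnames = list(conditions, NULL))
    for (cond in conditions) {
      rows <- setdiff(which(labels == cond), i)
      for (j in seq_len(ncol(power))) {
        v <- power[rows, j]
        v <- v[is.finite(v)]
        sig[cond, j] <- if (length(v)) mean(v) else NaN
      }
    }
    decoded[i] <- oracleDecodeTrial(power[i, ], sig)
  }
  decoded
}

# --- clustering -------------------------------------------------------------

# Connected components of supra-threshold sensor x frequency points via
# recursive flood fill (separate code path from the package's queue BFS).
oracleFloodClusters <- function(thresholdMap, tMap, adjacency) {
  pts <- which(thresholdMap & is.finite(tMap), arr.ind = TRUE)
  if (!nrow(pts)) return(list())
  n <- nrow(pts)
  neigh <- function(i, j) {
    same <- pts[i, 1] == pts[j, 1] || adjacency[pts[i, 1], pts[j, 1]]
    same && abs(pts[i, 2] - pts[j, 2]) <= 1 &&
      sign(tMap[pts[i, 1], pts[i, 2]]) == sign(tMap[pts[j, 1], pts[j, 2]])
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (j in seq_len(n)) {
        if (!comp[j] && i != j && neigh(i, j)) {
          comp[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
  }
  lapply(seq_len(cur), function(cc) {
    cells <- pts[comp == cc, , drop = FALSE]
    list(cells = cells, mass = sum(tMap[cells]))
  })
}

# Canonical representation of a cluster list for set comparison.
clusterKey <- function(clusters) {
  sort(vapply(clusters, function(cl) {
    cells <- cl$cells[order(cl$cells[, 1], cl$cells[, 2]), , drop = FALSE]
    paste(paste(cells[, 1], cells[, 2], sep = ","), collapse = ";")
  }, character(1)))
}

# --- SVR dual oracle --------------------------------------------------------

# Epsilon-insensitive linear SVR solved in the primal: for a single feature
# the objective 0.5 w^2 + C * sum(max(0, |y - w x - b| - eps)) is convex in
# just (w, b), so direct numerical minimization with multiple starts is an
# exact, independent route to the same fit.
oracleSvrFit <- function(x, y, cost = 1, epsilon = 0.1) {
  obj <- function(par) {
    r <- abs(y - par[1] * x - par[2]) - epsilon
    0.5 * par[1]^2 + cost * sum(pmax(0, r))
  }
  best <- NULL
  for (start in list(c(0, 0), c(1, 0), c(-1, 0),
                     c(cov(x, y) / max(var(x), 1e-12), mean(y)))) {
    fit <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  w <- best$par[1]
  b <- best$par[2]
  list(w = w, b = b, predict = function(xn) w * xn + b)
}

# --- JZS Bayes factor quadrature oracle -------------------------------------

# Fixed-grid Simpson quadrature of the Cauchy-mixture integrand over
# log-spaced g, at 10x the resolution any adaptive rule would need.
oracleJzsBF <- function(t, neff, df, rscale = sqrt(2) / 2, nGrid = 200001) {
  u <- seq(log(1e-12), log(1e12), length.out = nGrid)
  g <- exp(u)
  logf <- -0.5 * log1p(neff * g) -
    ((df + 1) / 2) * log1p(t^2 / ((1 + neff * g) * df)) +
    log(rscale) - 0.5 * log(2 * pi) - 1.5 * log(g) - rscale^2 / (2 * g) +
    log(g)                               # Jacobian of u = log g
  M <- max(logf)
  f <- exp(logf - M)
  h <- u[2] - u[1]
  wts <- rep(c(2, 4), length.out = nGrid)
  wts[1] <- 1
  wts[nGrid] <- 1
  I <- sum(wts * f) * h / 3
  exp(M + log(I) + ((df + 1) / 2) * log1p(t^2 / df))
}

# --- misc -------------------------------------------------------------------

# Loop re-binning of a spectrum into integer 1-40 Hz bins (round half up).
oracleBin1Hz <- function(freq, power) {
  out <- rep(NA_real_, 40)
  for (f in 1:40) {
    acc <- c()
    for (i in seq_along(freq)) if (floor(freq[i] + 0.5) == f) acc <- c(acc, power[i])
    if (length(acc)) out[f] <- mean(acc)
  }
  out
}

# Brute-force scan for runs of >= 2 consecutive frequencies above threshold.
oracleBandScan <- function(bf, threshold) {
  runs <- list()
  start <- NA
  for (f in 1:41) {
    ok <- f <= 40 && is.finite(bf[f]) && bf[f] >= threshold
    if (ok && is.na(start)) start <- f
    if (!ok && !is.na(start)) {
      if (f - start >= 2)
        runs[[length(runs) + 1]] <- c(start, f - 1)
      start <- NA
    }
  }
  runs
}
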
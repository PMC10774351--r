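# The synthetic generator: determinism, session structure, spectral shape
# against the analytic component spectra, coupling construction and recovery.

test_that("identical seeds give identical cohorts; session structure matches design", {
  cfg <- nullConfig(nParticipants = 2, nTrials = 3, nSensors = 4, seed = 33,
                    trialDuration = 4)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a@epochs[[1]]@signal, b@epochs[[1]]@signal)
  expect_identical(a@meta, b@meta)

  for (es in a@epochs) {
    expect_equal(unname(table(factor(es@condition, EEG_CONDITIONS))),
                 rep(3L, 3), ignore_attr = TRUE)
    # every imagery trial rated 1-5, rest trials unrated
    imag <- es@condition != "rest"
    expect_true(all(es@rating[imag] %in% 1:5))
    expect_true(all(is.na(es@rating[!imag])))
  }
  expect_true(all(a@truth@vividness$audio >= 1 & a@truth@vividness$audio <= 5))
  # sensor-mean is zero per trial (DC-free construction)
  expect_lt(max(abs(apply(a@epochs[[1]]@signal, c(1, 2), mean))), 1e-18)
  expect_error(generateTrialTimeseries(cfg, "P01", "sleep"),
               "unknown condition")
})

test_that("degenerate flat-noise config yields a flat binned spectrum", {
  cfg <- nullConfig(nParticipants = 1, nTrials = 20, nSensors = 2,
                    trialDuration = 4, seed = 8,
                    noiseExponent = 0, alphaPeakPower = 0)
  coh <- generateCohort(cfg)
  psd <- computePSD(coh@epochs[[1]])
  m <- apply(psd@power, 3, mean)
  slope <- coef(lm(m ~ c(1:40)))[2]
  expect_lt(abs(slope) * 40, 0.1 * mean(m))   # slope indistinguishable from flat
})

test_that("alpha peak dominates and matches the analytic spectrum before filtering", {
  cfg <- nullConfig(nParticipants = 1, nTrials = 20, nSensors = 2,
                    trialDuration = 4, seed = 44)
  coh <- generateCohort(cfg)
  psd <- computePSD(coh@epochs[[1]])
  m <- apply(psd@power, 3, mean)
  expect_equal(which.max(m[8:12]) + 7, 10)
  expect_gt(m[10], mean(m[20:40]))
  # analytic expectation: background + alpha peak, binned exactly as the
  # estimator bins the periodogram
  n <- 4 * 256
  freq <- seq_len(n %/% 2) * 256 / n
  S <- cfg@backgroundPower * pmax(freq, 0.5)^(-1) +
    cfg@alphaPeakPower * exp(-(freq - 10)^2 / (2 * 1.5^2))
  exp_m <- unname(binPower1Hz(freq, S))
  expect_lt(max(abs(m - exp_m) / exp_m), 0.2)   # Monte-Carlo bound, 60 trials
  expect_lt(mean(abs(m - exp_m) / exp_m), 0.06)
})

test_that("rest-vs-imagery alpha contrast matches the composed component spectra", {
  # imagery alpha reduced x0.5 uniformly -> rest minus imagery positive at
  # 10 Hz and equal to the analytic difference
  eff <- list(list(condition = "visual", band = c(8, 12), factor = 0.5,
                   topography = "uniform"))
  cfg <- nullConfig(nParticipants = 1, nTrials = 40, nSensors = 2,
                    trialDuration = 4, seed = 55)
  cfg@conditionEffects <- eff
  coh <- generateCohort(cfg)
  psd <- computePSD(coh@epochs[[1]])
  lab <- coh@epochs[[1]]@condition
  mRest <- apply(psd@power[lab == "rest", , , drop = FALSE], 3, mean)
  mVis <- apply(psd@power[lab == "visual", , , drop = FALSE], 3, mean)
  d10 <- mRest[10] - mVis[10]
  expect_gt(d10, 0)
  analytic <- 0.5 * (cfg@backgroundPower / 10 + cfg@alphaPeakPower)
  expect_lt(abs(d10 - analytic) / analytic, 0.25)
  # outside the band the conditions coincide
  expect_lt(abs(mRest[30] - mVis[30]), 0.3 * mRest[30])
})

test_that("zero coupling with zero rating noise gives no rating-power correlation", {
  cfg <- nullConfig(nParticipants = 30, nTrials = 4, nSensors = 2,
                    trialDuration = 2, seed = 66)
  sim <- simulateCohortPSD(cfg, epochDuration = 1.8)
  gd <- computeGlobalDifference(differencePSD(conditionMeans(sim$psd), "audio"))
  band <- rowMeans(gd[, 6:9])
  r <- cor(band, participantRatings(sim$psd, "audio"))
  expect_lt(abs(r), 3 / sqrt(30))
})

test_that("configured vividness coupling slope is recovered by regression", {
  slope <- -0.4
  nSeeds <- 20
  est <- se <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    cfg <- nullConfig(nParticipants = 44, nTrials = 6, nSensors = 2,
                      trialDuration = 2, seed = 700 + s)
    cfg@vividnessCouplings <- list(list(modality = "audio", band = c(6, 9),
                                        slope = slope, noiseSD = 0.05))
    sim <- simulateCohortPSD(cfg, epochDuration = 1.8)
    lab <- sim$psd@meta
    ids <- unique(lab$participant)
    # interior bins only: the 6 and 9 Hz bins straddle the band edges and
    # mix scaled with unscaled spectral content
    d <- vapply(ids, function(pid) {
      bandPow <- function(cond) {
        sel <- lab$participant == pid & lab$condition == cond
        mean(sim$psd@power[sel, , 7:8])
      }
      log(bandPow("audio")) - log(bandPow("rest"))
    }, numeric(1))
    v <- sim$truth@vividness$audio
    fit <- summary(lm(d ~ v))$coefficients
    est[s] <- fit[2, 1]
    se[s] <- fit[2, 2]
  }
  expect_lt(abs(mean(est) - slope), 2 * mean(se) / sqrt(nSeeds))
})

test_that("audio and visual latent vividness carry the configured correlation", {
  cfg <- nullConfig(nParticipants = 200, nTrials = 2, nSensors = 2,
                    trialDuration = 2, seed = 12)
  cfg@vividnessCorrelation <- 0.7
  coh <- generateCohort(cfg)
  r <- ratingCorrelation(coh@truth@vividness$audio, coh@truth@vividness$visual)
  expect_lt(abs(r$r - 0.7), 2 * (1 - 0.7^2) / sqrt(200))
})
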
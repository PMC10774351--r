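# Average referencing, centred epoching, amplitude screening, and their
# interaction with the synthetic generator's artifact bookkeeping.

test_that("average reference has the two-sensor closed form and idempotence", {
  x <- rbind(c(3, 5, -1), c(1, 1, 7))
  ref <- averageReference(x)
  expect_equal(ref[1, ], (x[1, ] - x[2, ]) / 2)
  expect_equal(ref[2, ], (x[2, ] - x[1, ]) / 2)
  expect_equal(averageReference(ref), ref)

  set.seed(7)
  big <- matrix(rnorm(64 * 1000), 64)
  expect_lt(max(abs(colMeans(averageReference(big)))), 1e-12)
  expect_error(averageReference(matrix(1:5, 1)), "at least 2 sensors")
})

test_that("centred epoching drops equal margins and keeps closed-form samples", {
  fs <- 1024
  x <- matrix(seq_len(10 * fs), 1)       # ramp 1..10240
  ep <- epochTrial(x, fs, 9)
  expect_equal(ncol(ep), 9216)
  expect_equal(ep[1, 1], 513)            # first kept sample = index 512 (0-based)
  expect_equal(ep[1, 9216], 9728)        # ramp value at 9.5 s
  expect_equal(epochTrial(x, fs, 10), x) # epoch = trial is the identity
  expect_error(epochTrial(x, fs, 11), "exceeds trial length")
})

test_that("amplitude screen masks on peak-to-peak range", {
  fs <- 256
  n <- 4 * fs
  thr <- 250e-6
  quiet <- 0.1 * thr * sin(2 * pi * 7 * (0:(n - 1)) / fs)  # amplitude 0.2 thr p2p
  spike <- quiet
  spike[n / 2] <- spike[n / 2] + 1.1 * thr
  sig <- array(0, c(2, 2, n))
  sig[1, 1, ] <- quiet
  sig[1, 2, ] <- spike
  sig[2, 1, ] <- quiet
  sig[2, 2, ] <- quiet
  es <- new("EpochSet", signal = sig, sfreq = fs,
            condition = c("audio", "rest"), rating = c(3, NA),
            participant = "P01", sensorNames = c("A", "B"),
            exclusionMask = matrix(FALSE, 0, 0))
  mask <- amplitudeExclusionMask(es, thr)
  expect_identical(mask, matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2))
  expect_error(amplitudeExclusionMask(es, 0), "positive")
})

test_that("injected artifacts are recovered exactly by the exclusion mask", {
  cfg <- nullConfig(nParticipants = 3, nTrials = 3, nSensors = 6,
                    seed = 21, artifactRate = 0.05)
  sim <- simulateCohortPSD(cfg)
  truth <- sim$truth@artifacts
  expect_gt(nrow(truth), 0)
  # NaN cells of the PSD (mask applied) must equal the injected locations
  nan <- which(is.na(sim$psd@power[, , 1]), arr.ind = TRUE)
  meta <- sim$psd@meta
  got <- data.frame(participant = meta$participant[nan[, 1]],
                    trialIndex = meta$trialIndex[nan[, 1]],
                    sensor = nan[, 2])
  keyG <- sort(paste(got$participant, got$trialIndex, got$sensor))
  keyT <- sort(paste(truth$participant, truth$trialIndex, truth$sensor))
  expect_identical(keyG, keyT)
})

test_that("artifact-free cohorts never trip the exclusion threshold", {
  cfg <- nullConfig(nParticipants = 2, nTrials = 3, nSensors = 6, seed = 5)
  sim <- simulateCohortPSD(cfg)
  expect_false(any(is.na(sim$psd@power)))
})
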
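# Nearest-neighbour leave-one-trial-out decoding: signature construction,
# absolute-difference distances against brute force, tie-breaking, hand
# enumeration of a toy set, and the shuffle test.

test_that("condition signatures are NaN-aware per-cell means", {
  set.seed(1)
  power <- matrix(rnorm(15 * 8), 15)
  power[2, 3] <- NaN
  labels <- rep(EEG_CONDITIONS, each = 5)
  sig <- conditionSignatures(power, labels)
  for (cond in EEG_CONDITIONS) {
    rows <- which(labels == cond)
    for (j in 1:8) {
      v <- power[rows, j]
      v <- v[is.finite(v)]
      expect_equal(unname(sig[cond, j]), mean(v))
    }
  }
  # one trial per condition: the signature is that trial
  sig1 <- conditionSignatures(power[c(1, 6, 11), ], EEG_CONDITIONS)
  expect_equal(unname(sig1), unname(power[c(1, 6, 11), ]))
  expect_error(conditionSignatures(power[1:10, ], labels[1:10]),
               "no trials")
})

test_that("trial decoding matches exhaustive absolute-difference computation", {
  set.seed(2)
  for (rep in 1:20) {
    sig <- matrix(rnorm(3 * 10), 3, dimnames = list(EEG_CONDITIONS, NULL))
    trial <- rnorm(10)
    trial[sample(10, 2)] <- NaN
    expect_identical(decodeTrial(trial, sig), oracleDecodeTrial(trial, sig))
  }
  # trial equal to one signature is decoded as that condition
  sig <- matrix(c(1, 5, 9), 3, 4, dimnames = list(EEG_CONDITIONS, NULL))
  expect_identical(decodeTrial(rep(5, 4), sig), "visual")
  # exact ties go to the earlier condition in fixed order
  sigTie <- matrix(c(2, 4, 4), 3, 1, dimnames = list(EEG_CONDITIONS, NULL))
  expect_identical(decodeTrial(3, sigTie), "audio")
  expect_identical(decodeTrial(4, sigTie), "visual")
})

test_that("leave-one-out decoding matches hand enumeration on a 6-trial toy", {
  # two trials per condition, one feature; leave-one-out signatures are the
  # remaining same-condition trial
  power <- matrix(c(1.0, 1.2,   5.0, 5.3,   9.0, 9.4), ncol = 1)
  labels <- rep(EEG_CONDITIONS, each = 2)
  res <- leaveOneOutDecode(power, labels)
  # e.g. trial 1 (1.0): signatures audio 1.2, visual 5.15, rest 9.2 -> audio
  expect_identical(res$decoded, labels)
  expect_equal(res$successRate, 1)
  expect_equal(unname(diag(res$confusion)), c(1, 1, 1))

  # push one audio trial next to the visual pair: it must decode as visual
  power[2, 1] <- 5.1
  res2 <- leaveOneOutDecode(power, labels)
  expect_identical(res2$decoded[2], "visual")
  expect_equal(res2$successRate, 5 / 6)

  # vectorized path equals the loop oracle on noisy NaN-ridden data
  set.seed(4)
  for (rep in 1:10) {
    p <- matrix(rnorm(18 * 12), 18)
    p[sample(length(p), 20)] <- NaN
    lab <- sample(rep(EEG_CONDITIONS, each = 6))
    expect_identical(leaveOneOutDecode(p, lab)$decoded, oracleLooDecode(p, lab))
  }
})

test_that("widely separated noiseless clusters decode perfectly", {
  set.seed(5)
  power <- rbind(matrix(rnorm(6 * 20, 0, 0.01), 6),
                 matrix(rnorm(6 * 20, 10, 0.01), 6),
                 matrix(rnorm(6 * 20, 20, 0.01), 6))
  labels <- rep(EEG_CONDITIONS, each = 6)
  expect_equal(leaveOneOutDecode(power, labels)$successRate, 1)
})

test_that("success rate is invariant to trial order", {
  set.seed(6)
  power <- matrix(rnorm(24 * 10), 24)
  labels <- rep(EEG_CONDITIONS, each = 8)
  base <- leaveOneOutDecode(power, labels)$successRate
  for (rep in 1:5) {
    o <- sample(24)
    expect_equal(leaveOneOutDecode(power[o, ], labels[o])$successRate, base)
  }
})

test_that("shuffle test: perfect separation attains the minimum p, and a seeded
           run equals brute-force recomputation", {
  set.seed(7)
  power <- rbind(matrix(rnorm(4 * 6, 0, 0.01), 4),
                 matrix(rnorm(4 * 6, 10, 0.01), 4),
                 matrix(rnorm(4 * 6, 20, 0.01), 4))
  labels <- rep(EEG_CONDITIONS, each = 4)
  st <- decodingShuffleTest(power, labels, nShuffles = 99)
  expect_equal(st$p, 1 / 100)

  # seeded oracle at nShuffles = 10: replay the same label draws through the
  # loop-based decoder
  p2 <- matrix(rnorm(12 * 5), 12)
  set.seed(123)
  st2 <- decodingShuffleTest(p2, labels, nShuffles = 10)
  set.seed(123)
  actual <- {
    d <- oracleLooDecode(p2, labels)
    mean(d == labels, na.rm = TRUE)
  }
  shuf <- vapply(1:10, function(i) {
    lab <- sample(labels)
    d <- oracleLooDecode(p2, lab)
    mean(d[!is.na(d)] == lab[!is.na(d)])
  }, numeric(1))
  expect_equal(st2$shuffled, shuf)
  expect_equal(st2$p, (1 + sum(shuf >= actual)) / 11)
})

test_that("cohort decoding summarises success against chance", {
  cfg <- nullConfig(nParticipants = 3, nTrials = 3, nSensors = 4,
                    trialDuration = 2, seed = 9)
  sim <- simulateCohortPSD(cfg, epochDuration = 1.8)
  dec <- decodeCohort(sim$psd, nShuffles = 19)
  expect_equal(nrow(dec@participants), 3)
  expect_true(all(dec@participants$successRate >= 0 &
                    dec@participants$successRate <= 1))
  expect_true(all(abs(colSums(dec@confusion) - 1) < 1e-12))
  expect_equal(dec@groupDf, 2)
  expect_true(all(dec@participants$shuffleP > 0 &
                    dec@participants$shuffleP <= 1))
})
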
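# Global difference scores, the repeated cross-validated SVR scheme, the
# dual-QP oracle for the single-feature fit, and BF band discovery.

test_that("global difference scores equal a brute-force triple loop", {
  set.seed(20)
  means <- list(audio = array(rnorm(5 * 3 * 6), c(5, 3, 6)),
                visual = array(rnorm(5 * 3 * 6), c(5, 3, 6)),
                rest = array(rnorm(5 * 3 * 6), c(5, 3, 6)))
  means$audio[2, 1, 3] <- NaN
  d <- differencePSD(means, "audio")
  expect_true(is.nan(d[2, 1, 3]))
  gd <- computeGlobalDifference(d)
  for (p in 1:5) for (f in 1:6) {
    acc <- c()
    for (s in 1:3) {
      v <- means$audio[p, s, f] - means$rest[p, s, f]
      if (is.finite(v)) acc <- c(acc, v)
    }
    expect_equal(gd[p, f], mean(acc))
  }
  # imagery == rest -> all zero; single sensor -> that sensor's difference
  z <- computeGlobalDifference(differencePSD(list(audio = means$rest,
                                                  rest = means$rest), "audio"))
  expect_true(all(z == 0))
  one <- list(audio = means$audio[, 1, , drop = FALSE],
              rest = means$rest[, 1, , drop = FALSE])
  g1 <- computeGlobalDifference(differencePSD(one, "audio"))
  expect_equal(g1[-2, ], (means$audio[, 1, ] - means$rest[, 1, ])[-2, ],
               ignore_attr = TRUE)
})

test_that("noiseless proportional target gives R = 1 in every fold", {
  set.seed(21)
  x <- rnorm(12)
  y <- 2.5 * x
  r <- svrCvRvalues(x, y, nIter = 5, k = 4)
  expect_length(r, 20)
  expect_true(all(abs(r - 1) < 1e-6))
})

test_that("independent target and shuffled labels centre the R distribution", {
  # a single dataset's 500 fold R-values share participants, so their mean
  # wanders by ~0.15 under the null; the zero-centring property is asserted
  # on the average over independent null datasets
  set.seed(22)
  r <- replicate(10, {
    x <- rnorm(44)
    y <- rnorm(44)
    mean(svrCvRvalues(x, y, nIter = 10, k = 4))
  })
  expect_lt(abs(mean(r)), 0.1)
  rs <- replicate(3, {
    x <- rnorm(44)
    mean(shuffledNullRvalues(x, 3 * x + rnorm(44, 0, 0.1), nIter = 10, k = 4))
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("the resampling scheme is rejected for uneven participant counts", {
  expect_error(svrCvRvalues(rnorm(10), rnorm(10), nIter = 2, k = 4),
               "divisible")
  expect_error(svrCvRvalues(rnorm(4), rnorm(4), nIter = 2, k = 4),
               "at least")
})

test_that("constant features yield all-zero R-values rather than NaN", {
  set.seed(23)
  r <- svrCvRvalues(rep(1, 8), rnorm(8), nIter = 3, k = 4)
  expect_true(all(r == 0))
})

test_that("fold fits match an independent dual-QP solution of the SVR", {
  set.seed(24)
  for (rep in 1:5) {
    x <- rnorm(8)
    y <- 0.8 * x + rnorm(8, 0, 0.5)
    train <- 1:6
    test <- 7:8
    # package path: z-scored fit via e1071
    mx <- mean(x[train]); sx <- sd(x[train])
    my <- mean(y[train]); sy <- sd(y[train])
    xt <- (x - mx) / sx
    yt <- (y - my) / sy
    fit <- e1071::svm(x = matrix(xt[train], ncol = 1), y = yt[train],
                      type = "eps-regression", kernel = "linear", cost = 1,
                      epsilon = 0.1, scale = FALSE)
    predPkg <- as.numeric(predict(fit, matrix(xt[test], ncol = 1)))
    oracle <- oracleSvrFit(xt[train], yt[train])
    predOra <- oracle$predict(xt[test])
    expect_equal(predPkg, predOra, tolerance = 5e-3)
    # fold R-values agree exactly in sign-and-correlation terms
    rPkg <- suppressWarnings(cor(predPkg, y[test]))
    rOra <- suppressWarnings(cor(predOra, y[test]))
    if (is.finite(rPkg) && is.finite(rOra)) expect_equal(rPkg, rOra)
  }
})

test_that("a seeded run is reproducible and bookkeeping is exact", {
  x <- rnorm(8)
  y <- rnorm(8)
  set.seed(25)
  r1 <- svrCvRvalues(x, y, nIter = 4, k = 4)
  set.seed(25)
  r2 <- svrCvRvalues(x, y, nIter = 4, k = 4)
  expect_identical(r1, r2)
  expect_length(r1, 16)
  expect_true(all(r1 >= -1 & r1 <= 1))
})

test_that("BF band discovery returns maximal runs of length >= 2", {
  expect_equal(nrow(frequencyBandClusters(rep(1, 40))), 0)
  bf <- rep(1, 40)
  bf[6:9] <- c(150, 1e4, 300, 101)
  b <- frequencyBandClusters(bf)
  expect_equal(b$lo, 6)
  expect_equal(b$hi, 9)
  expect_equal(b$minBF, 101)
  # isolated single frequency is not a band
  bf2 <- rep(1, 40)
  bf2[20] <- 1e6
  expect_equal(nrow(frequencyBandClusters(bf2)), 0)

  set.seed(26)
  for (rep in 1:20) {
    bfr <- exp(rnorm(40, 3, 3))
    got <- frequencyBandClusters(bfr)
    want <- oracleBandScan(bfr, 100)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$lo, vapply(want, `[`, numeric(1), 1))
      expect_equal(got$hi, vapply(want, `[`, numeric(1), 2))
    }
  }
})
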
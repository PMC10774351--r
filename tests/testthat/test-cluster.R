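# Outlier interpolation, paired-t maps, spatio-frequency clustering against
# a flood-fill oracle, exhaustive sign-flip enumeration, and symmetry.

gridAdjacency <- function(n) {       # chain adjacency: sensor i ~ i+1
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  adj
}

test_that("outlier interpolation replaces planted outliers by neighbour means", {
  # bounded (uniform) base data: no point can sit 3 inclusive SDs out, so
  # the untouched array passes through identically
  set.seed(10)
  means <- array(runif(30 * 4 * 5), c(30, 4, 5))
  adj <- gridAdjacency(4)
  expect_identical(outlierInterpolate(means, adj), means)
  # plant a 10-SD value at participant 3, sensor 2, freq 4 (detection uses
  # the all-participant mean and SD, which the outlier itself inflates; at
  # n = 30 a 10-SD spike still exceeds the 3-SD limit)
  m <- means
  m[3, 2, 4] <- 10 * sd(m[, 2, 4]) + mean(m[, 2, 4])
  out <- outlierInterpolate(m, adj)
  expect_equal(out[3, 2, 4], mean(m[3, c(1, 3), 4]))   # neighbours of sensor 2
  expect_identical(out[-3, , ], m[-3, , ])
  # all-NaN neighbours -> NaN
  m2 <- means
  m2[3, 2, 4] <- 10 * sd(m2[, 2, 4]) + mean(m2[, 2, 4])
  m2[3, 1, 4] <- NaN
  m2[3, 3, 4] <- NaN
  out2 <- outlierInterpolate(m2, adj)
  expect_true(is.nan(out2[3, 2, 4]))
})

test_that("paired-t map matches t.test cell by cell, with degenerate handling", {
  set.seed(11)
  a <- array(rnorm(10 * 3 * 4), c(10, 3, 4))
  b <- array(rnorm(10 * 3 * 4), c(10, 3, 4))
  b[4, 2, 3] <- NaN
  tm <- pairedTMap(a, b)
  for (s in 1:3) for (f in 1:4) {
    d <- a[, s, f] - b[, s, f]
    tt <- t.test(d[is.finite(d)])
    expect_equal(tm$t[s, f], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(tm$p[s, f], tt$p.value, tolerance = 1e-12)
  }
  expect_equal(tm$n[2, 3], 9)
  # identical conditions -> t = 0 everywhere
  t0 <- pairedTMap(a, a)
  expect_true(all(t0$t == 0))
  # constant nonzero difference -> infinite t, p = 0
  tc <- pairedTMap(a + 1, a)
  expect_true(all(is.infinite(tc$t) & tc$t > 0))
  expect_true(all(tc$p == 0))
})

test_that("cluster formation matches the flood-fill oracle on random maps", {
  expect_identical(formClusters(matrix(FALSE, 4, 6), matrix(0, 4, 6),
                                gridAdjacency(4)), list())
  # two supra-threshold points at one sensor, adjacent frequencies: 1 cluster
  thr <- matrix(FALSE, 4, 12)
  thr[2, 9] <- thr[2, 10] <- TRUE
  tm <- matrix(1, 4, 12)
  cl <- formClusters(thr, tm, gridAdjacency(4))
  expect_length(cl, 1)
  expect_equal(cl[[1]]$mass, 2)

  set.seed(12)
  adj <- delaunayAdjacency(defaultMontage(8))
  for (rep in 1:8) {
    tm <- matrix(rnorm(8 * 40), 8, 40)
    thr <- matrix(runif(8 * 40) < 0.2, 8, 40)
    got <- formClusters(thr, tm, adj)
    want <- oracleFloodClusters(thr, tm, adj)
    expect_identical(clusterKey(got), clusterKey(want))
    expect_equal(sort(vapply(got, `[[`, numeric(1), "mass")),
                 sort(vapply(want, `[[`, numeric(1), "mass")))
  }
})

test_that("signs cluster separately even when spatially adjacent", {
  thr <- matrix(FALSE, 2, 5)
  thr[1, 2] <- thr[1, 3] <- TRUE
  tm <- matrix(0, 2, 5)
  tm[1, 2] <- 3
  tm[1, 3] <- -3
  cl <- formClusters(thr, tm, gridAdjacency(2))
  expect_length(cl, 2)
})

test_that("n = 3 permutation null equals exhaustive sign-flip enumeration", {
  set.seed(13)
  a <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  b <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  adj <- gridAdjacency(4)
  res <- clusterPermutationTest(a, b, adj, nPerm = 8)
  expect_true(res@exhaustive)
  expect_equal(res@nPerm, 8L)

  # independent enumeration: all 2^3 sign patterns through t.test + oracle
  d <- a - b
  nullMax <- apply(expand.grid(c(1, -1), c(1, -1), c(1, -1)), 1, function(sg) {
    ds <- d * c(sg)
    tm <- matrix(NA_real_, 4, 6)
    pm <- matrix(NA_real_, 4, 6)
    for (s in 1:4) for (f in 1:6) {
      tt <- t.test(ds[, s, f])
      tm[s, f] <- tt$statistic
      pm[s, f] <- tt$p.value
    }
    cl <- oracleFloodClusters(pm < 0.05, tm, adj)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  })
  expect_equal(sort(res@nullMax), sort(nullMax), tolerance = 1e-10)
  for (cl in res@clusters)
    expect_equal(cl$p, mean(nullMax >= abs(cl$mass) - 1e-10))
})

test_that("swapping conditions negates t and masses but keeps p-values", {
  set.seed(14)
  a <- array(rnorm(6 * 4 * 8), c(6, 4, 8)) + 0.5
  b <- array(rnorm(6 * 4 * 8), c(6, 4, 8))
  adj <- gridAdjacency(4)
  r1 <- clusterPermutationTest(a, b, adj, nPerm = 64)
  r2 <- clusterPermutationTest(b, a, adj, nPerm = 64)
  expect_equal(r2@tMap, -r1@tMap)
  m1 <- sort(vapply(r1@clusters, `[[`, numeric(1), "mass"))
  m2 <- sort(-vapply(r2@clusters, `[[`, numeric(1), "mass"))
  expect_equal(sort(m1), sort(m2))
  expect_equal(sort(vapply(r1@clusters, `[[`, numeric(1), "p")),
               sort(vapply(r2@clusters, `[[`, numeric(1), "p")))
})

test_that("rating correlation has closed-form extremes and errors", {
  x <- c(1, 2, 3, 4.5)
  expect_equal(ratingCorrelation(x, x)$r, 1)
  expect_equal(ratingCorrelation(x, -x)$r, -1)
  expect_error(ratingCorrelation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(ratingCorrelation(c(1, 2), c(1, 2)), "at least 3")
})
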
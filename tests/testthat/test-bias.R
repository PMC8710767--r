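mkMask <- function(g = 6) array(TRUE, dim = rep(g, 3))

mkDelta <- function(mask, value) {
  m <- array(NA_real_, dim = dim(mask))
  m[mask] <- value
  m
}

test_that("bin means equal a brute-force group-by mean", {
  set.seed(14)
  mask <- mkMask()
  n <- 25
  ages <- runif(n, 18, 90)
  maps <- lapply(seq_len(n), function(i) mkDelta(mask, rnorm(sum(mask))))
  cal <- fitVoxelBins(maps, ages, mask)
  edges <- binEdges(cal)
  bins <- findInterval(ages, edges, rightmost.closed = TRUE)
  M <- vapply(maps, function(m) m[mask], numeric(sum(mask)))
  for (b in unique(bins)) {
    brute <- rowMeans(M[, bins == b, drop = FALSE])
    expect_equal(unname(cal@deltas[, as.character(b)]), unname(brute),
                 tolerance = 1e-12)
  }
  expect_equal(sum(binCounts(cal)), n)
})

test_that("constant deltas give constant bin means; singleton bins reproduce their member", {
  mask <- mkMask(4)
  ages <- c(20, 40, 70)
  maps <- list(mkDelta(mask, 3), mkDelta(mask, 3), mkDelta(mask, 3))
  cal <- fitVoxelBins(maps, ages, mask)
  expect_true(all(cal@deltas == 3))
  # one participant per bin: the stored mean is that participant's delta
  set.seed(2)
  vals <- lapply(1:3, function(i) rnorm(sum(mask)))
  maps2 <- lapply(vals, mkDelta, mask = mask)
  cal2 <- fitVoxelBins(maps2, ages, mask)
  adj <- applyVoxelDebias(maps2[[2]], ages[2], cal2)
  expect_true(all(abs(adj[mask]) < 1e-12))
})

test_that("de-biasing the calibration set itself zeroes every bin mean exactly", {
  set.seed(15)
  mask <- mkMask()
  n <- 30
  ages <- runif(n, 18, 90)
  maps <- lapply(seq_len(n), function(i)
    mkDelta(mask, rnorm(sum(mask), mean = 0.3 * (ages[i] - 54))))
  cal <- fitVoxelBins(maps, ages, mask)
  adj <- mapply(applyVoxelDebias, maps, ages,
                MoreArgs = list(calibration = cal), SIMPLIFY = FALSE)
  bins <- findInterval(ages, binEdges(cal), rightmost.closed = TRUE)
  A <- vapply(adj, function(m) m[mask], numeric(sum(mask)))
  for (b in unique(bins)) {
    mu <- rowMeans(A[, bins == b, drop = FALSE])
    expect_true(all(abs(mu) < 1e-12))
  }
})

test_that("ages outside the calibration range clamp to the nearest bin", {
  mask <- mkMask(4)
  ages <- c(20, 40, 70)
  set.seed(3)
  maps <- lapply(1:3, function(i) mkDelta(mask, rnorm(sum(mask))))
  cal <- fitVoxelBins(maps, ages, mask)
  a17 <- applyVoxelDebias(maps[[1]], 17, cal)       # clamps into [18,25)
  a20 <- applyVoxelDebias(maps[[1]], 20, cal)
  expect_identical(a17, a20)
  a99 <- applyVoxelDebias(maps[[3]], 99, cal)
  a70 <- applyVoxelDebias(maps[[3]], 70, cal)
  expect_identical(a99, a70)
  expect_error(applyVoxelDebias(maps[[1]], 17, cal, clamp = FALSE), "outside")
  # occupied-bin gap: age 55 clamps to nearest occupied bin when allowed
  expect_error(applyVoxelDebias(maps[[1]], 55, cal, clamp = FALSE),
               "uncalibrated bin")
})

test_that("voxel and global adjustments are equivariant to a constant shift", {
  set.seed(16)
  mask <- mkMask(4)
  n <- 12
  ages <- runif(n, 18, 90)
  maps <- lapply(seq_len(n), function(i) mkDelta(mask, rnorm(sum(mask))))
  mapsC <- lapply(maps, function(m) m + 2.5)
  cal <- fitVoxelBins(maps, ages, mask)
  calC <- fitVoxelBins(mapsC, ages, mask)
  a1 <- applyVoxelDebias(maps[[1]], ages[1], cal)
  a2 <- applyVoxelDebias(mapsC[[1]], ages[1], calC)
  expect_equal(a1[mask], a2[mask], tolerance = 1e-12)
  d <- rnorm(n); fit <- fitGlobalLinear(d, ages)
  fitC <- fitGlobalLinear(d + 2.5, ages)
  expect_equal(applyGlobalDebias(d, ages, fit),
               applyGlobalDebias(d + 2.5, ages, fitC), tolerance = 1e-12)
})

test_that("global linear fit matches the normal equations and zeroes linear bias", {
  set.seed(17)
  ages <- runif(40, 18, 90)
  # exactly linear bias: adjustment removes it entirely
  d <- -0.4 * ages + 12
  fit <- fitGlobalLinear(d, ages, "on_age")
  expect_equal(fit@slope, -0.4, tolerance = 1e-10)
  adj <- applyGlobalDebias(d, ages, fit)
  expect_true(all(abs(adj) < 1e-10))
  # age-independent deltas: only the mean is removed
  d0 <- rep(5, 40) + 0
  fit0 <- fitGlobalLinear(d0 + rnorm(40, sd = 1e-12), ages)
  expect_equal(fit0@slope, 0, tolerance = 1e-6)
  # random data: closed-form least squares oracle
  dr <- rnorm(40)
  fr <- fitGlobalLinear(dr, ages)
  sl <- sum((ages - mean(ages)) * (dr - mean(dr))) / sum((ages - mean(ages))^2)
  expect_equal(fr@slope, sl, tolerance = 1e-12)
  expect_equal(fr@intercept, mean(dr) - sl * mean(ages), tolerance = 1e-12)
  expect_error(fitGlobalLinear(dr, rep(1, 40)), "zero-variance")
  expect_error(fitGlobalLinear(dr[1:2], ages[1:2]), "at least 3")
})

test_that("a known age-dependent bias field is removed up to sampling error", {
  set.seed(18)
  mask <- mkMask(5)
  n <- 120
  ages <- runif(n, 18, 90)
  bias <- function(a) 0.25 * (a - 54)
  truthD <- lapply(seq_len(n), function(i) rnorm(sum(mask), sd = 0.3))
  maps <- lapply(seq_len(n), function(i)
    mkDelta(mask, truthD[[i]] + bias(ages[i])))
  cal <- fitVoxelBins(maps, ages, mask)
  adj <- mapply(applyVoxelDebias, maps, ages,
                MoreArgs = list(calibration = cal), SIMPLIFY = FALSE)
  resid <- mapply(function(a, t) mean(a[mask] - t), adj, truthD)
  # residual bias bounded by within-bin spread: bias slope 0.25/yr over a
  # 5-year bin plus noise-mean error
  expect_lt(max(abs(resid)), 1.5)
  # and the age trend is gone at the global level
  gl <- vapply(adj, function(m) mean(m[mask]), 0)
  expect_lt(abs(cor(gl, ages)), 0.3)
})
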
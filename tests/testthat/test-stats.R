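test_that("Welch t matches the reference implementation on random draws", {
  set.seed(20)
  for (r in 1:300) {
    x <- rnorm(sample(5:60, 1), mean = runif(1, -2, 2), sd = runif(1, 0.2, 3))
    y <- rnorm(sample(5:60, 1), mean = runif(1, -2, 2), sd = runif(1, 0.2, 3))
    got <- welchT(x, y)
    ref <- t.test(x, y)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch t closed-form example and symmetries", {
  a <- list(n = 100, mean = 1, var = 1)
  b <- list(n = 100, mean = 0, var = 1)
  got <- welchT(a, b)
  expect_equal(got$t, 1 / sqrt(2 / 100), tolerance = 1e-10)
  expect_equal(got$t, 7.0711, tolerance = 1e-4)
  expect_equal(got$df, 198, tolerance = 1e-10)
  swapped <- welchT(b, a)
  expect_equal(swapped$t, -got$t)
  expect_equal(swapped$df, got$df)
  expect_equal(welchT(a, a)$t, 0)
  expect_error(welchT(list(n = 5, mean = 1, var = 0),
                      list(n = 5, mean = 2, var = 0)), "undefined")
})

test_that("type-I error of the Welch test is nominal under the null", {
  set.seed(21)
  nsim <- 400
  hits <- 0
  for (r in seq_len(nsim)) {
    x <- rnorm(20, sd = 2); y <- rnorm(35, sd = 0.5)
    if (welchT(x, y)$p < 0.05) hits <- hits + 1
  }
  env <- qbinom(c(0.005, 0.995), nsim, 0.05)
  expect_gte(hits, env[1])
  expect_lte(hits, env[2])
})

test_that("Cohen's d uses the pooled SD and is shift/scale invariant", {
  a <- list(n = 30, mean = 1, var = 1)
  b <- list(n = 20, mean = 0, var = 1)
  expect_equal(cohensD(a, b), 1, tolerance = 1e-12)
  set.seed(22)
  x <- rnorm(25, 1, 2); y <- rnorm(18, 0, 1.5)
  d0 <- cohensD(x, y)
  expect_equal(cohensD(x + 5, y + 5), d0, tolerance = 1e-12)
  expect_equal(cohensD(3 * x, 3 * y), d0, tolerance = 1e-12)
  expect_equal(cohensD(x, x), 0)
  # closed-form oracle
  sp <- sqrt(((25 - 1) * var(x) + (18 - 1) * var(y)) / (25 + 18 - 2))
  expect_equal(d0, (mean(x) - mean(y)) / sp, tolerance = 1e-12)
})

test_that("the classical two-measurement ICC formula matches a hand computation", {
  x <- cbind(c(1, 2, 3), c(2, 4, 6))
  # hand evaluation: pooled mean 3; pooled variance
  # ((4+1+0)+(1+1+9))/6 = 16/6; cross term (-2)(-1)+(-1)(1)+0*3 = 1
  expect_equal(icc(x, "fisher"), 1 / (3 * (16 / 6)), tolerance = 1e-12)
  expect_error(icc(cbind(1:3, 1:3, 1:3), "fisher"), "exactly 2")
})

test_that("ICC(2,1) is 1 for duplicated columns, ~0 under independence, and degrades monotonically", {
  set.seed(23)
  x <- rnorm(50)
  expect_equal(icc(cbind(x, x)), 1, tolerance = 1e-12)
  big <- matrix(rnorm(2 * 10000), ncol = 2)
  expect_lt(abs(icc(big)), 0.05)
  i_small <- icc(cbind(x, x + rnorm(50, sd = 0.2)))
  i_large <- icc(cbind(x, x + rnorm(50, sd = 1.5)))
  expect_gt(i_small, i_large)
  expect_true(abs(icc(big)) <= 1)
  # a consistent rater offset lowers absolute agreement
  expect_lt(icc(cbind(x, x + 1)), 1)
  # k = 3 raters supported
  expect_equal(icc(cbind(x, x, x)), 1, tolerance = 1e-12)
  expect_error(icc(matrix(1, 4, 2)), "zero total variance")
})

test_that("vectorised ICC maps agree with the scalar ICC(2,1)", {
  set.seed(24)
  mask <- array(TRUE, dim = c(3, 3, 3))
  n <- 15
  maps1 <- lapply(seq_len(n), function(i) array(rnorm(27), dim = dim(mask)))
  maps2 <- lapply(seq_len(n), function(i)
    maps1[[i]] * 0.8 + array(rnorm(27, sd = 0.5), dim = dim(mask)))
  im <- iccMap(maps1, maps2, mask)
  for (v in sample(27, 6)) {
    x <- cbind(vapply(maps1, `[`, 0, v), vapply(maps2, `[`, 0, v))
    expect_equal(im[v], icc(x), tolerance = 1e-10)
  }
})

test_that("Pearson correlation matches its covariance formula", {
  expect_equal(pearsonR(1:10, 1:10), 1)
  expect_equal(pearsonR(1:10, -(1:10)), -1)
  set.seed(25)
  x <- rnorm(40); y <- rnorm(40)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonR(x, y), oracle, tolerance = 1e-12)
  expect_error(pearsonR(c(1, 1, 1), 1:3), "zero variance")
})

test_that("ROI aggregation equals a brute-force per-label mean and partitions the mask", {
  cfg <- tinyConfig(n_participants = 1)
  co <- generateCohort(cfg)
  mask <- brainMask(co$truth)
  atlas <- phantomAtlas(co$truth)
  set.seed(26)
  map <- array(NA_real_, dim = dim(mask))
  map[mask] <- rnorm(sum(mask), 60, 5)
  res <- roiAggregate(map, atlas, age_years = 50)
  lab <- atlasLabels(atlas)
  for (i in sample(nrow(res), 5)) {
    brute <- mean(map[lab == res$label[i]])
    expect_equal(res$mean_value[i], brute, tolerance = 1e-12)
    expect_equal(res$brain_pad[i], brute - 50, tolerance = 1e-12)
  }
  # ROI-volume bookkeeping and whole-mask commutation
  expect_equal(sum(res$n_voxels), sum(mask))
  expect_equal(res$volume_mm3, res$n_voxels * 1.5^3)
  expect_equal(sum(res$mean_value * res$n_voxels) / sum(res$n_voxels),
               mean(map[mask]), tolerance = 1e-12)
  # constant offset map: every ROI brain-PAD equals the offset
  map2 <- array(NA_real_, dim = dim(mask)); map2[mask] <- 55
  res2 <- roiAggregate(map2, atlas, age_years = 50)
  expect_true(all(abs(res2$brain_pad - 5) < 1e-12))
})

test_that("pairwise group comparisons carry Bonferroni-adjusted p-values", {
  set.seed(27)
  vals <- list(HC = rnorm(30), A = rnorm(25, 1), B = rnorm(20, 2))
  res <- compareGroups(vals, scope = "global")
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adj, pmin(1, res$p * 3), tolerance = 1e-12)
  one <- compareGroups(vals[1:2], scope = "roi", n_comparisons = 1)
  expect_equal(one$p_adj, one$p)
  expect_equal(bonferroni(0.03, 10), 0.3)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_error(compareGroups(list(a = 1:5, b = 2)), "n >= 2")
})

test_that("age matching keeps strictly older participants", {
  rec <- data.frame(participant_id = c("a", "b", "c"),
                    age_years = c(59, 60, 61))
  expect_equal(ageMatchedSubset(rec, 60)$participant_id, "c")
  expect_equal(nrow(ageMatchedSubset(rec, 0)), 3)
  expect_warning(out <- ageMatchedSubset(rec, 70), "no participants")
  expect_equal(nrow(out), 0)
})
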
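test_that("spatial contract holds for arbitrary weights", {
  net <- tinyNet(seed = 11)
  x <- array(runif(2 * 52^3), c(2, 52, 52, 52, 1))
  fw <- forwardNetwork(net, x)
  expect_equal(dim(fw$voxel), c(12, 12, 12, 1))
  expect_equal(dim(fw$aux), c(2, 1))
  expect_true(all(is.finite(fw$voxel)))
  # a spec that breaks the contract is rejected
  expect_error(unetSpec(input_side = 50), "contract|odd")
})

test_that("all-zero weights collapse outputs to the biases", {
  net <- tinyNet()
  p <- mapParams(function(x) { x[] <- 0; x }, networkParams(net))
  p$out$b[] <- 7.5
  p$aux1$b[] <- 3
  p$aux2$b[] <- 4
  slot(net, "params") <- p
  fw <- forwardNetwork(net, array(runif(2 * 52^3), c(2, 52, 52, 52, 1)))
  expect_true(all(fw$voxel == 7.5))
  expect_equal(fw$aux[, 1], c(3, 4))
})

test_that("composite loss matches a brute-force evaluation", {
  cfg <- lossConfig(alpha_init = c(0.7, 0.3), decay_iterations = 100)
  set.seed(42)
  for (r in 1:20) {
    N <- sample(1:4, 1)
    vox <- array(rnorm(12^3 * N, 50, 10), c(12, 12, 12, N))
    aux <- matrix(rnorm(2 * N, 50, 10), 2, N)
    ages <- runif(N, 18, 90)
    it <- sample(0:120, 1)
    got <- compositeLoss(list(voxel = vox, aux = aux), ages, cfg, it)
    # independent brute-force loop over voxels, heads and samples
    a <- pmax(0, 1 - it / 100) * c(0.7, 0.3)
    want <- 0
    for (n in seq_len(N)) {
      for (v in seq_len(12^3)) want <- want + abs(ages[n] - vox[v + (n - 1) * 12^3])
      for (b in 1:2) want <- want + a[b] * abs(ages[n] - aux[b, n])
    }
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("with zero auxiliary weight the loss is the voxel MAE sum", {
  cfg <- lossConfig(alpha_init = c(0, 0))
  vox <- array(50, c(12, 12, 12, 1))
  vox[1] <- 52
  got <- compositeLoss(list(voxel = vox, aux = matrix(0, 2, 1)), 50, cfg, 0)
  expect_equal(got, 2)
})

test_that("after the decay horizon the loss ignores the auxiliary heads", {
  cfg <- lossConfig(decay_iterations = 50000)
  vox <- array(40, c(12, 12, 12, 1))
  l1 <- compositeLoss(list(voxel = vox, aux = matrix(10, 2, 1)), 40, cfg, 50000)
  l2 <- compositeLoss(list(voxel = vox, aux = matrix(99, 2, 1)), 40, cfg, 60000)
  expect_equal(l1, 0)
  expect_equal(l2, 0)
  expect_equal(alphaSchedule(50000, cfg), c(0, 0))
  expect_equal(alphaSchedule(25000, cfg), c(0.5, 0.5))
  expect_error(compositeLoss(list(voxel = vox, aux = matrix(0, 2, 1)), 40,
                             lossConfig(alpha_init = c(-1, 0))), "alpha")
})

test_that("analytic gradients match finite differences through every block type", {
  net <- tinyNet(seed = 5)
  set.seed(9)
  x <- array(runif(2 * 52^3 * 2), c(2, 52, 52, 52, 2))
  ages <- c(40, 60)
  cfg <- lossConfig()
  fw <- forwardNetwork(net, x, cache = TRUE)
  lg <- localbrainage:::compositeLossGrad(fw[c("voxel", "aux")], ages, cfg, 0)
  g <- backwardNetwork(net, fw$cache, lg$dvox, lg$daux)
  lossAt <- function(nn) compositeLoss(forwardNetwork(nn, x), ages, cfg, 0)
  base <- lossAt(net)
  eps <- 1e-5
  probes <- list(c("c1", "w", 5), c("c4", "w", 17), c("c7", "w", 33),
                 c("c10", "b", 1), c("out", "w", 2), c("aux1", "w", 3),
                 c("aux2", "b", 1))
  for (pr in probes) {
    p2 <- networkParams(net)
    i <- as.integer(pr[3])
    p2[[pr[1]]][[pr[2]]][i] <- p2[[pr[1]]][[pr[2]]][i] + eps
    n2 <- net; slot(n2, "params") <- p2
    expect_equal(g[[pr[1]]][[pr[2]]][i], (lossAt(n2) - base) / eps,
                 tolerance = 1e-3)
  }
  # squeeze-and-excite path
  for (pr in list(c("c3", "w2", 1), c("c6", "b2", 2))) {
    p2 <- networkParams(net)
    i <- as.integer(pr[3])
    p2[[pr[1]]]$se[[pr[2]]][i] <- p2[[pr[1]]]$se[[pr[2]]][i] + eps
    n2 <- net; slot(n2, "params") <- p2
    expect_equal(g[[pr[1]]]$se[[pr[2]]][i], (lossAt(n2) - base) / eps,
                 tolerance = 1e-3)
  }
})

test_that("per-layer field accounting: +2 per convolution, +1 per pooling, 0 per upsampling", {
  net <- tinyNet()
  expect_equal(measureReceptiveField(net, upto = 1), 3)
  expect_equal(measureReceptiveField(net, upto = 2), 5)
  expect_equal(measureReceptiveField(net, upto = 3), 6)   # pooling
  expect_equal(measureReceptiveField(net, upto = 5), 10)
  expect_equal(measureReceptiveField(net), 23)
  # an extra valid convolution per scale widens the field by 2 per conv
  sp3 <- unetSpec(convs_per_scale = 3, input_side = 70, output_side = 10)
  expect_equal(measureReceptiveField(sp3, upto = 2), 5)
  expect_equal(measureReceptiveField(sp3, upto = 3), 7)
  expect_equal(measureReceptiveField(sp3), 33)
})

test_that("output is covariant to input shifts by the total pooling stride", {
  net <- tinyNet(seed = 13)
  # hold the squeeze-and-excite gates constant: their global average
  # pooling couples every voxel, so exact covariance is a property of the
  # convolutional geometry alone
  p <- networkParams(net)
  for (nm in paste0("c", 1:10)) {
    p[[nm]]$se$w1[] <- 0
    p[[nm]]$se$w2[] <- 0
  }
  slot(net, "params") <- p
  set.seed(21)
  x1 <- array(0, c(2, 52, 52, 52, 1))
  x1[, 9:44, 9:44, 9:44, 1] <- runif(2 * 36^3)
  x2 <- array(0, c(2, 52, 52, 52, 1))
  x2[, 5:52, , , ] <- x1[, 1:48, , , ]   # content shifted +4 along axis 1
  o1 <- forwardNetwork(net, x1)$voxel
  o2 <- forwardNetwork(net, x2)$voxel
  expect_equal(o2[5:12, , , 1], o1[1:8, , , 1], tolerance = 1e-10)
})

test_that("checkpoints round-trip the spec and weights", {
  net <- tinyNet(seed = 17)
  path <- tempfile(fileext = ".rds")
  saveNetwork(net, path)
  back <- loadNetwork(path)
  expect_identical(networkParams(back), networkParams(net))
  expect_identical(networkSpec(back), networkSpec(net))
})
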
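test_that("participant split is disjoint, exhaustive and deterministic", {
  rec <- data.frame(participant_id = sprintf("p%02d", 1:10),
                    age_years = runif(10, 20, 80))
  s <- splitCohort(rec, 0.8, seed = 4)
  expect_length(s$train, 8)
  expect_length(s$validation, 2)
  expect_length(intersect(s$train, s$validation), 0)
  expect_setequal(c(s$train, s$validation), rec$participant_id)
  expect_identical(splitCohort(rec, 0.8, seed = 4), s)
  expect_false(identical(splitCohort(rec, 0.8, seed = 5), s))
  expect_error(splitCohort(rec[1, , drop = FALSE], 0.8), "at least 2")
  expect_error(splitCohort(rec, 0.01), "empty split side")
  # duplicated ids (multi-scan) still split at participant level
  rec2 <- rbind(rec, rec)
  s2 <- splitCohort(rec2, 0.8, seed = 4)
  expect_length(intersect(s2$train, s2$validation), 0)
})

test_that("zero iterations leave the network unchanged", {
  cfg <- tinyConfig(n_participants = 4)
  co <- generateCohort(cfg)
  net <- tinyNet()
  tc <- trainConfig(max_iterations = 0, minibatch = 4, grad_splits = 2,
                    init_output_bias = FALSE)
  tr <- trainNetwork(net, co$volumes, co$records, brainMask(co$truth), tc)
  expect_identical(networkParams(tr$net), networkParams(net))
  expect_equal(nrow(tr$history), 0)
})

test_that("short training decreases the loss on a tiny phantom cohort", {
  cfg <- tinyConfig(n_participants = 8, noise_sd = 0.02, seed = 31)
  co <- generateCohort(cfg)
  net <- tinyNet(seed = 2)
  tc <- trainConfig(learning_rate = 3e-3, max_iterations = 40, minibatch = 4,
                    grad_splits = 4, seed = 6)
  tr <- trainNetwork(net, co$volumes, co$records, brainMask(co$truth), tc)
  h <- tr$history$train_loss
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))
  # deterministic given the seed
  tr2 <- trainNetwork(net, co$volumes, co$records, brainMask(co$truth), tc)
  expect_identical(tr2$history, tr$history)
  expect_identical(networkParams(tr2$net), networkParams(tr$net))
})

test_that("with zero auxiliary weight the trajectory ignores the aux heads", {
  cfg <- tinyConfig(n_participants = 4, seed = 33)
  co <- generateCohort(cfg)
  tc <- trainConfig(learning_rate = 1e-3, max_iterations = 4, minibatch = 4,
                    grad_splits = 2, loss = lossConfig(alpha_init = c(0, 0)),
                    seed = 8)
  netA <- tinyNet(seed = 2)
  netB <- tinyNet(seed = 2)
  pB <- networkParams(netB)
  pB$aux1$w <- pB$aux1$w + 5   # different aux heads, same trunk
  pB$aux2$w <- pB$aux2$w - 3
  slot(netB, "params") <- pB
  trA <- trainNetwork(netA, co$volumes, co$records, brainMask(co$truth), tc)
  trB <- trainNetwork(netB, co$volumes, co$records, brainMask(co$truth), tc)
  expect_identical(trA$history, trB$history)
  expect_identical(networkParams(trA$net)$c1, networkParams(trB$net)$c1)
})

test_that("a constant-output network predicts a constant map", {
  cfg <- tinyConfig(n_participants = 1)
  co <- generateCohort(cfg)
  mask <- brainMask(co$truth)
  net <- tinyNet()
  p <- mapParams(function(x) { x[] <- 0; x }, networkParams(net))
  p$out$b[] <- 55
  slot(net, "params") <- p
  m <- predictMap(net, co$volumes[[1]], mask)
  expect_true(all(m[mask] == 55))
  expect_true(all(is.na(m[!mask])))
  mw <- predictMap(net, co$volumes[[1]], mask, method = "whole")
  expect_true(all(mw[mask] == 55))
  # global prediction is the in-mask mean of the map by definition
  expect_equal(globalPrediction(m), 55)
})

test_that("stitched prediction is invariant to block evaluation order", {
  cfg <- tinyConfig(n_participants = 1, seed = 12)
  co <- generateCohort(cfg)
  mask <- brainMask(co$truth)
  net <- tinyNet(seed = 19)
  plan <- planBlocks(mask)
  m1 <- predictMap(net, co$volumes[[1]], mask, plan = plan)
  perm <- sample(nrow(blockOrigins(plan)))
  plan2 <- new("BlockPlan", origins = blockOrigins(plan)[perm, , drop = FALSE],
               inputSide = plan@inputSide, outputSide = plan@outputSide,
               volumeDim = plan@volumeDim)
  m2 <- predictMap(net, co$volumes[[1]], mask, plan = plan2)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("validation plateau stops training early", {
  cfg <- tinyConfig(n_participants = 6, seed = 35)
  co <- generateCohort(cfg)
  # a tiny learning rate cannot improve validation MAE beyond tolerance
  tc <- trainConfig(learning_rate = 1e-9, max_iterations = 30, minibatch = 4,
                    grad_splits = 2, eval_every = 2, plateau_patience = 3,
                    plateau_tol = 0.5, n_val_blocks = 4, seed = 9)
  tr <- trainNetwork(tinyNet(), co$volumes, co$records, brainMask(co$truth), tc)
  expect_lt(nrow(tr$history), 30)
})
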
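test_that("zero-effect, zero-noise cohort is constant across participants", {
  cfg <- tinyConfig(noise_sd = 0, beta_max = 0)
  co <- generateCohort(cfg)
  ref <- co$volumes[[1]]
  for (vp in co$volumes[-1]) {
    expect_identical(gmVolume(vp), gmVolume(ref))
    expect_identical(wmVolume(vp), wmVolume(ref))
  }
  # and equals the base map on each channel's support
  truth <- co$truth
  shell <- gmVolume(ref) > 0
  expect_equal(gmVolume(ref)[shell], baseMap(truth)[shell])
})

test_that("intensity declines strictly with age where the atrophy rate is positive", {
  cfg <- tinyConfig(noise_sd = 0)
  co <- generateCohort(cfg)
  truth <- co$truth
  v <- which(betaMap(truth) > 0.5 * max(betaMap(truth)) & gmVolume(co$volumes[[1]]) > 0)[1]
  ages <- co$records$age_years
  vals <- vapply(co$volumes, function(vp) gmVolume(vp)[v], 0)
  ord <- order(ages)
  expect_true(all(diff(vals[ord]) < 0))
})

test_that("a fixed seed reproduces the cohort exactly", {
  a <- generateCohort(tinyConfig(seed = 7))
  b <- generateCohort(tinyConfig(seed = 7))
  expect_identical(lapply(a$volumes, gmVolume), lapply(b$volumes, gmVolume))
  expect_identical(a$records, b$records)
  c <- generateCohort(tinyConfig(seed = 8))
  expect_false(identical(gmVolume(a$volumes[[1]]), gmVolume(c$volumes[[1]])))
})

test_that("noise-free generating model is exactly recoverable by least squares", {
  cfg <- tinyConfig(noise_sd = 0, n_participants = 12)
  co <- generateCohort(cfg)
  truth <- co$truth
  mask <- brainMask(truth)
  ages <- co$records$age_years - 18
  vox <- sample(which(mask), 50)
  total <- vapply(co$volumes, function(vp) gmVolume(vp) + wmVolume(vp),
                  array(0, dim(mask)))
  for (v in vox) {
    y <- apply(total, 4, function(x) x[v])
    fit <- lm(y ~ ages)
    expect_equal(unname(coef(fit)[2]), -betaMap(truth)[v], tolerance = 1e-8)
    expect_equal(unname(coef(fit)[1]), baseMap(truth)[v], tolerance = 1e-8)
  }
})

test_that("group atrophy is confined to the configured ROI labels", {
  cfg0 <- tinyConfig(noise_sd = 0, n_participants = 6)
  co0 <- generateCohort(cfg0)
  lab <- atlasLabels(phantomAtlas(co0$truth))
  roi <- sort(unique(lab[lab > 0]))[2]
  cfg <- tinyConfig(noise_sd = 0, n_participants = 6,
                    group_effects = list(AD = list(labels = roi, delta_years = 5)),
                    group_probs = c(AD = 1))
  co <- generateCohort(cfg)
  truth <- co$truth
  for (i in seq_along(co$volumes)) {
    age <- co$records$age_years[i]
    expected_hc <- baseMap(truth) - betaMap(truth) * (age - 18)
    resid <- gmVolume(co$volumes[[i]]) + wmVolume(co$volumes[[i]]) - expected_hc
    resid[!brainMask(truth)] <- 0
    outside <- brainMask(truth) & lab != roi
    inside <- lab == roi & betaMap(truth) > 0
    expect_equal(max(abs(resid[outside])), 0)
    expect_true(all(resid[inside] <= 0))
    expect_lt(min(resid[inside]), 0)
  }
})

test_that("noise-free repeats are identical and between-scanner repeats degrade agreement", {
  cfg <- tinyConfig(noise_sd = 0.02, n_participants = 8)
  co <- generateCohort(cfg)
  mask <- brainMask(co$truth)
  reps0 <- generateRepeatScans(co, cfg, n_repeats = 2, within_noise_sd = 0,
                               between_scanner_shift = 0)
  expect_identical(gmVolume(reps0[[1]][[1]]), gmVolume(reps0[[2]][[1]]))
  # ICC on raw intensities: within-scanner (noise only) vs between-scanner
  repsW <- generateRepeatScans(co, cfg, n_repeats = 2, within_noise_sd = 0.02,
                               between_scanner_shift = 0, seed = 11)
  repsB <- generateRepeatScans(co, cfg, n_repeats = 2, within_noise_sd = 0.02,
                               between_scanner_shift = 0.2, seed = 11)
  totals <- function(rr) lapply(rr, function(vp) gmVolume(vp) + wmVolume(vp))
  iw <- iccMap(totals(repsW[[1]]), totals(repsW[[2]]), mask)
  ib <- iccMap(totals(repsB[[1]]), totals(repsB[[2]]), mask)
  expect_gt(median(iw, na.rm = TRUE), median(ib, na.rm = TRUE))
})

test_that("overwhelming within-scanner noise drives ICC toward zero", {
  cfg <- tinyConfig(noise_sd = 0.02, n_participants = 30, smoothing_fwhm = 0)
  co <- generateCohort(cfg)
  mask <- brainMask(co$truth)
  reps <- generateRepeatScans(co, cfg, n_repeats = 2, within_noise_sd = 5,
                              between_scanner_shift = 0, seed = 4)
  totals <- function(rr) lapply(rr, function(vp) gmVolume(vp) + wmVolume(vp))
  im <- iccMap(totals(reps[[1]]), totals(reps[[2]]), mask)
  # generating-model oracle: ICC ~ var_signal / (var_signal + var_noise);
  # per-voxel age signal sd <= beta_max * age sd << noise sd 5
  beta <- betaMap(co$truth)
  var_sig <- beta[mask]^2 * var(co$records$age_years)
  bound <- max(var_sig) / (max(var_sig) + 25)
  expect_lt(abs(median(im[mask], na.rm = TRUE)), bound + 0.1)
})

test_that("degenerate configurations are rejected", {
  expect_error(phantomConfig(grid_side = 16), "grid_side")
  expect_error(phantomConfig(age_range = c(10, 50)))
  expect_error(phantomConfig(noise_sd = -1))
  expect_error(phantomConfig(group_effects = list(AD = list(labels = 1, delta_years = 2)),
                             group_probs = c(HC = 1)), "probability")
})
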
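#' Voxelwise ICC map between two sets of repeated prediction maps
#'
#' Computes, at every in-mask voxel, the intraclass correlation across
#' participants between two repeated measurements (e.g. test/retest
#' predicted age), using ICC(2,1) (two-way random effects, absolute
#' agreement, single measure) vectorised over voxels.
#'
#' @param maps1,maps2 lists of 3D maps (same participants, same order).
#' @param mask 3D logical array.
#' @return 3D array of ICC values, NA outside the mask.
#' @export
iccMap <- function(maps1, maps2, mask) {
  stopifnot(length(maps1) == length(maps2), length(maps1) >= 2)
  idx <- which(mask)
  N <- length(maps1)
  X1 <- vapply(maps1, function(m) m[idx], numeric(length(idx)))
  X2 <- vapply(maps2, function(m) m[idx], numeric(length(idx)))
  grand <- (rowSums(X1) + rowSums(X2)) / (2 * N)
  rowm <- (X1 + X2) / 2
  colm1 <- rowMeans(X1); colm2 <- rowMeans(X2)
  MSR <- 2 * rowSums((rowm - grand)^2) / (N - 1)
  MSC <- N * ((colm1 - grand)^2 + (colm2 - grand)^2)
  E1 <- X1 - rowm - (colm1 - grand)
  E2 <- X2 - rowm - (colm2 - grand)
  MSE <- (rowSums(E1^2) + rowSums(E2^2)) / (N - 1)
  den <- MSR + MSE + (2 / N) * (MSC - MSE)
  val <- (MSR - MSE) / den
  val[den == 0] <- NA_real_
  out <- array(NA_real_, dim = dim(mask))
  out[idx] <- val
  out
}

#' Desk-scale pipeline configuration
#'
#' The packaged end-to-end study configuration: a 48^3 phantom cohort of 100
#' healthy participants for training (80/20 split), held-out healthy test,
#' calibration and clinical cohorts sharing the same generating fields, a
#' narrow network (base width 2; the layer structure, spatial contract and
#' receptive field are width-independent) trained for a few hundred
#' iterations with a learning rate scaled up to match the short schedule.
#'
#' @param seed master seed; every stage derives its RNG stream from it.
#' @return nested configuration list for \code{\link{runPipeline}}.
#' @export
deskConfig <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(seed = seed,
       phantom = list(grid_side = 48L, n_train_cohort = 100L,
                      noise_sd = 0.05, beta_max = 0.004,
                      control_fraction = 0.3, smoothing_fwhm = 2.7,
                      atlas_partitions = 3L),
       cohorts = list(n_test = 30L, n_calibration = 60L, n_clinical = 20L,
                      clinical_group = "AD", clinical_delta_years = 5,
                      clinical_age_range = c(60, 90), n_reliability = 6L,
                      between_scanner_shift = 0.03, match_age = 60),
       network = list(base_channels = 2L),
       train = list(learning_rate = 1e-3, max_iterations = 200L,
                    minibatch = 4L, grad_splits = 4L, eval_every = 50L))
}

subSeed <- function(seed, k) (as.integer(seed) %% 100000L) * 101L + k

pipelineLog <- function(con, stage, msg) {
  line <- jsonlite::toJSON(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                stage = stage, message = msg),
                           auto_unbox = TRUE)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Run the four-stage local brain-age study on synthetic data
#'
#' Executes the full study design end-to-end: (1) train the U-Net on a
#' healthy phantom cohort with an 80/20 participant split; (2) predict
#' whole-brain age maps for held-out healthy phantoms and compute global and
#' voxel-level MAE and age correlations; (3) estimate voxelwise test-retest
#' reliability (within- and between-scanner ICC) from repeated scans;
#' (4) de-bias voxelwise deltas with the per-voxel age-bin calibration and
#' compare an age-matched healthy subset against the clinical phantom group
#' at global, ROI and voxel scope (Welch's t, Bonferroni, Cohen's d).
#'
#' @param config configuration list (see \code{\link{deskConfig}}) or a path
#'   to a YAML file with the same structure.
#' @param out_dir output directory; subdirectories maps/, stats/,
#'   checkpoints/, logs/ are created. NULL skips all file output.
#' @param verbose print stage progress.
#' @return list with the trained network, histories, metrics, ICC and group
#'   comparison tables, truth fields and the manifest.
#' @export
runPipeline <- function(config = deskConfig(), out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed
  log_con <- NULL
  if (!is.null(out_dir)) {
    for (d in c("maps", "stats", "checkpoints", "logs"))
      dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "logs", "pipeline.jsonl"), "w")
    on.exit(close(log_con), add = TRUE)
  }
  manifest <- list(config = config, seed = seed,
                   version = as.character(utils::packageVersion("localbrainage")),
                   stages = list())
  stamp <- function(stage) manifest$stages[[stage]] <<-
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

  ph <- config$phantom; co <- config$cohorts
  baseCfg <- function(n, seed, age_range = c(18, 90), group_effects = list(),
                      group_probs = c(HC = 1))
    phantomConfig(grid_side = ph$grid_side, n_participants = n,
                  age_range = age_range, beta_max = ph$beta_max,
                  control_fraction = ph$control_fraction,
                  noise_sd = ph$noise_sd, smoothing_fwhm = ph$smoothing_fwhm,
                  atlas_partitions = ph$atlas_partitions,
                  group_effects = group_effects, group_probs = group_probs,
                  seed = seed)

  # ---- stage 1: simulate + train --------------------------------------
  pipelineLog(log_con, "simulate", "generating cohorts")
  train_cfgP <- baseCfg(ph$n_train_cohort, subSeed(seed, 1L))
  trainCohort <- generateCohort(train_cfgP)
  truth <- trainCohort$truth
  mask <- brainMask(truth)
  atlas <- phantomAtlas(truth)
  # clinical effect: the ROI with the strongest atrophy gradient
  roi_beta <- roiAggregate(ifelse(mask, betaMap(truth), NA), atlas)
  affected <- roi_beta$label[which.max(roi_beta$mean_value)]
  eff <- list()
  eff[[co$clinical_group]] <- list(labels = affected,
                                   delta_years = co$clinical_delta_years)
  testCohort <- generateCohort(baseCfg(co$n_test, subSeed(seed, 2L)))
  calibCohort <- generateCohort(baseCfg(co$n_calibration, subSeed(seed, 3L)))
  clinProbs <- c(1); names(clinProbs) <- co$clinical_group
  clinCohort <- generateCohort(baseCfg(co$n_clinical, subSeed(seed, 4L),
                                       age_range = co$clinical_age_range,
                                       group_effects = eff,
                                       group_probs = clinProbs))
  stamp("simulate")

  pipelineLog(log_con, "train", "training network")
  net <- buildNetwork(unetSpec(base_channels = config$network$base_channels),
                      seed = subSeed(seed, 5L))
  tc <- do.call(trainConfig, c(config$train, list(seed = subSeed(seed, 6L))))
  trained <- trainNetwork(net, trainCohort$volumes, trainCohort$records,
                          mask, tc, verbose = verbose)
  net <- trained$net
  stamp("train")

  # ---- stage 2: held-out accuracy -------------------------------------
  pipelineLog(log_con, "test", "predicting held-out maps")
  plan <- planBlocks(mask, net@spec$input_side, net@spec$output_side)
  predictAll <- function(cohort) lapply(cohort$volumes, predictMap,
                                        net = net, mask = mask,
                                        method = "whole")
  testMaps <- predictAll(testCohort)
  test_ages <- testCohort$records$age_years
  global_pred <- vapply(testMaps, globalPrediction, 0)
  global_mae <- mean(abs(global_pred - test_ages))
  global_r <- pearsonR(global_pred, test_ages)
  # per-voxel MAE across participants
  idx <- which(mask)
  P <- vapply(testMaps, function(m) m[idx], numeric(length(idx)))
  voxel_mae <- .rowMeans(abs(sweep(P, 2, test_ages)), length(idx),
                         length(test_ages))
  beta_in <- betaMap(truth)[idx]
  metrics <- list(global_mae = global_mae, global_r = global_r,
                  voxel_mae_mean = mean(voxel_mae),
                  voxel_mae_median = median(voxel_mae),
                  voxel_mae_signal = mean(voxel_mae[beta_in > 0]),
                  voxel_mae_control = mean(voxel_mae[beta_in == 0]))
  stamp("test")

  # ---- stage 3: reliability -------------------------------------------
  pipelineLog(log_con, "reliability", "repeat scans and ICC maps")
  relRecords <- testCohort$records[seq_len(co$n_reliability), , drop = FALSE]
  relCohort <- list(records = relRecords)
  relCfg <- baseCfg(co$n_reliability, subSeed(seed, 7L))
  reps_w <- generateRepeatScans(relCohort, relCfg, n_repeats = 2,
                                within_noise_sd = ph$noise_sd,
                                between_scanner_shift = 0,
                                seed = subSeed(seed, 8L))
  reps_b <- generateRepeatScans(relCohort, relCfg, n_repeats = 2,
                                within_noise_sd = ph$noise_sd,
                                between_scanner_shift = co$between_scanner_shift,
                                seed = subSeed(seed, 9L))
  mapsOf <- function(rr) lapply(rr, predictMap, net = net, mask = mask,
                                method = "whole")
  icc_within <- iccMap(mapsOf(reps_w[[1]]), mapsOf(reps_w[[2]]), mask)
  icc_between <- iccMap(mapsOf(reps_b[[1]]), mapsOf(reps_b[[2]]), mask)
  icc_summary <- data.frame(
    comparison = c("within_scanner", "between_scanner"),
    median_icc = c(median(icc_within[idx], na.rm = TRUE),
                   median(icc_between[idx], na.rm = TRUE)))
  stamp("reliability")

  # ---- stage 4: de-bias + group comparisons ---------------------------
  pipelineLog(log_con, "groups", "calibration and group comparisons")
  calibMaps <- predictAll(calibCohort)
  calib_ages <- calibCohort$records$age_years
  calibDeltas <- mapply(deltaMap, calibMaps, calib_ages, SIMPLIFY = FALSE)
  calibration <- fitVoxelBins(calibDeltas, calib_ages, mask)
  calib_global_delta <- vapply(calibMaps, globalPrediction, 0) - calib_ages
  globalFit <- fitGlobalLinear(calib_global_delta, calib_ages, "on_age")

  hcRecords <- ageMatchedSubset(testCohort$records, co$match_age)
  hcMaps <- testMaps[hcRecords$participant_id]
  clinMaps <- predictAll(clinCohort)
  adjDeltas <- function(maps, records) mapply(function(m, a)
    applyVoxelDebias(deltaMap(m, a), a, calibration),
    maps, records$age_years, SIMPLIFY = FALSE)
  hcAdj <- adjDeltas(hcMaps, hcRecords)
  clinAdj <- adjDeltas(clinMaps, clinCohort$records)
  groupLab <- co$clinical_group

  globalVals <- list(HC = vapply(hcAdj, function(m) mean(m, na.rm = TRUE), 0),
                     CL = vapply(clinAdj, function(m) mean(m, na.rm = TRUE), 0))
  names(globalVals)[2] <- groupLab
  cmp_global <- compareGroups(globalVals, scope = "global")

  voxelVals <- list(HC = as.numeric(vapply(hcAdj, function(m) m[idx],
                                           numeric(length(idx)))),
                    CL = as.numeric(vapply(clinAdj, function(m) m[idx],
                                           numeric(length(idx)))))
  names(voxelVals)[2] <- groupLab
  cmp_voxel <- compareGroups(voxelVals, scope = "voxel")

  roiVals <- function(adj, recs) {
    t(mapply(function(m, a) roiAggregate(m, atlas)$mean_value,
             adj, recs$age_years))
  }
  hcRoi <- roiVals(hcAdj, hcRecords)      # participants x ROI
  clRoi <- roiVals(clinAdj, clinCohort$records)
  roi_tab <- atlasNames(atlas)
  cmp_roi <- do.call(rbind, lapply(seq_len(nrow(roi_tab)), function(i) {
    v <- list(HC = hcRoi[, i], CL = clRoi[, i])
    names(v)[2] <- groupLab
    cbind(compareGroups(v, scope = "roi", n_comparisons = nrow(roi_tab)),
          label = roi_tab$label[i], name = roi_tab$name[i])
  }))
  stamp("groups")

  result <- list(config = config, manifest = manifest, net = net,
                 history = trained$history, split = trained$split,
                 truth = truth, plan = plan, metrics = metrics,
                 voxel_mae = voxel_mae, icc_summary = icc_summary,
                 icc_within = icc_within, icc_between = icc_between,
                 calibration = calibration, global_fit = globalFit,
                 affected_roi = affected,
                 comparisons = list(global = cmp_global, voxel = cmp_voxel,
                                    roi = cmp_roi),
                 test = list(records = testCohort$records,
                             global_pred = global_pred))

  if (!is.null(out_dir)) {
    aff <- trainCohort$volumes[[1]]@affine
    saveNetwork(net, file.path(out_dir, "checkpoints", "unet.rds"))
    write.csv(trained$history, file.path(out_dir, "stats", "loss_history.csv"),
              row.names = FALSE)
    write.csv(cmp_roi, file.path(out_dir, "stats", "roi_comparisons.csv"),
              row.names = FALSE)
    write.csv(rbind(cmp_global, cmp_voxel),
              file.path(out_dir, "stats", "group_comparisons.csv"),
              row.names = FALSE)
    write.csv(icc_summary, file.path(out_dir, "stats", "icc_summary.csv"),
              row.names = FALSE)
    write.csv(data.frame(metric = names(unlist(metrics)),
                         value = unlist(metrics)),
              file.path(out_dir, "stats", "test_metrics.csv"),
              row.names = FALSE)
    vm <- array(NA_real_, dim = dim(mask)); vm[idx] <- voxel_mae
    saveMap(vm, aff, file.path(out_dir, "maps", "voxel_mae.nii.gz"))
    saveMap(icc_within, aff, file.path(out_dir, "maps", "icc_within.nii.gz"))
    saveMap(icc_between, aff, file.path(out_dir, "maps", "icc_between.nii.gz"))
    for (id in names(testMaps))
      saveMap(testMaps[[id]], aff,
              file.path(out_dir, "maps", paste0(id, "_predage.nii.gz")))
    files <- list.files(file.path(out_dir, "maps"), full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    manifest$stages <- manifest$stages
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result
}
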
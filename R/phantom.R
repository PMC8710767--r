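#' Configuration for a synthetic phantom cohort
#'
#' Defines the generating model of a cohort of two-channel (GM/WM) brain
#' phantoms whose local intensity declines linearly with age at a spatially
#' varying rate. The brain mask is a superellipsoid; the white-matter channel
#' occupies its core and the grey-matter channel the surrounding shell (a
#' crude cortex/white-matter analogue with disjoint supports). The default
#' atrophy-rate field is a linear anterior-posterior gradient with a
#' zero-rate posterior control region, so age is locally decodable in some
#' regions and not in others.
#'
#' Intensity model for participant i at voxel v:
#' \deqn{I_i(v) = base(v) - beta(v) (age_i - 18) - beta(v) \delta_{g(i)}(v) + \epsilon_i(v)}
#' where \eqn{\delta_g} is the group-specific extra atrophy in years
#' equivalent (confined to configured ROI labels) and \eqn{\epsilon} is
#' Gaussian noise smoothed with the same kernel as the structural fields.
#' Smoothing (FWHM in voxels) is applied after noise; the stored truth fields
#' are the smoothed, masked fields so the model is exactly linear in age.
#'
#' @param grid_side voxels per axis (>= 32).
#' @param n_participants cohort size.
#' @param age_range two ages in years within [18, 90]; ages are drawn
#'   uniformly over this range.
#' @param beta_max maximum atrophy rate, intensity units per year.
#' @param control_fraction fraction of the mask extent along the gradient
#'   axis with zero atrophy rate (the control region).
#' @param noise_sd standard deviation of the pre-smoothing voxel noise.
#' @param smoothing_fwhm Gaussian smoothing FWHM in voxels (default 2.7,
#'   emulating a 4 mm kernel at 1.5 mm voxels).
#' @param group_effects named list mapping a group name to
#'   \code{list(labels = <ROI labels>, delta_years = <extra atrophy>)}.
#' @param group_probs named numeric vector of group assignment probabilities
#'   (must include all groups in \code{group_effects}; default all healthy).
#' @param voxel_size voxel edge length in mm for the written affine.
#' @param atlas_partitions blocks per axis of the ROI partition atlas.
#' @param seed integer RNG seed; a fixed seed reproduces the cohort exactly.
#' @return A \code{phantom_config} list.
#' @export
phantomConfig <- function(grid_side = 64, n_participants = 100,
                          age_range = c(18, 90), beta_max = 0.004,
                          control_fraction = 0.3, noise_sd = 0.05,
                          smoothing_fwhm = 2.7, group_effects = list(),
                          group_probs = c(HC = 1), voxel_size = 1.5,
                          atlas_partitions = 3L, seed = 1L) {
  stopifnot(grid_side >= 32, n_participants >= 1,
            length(age_range) == 2, age_range[1] >= 18, age_range[2] <= 90,
            age_range[1] <= age_range[2],
            noise_sd >= 0, beta_max >= 0, smoothing_fwhm >= 0)
  if (length(group_effects) && !all(names(group_effects) %in% names(group_probs)))
    stop("every group in group_effects needs a probability in group_probs")
  structure(list(grid_side = as.integer(grid_side),
                 n_participants = as.integer(n_participants),
                 age_range = age_range, beta_max = beta_max,
                 control_fraction = control_fraction, noise_sd = noise_sd,
                 smoothing_fwhm = smoothing_fwhm,
                 group_effects = group_effects,
                 group_probs = group_probs / sum(group_probs),
                 voxel_size = voxel_size,
                 atlas_partitions = as.integer(atlas_partitions),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

smooth3d <- function(x, fwhm) {
  if (fwhm <= 0) return(x)
  .gaussSmooth3d(x, fwhmToSigma(fwhm))
}

# Superellipsoid masks: |x/a|^4 + |y/b|^4 + |z/c|^4 <= 1.
phantomGeometry <- function(g) {
  ax <- 0.42 * g
  ctr <- (g + 1) / 2
  co <- (seq_len(g) - ctr)
  f <- function(scale) {
    r <- outer(outer(abs(co / (ax * scale))^4, abs(co / (ax * scale))^4, "+"),
               abs(co / (ax * scale))^4, "+")
    r <= 1
  }
  mask <- f(1)
  core <- f(0.55)
  list(mask = mask, core = core & mask, shell = mask & !f(0.55))
}

phantomFields <- function(config) {
  g <- config$grid_side
  geo <- phantomGeometry(g)
  mask <- geo$mask
  if (!any(mask)) stop("degenerate (empty) brain mask")
  # baseline intensity: GM shell 1.0, WM core 0.9 before smoothing
  base <- array(0, dim = c(g, g, g))
  base[geo$shell] <- 1.0
  base[geo$core] <- 0.9
  # atrophy rate: linear gradient along axis 2 (anterior-posterior), with a
  # posterior control region at rate 0
  ys <- which(apply(mask, 2, any))
  y0 <- min(ys); y1 <- max(ys)
  cut <- y0 + config$control_fraction * (y1 - y0)
  ramp <- pmax(0, (seq_len(g) - cut) / (y1 - cut))
  beta <- array(rep(rep(config$beta_max * ramp, each = g), g), dim = c(g, g, g))
  beta[!mask] <- 0
  sbase <- smooth3d(base, config$smoothing_fwhm)
  sbeta <- smooth3d(beta, config$smoothing_fwhm)
  sbase[!mask] <- 0
  sbeta[!mask] <- 0
  sbeta[sbeta < 0] <- 0
  # cap the rate so intensity stays positive over the full age span plus any
  # plausible group effect; keeps the generating model exactly linear in age
  sbeta <- array(pmin(sbeta, sbase / 100), dim = dim(sbase))
  list(mask = mask, core = geo$core, shell = geo$shell,
       base = sbase, beta = sbeta)
}

phantomBlockAtlas <- function(mask, partitions) {
  g <- dim(mask)[1]
  idx <- which(mask, arr.ind = TRUE)
  lab <- array(0L, dim = dim(mask))
  bin <- function(v, lo, hi) pmin(partitions, 1L + floor(partitions * (v - lo) / (hi - lo + 1e-9)))
  rng <- apply(idx, 2, range)
  b1 <- bin(idx[, 1], rng[1, 1], rng[2, 1])
  b2 <- bin(idx[, 2], rng[1, 2], rng[2, 2])
  b3 <- bin(idx[, 3], rng[1, 3], rng[2, 3])
  raw <- b1 + partitions * (b2 - 1L) + partitions^2 * (b3 - 1L)
  relab <- match(raw, sort(unique(raw)))
  lab[mask] <- relab
  roiAtlas(lab)
}

phantomGroupField <- function(config, truth_beta, atlas) {
  # group -> per-voxel intensity offset (years-equivalent extra atrophy)
  out <- list()
  for (gname in names(config$group_effects)) {
    eff <- config$group_effects[[gname]]
    roi <- atlasLabels(atlas) %in% eff$labels
    fld <- array(0, dim = dim(truth_beta))
    fld[roi] <- -truth_beta[roi] * eff$delta_years
    out[[gname]] <- fld
  }
  out
}

#' Generate a synthetic phantom cohort
#'
#' Draws ages uniformly over the configured range, assigns groups, and builds
#' each participant's two-channel volume from the generating model described
#' in \code{\link{phantomConfig}}. With \code{noise_sd = 0} the cohort is an
#' exact linear function of age, so per-voxel least squares recovers the
#' truth fields to numerical precision.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @return \code{list(volumes, records, truth)}: a list of
#'   \code{\link{VolumePair}} objects, a cohort data.frame
#'   (participant_id, age_years, site, group) and a
#'   \code{\link{PhantomTruth}}.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  fl <- phantomFields(config)
  atlas <- phantomBlockAtlas(fl$mask, config$atlas_partitions)
  gfields <- phantomGroupField(config, fl$beta, atlas)
  n <- config$n_participants
  ages <- runif(n, config$age_range[1], config$age_range[2])
  groups <- sample(names(config$group_probs), n, replace = TRUE,
                   prob = config$group_probs)
  records <- data.frame(participant_id = sprintf("sub-%04d", seq_len(n)),
                        age_years = ages, site = "sim", group = groups,
                        stringsAsFactors = FALSE)
  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- fl$base - fl$beta * (ages[i] - 18)
    if (!is.null(gfields[[groups[i]]])) vol <- vol + gfields[[groups[i]]]
    if (config$noise_sd > 0) {
      eps <- array(rnorm(length(vol), sd = config$noise_sd), dim = dim(vol))
      vol <- vol + smooth3d(eps, config$smoothing_fwhm)
    }
    vol[!fl$mask] <- 0
    vol[vol < 0] <- 0
    gm <- vol; gm[!fl$shell] <- 0
    wm <- vol; wm[!fl$core] <- 0
    volumes[[i]] <- volumePair(gm, wm, voxelSize = config$voxel_size)
  }
  names(volumes) <- records$participant_id
  truth <- new("PhantomTruth", betaMap = fl$beta, baseMap = fl$base,
               mask = fl$mask, atlas = atlas)
  list(volumes = volumes, records = records, truth = truth)
}

#' Generate repeated scans for reliability analyses
#'
#' Produces \code{n_repeats} scan sets for each participant of a cohort. All
#' repeats share the participant's age signal; repeats differ by fresh
#' within-scanner noise, and repeats beyond the first can additionally carry
#' a smooth multiplicative between-scanner field (a scanner/site effect)
#' scaled by \code{between_scanner_shift}.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param config the \code{\link{phantomConfig}} used to generate it.
#' @param n_repeats number of repeats (>= 2).
#' @param within_noise_sd pre-smoothing noise SD per repeat.
#' @param between_scanner_shift amplitude of the smooth site field applied to
#'   repeats 2..n (0 = same scanner).
#' @param seed RNG seed.
#' @return list (one element per repeat) of lists of \code{VolumePair}.
#' @export
generateRepeatScans <- function(cohort, config, n_repeats = 2,
                                within_noise_sd = config$noise_sd,
                                between_scanner_shift = 0, seed = config$seed + 1L) {
  stopifnot(n_repeats >= 2)
  set.seed(seed)
  fl <- phantomFields(config)
  gfields <- phantomGroupField(config, fl$beta,
                               phantomBlockAtlas(fl$mask, config$atlas_partitions))
  ages <- cohort$records$age_years
  groups <- cohort$records$group
  n <- length(ages)
  g <- config$grid_side
  # one smooth site field per repeat > 1 (scanner property, shared across
  # participants)
  site_fields <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    if (r == 1 || between_scanner_shift == 0) {
      site_fields[r] <- list(NULL)
    } else {
      raw <- array(rnorm(g^3), dim = c(g, g, g))
      sm <- smooth3d(raw, 4 * max(config$smoothing_fwhm, 1))
      sm <- sm / max(abs(sm[fl$mask]))
      site_fields[[r]] <- 1 + between_scanner_shift * sm
    }
  }
  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    reps <- vector("list", n)
    for (i in seq_len(n)) {
      vol <- fl$base - fl$beta * (ages[i] - 18)
      if (!is.null(gfields[[groups[i]]])) vol <- vol + gfields[[groups[i]]]
      if (within_noise_sd > 0) {
        eps <- array(rnorm(length(vol), sd = within_noise_sd), dim = dim(vol))
        vol <- vol + smooth3d(eps, config$smoothing_fwhm)
      }
      if (!is.null(site_fields[[r]])) vol <- vol * site_fields[[r]]
      vol[!fl$mask] <- 0
      vol[vol < 0] <- 0
      gm <- vol; gm[!fl$shell] <- 0
      wm <- vol; wm[!fl$core] <- 0
      reps[[i]] <- volumePair(gm, wm, voxelSize = config$voxel_size)
    }
    names(reps) <- cohort$records$participant_id
    out[[r]] <- reps
  }
  out
}

#' Write a phantom cohort to disk
#'
#' Writes per-participant GM/WM NIfTI volumes, the cohort CSV, the brain mask
#' and the integer ROI atlas into a directory.
#'
#' @param cohort result of \code{\link{generateCohort}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the cohort table augmented with file paths.
#' @export
writePhantomCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  aff <- cohort$volumes[[1]]@affine
  tab <- cohort$records
  tab$gm_path <- file.path(dir, paste0(tab$participant_id, "_gm.nii.gz"))
  tab$wm_path <- file.path(dir, paste0(tab$participant_id, "_wm.nii.gz"))
  for (i in seq_len(nrow(tab))) {
    saveMap(gmVolume(cohort$volumes[[i]]), aff, tab$gm_path[i])
    saveMap(wmVolume(cohort$volumes[[i]]), aff, tab$wm_path[i])
  }
  saveMap(brainMask(cohort$truth) * 1, aff, file.path(dir, "mask.nii.gz"))
  saveMap(atlasLabels(phantomAtlas(cohort$truth)) + 0, aff,
          file.path(dir, "atlas.nii.gz"))
  write.csv(cohort$records, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(tab)
}
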
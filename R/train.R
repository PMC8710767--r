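#' Split a cohort into training and validation participants
#'
#' Participant-level split (no participant appears on both sides),
#' deterministic for a fixed seed.
#'
#' @param records cohort data.frame with \code{participant_id}.
#' @param fraction training fraction (0 < fraction < 1).
#' @param seed integer seed.
#' @return list with \code{train} and \code{validation} id vectors.
#' @export
splitCohort <- function(records, fraction = 0.8, seed = 1L) {
  ids <- unique(records$participant_id)
  if (length(ids) < 2) stop("need at least 2 participants to split")
  n_train <- round(fraction * length(ids))
  if (n_train < 1 || n_train >= length(ids))
    stop("fraction ", fraction, " produces an empty split side")
  set.seed(seed)
  tr <- sort(sample(ids, n_train))
  list(train = tr, validation = sort(setdiff(ids, tr)))
}

#' Training configuration
#'
#' @param learning_rate Adam step size (the reference model used 1e-4 over
#'   5e5 iterations; short desk-scale runs use a proportionally larger
#'   rate).
#' @param max_iterations number of minibatch iterations.
#' @param minibatch samples per iteration (reference: 32).
#' @param grad_splits gradient-averaging splits per minibatch (reference: 4;
#'   the minibatch is processed as \code{grad_splits} accumulation
#'   micro-steps of \code{minibatch / grad_splits} samples).
#' @param split_fraction training fraction of the participant-level split.
#' @param loss a \code{\link{lossConfig}}.
#' @param eval_every validation-evaluation period in iterations (0 disables).
#' @param plateau_patience stop after this many consecutive evaluations
#'   without improvement beyond \code{plateau_tol} (Inf disables).
#' @param plateau_tol minimal improvement in validation voxel-MAE (years).
#' @param n_val_blocks validation blocks held fixed for evaluation.
#' @param init_output_bias initialise the output and auxiliary biases at the
#'   training-mean age before the first iteration (only meaningful without
#'   standardisation; with it, predictions already start at the mean age).
#' @param standardize input/target standardisation mode, stored in the
#'   network spec so it travels with the checkpoint. \code{"voxel"}
#'   (default): z-score every voxel against its mean/SD across the training
#'   cohort (a cohort template), removing the anatomical mean so the age
#'   signal is O(1) at the input; \code{"global"}: scalar channelwise
#'   z-scoring; \code{"none"}. Either mode predicts age through an affine
#'   head \code{age_mean + age_sd * raw}. Without standardisation a short
#'   training run spends its entire budget crawling from the fan-in-scaled
#'   initialisation toward the age scale, because the anatomy dwarfs the
#'   age contrast.
#' @param seed RNG seed for sampling and shuffling.
#' @return a \code{train_config} list.
#' @export
trainConfig <- function(learning_rate = 1e-4, max_iterations = 1000L,
                        minibatch = 32L, grad_splits = 4L,
                        split_fraction = 0.8, loss = lossConfig(),
                        eval_every = 0L, plateau_patience = Inf,
                        plateau_tol = 0.01, n_val_blocks = 16L,
                        init_output_bias = TRUE, standardize = "voxel",
                        seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1,
            minibatch %% grad_splits == 0, learning_rate > 0)
  if (is.logical(standardize)) standardize <- if (standardize) "global" else "none"
  standardize <- match.arg(standardize, c("voxel", "global", "none"))
  structure(list(learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 minibatch = as.integer(minibatch),
                 grad_splits = as.integer(grad_splits),
                 split_fraction = split_fraction, loss = loss,
                 eval_every = as.integer(eval_every),
                 plateau_patience = plateau_patience,
                 plateau_tol = plateau_tol,
                 n_val_blocks = as.integer(n_val_blocks),
                 init_output_bias = init_output_bias,
                 standardize = standardize,
                 seed = as.integer(seed)), class = "train_config")
}

# input/target standardisation constants from the training cohort
computeInputNorm <- function(train_volumes, train_ages, type) {
  if (type == "global") {
    gms <- unlist(lapply(train_volumes, gmVolume), use.names = FALSE)
    wms <- unlist(lapply(train_volumes, wmVolume), use.names = FALSE)
    norm <- list(type = "global",
                 in_mean = c(mean(gms), mean(wms)),
                 in_sd = c(max(sd(gms), 1e-8), max(sd(wms), 1e-8)))
  } else {
    n <- length(train_volumes)
    statMaps <- function(get) {
      s1 <- get(train_volumes[[1]]) * 0
      s2 <- s1
      for (v in train_volumes) {
        x <- get(v)
        s1 <- s1 + x
        s2 <- s2 + x^2
      }
      mu <- s1 / n
      sd <- sqrt(pmax(s2 / n - mu^2, 0) * n / (n - 1))
      dim(sd) <- dim(mu)
      # floor tiny SDs (flat voxels) so z-values stay bounded
      floor_sd <- 0.1 * stats::median(sd[sd > 0])
      list(mean = mu, sd = array(pmax(sd, floor_sd), dim = dim(mu)))
    }
    norm <- list(type = "voxel", gm = statMaps(gmVolume), wm = statMaps(wmVolume))
  }
  norm$age_mean <- mean(train_ages)
  norm$age_sd <- max(sd(train_ages), 1e-8)
  norm
}

# voxelwise z-scoring of one volume pair against the cohort template;
# returns plain arrays (z-maps are signed)
normalizeVolume <- function(vp, norm) {
  gm <- (gmVolume(vp) - norm$gm$mean) / norm$gm$sd
  wm <- (wmVolume(vp) - norm$wm$mean) / norm$wm$sd
  list(gm = array(gm, dim = dim(gm)), wm = array(wm, dim = dim(wm)))
}

# elementwise recursion over parallel nested parameter lists
mapParams <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- args[[1]]
    for (nm in names(args[[1]]))
      out[[nm]] <- do.call(mapParams, c(list(f), lapply(args, `[[`, nm)))
    out
  } else do.call(f, args)
}

zeroLike <- function(p) mapParams(function(x)
  if (is.null(dim(x))) numeric(length(x)) else array(0, dim = dim(x)), p)

adamInit <- function(params) list(m = zeroLike(params), v = zeroLike(params), t = 0L)

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- mapParams(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- mapParams(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- mapParams(function(p, m, v) {
    upd <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    dim(upd) <- dim(p)
    upd
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# assemble a batched input tensor from (participant, block-origin) draws
assembleBatch <- function(volumes, records, plan, pick) {
  s <- plan@inputSide
  n <- nrow(pick)
  x <- array(0, dim = c(2L, s, s, s, n))
  ages <- numeric(n)
  for (j in seq_len(n)) {
    vp <- volumes[[pick$participant[j]]]
    x[, , , , j] <- extractInputBlock(vp, plan, plan@origins[pick$block[j], ])
    ages[j] <- records$age_years[records$participant_id == pick$participant[j]]
  }
  list(x = x, ages = ages)
}

samplePicks <- function(ids, n_blocks, n) {
  data.frame(participant = sample(ids, n, replace = TRUE),
             block = sample.int(n_blocks, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Train the U-Net on a phantom or real cohort
#'
#' Minibatch Adam on the composite loss with the decaying auxiliary-weight
#' schedule. Each iteration draws blocks uniformly over the planned in-mask
#' blocks of uniformly drawn training participants, accumulates gradients
#' over \code{grad_splits} micro-steps, and takes one Adam step on the
#' averaged gradient. Validation voxel-MAE is evaluated on a fixed set of
#' validation blocks every \code{eval_every} iterations and training stops
#' early when it plateaus (no improvement beyond \code{plateau_tol} for
#' \code{plateau_patience} evaluations).
#'
#' @param net a \code{\link{UNet3D-class}}.
#' @param volumes named list of \code{\link{VolumePair}} (names = ids).
#' @param records cohort data.frame.
#' @param mask 3D logical array.
#' @param config a \code{\link{trainConfig}}.
#' @param split optional precomputed \code{\link{splitCohort}} result.
#' @param verbose print progress lines.
#' @return list: trained \code{net}, \code{history} data.frame (iteration,
#'   train_loss, alpha1, alpha2, val_mae), \code{split}.
#' @export
trainNetwork <- function(net, volumes, records, mask, config = trainConfig(),
                         split = NULL, verbose = FALSE) {
  stopifnot(length(volumes) >= 1)
  plan <- planBlocks(mask, net@spec$input_side, net@spec$output_side)
  if (is.null(split))
    split <- splitCohort(records, config$split_fraction, config$seed)
  set.seed(config$seed)
  params <- net@params
  train_ages <- records$age_years[records$participant_id %in% split$train]
  if (config$standardize != "none") {
    net@spec$norm <- computeInputNorm(volumes[split$train], train_ages,
                                      config$standardize)
  } else if (config$init_output_bias) {
    mean_age <- mean(train_ages)
    params$out$b[] <- mean_age
    params$aux1$b[] <- mean_age
    params$aux2$b[] <- mean_age
  }
  if (!is.null(net@spec$norm) && net@spec$norm$type == "voxel")
    volumes <- lapply(volumes, normalizeVolume, norm = net@spec$norm)
  opt <- adamInit(params)
  n_blocks <- nrow(plan@origins)
  val_batch <- NULL
  if (config$eval_every > 0 && length(split$validation) > 0) {
    vp_ids <- samplePicks(split$validation, n_blocks, config$n_val_blocks)
    val_batch <- assembleBatch(volumes, records, plan, vp_ids)
  }
  per_split <- config$minibatch %/% config$grad_splits
  hist <- data.frame(iteration = integer(), train_loss = numeric(),
                     alpha1 = numeric(), alpha2 = numeric(),
                     val_mae = numeric())
  best_val <- Inf; stale <- 0L
  tmp_net <- net
  for (it in seq_len(config$max_iterations)) {
    grads <- NULL
    loss_it <- 0
    for (sp in seq_len(config$grad_splits)) {
      pick <- samplePicks(split$train, n_blocks, per_split)
      batch <- assembleBatch(volumes, records, plan, pick)
      tmp_net@params <- params
      fw <- forwardNetwork(tmp_net, batch$x, cache = TRUE)
      loss <- compositeLoss(fw[c("voxel", "aux")], batch$ages, config$loss,
                            it - 1L)
      if (!is.finite(loss))
        stop("non-finite loss at iteration ", it, "; aborting")
      lg <- compositeLossGrad(fw[c("voxel", "aux")], batch$ages, config$loss,
                              it - 1L)
      g <- backwardNetwork(tmp_net, fw$cache, lg$dvox, lg$daux)
      grads <- if (is.null(grads)) g else mapParams(`+`, grads, g)
      loss_it <- loss_it + loss
    }
    grads <- mapParams(function(g) g / config$grad_splits, grads)
    stepped <- adamStep(params, grads, opt, config$learning_rate)
    params <- stepped$params; opt <- stepped$state
    alpha <- alphaSchedule(it - 1L, config$loss)
    val_mae <- NA_real_
    if (!is.null(val_batch) && it %% config$eval_every == 0) {
      tmp_net@params <- params
      fwv <- forwardNetwork(tmp_net, val_batch$x, cache = FALSE)
      S3 <- prod(dim(fwv$voxel)[1:3])
      vv <- fwv$voxel; dim(vv) <- c(S3, length(val_batch$ages))
      val_mae <- mean(abs(sweep(vv, 2, val_batch$ages)))
      if (val_mae < best_val - config$plateau_tol) {
        best_val <- val_mae; stale <- 0L
      } else stale <- stale + 1L
    }
    hist <- rbind(hist, data.frame(iteration = it,
                                   train_loss = loss_it / config$minibatch,
                                   alpha1 = alpha[1], alpha2 = alpha[2],
                                   val_mae = val_mae))
    if (verbose && it %% 10 == 0)
      message(sprintf("iter %d  loss/sample %.3f  val %.3f", it,
                      loss_it / config$minibatch, val_mae))
    if (is.finite(config$plateau_patience) && stale >= config$plateau_patience) {
      if (verbose) message("validation plateau reached at iteration ", it)
      break
    }
  }
  net@params <- params
  list(net = net, history = hist, split = split)
}

#' Predict a whole-brain voxelwise age map
#'
#' Plans blocks over the mask (or reuses a plan), extracts every input
#' window, runs the network and stitches the 12^3 predictions back into a
#' whole-brain map. Overlapping predictions are averaged; out-of-mask voxels
#' carry the NA sentinel. The result does not depend on the order in which
#' blocks are evaluated.
#'
#' @param net a trained \code{\link{UNet3D-class}}.
#' @param vp a \code{\link{VolumePair}}.
#' @param mask 3D logical array.
#' @param plan optional precomputed \code{\link{BlockPlan-class}}.
#' @param batch_size forward-pass batch size.
#' @param method \code{"blocks"} runs the planned overlapping windows and
#'   stitches them (the reference procedure); \code{"whole"} exploits the
#'   fully convolutional architecture to predict the entire volume in one
#'   forward pass over the margin-padded volume — an order of magnitude
#'   faster and identical up to the pooling-phase alignment of individual
#'   blocks.
#' @return 3D array of predicted age (years), NA outside the mask.
#' @export
predictMap <- function(net, vp, mask, plan = NULL, batch_size = 8L,
                       method = c("blocks", "whole")) {
  method <- match.arg(method)
  if (method == "whole") return(predictMapWhole(net, vp, mask))
  if (is.null(plan))
    plan <- planBlocks(mask, net@spec$input_side, net@spec$output_side)
  if (!identical(as.integer(dim(gmVolume(vp))), plan@volumeDim))
    stop("geometry mismatch between volume and plan")
  norm <- net@spec$norm
  if (!is.null(norm) && norm$type == "voxel")
    vp <- normalizeVolume(vp, norm)
  n <- nrow(plan@origins)
  s <- plan@inputSide
  so <- plan@outputSide
  preds <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    x <- array(0, dim = c(2L, s, s, s, j - i + 1L))
    for (q in i:j)
      x[, , , , q - i + 1L] <- extractInputBlock(vp, plan, plan@origins[q, ])
    fw <- forwardNetwork(net, x, cache = FALSE)
    for (q in i:j)
      preds[[q]] <- array(fw$voxel[, , , q - i + 1L], dim = rep(so, 3))
    i <- j + 1L
  }
  stitchBlocks(preds, plan, mask)
}

# one-shot fully convolutional whole-volume prediction: pad the volume by
# the network margin (20) up to a pooling-compatible input side, forward
# once, crop the output back onto the volume grid
predictMapWhole <- function(net, vp, mask) {
  sp <- net@spec
  if (!is.null(sp$norm) && sp$norm$type == "voxel")
    vp <- normalizeVolume(vp, sp$norm)
  margin <- (sp$input_side - sp$output_side) %/% 2L
  G <- dim(if (is(vp, "VolumePair")) gmVolume(vp) else vp$gm)
  if (length(unique(G)) != 1L)
    stop("whole-volume prediction expects a cubic grid")
  g <- G[1]
  S <- g + 2L * margin
  repeat {
    ok <- !inherits(try(unetSides(sp, S), silent = TRUE), "try-error")
    if (ok) break
    S <- S + 1L
  }
  x <- array(0, dim = c(2L, S, S, S, 1L))
  idx <- (margin + 1):(margin + g)
  x[1, idx, idx, idx, 1] <- if (is(vp, "VolumePair")) gmVolume(vp) else vp$gm
  x[2, idx, idx, idx, 1] <- if (is(vp, "VolumePair")) wmVolume(vp) else vp$wm
  fw <- forwardNetwork(net, x, cache = FALSE)
  outside <- dim(fw$voxel)[1]
  out <- array(fw$voxel[seq_len(g), seq_len(g), seq_len(g), 1], dim = G)
  stopifnot(outside >= g)
  out[!mask] <- NA_real_
  out
}

#' Global brain-age from a prediction map
#'
#' The participant's global brain-predicted age: the mean over in-mask
#' voxels of the voxelwise map.
#' @param map prediction map (NA outside mask).
#' @return scalar predicted age in years.
#' @export
globalPrediction <- function(map) mean(map, na.rm = TRUE)
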
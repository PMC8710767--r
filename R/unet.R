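#' Architecture specification for the local brain-age U-Net
#'
#' Describes the 3-scale regression U-Net: two valid (unpadded) 3^3
#' convolutions per scale with channel doubling down the encoder, 2^3
#' average pooling, 2x nearest ("repeat") upsampling, leaky rectifier
#' activations (slope 0.2), a squeeze-and-excite channel gate at each
#' convolution, and two auxiliary block-level age heads (global average
#' pooling followed by one dense layer) at the two coarser scales. The
#' spatial contract 52^3 -> 12^3 holds by construction for any weights.
#'
#' @param in_channels input channels (2: GM and WM).
#' @param base_channels channels at the first scale (64 in the reference
#'   architecture; smaller widths keep the layer structure and spatial
#'   contract intact).
#' @param scales number of resolution scales (fixed at 3).
#' @param conv_kernel convolution kernel side (fixed at 3).
#' @param convs_per_scale convolutions per scale (2 in the built network;
#'   other values are allowed for receptive-field studies only).
#' @param input_side,output_side spatial contract (52 -> 12).
#' @param leaky_slope negative-side slope of the leaky rectifier.
#' @param se_reduction squeeze-and-excite bottleneck reduction ratio
#'   (hidden width = max(1, floor(channels / se_reduction))).
#' @param aux_heads number of auxiliary scalar age heads (2).
#' @return an \code{unet_spec} list.
#' @export
unetSpec <- function(in_channels = 2L, base_channels = 64L, scales = 3L,
                     conv_kernel = 3L, convs_per_scale = 2L,
                     input_side = 52L, output_side = 12L,
                     leaky_slope = 0.2, se_reduction = 16L, aux_heads = 2L) {
  spec <- list(in_channels = as.integer(in_channels),
               base_channels = as.integer(base_channels),
               scales = as.integer(scales),
               conv_kernel = as.integer(conv_kernel),
               convs_per_scale = as.integer(convs_per_scale),
               input_side = as.integer(input_side),
               output_side = as.integer(output_side),
               leaky_slope = leaky_slope,
               se_reduction = as.integer(se_reduction),
               aux_heads = as.integer(aux_heads))
  class(spec) <- "unet_spec"
  if (spec$scales != 3L || spec$conv_kernel != 3L || spec$aux_heads != 2L)
    stop("the built architecture has 3 scales, 3^3 kernels and 2 aux heads")
  if (spec$base_channels < 1L || spec$se_reduction < 1L)
    stop("base_channels and se_reduction must be positive")
  sides <- unetSides(spec)
  if (sides$out != spec$output_side)
    stop("spec violates the ", spec$input_side, " -> ", spec$output_side,
         " spatial contract (would produce ", sides$out, ")")
  spec
}

# spatial sizes along the network for a given input side; errors if pooling
# meets an odd size
unetSides <- function(spec, input_side = spec$input_side) {
  k <- spec$convs_per_scale
  s1 <- input_side - 2L * k
  if (s1 %% 2L) stop("odd size ", s1, " at first pooling")
  s2 <- s1 %/% 2L - 2L * k
  if (s2 %% 2L) stop("odd size ", s2, " at second pooling")
  s3 <- s2 %/% 2L - 2L * k
  d2 <- 2L * s3 - 2L * k
  d1 <- 2L * d2 - 2L * k
  list(e1 = s1, e2 = s2, bott = s3, d2 = d2, out = d1)
}

seHidden <- function(C, r) max(1L, C %/% r)

initArray <- function(dims, sd) array(rnorm(prod(dims), sd = sd), dim = dims)

seInit <- function(C, r) {
  h <- seHidden(C, r)
  list(w1 = initArray(c(h, C), sqrt(2 / C)), b1 = numeric(h),
       w2 = initArray(c(C, h), sqrt(2 / h)),
       # gate starts near 1 (sigmoid(2) ~ 0.88) so stacked blocks do not
       # attenuate the forward signal at initialisation
       b2 = rep(2, C))
}

convInit <- function(Cout, Cin, k, r) {
  list(w = initArray(c(Cout, Cin, k, k, k), sqrt(2 / (Cin * k^3))),
       b = numeric(Cout), se = seInit(Cout, r))
}

#' Build a local brain-age U-Net
#'
#' Instantiates the network of \code{\link{unetSpec}} with variance-scaled
#' (fan-in) Gaussian weight initialisation under a fixed seed.
#'
#' @param spec an \code{\link{unetSpec}}.
#' @param seed integer seed for the weight initialisation.
#' @return a \code{\link{UNet3D-class}} object.
#' @export
buildNetwork <- function(spec = unetSpec(), seed = 1L) {
  if (spec$convs_per_scale != 2L)
    stop("the built network uses 2 convolutions per scale")
  set.seed(seed)
  b <- spec$base_channels; r <- spec$se_reduction; k <- spec$conv_kernel
  params <- list(
    c1 = convInit(b, spec$in_channels, k, r),
    c2 = convInit(b, b, k, r),
    c3 = convInit(2L * b, b, k, r),
    c4 = convInit(2L * b, 2L * b, k, r),
    c5 = convInit(4L * b, 2L * b, k, r),
    c6 = convInit(4L * b, 4L * b, k, r),
    c7 = convInit(2L * b, 6L * b, k, r),
    c8 = convInit(2L * b, 2L * b, k, r),
    c9 = convInit(b, 3L * b, k, r),
    c10 = convInit(b, b, k, r),
    out = list(w = initArray(c(1L, b, 1L, 1L, 1L), sqrt(1 / b)),
               b = numeric(1)),
    aux1 = list(w = initArray(c(4L * b), sqrt(1 / (4 * b))), b = numeric(1)),
    aux2 = list(w = initArray(c(2L * b), sqrt(1 / (2 * b))), b = numeric(1)))
  new("UNet3D", spec = structure(spec, class = NULL), params = params)
}

lrelu <- function(x, a) {
  y <- x
  neg <- x < 0
  y[neg] <- a * x[neg]
  y
}

lreluGrad <- function(z, a) {
  g <- array(1, dim = dim(z))
  g[z < 0] <- a
  g
}

seForward <- function(a, p) {
  d <- dim(a); C <- d[1]; S3 <- prod(d[2:4]); N <- d[5]
  A <- a; dim(A) <- c(C, S3, N)
  m <- matrix(0, C, N)
  for (n in seq_len(N)) m[, n] <- .rowMeans(A[, , n], C, S3)
  z1 <- p$w1 %*% m + p$b1
  h1 <- pmax(z1, 0)
  z2 <- p$w2 %*% h1 + p$b2
  g <- 1 / (1 + exp(-z2))
  out <- A
  for (n in seq_len(N)) out[, , n] <- A[, , n] * g[, n]
  dim(out) <- d
  list(out = out, m = m, z1 = z1, h1 = h1, g = g)
}

seBackward <- function(dout, a, cache, p) {
  d <- dim(a); C <- d[1]; S3 <- prod(d[2:4]); N <- d[5]
  A <- a; dim(A) <- c(C, S3, N)
  DO <- dout; dim(DO) <- c(C, S3, N)
  g <- cache$g
  da <- DO
  dg <- matrix(0, C, N)
  for (n in seq_len(N)) {
    dg[, n] <- .rowSums(DO[, , n] * A[, , n], C, S3)
    da[, , n] <- DO[, , n] * g[, n]
  }
  dz2 <- dg * g * (1 - g)
  dw2 <- dz2 %*% t(cache$h1)
  db2 <- .rowSums(dz2, nrow(dz2), ncol(dz2))
  dh1 <- crossprod(p$w2, dz2)
  dz1 <- dh1 * (cache$z1 > 0)
  dw1 <- dz1 %*% t(cache$m)
  db1 <- .rowSums(dz1, nrow(dz1), ncol(dz1))
  dm <- crossprod(p$w1, dz1)
  for (n in seq_len(N)) da[, , n] <- da[, , n] + dm[, n] / S3
  dim(da) <- d
  list(da = da, grads = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2))
}

convBlockForward <- function(x, p, slope) {
  z <- .conv3dForward(x, p$w, p$b)
  act <- lrelu(z, slope)
  se <- seForward(act, p$se)
  list(out = se$out, x = x, z = z, act = act, se = se)
}

convBlockBackward <- function(dout, cache, p, slope) {
  sb <- seBackward(dout, cache$act, cache$se, p$se)
  dz <- sb$da * lreluGrad(cache$z, slope)
  cb <- .conv3dBackward(cache$x, p$w, dz)
  list(dx = cb$dx, grads = list(w = cb$dw, b = cb$db, se = sb$grads))
}

gapDenseForward <- function(a, p) {
  d <- dim(a); C <- d[1]; S3 <- prod(d[2:4]); N <- d[5]
  A <- a; dim(A) <- c(C, S3, N)
  m <- matrix(0, C, N)
  for (n in seq_len(N)) m[, n] <- .rowMeans(A[, , n], C, S3)
  list(pred = as.numeric(crossprod(m, p$w)) + p$b, m = m)
}

gapDenseBackward <- function(dpred, a, cache, p) {
  d <- dim(a); C <- d[1]; S3 <- prod(d[2:4]); N <- d[5]
  dw <- as.numeric(cache$m %*% dpred)
  db <- sum(dpred)
  da <- array(0, dim = d)
  dim(da) <- c(C, S3, N)
  for (n in seq_len(N)) da[, , n] <- (p$w * dpred[n]) / S3
  dim(da) <- d
  list(da = da, grads = list(w = dw, b = db))
}

cropCenter <- function(x, side) {
  cur <- dim(x)[2]
  off <- (cur - side) %/% 2L
  x[, (off + 1):(off + side), (off + 1):(off + side),
    (off + 1):(off + side), , drop = FALSE]
}

padCenterAdd <- function(acc, d, side) {
  cur <- dim(acc)[2]
  off <- (cur - side) %/% 2L
  idx <- (off + 1):(off + side)
  acc[, idx, idx, idx, ] <- acc[, idx, idx, idx, , drop = FALSE] + d
  acc
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2:5]))
  out[seq_len(da[1]), , , , ] <- a
  out[da[1] + seq_len(db[1]), , , , ] <- b
  out
}

#' Forward pass of the U-Net
#'
#' Maps a batched two-channel input tensor to voxel-level age predictions
#' and the two auxiliary block-level age predictions.
#'
#' @param net a \code{\link{UNet3D-class}}.
#' @param x numeric array of dim (2, s, s, s, N) with s the spec input side.
#' @param cache keep intermediate activations for a backward pass.
#' @return list: \code{voxel} (array s_out x s_out x s_out x N),
#'   \code{aux} (matrix 2 x N), and \code{cache} when requested.
#' @export
forwardNetwork <- function(net, x, cache = FALSE) {
  sp <- net@spec; p <- net@params; sl <- sp$leaky_slope
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x), 1L)
  stopifnot(dim(x)[1] == sp$in_channels)
  norm <- sp$norm
  if (!is.null(norm) && identical(norm$type, "global"))
    for (ch in seq_len(sp$in_channels))  # scalar channelwise z-scoring
      x[ch, , , , ] <- (x[ch, , , , ] - norm$in_mean[ch]) / norm$in_sd[ch]
  # voxelwise ("template") normalisation is applied at the volume level by
  # trainNetwork/predictMap before blocks are cut; only the output affine
  # applies here
  sides <- unetSides(sp, dim(x)[2])
  f1 <- convBlockForward(x, p$c1, sl)
  f2 <- convBlockForward(f1$out, p$c2, sl)      # skip1
  p1 <- .avgPool2Forward(f2$out)
  f3 <- convBlockForward(p1, p$c3, sl)
  f4 <- convBlockForward(f3$out, p$c4, sl)      # skip2
  p2 <- .avgPool2Forward(f4$out)
  f5 <- convBlockForward(p2, p$c5, sl)
  f6 <- convBlockForward(f5$out, p$c6, sl)      # bottleneck
  aux1 <- gapDenseForward(f6$out, p$aux1)
  u2 <- .upsample2Forward(f6$out)
  cat2 <- catChannels(u2, cropCenter(f4$out, dim(u2)[2]))
  f7 <- convBlockForward(cat2, p$c7, sl)
  f8 <- convBlockForward(f7$out, p$c8, sl)
  aux2 <- gapDenseForward(f8$out, p$aux2)
  u1 <- .upsample2Forward(f8$out)
  cat1 <- catChannels(u1, cropCenter(f2$out, dim(u1)[2]))
  f9 <- convBlockForward(cat1, p$c9, sl)
  f10 <- convBlockForward(f9$out, p$c10, sl)
  vox <- .conv3dForward(f10$out, p$out$w, p$out$b)
  dv <- dim(vox)
  voxOut <- vox
  dim(voxOut) <- dv[2:5]
  auxOut <- rbind(aux1$pred, aux2$pred)
  if (!is.null(norm)) {   # map standardised predictions back to years
    voxOut <- norm$age_mean + norm$age_sd * voxOut
    auxOut <- norm$age_mean + norm$age_sd * auxOut
  }
  res <- list(voxel = voxOut, aux = auxOut)
  if (cache)
    res$cache <- list(x = x, f1 = f1, f2 = f2, p1 = p1, f3 = f3, f4 = f4,
                      p2 = p2, f5 = f5, f6 = f6, aux1 = aux1, u2 = u2,
                      cat2 = cat2, f7 = f7, f8 = f8, aux2 = aux2, u1 = u1,
                      cat1 = cat1, f9 = f9, f10 = f10, vox = vox,
                      sides = sides)
  res
}

#' Backward pass of the U-Net
#'
#' Backpropagates gradients of a scalar loss with respect to the voxel
#' predictions and the two auxiliary predictions, returning parameter
#' gradients in the same nested shape as \code{networkParams}.
#'
#' @param net a \code{\link{UNet3D-class}}.
#' @param cache forward cache from \code{forwardNetwork(..., cache = TRUE)}.
#' @param dvox gradient w.r.t. voxel output (s_out^3 x N array).
#' @param daux gradient w.r.t. auxiliary outputs (2 x N matrix).
#' @return nested gradient list.
#' @export
backwardNetwork <- function(net, cache, dvox, daux) {
  sp <- net@spec; p <- net@params; sl <- sp$leaky_slope
  if (!is.null(sp$norm)) { # chain rule through the output affine (years)
    dvox <- dvox * sp$norm$age_sd
    daux <- daux * sp$norm$age_sd
  }
  dv <- dvox
  dim(dv) <- dim(cache$vox)
  g <- list()
  cb <- .conv3dBackward(cache$f10$out, p$out$w, dv)
  g$out <- list(w = cb$dw, b = cb$db)
  b10 <- convBlockBackward(cb$dx, cache$f10, p$c10, sl); g$c10 <- b10$grads
  b9 <- convBlockBackward(b10$dx, cache$f9, p$c9, sl); g$c9 <- b9$grads
  C8 <- dim(cache$f8$out)[1]
  du1 <- b9$dx[seq_len(C8), , , , , drop = FALSE]
  dskip1 <- b9$dx[(C8 + 1):dim(b9$dx)[1], , , , , drop = FALSE]
  dd8 <- .upsample2Backward(du1)
  a2 <- gapDenseBackward(daux[2, ], cache$f8$out, cache$aux2, p$aux2)
  g$aux2 <- a2$grads
  b8 <- convBlockBackward(dd8 + a2$da, cache$f8, p$c8, sl); g$c8 <- b8$grads
  b7 <- convBlockBackward(b8$dx, cache$f7, p$c7, sl); g$c7 <- b7$grads
  C6 <- dim(cache$f6$out)[1]
  du2 <- b7$dx[seq_len(C6), , , , , drop = FALSE]
  dskip2 <- b7$dx[(C6 + 1):dim(b7$dx)[1], , , , , drop = FALSE]
  dd6 <- .upsample2Backward(du2)
  a1 <- gapDenseBackward(daux[1, ], cache$f6$out, cache$aux1, p$aux1)
  g$aux1 <- a1$grads
  b6 <- convBlockBackward(dd6 + a1$da, cache$f6, p$c6, sl); g$c6 <- b6$grads
  b5 <- convBlockBackward(b6$dx, cache$f5, p$c5, sl); g$c5 <- b5$grads
  dd4 <- .avgPool2Backward(b5$dx)
  dd4 <- padCenterAdd(dd4, dskip2, dim(dskip2)[2])
  b4 <- convBlockBackward(dd4, cache$f4, p$c4, sl); g$c4 <- b4$grads
  b3 <- convBlockBackward(b4$dx, cache$f3, p$c3, sl); g$c3 <- b3$grads
  dd2 <- .avgPool2Backward(b3$dx)
  dd2 <- padCenterAdd(dd2, dskip1, dim(dskip1)[2])
  b2 <- convBlockBackward(dd2, cache$f2, p$c2, sl); g$c2 <- b2$grads
  b1 <- convBlockBackward(b2$dx, cache$f1, p$c1, sl); g$c1 <- b1$grads
  g[names(net@params)]
}

#' Loss configuration (voxel MAE plus decaying auxiliary terms)
#'
#' The training loss sums, over the minibatch, the absolute voxel-level
#' errors over the output block plus alpha-weighted absolute errors of the
#' two auxiliary block-level predictions. The auxiliary weights start at
#' \code{alpha_init} and decay linearly to zero at \code{decay_iterations},
#' after which gradients flow exclusively from the voxel-level predictions.
#'
#' @param alpha_init initial auxiliary weights (length 2, >= 0).
#' @param decay_iterations iteration at which the auxiliary weights reach 0.
#' @return a \code{loss_config} list.
#' @export
lossConfig <- function(alpha_init = c(1, 1), decay_iterations = 50000L) {
  stopifnot(length(alpha_init) == 2, all(alpha_init >= 0),
            decay_iterations > 0)
  structure(list(alpha_init = alpha_init,
                 decay_iterations = as.integer(decay_iterations)),
            class = "loss_config")
}

#' Auxiliary-weight schedule
#' @param iteration 0-based training iteration.
#' @param config a \code{\link{lossConfig}}.
#' @return numeric length-2 vector of alpha values.
#' @export
alphaSchedule <- function(iteration, config = lossConfig()) {
  config$alpha_init * max(0, 1 - iteration / config$decay_iterations)
}

#' Composite training loss
#'
#' @param predictions list with \code{voxel} (s^3 x N array) and \code{aux}
#'   (2 x N matrix), as returned by \code{\link{forwardNetwork}}.
#' @param target_age numeric vector of chronological ages (length N).
#' @param config a \code{\link{lossConfig}}.
#' @param iteration 0-based iteration, sets the auxiliary weights.
#' @return scalar loss (sum over the minibatch).
#' @export
compositeLoss <- function(predictions, target_age, config = lossConfig(),
                          iteration = 0L) {
  alpha <- alphaSchedule(iteration, config)
  if (any(alpha < 0)) stop("negative auxiliary weight")
  v <- predictions$voxel
  nd <- length(dim(v))
  N <- if (is.null(dim(v))) 1L else dim(v)[nd]
  stopifnot(length(target_age) == N)
  S3 <- length(v) / N
  dim(v) <- c(S3, N)
  yv <- matrix(target_age, S3, N, byrow = TRUE)
  loss <- sum(abs(v - yv))
  aux <- predictions$aux
  for (b in 1:2)
    loss <- loss + alpha[b] * sum(abs(target_age - aux[b, ]))
  loss
}

# gradient of compositeLoss w.r.t. voxel and aux predictions
compositeLossGrad <- function(predictions, target_age, config, iteration) {
  alpha <- alphaSchedule(iteration, config)
  v <- predictions$voxel
  nd <- dim(v)
  N <- nd[length(nd)]
  S3 <- length(v) / N
  dim(v) <- c(S3, N)
  yv <- matrix(target_age, S3, N, byrow = TRUE)
  dvox <- sign(v - yv)
  daux <- rbind(alpha[1] * sign(predictions$aux[1, ] - target_age),
                alpha[2] * sign(predictions$aux[2, ] - target_age))
  list(dvox = dvox, daux = daux)
}

# ordered layer sequence along the encoder-decoder path
unetLayerSequence <- function(spec) {
  k <- spec$convs_per_scale
  c(rep("conv3", k), "pool", rep("conv3", k), "pool", rep("conv3", k),
    "up", rep("conv3", k), "up", rep("conv3", k), "conv1")
}

# empirical one-output-voxel sensitivity support (side length, per axis) of a
# single layer, via finite perturbation with non-negative weights
layerSupportSide <- function(type, weight = NULL) {
  if (type == "conv3" || type == "conv1") {
    k <- if (type == "conv3") 3L else 1L
    if (is.null(weight)) weight <- array(1, dim = c(1, 1, k, k, k))
    w <- abs(weight) + 0.01           # non-negative, sensitivity-preserving
    Cin <- dim(w)[2]
    side <- k + 2L
    x0 <- array(1, dim = c(Cin, side, side, side, 1L))
    base <- .conv3dForward(x0, w, numeric(dim(w)[1]))
    ctr <- (dim(base)[2] + 1L) %/% 2L
    ref <- sum(base[, ctr, ctr, ctr, 1])
    hit <- array(FALSE, dim = c(side, side, side))
    for (i in seq_len(side)) for (j in seq_len(side)) for (l in seq_len(side)) {
      x1 <- x0
      x1[, i, j, l, ] <- x1[, i, j, l, ] + 1
      y <- .conv3dForward(x1, w, numeric(dim(w)[1]))
      hit[i, j, l] <- abs(sum(y[, ctr, ctr, ctr, 1]) - ref) > 1e-12
    }
  } else if (type == "pool") {
    side <- 4L
    x0 <- array(1, dim = c(1L, side, side, side, 1L))
    base <- .avgPool2Forward(x0)
    hit <- array(FALSE, dim = c(side, side, side))
    for (i in seq_len(side)) for (j in seq_len(side)) for (l in seq_len(side)) {
      x1 <- x0; x1[, i, j, l, ] <- 2
      y <- .avgPool2Forward(x1)
      hit[i, j, l] <- abs(y[1, 1, 1, 1, 1] - base[1, 1, 1, 1, 1]) > 1e-12
    }
  } else if (type == "up") {
    side <- 2L
    x0 <- array(1, dim = c(1L, side, side, side, 1L))
    base <- .upsample2Forward(x0)
    ctr <- 2L
    hit <- array(FALSE, dim = c(side, side, side))
    for (i in seq_len(side)) for (j in seq_len(side)) for (l in seq_len(side)) {
      x1 <- x0; x1[, i, j, l, ] <- 2
      y <- .upsample2Forward(x1)
      hit[i, j, l] <- abs(y[1, ctr, ctr, ctr, 1] - base[1, ctr, ctr, ctr, 1]) > 1e-12
    }
  } else stop("unknown layer type ", type)
  ax <- which(hit, arr.ind = TRUE)
  vapply(1:3, function(a) diff(range(ax[, a])) + 1L, 0L)
}

#' Measure the network's effective receptive field
#'
#' Empirical field-of-view accounting of the voxel-level predictions: for
#' each layer along the encoder-decoder path, the sensitivity support of one
#' output voxel with respect to that layer's input is measured by finite
#' perturbation (convolution weights replaced by their absolute values plus
#' a positive offset so no cancellation can hide influence; squeeze-and-
#' excite gates are channel reweightings, not spatial mixings, and are held
#' fixed), on the layer's own grid. The per-layer support growths compose
#' additively across the path: a 3^3 convolution contributes +2 per axis, a
#' 2^3 average pooling +1, repeat-upsampling 0. The full architecture yields
#' a side of 23 voxels, the effective local resolution of the predictions.
#'
#' Note this composes fields on each layer's native grid (equivalent to
#' unit-stride accounting of the pooling); the bounding box of input voxels
#' with any nonzero end-to-end influence is wider, because downsampling
#' dilates deeper layers' fields in input coordinates.
#'
#' @param net a \code{\link{UNet3D-class}} or an \code{\link{unetSpec}}.
#' @param upto optional number of leading layers to include (e.g. 1 for the
#'   first convolution alone, which gives 3).
#' @return integer side length in voxels.
#' @export
measureReceptiveField <- function(net, upto = NULL) {
  if (is(net, "UNet3D")) {
    spec <- net@spec
    convW <- lapply(net@params[c("c1", "c2", "c3", "c4", "c5", "c6", "c7",
                                 "c8", "c9", "c10")], `[[`, "w")
    outW <- net@params$out$w
  } else {
    spec <- net
    convW <- NULL
    outW <- NULL
  }
  layers <- unetLayerSequence(spec)
  if (!is.null(upto)) layers <- layers[seq_len(upto)]
  growth <- c(0L, 0L, 0L)
  ci <- 0L
  for (ty in layers) {
    w <- NULL
    if (ty == "conv3" && !is.null(convW)) { ci <- ci + 1L; w <- convW[[ci]] }
    if (ty == "conv1" && !is.null(outW)) w <- outW
    supp <- layerSupportSide(ty, w)
    growth <- growth + (supp - 1L)
  }
  side <- growth + 1L
  if (length(unique(side)) != 1L)
    stop("anisotropic receptive field measured: ", paste(side, collapse = "x"))
  as.integer(side[1])
}

#' Save / load a network checkpoint
#'
#' Single-file checkpoint with the architecture spec embedded.
#' @param net a \code{\link{UNet3D-class}}.
#' @param path file path.
#' @return \code{loadNetwork} returns the \code{UNet3D}.
#' @export
saveNetwork <- function(net, path) {
  saveRDS(list(spec = net@spec, params = net@params), path)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  x <- readRDS(path)
  new("UNet3D", spec = x$spec, params = x$params)
}
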
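#' @useDynLib localbrainage, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif sd var pt lm coef cor qnorm quantile median
#' @importFrom utils read.csv write.csv head
NULL

#' VolumePair: co-registered grey- and white-matter volume maps
#'
#' Container for one participant's two-channel tissue-volume image: a
#' grey-matter (GM) and a white-matter (WM) 3D map sharing the same grid and
#' voxel-to-world affine, as produced by a VBM-style segmentation and spatial
#' normalisation pipeline (or by the synthetic phantom generator).
#'
#' @slot gm 3D numeric array of grey-matter tissue volume (arbitrary
#'   modulated-density units, non-negative).
#' @slot wm 3D numeric array of white-matter tissue volume, same shape as
#'   \code{gm}.
#' @slot affine 4x4 voxel-to-world transform (mm); voxel indices are 0-based
#'   when mapped through the affine.
#' @slot voxelSize scalar voxel edge length in mm (isotropic).
#'
#' @export
setClass("VolumePair",
  representation(gm = "array", wm = "array", affine = "matrix",
                 voxelSize = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@gm), dim(object@wm)))
      return("gm and wm must have identical dimensions")
    if (length(dim(object@gm)) != 3L) return("gm must be a 3D array")
    if (!all(is.finite(object@gm)) || !all(is.finite(object@wm)))
      return("tissue maps must be finite")
    if (min(object@gm) < 0 || min(object@wm) < 0)
      return("tissue maps must be non-negative")
    if (!identical(dim(object@affine), c(4L, 4L)))
      return("affine must be 4x4")
    if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
      return("voxelSize must be a positive scalar")
    TRUE
  })

#' Construct a VolumePair
#'
#' @param gm,wm 3D numeric arrays of identical shape.
#' @param voxelSize voxel edge length in mm (default 1.5, the resolution of
#'   the normalisation pipeline the model assumes).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   affine with spacing \code{voxelSize} centred at the origin.
#' @return A \code{VolumePair}.
#' @export
volumePair <- function(gm, wm, voxelSize = 1.5, affine = NULL) {
  if (is.null(affine)) {
    affine <- diag(c(rep(voxelSize, 3), 1))
    affine[1:3, 4] <- -voxelSize * (dim(gm) - 1) / 2
  }
  new("VolumePair", gm = gm, wm = wm, affine = affine, voxelSize = voxelSize)
}

setMethod("show", "VolumePair", function(object) {
  d <- dim(object@gm)
  cat(sprintf("VolumePair: %d x %d x %d voxels @ %.2f mm\n",
              d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  GM volume sum %.1f, WM volume sum %.1f\n",
              sum(object@gm), sum(object@wm)))
})

#' @describeIn VolumePair-class grey-matter array accessor
#' @param x a \code{VolumePair}
#' @export
gmVolume <- function(x) x@gm

#' @describeIn VolumePair-class white-matter array accessor
#' @export
wmVolume <- function(x) x@wm

#' @describeIn VolumePair-class voxel-to-world affine accessor
#' @export
volumeAffine <- function(x) x@affine

#' RoiAtlas: integer-labelled region-of-interest parcellation
#'
#' @slot labels 3D integer array; 0 is background, positive integers are ROI
#'   labels.
#' @slot names data.frame with columns \code{label} and \code{name} mapping
#'   every named label to a region name.
#' @export
setClass("RoiAtlas",
  representation(labels = "array", names = "data.frame"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
    if (!all(c("label", "name") %in% colnames(object@names)))
      return("names must have columns label, name")
    present <- unique(as.integer(object@labels))
    if (!all(object@names$label %in% present))
      return("every named label must occur in the label map")
    if (any(object@names$label == 0L)) return("label 0 is reserved for background")
    TRUE
  })

#' Construct an RoiAtlas
#' @param labels 3D integer array (0 = background).
#' @param names optional data.frame(label, name); defaults to "roi_<k>" names
#'   for every positive label present.
#' @return An \code{RoiAtlas}.
#' @export
roiAtlas <- function(labels, names = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(names)) {
    labs <- sort(setdiff(unique(as.integer(labels)), 0L))
    names <- data.frame(label = labs, name = sprintf("roi_%02d", labs))
  }
  new("RoiAtlas", labels = labels, names = names)
}

setMethod("show", "RoiAtlas", function(object) {
  cat(sprintf("RoiAtlas: %s voxels, %d regions\n",
              paste(dim(object@labels), collapse = " x "),
              nrow(object@names)))
})

#' @describeIn RoiAtlas-class label array accessor
#' @param x an \code{RoiAtlas}
#' @export
atlasLabels <- function(x) x@labels

#' @describeIn RoiAtlas-class label/name table accessor
#' @export
atlasNames <- function(x) x@names

#' PhantomTruth: generating model of a synthetic cohort
#'
#' Ground truth for a phantom cohort: the per-voxel baseline intensity at age
#' 18, the per-voxel atrophy rate (intensity units per year), the brain mask
#' and the block-partition ROI atlas. The stored fields are the effective
#' (smoothed, masked) fields, so that at zero noise an ordinary least-squares
#' regression of intensity on age recovers them exactly.
#'
#' @slot betaMap 3D array, atrophy rate per year; >= 0 inside the mask,
#'   0 outside.
#' @slot baseMap 3D array, age-18 intensity.
#' @slot mask 3D logical array.
#' @slot atlas \code{RoiAtlas} whose labels cover exactly the mask.
#' @export
setClass("PhantomTruth",
  representation(betaMap = "array", baseMap = "array", mask = "array",
                 atlas = "RoiAtlas"),
  validity = function(object) {
    m <- object@mask
    if (!is.logical(m)) return("mask must be logical")
    if (any(object@betaMap[!m] != 0)) return("betaMap must be 0 outside mask")
    if (any(object@betaMap[m] < 0)) return("betaMap must be >= 0 inside mask")
    lab <- atlasLabels(object@atlas)
    if (!all((lab > 0L) == m)) return("atlas labels must cover exactly the mask")
    TRUE
  })

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %s grid, %d mask voxels, %d ROIs\n",
              paste(dim(object@mask), collapse = " x "), sum(object@mask),
              nrow(atlasNames(object@atlas))))
  cat(sprintf("  atrophy rate range %.4g..%.4g /year (in-mask)\n",
              min(object@betaMap[object@mask]), max(object@betaMap[object@mask])))
})

#' @describeIn PhantomTruth-class per-voxel atrophy-rate accessor
#' @param x a \code{PhantomTruth}
#' @export
betaMap <- function(x) x@betaMap

#' @describeIn PhantomTruth-class baseline (age-18) intensity accessor
#' @export
baseMap <- function(x) x@baseMap

#' @describeIn PhantomTruth-class brain-mask accessor
#' @export
brainMask <- function(x) x@mask

#' @describeIn PhantomTruth-class ROI atlas accessor
#' @export
phantomAtlas <- function(x) x@atlas

#' BlockPlan: tiling of a mask into output blocks
#'
#' Plan of overlapping input windows and their output regions: output origins
#' lie on a stride-\code{outputSide} lattice anchored at the mask bounding
#' box, clipped at the far volume edge (clipped blocks overlap their
#' neighbour and overlapping predictions are averaged at stitch time). Blocks
#' whose output region contains no in-mask voxel are dropped.
#'
#' @slot origins integer matrix (n x 3) of 0-based output-region origins.
#' @slot inputSide,outputSide input window and output region side lengths.
#' @slot volumeDim dimensions of the planned volume.
#' @export
setClass("BlockPlan",
  representation(origins = "matrix", inputSide = "integer",
                 outputSide = "integer", volumeDim = "integer"),
  validity = function(object) {
    if (ncol(object@origins) != 3L) return("origins must be n x 3")
    if ((object@inputSide - object@outputSide) %% 2L != 0L)
      return("input/output sides must differ by an even margin")
    if (object@inputSide <= object@outputSide)
      return("inputSide must exceed outputSide")
    TRUE
  })

setMethod("show", "BlockPlan", function(object) {
  cat(sprintf("BlockPlan: %d blocks (%d^3 in -> %d^3 out) over %s volume\n",
              nrow(object@origins), object@inputSide, object@outputSide,
              paste(object@volumeDim, collapse = " x ")))
})

#' @describeIn BlockPlan-class 0-based output-origin matrix accessor
#' @param x a \code{BlockPlan}
#' @export
blockOrigins <- function(x) x@origins

#' UNet3D: the voxel-level brain-age regression network
#'
#' A 3-scale encoder--decoder convolutional network mapping a two-channel
#' 52^3 tissue block to a 12^3 block of voxelwise predicted ages plus two
#' scalar auxiliary (block-level) age predictions. All convolutions are
#' valid (unpadded) 3^3 kernels with stride 1; downsampling is 2^3 average
#' pooling; upsampling repeats values 2x per axis; each convolution is
#' followed by a leaky rectifier (slope 0.2) and a squeeze-and-excite
#' channel gate.
#'
#' @slot spec architecture specification list (see \code{\link{unetSpec}}).
#' @slot params named list of weight arrays.
#' @export
setClass("UNet3D", representation(spec = "list", params = "list"))

setMethod("show", "UNet3D", function(object) {
  s <- object@spec
  np <- sum(vapply(object@params, length, 0L))
  cat(sprintf("UNet3D: base channels %d, %d scales, %s parameters\n",
              s$base_channels, s$scales, format(np, big.mark = ",")))
  cat(sprintf("  input %d^3 x %d channels -> %d^3 voxel ages + %d auxiliary ages\n",
              s$input_side, s$in_channels, s$output_side, s$aux_heads))
})

#' @describeIn UNet3D-class architecture specification accessor
#' @param x a \code{UNet3D}
#' @export
networkSpec <- function(x) x@spec

#' @describeIn UNet3D-class parameter-list accessor
#' @export
networkParams <- function(x) x@params

#' BinCalibration: per-voxel, per-age-bin mean brain-age delta
#'
#' Calibration object for the voxel-level bias adjustment: healthy
#' calibration participants are binned by chronological age ([18,25) then
#' 5-year bins, last bin closed) and the mean voxelwise brain-age delta of
#' each occupied bin is stored; de-biasing subtracts the bin mean.
#'
#' @slot edges numeric vector of bin edges (length nbins + 1).
#' @slot deltas matrix (in-mask voxels x occupied bins) of mean deltas.
#' @slot counts integer vector of calibration participants per bin.
#' @slot maskIdx integer vector of in-mask linear voxel indices.
#' @slot volumeDim dimensions of the calibrated volume.
#' @export
setClass("BinCalibration",
  representation(edges = "numeric", deltas = "matrix", counts = "integer",
                 maskIdx = "integer", volumeDim = "integer"),
  validity = function(object) {
    if (ncol(object@deltas) != length(object@counts))
      return("one count per stored bin")
    if (any(object@counts < 1L)) return("stored bins must have counts >= 1")
    if (nrow(object@deltas) != length(object@maskIdx))
      return("deltas rows must match mask voxels")
    TRUE
  })

setMethod("show", "BinCalibration", function(object) {
  cat(sprintf("BinCalibration: %d occupied age bins over [%g, %g], %d voxels\n",
              ncol(object@deltas), min(object@edges), max(object@edges),
              nrow(object@deltas)))
  cat("  participants per bin:", paste(object@counts, collapse = " "), "\n")
})

#' @describeIn BinCalibration-class bin-edge accessor
#' @param x a \code{BinCalibration}
#' @export
binEdges <- function(x) x@edges

#' @describeIn BinCalibration-class per-bin participant counts
#' @export
binCounts <- function(x) x@counts

#' GlobalBiasFit: straight-line fit of brain-age delta on a covariate
#'
#' The conventional global bias adjustment: delta = slope * covariate +
#' intercept fitted by least squares, where the covariate is chronological
#' age or predicted age.
#'
#' @slot slope,intercept fitted coefficients.
#' @slot mode \code{"on_age"} or \code{"on_predicted"}.
#' @export
setClass("GlobalBiasFit",
  representation(slope = "numeric", intercept = "numeric", mode = "character"),
  validity = function(object) {
    if (!object@mode %in% c("on_age", "on_predicted"))
      return("mode must be on_age or on_predicted")
    if (!is.finite(object@slope) || !is.finite(object@intercept))
      return("coefficients must be finite")
    TRUE
  })

setMethod("show", "GlobalBiasFit", function(object) {
  cat(sprintf("GlobalBiasFit (%s): delta = %.4f * covariate + %.4f\n",
              object@mode, object@slope, object@intercept))
})
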
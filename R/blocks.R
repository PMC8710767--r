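#' Plan overlapping input blocks over a brain mask
#'
#' Tiles the mask with \code{outputSide}^3 output regions whose origins lie
#' on a stride-\code{outputSide} lattice anchored at the mask bounding box.
#' A lattice origin overshooting the far volume edge is clipped back to the
#' edge (its region then overlaps its neighbour; overlaps are averaged at
#' stitch time). Each output region sits at the centre of an
#' \code{inputSide}^3 input window (margin \code{(inputSide-outputSide)/2}
#' per side); windows may extend past the volume and are zero-padded at
#' extraction. Blocks whose output region contains no in-mask voxel are
#' dropped: they carry no discriminative tissue.
#'
#' @param mask 3D logical array.
#' @param inputSide input window side (default 52).
#' @param outputSide output region side (default 12).
#' @return A \code{\link{BlockPlan-class}} object.
#' @export
planBlocks <- function(mask, inputSide = 52L, outputSide = 12L) {
  stopifnot(length(dim(mask)) == 3L)
  inputSide <- as.integer(inputSide); outputSide <- as.integer(outputSide)
  if (inputSide <= outputSide || (inputSide - outputSide) %% 2L != 0L)
    stop("inputSide must exceed outputSide by an even margin")
  if (!any(mask)) stop("degenerate (empty) mask")
  dm <- dim(mask)
  if (any(dm < outputSide))
    stop("mask volume smaller than one output block; not addressable")
  axisOrigins <- function(ax) {
    r <- range(which(apply(mask, ax, any))) - 1L  # 0-based bbox
    o <- seq(r[1], r[2], by = outputSide)
    o <- pmin(o, dm[ax] - outputSide)  # clip at far edge (overlap allowed)
    o <- pmax(o, 0L)
    sort(unique(o))
  }
  o1 <- axisOrigins(1); o2 <- axisOrigins(2); o3 <- axisOrigins(3)
  grid <- as.matrix(expand.grid(o1, o2, o3))
  colnames(grid) <- NULL
  keep <- vapply(seq_len(nrow(grid)), function(i) {
    o <- grid[i, ]
    any(mask[(o[1] + 1):(o[1] + outputSide),
             (o[2] + 1):(o[2] + outputSide),
             (o[3] + 1):(o[3] + outputSide)])
  }, logical(1))
  new("BlockPlan", origins = grid[keep, , drop = FALSE],
      inputSide = inputSide, outputSide = outputSide,
      volumeDim = as.integer(dm))
}

#' Per-voxel cover count of a block plan
#'
#' Number of planned output regions covering each voxel. Every in-mask voxel
#' of a valid plan is covered at least once.
#'
#' @param plan a \code{\link{BlockPlan-class}}.
#' @return 3D integer array of cover counts.
#' @export
blockCoverCount <- function(plan) {
  cnt <- array(0L, dim = plan@volumeDim)
  s <- plan@outputSide
  for (i in seq_len(nrow(plan@origins))) {
    o <- plan@origins[i, ]
    cnt[(o[1] + 1):(o[1] + s), (o[2] + 1):(o[2] + s), (o[3] + 1):(o[3] + s)] <-
      cnt[(o[1] + 1):(o[1] + s), (o[2] + 1):(o[2] + s), (o[3] + 1):(o[3] + s)] + 1L
  }
  cnt
}

# Zero-padded extraction of one input window (0-based origin of the OUTPUT
# region); returns (2, inputSide^3) array. Accepts a VolumePair or a plain
# list(gm, wm) of arrays (e.g. normalised volumes).
extractInputBlock <- function(vp, plan, origin) {
  gm <- if (is(vp, "VolumePair")) gmVolume(vp) else vp$gm
  wm <- if (is(vp, "VolumePair")) wmVolume(vp) else vp$wm
  s <- plan@inputSide
  margin <- (plan@inputSide - plan@outputSide) %/% 2L
  io <- origin - margin                      # 0-based input origin
  dm <- dim(gm)
  block <- array(0, dim = c(2L, s, s, s))
  lo <- pmax(io, 0L)                         # 0-based clamp
  hi <- pmin(io + s, dm)                     # exclusive
  if (any(hi <= lo)) return(block)
  src <- lapply(1:3, function(a) (lo[a] + 1):(hi[a]))
  dst <- lapply(1:3, function(a) (lo[a] - io[a] + 1):(hi[a] - io[a]))
  block[1, dst[[1]], dst[[2]], dst[[3]]] <- gm[src[[1]], src[[2]], src[[3]]]
  block[2, dst[[1]], dst[[2]], dst[[3]]] <- wm[src[[1]], src[[2]], src[[3]]]
  block
}

#' Extract block samples from a volume pair
#'
#' Cuts every planned input window (zero-padded where it extends past the
#' volume) and pairs it with its constant target: a block filled with the
#' participant's chronological age, the voxel-level ground-truth objective.
#'
#' @param vp a \code{\link{VolumePair}}.
#' @param plan a \code{\link{BlockPlan-class}}.
#' @param record one-row data.frame with \code{participant_id} and
#'   \code{age_years} (omit for prediction-only extraction).
#' @return list of samples: \code{input} (2 x s^3 array),
#'   \code{target_age}, \code{origin} (0-based), \code{participant_id}.
#' @export
extractBlocks <- function(vp, plan, record = NULL) {
  lapply(seq_len(nrow(plan@origins)), function(i) {
    o <- plan@origins[i, ]
    list(input = extractInputBlock(vp, plan, o),
         target_age = if (is.null(record)) NA_real_ else record$age_years,
         origin = o,
         participant_id = if (is.null(record)) NA_character_ else
           record$participant_id)
  })
}

#' Stitch predicted blocks into a whole-brain map
#'
#' Reassembles per-block 12^3 predictions into a volume: each voxel takes the
#' mean over all output regions covering it (overlap arises only at
#' lattice-clipping boundaries); voxels outside the mask are set to the NA
#' sentinel (never 0, since 0 is a legal value).
#'
#' @param blocks list of numeric arrays of side \code{plan@outputSide}, one
#'   per plan origin, in plan order.
#' @param plan a \code{\link{BlockPlan-class}}.
#' @param mask 3D logical array.
#' @return 3D numeric array; NA outside the mask.
#' @export
stitchBlocks <- function(blocks, plan, mask) {
  if (length(blocks) != nrow(plan@origins))
    stop("need one predicted block per plan origin (got ", length(blocks),
         ", plan has ", nrow(plan@origins), ")")
  s <- plan@outputSide
  acc <- array(0, dim = plan@volumeDim)
  cnt <- array(0L, dim = plan@volumeDim)
  for (i in seq_len(nrow(plan@origins))) {
    o <- plan@origins[i, ]
    b <- blocks[[i]]
    if (!identical(as.integer(dim(b)), rep(s, 3L)))
      stop("block ", i, " has wrong dimensions")
    ix <- (o[1] + 1):(o[1] + s); iy <- (o[2] + 1):(o[2] + s)
    iz <- (o[3] + 1):(o[3] + s)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + b
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
  }
  out <- array(NA_real_, dim = plan@volumeDim)
  covered <- cnt > 0L
  out[covered] <- acc[covered] / cnt[covered]
  out[!mask] <- NA_real_
  out
}

#' Serialize a block plan to JSON
#' @param plan a \code{\link{BlockPlan-class}}.
#' @param path optional file to write.
#' @return JSON string (invisibly if written to file).
#' @export
blockPlanToJson <- function(plan, path = NULL) {
  js <- jsonlite::toJSON(list(origins = plan@origins,
                              input_side = plan@inputSide,
                              output_side = plan@outputSide,
                              volume_dim = plan@volumeDim), auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Deserialize a block plan from JSON
#' @param json JSON string or file path.
#' @return A \code{\link{BlockPlan-class}}.
#' @export
blockPlanFromJson <- function(json) {
  x <- jsonlite::fromJSON(json)
  new("BlockPlan", origins = matrix(as.integer(x$origins), ncol = 3),
      inputSide = as.integer(x$input_side),
      outputSide = as.integer(x$output_side),
      volumeDim = as.integer(x$volume_dim))
}
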
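#' Brain-age delta map
#'
#' Voxelwise brain-predicted age difference: predicted minus chronological
#' age. NA outside the mask is preserved.
#' @param prediction_map 3D predicted-age array (NA outside mask).
#' @param age_years chronological age.
#' @return 3D delta array (years).
#' @export
deltaMap <- function(prediction_map, age_years) prediction_map - age_years

# default age-bin edges: [18,25) then 5-year bins, last bin closed at the
# calibration maximum
defaultBinEdges <- function(max_age = 90) {
  e <- c(18, seq(25, max_age, by = 5))
  if (e[length(e)] < max_age) e <- c(e, max_age)
  e
}

binIndex <- function(age, edges, clamp = TRUE) {
  if (clamp) age <- pmin(pmax(age, edges[1]), edges[length(edges)])
  i <- findInterval(age, edges, rightmost.closed = TRUE)
  if (any(i < 1 | i >= length(edges)))
    stop("age ", paste(age[i < 1 | i >= length(edges)], collapse = ", "),
         " outside the calibration range and clamping disabled")
  i
}

#' Fit the per-voxel, per-age-bin delta calibration
#'
#' Bins the calibration participants by chronological age ([18,25) then
#' 5-year intervals; the final bin is closed at the calibration maximum) and
#' stores the mean voxelwise brain-age delta of each occupied bin. The
#' calibration participants must be disjoint from the training, validation
#' and test sets.
#'
#' @param delta_maps list of 3D delta arrays (NA outside mask).
#' @param ages chronological ages, one per map.
#' @param mask 3D logical array.
#' @param edges optional bin edges (defaults to [18,25) + 5-year bins up to
#'   \code{max(ages)} rounded into the standard grid).
#' @return A \code{\link{BinCalibration-class}}.
#' @export
fitVoxelBins <- function(delta_maps, ages, mask, edges = NULL) {
  if (length(delta_maps) == 0) stop("empty calibration set")
  stopifnot(length(delta_maps) == length(ages))
  if (is.null(edges)) edges <- defaultBinEdges(max(90, max(ages)))
  idx <- which(mask)
  M <- vapply(delta_maps, function(m) m[idx], numeric(length(idx)))
  bins <- binIndex(ages, edges, clamp = TRUE)
  occupied <- sort(unique(bins))
  deltas <- vapply(occupied, function(b)
    .rowMeans(M[, bins == b, drop = FALSE], length(idx), sum(bins == b)),
    numeric(length(idx)))
  counts <- vapply(occupied, function(b) sum(bins == b), 0L)
  colnames(deltas) <- as.character(occupied)
  new("BinCalibration", edges = edges, deltas = deltas, counts = counts,
      maskIdx = as.integer(idx), volumeDim = as.integer(dim(mask)))
}

#' Apply the voxel-level de-bias
#'
#' Subtracts the calibration bin's per-voxel mean delta from a participant's
#' delta map. Ages outside the calibrated range are clamped to the nearest
#' bin (refusing would break clinical cohorts older than the healthy
#' calibration range); with \code{clamp = FALSE} an agE outside the range or
#' in an unoccupied bin is an error.
#'
#' @param delta_map 3D delta array.
#' @param age chronological age of the participant.
#' @param calibration a \code{\link{BinCalibration-class}}.
#' @param clamp clamp out-of-range ages / unoccupied bins to the nearest
#'   occupied bin.
#' @return adjusted 3D delta array.
#' @export
applyVoxelDebias <- function(delta_map, age, calibration, clamp = TRUE) {
  b <- binIndex(age, calibration@edges, clamp = clamp)
  occ <- as.integer(colnames(calibration@deltas))
  if (!b %in% occ) {
    if (!clamp) stop("age ", age, " falls in an uncalibrated bin")
    b <- occ[which.min(abs(occ - b))]
  }
  out <- delta_map
  out[calibration@maskIdx] <- delta_map[calibration@maskIdx] -
    calibration@deltas[, as.character(b)]
  out
}

#' Fit the global linear bias model
#'
#' Least-squares straight line of global brain-age delta on chronological
#' age (\code{mode = "on_age"}) or on predicted age
#' (\code{mode = "on_predicted"}); the adjustment subtracts the fitted line.
#'
#' @param deltas global brain-age deltas (years).
#' @param covariate chronological or predicted ages (same length).
#' @param mode \code{"on_age"} or \code{"on_predicted"}.
#' @return A \code{\link{GlobalBiasFit-class}}.
#' @export
fitGlobalLinear <- function(deltas, covariate, mode = c("on_age", "on_predicted")) {
  mode <- match.arg(mode)
  stopifnot(length(deltas) == length(covariate))
  if (length(deltas) < 3) stop("need at least 3 points")
  if (var(covariate) == 0) stop("zero-variance covariate")
  fit <- lm(deltas ~ covariate)
  new("GlobalBiasFit", slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), mode = mode)
}

#' Apply the global linear de-bias
#'
#' @param deltas deltas to adjust (scalar per participant, or a voxelwise
#'   map).
#' @param covariate covariate value(s) matching the fit's mode.
#' @param fit a \code{\link{GlobalBiasFit-class}}.
#' @return adjusted deltas: \code{deltas - (slope * covariate + intercept)}.
#' @export
applyGlobalDebias <- function(deltas, covariate, fit) {
  deltas - (fit@slope * covariate + fit@intercept)
}
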
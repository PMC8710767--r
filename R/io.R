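#' Save a 3D map as NIfTI
#'
#' Writes a 3D array with its voxel-to-world affine to a NIfTI-1 file
#' (.nii or .nii.gz). NaN/NA values (the out-of-mask sentinel used by
#' prediction and delta maps) are preserved through the float round-trip.
#'
#' @param map3d 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (diagonal scales supported).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
saveMap <- function(map3d, affine, path) {
  stopifnot(length(dim(map3d)) == 3L, identical(dim(affine), c(4L, 4L)))
  img <- RNifti::asNifti(map3d, pixdim = abs(diag(affine)[1:3]))
  # sform only: a quaternion form quantises the scales on round-trip
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D map from NIfTI
#'
#' @param path NIfTI file path.
#' @return list with \code{data} (3D array) and \code{affine} (4x4 matrix).
#' @export
readMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  data <- array(as.numeric(img), dim = dim(img))
  list(data = data, affine = aff)
}

#' Read a GM/WM pair of NIfTI volumes
#'
#' @param gm_path,wm_path paths to the grey- and white-matter maps.
#' @return A \code{\link{VolumePair}}; errors if shapes or affines disagree.
#' @export
readVolumePair <- function(gm_path, wm_path) {
  g <- readMap(gm_path)
  w <- readMap(wm_path)
  if (!identical(dim(g$data), dim(w$data)))
    stop("geometry error: GM/WM shape mismatch for ", gm_path)
  if (max(abs(g$affine - w$affine)) > 1e-4)
    stop("geometry error: GM/WM affine mismatch for ", gm_path)
  volumePair(g$data, w$data, voxelSize = abs(g$affine[1, 1]), affine = g$affine)
}

#' Load a cohort of volumes with its metadata table
#'
#' Reads one GM and one WM NIfTI per participant listed in a cohort CSV
#' (columns \code{participant_id}, \code{age_years}, optional \code{site},
#' \code{group}, \code{gm_path}, \code{wm_path}), checks that every volume
#' shares the mask's grid and affine, and joins records to volumes by id.
#'
#' @param table_path cohort CSV path.
#' @param mask_path optional brain-mask NIfTI path.
#' @param dir directory used to resolve relative paths and default file
#'   names (\code{<id>_gm.nii.gz} / \code{<id>_wm.nii.gz}).
#' @return \code{list(volumes, records, mask)} where \code{mask} is a logical
#'   array or NULL.
#' @export
loadCohort <- function(table_path, mask_path = NULL, dir = dirname(table_path)) {
  records <- read.csv(table_path, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "age_years") %in% colnames(records)))
    stop("cohort table needs participant_id and age_years columns")
  if (anyDuplicated(records$participant_id))
    stop("duplicate participant ids in cohort table")
  if (any(records$age_years <= 0 | records$age_years >= 130))
    stop("age_years must lie in (0, 130)")
  gm <- if ("gm_path" %in% colnames(records)) records$gm_path else
    file.path(dir, paste0(records$participant_id, "_gm.nii.gz"))
  wm <- if ("wm_path" %in% colnames(records)) records$wm_path else
    file.path(dir, paste0(records$participant_id, "_wm.nii.gz"))
  missing <- !file.exists(gm) | !file.exists(wm)
  if (any(missing))
    stop("join error: no volume files for id(s): ",
         paste(records$participant_id[missing], collapse = ", "))
  volumes <- vector("list", nrow(records))
  ref_dim <- NULL; ref_aff <- NULL
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- readMap(mask_path)
    mask <- m$data > 0.5
    ref_dim <- dim(mask); ref_aff <- m$affine
  }
  for (i in seq_len(nrow(records))) {
    vp <- readVolumePair(gm[i], wm[i])
    if (is.null(ref_dim)) { ref_dim <- dim(gmVolume(vp)); ref_aff <- vp@affine }
    if (!identical(dim(gmVolume(vp)), ref_dim))
      stop("geometry error: shape mismatch in ", gm[i])
    if (max(abs(vp@affine - ref_aff)) > 1e-4)
      stop("geometry error: affine mismatch in ", gm[i])
    volumes[[i]] <- vp
  }
  names(volumes) <- records$participant_id
  list(volumes = volumes, records = records, mask = mask)
}
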
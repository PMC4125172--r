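# Volume / mask containers and NIfTI + CSV input/output.
#
# Conventions: voxel HU are integers (CT convention, so 1-HU histogram bins
# are exact); axes are (x, y, z) with z the slice index; physical sizes in
# mm, volumes in cm^3; masks are inclusive (a voxel belongs to the nodule
# iff flagged).

HU_MIN <- -1024L
HU_MAX <- 3071L

#' CT volume container
#'
#' Wraps a 3D integer grid of Hounsfield units together with its physical
#' voxel spacing. Axis order is (x, y, z) with z the slice index.
#'
#' @param voxels 3D numeric array of HU values; coerced to integer.
#' @param spacing_mm numeric length-3, voxel spacing in mm (dx, dy, dz).
#' @return An object of class `ct_volume`: a list with elements `voxels`
#'   (integer array) and `spacing_mm`.
#' @export
ct_volume <- function(voxels, spacing_mm) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  if (any(!is.finite(voxels))) stop("non-finite voxel values")
  v <- as.integer(round(voxels))
  if (any(v < HU_MIN | v > HU_MAX)) {
    stop(sprintf("HU values out of range [%d, %d]", HU_MIN, HU_MAX))
  }
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("spacing_mm must be 3 positive reals")
  }
  dim(v) <- dim(voxels)
  structure(list(voxels = v, spacing_mm = spacing_mm), class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%d, %d]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary nodule mask
#'
#' A binary 3D region marking segmented tumor voxels. Large vessels are
#' assumed excluded upstream: the mask is taken at face value.
#'
#' @param voxels 3D logical (or 0/1) array, same shape as its CT volume.
#' @param check_connected validate that the mask is one 26-connected
#'   component (done at load time for files).
#' @return An object of class `nodule_mask`: list with logical array `voxels`.
#' @export
nodule_mask <- function(voxels, check_connected = FALSE) {
  if (length(dim(voxels)) != 3) stop("mask must be a 3D array")
  m <- array(as.logical(voxels), dim(voxels))
  if (any(is.na(m))) stop("mask contains missing values")
  if (!any(m)) stop("empty mask")
  if (check_connected && n_components(m) != 1L) {
    stop("mask is not a single 26-connected component")
  }
  structure(list(voxels = m), class = "nodule_mask")
}

#' @export
print.nodule_mask <- function(x, ...) {
  cat(sprintf("<nodule_mask> %s grid, %d voxels set\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

#' Write / read CT volumes and masks as NIfTI
#'
#' Volumes and masks are stored as `.nii` / `.nii.gz` with the voxel spacing
#' in the header. Masks are written as 0/1 integers. `load_mask` validates
#' the segmentation contract: the mask must be non-empty, match the volume's
#' shape, and form a single 26-connected component.
#'
#' @param volume a [ct_volume()].
#' @param mask a [nodule_mask()].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `load_volume` returns a `ct_volume`; `load_mask` a `nodule_mask`;
#'   writers return `path` invisibly.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname nifti_io
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3) stop("expected a 3D NIfTI volume: ", path)
  if (any(!is.finite(a))) stop("non-finite voxels in ", path)
  ct_volume(a, RNifti::pixdim(img)[1:3])
}

#' @rdname nifti_io
#' @export
write_mask <- function(mask, path, spacing_mm = c(1, 1, 1)) {
  stopifnot(inherits(mask, "nodule_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim(mask$voxels)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname nifti_io
#' @param volume the `ct_volume` this mask segments (shape check).
#' @export
load_mask <- function(path, volume) {
  if (!file.exists(path)) stop("file not found: ", path)
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) != 3) stop("expected a 3D NIfTI mask: ", path)
  if (!is.null(volume)) {
    stopifnot(inherits(volume, "ct_volume"))
    if (!identical(dim(a), dim(volume$voxels))) {
      stop("shape mismatch: mask ", paste(dim(a), collapse = "x"),
           " vs volume ", paste(dim(volume$voxels), collapse = "x"))
    }
  }
  if (!any(a != 0)) stop("empty mask: ", path)
  nodule_mask(a != 0, check_connected = TRUE)
}

#' Feature and metadata tables on disk
#'
#' CSV (UTF-8, header row) round-trip for feature tables and cohort
#' metadata. Column names follow the `nodule_features` field names exactly.
#'
#' @param x data frame to write.
#' @param path CSV path.
#' @return the data frame (readers) or `path`, invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname table_io
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Apply the solid-component cohort-inclusion filter
#'
#' Nodules whose solid component measures >= 5 mm on the mediastinal
#' (soft-tissue) window are excluded from a GGN cohort; the rule is
#' inclusive (exactly 5.0 mm is excluded). The filter is idempotent.
#'
#' @param records data frame of cohort records with a `nodule_id` column.
#' @param features data frame with `nodule_id` and `size_mediastinal_mm`.
#' @param max_solid_mm exclusion threshold in mm (default 5).
#' @return list with `retained` and `excluded` record data frames and
#'   `log`, a data frame (nodule_id, size_mediastinal_mm, excluded, reason).
#' @export
filter_cohort <- function(records, features, max_solid_mm = 5) {
  if (!"nodule_id" %in% names(records)) stop("records must have nodule_id")
  if (!all(c("nodule_id", "size_mediastinal_mm") %in% names(features))) {
    stop("features must include nodule_id and size_mediastinal_mm")
  }
  sz <- features$size_mediastinal_mm[match(records$nodule_id, features$nodule_id)]
  if (any(is.na(sz))) stop("missing size_mediastinal_mm for some records")
  excluded <- sz >= max_solid_mm
  log <- data.frame(
    nodule_id = records$nodule_id,
    size_mediastinal_mm = sz,
    excluded = excluded,
    reason = ifelse(excluded,
                    sprintf("solid component >= %g mm on mediastinal window", max_solid_mm),
                    ""),
    stringsAsFactors = FALSE
  )
  list(
    retained = records[!excluded, , drop = FALSE],
    excluded = records[excluded, , drop = FALSE],
    log = log
  )
}

#' Write an exclusion log as JSON
#'
#' @param log the `log` element returned by [filter_cohort()].
#' @param path output JSON path.
#' @export
write_exclusion_log <- function(log, path) {
  jsonlite::write_json(log, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
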
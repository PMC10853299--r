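#' Construct an MRI volume
#'
#' A volume is a 3-D scalar grid with a voxel-to-world affine and isotropic
#' or anisotropic voxel spacing. All analysis in this package is carried out
#' in voxel space, so the affine is stored as given and only used for grid
#' compatibility checks and on-disk round-trips.
#'
#' @param data 3-D numeric array of finite values.
#' @param voxel_size_mm per-axis voxel spacing in mm; scalar values are
#'   recycled to all three axes. Default 0.5 mm isotropic.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size_mm`.
#' @return an object of class `mri_volume` with elements `data`, `affine`
#'   and `voxel_size_mm`.
#' @export
volume <- function(data, voxel_size_mm = 0.5, affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  if (any(!is.finite(data)))
    stop("volume contains non-finite values (NaN/Inf are rejected)")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0))
    stop("voxel spacings must be strictly positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)))
      stop("'affine' must be a 4x4 matrix")
  }
  structure(list(data = data, affine = affine, voxel_size_mm = voxel_size_mm),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mri_volume> %d x %d x %d voxels, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size_mm, digits = 3), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Volume of one voxel in cubic millimetres
#'
#' @param vol an `mri_volume`.
#' @return scalar, the product of the per-axis spacings.
#' @export
voxel_volume <- function(vol) {
  stopifnot(inherits(vol, "mri_volume"))
  prod(vol$voxel_size_mm)
}

#' Read a 3-D NIfTI volume
#'
#' Reads a `.nii` / `.nii.gz` file. Non-3-D images are rejected (a trailing
#' singleton fourth dimension is dropped), as are images containing NaN or
#' infinite voxels: the normalization landmarks are percentile-based and
#' silently masking NaNs would bias them.
#'
#' @param path file path.
#' @return an `mri_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, d[1:3])
    d <- dim(arr)
  }
  if (length(d) != 3L)
    stop("expected a 3-D image, got ", length(d), " dimensions: ", path)
  if (any(!is.finite(arr)))
    stop("image contains NaN or infinite voxels: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  volume(arr, voxel_size_mm = abs(RNifti::pixdim(img)[1:3]), affine = aff)
}

#' Write a volume to NIfTI
#'
#' @param vol an `mri_volume` (or binary mask volume).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI on-disk datatype; masks should use `"uint8"`.
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(inherits(vol, "mri_volume"))
  img <- RNifti::asNifti(vol$data, internal = FALSE)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  img <- RNifti::asNifti(img)  # sync header before writing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Binarize a probability map
#'
#' Thresholds a map at an inclusive lower bound: a voxel is foreground iff
#' its value is greater than or equal to `threshold` (lesion-probability
#' maps are conventionally cut at 0.5).
#'
#' @param prob_map an `mri_volume`.
#' @param threshold finite scalar threshold, default 0.5.
#' @return an `mri_volume` whose data is 0/1.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  stopifnot(inherits(prob_map, "mri_volume"))
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  out <- prob_map
  out$data <- array(as.numeric(prob_map$data >= threshold), dim(prob_map$data))
  out
}

# TRUE if volume data is already 0/1
is_binary <- function(vol) {
  all(vol$data %in% c(0, 1))
}

#' Check that volumes share a grid
#'
#' Errors unless all volumes have identical array dimensions and affines
#' equal within an absolute tolerance of 1e-5 (co-registration is assumed,
#' never performed, by this package).
#'
#' @param ... two or more `mri_volume` objects; a named list may be passed
#'   as a single argument.
#' @param tol absolute tolerance on affine entries.
#' @return invisibly `TRUE`, or an error naming the offending pair.
#' @export
check_compatible <- function(..., tol = 1e-5) {
  vols <- list(...)
  if (length(vols) == 1L && is.list(vols[[1]]) && !inherits(vols[[1]], "mri_volume"))
    vols <- vols[[1]]
  if (length(vols) < 2L) stop("need at least two volumes to compare")
  nms <- names(vols)
  if (is.null(nms) || any(nms == "")) nms <- paste0("volume", seq_along(vols))
  ref <- vols[[1]]
  for (i in seq_along(vols)[-1]) {
    v <- vols[[i]]
    if (!all(dim(v$data) == dim(ref$data)))
      stop(sprintf("grid mismatch between %s and %s: shapes differ", nms[1], nms[i]))
    if (max(abs(v$affine - ref$affine)) > tol)
      stop(sprintf("grid mismatch between %s and %s: affines differ", nms[1], nms[i]))
  }
  invisible(TRUE)
}
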
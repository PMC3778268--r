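#' Construct a tissue-abnormality image
#'
#' An abnormality image is the output of an upstream automated
#' lesion-identification step: a 3-D grid, in standard (MNI-like) space, in
#' which each voxel codes the degree of abnormality of the underlying tissue
#' on a 0--1 scale. Together with its voxel-to-world affine it is the raw
#' input to lesion binarization.
#'
#' @param grid 3-D numeric array with all values in `[0, 1]`.
#' @param affine 4x4 voxel-to-world matrix (mm). Voxel indices are 0-based
#'   when mapped through the affine, i.e. the R array element `[1, 1, 1]`
#'   sits at world position `affine %*% c(0, 0, 0, 1)`.
#' @return An object of class `abnormality_image` with fields `grid`,
#'   `affine` and `voxel_size` (mm per axis, from the affine columns).
#' @seealso [binarize_lesion()], [read_abnormality_image()]
#' @export
abnormality_image <- function(grid, affine = diag(c(2, 2, 2, 1))) {
  if (!is.array(grid) || length(dim(grid)) != 3L || length(grid) == 0L)
    stop("`grid` must be a non-empty 3-D array")
  if (any(!is.finite(grid)))
    stop("abnormality image contains non-finite voxel values")
  if (any(grid < 0) || any(grid > 1))
    stop("abnormality values must lie in [0, 1]")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    stop("`affine` must be a finite 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be invertible")
  structure(
    list(grid = grid, affine = affine,
         voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))),
    class = "abnormality_image")
}

#' Read an abnormality image from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file with values in `[0, 1]`.
#' @return An [abnormality_image()].
#' @export
read_abnormality_image <- function(path) {
  img <- RNifti::readNifti(path)
  abnormality_image(array(as.numeric(img), dim = dim(img)),
                    affine = unclass(RNifti::xform(img)))
}

# Write a 3-D array + affine as NIfTI. `datatype` "double" keeps exact
# round trips for generated fixtures.
write_nifti_volume <- function(grid, affine, path, datatype = "double") {
  img <- RNifti::asNifti(grid)
  img <- RNifti::`pixdim<-`(img, sqrt(colSums(affine[1:3, 1:3]^2)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Binarize an abnormality image into a lesion mask
#'
#' Voxels with abnormality strictly greater than `threshold` are marked
#' lesioned, then connected components smaller than `min_cluster` voxels are
#' discarded, so that only focal damage of at least `min_cluster` contiguous
#' voxels survives. The defaults (threshold 0.3, 100 voxels of 2 mm, i.e.
#' 0.8 ml) are the standard operating point for abnormality images of this
#' kind.
#'
#' @param img An [abnormality_image()].
#' @param threshold Abnormality threshold; a voxel is a lesion candidate iff
#'   its value is *strictly* greater than this. Default 0.3.
#' @param min_cluster Minimum connected-component size in voxels. Default 100.
#' @param connectivity Voxel adjacency defining "contiguous": 6 (faces),
#'   18 (faces + edges) or 26 (faces + edges + corners, default).
#' @return An object of class `binary_lesion` with fields `mask` (3-D logical
#'   array), `affine`, `n_voxels`, and lateralised counts `n_left`/`n_right`
#'   (by world-x sign of the voxel center; midline voxels counted in neither).
#' @export
binarize_lesion <- function(img, threshold = 0.3, min_cluster = 100,
                            connectivity = 26) {
  stopifnot(inherits(img, "abnormality_image"))
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("`threshold` must lie in [0, 1)")
  if (min_cluster < 1) stop("`min_cluster` must be >= 1")
  candidate <- img$grid > threshold
  mask <- array(FALSE, dim = dim(img$grid))
  if (any(candidate)) {
    labels <- label_components_cpp(as.logical(candidate), dim(candidate),
                                   as.integer(connectivity))
    sizes <- tabulate(labels)
    keep <- which(sizes >= min_cluster)
    if (length(keep)) mask <- array(labels %in% keep, dim = dim(candidate))
  }
  new_binary_lesion(mask, img$affine)
}

new_binary_lesion <- function(mask, affine) {
  lat <- lateralised_counts(mask, affine)
  structure(
    list(mask = mask, affine = affine, n_voxels = sum(mask),
         n_left = lat[["left"]], n_right = lat[["right"]]),
    class = "binary_lesion")
}

# World x-coordinate of every voxel center (0-based indices through the
# affine), returned as an array matching `dims`.
world_x <- function(dims, affine) {
  i <- seq_len(dims[1]) - 1
  j <- seq_len(dims[2]) - 1
  k <- seq_len(dims[3]) - 1
  outer(outer(affine[1, 1] * i, affine[1, 2] * j, `+`),
        affine[1, 3] * k + affine[1, 4], `+`)
}

lateralised_counts <- function(mask, affine, tol = 1e-8) {
  if (!any(mask)) return(c(left = 0L, right = 0L))
  x <- world_x(dim(mask), affine)[mask]
  c(left = sum(x < -tol), right = sum(x > tol))
}

#' Lesion volume in voxels
#'
#' @param lesion A `binary_lesion` (see [binarize_lesion()]).
#' @return Total number of lesioned voxels.
#' @export
lesion_volume <- function(lesion) {
  stopifnot(inherits(lesion, "binary_lesion"))
  sum(lesion$mask)
}

#' Lateralised lesion volumes
#'
#' Counts lesioned voxels in the left (world x < 0) and right (world x > 0)
#' hemispheres, assigning each voxel by the world x-coordinate of its center.
#' Voxels whose center lies exactly on the midline (x = 0) are counted in
#' neither hemisphere.
#'
#' @inheritParams lesion_volume
#' @return Named integer vector `c(left = , right = )`.
#' @export
lateralised_volumes <- function(lesion) {
  stopifnot(inherits(lesion, "binary_lesion"))
  if (is.null(lesion$affine)) stop("lesion has no affine")
  lateralised_counts(lesion$mask, lesion$affine)
}

#' Lesion overlap map across a cohort
#'
#' Voxelwise count of how many patients have a lesion at each location; the
#' cohort-level summary conventionally displayed as a lesion frequency map.
#'
#' @param masks List of `binary_lesion` objects sharing shape and affine.
#' @return An object of class `overlap_map` with fields `counts` (3-D integer
#'   array), `n_patients` and `affine`.
#' @export
overlap_map <- function(masks) {
  stopifnot(length(masks) >= 1, all(vapply(masks, inherits, TRUE, "binary_lesion")))
  ref_dim <- dim(masks[[1]]$mask)
  ref_aff <- masks[[1]]$affine
  counts <- array(0L, dim = ref_dim)
  for (m in masks) {
    if (!identical(dim(m$mask), ref_dim))
      stop("all masks must share the same grid shape")
    if (max(abs(m$affine - ref_aff)) > 1e-6)
      stop("all masks must share the same affine")
    counts <- counts + m$mask
  }
  structure(list(counts = counts, n_patients = length(masks),
                 affine = ref_aff),
            class = "overlap_map")
}

#' @export
print.binary_lesion <- function(x, ...) {
  cat(sprintf("Binary lesion mask: %d voxels (%d left / %d right), grid %s\n",
              x$n_voxels, x$n_left, x$n_right,
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf("Lesion overlap map over %d patients; max overlap %d\n",
              x$n_patients, max(x$counts)))
  invisible(x)
}

#' Write a binary lesion mask or overlap map as NIfTI
#'
#' @param x A `binary_lesion` or `overlap_map`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_lesion_nifti <- function(x, path) {
  if (inherits(x, "binary_lesion"))
    write_nifti_volume(array(as.integer(x$mask), dim = dim(x$mask)),
                       x$affine, path, datatype = "uint8")
  else if (inherits(x, "overlap_map"))
    write_nifti_volume(x$counts, x$affine, path, datatype = "int")
  else stop("unsupported object")
}
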
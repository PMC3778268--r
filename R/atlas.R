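#' Construct a parcellation atlas
#'
#' A parcellation assigns every in-brain voxel to one anatomical region via
#' an integer label image (0 = background), with a region table carrying ids,
#' names and hemisphere tags. Lesions are encoded against it as per-region
#' damage proportions, turning a 3-D mask into a fixed-length feature vector.
#'
#' @param labels 3-D integer array of region labels, 0 for background, in the
#'   same space as the lesion masks.
#' @param regions Data frame with columns `region_id` (unique, > 0), `name`
#'   and `hemisphere` (`"L"`, `"R"` or `"M"`).
#' @param affine 4x4 voxel-to-world matrix shared with the lesion masks.
#' @return An object of class `parcellation`; the region table gains an
#'   `n_voxels` column counted from the label image.
#' @export
parcellation <- function(labels, regions, affine = diag(c(2, 2, 2, 1))) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  storage.mode(labels) <- "integer"
  regions <- as.data.frame(regions)
  if (!all(c("region_id", "name", "hemisphere") %in% names(regions)))
    stop("`regions` needs columns region_id, name, hemisphere")
  ids <- regions$region_id
  if (anyDuplicated(ids) || any(ids <= 0))
    stop("region ids must be unique and > 0")
  present <- sort(unique(labels[labels > 0L]))
  missing_ids <- setdiff(present, ids)
  if (length(missing_ids))
    stop("label image contains region id(s) absent from the table: ",
         paste(missing_ids, collapse = ", "))
  counts <- tabulate(labels, nbins = max(ids))
  regions$n_voxels <- counts[ids]
  # ids declared in the table but absent from the label image are kept (the
  # table is the authoritative region list) but flagged: they can never carry
  # damage, so downstream proportions for them are 0 by convention.
  if (any(regions$n_voxels == 0L))
    warning("region(s) declared in table but empty in label image: ",
            paste(ids[regions$n_voxels == 0L], collapse = ", "))
  structure(list(labels = labels, regions = regions,
                 affine = as.matrix(affine)),
            class = "parcellation")
}

#' Load a parcellation from a NIfTI label image and a region CSV
#'
#' @param label_path NIfTI label image (0 = background).
#' @param region_path CSV with columns `region_id,name,hemisphere`.
#' @return A [parcellation()].
#' @export
load_parcellation <- function(label_path, region_path) {
  img <- RNifti::readNifti(label_path)
  labels <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  regions <- read.csv(region_path, stringsAsFactors = FALSE)
  parcellation(labels, regions, affine = unclass(RNifti::xform(img)))
}

#' Encode a lesion as per-region damage proportions
#'
#' For each atlas region r the damage value is
#' \eqn{|mask \cap region_r| / |region_r|}: the proportion of the region's
#' voxels that fall inside the binary lesion, in `[0, 1]`. The vector is
#' ordered by the parcellation's region table.
#'
#' @param lesion A `binary_lesion` (see [binarize_lesion()]).
#' @param atlas A [parcellation()] in the same space as the mask.
#' @return Named numeric vector of length `nrow(atlas$regions)`, names taken
#'   from the region table.
#' @export
atlas_proportions <- function(lesion, atlas) {
  stopifnot(inherits(lesion, "binary_lesion"), inherits(atlas, "parcellation"))
  if (!identical(dim(lesion$mask), dim(atlas$labels)))
    stop("lesion mask and atlas label image have different shapes")
  if (max(abs(lesion$affine - atlas$affine)) > 1e-6)
    stop("lesion mask and atlas are in different spaces (affine mismatch)")
  ids <- atlas$regions$region_id
  hit <- tabulate(atlas$labels[lesion$mask], nbins = max(ids))
  nv <- atlas$regions$n_voxels
  vals <- ifelse(nv > 0L, hit[ids] / pmax(nv, 1L), 0)
  names(vals) <- atlas$regions$name
  vals
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: %d regions, grid %s, %d labelled voxels\n",
              nrow(x$regions), paste(dim(x$labels), collapse = "x"),
              sum(x$labels > 0L)))
  invisible(x)
}
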
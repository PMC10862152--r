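#' Construct a labelled 3D segmentation volume
#'
#' A label volume is a 3D integer array (one label id per voxel, 0 =
#' background), the voxel spacing in mm per axis, and a label dictionary
#' mapping every nonzero label id to a structure code and kind
#' (`"muscle"` or `"bone"`). Physical coordinates place the centre of
#' voxel `(i, j, k)` at `((i, j, k) - 0.5) * spacing` mm.
#'
#' @param array 3D integer array of label ids.
#' @param spacing Numeric length-3, voxel spacing in mm; strictly positive.
#' @param labels Data frame with columns `label`, `code`, `kind`.
#' @return An object of class `label_volume`.
#' @export
as_label_volume <- function(array, spacing, labels) {
  stopifnot(length(dim(array)) == 3)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("voxel spacing must be three strictly positive values (mm)")
  }
  stopifnot(all(c("label", "code", "kind") %in% names(labels)))
  if (any(labels$label == 0)) stop("label 0 is reserved for background")
  if (anyDuplicated(labels$label)) stop("label ids must be unique")
  present <- setdiff(unique(as.vector(array)), 0L)
  orphan <- setdiff(present, labels$label)
  if (length(orphan) > 0) {
    stop("labels present in the array but not in the dictionary: ",
         paste(orphan, collapse = ", "))
  }
  structure(list(array = array, spacing = as.numeric(spacing),
                 labels = as.data.frame(labels)),
            class = "label_volume")
}

resolve_label <- function(lv, label) {
  if (is.character(label)) {
    i <- match(label, lv$labels$code)
    if (is.na(i)) stop("unknown label code: ", label)
    return(lv$labels$label[i])
  }
  if (!label %in% lv$labels$label) stop("unknown label id: ", label)
  label
}

#' Volume of one labelled structure
#'
#' Voxel-count volumetry: the number of voxels carrying the label times
#' the voxel volume. Returns 0 for a label that is in the dictionary but
#' absent from the array.
#'
#' @param lv A [as_label_volume()] object.
#' @param label Label id (integer) or structure code (character).
#' @return Volume in cm^3.
#' @export
label_volume <- function(lv, label) {
  id <- resolve_label(lv, label)
  sum(lv$array == id) * prod(lv$spacing) / 1000
}

#' Length of a bone along its principal axis
#'
#' Maximum extent of the structure along the first principal component of
#' its voxel-centre coordinate cloud (physical mm units): coordinates are
#' centred, projected onto the dominant eigenvector of their covariance,
#' and the projection range (max minus min) is returned in cm.
#'
#' @inheritParams label_volume
#' @return Length in cm.
#' @export
bone_length <- function(lv, label) {
  id <- resolve_label(lv, label)
  idx <- which(lv$array == id, arr.ind = TRUE)
  if (nrow(idx) < 2) stop("degenerate geometry: fewer than 2 voxels carry label ", label)
  coords <- sweep(idx - 0.5, 2, lv$spacing, "*")
  cc <- sweep(coords, 2, colMeans(coords))
  v1 <- eigen(crossprod(cc) / (nrow(cc) - 1), symmetric = TRUE)$vectors[, 1]
  proj <- cc %*% v1
  (max(proj) - min(proj)) / 10
}

#' Write or read a label volume as NIfTI plus a JSON sidecar
#'
#' The 3D integer array is written as a NIfTI volume whose pixdim carries
#' the voxel spacing; the label dictionary (and, for phantoms, the
#' analytic ground truth) goes into `<path>.json`.
#'
#' @param lv A [as_label_volume()] object.
#' @param path Path to the `.nii` (or `.nii.gz`) file.
#' @return `write_label_volume()` returns `path` invisibly;
#'   `read_label_volume()` returns a [as_label_volume()] object.
#' @export
write_label_volume <- function(lv, path) {
  img <- RNifti::asNifti(lv$array + 0L)
  RNifti::pixdim(img) <- lv$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  side <- list(labels = lv$labels, spacing = lv$spacing)
  gt <- attr(lv, "ground_truth")
  if (!is.null(gt)) side$ground_truth <- gt
  jsonlite::write_json(side, paste0(path, ".json"), dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(as.integer(img), dim = dim(img))
  lv <- as_label_volume(arr, RNifti::pixdim(img)[1:3], as.data.frame(side$labels))
  if (!is.null(side$ground_truth)) {
    attr(lv, "ground_truth") <- as.data.frame(side$ground_truth)
  }
  lv
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("Label volume %s voxels at %s mm; %d labelled structures\n",
              paste(dim(x$array), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"), nrow(x$labels)))
  invisible(x)
}
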
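# Volume handling: left-right flipping and label-volume I/O.
#
# Preprocessing (lesion mapping, registration, normalisation) is assumed
# done upstream; all volumes handled here are taken to be co-registered on a
# common grid.  The only spatial operation the pipeline itself needs is the
# mid-sagittal flip used to pool left- and right-lesion patients: patients
# with a left-sided lesion are mirrored so that, for every patient, the
# right hemisphere is the ipsilesional one.

#' Mirror a volume across the mid-sagittal plane
#'
#' Reverses the voxel order along the left-right axis, leaving every other
#' axis and all metadata untouched.  Applying the flip twice returns the
#' original voxel array (involution).
#'
#' For NIfTI images (`RNifti` `niftiImage` or anything `RNifti::niftiHeader`
#' understands) the left-right axis is located from the image's orientation
#' string.  For bare arrays there is no orientation metadata, so `lr_axis`
#' must be given explicitly.
#'
#' @param volume A 3D or 4D array or NIfTI image.
#' @param lr_axis Integer axis index (1-3) of the left-right axis; required
#'   for bare arrays, ignored (derived from the header) for NIfTI images.
#' @return The mirrored volume, same class as the input.
#' @examples
#' v <- array(seq_len(24), dim = c(2, 3, 4))
#' identical(flip_lr(flip_lr(v, lr_axis = 1), lr_axis = 1), v)
#' @export
flip_lr <- function(volume, lr_axis = NULL) {
  is_nifti <- inherits(volume, "niftiImage")
  if (is_nifti) {
    orient <- RNifti::orientation(volume)
    lr_axis <- match_lr_axis(orient)
  } else if (is.null(lr_axis)) {
    stop_cbtc("volume has no orientation metadata; supply `lr_axis` or pass ",
              "a NIfTI image with its orientation set")
  }
  d <- dim(volume)
  if (is.null(d) || length(d) < 3L || length(d) > 4L) {
    stop_cbtc("expected a 3D or 4D volume")
  }
  if (lr_axis < 1L || lr_axis > 3L) stop_cbtc("lr_axis must be 1, 2 or 3")
  idx <- rep(list(quote(expr = )), length(d))
  idx[[lr_axis]] <- d[lr_axis]:1L
  arr <- do.call(`[`, c(list(as.array(volume)), idx, list(drop = FALSE)))
  if (is_nifti) RNifti::asNifti(arr, reference = volume) else arr
}

match_lr_axis <- function(orient) {
  codes <- strsplit(orient, "")[[1L]]
  ax <- which(codes %in% c("L", "R"))
  if (length(ax) != 1L) {
    stop_cbtc("cannot identify the left-right axis from orientation '",
              orient, "'; set the image orientation first")
  }
  ax
}

#' Read an integer label volume with its sidecar region table
#'
#' Label volumes map voxels to integer codes; a sidecar TSV with header
#' `label  name  kind  hemisphere  parent  tag` maps codes to region labels.
#'
#' @param nifti_path Path to the NIfTI label volume.
#' @param sidecar_path Path to the sidecar TSV; defaults to `nifti_path`
#'   with the extension replaced by `.tsv`.
#' @return A list with `volume` (the image) and `regions` (the sidecar data
#'   frame).
#' @export
read_label_volume <- function(nifti_path,
                              sidecar_path = sub("\\.nii(\\.gz)?$", ".tsv",
                                                 nifti_path)) {
  vol <- RNifti::readNifti(nifti_path)
  if (!file.exists(sidecar_path)) {
    stop_cbtc("sidecar region table not found: '", sidecar_path, "'")
  }
  regions <- utils::read.delim(sidecar_path, stringsAsFactors = FALSE)
  need <- c("label", "name", "kind", "hemisphere")
  miss <- setdiff(need, names(regions))
  if (length(miss)) {
    stop_cbtc("sidecar '", sidecar_path, "' missing column(s): ",
              paste(miss, collapse = ", "))
  }
  list(volume = vol, regions = regions)
}

#' Write an integer label volume with a sidecar region table
#'
#' @param labels 3D integer array of label codes (0 = background).
#' @param regions Data frame with at least `label` and `name` columns;
#'   `kind`, `hemisphere`, `parent`, `tag` are filled with `NA` if absent.
#' @param nifti_path Output NIfTI path (`.nii` or `.nii.gz`).
#' @return `nifti_path`, invisibly.
#' @export
write_label_volume <- function(labels, regions, nifti_path) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  for (col in c("kind", "hemisphere", "parent", "tag")) {
    if (is.null(regions[[col]])) regions[[col]] <- NA_character_
  }
  RNifti::writeNifti(RNifti::asNifti(labels), nifti_path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".tsv", nifti_path)
  utils::write.table(
    regions[, c("label", "name", "kind", "hemisphere", "parent", "tag")],
    sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nifti_path)
}
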
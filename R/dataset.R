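#' Construct an images-by-voxels dataset
#'
#' The internal representation of a functional image series: an N x V
#' activation matrix (images in rows, in standardized BOLD units for real
#' data) together with a V x D voxel coordinate table, and optional
#' per-image condition and epoch labels used by the network analyses.
#'
#' @param activations N x V numeric matrix, one image per row.
#' @param coords V x D numeric matrix of voxel locations (world/mm space for
#'   NIfTI input, grid units for synthetic data). Rows must be unique.
#' @param mask_shape Optional integer grid dimensions of the originating
#'   volume (round-tripped to NIfTI output).
#' @param affine Optional 4 x 4 voxel-to-world transform (round-tripped).
#' @param condition_labels Optional length-N factor/character of conditions.
#' @param epoch_labels Optional length-N integer epoch tags.
#' @param provenance Optional list of provenance metadata.
#' @return An object of class `"tfa_dataset"`.
#' @export
tfa_dataset <- function(activations, coords, mask_shape = NULL, affine = NULL,
                        condition_labels = NULL, epoch_labels = NULL,
                        provenance = list()) {
  activations <- as_matrix(activations, "activations")
  coords <- as_matrix(coords, "coords")
  if (nrow(activations) < 1L || ncol(activations) < 1L) {
    stop("`activations` must have at least one image and one voxel", call. = FALSE)
  }
  if (nrow(coords) != ncol(activations)) {
    stop(sprintf("coords has %d rows but activations has %d voxels",
                 nrow(coords), ncol(activations)), call. = FALSE)
  }
  if (anyDuplicated(coords)) {
    stop("voxel coordinate rows must be unique", call. = FALSE)
  }
  N <- nrow(activations)
  if (!is.null(condition_labels)) {
    condition_labels <- as.factor(condition_labels)
    if (length(condition_labels) != N) {
      stop("`condition_labels` must have one entry per image", call. = FALSE)
    }
  }
  if (!is.null(epoch_labels)) {
    epoch_labels <- as.integer(epoch_labels)
    if (length(epoch_labels) != N) {
      stop("`epoch_labels` must have one entry per image", call. = FALSE)
    }
  }
  structure(list(activations = activations, coords = coords,
                 mask_shape = mask_shape, affine = affine,
                 condition_labels = condition_labels,
                 epoch_labels = epoch_labels, provenance = provenance),
            class = "tfa_dataset")
}

#' @export
print.tfa_dataset <- function(x, ...) {
  cat(sprintf("TFA dataset: %d images x %d voxels (%d-D coordinates)\n",
              nrow(x$activations), ncol(x$activations), ncol(x$coords)))
  if (!is.null(x$condition_labels)) {
    cat(sprintf("  conditions: %s\n",
                paste(levels(x$condition_labels), collapse = ", ")))
  }
  if (!is.null(x$epoch_labels)) {
    cat(sprintf("  epochs: %d\n", length(unique(x$epoch_labels))))
  }
  if (length(x$provenance)) {
    src <- x$provenance$image %||% "in-memory"
    cat(sprintf("  source: %s\n", src))
  }
  invisible(x)
}

# Coerce the objects users commonly hand to fitting/analysis functions.
as_tfa_dataset <- function(x) {
  if (inherits(x, "tfa_dataset")) return(x)
  if (inherits(x, "tfa_bundle")) return(x$data)
  stop("expected a `tfa_dataset` (or synthetic bundle); see `tfa_dataset()`",
       call. = FALSE)
}
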
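# NIfTI ingestion, result export, and fit checkpoints.

# Zero-based voxel grid indices for a dataset that knows its grid.
dataset_voxel_indices <- function(data) {
  if (is.null(data$affine)) {
    stop("dataset has no affine; cannot map coordinates to grid indices",
         call. = FALSE)
  }
  D <- ncol(data$coords)
  hom <- rbind(t(data$coords), matrix(0, 3 - D, nrow(data$coords)),
               rep(1, nrow(data$coords)))
  idx <- solve(data$affine) %*% hom
  round(t(idx[seq_len(3), , drop = FALSE]))
}

#' Read a 4-D NIfTI series (and optional mask) as a dataset
#'
#' Retains the voxels where the mask is positive (all voxels when no mask
#' is given), takes voxel coordinates from the image's voxel-to-world
#' transform, and maps the time axis to image rows. Provenance (paths,
#' mask voxel count, affine) is recorded on the dataset.
#'
#' @param image_path Path to a 4-D NIfTI image series.
#' @param mask_path Optional path to a 3-D NIfTI mask on the same grid.
#' @return A [tfa_dataset].
#' @export
read_tfa_dataset <- function(image_path, mask_path = NULL) {
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) < 4L) dim(arr) <- c(dim(arr), 1L, 1L, 1L)[1:4]
  if (length(dim(arr)) != 4L) {
    stop(sprintf("expected a 4-D image series, got %d dimensions",
                 length(dim(arr))), call. = FALSE)
  }
  shape <- dim(arr)[1:3]
  if (!is.null(mask_path)) {
    mask <- as.array(RNifti::readNifti(mask_path))
    dim(mask) <- c(dim(mask), 1L, 1L)[1:3]
    if (!identical(dim(mask)[1:3], shape)) {
      stop(sprintf("mask grid (%s) does not match image grid (%s)",
                   paste(dim(mask), collapse = "x"),
                   paste(shape, collapse = "x")), call. = FALSE)
    }
    keep <- which(mask > 0)
  } else {
    keep <- seq_len(prod(shape))
  }
  if (length(keep) == 0L) stop("mask retains no voxels", call. = FALSE)
  N <- dim(arr)[4L]
  flat <- matrix(arr, nrow = prod(shape))   # voxels x images
  Y <- t(flat[keep, , drop = FALSE])
  idx <- arrayInd(keep, shape) - 1L
  aff <- structure(RNifti::xform(img), class = NULL)
  world <- aff %*% rbind(t(idx), rep(1, length(keep)))
  drop_dims <- which(shape == 1L & seq_along(shape) == 3L)
  coords <- t(world[seq_len(3), , drop = FALSE])
  if (length(drop_dims)) coords <- coords[, -3L, drop = FALSE]
  labels <- read_labels_if_present(image_path)
  tfa_dataset(Y, coords, mask_shape = shape, affine = aff,
              condition_labels = labels$condition,
              epoch_labels = labels$epoch,
              provenance = list(image = image_path, mask = mask_path,
                                n_mask_voxels = length(keep), affine = aff))
}

# A labels TSV written by write_tfa_dataset next to the image is picked up
# automatically (condition/epoch columns, one row per image).
read_labels_if_present <- function(image_path) {
  lp <- file.path(dirname(image_path), "labels.tsv")
  if (!file.exists(lp)) return(list(condition = NULL, epoch = NULL))
  tab <- read.table(lp, header = TRUE, sep = "\t")
  list(condition = tab$condition, epoch = tab$epoch)
}

#' Write a dataset (or synthetic bundle) as a NIfTI file set
#'
#' Writes the 4-D image series and a mask; a synthetic bundle additionally
#' gets ground-truth TSVs (sources, weights) so the full pipeline can be
#' exercised end to end without any external download. Labels, when
#' present, go to `labels.tsv`.
#'
#' @param x A [tfa_dataset] or `"tfa_bundle"` carrying grid metadata.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_tfa_dataset <- function(x, dir) {
  bundle <- if (inherits(x, "tfa_bundle")) x else NULL
  data <- as_tfa_dataset(x)
  if (is.null(data$mask_shape)) {
    stop("dataset has no grid metadata (mask_shape); cannot write NIfTI",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shape <- as.integer(data$mask_shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  N <- nrow(data$activations)
  idx <- dataset_voxel_indices(data)
  lin <- idx[, 1L] + shape[1L] * (idx[, 2L] + shape[2L] * idx[, 3L]) + 1L
  flat <- matrix(0, prod(shape), N)
  flat[lin, ] <- t(data$activations)
  arr <- array(flat, dim = c(shape, N))
  # note: read_tfa_dataset() enumerates mask voxels in NIfTI linear order,
  # so a write/read round trip preserves (coordinate, activation) pairs but
  # may permute voxel rows relative to this dataset
  mask <- array(0L, dim = shape)
  mask[lin] <- 1L
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(data$affine, code = 2L))
  RNifti::writeNifti(img, file.path(dir, "images.nii"), compression = 0)
  mimg <- RNifti::asNifti(mask)
  mimg <- RNifti::`sform<-`(mimg, structure(data$affine, code = 2L))
  RNifti::writeNifti(mimg, file.path(dir, "mask.nii"), compression = 0)
  if (!is.null(data$condition_labels) || !is.null(data$epoch_labels)) {
    write.table(data.frame(condition = data$condition_labels %||% rep(NA, N),
                           epoch = data$epoch_labels %||% rep(NA, N)),
                file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(bundle)) {
    write_init_report(bundle$truth$sources,
                      file.path(dir, "truth_sources.tsv"))
    write.table(bundle$truth$weights, file.path(dir, "truth_weights.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(dir)
}

#' Save and restore a fit checkpoint
#'
#' The checkpoint holds the complete variational state (all means, log
#' precisions and gradient accumulators), the control settings, the ELBO
#' trace and the seed, in R's native serialization; reloading reproduces
#' reconstructions exactly.
#'
#' @param fit A fitted [tfa] object (or a bare [tfa_state]).
#' @param path Checkpoint path (conventionally `.rds`).
#' @return `path` (write) / the restored object (read).
#' @export
write_tfa_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_tfa_checkpoint
#' @export
read_tfa_checkpoint <- function(path) {
  readRDS(path)
}

#' Save a fitted model as a file set
#'
#' Writes the source table (`sources.tsv`: id, center coordinates, log
#' width mean, and the expected width `exp(width mean)`), the weight
#' matrix (`weights.tsv`), a reconstruction NIfTI when the dataset carries
#' grid metadata, optional network tables, a checkpoint, and a JSON run
#' manifest (control settings, seed, package version, ELBO trace).
#'
#' @param fit A fitted [tfa] object.
#' @param out_dir Output directory.
#' @param networks Optional list of `"tfa_network"` objects to export.
#' @return The output directory, invisibly.
#' @export
save_tfa_results <- function(fit, out_dir, networks = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  src <- fit$sources
  D <- ncol(src$centers)
  tab <- data.frame(source = seq_len(nrow(src$centers)), src$centers,
                    log_width = src$log_widths,
                    expected_width = exp(src$log_widths))
  names(tab)[1L + seq_len(D)] <- c("x", "y", "z")[seq_len(D)]
  write.table(tab, file.path(out_dir, "sources.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fit$weights, file.path(out_dir, "weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(fit$data$mask_shape)) {
    recon <- fit$data
    recon$activations <- fitted(fit)
    write_tfa_dataset(recon, file.path(out_dir, "reconstruction"))
  }
  if (!is.null(networks)) {
    for (i in seq_along(networks)) {
      nm <- names(networks)[i] %||% as.character(i)
      if (is.null(names(networks)) || nm == "") nm <- as.character(i)
      write_network(networks[[i]], file.path(out_dir, paste0("network_", nm)),
                    sources = src)
    }
  }
  write_tfa_checkpoint(fit, file.path(out_dir, "checkpoint.rds"))
  manifest <- list(
    package = "topofa",
    version = as.character(utils::packageVersion("topofa")),
    seed = fit$seed, K = fit$K, init = fit$init,
    control = fit$control[!vapply(fit$control, is.null, logical(1L))],
    converged = fit$converged,
    elbo_trace = fit$elbo_trace)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
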
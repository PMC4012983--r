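#' Sample from the generative process
#'
#' Runs the model forward once: draws K source centers and log widths from
#' their priors, N weight vectors i.i.d. from the weight prior, and voxel
#' activations from the Gaussian likelihood around the weighted sum of
#' source images. Identical seeds give identical output.
#'
#' @param K Number of sources.
#' @param hyper A [tfa_hyper] object.
#' @param coords V x D voxel coordinate matrix.
#' @param N Number of images.
#' @param seed Integer seed (required; the reproducibility contract).
#' @return A list with elements `sources` ([tfa_sources]), `weights`
#'   (N x K matrix) and `data` ([tfa_dataset]).
#' @export
tfa_sample_generative <- function(K, hyper, coords, N, seed) {
  stopifnot(K >= 1L, N >= 1L)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  coords <- as_matrix(coords, "coords")
  D <- ncol(coords)
  local_seed(seed, {
    centers <- matrix(rnorm(K * D,
                            mean = rep(hyper$center_mean, each = K),
                            sd = rep(exp(-hyper$center_log_precision / 2), each = K)),
                      nrow = K)
    log_widths <- rnorm(K, hyper$width_mean, exp(-hyper$width_log_precision / 2))
    weights <- matrix(rnorm(N * K, hyper$weight_mean,
                            exp(-hyper$weight_log_precision / 2)), nrow = N)
    sources <- tfa_sources(centers, log_widths)
    mu <- weights %*% rbf_basis(sources, coords)
    Y <- mu + matrix(rnorm(length(mu), 0, hyper$noise_sd), nrow = N)
    list(sources = sources, weights = weights,
         data = tfa_dataset(Y, coords))
  })
}

#' Log joint density of latents and data
#'
#' The joint density factorizes into Gaussian priors over weights, centers
#' and log widths times the Gaussian likelihood of the voxel activations
#' around `W %*% F`. When image and/or voxel subsets are supplied, the
#' image-dependent terms (weight prior and likelihood) are rescaled by
#' `N/N'` and the likelihood additionally by `V/V'`, so the subsampled value
#' is an unbiased estimate of the full sum over a uniformly drawn subset.
#'
#' @param sources A [tfa_sources] object.
#' @param weights N x K weight matrix (rows aligned with the dataset).
#' @param data A [tfa_dataset].
#' @param hyper A [tfa_hyper] object.
#' @param image_subset,voxel_subset `"all"` (default) or index vectors.
#' @return A scalar log density.
#' @export
tfa_log_joint <- function(sources, weights, data, hyper,
                          image_subset = "all", voxel_subset = "all") {
  data <- as_tfa_dataset(data)
  weights <- as_matrix(weights, "weights")
  N <- nrow(data$activations)
  V <- ncol(data$activations)
  img <- resolve_subset(image_subset, N, "image_subset")
  vox <- resolve_subset(voxel_subset, V, "voxel_subset")
  parts <- log_joint_parts(
    centers = sources$centers, log_widths = sources$log_widths,
    W = weights[img, , drop = FALSE],
    Y = data$activations[img, vox, drop = FALSE],
    coords = data$coords[vox, , drop = FALSE],
    hyper = hyper,
    scale_img = N / length(img), scale_vox = V / length(vox))
  parts$prior_centers + parts$prior_widths + parts$prior_weights + parts$loglik
}

# Internal workhorse: the four additive terms, for weights/data already cut
# down to the in-scope images and voxels.
log_joint_parts <- function(centers, log_widths, W, Y, coords, hyper,
                            scale_img = 1, scale_vox = 1) {
  K <- nrow(centers)
  pc <- sum(gauss_logdens(centers,
                          rep(hyper$center_mean, each = K),
                          rep(hyper$center_log_precision, each = K)))
  pw <- sum(gauss_logdens(log_widths, hyper$width_mean, hyper$width_log_precision))
  pwt <- scale_img * sum(gauss_logdens(W, hyper$weight_mean,
                                       hyper$weight_log_precision))
  Fm <- rbf_basis(list(centers = centers, log_widths = log_widths), coords)
  mu <- W %*% Fm
  ll <- scale_img * scale_vox *
    sum(gauss_logdens(Y, mu, hyper$noise_log_precision))
  list(prior_centers = pc, prior_widths = pw, prior_weights = pwt, loglik = ll)
}

#' Reconstruct images from sources and weights
#'
#' The model's mean surface: the weighted sum `W %*% F` of the source
#' images evaluated at the given coordinates. Because sources are spatial
#' functions, `coords` may be any locations, including voxels never seen
#' during fitting.
#'
#' @inheritParams tfa_log_joint
#' @param coords Locations at which to evaluate the reconstruction.
#' @return An N x V matrix of reconstructed activations.
#' @export
tfa_reconstruct <- function(sources, weights, coords) {
  weights <- as_matrix(weights, "weights")
  Fm <- rbf_basis(sources, coords)
  if (ncol(weights) != nrow(Fm)) {
    stop(sprintf("weights have %d columns but there are %d sources",
                 ncol(weights), nrow(Fm)), call. = FALSE)
  }
  weights %*% Fm
}
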
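#' Model hyperparameters (the fixed prior)
#'
#' The prior over latent variables is a set of independent Gaussians in
#' mean / log-precision form (variance = `exp(-log_precision)`):
#' weights \eqn{w_{nk} \sim N(c_w, e^{-\rho_w})}, centers
#' \eqn{\mu_k \sim N(c_\mu, \mathrm{diag}(e^{-\rho_\mu}))}, log widths
#' \eqn{\lambda_k \sim N(c_\lambda, e^{-\rho_\lambda})}, and i.i.d. Gaussian
#' voxel noise. Data-derived defaults: the center prior mean is the centroid
#' of the voxel coordinates and its per-dimension log precision is minus the
#' log of the coordinate variance along that dimension, so the prior covers
#' the imaged volume. The remaining log precisions default to broad values
#' (prior standard deviations about twice the relevant data scale), keeping
#' the prior uninformative.
#'
#' @param coords V x D voxel coordinate matrix (used for the center prior).
#' @param voxel_noise Voxel noise parameter; by default 0.1, read on the
#'   scale given by `noise_scale`.
#' @param noise_scale How to interpret `voxel_noise`: as a standard
#'   deviation (default), a variance, or a precision.
#' @param weight_mean,weight_log_precision Prior mean and log precision of
#'   the source weights (defaults 0 and `-2*log(2)`: sd 2).
#' @param width_mean,width_log_precision Prior mean and log precision of the
#'   source log widths (defaults 1 and `-2*log(2)`: sd 2).
#' @param center_mean,center_log_precision Optional overrides of the
#'   data-derived center prior (length-D each).
#' @return An object of class `"tfa_hyper"` with the noise stored as
#'   `noise_sd` plus the Gaussian prior parameters.
#' @export
tfa_hyper <- function(coords,
                      voxel_noise = 0.1,
                      noise_scale = c("sd", "variance", "precision"),
                      weight_mean = 0,
                      weight_log_precision = -2 * log(2),
                      width_mean = 1,
                      width_log_precision = -2 * log(2),
                      center_mean = NULL,
                      center_log_precision = NULL) {
  noise_scale <- match.arg(noise_scale)
  coords <- as_matrix(coords, "coords")
  if (!is.finite(voxel_noise) || voxel_noise <= 0) {
    stop("`voxel_noise` must be a positive number", call. = FALSE)
  }
  noise_sd <- switch(noise_scale,
                     sd = voxel_noise,
                     variance = sqrt(voxel_noise),
                     precision = 1 / sqrt(voxel_noise))
  if (is.null(center_mean)) center_mean <- colMeans(coords)
  if (is.null(center_log_precision)) {
    v <- apply(coords, 2L, var)
    v[!is.finite(v) | v <= 0] <- 1
    center_log_precision <- -log(v)
  }
  stopifnot(length(center_mean) == ncol(coords),
            length(center_log_precision) == ncol(coords))
  h <- list(noise_sd = noise_sd,
            noise_log_precision = -2 * log(noise_sd),
            weight_mean = weight_mean,
            weight_log_precision = weight_log_precision,
            center_mean = as.numeric(center_mean),
            center_log_precision = as.numeric(center_log_precision),
            width_mean = width_mean,
            width_log_precision = width_log_precision)
  for (nm in names(h)) check_finite(h[[nm]], nm)
  structure(h, class = "tfa_hyper")
}

#' @export
print.tfa_hyper <- function(x, ...) {
  cat("TFA hyperparameters\n")
  cat(sprintf("  voxel noise sd:        %.4g\n", x$noise_sd))
  cat(sprintf("  weight prior:          N(%.3g, sd %.3g)\n",
              x$weight_mean, exp(-x$weight_log_precision / 2)))
  cat(sprintf("  center prior mean:     (%s)\n",
              paste(signif(x$center_mean, 4), collapse = ", ")))
  cat(sprintf("  center prior sd:       (%s)\n",
              paste(signif(exp(-x$center_log_precision / 2), 4), collapse = ", ")))
  cat(sprintf("  log-width prior:       N(%.3g, sd %.3g)\n",
              x$width_mean, exp(-x$width_log_precision / 2)))
  invisible(x)
}
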
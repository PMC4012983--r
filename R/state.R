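#' Variational state
#'
#' Holds one (mean, log precision) pair for every latent variable of the
#' model — per-image weights, source centers, source log widths — plus the
#' squared-gradient accumulators driving the adaptive learning rates and the
#' iteration counter. Variances are `exp(-log_precision)` throughout.
#'
#' @param weight_mean,weight_log_precision N x K matrices.
#' @param center_mean,center_log_precision K x D matrices.
#' @param width_mean,width_log_precision Length-K vectors.
#' @return An object of class `"tfa_state"`.
#' @export
tfa_state <- function(weight_mean, weight_log_precision,
                      center_mean, center_log_precision,
                      width_mean, width_log_precision) {
  weight_mean <- as_matrix(weight_mean, "weight_mean")
  weight_log_precision <- as_matrix(weight_log_precision, "weight_log_precision")
  center_mean <- as_matrix(center_mean, "center_mean")
  center_log_precision <- as_matrix(center_log_precision, "center_log_precision")
  width_mean <- as.numeric(width_mean)
  width_log_precision <- as.numeric(width_log_precision)
  check_finite(width_mean, "width_mean")
  check_finite(width_log_precision, "width_log_precision")
  K <- nrow(center_mean)
  stopifnot(identical(dim(weight_mean), dim(weight_log_precision)),
            identical(dim(center_mean), dim(center_log_precision)),
            ncol(weight_mean) == K,
            length(width_mean) == K,
            length(width_log_precision) == K)
  zeros <- function(x) array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  structure(list(
    weight_mean = weight_mean,
    weight_log_precision = weight_log_precision,
    center_mean = center_mean,
    center_log_precision = center_log_precision,
    width_mean = width_mean,
    width_log_precision = width_log_precision,
    grad_sq = list(weight_mean = zeros(weight_mean),
                   weight_log_precision = zeros(weight_log_precision),
                   center_mean = zeros(center_mean),
                   center_log_precision = zeros(center_log_precision),
                   width_mean = zeros(width_mean),
                   width_log_precision = zeros(width_log_precision)),
    iteration = 0L), class = "tfa_state")
}

#' @export
print.tfa_state <- function(x, ...) {
  cat(sprintf("TFA variational state: N = %d images, K = %d sources, %d-D (iteration %d)\n",
              nrow(x$weight_mean), ncol(x$weight_mean), ncol(x$center_mean),
              x$iteration))
  invisible(x)
}

# Names/order of the flattened parameter vector over an image subset:
# weight means, weight log precisions (column-major over the subset rows),
# then center means, center log precisions, width means, width log
# precisions. Used by the score matrix and the exported gradient op.
state_param_groups <- function(state, image_subset) {
  Np <- length(image_subset)
  K <- ncol(state$weight_mean)
  D <- ncol(state$center_mean)
  list(weight_mean = Np * K, weight_log_precision = Np * K,
       center_mean = K * D, center_log_precision = K * D,
       width_mean = K, width_log_precision = K)
}

#' Extract point estimates from a variational state
#'
#' The variational means of the global factors as a [tfa_sources] object.
#' @param state A [tfa_state].
#' @return A [tfa_sources] object.
#' @export
state_sources <- function(state) {
  tfa_sources(state$center_mean, state$width_mean)
}
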
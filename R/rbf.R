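#' Evaluate a spherical Gaussian radial basis function
#'
#' Each latent source is an isotropic Gaussian RBF with a center \eqn{\mu}
#' and a log width \eqn{\lambda}. Its activation at a location \eqn{r} is
#' \deqn{f(r; \mu, \lambda) = \exp\left(-\frac{\|r - \mu\|^2}{e^{\lambda}}\right),}
#' so \eqn{e^{\lambda}} is a squared length scale and the value lies in
#' \eqn{(0, 1]}, reaching 1 exactly at the center. Parameterizing the width on
#' the log scale keeps it unrestricted during stochastic optimization.
#'
#' @param center Numeric vector of length D (source center coordinates).
#' @param log_width Scalar log squared-length-scale \eqn{\lambda}.
#' @param location Numeric vector of length D, or a matrix with D columns to
#'   evaluate many locations at once.
#' @return A scalar in \eqn{(0, 1]}, or a vector with one value per row of
#'   `location`.
#' @examples
#' rbf_evaluate(c(0, 0, 0), log_width = 0, location = c(1, 0, 0))
#' @seealso [rbf_basis()]
#' @export
rbf_evaluate <- function(center, log_width, location) {
  center <- as.numeric(center)
  check_finite(center, "center")
  if (length(log_width) != 1L || !is.finite(log_width)) {
    stop("`log_width` must be a single finite number", call. = FALSE)
  }
  if (is.matrix(location)) {
    check_finite(location, "location")
    if (ncol(location) != length(center)) {
      stop("`location` must have one column per center coordinate", call. = FALSE)
    }
    d2 <- colSums((t(location) - center)^2)
  } else {
    location <- as.numeric(location)
    check_finite(location, "location")
    if (length(location) != length(center)) {
      stop("`center` and `location` must have the same length", call. = FALSE)
    }
    d2 <- sum((location - center)^2)
  }
  exp(-d2 / exp(log_width))
}

#' Build the K x V basis (source image) matrix
#'
#' Row k holds source k's RBF evaluated at every voxel location: the matrix
#' `F` whose weighted row sums reconstruct images.
#'
#' @param sources A [tfa_sources] object, or a list with elements `centers`
#'   (K x D) and `log_widths` (length K).
#' @param coords V x D matrix of voxel coordinates.
#' @return A K x V numeric matrix with entries in \eqn{(0, 1]}.
#' @export
rbf_basis <- function(sources, coords) {
  centers <- as_matrix(sources$centers, "centers")
  log_widths <- as.numeric(sources$log_widths)
  check_finite(log_widths, "log_widths")
  coords <- as_matrix(coords, "coords")
  if (ncol(centers) != ncol(coords)) {
    stop(sprintf("centers have %d dimensions but coords have %d",
                 ncol(centers), ncol(coords)), call. = FALSE)
  }
  if (nrow(centers) != length(log_widths)) {
    stop("one log width is required per center", call. = FALSE)
  }
  K <- nrow(centers)
  V <- nrow(coords)
  # squared distances via the expansion ||r||^2 - 2 mu'r + ||mu||^2
  cross <- centers %*% t(coords)                       # K x V
  d2 <- outer(rowSums(centers^2), rep(1, V)) - 2 * cross +
    outer(rep(1, K), rowSums(coords^2))
  d2[d2 < 0] <- 0                                      # numerical guard
  exp(-d2 / exp(log_widths))
}

#' Source parameter container
#'
#' Bundles the global latent variables of the model: K source centers and
#' K log widths. Centers are in the same units as the voxel coordinates and
#' need not lie inside the brain mask.
#'
#' @param centers K x D numeric matrix.
#' @param log_widths Numeric vector of length K.
#' @return An object of class `"tfa_sources"`.
#' @export
tfa_sources <- function(centers, log_widths) {
  centers <- as_matrix(centers, "centers")
  log_widths <- as.numeric(log_widths)
  check_finite(log_widths, "log_widths")
  if (nrow(centers) < 1L) stop("at least one source is required", call. = FALSE)
  if (!ncol(centers) %in% c(2L, 3L)) {
    stop("source centers must be 2- or 3-dimensional", call. = FALSE)
  }
  if (length(log_widths) != nrow(centers)) {
    stop("`log_widths` must have one entry per center", call. = FALSE)
  }
  structure(list(centers = centers, log_widths = log_widths),
            class = "tfa_sources")
}

#' @export
print.tfa_sources <- function(x, ...) {
  K <- nrow(x$centers)
  cat(sprintf("TFA source set: %d source%s in %d-D\n", K,
              if (K == 1L) "" else "s", ncol(x$centers)))
  tab <- data.frame(x$centers, log_width = x$log_widths,
                    length_scale = sqrt(exp(x$log_widths)))
  names(tab)[seq_len(ncol(x$centers))] <- paste0("c", seq_len(ncol(x$centers)))
  print(utils::head(tab, 10L), digits = 4)
  if (K > 10L) cat(sprintf("... and %d more\n", K - 10L))
  invisible(x)
}
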
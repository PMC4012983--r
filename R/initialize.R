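# Hotspot initialization: deterministic placement of source centers and
# widths from the centered, folded mean image, plus regression weights.

#' Centered and folded mean image
#'
#' Averages the images, subtracts the scalar mean of that average, and takes
#' absolute values, so that both strongly positive and strongly negative
#' regions of the mean image appear as non-negative peaks ("hotspots").
#'
#' @param data A [tfa_dataset].
#' @return A list of class `"tfa_folded"` with `values` (length V,
#'   non-negative) and `coords` (V x D).
#' @export
fold_mean_image <- function(data) {
  data <- as_tfa_dataset(data)
  m <- colMeans(data$activations)
  structure(list(values = abs(m - mean(m)), coords = data$coords),
            class = "tfa_folded")
}

#' Fit a single source width to a folded image by scalar optimization
#'
#' With the center fixed at a hotspot and the amplitude fixed at the folded
#' value of the peak voxel, minimizes the sum of squared differences between
#' the folded image and the amplitude-scaled RBF over the log width alone —
#' a bounded one-dimensional convex-style search solved by [stats::optimize()].
#' The search interval is `[log(0.25 s^2), log(4 span^2)]` where `s` is the
#' voxel spacing and `span` the bounding-box diagonal of the coordinates.
#'
#' @param folded A `"tfa_folded"` object (or any list with `values` and
#'   `coords`), typically a residual image during hotspot placement.
#' @param center Length-D center at which the source sits.
#' @param amplitude Amplitude multiplying the RBF; defaults to the folded
#'   value at the voxel nearest `center`.
#' @return The fitted log width (scalar).
#' @export
fit_width_scalar <- function(folded, center, amplitude = NULL) {
  values <- as.numeric(folded$values)
  coords <- as_matrix(folded$coords, "coords")
  center <- as.numeric(center)
  check_finite(center, "center")
  if (all(values == 0)) {
    stop("folded image is identically zero: no hotspot to fit", call. = FALSE)
  }
  d2 <- colSums((t(coords) - center)^2)
  if (is.null(amplitude)) amplitude <- values[which.min(d2)]
  s <- voxel_spacing(coords)
  span2 <- sum((apply(coords, 2L, max) - apply(coords, 2L, min))^2)
  lo <- log(0.25 * s^2)
  hi <- log(4 * max(span2, s^2))
  obj <- function(lw) sum((values - amplitude * exp(-d2 / exp(lw)))^2)
  stats::optimize(obj, interval = c(lo, hi), tol = 1e-7)$minimum
}

#' Hotspot initialization of source centers and widths
#'
#' Places K sources one at a time on the centered, folded mean image: the
#' next center goes at the current residual's peak voxel (ties broken by
#' lowest voxel index), the width is fit by [fit_width_scalar()], and the
#' amplitude-scaled source image is subtracted before placing the next
#' source. The image is folded only once at the start; residuals are used
#' as-is afterwards and may go negative where a source over-explains.
#'
#' @param data A [tfa_dataset].
#' @param K Number of sources to place.
#' @return A [tfa_sources] object with attributes `amplitudes` (per-source
#'   peak amplitudes) and `residual_norms` (residual sum of squares after
#'   each placement, preceded by the initial value).
#' @export
hotspot_init <- function(data, K) {
  data <- as_tfa_dataset(data)
  stopifnot(K >= 1L)
  folded <- fold_mean_image(data)
  residual <- folded$values
  coords <- folded$coords
  D <- ncol(coords)
  centers <- matrix(NA_real_, K, D)
  log_widths <- numeric(K)
  amplitudes <- numeric(K)
  norms <- numeric(K + 1L)
  norms[1L] <- sum(residual^2)
  used <- integer(0)
  for (k in seq_len(K)) {
    if (all(residual <= 0)) {
      warning(sprintf(
        "residual exhausted after %d source(s); placing the rest at the largest residual magnitudes",
        k - 1L), call. = FALSE)
      remaining <- setdiff(order(-abs(residual)), used)
      for (kk in k:K) {
        peak <- remaining[kk - k + 1L]
        centers[kk, ] <- coords[peak, ]
        amplitudes[kk] <- abs(residual[peak])
        log_widths[kk] <- fit_width_scalar(
          list(values = abs(residual), coords = coords),
          coords[peak, ], amplitudes[kk])
        norms[kk + 1L] <- norms[k]
        used <- c(used, peak)
      }
      break
    }
    peak <- which.max(residual)   # ties: lowest index
    centers[k, ] <- coords[peak, ]
    amplitudes[k] <- residual[peak]
    log_widths[k] <- fit_width_scalar(
      list(values = residual, coords = coords), coords[peak, ], amplitudes[k])
    residual <- residual - amplitudes[k] *
      rbf_evaluate(coords[peak, ], log_widths[k], coords)
    norms[k + 1L] <- sum(residual^2)
    used <- c(used, peak)
  }
  src <- tfa_sources(centers, log_widths)
  attr(src, "amplitudes") <- amplitudes
  attr(src, "residual_norms") <- norms
  src
}

#' Least-squares source weights
#'
#' Solves, per image, the ordinary least squares problem
#' \eqn{y_n \approx w_n F}, i.e. \eqn{W = Y F^\top (F F^\top)^{-1}}. With a
#' rank-deficient \eqn{F F^\top} (e.g. two coincident sources) the
#' pseudoinverse is used with a warning.
#'
#' @param data A [tfa_dataset], or an N x V activation matrix.
#' @param basis K x V basis matrix from [rbf_basis()].
#' @param image_subset `"all"` or image indices to solve for.
#' @return An N' x K weight matrix.
#' @export
solve_weights <- function(data, basis, image_subset = "all") {
  Y <- if (inherits(data, c("tfa_dataset", "tfa_bundle"))) {
    as_tfa_dataset(data)$activations
  } else {
    as_matrix(data, "data")
  }
  img <- resolve_subset(image_subset, nrow(Y), "image_subset")
  Y <- Y[img, , drop = FALSE]
  if (ncol(basis) != ncol(Y)) {
    stop(sprintf("basis has %d voxels but data has %d", ncol(basis), ncol(Y)),
         call. = FALSE)
  }
  G <- basis %*% t(basis)
  B <- basis %*% t(Y)
  W <- tryCatch(t(solve(G, B)), error = function(e) {
    warning("basis Gram matrix is rank deficient; using the pseudoinverse",
            call. = FALSE)
    t(MASS::ginv(G) %*% B)
  })
  unname(W)
}

#' Initialize the variational state
#'
#' Hotspot mode (deterministic): centers and widths from [hotspot_init()],
#' weight means from [solve_weights()] on the full image set. Random mode:
#' one draw of all means from the prior via [tfa_sample_generative()].
#' Initial log precisions come from the control settings; unset values
#' default to a weight sd of 0.1, a center sd of half a voxel spacing, and
#' a log-width sd of 0.25.
#'
#' @param data A [tfa_dataset].
#' @param K Number of sources.
#' @param mode `"hotspot"` or `"random"`.
#' @param hyper A [tfa_hyper]; defaults from the dataset's coordinates.
#' @param control A [tfa_control].
#' @param seed Seed for random mode (ignored by hotspot mode, which is
#'   deterministic).
#' @return A [tfa_state].
#' @export
initialize_state <- function(data, K, mode = c("hotspot", "random"),
                             hyper = NULL, control = tfa_control(),
                             seed = 1L) {
  data <- as_tfa_dataset(data)
  mode <- match.arg(mode)
  if (is.null(hyper)) hyper <- tfa_hyper(data$coords)
  N <- nrow(data$activations)
  D <- ncol(data$coords)
  if (mode == "hotspot") {
    src <- hotspot_init(data, K)
    W <- solve_weights(data, rbf_basis(src, data$coords))
  } else {
    draw <- tfa_sample_generative(K, hyper, data$coords, N, seed = seed)
    src <- draw$sources
    W <- draw$weights
  }
  spacing <- voxel_spacing(data$coords)
  wlp <- control$init_weight_log_precision %||% (-2 * log(0.1))
  clp <- control$init_center_log_precision %||% (-2 * log(spacing / 2))
  llp <- control$init_width_log_precision %||% (-2 * log(0.25))
  tfa_state(weight_mean = W,
            weight_log_precision = matrix(wlp, N, K),
            center_mean = src$centers,
            center_log_precision = matrix(clp, K, D),
            width_mean = src$log_widths,
            width_log_precision = rep(llp, K))
}

#' Write a per-source initialization report
#'
#' Tab-separated table of center coordinates, log widths and peak
#' amplitudes for a hotspot-initialized source set.
#'
#' @param sources Result of [hotspot_init()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_init_report <- function(sources, path) {
  D <- ncol(sources$centers)
  tab <- data.frame(source = seq_len(nrow(sources$centers)), sources$centers,
                    log_width = sources$log_widths,
                    amplitude = attr(sources, "amplitudes") %||%
                      rep(NA_real_, nrow(sources$centers)))
  names(tab)[1L + seq_len(D)] <- c("x", "y", "z")[seq_len(D)]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
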
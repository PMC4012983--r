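# S3 methods for fitted "tfa" objects.

#' @export
print.tfa <- function(x, ...) {
  N <- nrow(x$data$activations); V <- ncol(x$data$activations)
  cat(sprintf("Topographic factor analysis fit: K = %d sources, %d images x %d voxels\n",
              x$K, N, V))
  cat(sprintf("  init: %s | iterations: %d | converged: %s\n",
              x$init, x$state$iteration, x$converged))
  if (length(x$elbo_trace)) {
    cat(sprintf("  smoothed ELBO (last %d iters): %.6g\n",
                min(length(x$elbo_trace), x$control$window),
                moving_avg(x$elbo_trace, x$control$window)))
  }
  invisible(x)
}

#' @export
summary.tfa <- function(object, ...) {
  res <- residuals(object)
  out <- list(K = object$K,
              n_images = nrow(object$data$activations),
              n_voxels = ncol(object$data$activations),
              iterations = object$state$iteration,
              converged = object$converged,
              elbo = if (length(object$elbo_trace)) {
                moving_avg(object$elbo_trace, object$control$window)
              } else NA_real_,
              rmse = sqrt(mean(res^2)),
              var_explained = 1 - sum(res^2) / sum(scale(object$data$activations,
                                                         scale = FALSE)^2),
              sources = data.frame(
                source = seq_len(object$K),
                object$sources$centers,
                log_width = object$sources$log_widths,
                length_scale = sqrt(exp(object$sources$log_widths)),
                weight_sd = apply(object$weights, 2L, sd)))
  D <- ncol(object$sources$centers)
  names(out$sources)[1L + seq_len(D)] <- c("x", "y", "z")[seq_len(D)]
  class(out) <- "summary.tfa"
  out
}

#' @export
print.summary.tfa <- function(x, ...) {
  cat(sprintf("TFA fit: K = %d, %d images x %d voxels (%d iterations%s)\n",
              x$K, x$n_images, x$n_voxels, x$iterations,
              if (x$converged) ", converged" else ""))
  cat(sprintf("  smoothed ELBO %.6g | reconstruction RMSE %.4g | variance explained %.1f%%\n",
              x$elbo, x$rmse, 100 * x$var_explained))
  cat("Sources (variational means):\n")
  print(x$sources, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tfa <- function(object, type = c("sources", "weights"), ...) {
  type <- match.arg(type)
  if (type == "weights") return(object$weights)
  cbind(object$sources$centers, log_width = object$sources$log_widths)
}

#' @export
fitted.tfa <- function(object, ...) {
  tfa_reconstruct(object$sources, object$weights, object$data$coords)
}

#' @export
residuals.tfa <- function(object, ...) {
  object$data$activations - fitted(object)
}

#' Predict activations at (possibly new) voxel locations
#'
#' Because sources are spatial functions, a fitted model predicts
#' activation at any coordinate, including voxels never seen during
#' fitting: the prediction is the weighted sum of the fitted source RBFs
#' evaluated there.
#'
#' @param object A fitted [tfa] object.
#' @param newcoords Optional V* x D matrix of locations; defaults to the
#'   training coordinates.
#' @param images Optional image indices to predict for (default all).
#' @param ... Unused.
#' @return An N' x V* matrix of predicted activations.
#' @export
predict.tfa <- function(object, newcoords = NULL, images = NULL, ...) {
  coords <- if (is.null(newcoords)) object$data$coords else
    as_matrix(newcoords, "newcoords")
  img <- resolve_subset(images %||% "all", nrow(object$weights), "images")
  tfa_reconstruct(object$sources, object$weights[img, , drop = FALSE], coords)
}

#' Simulate image series from a fitted model
#'
#' Posterior-predictive simulation: each replicate draws the latent
#' variables from the fitted variational distribution and adds i.i.d.
#' Gaussian voxel noise at the model's noise level.
#'
#' @param object A fitted [tfa] object.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` activation matrices (N x V).
#' @export
simulate.tfa <- function(object, nsim = 1, seed = NULL, ...) {
  st <- object$state
  N <- nrow(st$weight_mean)
  local_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      smp <- sample_q(st, 1L)
      src <- tfa_sources(matrix(smp$centers[1L, , ], nrow = object$K),
                         smp$log_widths[1L, ])
      W <- matrix(smp$weights[1L, , ], nrow = N)
      mu <- tfa_reconstruct(src, W, object$data$coords)
      mu + matrix(rnorm(length(mu), 0, object$hyper$noise_sd), nrow = N)
    })
  })
}

#' Plot a fitted TFA model
#'
#' Two panels: the stochastic ELBO trace with its moving average, and a
#' spatial map of the fitted sources (centers as circles with radius equal
#' to the RBF length scale) over the voxel cloud, projected onto the first
#' two coordinate dimensions.
#'
#' @param x A fitted [tfa] object.
#' @param ... Passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.tfa <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  tr <- x$elbo_trace
  if (length(tr)) {
    plot(tr, type = "l", col = "grey60", xlab = "iteration",
         ylab = "ELBO estimate", main = "optimization trace", ...)
    w <- min(x$control$window, length(tr))
    sm <- stats::filter(tr, rep(1 / w, w), sides = 1)
    lines(as.numeric(sm), col = "firebrick", lwd = 2)
  } else {
    plot.new(); text(0.5, 0.5, "no trace")
  }
  plot(x$data$coords[, 1L], x$data$coords[, 2L], pch = ".", col = "grey70",
       xlab = "dim 1", ylab = "dim 2", main = "fitted sources", asp = 1)
  symbols(x$sources$centers[, 1L], x$sources$centers[, 2L],
          circles = sqrt(exp(x$sources$log_widths)), inches = FALSE,
          add = TRUE, fg = "firebrick", lwd = 2)
  invisible(x)
}
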
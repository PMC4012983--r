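#' Fitting configuration
#'
#' Collects the tunables of the stochastic variational fitting loop.
#'
#' @param samples Monte Carlo samples per update (`M`; default 500). At
#'   least 2 (the control variates estimate a covariance per batch).
#' @param image_subsample Images drawn per iteration (`N'`); `NULL` means
#'   `min(100, N)`.
#' @param voxel_subsample Contiguous voxels drawn per iteration (`V'`);
#'   `NULL` means `min(1000, V)`. Contiguity is realized as the `V'` voxels
#'   nearest (Euclidean) to a uniformly drawn seed voxel, which respects
#'   arbitrary masks.
#' @param max_step_size Per-coordinate cap on the applied step (default 1).
#' @param rate_scale Master numerator of the adaptive learning rate
#'   (default 0.1). The rate for a coordinate is
#'   `rate_scale / (adagrad_delta + sqrt(accumulated squared gradients))`;
#'   the resulting step is additionally clipped at `max_step_size`.
#' @param adagrad_delta Small positive constant guarding the adaptive rate
#'   denominator (default 1e-6).
#' @param max_iter Cap on outer iterations (default 200).
#' @param tol Relative-change tolerance on the moving-average ELBO trace
#'   (default 1e-4).
#' @param window Moving-average window for convergence smoothing
#'   (default 25).
#' @param divergence Abort if the smoothed ELBO worsens from its best value
#'   by more than this multiple of the trace's spread (default 10; `Inf`
#'   disables the guard).
#' @param final_max_iter Iteration cap for the closing full-data weight
#'   update (default 400).
#' @param final_window Smoothing window during the final update (default 20).
#' @param final_average Average the weight parameters over the last
#'   `final_window` iterations of the final update (tail/Polyak averaging;
#'   default `TRUE`), damping the residual stochastic jitter.
#' @param weight_resolve Re-solve the in-scope weight means by least squares
#'   after every global-parameter update (default `TRUE`).
#' @param init_weight_log_precision,init_center_log_precision,init_width_log_precision
#'   Initial variational log precisions. `NULL` picks data-scaled defaults:
#'   weight sd 0.1, center sd half a voxel spacing, log-width sd 0.25.
#' @param verbose Emit per-iteration progress messages.
#' @return A list of class `"tfa_control"`.
#' @export
tfa_control <- function(samples = 500L,
                        image_subsample = NULL,
                        voxel_subsample = NULL,
                        max_step_size = 1,
                        rate_scale = 0.1,
                        adagrad_delta = 1e-6,
                        max_iter = 200L,
                        tol = 1e-4,
                        window = 25L,
                        divergence = 10,
                        final_max_iter = 400L,
                        final_window = 20L,
                        final_average = TRUE,
                        weight_resolve = TRUE,
                        init_weight_log_precision = NULL,
                        init_center_log_precision = NULL,
                        init_width_log_precision = NULL,
                        verbose = FALSE) {
  samples <- as.integer(samples)
  if (samples < 2L) stop("`samples` must be at least 2", call. = FALSE)
  if (max_step_size <= 0) stop("`max_step_size` must be positive", call. = FALSE)
  if (rate_scale <= 0) stop("`rate_scale` must be positive", call. = FALSE)
  if (adagrad_delta <= 0) stop("`adagrad_delta` must be positive", call. = FALSE)
  structure(list(samples = samples,
                 image_subsample = image_subsample,
                 voxel_subsample = voxel_subsample,
                 max_step_size = max_step_size,
                 rate_scale = rate_scale,
                 adagrad_delta = adagrad_delta,
                 max_iter = as.integer(max_iter),
                 tol = tol,
                 window = as.integer(window),
                 divergence = divergence,
                 final_max_iter = as.integer(final_max_iter),
                 final_window = as.integer(final_window),
                 final_average = isTRUE(final_average),
                 weight_resolve = isTRUE(weight_resolve),
                 init_weight_log_precision = init_weight_log_precision,
                 init_center_log_precision = init_center_log_precision,
                 init_width_log_precision = init_width_log_precision,
                 verbose = isTRUE(verbose)),
            class = "tfa_control")
}
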
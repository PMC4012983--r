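# The stochastic variational fitting loop and the closing full-data update
# of the per-image weight factors.

moving_avg <- function(x, window) {
  n <- length(x)
  mean(x[max(1L, n - window + 1L):n])
}

# One pass of the optimization loop. Updates `state` in place (by value) and
# returns it with the ELBO trace. The same sample batch is reused for every
# parameter update within an iteration; weight-parameter gradients use the
# per-image part of the objective (terms not involving an image have zero
# expected contribution to its score gradient), global parameters use the
# full subsampling-scaled objective.
fit_variational <- function(data, state, hyper, control, seed = 1L) {
  data <- as_tfa_dataset(data)
  N <- nrow(data$activations)
  V <- ncol(data$activations)
  K <- ncol(state$weight_mean)
  D <- ncol(state$center_mean)
  Np <- min(control$image_subsample %||% min(100L, N), N)
  Vp <- min(control$voxel_subsample %||% min(1000L, V), V)
  M <- control$samples
  delta <- control$adagrad_delta
  ms <- control$max_step_size
  rs <- control$rate_scale %||% ms
  trace <- numeric(0)
  best_avg <- -Inf
  converged <- FALSE
  # tail (Polyak-style) averages of the global parameters over the last
  # `window` iterations, damping the stationary jitter of the sign-like
  # early AdaGrad steps
  gtail <- vector("list", control$window)

  local_seed(seed, {
    for (t in seq_len(control$max_iter)) {
      img <- sample.int(N, Np)
      vox <- contiguous_voxel_subset(data$coords, Vp)
      smp <- sample_q(state, M, img)
      lq_pieces <- log_q_pieces(state, smp)
      lq_w_rows <- matrix(
        rowSums(array(lq_pieces$weights, dim = c(M, Np, K)), dims = 2L),
        nrow = M)
      lq_total <- rowSums(lq_pieces$weights) + rowSums(lq_pieces$centers) +
        rowSums(lq_pieces$log_widths)
      lj <- log_joint_samples(state, smp, data, hyper, vox)
      f_full <- lj$logp - lq_total
      f_img <- lj$scale_vox * lj$loglik_rows + lj$prior_w_rows - lq_w_rows

      h <- score_matrix(state, smp)
      nw <- Np * K
      f_cols <- cbind(f_img[, rep(seq_len(Np), times = K), drop = FALSE],
                      f_img[, rep(seq_len(Np), times = K), drop = FALSE],
                      matrix(f_full, M, 2L * K * D + 2L * K))
      adj <- control_variate_adjust(h * f_cols, h)
      g <- colMeans(adj$adjusted)

      # unpack, accumulate, step (clipped per coordinate)
      sizes <- unlist(state_param_groups(state, img))
      ends <- cumsum(sizes)
      starts <- ends - sizes + 1L
      take <- function(i) g[starts[i]:ends[i]]
      upd <- function(gpart, acc) {
        acc <- acc + gpart^2
        step <- adagrad_rate(acc, rs, delta) * gpart
        list(step = pmin(pmax(step, -ms), ms), acc = acc)
      }
      u <- upd(matrix(take(1L), Np, K), state$grad_sq$weight_mean[img, , drop = FALSE])
      state$weight_mean[img, ] <- state$weight_mean[img, , drop = FALSE] + u$step
      state$grad_sq$weight_mean[img, ] <- u$acc
      u <- upd(matrix(take(2L), Np, K),
               state$grad_sq$weight_log_precision[img, , drop = FALSE])
      state$weight_log_precision[img, ] <-
        state$weight_log_precision[img, , drop = FALSE] + u$step
      state$grad_sq$weight_log_precision[img, ] <- u$acc
      u <- upd(matrix(take(3L), K, D), state$grad_sq$center_mean)
      state$center_mean <- state$center_mean + u$step
      state$grad_sq$center_mean <- u$acc
      u <- upd(matrix(take(4L), K, D), state$grad_sq$center_log_precision)
      state$center_log_precision <- state$center_log_precision + u$step
      state$grad_sq$center_log_precision <- u$acc
      u <- upd(take(5L), state$grad_sq$width_mean)
      state$width_mean <- state$width_mean + u$step
      state$grad_sq$width_mean <- u$acc
      u <- upd(take(6L), state$grad_sq$width_log_precision)
      state$width_log_precision <- state$width_log_precision + u$step
      state$grad_sq$width_log_precision <- u$acc

      # re-solve the in-scope weight means against the updated sources:
      # the regression solution is reliably at (or extremely near) a local
      # optimum, which stabilizes the loop after every global update
      if (control$weight_resolve) {
        Fm <- rbf_basis(state_sources(state), data$coords)
        state$weight_mean[img, ] <- solve_weights(data, Fm, img)
      }
      state$iteration <- state$iteration + 1L
      trace <- c(trace, mean(f_full))
      gtail[[1L + (t - 1L) %% control$window]] <-
        list(cm = state$center_mean, clp = state$center_log_precision,
             wm = state$width_mean, wlp = state$width_log_precision)

      w <- control$window
      if (t >= w) {
        avg <- moving_avg(trace, w)
        spread <- stats::sd(trace) + 1e-12
        if (avg > best_avg) best_avg <- avg
        if (is.finite(control$divergence) &&
            avg < best_avg - control$divergence * spread) {
          stop(sprintf(
            "optimization diverged at iteration %d (smoothed ELBO %.4g, best %.4g)",
            t, avg, best_avg), call. = FALSE)
        }
        if (control$verbose) {
          message(sprintf("iter %4d | elbo(smoothed) %.6g | step-norm %.3g",
                          t, avg, sqrt(sum(g^2))))
        }
        if (t >= 2L * w) {
          prev <- mean(trace[(t - 2L * w + 1L):(t - w)])
          if (abs(avg - prev) < control$tol * (abs(prev) + 1e-8)) {
            converged <- TRUE
            break
          }
        }
      }
    }
    snaps <- Filter(Negate(is.null), gtail)
    if (length(snaps) > 1L) {
      avg_of <- function(nm) Reduce(`+`, lapply(snaps, `[[`, nm)) / length(snaps)
      state$center_mean <- avg_of("cm")
      state$center_log_precision <- avg_of("clp")
      state$width_mean <- avg_of("wm")
      state$width_log_precision <- avg_of("wlp")
      if (control$weight_resolve) {
        Fm <- rbf_basis(state_sources(state), data$coords)
        state$weight_mean <- solve_weights(data, Fm)
      }
    }
    list(state = state, elbo_trace = trace, converged = converged)
  })
}

#' Final full-data update of the per-image weights
#'
#' Image subsampling means some images may never have been drawn during the
#' main loop, so their weight factors still sit at initialization. The
#' final update freezes the global parameters (centers and widths), takes
#' the image subset to be all N images and the voxel subset to be all V
#' voxels, and re-runs the stochastic updates on the per-image weight
#' means and log precisions alone until they converge. The basis matrix is
#' evaluated once at the frozen center/width means, making the N weight
#' subproblems independent; sufficient statistics (`F F'`, `F Y'`) reduce
#' each Monte Carlo evaluation to K x K quadratic forms.
#'
#' @param state A [tfa_state] from a completed fit.
#' @param data The [tfa_dataset] that was fit.
#' @param hyper A [tfa_hyper].
#' @param control A [tfa_control]; `final_max_iter`, `final_window`,
#'   `final_average` and `tol` govern this phase.
#' @param seed Integer seed.
#' @return The updated [tfa_state], with attribute `elbo_trace` for the
#'   update phase.
#' @export
tfa_final_update <- function(state, data, hyper, control = tfa_control(),
                             seed = 1L) {
  data <- as_tfa_dataset(data)
  Y <- data$activations
  N <- nrow(Y); V <- ncol(Y); K <- ncol(state$weight_mean)
  M <- control$samples
  delta <- control$adagrad_delta
  ms <- control$max_step_size
  rs <- control$rate_scale %||% ms
  Fm <- rbf_basis(state_sources(state), data$coords)
  G <- Fm %*% t(Fm)                      # K x K
  B <- Fm %*% t(Y)                       # K x N
  yss <- rowSums(Y^2)                    # N
  lp_n <- hyper$noise_log_precision
  const_row <- 0.5 * V * (lp_n - log(2 * pi))
  globals_before <- list(cm = state$center_mean, clp = state$center_log_precision,
                         wm = state$width_mean, wlp = state$width_log_precision)
  trace <- numeric(0)
  w <- control$final_window
  tail_mean <- NULL
  tail_lp <- NULL
  tail_n <- 0L
  local_seed(seed, {
    for (t in seq_len(control$final_max_iter)) {
      mu <- rep(as.vector(state$weight_mean), each = M)
      sdv <- rep(exp(-as.vector(state$weight_log_precision) / 2), each = M)
      Wfl <- matrix(rnorm(M * N * K, mu, sdv), nrow = M)   # cols: (n,k) pairs
      Warr <- array(Wfl, dim = c(M, N, K))
      # SSE_mn = ||y_n||^2 - 2 w'B_n + w'Gw, expanded over the K^2 terms
      quad <- matrix(0, M, N)
      lin <- matrix(0, M, N)
      for (i in seq_len(K)) {
        lin <- lin + sweep(Warr[, , i, drop = FALSE][, , 1L], 2L, B[i, ], `*`)
        for (j in seq_len(K)) {
          quad <- quad + G[i, j] *
            Warr[, , i, drop = FALSE][, , 1L] * Warr[, , j, drop = FALSE][, , 1L]
        }
      }
      sse <- sweep(quad - 2 * lin, 2L, yss, `+`)
      loglik <- const_row - 0.5 * exp(lp_n) * sse                 # M x N
      prior <- matrix(rowSums(array(
        gauss_logdens(Warr, hyper$weight_mean, hyper$weight_log_precision),
        dim = c(M, N, K)), dims = 2L), nrow = M)
      lpv <- rep(as.vector(state$weight_log_precision), each = M)
      lq_cols <- gauss_logdens(Wfl, mu, lpv)
      lq_rows <- matrix(rowSums(array(lq_cols, dim = c(M, N, K)), dims = 2L),
                        nrow = M)
      f_img <- loglik + prior - lq_rows                           # M x N
      h_mean <- gauss_score_mean(Wfl, mu, lpv)
      h_lp <- gauss_score_lp(Wfl, mu, lpv)
      fc <- f_img[, rep(seq_len(N), times = K), drop = FALSE]
      adj_m <- control_variate_adjust(h_mean * fc, h_mean)
      adj_l <- control_variate_adjust(h_lp * fc, h_lp)
      g_mean <- matrix(colMeans(adj_m$adjusted), N, K)
      g_lp <- matrix(colMeans(adj_l$adjusted), N, K)
      state$grad_sq$weight_mean <- state$grad_sq$weight_mean + g_mean^2
      state$grad_sq$weight_log_precision <-
        state$grad_sq$weight_log_precision + g_lp^2
      step_m <- adagrad_rate(state$grad_sq$weight_mean, rs, delta) * g_mean
      step_l <- adagrad_rate(state$grad_sq$weight_log_precision, rs, delta) * g_lp
      state$weight_mean <- state$weight_mean + pmin(pmax(step_m, -ms), ms)
      state$weight_log_precision <- state$weight_log_precision +
        pmin(pmax(step_l, -ms), ms)
      state$iteration <- state$iteration + 1L
      trace <- c(trace, mean(rowSums(f_img)))
      if (control$final_average && t > control$final_max_iter - w) {
        tail_mean <- if (is.null(tail_mean)) state$weight_mean else
          tail_mean + state$weight_mean
        tail_lp <- if (is.null(tail_lp)) state$weight_log_precision else
          tail_lp + state$weight_log_precision
        tail_n <- tail_n + 1L
      }
      if (t >= 2L * w && !control$final_average) {
        avg <- moving_avg(trace, w)
        prev <- mean(trace[(t - 2L * w + 1L):(t - w)])
        if (abs(avg - prev) < control$tol * (abs(prev) + 1e-8)) break
      }
    }
    if (tail_n > 0L) {
      state$weight_mean <- tail_mean / tail_n
      state$weight_log_precision <- tail_lp / tail_n
    }
    stopifnot(identical(globals_before$cm, state$center_mean),
              identical(globals_before$wm, state$width_mean))
    attr(state, "elbo_trace") <- trace
    state
  })
}

#' Fit topographic factor analysis to an image series
#'
#' The main entry point. Decomposes an N x V image series into K spherical
#' Gaussian RBF sources and per-image source weights by black-box
#' stochastic variational inference: the variational parameters are
#' initialized (deterministically from the folded mean image by default),
#' optimized with score-function gradients, control variates, adaptive
#' per-parameter learning rates and image/voxel subsampling, and the
#' per-image weight factors are then brought to convergence on the full
#' data with the sources frozen.
#'
#' @param data A [tfa_dataset] (from [read_tfa_dataset()] or a synthetic
#'   generator), or a synthetic bundle.
#' @param K Number of sources to fit.
#' @param init Initialization mode, `"hotspot"` (deterministic, default) or
#'   `"random"` (one draw from the prior).
#' @param hyper A [tfa_hyper]; defaults derived from the coordinates.
#' @param control A [tfa_control].
#' @param seed Integer seed; a fit is reproducible given `(seed, control)`.
#' @param final_update Run the closing full-data weight update (default
#'   `TRUE`).
#' @return An object of class `"tfa"`: a list with the fitted `sources`
#'   (variational means), `weights` (N x K posterior-mean weights), the
#'   full variational `state`, the `elbo_trace`, and the call ingredients.
#' @examples
#' bundle <- generate_tfa_dataset(K = 2, N = 30, grid = make_grid(c(8, 8)),
#'                                seed = 1)
#' fit <- tfa(bundle, K = 2, control = tfa_control(samples = 50, max_iter = 20,
#'                                                 final_max_iter = 40),
#'            seed = 1)
#' fit
#' @export
tfa <- function(data, K, init = c("hotspot", "random"), hyper = NULL,
                control = tfa_control(), seed = 1L, final_update = TRUE) {
  data <- as_tfa_dataset(data)
  init <- match.arg(init)
  if (is.null(hyper)) hyper <- tfa_hyper(data$coords)
  state0 <- initialize_state(data, K, mode = init, hyper = hyper,
                             control = control, seed = seed)
  fv <- fit_variational(data, state0, hyper, control, seed = seed)
  state <- fv$state
  final_trace <- numeric(0)
  if (final_update) {
    state <- tfa_final_update(state, data, hyper, control, seed = seed + 1L)
    final_trace <- attr(state, "elbo_trace") %||% numeric(0)
    attr(state, "elbo_trace") <- NULL
  }
  structure(list(sources = state_sources(state),
                 weights = state$weight_mean,
                 state = state,
                 elbo_trace = fv$elbo_trace,
                 final_elbo_trace = final_trace,
                 converged = fv$converged,
                 data = data, hyper = hyper, control = control,
                 init = init, K = as.integer(K), seed = seed),
            class = "tfa")
}
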
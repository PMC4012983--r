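# Mean-field Gaussian variational family: sampling, densities, scores,
# ELBO estimation, control variates, and the adaptive learning rate.

#' Draw a batch of joint samples from the variational distribution
#'
#' Every latent variable has an independent Gaussian factor (the mean-field
#' assumption), so a joint draw simply samples each factor at its mean and
#' variance `exp(-log_precision)`. Weights are drawn only for the images in
#' scope.
#'
#' @param state A [tfa_state].
#' @param M Number of joint samples.
#' @param image_subset `"all"` or an index vector of images in scope.
#' @param seed Optional integer seed.
#' @return An object of class `"tfa_q_samples"`: a batch of `M` joint draws
#'   stored as arrays `weights` (M x N' x K), `centers` (M x K x D) and
#'   `log_widths` (M x K), with the `image_subset` attached.
#' @export
sample_q <- function(state, M, image_subset = "all", seed = NULL) {
  stopifnot(M >= 1L)
  N <- nrow(state$weight_mean)
  img <- resolve_subset(image_subset, N, "image_subset")
  Np <- length(img)
  K <- ncol(state$weight_mean)
  D <- ncol(state$center_mean)
  wm <- state$weight_mean[img, , drop = FALSE]
  wlp <- state$weight_log_precision[img, , drop = FALSE]
  local_seed(seed, {
    w <- array(rnorm(M * Np * K,
                     mean = rep(as.vector(wm), each = M),
                     sd = rep(exp(-as.vector(wlp) / 2), each = M)),
               dim = c(M, Np, K))
    cen <- array(rnorm(M * K * D,
                       mean = rep(as.vector(state$center_mean), each = M),
                       sd = rep(exp(-as.vector(state$center_log_precision) / 2),
                                each = M)),
                 dim = c(M, K, D))
    lw <- matrix(rnorm(M * K,
                       mean = rep(state$width_mean, each = M),
                       sd = rep(exp(-state$width_log_precision / 2), each = M)),
                 nrow = M)
    structure(list(weights = w, centers = cen, log_widths = lw,
                   image_subset = img, M = M),
              class = "tfa_q_samples")
  })
}

# Per-factor-group log-q matrices; rowSums give totals.
log_q_pieces <- function(state, samples) {
  img <- samples$image_subset
  M <- samples$M
  wm <- as.vector(state$weight_mean[img, , drop = FALSE])
  wlp <- as.vector(state$weight_log_precision[img, , drop = FALSE])
  Xw <- matrix(samples$weights, nrow = M)
  lq_w <- gauss_logdens(Xw, rep(wm, each = M), rep(wlp, each = M))
  cm <- as.vector(state$center_mean)
  clp <- as.vector(state$center_log_precision)
  Xc <- matrix(samples$centers, nrow = M)
  lq_c <- gauss_logdens(Xc, rep(cm, each = M), rep(clp, each = M))
  lq_l <- gauss_logdens(samples$log_widths,
                        rep(state$width_mean, each = M),
                        rep(state$width_log_precision, each = M))
  list(weights = lq_w, centers = lq_c, log_widths = lq_l)
}

#' Variational log density of a sample batch
#'
#' Sums the independent Gaussian factor log densities over all factors in
#' scope (weights for the sampled images, plus the global center and width
#' factors).
#'
#' @param state A [tfa_state].
#' @param samples A batch from [sample_q()].
#' @return A length-`M` vector of log densities, one per joint sample.
#' @export
log_q <- function(state, samples) {
  if (!inherits(samples, "tfa_q_samples")) {
    stop("`samples` must come from sample_q()", call. = FALSE)
  }
  p <- log_q_pieces(state, samples)
  rowSums(p$weights) + rowSums(p$centers) + rowSums(p$log_widths)
}

# Score matrix: d log q / d alpha for every sample (rows) and every
# variational parameter in scope (columns), in the canonical packing order.
score_matrix <- function(state, samples) {
  img <- samples$image_subset
  M <- samples$M
  wm <- rep(as.vector(state$weight_mean[img, , drop = FALSE]), each = M)
  wlp <- rep(as.vector(state$weight_log_precision[img, , drop = FALSE]), each = M)
  Xw <- matrix(samples$weights, nrow = M)
  cm <- rep(as.vector(state$center_mean), each = M)
  clp <- rep(as.vector(state$center_log_precision), each = M)
  Xc <- matrix(samples$centers, nrow = M)
  lm <- rep(state$width_mean, each = M)
  llp <- rep(state$width_log_precision, each = M)
  Xl <- samples$log_widths
  cbind(gauss_score_mean(Xw, wm, wlp),
        gauss_score_lp(Xw, wm, wlp),
        gauss_score_mean(Xc, cm, clp),
        gauss_score_lp(Xc, cm, clp),
        gauss_score_mean(Xl, lm, llp),
        gauss_score_lp(Xl, lm, llp))
}

# Per-sample log joint (scaled for subsampling) plus per-image pieces used
# for the factorized weight-parameter gradients inside the fitting loop.
# Fully batched over the M samples: one (M*K) x V' basis evaluation, one
# BLAS product against Y', and K^2 accumulations for the Gram quadratic
# form, instead of an R-level loop over samples.
log_joint_samples <- function(state, samples, data, hyper, voxel_subset) {
  img <- samples$image_subset
  N <- nrow(data$activations)
  V <- ncol(data$activations)
  vox <- resolve_subset(voxel_subset, V, "voxel_subset")
  Y <- data$activations[img, vox, drop = FALSE]
  coords <- data$coords[vox, , drop = FALSE]
  M <- samples$M
  Np <- length(img)
  K <- ncol(samples$log_widths)
  D <- ncol(coords)
  Vp <- length(vox)
  scale_img <- N / Np
  scale_vox <- V / Vp
  lp_n <- hyper$noise_log_precision
  const_row <- 0.5 * Vp * (lp_n - log(2 * pi))
  # all M*K source images in one shot; rows ordered k-fastest within m
  Call <- matrix(aperm(samples$centers, c(2L, 1L, 3L)), M * K, D)
  lw_all <- as.vector(t(samples$log_widths))
  d2 <- -2 * (Call %*% t(coords))
  d2 <- d2 + rowSums(Call^2)                  # recycled down rows
  d2 <- sweep(d2, 2L, rowSums(coords^2), `+`)
  d2[d2 < 0] <- 0
  Fall <- exp(-d2 / exp(lw_all))              # (M*K) x V', recycled by row
  FY <- Fall %*% t(Y)                         # (M*K) x N'
  FYarr <- array(FY, dim = c(K, M, Np))
  Warr <- aperm(samples$weights, c(3L, 1L, 2L))   # K x M x N'
  lin <- colSums(Warr * FYarr)                # M x N'
  quad <- matrix(0, M, Np)
  krow <- function(k) seq.int(k, M * K, by = K)
  for (k in seq_len(K)) {
    Gkk <- rowSums(Fall[krow(k), , drop = FALSE]^2)        # length M
    quad <- quad + samples$weights[, , k]^2 * Gkk
    if (k < K) for (l in seq.int(k + 1L, K)) {
      Gkl <- rowSums(Fall[krow(k), , drop = FALSE] *
                       Fall[krow(l), , drop = FALSE])
      quad <- quad + 2 * samples$weights[, , k] * samples$weights[, , l] * Gkl
    }
  }
  sse <- sweep(quad - 2 * lin, 2L, rowSums(Y^2), `+`)
  loglik_rows <- const_row - 0.5 * exp(lp_n) * sse          # M x N'
  prior_c <- rowSums(matrix(
    gauss_logdens(matrix(samples$centers, nrow = M),
                  rep(rep(hyper$center_mean, each = K), each = M),
                  rep(rep(hyper$center_log_precision, each = K), each = M)),
    nrow = M))
  prior_l <- rowSums(gauss_logdens(samples$log_widths,
                                   matrix(hyper$width_mean, M, K),
                                   matrix(hyper$width_log_precision, M, K)))
  prior_w_rows <- matrix(
    rowSums(array(gauss_logdens(samples$weights, hyper$weight_mean,
                                hyper$weight_log_precision),
                  dim = c(M, Np, K)), dims = 2L),
    nrow = M)
  logp <- prior_c + prior_l + scale_img * rowSums(prior_w_rows) +
    scale_img * scale_vox * rowSums(loglik_rows)
  list(logp = logp, loglik_rows = loglik_rows, prior_w_rows = prior_w_rows,
       scale_img = scale_img, scale_vox = scale_vox)
}

#' Monte Carlo estimate of the evidence lower bound
#'
#' Approximates the ELBO by averaging `log_joint - log_q` over `M` joint
#' draws from the variational distribution; the approximation becomes exact
#' as `M` grows. With `include_likelihood = FALSE` only the prior and
#' entropy terms are kept (the estimate is then `-KL(q || prior)`, which is
#' 0 when q equals the prior).
#'
#' @param state A [tfa_state].
#' @param data A [tfa_dataset].
#' @param hyper A [tfa_hyper].
#' @param M Number of Monte Carlo samples.
#' @param image_subset,voxel_subset Scope, as in [tfa_log_joint()].
#' @param include_likelihood Include the data term (default `TRUE`).
#' @param seed Optional seed.
#' @return A scalar stochastic ELBO estimate.
#' @export
elbo_estimate <- function(state, data, hyper, M = 500L,
                          image_subset = "all", voxel_subset = "all",
                          include_likelihood = TRUE, seed = NULL) {
  data <- as_tfa_dataset(data)
  smp <- sample_q(state, M, image_subset, seed = seed)
  lq <- log_q(state, smp)
  if (include_likelihood) {
    lj <- log_joint_samples(state, smp, data, hyper, voxel_subset)$logp
  } else {
    img <- smp$image_subset
    scale_img <- nrow(data$activations) / length(img)
    K <- ncol(smp$log_widths)
    lj <- numeric(M)
    for (m in seq_len(M)) {
      cen <- matrix(smp$centers[m, , ], nrow = K)
      lj[m] <- sum(gauss_logdens(cen, rep(hyper$center_mean, each = K),
                                 rep(hyper$center_log_precision, each = K))) +
        sum(gauss_logdens(smp$log_widths[m, ], hyper$width_mean,
                          hyper$width_log_precision)) +
        scale_img * sum(gauss_logdens(matrix(smp$weights[m, , ],
                                             nrow = length(img)),
                                      hyper$weight_mean,
                                      hyper$weight_log_precision))
    }
  }
  mean(lj - lq)
}

#' Score-function (black-box) gradient estimate of the ELBO
#'
#' For each variational parameter \eqn{\alpha_i}, the estimator is the
#' sample mean of \eqn{\nabla_{\alpha_i} \log q(\xi_m) \,
#' [\log p(\xi_m, Y) - \log q(\xi_m)]}; its expectation is the exact ELBO
#' gradient. The Gaussian factor scores are analytic:
#' \eqn{\partial/\partial\mathrm{mean} = e^{\lambda}(x - \mathrm{mean})} and
#' \eqn{\partial/\partial\lambda = 1/2 - e^{\lambda}(x-\mathrm{mean})^2/2}
#' where \eqn{\lambda} is the factor's log precision. No control variates
#' are applied here; see [control_variate_adjust()].
#'
#' @inheritParams elbo_estimate
#' @param samples A batch of at least 2 draws from [sample_q()].
#' @return A named numeric vector of length L (one entry per variational
#'   parameter in scope, packed as weight means, weight log precisions,
#'   center means, center log precisions, width means, width log
#'   precisions).
#' @export
score_gradient <- function(state, data, hyper, samples, voxel_subset = "all") {
  if (!inherits(samples, "tfa_q_samples")) {
    stop("`samples` must come from sample_q()", call. = FALSE)
  }
  if (samples$M < 2L) stop("at least 2 samples are required", call. = FALSE)
  data <- as_tfa_dataset(data)
  f <- log_joint_samples(state, samples, data, hyper, voxel_subset)$logp -
    log_q(state, samples)
  h <- score_matrix(state, samples)
  g <- colMeans(h * f)
  sizes <- state_param_groups(state, samples$image_subset)
  names(g) <- unlist(lapply(names(sizes), function(nm) {
    paste0(nm, "_", seq_len(sizes[[nm]]))
  }), use.names = FALSE)
  g
}

#' Control-variate adjustment of a score-function estimator
#'
#' The score \eqn{h = \nabla \log q} has expectation zero under q, so
#' subtracting \eqn{a^* h} from the per-sample estimates \eqn{h f} leaves
#' the estimator's expectation unchanged while shrinking its variance. The
#' optimal coefficient, estimated from the same batch, is
#' \eqn{a^* = \widehat{\mathrm{Cov}}(h f, h) / \widehat{\mathrm{Var}}(h)}
#' per parameter dimension. A zero-variance score dimension is left
#' unadjusted with \eqn{a^* = 0}.
#'
#' @param per_sample_score Length-M vector (or M x L matrix) of per-sample
#'   products \eqn{h f}.
#' @param per_sample_h Matching vector/matrix of scores \eqn{h}.
#' @return A list with `adjusted` (same shape as the input) and `a_star`
#'   (scalar or length-L vector).
#' @export
control_variate_adjust <- function(per_sample_score, per_sample_h) {
  vec_in <- is.null(dim(per_sample_score))
  s <- if (vec_in) cbind(per_sample_score) else per_sample_score
  h <- if (vec_in) cbind(per_sample_h) else per_sample_h
  if (!identical(dim(s), dim(h))) {
    stop("score and h must have matching shapes", call. = FALSE)
  }
  if (nrow(s) < 2L) stop("at least 2 samples are required", call. = FALSE)
  M <- nrow(s)
  hc <- sweep(h, 2L, colMeans(h))
  sc <- sweep(s, 2L, colMeans(s))
  var_h <- colSums(hc^2) / (M - 1)
  cov_sh <- colSums(sc * hc) / (M - 1)
  a <- ifelse(var_h > 0, cov_sh / var_h, 0)
  adjusted <- s - sweep(h, 2L, a, `*`)
  if (vec_in) list(adjusted = drop(adjusted), a_star = unname(a[1L]))
  else list(adjusted = adjusted, a_star = a)
}

#' Adaptive per-parameter learning rate
#'
#' The step size for a parameter whose squared gradients accumulate to `a`
#' is `max_step_size / (delta + sqrt(a))`: parameters with a history of
#' large gradients take smaller steps, and under a constant unit gradient
#' the rate decays like \eqn{1/\sqrt{t}}. The rate is non-increasing in the
#' accumulator and bounded by `max_step_size / delta`.
#'
#' @param grad_sq_accumulator Non-negative accumulated squared gradients
#'   (vectorized).
#' @param max_step_size Numerator of the rate (default 1).
#' @param delta Small positive guard (default 1e-6).
#' @return Learning rate(s), same shape as the accumulator.
#' @export
adagrad_rate <- function(grad_sq_accumulator, max_step_size = 1, delta = 1e-6) {
  if (any(grad_sq_accumulator < 0)) {
    stop("`grad_sq_accumulator` must be non-negative", call. = FALSE)
  }
  max_step_size / (delta + sqrt(grad_sq_accumulator))
}
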
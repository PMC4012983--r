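# Synthetic datasets with the exact statistical structure the model
# assumes, plus condition-structured variants for the network analyses and
# a 2-D many-source demo for the hotspot initializer.

#' Regular coordinate grid
#'
#' Row-major enumeration of a D-dimensional grid (last dimension fastest),
#' scaled by the spacing.
#'
#' @param shape Integer vector of grid dimensions.
#' @param spacing Grid step (default 1).
#' @return A `prod(shape)` x D coordinate matrix.
#' @export
make_grid <- function(shape, spacing = 1) {
  shape <- as.integer(shape)
  stopifnot(all(shape >= 1L), spacing > 0)
  axes <- lapply(shape, function(s) seq(0L, s - 1L))
  idx <- as.matrix(do.call(expand.grid, rev(axes)))
  idx <- idx[, rev(seq_along(shape)), drop = FALSE]
  dimnames(idx) <- NULL
  idx * spacing
}

#' Generate a model-true synthetic dataset
#'
#' Runs the generative process (sources from their priors, i.i.d. Gaussian
#' weights, Gaussian voxel noise) with two additions for controlled
#' experiments: the noise variance is set so that
#' `var(signal) / var(noise)` equals the requested SNR, and the
#' `separated` option redraws any center that lands within twice the mean
#' RBF length scale of an already-accepted center, guaranteeing
#' well-separated ground truth.
#'
#' @param K Number of sources.
#' @param N Number of images.
#' @param grid V x D coordinate matrix (see [make_grid()]).
#' @param hyper Optional [tfa_hyper]; defaults derived from `grid`.
#' @param snr Signal-to-noise variance ratio (default 5).
#' @param seed Integer seed.
#' @param separated Enforce well-separated centers (default TRUE).
#' @param within_volume Reject ground-truth centers outside the coordinate
#'   bounding box (default TRUE), so every source is visible in the data.
#' @param width_range Allowed RBF length-scale range for the ground-truth
#'   sources, in voxel spacings (default `c(1, 4)`): log widths are drawn
#'   from the prior truncated to this range, so every source is resolvable
#'   on the grid (wider than a voxel, narrower than the field of view).
#'   `NULL` disables the truncation.
#' @param max_draws Center redraw budget before giving up (default 10000).
#' @return A list of class `"tfa_bundle"`: `data` (a [tfa_dataset]) and
#'   ground `truth` (`sources`, `weights`, `noise_sd`, `snr`).
#' @export
generate_tfa_dataset <- function(K, N, grid, hyper = NULL, snr = 5, seed,
                                 separated = TRUE, width_range = c(1, 4),
                                 within_volume = TRUE, max_draws = 10000L) {
  stopifnot(snr > 0, K >= 1L, N >= 1L)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  coords <- as_matrix(grid, "grid")
  if (is.null(hyper)) hyper <- tfa_hyper(coords)
  D <- ncol(coords)
  local_seed(seed, {
    draw_widths <- function(n) rnorm(n, hyper$width_mean,
                                     exp(-hyper$width_log_precision / 2))
    log_widths <- draw_widths(K)
    if (!is.null(width_range)) {
      sp <- voxel_spacing(coords)
      lo <- log((width_range[1L] * sp)^2)
      hi <- log((width_range[2L] * sp)^2)
      for (i in seq_len(max_draws)) {
        bad <- log_widths < lo | log_widths > hi
        if (!any(bad)) break
        log_widths[bad] <- draw_widths(sum(bad))
      }
      log_widths <- pmin(pmax(log_widths, lo), hi)
    }
    min_sep <- 2 * mean(sqrt(exp(log_widths)))
    centers <- matrix(NA_real_, K, D)
    draws <- 0L
    for (k in seq_len(K)) {
      repeat {
        draws <- draws + 1L
        if (draws > max_draws) {
          stop(sprintf(
            "could not draw %d centers at pairwise separation >= %.3g within %d draws",
            K, min_sep, max_draws), call. = FALSE)
        }
        cand <- rnorm(D, hyper$center_mean, exp(-hyper$center_log_precision / 2))
        if (within_volume &&
            (any(cand < apply(coords, 2L, min)) ||
             any(cand > apply(coords, 2L, max)))) next
        if (!separated || k == 1L ||
            min(sqrt(colSums((t(centers[seq_len(k - 1L), , drop = FALSE]) -
                                cand)^2))) >= min_sep) break
      }
      centers[k, ] <- cand
    }
    sources <- tfa_sources(centers, log_widths)
    weights <- matrix(rnorm(N * K, hyper$weight_mean,
                            exp(-hyper$weight_log_precision / 2)), nrow = N)
    signal <- weights %*% rbf_basis(sources, coords)
    noise_sd <- sqrt(var(as.vector(signal)) / snr)
    Y <- signal + matrix(rnorm(length(signal), 0, noise_sd), nrow = N)
    hyper$noise_sd <- noise_sd
    hyper$noise_log_precision <- -2 * log(noise_sd)
    spacing <- voxel_spacing(coords)
    shape <- vapply(seq_len(D), function(d) length(unique(coords[, d])), 0L)
    structure(list(
      data = tfa_dataset(Y, coords,
                         mask_shape = shape,
                         affine = diag(c(rep(spacing, D), rep(1, 4 - D))),
                         provenance = list(generator = "generate_tfa_dataset",
                                           seed = seed, snr = snr)),
      truth = list(sources = sources, weights = weights, noise_sd = noise_sd,
                   snr = snr, hyper = hyper)),
      class = "tfa_bundle")
  })
}

#' Generate a dataset with condition-structured weight covariance
#'
#' Emulates a category-viewing experiment: sources are shared, but each
#' condition's weight vectors are drawn from a Gaussian whose covariance is
#' a shared base (the prior weight variance times the identity) plus
#' `effect_size` times a condition-specific rank-1 perturbation
#' \eqn{u_c u_c^\top}. At `effect_size = 0` the conditions are
#' exchangeable — the null of the split-half permutation test. Epochs are
#' assigned round-robin within condition.
#'
#' @param K Number of sources.
#' @param N_per_condition Images per condition.
#' @param conditions Number of conditions (or a character vector of names).
#' @param grid V x D coordinate matrix.
#' @param effect_size Strength of the condition-specific covariance
#'   perturbation (>= 0).
#' @param seed Integer seed.
#' @param n_epochs Number of epochs (default 6).
#' @param hyper Optional [tfa_hyper].
#' @param snr Signal-to-noise ratio (default 5).
#' @param separated Enforce well-separated source centers (default FALSE;
#'   the network analyses do not depend on source geometry).
#' @return A `"tfa_bundle"` whose dataset carries `condition_labels` and
#'   `epoch_labels`; `truth` additionally records the per-condition weight
#'   covariance matrices.
#' @export
generate_condition_dataset <- function(K, N_per_condition, conditions, grid,
                                       effect_size, seed, n_epochs = 6L,
                                       hyper = NULL, snr = 5,
                                       separated = FALSE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  cond_names <- if (is.character(conditions)) conditions else
    paste0("cond", seq_len(conditions))
  C <- length(cond_names)
  stopifnot(C >= 2L, N_per_condition >= 2L, effect_size >= 0)
  coords <- as_matrix(grid, "grid")
  if (is.null(hyper)) hyper <- tfa_hyper(coords)
  local_seed(seed, {
    base_var <- exp(-hyper$weight_log_precision)
    covs <- lapply(seq_len(C), function(ci) {
      u <- rnorm(K); u <- u / sqrt(sum(u^2))
      S <- diag(base_var, K) + effect_size * tcrossprod(u)
      ev <- eigen(S, symmetric = TRUE)
      if (any(ev$values <= 0)) {
        warning("flooring non-positive eigenvalues of a condition covariance",
                call. = FALSE)
        ev$values <- pmax(ev$values, 1e-8)
        S <- ev$vectors %*% diag(ev$values, K) %*% t(ev$vectors)
      }
      S
    })
    names(covs) <- cond_names
    gen <- generate_tfa_dataset(K, 1L, coords, hyper = hyper, snr = snr,
                                separated = separated,
                                seed = sample.int(2^30, 1L))
    sources <- gen$truth$sources
    N <- C * N_per_condition
    weights <- matrix(NA_real_, N, K)
    labels <- rep(cond_names, each = N_per_condition)
    epochs <- rep(rep_len(seq_len(n_epochs), N_per_condition), times = C)
    for (ci in seq_len(C)) {
      R <- chol(covs[[ci]])
      Z <- matrix(rnorm(N_per_condition * K), N_per_condition, K)
      weights[labels == cond_names[ci], ] <- hyper$weight_mean + Z %*% R
    }
    signal <- weights %*% rbf_basis(sources, coords)
    noise_sd <- sqrt(var(as.vector(signal)) / snr)
    Y <- signal + matrix(rnorm(length(signal), 0, noise_sd), nrow = N)
    D <- ncol(coords)
    spacing <- voxel_spacing(coords)
    shape <- vapply(seq_len(D), function(d) length(unique(coords[, d])), 0L)
    structure(list(
      data = tfa_dataset(Y, coords, mask_shape = shape,
                         affine = diag(c(rep(spacing, D), rep(1, 4 - D))),
                         condition_labels = labels, epoch_labels = epochs,
                         provenance = list(generator = "generate_condition_dataset",
                                           seed = seed,
                                           effect_size = effect_size)),
      truth = list(sources = sources, weights = weights,
                   condition_covariances = covs, noise_sd = noise_sd,
                   snr = snr, effect_size = effect_size)),
      class = "tfa_bundle")
  })
}

#' Two-dimensional 25-source demo dataset
#'
#' A 2-D image series built from 25 well-separated RBF sources laid out on
#' a jittered 5 x 5 lattice with alternating-sign amplitudes — the standard
#' testbed for the hotspot initializer, whose residual behavior (holes
#' where sources are subtracted, unexplained regions when K is too small)
#' is easiest to see in 2-D.
#'
#' @param seed Integer seed (default 1).
#' @param N Number of images (default 20).
#' @return A `"tfa_bundle"` with 25 ground-truth sources on a 40 x 40 grid.
#' @export
generate_hotspot_demo <- function(seed = 1L, N = 20L) {
  coords <- make_grid(c(40L, 40L))
  local_seed(seed, {
    lattice <- as.matrix(expand.grid(seq(4, 36, by = 8), seq(4, 36, by = 8)))
    centers <- lattice + matrix(runif(50, -1, 1), 25L, 2L)
    log_widths <- rnorm(25L, log(4), 0.2)
    amplitudes <- sample(c(-1, 1), 25L, replace = TRUE) * runif(25L, 1.5, 3)
    sources <- tfa_sources(centers, log_widths)
    weights <- matrix(rep(amplitudes, each = N), N, 25L) +
      matrix(rnorm(N * 25L, 0, 0.15), N, 25L)
    signal <- weights %*% rbf_basis(sources, coords)
    Y <- signal + matrix(rnorm(length(signal), 0, 0.05), nrow = N)
    structure(list(
      data = tfa_dataset(Y, coords, mask_shape = c(40L, 40L),
                         affine = diag(4),
                         provenance = list(generator = "generate_hotspot_demo",
                                           seed = seed)),
      truth = list(sources = sources, weights = weights,
                   amplitudes = amplitudes, noise_sd = 0.05)),
      class = "tfa_bundle")
  })
}

#' @export
print.tfa_bundle <- function(x, ...) {
  cat(sprintf("Synthetic TFA bundle: %d ground-truth sources\n",
              nrow(x$truth$sources$centers)))
  print(x$data)
  invisible(x)
}
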
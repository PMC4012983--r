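test_that("folding the mean image centers and rectifies it", {
  # constant dataset folds to all zeros
  g <- make_grid(c(3, 3))
  d <- tfa_dataset(matrix(2.5, 4, 9), g)
  expect_equal(fold_mean_image(d)$values, rep(0, 9))
  # hand case: mean image (-2, 0, 2) has scalar mean 0 -> (2, 0, 2)
  d2 <- tfa_dataset(rbind(c(-2, 0, 2), c(-2, 0, 2)), matrix(c(0, 1, 2, 0, 0, 0), 3))
  expect_equal(fold_mean_image(d2)$values, c(2, 0, 2))
  # random dataset: composition of the three elementwise operations
  set.seed(4)
  Y <- matrix(rnorm(60), 5)
  d3 <- tfa_dataset(Y, make_grid(c(4, 3)))
  m <- colMeans(Y)
  expect_equal(fold_mean_image(d3)$values, abs(m - mean(m)), tolerance = 1e-14)
})

test_that("scalar width fitting recovers a planted width and matches a grid search", {
  g <- make_grid(c(15, 15))
  center <- c(7, 7)
  lw0 <- log(6)
  folded <- list(values = 1.8 * rbf_evaluate(center, lw0, g), coords = g)
  expect_equal(fit_width_scalar(folded, center, amplitude = 1.8), lw0,
               tolerance = 1e-4)
  # grid-search oracle on noisy instances
  set.seed(13)
  for (i in 1:10) {
    lw <- runif(1, log(1), log(20))
    amp <- runif(1, 0.5, 3)
    vals <- amp * rbf_evaluate(center, lw, g) + rnorm(225, 0, 0.02)
    fobj <- list(values = abs(vals), coords = g)
    fitted_lw <- fit_width_scalar(fobj, center, amplitude = amp)
    grid_lws <- seq(log(0.25), log(4 * 2 * 14^2), length.out = 2000)
    sse <- vapply(grid_lws, function(l) {
      sum((fobj$values - amp * rbf_evaluate(center, l, g))^2)
    }, 0)
    expect_lt(abs(fitted_lw - grid_lws[which.min(sse)]),
              1.5 * diff(grid_lws[1:2]) + 1e-6)
  }
})

test_that("recovered width grows monotonically with the planted width", {
  g <- make_grid(c(15, 15))
  lws <- log(c(2, 4, 8, 16))
  rec <- vapply(lws, function(l) {
    fit_width_scalar(list(values = rbf_evaluate(c(7, 7), l, g), coords = g),
                     c(7, 7), amplitude = 1)
  }, 0)
  expect_true(all(diff(rec) > 0))
})

test_that("width fitting refuses an all-zero folded image", {
  g <- make_grid(c(3, 3))
  expect_error(fit_width_scalar(list(values = rep(0, 9), coords = g), c(1, 1)),
               "zero")
})

test_that("hotspot initialization recovers a single planted source at its exact peak", {
  g <- make_grid(c(20, 20))
  center <- g[8 + 20 * 11 + 1, ]   # an exact grid point
  lw0 <- log(8)
  Y <- matrix(rep(3 * rbf_evaluate(center, lw0, g), 2), 2, byrow = TRUE)
  d <- tfa_dataset(Y, g)
  src <- hotspot_init(d, 1)
  expect_equal(as.vector(src$centers[1, ]), as.vector(center))
  # width agrees with a dense grid search on the same folded image
  # (centering the mean image shifts the profile slightly, so the oracle is
  # the folded-image least-squares optimum, not the generative width)
  folded <- fold_mean_image(d)
  amp <- attr(src, "amplitudes")[1]
  grid_lws <- seq(log(0.25), log(4 * 2 * 19^2), length.out = 2000)
  sse <- vapply(grid_lws, function(l) {
    sum((folded$values - amp * rbf_evaluate(center, l, g))^2)
  }, 0)
  expect_lt(abs(src$log_widths[1] - grid_lws[which.min(sse)]),
            1.5 * diff(grid_lws[1:2]))
  expect_lt(abs(src$log_widths[1] - lw0), 0.2)
})

test_that("two well-separated equal sources are both recovered, strongest first", {
  g <- make_grid(c(20, 20))
  c1 <- c(5, 5); c2 <- c(14, 14)
  img <- 2.0 * rbf_evaluate(c1, log(4), g) + 1.2 * rbf_evaluate(c2, log(4), g)
  d <- tfa_dataset(rbind(img, img), g)
  src <- hotspot_init(d, 2)
  expect_equal(as.vector(src$centers[1, ]), c1)   # taller peak first
  expect_lt(sqrt(sum((src$centers[2, ] - c2)^2)), 1.5)
  expect_false(all(src$centers[1, ] == src$centers[2, ]))
})

test_that("residual norm decreases strictly at every hotspot placement", {
  b <- generate_hotspot_demo(seed = 3)
  src <- hotspot_init(b$data, 10)
  norms <- attr(src, "residual_norms")
  expect_length(norms, 11)
  expect_true(all(diff(norms) < 0))
  # under-provisioned K leaves unexplained structure
  expect_gt(norms[11] / norms[1], 0.05)
})

test_that("least-squares weights recover a noiseless factorization", {
  set.seed(19)
  g <- make_grid(c(6, 6))
  src <- tfa_sources(matrix(runif(6, 0, 5), 3), rnorm(3, 1, 0.3))
  Fm <- rbf_basis(src, g)
  W0 <- matrix(rnorm(12), 4)
  d <- tfa_dataset(W0 %*% Fm, g)
  expect_equal(solve_weights(d, Fm), W0, tolerance = 1e-8)
})

test_that("K = 1 weights reduce to the scalar projection", {
  g <- make_grid(c(5, 5))
  src <- tfa_sources(matrix(c(2, 2), 1), 0.5)
  f <- as.vector(rbf_basis(src, g))
  set.seed(20)
  Y <- matrix(rnorm(3 * 25), 3)
  W <- solve_weights(tfa_dataset(Y, g), rbf_basis(src, g))
  expect_equal(as.vector(W), as.vector(Y %*% f) / sum(f^2), tolerance = 1e-10)
})

test_that("noisy weights match an independent least-squares solver", {
  set.seed(21)
  g <- make_grid(c(7, 7))
  src <- tfa_sources(matrix(runif(4, 0, 6), 2), c(1, 0.5))
  Fm <- rbf_basis(src, g)
  Y <- matrix(rnorm(5 * 49), 5)
  W <- solve_weights(tfa_dataset(Y, g), Fm)
  for (n in 1:5) {
    ref <- qr.solve(t(Fm), Y[n, ])
    expect_equal(as.vector(W[n, ]), as.vector(ref), tolerance = 1e-8)
  }
})

test_that("coincident sources fall back to the pseudoinverse with a warning", {
  g <- make_grid(c(5, 5))
  src <- tfa_sources(rbind(c(2, 2), c(2, 2)), c(1, 1))
  Fm <- rbf_basis(src, g)
  Y <- matrix(rnorm(2 * 25), 2)
  expect_warning(W <- solve_weights(tfa_dataset(Y, g), Fm), "pseudoinverse")
  expect_true(all(is.finite(W)))
})

test_that("regression weights sit at a per-image optimum of reconstruction error", {
  set.seed(22)
  b <- tiny_bundle(seed = 23, K = 2, N = 5)
  Fm <- rbf_basis(b$truth$sources, b$data$coords)
  W <- solve_weights(b$data, Fm)
  err0 <- sum((b$data$activations - W %*% Fm)^2)
  for (i in 1:100) {
    Wp <- W + matrix(rnorm(length(W), 0, 0.05), nrow(W))
    expect_gt(sum((b$data$activations - Wp %*% Fm)^2), err0)
  }
})

test_that("state initialization is deterministic in hotspot mode, seeded in random mode", {
  b <- tiny_bundle(seed = 24)
  h <- tfa_hyper(b$data$coords)
  s1 <- initialize_state(b$data, 2, "hotspot", h)
  s2 <- initialize_state(b$data, 2, "hotspot", h)
  expect_identical(s1, s2)
  r1 <- initialize_state(b$data, 2, "random", h, seed = 5)
  r2 <- initialize_state(b$data, 2, "random", h, seed = 5)
  expect_identical(r1, r2)
  r3 <- initialize_state(b$data, 2, "random", h, seed = 6)
  expect_false(identical(r1$center_mean, r3$center_mean))
})

test_that("hotspot initialization beats random initialization", {
  # reconstruction error comparison on seeded synthetic datasets
  wins_recon <- 0; wins_elbo <- 0
  for (s in 1:5) {
    b <- generate_tfa_dataset(K = 3, N = 40, grid = make_grid(c(10, 10)),
                              snr = 5, seed = 300 + s)
    h <- tfa_hyper(b$data$coords)
    recon_err <- function(st) {
      sum((b$data$activations -
             tfa_reconstruct(state_sources(st), st$weight_mean,
                             b$data$coords))^2)
    }
    sh <- initialize_state(b$data, 3, "hotspot", h)
    sr <- initialize_state(b$data, 3, "random", h, seed = s)
    wins_recon <- wins_recon + (recon_err(sh) <= recon_err(sr))
    wins_elbo <- wins_elbo +
      (elbo_estimate(sh, b$data, h, M = 300, seed = 1) >=
         elbo_estimate(sr, b$data, h, M = 300, seed = 1))
  }
  expect_gte(wins_recon, 4)
  expect_gte(wins_elbo, 4)
})

test_that("the initialization report round-trips through TSV", {
  b <- generate_hotspot_demo(seed = 5, N = 4)
  src <- hotspot_init(b$data, 3)
  path <- tempfile(fileext = ".tsv")
  write_init_report(src, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$x, src$centers[, 1])
  expect_equal(tab$amplitude, attr(src, "amplitudes"))
})
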
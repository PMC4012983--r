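# The mean-field family, its densities and scores, the ELBO estimator,
# control variates and the adaptive rate.

make_state <- function(N = 4, K = 2, D = 2, seed = 1) {
  set.seed(seed)
  tfa_state(weight_mean = matrix(rnorm(N * K), N),
            weight_log_precision = matrix(rnorm(N * K, 1, 0.3), N),
            center_mean = matrix(rnorm(K * D, 3, 1), K),
            center_log_precision = matrix(rnorm(K * D, 0.5, 0.3), K),
            width_mean = rnorm(K, 1, 0.5),
            width_log_precision = rnorm(K, 1, 0.3))
}

test_that("q samples are deterministic given a seed and collapse as precision grows", {
  st <- make_state()
  s1 <- sample_q(st, 5, seed = 3)
  s2 <- sample_q(st, 5, seed = 3)
  expect_identical(s1, s2)
  st2 <- st
  st2$weight_log_precision[] <- 60
  st2$center_log_precision[] <- 60
  st2$width_log_precision[] <- 60
  s3 <- sample_q(st2, 3, seed = 1)
  expect_equal(matrix(s3$weights[2, , ], 4), st2$weight_mean, tolerance = 1e-10)
  expect_equal(matrix(s3$centers[3, , ], 2), st2$center_mean, tolerance = 1e-10)
  expect_equal(s3$log_widths[1, ], st2$width_mean, tolerance = 1e-10)
})

test_that("q sample moments match the factor parameters", {
  st <- make_state(N = 1, K = 1, D = 2)
  st$weight_mean[1, 1] <- 0.4
  st$weight_log_precision[1, 1] <- -2 * log(0.8)   # sd 0.8
  s <- sample_q(st, 50000, seed = 5)
  x <- s$weights[, 1, 1]
  expect_lt(abs(mean(x) - 0.4), 3 * 0.8 / sqrt(50000))
  expect_lt(abs(var(x) - 0.64), 3 * 0.64 * sqrt(2 / 49999))
})

test_that("log q of a scalar factor at its mean has the closed form", {
  st <- make_state(N = 1, K = 1)
  st$weight_log_precision[1, 1] <- 1.7
  # tighten everything else to a near-point mass and sample at the mean
  st$center_log_precision[] <- 80
  st$width_log_precision[] <- 80
  s <- sample_q(st, 1, seed = 2)
  s$weights[1, 1, 1] <- st$weight_mean[1, 1]
  s$centers[1, , ] <- st$center_mean
  s$log_widths[1, ] <- st$width_mean
  expected_w <- -0.5 * log(2 * pi) + 0.5 * 1.7
  others <- sum(-0.5 * log(2 * pi) + 0.5 * 80) * (2 + 1)  # 2 center dims + width
  expect_equal(log_q(st, s), expected_w + others, tolerance = 1e-10)
})

test_that("log q factorizes over independent factors", {
  st <- make_state(N = 3, K = 2)
  s <- sample_q(st, 10, seed = 4)
  total <- log_q(st, s)
  p <- topofa:::log_q_pieces(st, s)
  expect_equal(total, rowSums(p$weights) + rowSums(p$centers) +
                 rowSums(p$log_widths), tolerance = 1e-12)
  # each piece is a sum of scalar Gaussian log densities
  ref <- sapply(1:10, function(m) {
    sum(dnorm(matrix(s$weights[m, , ], 3), st$weight_mean,
              exp(-st$weight_log_precision / 2), log = TRUE))
  })
  expect_equal(rowSums(p$weights), ref, tolerance = 1e-10)
})

test_that("each variational factor integrates to one (quadrature)", {
  st <- make_state(N = 1, K = 1)
  mu <- st$weight_mean[1, 1]; lp <- st$weight_log_precision[1, 1]
  dens <- function(x) exp(0.5 * lp - 0.5 * log(2 * pi) -
                            0.5 * exp(lp) * (x - mu)^2)
  total <- integrate(dens, mu - 12 * exp(-lp / 2), mu + 12 * exp(-lp / 2),
                     rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("ELBO is ~0 when q equals the prior and the data term is excluded", {
  g <- make_grid(c(4, 4))
  h <- tfa_hyper(g)
  N <- 3; K <- 2
  st <- tfa_state(weight_mean = matrix(h$weight_mean, N, K),
                  weight_log_precision = matrix(h$weight_log_precision, N, K),
                  center_mean = matrix(rep(h$center_mean, each = K), K),
                  center_log_precision = matrix(rep(h$center_log_precision,
                                                    each = K), K),
                  width_mean = rep(h$width_mean, K),
                  width_log_precision = rep(h$width_log_precision, K))
  d <- tfa_dataset(matrix(0, N, nrow(g)), g)
  est <- elbo_estimate(st, d, h, M = 4000, include_likelihood = FALSE,
                       seed = 8)
  expect_lt(abs(est), 0.15)   # -KL(prior || prior) = 0 up to MC error
})

test_that("ELBO estimator is consistent across sample sizes", {
  b <- tiny_bundle(seed = 3, K = 2, N = 6, shape = c(6, 6))
  h <- tfa_hyper(b$data$coords)
  st <- initialize_state(b$data, 2, hyper = h)
  small <- vapply(1:50, function(s) elbo_estimate(st, b$data, h, M = 200,
                                                  seed = s), 0)
  big <- elbo_estimate(st, b$data, h, M = 10000, seed = 999)
  se <- sd(small) / sqrt(50)
  expect_lt(abs(mean(small) - big), 3 * (se + abs(big) * 1e-3))
})

test_that("ELBO lower-bounds the closed-form log marginal on a conjugate instance", {
  # one source, one image, one voxel, RBF value 1 at the voxel:
  # y = w + noise, w ~ N(0, tau^2)  =>  y ~ N(0, tau^2 + sigma^2)
  coords <- matrix(c(0, 0), 1)
  sigma <- 0.4; tau <- 1.3
  h <- tfa_hyper(coords, voxel_noise = sigma, weight_mean = 0,
                 weight_log_precision = -2 * log(tau),
                 center_mean = c(0, 0), center_log_precision = c(0, 0))
  y <- 0.9
  d <- tfa_dataset(matrix(y, 1, 1), coords)
  # center/width factors are pinned to near-point masses at the prior
  # means, so the RBF at the (coincident) voxel is 1 to ~1e-20 and the
  # instance is exactly the 1-D conjugate model; those pinned factors
  # contribute an analytically known -KL(q_g || prior_g) to the ELBO,
  # which is added back before comparing with the 1-D marginal
  st <- tfa_state(weight_mean = matrix(0.2, 1, 1),
                  weight_log_precision = matrix(0, 1, 1),
                  center_mean = matrix(c(0, 0), 1),
                  center_log_precision = matrix(40, 1, 2),
                  width_mean = h$width_mean,
                  width_log_precision = 40)
  kl_gauss <- function(v1, v0) 0.5 * (v1 / v0 - 1 + log(v0 / v1))
  kl_globals <- 2 * kl_gauss(exp(-40), exp(-0)) +        # center dims, prior var 1
    kl_gauss(exp(-40), exp(-h$width_log_precision))      # width factor
  log_marg <- dnorm(y, 0, sqrt(tau^2 + sigma^2), log = TRUE)
  est <- elbo_estimate(st, d, h, M = 20000, seed = 17) + kl_globals
  expect_lt(est, log_marg)
  expect_gt(est, log_marg - 5)   # a bound, but not a vacuous one
  # and the gap closes when q(w) is the exact posterior
  prec <- 1 / tau^2 + 1 / sigma^2
  st2 <- st
  st2$weight_mean[1, 1] <- (y / sigma^2) / prec
  st2$weight_log_precision[1, 1] <- log(prec)
  est2 <- elbo_estimate(st2, d, h, M = 20000, seed = 18) + kl_globals
  expect_lt(abs(est2 - log_marg), 0.02)
})

test_that("analytic factor scores match central finite differences of log q", {
  st <- make_state(N = 2, K = 2)
  s <- sample_q(st, 1, seed = 6)
  eps <- 1e-5
  num_grad <- function(get, set) {
    st_p <- set(st, get(st) + eps); st_m <- set(st, get(st) - eps)
    (log_q(st_p, s) - log_q(st_m, s)) / (2 * eps)
  }
  set.seed(30)
  checked <- 0
  for (i in 1:30) {
    field <- sample(c("weight_mean", "weight_log_precision", "center_mean",
                      "center_log_precision", "width_mean",
                      "width_log_precision"), 1)
    obj <- st[[field]]
    j <- sample(length(obj), 1)
    get <- function(x) x[[field]][j]
    set <- function(x, v) { x[[field]][j] <- v; x }
    h <- topofa:::score_matrix(st, s)
    sizes <- unlist(topofa:::state_param_groups(st, s$image_subset))
    offset <- c(0, cumsum(sizes))[match(field, names(sizes))]
    analytic <- h[1, offset + j]
    numeric <- num_grad(get, set)
    expect_equal(analytic, numeric, tolerance = 1e-5)
    checked <- checked + 1
  }
  expect_equal(checked, 30)
})

test_that("weight-mean score gradient vanishes at the exact conjugate posterior", {
  g <- make_grid(c(5, 5))
  src <- tfa_sources(matrix(c(2, 2), 1), log_widths = log(3))
  f <- as.vector(rbf_basis(src, g))
  sigma <- 0.5
  set.seed(9)
  y <- 1.4 * f + rnorm(25, 0, sigma)
  h <- tfa_hyper(g, voxel_noise = sigma, weight_mean = 0,
                 weight_log_precision = 0)   # prior var 1
  d <- tfa_dataset(matrix(y, 1), g)
  prec <- 1 + sum(f^2) / sigma^2
  post_mean <- sum(y * f) / sigma^2 / prec
  st <- tfa_state(weight_mean = matrix(post_mean, 1, 1),
                  weight_log_precision = matrix(log(prec), 1, 1),
                  center_mean = src$centers,
                  center_log_precision = matrix(40, 1, 2),
                  width_mean = src$log_widths, width_log_precision = 40)
  smp <- sample_q(st, 50000, seed = 10)
  gvec <- score_gradient(st, d, h, smp)
  # batch standard error of the weight-mean component
  hmat <- topofa:::score_matrix(st, smp)
  fval <- topofa:::log_joint_samples(st, smp, d, h, "all")$logp - log_q(st, smp)
  per_sample <- hmat[, 1] * fval
  se <- sd(per_sample) / sqrt(length(fval))
  expect_lt(abs(gvec[["weight_mean_1"]]), 3 * se)
})

test_that("score-function gradient is unbiased against a quadrature ELBO gradient", {
  # single weight factor; everything else near-deterministic
  g <- make_grid(c(4, 4))
  src <- tfa_sources(matrix(c(1.5, 1.5), 1), log_widths = log(2))
  f <- as.vector(rbf_basis(src, g))
  sigma <- 0.6
  set.seed(12)
  y <- 0.8 * f + rnorm(16, 0, sigma)
  h <- tfa_hyper(g, voxel_noise = sigma, weight_mean = 0,
                 weight_log_precision = 0)
  d <- tfa_dataset(matrix(y, 1), g)
  mk <- function(mu, lam) {
    tfa_state(weight_mean = matrix(mu, 1, 1),
              weight_log_precision = matrix(lam, 1, 1),
              center_mean = src$centers,
              center_log_precision = matrix(45, 1, 2),
              width_mean = src$log_widths, width_log_precision = 45)
  }
  mu0 <- 0.5; lam0 <- 1.2
  # exact ELBO as a function of (mu, lam), by quadrature over w, holding
  # the near-point global factors fixed (their contribution is constant)
  elbo_w <- function(mu, lam) {
    sdq <- exp(-lam / 2)
    integrand <- function(w) {
      logp <- dnorm(w, 0, 1, log = TRUE) +
        vapply(w, function(wi) sum(dnorm(y, wi * f, sigma, log = TRUE)), 0)
      logq <- dnorm(w, mu, sdq, log = TRUE)
      exp(logq) * (logp - logq)
    }
    integrate(integrand, mu - 10 * sdq, mu + 10 * sdq, rel.tol = 1e-10)$value
  }
  eps <- 1e-4
  exact_mu <- (elbo_w(mu0 + eps, lam0) - elbo_w(mu0 - eps, lam0)) / (2 * eps)
  exact_lam <- (elbo_w(mu0, lam0 + eps) - elbo_w(mu0, lam0 - eps)) / (2 * eps)
  st <- mk(mu0, lam0)
  ests <- t(vapply(1:50, function(s) {
    smp <- sample_q(st, 500, seed = 100 + s)
    gv <- score_gradient(st, d, h, smp)
    c(gv[["weight_mean_1"]], gv[["weight_log_precision_1"]])
  }, c(0, 0)))
  se <- apply(ests, 2, sd) / sqrt(50)
  expect_lt(abs(mean(ests[, 1]) - exact_mu), 3 * se[1])
  expect_lt(abs(mean(ests[, 2]) - exact_lam), 3 * se[2])
})

test_that("control variates preserve the estimate and guard degenerate input", {
  set.seed(14)
  h <- rnorm(200)
  # f proportional to a constant: adjusted values are exactly zero-variance
  adj <- control_variate_adjust(h * 3, h)
  expect_equal(adj$a_star, 3, tolerance = 1e-12)
  expect_equal(var(adj$adjusted), 0, tolerance = 1e-20)
  # zero-variance score: returned unchanged with a* = 0
  z <- rep(0, 200)
  adj0 <- control_variate_adjust(z * 5 + 1, z)
  expect_equal(adj0$a_star, 0)
  expect_equal(adj0$adjusted, z * 5 + 1)
  expect_error(control_variate_adjust(1, 1), "2 samples")
})

test_that("control variates reduce variance without shifting the mean on a toy problem", {
  # fixed toy: h = score of N(mu, 1) at mu = 0, f = a quadratic of the sample
  set.seed(15)
  raw_means <- adj_means <- raw_var <- adj_var <- numeric(500)
  raw_all <- adj_all <- numeric(500)
  for (b in 1:500) {
    x <- rnorm(500)
    hb <- x                    # d/dmu log N(x; mu, 1) at mu = 0
    fb <- 2 + 1.5 * x - 0.8 * x^2
    adj <- control_variate_adjust(hb * fb, hb)
    raw_all[b] <- mean(hb * fb)
    adj_all[b] <- mean(adj$adjusted)
  }
  expect_lt(var(adj_all), var(raw_all))
  # a* is estimated within-batch, so the adjusted estimator carries an
  # O(1/M) bias; the means must agree on the estimators' own MC scale
  se <- sqrt(var(raw_all) / 500 + var(adj_all) / 500)
  expect_lt(abs(mean(raw_all) - mean(adj_all)), 3 * se)
})

test_that("adaptive rate follows the adopted closed form and its properties", {
  # constant unit gradient for t steps: accumulator t, rate ~ 1/sqrt(t)
  for (t in c(1, 4, 100)) {
    expect_equal(adagrad_rate(t, max_step_size = 1, delta = 0),
                 1 / sqrt(t), tolerance = 1e-12)
  }
  expect_equal(adagrad_rate(0, max_step_size = 2, delta = 1e-6), 2e6)
  set.seed(16)
  a <- sort(runif(50, 0, 10))
  r <- adagrad_rate(a)
  expect_true(all(diff(r) <= 0))
  expect_error(adagrad_rate(-1), "non-negative")
})
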
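# Shared helpers for the test suite.

# All permutations of a small index vector (for assignment matching of
# fitted sources to ground truth; K is always tiny in tests).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Minimal-cost assignment of estimated centers to true centers: mean
# Euclidean error under the best permutation, plus that permutation.
match_sources <- function(true_centers, est_centers) {
  ps <- all_perms(seq_len(nrow(true_centers)))
  errs <- vapply(ps, function(p) {
    mean(sqrt(rowSums((true_centers - est_centers[p, , drop = FALSE])^2)))
  }, 0)
  i <- which.min(errs)
  list(error = errs[i], perm = ps[[i]])
}

# Small reusable fixtures
tiny_bundle <- function(seed = 42L, K = 2L, N = 15L, shape = c(8L, 8L),
                        snr = 5) {
  generate_tfa_dataset(K = K, N = N, grid = make_grid(shape), snr = snr,
                       seed = seed)
}

quick_control <- function(...) {
  tfa_control(samples = 60L, max_iter = 40L, window = 10L,
              final_max_iter = 30L, final_window = 10L, ...)
}
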
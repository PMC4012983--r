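# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

check_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` must contain only finite values", name), call. = FALSE)
  }
  invisible(x)
}

as_matrix <- function(x, name) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  check_finite(x, name)
  x
}

# Gaussian log density in mean / log-precision parameterization:
# variance = exp(-log_prec). Vectorized elementwise.
gauss_logdens <- function(x, mean, log_prec) {
  0.5 * log_prec - 0.5 * log(2 * pi) - 0.5 * exp(log_prec) * (x - mean)^2
}

# d/d mean and d/d log_prec of gauss_logdens (the score of a Gaussian factor
# with respect to its variational parameters).
gauss_score_mean <- function(x, mean, log_prec) {
  exp(log_prec) * (x - mean)
}

gauss_score_lp <- function(x, mean, log_prec) {
  0.5 - 0.5 * exp(log_prec) * (x - mean)^2
}

# Strict upper triangle of a square matrix as a vector (row/col order fixed).
upper_tri_vec <- function(m) {
  m[upper.tri(m, diag = FALSE)]
}

# Resolve an image/voxel subset argument ("all" or an index vector).
resolve_subset <- function(subset, n, name) {
  if (is.null(subset) || identical(subset, "all")) return(seq_len(n))
  subset <- as.integer(subset)
  if (length(subset) == 0L) {
    stop(sprintf("`%s` must not be empty", name), call. = FALSE)
  }
  if (anyNA(subset) || any(subset < 1L) || any(subset > n)) {
    stop(sprintf("`%s` contains indices outside 1..%d", name, n), call. = FALSE)
  }
  subset
}

# A contiguous voxel subset: the `size` voxels nearest (Euclidean) to a
# uniformly drawn seed voxel. Respects arbitrary masks since it works on the
# coordinate table directly.
contiguous_voxel_subset <- function(coords, size) {
  V <- nrow(coords)
  size <- min(size, V)
  if (size == V) return(seq_len(V))
  seed_vox <- sample.int(V, 1L)
  d2 <- colSums((t(coords) - coords[seed_vox, ])^2)
  order(d2)[seq_len(size)]
}

# Smallest positive grid step per dimension; used for width-search bounds and
# voxel-spacing-based defaults. Falls back to 1 for degenerate dimensions.
voxel_spacing <- function(coords) {
  spac <- apply(coords, 2L, function(x) {
    u <- sort(unique(x))
    if (length(u) < 2L) return(NA_real_)
    min(diff(u))
  })
  if (all(is.na(spac))) return(1)
  min(spac, na.rm = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
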
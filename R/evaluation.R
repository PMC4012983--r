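# Reconstruction diagnostics, held-out covariance prediction by
# cross-validation, and selection of the number of sources.

#' Across-image covariance matrix
#'
#' The N x N sample covariance between images, treating voxels as the
#' observations (denominator V - 1). Invariant to voxel ordering.
#'
#' @param images N x V activation matrix.
#' @return An N x N covariance matrix.
#' @export
image_covariance <- function(images) {
  images <- as_matrix(images, "images")
  if (ncol(images) < 2L) {
    stop("at least 2 voxels are required", call. = FALSE)
  }
  cov(t(images))
}

#' Agreement between observed and estimated covariance matrices
#'
#' Pearson correlation over the matrix entries. By default every entry is
#' compared; `scope = "offdiag"` restricts to off-diagonal entries.
#'
#' @param observed,estimated Same-shape covariance matrices.
#' @param scope `"all"` (default) or `"offdiag"`.
#' @return A correlation in `[-1, 1]`.
#' @export
covariance_agreement <- function(observed, estimated,
                                 scope = c("all", "offdiag")) {
  scope <- match.arg(scope)
  observed <- as_matrix(observed, "observed")
  estimated <- as_matrix(estimated, "estimated")
  if (!identical(dim(observed), dim(estimated))) {
    stop("covariance matrices must have the same shape", call. = FALSE)
  }
  if (scope == "offdiag") {
    keep <- row(observed) != col(observed)
    observed <- observed[keep]
    estimated <- estimated[keep]
  }
  if (sd(observed) == 0 || sd(estimated) == 0) {
    stop("covariance agreement is undefined for zero-variance input",
         call. = FALSE)
  }
  cor(as.vector(observed), as.vector(estimated))
}

# Balanced fold assignment, stratified within condition labels when present.
assign_folds <- function(N, n_folds, condition_labels = NULL) {
  folds <- integer(N)
  if (is.null(condition_labels)) {
    folds <- sample(rep_len(seq_len(n_folds), N))
  } else {
    for (cn in levels(as.factor(condition_labels))) {
      idx <- which(condition_labels == cn)
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  }
  folds
}

#' Cross-validated held-out covariance prediction
#'
#' Assesses, for each candidate number of sources, how well source
#' parameters learned from out-of-fold images predict the across-image
#' covariance of held-out voxels: per fold, source centers/widths are fit
#' to the out-of-fold images; voxels are split into two balanced groups;
#' in-fold weights are solved from the in-group voxels only; held-out
#' (out-of-group) voxel activations are then predicted from the source
#' functions evaluated at the held-out coordinates, and scored by
#' [covariance_agreement()] against the observed held-out covariance. Each
#' K gets `n_folds x 2` scores, summarized by the median with a
#' percentile-bootstrap confidence interval.
#'
#' @param data A [tfa_dataset].
#' @param K_grid Integer vector of candidate source counts (length >= 2
#'   for [select_k()]).
#' @param control A [tfa_control] governing the per-fold fits.
#' @param seed Integer seed (fold assignment, voxel splits, fits).
#' @param n_folds Number of image folds (default 6).
#' @param hyper Optional [tfa_hyper].
#' @param n_boot Bootstrap resamples for the CI (default 10000).
#' @param init Initialization mode for the per-fold fits.
#' @return An object of class `"tfa_cv"`: `table` (columns `K`, `fold`,
#'   `voxel_group`, `correlation`) and `summary` (per-K `median`, `lo`,
#'   `hi`).
#' @export
tfa_cross_validate <- function(data, K_grid, control = tfa_control(),
                               seed = 1L, n_folds = 6L, hyper = NULL,
                               n_boot = 10000L, init = "hotspot") {
  data <- as_tfa_dataset(data)
  Y <- data$activations
  N <- nrow(Y); V <- ncol(Y)
  if (is.null(hyper)) hyper <- tfa_hyper(data$coords)
  K_grid <- sort(unique(as.integer(K_grid)))
  feasible <- K_grid <= floor(V / 2)
  if (any(!feasible)) {
    warning(sprintf("skipping K > V/2: %s",
                    paste(K_grid[!feasible], collapse = ", ")), call. = FALSE)
    K_grid <- K_grid[feasible]
  }
  rows <- list()
  local_seed(seed, {
    folds <- assign_folds(N, n_folds, data$condition_labels)
    for (K in K_grid) {
      for (fold in seq_len(n_folds)) {
        train <- which(folds != fold)
        test <- which(folds == fold)
        sub <- tfa_dataset(Y[train, , drop = FALSE], data$coords)
        fit_seed <- sample.int(2^30, 1L)
        fit <- tfa(sub, K, init = init, hyper = hyper, control = control,
                   seed = fit_seed, final_update = FALSE)
        Fm <- rbf_basis(fit$sources, data$coords)
        grp <- sample(rep_len(1:2, V))
        for (g in 1:2) {
          vin <- which(grp == g)
          vout <- which(grp != g)
          W_in <- solve_weights(Y[test, vin, drop = FALSE],
                                Fm[, vin, drop = FALSE])
          pred <- W_in %*% Fm[, vout, drop = FALSE]
          score <- covariance_agreement(
            image_covariance(Y[test, vout, drop = FALSE]),
            image_covariance(pred))
          rows[[length(rows) + 1L]] <- data.frame(
            K = K, fold = fold, voxel_group = g, correlation = score)
        }
      }
    }
    tab <- do.call(rbind, rows)
    summ <- do.call(rbind, lapply(split(tab$correlation, tab$K), function(x) {
      boots <- replicate(n_boot, median(sample(x, replace = TRUE)))
      data.frame(median = median(x),
                 lo = quantile(boots, 0.025, names = FALSE),
                 hi = quantile(boots, 0.975, names = FALSE))
    }))
    summ <- cbind(K = as.integer(rownames(summ)), summ)
    rownames(summ) <- NULL
    structure(list(table = tab, summary = summ, n_folds = n_folds),
              class = "tfa_cv")
  })
}

#' @export
print.tfa_cv <- function(x, ...) {
  cat(sprintf("TFA cross-validation: %d folds x 2 voxel groups\n", x$n_folds))
  print(x$summary, digits = 3, row.names = FALSE)
  cat(sprintf("selected K = %d\n", select_k(x)))
  invisible(x)
}

#' @export
plot.tfa_cv <- function(x, ...) {
  s <- x$summary
  plot(s$K, s$median, type = "b", pch = 19, ylim = range(c(s$lo, s$hi)),
       xlab = "number of sources K", ylab = "median held-out correlation",
       main = "held-out covariance prediction", ...)
  arrows(s$K, s$lo, s$K, s$hi, angle = 90, code = 3, length = 0.04)
  abline(v = select_k(x), lty = 3)
  invisible(x)
}

#' Select the number of sources from a cross-validation curve
#'
#' The K with the largest median held-out correlation; ties go to the
#' smallest K. A maximum at the largest grid value triggers an overfitting
#' warning, since the peak may lie beyond the grid.
#'
#' @param cv A `"tfa_cv"` object (or its `summary` data frame).
#' @return The selected integer K.
#' @export
select_k <- function(cv) {
  s <- if (inherits(cv, "tfa_cv")) cv$summary else cv
  if (nrow(s) < 2L) stop("at least 2 grid points are required", call. = FALSE)
  best <- s$K[which.max(s$median)]   # which.max takes the first (smallest K) tie
  if (best == max(s$K) && all(diff(s$median) >= 0)) {
    warning("median correlation still increasing at the largest K; the model may want more sources",
            call. = FALSE)
  }
  as.integer(best)
}

#' Write cross-validation results to disk
#'
#' The fold-level table as TSV plus a JSON summary with per-K medians and
#' confidence intervals.
#'
#' @param cv A `"tfa_cv"` object.
#' @param prefix Output path prefix (`_folds.tsv`, `_summary.json`).
#' @return Written paths, invisibly.
#' @export
write_cv_report <- function(cv, prefix) {
  paths <- c(folds = paste0(prefix, "_folds.tsv"),
             summary = paste0(prefix, "_summary.json"))
  write.table(cv$table, paths[["folds"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(selected_K = select_k(cv), summary = cv$summary),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
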
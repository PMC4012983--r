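# Source-network inference: weight covariance, thresholding for display,
# split-half reliability with a row-shuffle permutation test.

#' Source-interaction network from weight covariance
#'
#' The covariance of the K weight columns across a set of images is a
#' compact K x K stand-in for the full voxel-by-voxel connectivity matrix:
#' positive entries are read as excitatory interactions between sources,
#' negative as inhibitory.
#'
#' @param weights N x K weight matrix (e.g. `coef(fit, "weights")`).
#' @param image_subset `"all"` or image indices (at least 2).
#' @param condition Optional label stored with the result.
#' @return An object of class `"tfa_network"`: list with `interaction`
#'   (K x K sample covariance, denominator n-1), `condition`, `n_images`.
#' @export
weight_covariance <- function(weights, image_subset = "all", condition = NA) {
  weights <- as_matrix(weights, "weights")
  img <- resolve_subset(image_subset, nrow(weights), "image_subset")
  if (length(img) < 2L) {
    stop("at least 2 images are required to form a covariance", call. = FALSE)
  }
  structure(list(interaction = cov(weights[img, , drop = FALSE]),
                 condition = condition, n_images = length(img)),
            class = "tfa_network")
}

#' @export
print.tfa_network <- function(x, ...) {
  K <- nrow(x$interaction)
  cat(sprintf("Source network: %d sources, %d images%s\n", K, x$n_images,
              if (is.na(x$condition)) "" else paste0(", condition ", x$condition)))
  cat(sprintf("  interaction strengths: %d pairs, |strength| range [%.3g, %.3g]\n",
              K * (K - 1L) / 2L,
              min(abs(upper_tri_vec(x$interaction))),
              max(abs(upper_tri_vec(x$interaction)))))
  invisible(x)
}

#' Threshold a network for display
#'
#' Keeps the edges whose absolute strength is at least the given percentile
#' of the reference network's absolute off-diagonal strengths. This is a
#' visualization aid only; reliability statistics are always computed on
#' unthresholded networks.
#'
#' @param net A `"tfa_network"`.
#' @param percentile Percentile in `[0, 100)` below which edges are dropped.
#' @param reference Network supplying the threshold (default: `net` itself).
#' @return A data frame with columns `source_i`, `source_j`, `strength`.
#' @export
threshold_network <- function(net, percentile, reference = net) {
  stopifnot(percentile >= 0, percentile < 100)
  K <- nrow(net$interaction)
  idx <- which(upper.tri(net$interaction), arr.ind = TRUE)
  strength <- net$interaction[idx]
  cut <- if (percentile == 0) 0 else
    quantile(abs(upper_tri_vec(reference$interaction)), percentile / 100,
             names = FALSE, type = 7)
  keep <- abs(strength) >= cut
  data.frame(source_i = idx[keep, 1L], source_j = idx[keep, 2L],
             strength = strength[keep])
}

# Per-condition odd/even-epoch networks -> confusion matrix of Pearson
# correlations between vectorized upper-triangle interaction strengths.
condition_confusion <- function(weights, condition_labels, epoch_labels) {
  weights <- as_matrix(weights, "weights")
  condition_labels <- as.factor(condition_labels)
  epoch_labels <- as.integer(epoch_labels)
  stopifnot(length(condition_labels) == nrow(weights),
            length(epoch_labels) == nrow(weights))
  odd <- epoch_labels %% 2L == 1L
  conds <- levels(condition_labels)
  nets <- lapply(c(TRUE, FALSE), function(is_odd) {
    lapply(conds, function(cn) {
      idx <- which(condition_labels == cn & (odd == is_odd))
      if (length(idx) < 2L) {
        stop(sprintf("condition '%s' has fewer than 2 images in the %s-epoch split",
                     cn, if (is_odd) "odd" else "even"), call. = FALSE)
      }
      upper_tri_vec(cov(weights[idx, , drop = FALSE]))
    })
  })
  C <- length(conds)
  conf <- matrix(NA_real_, C, C, dimnames = list(odd = conds, even = conds))
  for (i in seq_len(C)) for (j in seq_len(C)) {
    conf[i, j] <- cor(nets[[1L]][[i]], nets[[2L]][[j]])
  }
  conf
}

# Welch t comparing same-condition (diagonal) vs different-condition
# (off-diagonal) confusion entries.
confusion_t <- function(conf) {
  unname(t.test(diag(conf), conf[row(conf) != col(conf)])$statistic)
}

# Row-shuffle permutation null with +1 smoothing, one-sided (>=).
permute_confusion <- function(conf, n_permutations, t_obs) {
  C <- nrow(conf)
  t_perm <- replicate(n_permutations, confusion_t(conf[sample.int(C), ,
                                                       drop = FALSE]))
  (1 + sum(t_perm >= t_obs)) / (1 + n_permutations)
}

#' Split-half reliability of condition-specific networks
#'
#' Splits the images into odd and even epochs, infers one network per
#' condition per split, and asks whether same-condition networks are more
#' similar across splits than different-condition networks. The confusion
#' matrix holds the Pearson correlation between the vectorized off-diagonal
#' interaction strengths of every odd-split / even-split condition pair; the
#' observed statistic is a Welch two-sample t comparing its diagonal with
#' its off-diagonal entries, and the null distribution comes from uniformly
#' shuffling the confusion matrix's rows.
#'
#' @param weights N x K weight matrix.
#' @param condition_labels Length-N condition labels.
#' @param epoch_labels Length-N integer epoch tags (odd/even define the
#'   split); every condition must appear in both splits.
#' @param n_permutations Number of row shuffles (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `"tfa_reliability"`: `confusion` (C x C),
#'   `t_statistic`, `permutation_p` (with +1 smoothing, so at least
#'   `1/(n_permutations+1)`), `n_permutations`.
#' @export
split_half_reliability <- function(weights, condition_labels, epoch_labels,
                                   n_permutations = 1000L, seed = NULL) {
  stopifnot(n_permutations >= 1L)
  conf <- condition_confusion(weights, condition_labels, epoch_labels)
  t_obs <- confusion_t(conf)
  p <- local_seed(seed, permute_confusion(conf, n_permutations, t_obs))
  structure(list(confusion = conf, t_statistic = t_obs, permutation_p = p,
                 n_permutations = as.integer(n_permutations)),
            class = "tfa_reliability")
}

#' @export
print.tfa_reliability <- function(x, ...) {
  cat(sprintf("Split-half network reliability: %d conditions\n",
              nrow(x$confusion)))
  cat(sprintf("  t (same vs different condition) = %.3f, permutation p = %.4g (%d shuffles)\n",
              x$t_statistic, x$permutation_p, x$n_permutations))
  invisible(x)
}

#' Pool split-half confusions across participants
#'
#' Takes the element-wise mean of the per-participant confusion matrices
#' and applies the same t statistic and row-shuffle permutation test to the
#' pooled matrix.
#'
#' @param confusions A list of C x C confusion matrices (or
#'   `"tfa_reliability"` objects), all the same shape.
#' @param n_permutations,seed As in [split_half_reliability()].
#' @return A `"tfa_reliability"` object for the pooled confusion.
#' @export
aggregate_reliability <- function(confusions, n_permutations = 1000L,
                                  seed = NULL) {
  mats <- lapply(confusions, function(x) {
    if (inherits(x, "tfa_reliability")) x$confusion else as.matrix(x)
  })
  d1 <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), d1), logical(1L)))) {
    stop("all confusion matrices must have the same shape", call. = FALSE)
  }
  conf <- Reduce(`+`, mats) / length(mats)
  t_obs <- confusion_t(conf)
  p <- local_seed(seed, permute_confusion(conf, n_permutations, t_obs))
  structure(list(confusion = conf, t_statistic = t_obs, permutation_p = p,
                 n_permutations = as.integer(n_permutations)),
            class = "tfa_reliability")
}

#' Export a network as plain-text tables
#'
#' Writes the symmetric interaction matrix, an edge list
#' (`source_i`, `source_j`, `strength`) and, when sources are supplied, a
#' node table (center coordinates and widths) consumable by standard graph
#' viewers.
#'
#' @param net A `"tfa_network"`.
#' @param prefix Output path prefix; files get `_matrix.tsv`, `_edges.tsv`
#'   and `_nodes.tsv` suffixes.
#' @param sources Optional [tfa_sources] for the node table.
#' @return The written paths, invisibly.
#' @export
write_network <- function(net, prefix, sources = NULL) {
  paths <- c(matrix = paste0(prefix, "_matrix.tsv"),
             edges = paste0(prefix, "_edges.tsv"))
  write.table(net$interaction, paths[["matrix"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(threshold_network(net, 0), paths[["edges"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sources)) {
    paths <- c(paths, nodes = paste0(prefix, "_nodes.tsv"))
    tab <- data.frame(source = seq_len(nrow(sources$centers)),
                      sources$centers, log_width = sources$log_widths)
    D <- ncol(sources$centers)
    names(tab)[1L + seq_len(D)] <- c("x", "y", "z")[seq_len(D)]
    write.table(tab, paths[["nodes"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
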
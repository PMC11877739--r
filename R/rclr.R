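## Robust centered log-ratio transform and robust Aitchison (low-rank
## completion) ordination.

#' Robust centered log-ratio (RCLR) transform
#'
#' Log-transforms positive entries and centers each sample by the mean of
#' its observed (nonzero) log values; zeros are treated as missing (`NA`),
#' never imputed as log 0. Samples with fewer than two observed taxa are
#' dropped with a warning.
#'
#' @param x An `abundance_table` (RPKM values are used; the per-sample
#'   centering makes the transform invariant to the per-sample scale) or a
#'   non-negative taxa x samples matrix.
#' @return A samples x taxa matrix of class `rclr_matrix` with `NA` at
#'   unobserved entries; each row's observed entries have mean 0.
#' @export
rclr <- function(x) {
  if (inherits(x, "abundance_table")) x <- x$rpkm
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE)) stop("rclr requires non-negative input")
  m <- t(x)                               # samples x taxa
  m[m == 0] <- NA
  nobs <- rowSums(!is.na(m))
  if (any(nobs < 2)) {
    warning("dropping sample(s) with fewer than 2 observed taxa: ",
            paste(rownames(m)[nobs < 2], collapse = ", "))
    m <- m[nobs >= 2, , drop = FALSE]
  }
  lm <- log(m)
  out <- lm - rowMeans(lm, na.rm = TRUE)
  class(out) <- c("rclr_matrix", "matrix", "array")
  out
}

#' Robust Aitchison PCA (low-rank completion of the RCLR matrix)
#'
#' Completes the missing (zero-count) entries of an RCLR matrix by
#' alternating truncated-SVD imputation: missing entries are initialized at
#' 0 (the row-centered null), the matrix is repeatedly replaced by its
#' rank-`rank` SVD truncation at the missing positions only, and iteration
#' stops when the relative Frobenius change of the reconstruction falls
#' below `tol`. Sample scores are `U %*% diag(d)` of the final truncation,
#' so Euclidean distances between scores are the robust Aitchison distances
#' between rank-reduced samples.
#'
#' @param x An `rclr_matrix` (or an `abundance_table`/matrix passed through
#'   [rclr()]).
#' @param rank Target rank of the completion (< min dimension).
#' @param max_iter Maximum number of SVD iterations.
#' @param tol Relative-change convergence tolerance.
#' @return An object of class `rpca`: `scores` (samples x rank),
#'   `loadings` (taxa x rank), `eig` (singular values), `distance` (a
#'   `dist` of sample scores), `proportion_explained`, `converged`,
#'   `iterations`, `completed` (the completed RCLR matrix).
#' @export
rpca <- function(x, rank = 3, max_iter = 200, tol = 1e-7) {
  if (!inherits(x, "rclr_matrix")) x <- rclr(x)
  m <- unclass(x)
  miss <- is.na(m)
  if (rank >= min(dim(m)))
    stop("rank must be smaller than both matrix dimensions")
  filled <- m
  filled[miss] <- 0
  prev <- NULL
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    sv <- svd(filled, nu = rank, nv = rank)
    d <- sv$d[seq_len(rank)]
    hat <- sv$u %*% (d * t(sv$v))
    if (!is.null(prev)) {
      delta <- sqrt(sum((hat - prev)^2)) / max(sqrt(sum(prev^2)), 1e-12)
      if (delta < tol) { converged <- TRUE; filled[miss] <- hat[miss]; break }
    }
    prev <- hat
    filled[miss] <- hat[miss]
    if (!any(miss)) { converged <- TRUE; break }
  }
  sv <- svd(filled, nu = rank, nv = rank)
  d <- sv$d[seq_len(rank)]
  scores <- sv$u %*% diag(d, rank)
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(rank))
  loadings <- sv$v
  rownames(loadings) <- colnames(m)
  colnames(loadings) <- colnames(scores)
  structure(list(scores = scores, loadings = loadings, eig = d,
                 proportion_explained = d^2 / sum(sv$d^2),
                 distance = stats::dist(scores), converged = converged,
                 iterations = it, completed = filled, rank = rank),
            class = "rpca")
}

#' @export
print.rpca <- function(x, ...) {
  cat(sprintf("Robust Aitchison PCA: %d samples x %d taxa, rank %d (%s, %d iterations)\n",
              nrow(x$scores), nrow(x$loadings), x$rank,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("  proportion explained:",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
plot.rpca <- function(x, labels = NULL, dims = c(1, 2), ...) {
  s <- x$scores[, dims, drop = FALSE]
  col <- if (is.null(labels)) 1 else as.integer(factor(labels))
  graphics::plot(s, col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", dims[1],
                                100 * x$proportion_explained[dims[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", dims[2],
                                100 * x$proportion_explained[dims[2]]), ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))), pch = 19,
                     cex = 0.8)
  invisible(x)
}

#' Classical principal coordinate analysis of a distance matrix
#'
#' Deterministic metric ordination (eigendecomposition of the
#' Gower-centered squared-distance matrix) via [stats::cmdscale()].
#'
#' @param d A `dist` object or square symmetric matrix.
#' @param k Number of coordinate axes.
#' @return List with `points` (samples x k) and `eig` (all eigenvalues).
#' @export
pcoa_ordination <- function(d, k = 2) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  colnames(fit$points) <- paste0("PCo", seq_len(ncol(fit$points)))
  list(points = fit$points, eig = fit$eig)
}
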
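#' Low-rank singular-value imputation of a genotype x environment table
#'
#' Completes an incomplete matrix by iterative rank-`rank` singular value
#' decomposition: missing cells are initialized with column means, then the
#' loop \{column-center, truncated SVD, rebuild, overwrite only the missing
#' cells\} repeats until the largest absolute change on the filled cells
#' drops below `tol`. Observed cells are never modified.
#'
#' @param m Numeric matrix with `NA` gaps; every row and column must contain
#'   at least one observed cell, and `rank < min(dim(m))`.
#' @param rank Reconstruction rank (default 2, matching a two-axis biplot).
#' @param tol Convergence threshold on the fill-in change (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @return The completed matrix, with attributes `iterations`, `converged`
#'   and `last_delta`. Non-convergence is flagged with a warning, never
#'   hidden.
#' @export
impute_gaps <- function(m, rank = 2, tol = 1e-6, max_iter = 500) {
  m <- as.matrix(m)
  miss <- is.na(m)
  if (!any(miss)) {
    attr(m, "iterations") <- 0L
    attr(m, "converged") <- TRUE
    attr(m, "last_delta") <- 0
    return(m)
  }
  if (any(rowSums(!miss) == 0) || any(colSums(!miss) == 0))
    stop("every row and column needs at least one observed cell")
  if (rank >= min(dim(m))) stop("rank must be below min(dim(m))")
  col_means <- colMeans(m, na.rm = TRUE)
  filled <- m
  filled[miss] <- col_means[col(m)[miss]]
  delta <- Inf
  it <- 0L
  while (delta >= tol && it < max_iter) {
    it <- it + 1L
    mu <- colMeans(filled)
    centered <- sweep(filled, 2, mu)
    sv <- svd(centered, nu = rank, nv = rank)
    approx_m <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    rebuilt <- sweep(approx_m, 2, mu, `+`)
    delta <- max(abs(rebuilt[miss] - filled[miss]))
    filled[miss] <- rebuilt[miss]
  }
  if (delta >= tol)
    warning(sprintf("impute_gaps did not converge in %d iterations (last delta %.3g)",
                    max_iter, delta))
  attr(filled, "iterations") <- it
  attr(filled, "converged") <- delta < tol
  attr(filled, "last_delta") <- delta
  filled
}

#' Genotype x ECG biplot from a completed yield table
#'
#' Column-centers the hybrid x environment-category mean-yield matrix and
#' takes its singular value decomposition. Hybrid scores are `U D` and
#' category loadings `V D^(1/2)`-free: loadings are returned as `V` scaled by
#' the singular values (covariance-style biplot), so the cosine of the angle
#' between two category vectors approximates their correlation over hybrids
#' — vectors near 180 degrees mark negatively correlated categories, near 90
#' degrees uncorrelated ones.
#'
#' @param m Hybrid x category matrix of mean yields (no gaps; complete with
#'   [impute_gaps()] first), at least 3 hybrids.
#' @return A list of class `ecg_biplot`: `scores` (hybrids x 2), `loadings`
#'   (categories x 2), `pc_variance_fractions` (all PCs, non-increasing,
#'   summing to 1), `angles` (category x category matrix, degrees), `flags`.
#' @export
ecg_biplot <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix has gaps; run impute_gaps first")
  if (nrow(m) < 3) stop("need at least 3 hybrids")
  centered <- sweep(m, 2, colMeans(m))
  sv <- svd(centered)
  flags <- character()
  if (sum(sv$d > max(dim(m)) * .Machine$double.eps * sv$d[1]) < 2)
    flags <- "rank below 2: second axis is numerical noise"
  frac <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  loadings <- sv$v[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], 2)
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  colnames(scores) <- colnames(loadings) <- c("PC1", "PC2")
  norm <- sqrt(rowSums(loadings^2))
  cosang <- (loadings %*% t(loadings)) / outer(norm, norm)
  cosang <- pmin(pmax(cosang, -1), 1)   # matrix first so dimnames survive
  structure(list(scores = scores, loadings = loadings,
                 pc_variance_fractions = frac,
                 angles = acos(cosang) * 180 / pi, flags = flags),
            class = "ecg_biplot")
}
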
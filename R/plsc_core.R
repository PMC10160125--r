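#' Cross-covariance matrix between design and brain blocks
#'
#' Forms `R = t(Y) %*% X`, the (design columns x voxels) cross-covariance
#' matrix of the two standardized blocks. No further scaling is applied:
#' with both blocks z-scored by the population convention, dividing by n
#' would give correlations, but PLS-C operates on the raw product and the
#' scale cancels in all downstream statistics.
#'
#' @param Y Design matrix (scans x design columns) or a `design_matrix`.
#' @param X Brain matrix (scans x voxels) or a `brain_data_matrix`.
#' @return Matrix, design columns x voxels.
#' @export
cross_covariance <- function(Y, X) {
  if (inherits(Y, "design_matrix")) Y <- Y$Y
  if (inherits(X, "brain_data_matrix")) X <- X$X
  if (nrow(Y) != nrow(X))
    stop2("Y and X must have the same number of rows (scans)")
  crossprod(Y, X)
}

# Joint deterministic sign convention: for each component flip (U_k, V_k)
# together so the largest-|.|.| entry of U_k is positive. Ties broken by
# the first index. Keeps outputs identical across LAPACK backends.
apply_sign_convention <- function(U, V) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  list(U = U, V = V)
}

#' Singular value decomposition of the cross-covariance matrix
#'
#' Computes `R = U S t(V)` and applies a deterministic sign convention:
#' each pair of saliences (U_k, V_k) is jointly flipped so that the entry
#' of U_k with the largest absolute value is positive. All
#' `min(nrow(R), ncol(R))` components are retained.
#'
#' @param R Cross-covariance matrix from [cross_covariance()].
#' @return List with `U` (design saliences, columns unit norm), `S`
#'   (singular values, descending), `V` (brain saliences, columns unit
#'   norm).
#' @export
svd_decompose <- function(R) {
  R <- as.matrix(R)
  if (!all(is.finite(R))) stop2("R contains non-finite values")
  k <- min(dim(R))
  s <- svd(R, nu = k, nv = k)
  fixed <- apply_sign_convention(s$u, s$v)
  rownames(fixed$U) <- rownames(R)
  rownames(fixed$V) <- colnames(R)
  list(U = fixed$U, S = s$d[seq_len(k)], V = fixed$V)
}

#' Latent-variable scores
#'
#' Projects each scan's data onto the saliences: brain scores
#' `Lx = X %*% V` and design scores `Ly = Y %*% U`. A scan's brain score
#' on component k expresses how strongly its connectivity map resembles
#' the k-th multivariate brain pattern. With both blocks standardized by
#' the population convention, the population covariance of (Lx_k, Ly_k)
#' equals S_k / n.
#'
#' @param X Brain matrix (scans x voxels).
#' @param Y Design matrix (scans x design columns).
#' @param U Design saliences.
#' @param V Brain saliences.
#' @return List with `Lx` and `Ly` (scans x components).
#' @export
compute_scores <- function(X, Y, U, V) {
  if (inherits(Y, "design_matrix")) Y <- Y$Y
  if (inherits(X, "brain_data_matrix")) X <- X$X
  if (ncol(X) != nrow(V)) stop2("X and V are not conformable")
  if (ncol(Y) != nrow(U)) stop2("Y and U are not conformable")
  list(Lx = X %*% V, Ly = Y %*% U)
}

#' Per-component explained cross-covariance fractions
#'
#' Fraction of the total squared cross-covariance carried by each
#' component: `S_k^2 / sum(S^2)`. Values are sorted descending before the
#' fractions are formed.
#'
#' @param S Non-negative singular values.
#' @return Numeric vector of fractions summing to 1.
#' @export
explained_covariance <- function(S) {
  if (any(S < 0)) stop2("singular values must be non-negative")
  if (all(S == 0)) stop2("all singular values are zero")
  S <- sort(S, decreasing = TRUE)
  S^2 / sum(S^2)
}

#' Partial least squares correlation of two blocks
#'
#' The full PLS-C decomposition: forms the cross-covariance
#' `R = t(Y) %*% X` of the standardized design and brain blocks, takes
#' its SVD `R = U S t(V)` into latent components, and computes the latent
#' scores. Each latent component pairs a design salience (weights over
#' the design variables) with a brain salience (weights over voxels),
#' with singular value S_k measuring the cross-covariance the pair
#' captures.
#'
#' @param X Brain matrix (scans x voxels), confound-residualized and
#'   standardized (see [regress_confounds()]); or a `brain_data_matrix`.
#' @param Y Design matrix (scans x design columns), standardized (see
#'   [build_design_matrix()]); or a `design_matrix`.
#' @return Object of class `plsc_result`: list with `U`, `S`, `V`, `Lx`,
#'   `Ly`, `explained`, `n` (scans), and the input `X`, `Y` blocks.
#' @export
plsc <- function(X, Y) {
  if (inherits(Y, "design_matrix")) Y <- Y$Y
  if (inherits(X, "brain_data_matrix")) X <- X$X
  R <- cross_covariance(Y, X)
  dec <- svd_decompose(R)
  sc <- compute_scores(X, Y, dec$U, dec$V)
  structure(list(U = dec$U, S = dec$S, V = dec$V,
                 Lx = sc$Lx, Ly = sc$Ly,
                 explained = explained_covariance(dec$S),
                 n = nrow(X), X = X, Y = Y),
            class = "plsc_result")
}

#' @export
print.plsc_result <- function(x, ...) {
  cat("PLS-C decomposition:", nrow(x$U), "design variables x",
      nrow(x$V), "voxels,", x$n, "scans\n")
  cat("singular values:", format(x$S, digits = 4), "\n")
  cat("explained cross-covariance:",
      paste0(format(100 * x$explained, digits = 3), "%"), "\n")
  invisible(x)
}
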
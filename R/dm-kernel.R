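#' The deletion-mutant (DM) kernel on discrete expression calls
#'
#' Similarity between two signed calls: 1 when both are up-regulated or both
#' down-regulated, 0 otherwise. In particular two "no change" calls score 0 --
#' the kernel deliberately discards co-absence of differential expression,
#' which dominates sparse deletion-mutant profiles and would otherwise
#' swamp the learner with spurious similarity.
#'
#' @param x,y calls in \{-1, 0, 1\}; vectors are compared elementwise.
#' @return 0/1 values: \code{1} iff \code{x == y} and \code{x != 0}.
#' @examples
#' dm_kernel_value(1, 1)    # 1
#' dm_kernel_value(0, 0)    # 0
#' dm_kernel_value(1, -1)   # 0
#' @export
dm_kernel_value <- function(x, y) {
  check_calls(x); check_calls(y)
  as.numeric(x == y & x != 0L)
}

check_calls <- function(x) {
  if (!all(x %in% c(-1L, 0L, 1L)))
    stop("calls must be -1, 0 or 1")
  invisible(x)
}

#' Exact rank-2 feature map of the DM kernel
#'
#' The DM kernel factorizes exactly as the inner product of a two-dimensional
#' indicator map phi(x) = (1\{x = +1\}, 1\{x = -1\}): both indicators can
#' never be 1 together, and phi(x).phi(y) reproduces
#' \code{\link{dm_kernel_value}} entrywise. All production Kernel Generalized
#' Variance computations run in this feature space, so no N x N Gram matrix
#' is ever formed outside of test oracles.
#'
#' @param column integer vector of calls in \{-1, 0, 1\} (one mutant's
#'   profile over N genes).
#' @param center logical; subtract each indicator column's mean (default
#'   TRUE, the form consumed by the KGV estimator).
#' @return an N x 2 numeric matrix (columns \code{up}, \code{down}),
#'   centered unless \code{center = FALSE}.
#' @export
feature_block <- function(column, center = TRUE) {
  check_calls(column)
  phi <- cbind(up = as.numeric(column == 1L), down = as.numeric(column == -1L))
  if (center) phi <- sweep(phi, 2L, colMeans(phi))
  phi
}

#' Centered DM-kernel Gram matrix
#'
#' Returns H K H for K[i, j] = dm_kernel_value(column[i], column[j]) and the
#' usual centering projector H = I - 11'/N. Symmetric, positive
#' semi-definite, rank at most 2; provided for inspection and as the slow
#' reference formulation -- production scoring uses
#' \code{\link{feature_block}} instead.
#'
#' @param column integer vector of calls.
#' @return an N x N numeric matrix equal to the centered feature outer
#'   product.
#' @export
centered_gram <- function(column) {
  phi <- feature_block(column, center = TRUE)
  tcrossprod(phi)
}

#' Kernel Generalized Variance mutual-information surrogate
#'
#' Estimates the multi-information (in nats) among m discrete variables under
#' the DM kernel. With centered feature blocks Phi_i, the empirical
#' covariance blocks are C_ij = Phi_i' Phi_j / N; the estimator is
#' \deqn{J = -\frac{1}{2}\,\log\frac{\det(C + \Lambda)}{\prod_i \det(C_{ii} + \lambda_i I)}}
#' where C is the full block covariance matrix and Lambda is the
#' block-diagonal ridge with \eqn{\lambda_i = \kappa \cdot \bar v_i},
#' \eqn{\bar v_i = \mathrm{tr}(C_{ii})/2} the variable's mean feature
#' variance. Scaling the ridge by each variable's own variance makes the
#' implied shrinkage of every canonical correlation a uniform
#' \eqn{1/(1+\kappa)}, independent of how sparse the profiles are -- an
#' absolute ridge would shrink weakly and unevenly on sparse data and leak
#' large spurious partial correlations into conditional scores. Variables
#' whose feature block is identically zero contribute nothing (their rows
#' and columns cancel exactly in the ratio) and are dropped. A single
#' variable scores exactly 0. Computed entirely in the (2m)-dimensional
#' feature space.
#'
#' @param blocks list of centered feature blocks (all N x 2, same N), as
#'   returned by \code{\link{feature_block}}.
#' @param kappa regularization constant, > 0 (default 0.01).
#' @return a nonnegative scalar (nats); tiny negative round-off is clamped
#'   to 0.
#' @examples
#' x <- c(1L, -1L, 0L, 1L)
#' kgv_multiinfo(list(feature_block(x), feature_block(x)))  # > 0
#' kgv_multiinfo(list(feature_block(x)))                    # exactly 0
#' @export
kgv_multiinfo <- function(blocks, kappa = 0.01) {
  if (!is.list(blocks) || !length(blocks)) stop("blocks must be a non-empty list")
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0)
    stop("kappa must be a positive scalar")
  n <- vapply(blocks, nrow, integer(1))
  if (any(n != n[1L])) stop("all feature blocks must share the same number of rows")
  m <- length(blocks)
  if (m == 1L) return(0)
  N <- n[1L]
  C <- crossprod(do.call(cbind, blocks)) / N
  kgv_from_cov(C, rep(2L, m), kappa)
}

# Core determinant computation shared by kgv_multiinfo and the structure
# scorer: C is the full block covariance over the selected variables, dims
# gives the feature dimension of each block (always 2 here). Ridge per
# block is kappa times the block's mean diagonal; zero-variance blocks are
# dropped (exact: they cancel in the determinant ratio).
kgv_from_cov <- function(C, dims, kappa) {
  off <- c(0L, cumsum(dims))
  idxs <- lapply(seq_along(dims), function(i) (off[i] + 1L):off[i + 1L])
  vbar <- vapply(idxs, function(ix) mean(diag(C)[ix]), numeric(1))
  live <- vbar > 0
  if (sum(live) < 2L) return(0)
  idxs <- idxs[live]; vbar <- vbar[live]
  keep <- unlist(idxs)
  ridge <- rep(kappa * vbar, times = dims[live])
  M <- C[keep, keep, drop = FALSE] + diag(ridge, length(keep))
  ld_full <- determinant(M, logarithm = TRUE)$modulus
  pos <- c(0L, cumsum(dims[live]))
  ld_diag <- 0
  for (i in seq_along(idxs)) {
    ix <- (pos[i] + 1L):pos[i + 1L]
    ld_diag <- ld_diag + determinant(M[ix, ix, drop = FALSE],
                                     logarithm = TRUE)$modulus
  }
  val <- -0.5 * as.numeric(ld_full - ld_diag)
  if (val < 0) {
    if (val < -1e-9) warning(sprintf("KGV clamped from %g to 0", val))
    val <- 0
  }
  val
}
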
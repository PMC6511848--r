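# Regularized Laplacian diffusion kernel and the label-smoothing solve it
# is derived from.

#' Graph Laplacian of a network
#'
#' Returns `L = D - A` where `D` is the diagonal degree matrix and `A` the
#' adjacency matrix, in the network's (lexicographic) node order.
#'
#' @param net a [ppi_network()].
#' @return dense symmetric matrix with zero row sums and node degrees on
#'   the diagonal; dimnames are the node identifiers.
#' @export
graph_laplacian <- function(net) {
  n <- length(net$nodes)
  L <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges) > 0L) {
    i <- match(net$edges[, 1L], net$nodes)
    j <- match(net$edges[, 2L], net$nodes)
    L[cbind(i, j)] <- -1
    L[cbind(j, i)] <- -1
    diag(L) <- -rowSums(L)
  }
  L
}

#' Regularized Laplacian kernel
#'
#' Computes the diffusion kernel `(I + lambda * L)^{-1}`, the closed-form
#' solution operator of the guilt-by-association label-smoothing objective
#' (see [smooth_labels()]). The matrix is symmetric positive definite with
#' eigenvalues in (0, 1], hence a valid kernel; larger `lambda` diffuses
#' further along the network.
#'
#' The inverse is taken by Cholesky factorization and the result is
#' symmetrized as `(M + t(M))/2` to suppress round-off asymmetry.
#'
#' @param net a [ppi_network()].
#' @param lambda positive diffusion strength (default 0.05).
#' @return dense symmetric kernel matrix with node dimnames and attribute
#'   `lambda`.
#' @examples
#' net <- ppi_network(rbind(c("a", "b")))
#' regularized_laplacian(net, lambda = 1)  # (1/3) * [[2,1],[1,2]]
#' @export
regularized_laplacian <- function(net, lambda = 0.05) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop_input("lambda must be a positive scalar")
  }
  L <- graph_laplacian(net)
  M <- diag(nrow(L)) + lambda * L
  K <- chol2inv(chol(M))
  K <- (K + t(K)) / 2
  dimnames(K) <- dimnames(L)
  attr(K, "lambda") <- lambda
  K
}

# KernelMatrix invariants: symmetric within tol_sym, eigenvalues >= -tol_psd.
check_kernel_matrix <- function(K, tol_sym = 1e-10, tol_psd = 1e-8) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) return("not a square matrix")
  if (max(abs(K - t(K))) > tol_sym) return("not symmetric")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol_psd) return("not positive semidefinite")
  NULL
}

#' Diffuse (smooth) a label vector over a network
#'
#' Solves the guilt-by-association objective
#' `min_y' sum_i (y'_i - y_i)^2 + lambda * sum_ij a_ij (y'_i - y'_j)^2`,
#' balancing fidelity to the given labels against smoothness over edges.
#' The unique minimizer satisfies `(I + lambda * L) yhat = y`, which is
#' solved as a linear system (no explicit inversion).
#'
#' @param net a [ppi_network()].
#' @param y numeric label vector, either in node order or named by node id.
#' @param lambda positive trade-off parameter.
#' @return named numeric vector of smoothed labels in node order.
#' @export
smooth_labels <- function(net, y, lambda = 0.05) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop_input("lambda must be a positive scalar")
  }
  n <- length(net$nodes)
  if (length(y) != n) stop_input("label vector length does not match network")
  if (!is.null(names(y))) {
    if (!setequal(names(y), net$nodes)) {
      stop_input("label vector names do not match network nodes")
    }
    y <- y[net$nodes]
  }
  L <- graph_laplacian(net)
  yhat <- solve(diag(n) + lambda * L, as.numeric(y))
  stats::setNames(as.numeric(yhat), net$nodes)
}
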
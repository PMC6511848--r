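# RKHS factorization of the source kernel, landmark selection, and the
# minimum-norm landmark solve that places target nodes in the source space.

#' Factorize a kernel matrix into RKHS coordinates
#'
#' Computes `C` with `C %*% t(C) = K` via the symmetric eigendecomposition
#' `K = V diag(e) V'`, taking `C = V diag(sqrt(e))`. The factor is unique
#' only up to an orthogonal rotation; all downstream cross-species scores
#' are invariant to that ambiguity. Columns are ordered by descending
#' eigenvalue, eigenvalues below `1e-10` are dropped (this defines the
#' embedding dimension `k`), and each column's sign is fixed so that its
#' largest-magnitude entry is positive.
#'
#' @param K symmetric positive semidefinite matrix with node dimnames.
#' @return n x k coordinate matrix with rownames equal to the node ids and
#'   attribute `source_flag = "factorized"`.
#' @export
factorize_kernel <- function(K) {
  msg <- check_kernel_matrix(K)
  if (!is.null(msg)) stop_input("not a kernel matrix: ", msg)
  eig <- eigen(K, symmetric = TRUE)
  keep <- eig$values >= 1e-10
  V <- eig$vectors[, keep, drop = FALSE]
  ev <- eig$values[keep]
  C <- V %*% diag(sqrt(ev), nrow = length(ev))
  # deterministic sign: largest-|.| entry of each column positive
  for (j in seq_len(ncol(C))) {
    m <- which.max(abs(C[, j]))
    if (C[m, j] < 0) C[, j] <- -C[, j]
  }
  rownames(C) <- rownames(K)
  attr(C, "source_flag") <- "factorized"
  C
}

#' Select landmark pairs from homolog candidates
#'
#' @param candidates a [homolog_pairs()] data frame.
#' @param n_landmarks number of landmark pairs to select; must not exceed
#'   the number of candidates.
#' @param strategy `"random"` draws without replacement under `seed`;
#'   `"degree"` sorts candidates by the average of their within-species
#'   degree ranks (rank 1 = highest degree), ties broken by source id.
#' @param seed RNG seed for the random strategy.
#' @param net1,net2 networks supplying the degrees for the degree strategy.
#' @return a `landmark_list` data frame (columns `source`, `target`) whose
#'   row order defines the shared landmark order of all derived matrices.
#' @export
select_landmarks <- function(candidates, n_landmarks,
                             strategy = c("random", "degree"),
                             seed = NULL, net1 = NULL, net2 = NULL) {
  strategy <- match.arg(strategy)
  n_cand <- nrow(candidates)
  if (n_landmarks < 1L || n_landmarks > n_cand) {
    stop_input("n_landmarks must be between 1 and the number of candidates (",
               n_cand, ")")
  }
  if (strategy == "random") {
    idx <- with_seed(seed, sample.int(n_cand, n_landmarks))
  } else {
    if (is.null(net1) || is.null(net2)) {
      stop_input("degree strategy needs net1 and net2")
    }
    d1 <- network_degree(net1)[candidates$source]
    d2 <- network_degree(net2)[candidates$target]
    r1 <- rank(-d1, ties.method = "min")
    r2 <- rank(-d2, ties.method = "min")
    idx <- order((r1 + r2) / 2, candidates$source)[seq_len(n_landmarks)]
  }
  out <- candidates[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("landmark_list", "data.frame")
  out
}

# Moore-Penrose pseudoinverse via SVD with relative singular-value cutoff.
pseudoinverse <- function(A, rel_tol = 1e-12) {
  sv <- svd(A)
  keep <- sv$d > rel_tol * sv$d[1L]
  if (!all(keep)) {
    message(sum(!keep), " singular value(s) below cutoff dropped in pseudoinverse")
  }
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Embed target-network nodes into the source RKHS
#'
#' Solves the underdetermined linear system `C1L %*% t(C2hat) = D2L`,
#' where `C1L` holds the source-landmark coordinate rows and `D2L` the
#' target-kernel rows at the landmark targets. Among all solutions
#' `t(C2hat) = pinv(C1L) %*% D2L + (I - pinv(C1L) %*% C1L) %*% W`, the
#' minimum-Frobenius-norm one (`W = 0`) is returned.
#'
#' @param C1 source coordinates from [factorize_kernel()].
#' @param D2 target kernel matrix with node dimnames.
#' @param landmarks a `landmark_list` from [select_landmarks()].
#' @return n x k coordinate matrix for all target nodes, rownames = target
#'   node ids, attribute `source_flag = "solved"`.
#' @export
embed_target <- function(C1, D2, landmarks) {
  if (NROW(landmarks) == 0L) stop_input("empty landmark list")
  if (!all(landmarks$source %in% rownames(C1))) {
    stop_input("landmark source node(s) missing from source embedding")
  }
  if (!all(landmarks$target %in% rownames(D2))) {
    stop_input("landmark target node(s) missing from target kernel")
  }
  C1L <- C1[landmarks$source, , drop = FALSE]
  D2L <- D2[landmarks$target, , drop = FALSE]
  C2hatT <- pseudoinverse(C1L) %*% D2L
  C2hat <- t(C2hatT)
  rownames(C2hat) <- colnames(D2)
  attr(C2hat, "source_flag") <- "solved"
  C2hat
}

#' Cross-species similarity scores
#'
#' Inner products `C1 %*% t(C2hat)` between every source node and every
#' target node, both expressed in the shared RKHS.
#'
#' @param C1 source coordinates.
#' @param C2hat target coordinates from [embed_target()].
#' @return m x n score matrix, rows = source nodes, columns = target nodes.
#' @export
cross_species_scores <- function(C1, C2hat) {
  if (ncol(C1) != ncol(C2hat)) {
    stop_input("embedding dimension mismatch: ", ncol(C1), " vs ", ncol(C2hat))
  }
  C1 %*% t(C2hat)
}

#' Convert similarity scores to dissimilarities
#'
#' Positive scores are mapped to their reciprocals, so small values mean
#' functionally close; the ordering of positive scores is exactly reversed.
#' Non-positive scores, which can arise after the landmark solve, have no
#' meaningful reciprocal and are mapped to `Inf`.
#'
#' @param scores score matrix from [cross_species_scores()].
#' @return matrix of the same shape; entries `1/s` for `s > 0`, else `Inf`.
#' @export
to_dissimilarity <- function(scores) {
  out <- ifelse(scores > 0, 1 / scores, Inf)
  dimnames(out) <- dimnames(scores)
  out
}
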
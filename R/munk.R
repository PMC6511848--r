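# The main fit: joint embedding of two PPI networks in one RKHS.

#' Fit a cross-species network embedding
#'
#' Embeds the proteins of a source and a target interaction network into a
#' single shared vector space. The pipeline is: (optionally) preprocess
#' both networks to the two-core of their largest connected component;
#' compute the regularized Laplacian diffusion kernel of each network;
#' factorize the source kernel into RKHS coordinates `C1`; select landmark
#' homolog pairs; solve the minimum-norm landmark system for the target
#' coordinates `C2hat`; and form the cross-species score matrix
#' `D12 = C1 %*% t(C2hat)`. Inner products between rows of `C1` and
#' `C2hat` estimate cross-species functional similarity.
#'
#' By convention the larger network is usually taken as the source and the
#' smaller embedded into it; the function itself uses the networks exactly
#' as passed.
#'
#' @param source,target [ppi_network()] objects (source defines the RKHS).
#' @param homologs homolog candidate pairs: anything [homolog_pairs()]
#'   accepts (filtering against the preprocessed networks is redone here).
#' @param lambda diffusion strength of the regularized Laplacian
#'   (default 0.05).
#' @param n_landmarks number of landmark pairs; the default `NULL` uses
#'   `min(400, number of candidates)`.
#' @param strategy landmark selection strategy, `"random"` or `"degree"`.
#' @param seed RNG seed for random landmark selection.
#' @param preprocess apply [preprocess_network()] to both networks first
#'   (default `TRUE`).
#' @return an object of class `munk` with components `C1`, `C2hat`
#'   (embedding coordinate matrices), `D1`, `D2` (per-network kernels),
#'   `D12` (cross-species scores), `landmarks`, `homologs` (the filtered
#'   candidate set), `source_network`, `target_network`, `lambda`, `call`.
#' @seealso [predict.munk()], [residuals.munk()], [pair_representation()]
#' @examples
#' pair <- make_network_pair(n = 60, density = 0.08, rewire_fraction = 0.1,
#'                           seed = 1)
#' fit <- munk(pair$net1, pair$net2, truth_pairs(pair),
#'             n_landmarks = 10, seed = 1)
#' fit
#' @export
munk <- function(source, target, homologs, lambda = 0.05,
                 n_landmarks = NULL, strategy = c("random", "degree"),
                 seed = NULL, preprocess = TRUE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(source, "ppi_network"), inherits(target, "ppi_network"))
  if (preprocess) {
    source <- preprocess_network(source)
    target <- preprocess_network(target)
  }
  if (length(source$nodes) == 0L || length(target$nodes) == 0L) {
    stop_input("a network is empty after preprocessing")
  }
  homologs <- homolog_pairs(homologs, source, target)
  if (is.null(n_landmarks)) n_landmarks <- min(400L, nrow(homologs))
  D1 <- regularized_laplacian(source, lambda)
  D2 <- regularized_laplacian(target, lambda)
  C1 <- factorize_kernel(D1)
  landmarks <- select_landmarks(homologs, n_landmarks, strategy, seed,
                                source, target)
  C2hat <- embed_target(C1, D2, landmarks)
  D12 <- cross_species_scores(C1, C2hat)
  structure(list(C1 = C1, C2hat = C2hat, D1 = D1, D2 = D2, D12 = D12,
                 landmarks = landmarks, homologs = homologs,
                 source_network = source, target_network = target,
                 lambda = lambda, strategy = strategy, seed = seed,
                 call = match.call()),
            class = "munk")
}

#' @export
print.munk <- function(x, ...) {
  cat("Cross-species network embedding (regularized Laplacian kernel)\n")
  cat(sprintf("  source: '%s' (%d nodes) -> target: '%s' (%d nodes)\n",
              x$source_network$species, nrow(x$C1),
              x$target_network$species, nrow(x$C2hat)))
  cat(sprintf("  embedding dimension k = %d, lambda = %g\n",
              ncol(x$C1), x$lambda))
  cat(sprintf("  landmarks: %d of %d homolog candidates (%s)\n",
              nrow(x$landmarks), nrow(x$homologs), x$strategy))
  invisible(x)
}

#' @export
summary.munk <- function(object, ...) {
  res <- residuals(object)
  out <- list(
    fit = object,
    landmark_residual_max = max(abs(res)),
    reconstruction_error = max(abs(object$C1 %*% t(object$C1) - object$D1))
  )
  dis <- to_dissimilarity(object$D12)
  held_out <- object$homologs[!(object$homologs$source %in% object$landmarks$source |
                                object$homologs$target %in% object$landmarks$target), ,
                              drop = FALSE]
  if (nrow(held_out) > 0L) {
    out$contrast <- homolog_score_contrast(dis, object$homologs, object$landmarks)
  }
  class(out) <- "summary.munk"
  out
}

#' @export
print.summary.munk <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  source kernel reconstruction max error: %.3g\n",
              x$reconstruction_error))
  cat(sprintf("  landmark constraint max residual:       %.3g\n",
              x$landmark_residual_max))
  if (!is.null(x$contrast)) {
    cat(sprintf(paste0("  mean dissimilarity, held-out homologs vs other",
                       " pairs: %.4g vs %.4g (ratio %.3f)\n"),
                x$contrast["mean_homolog"], x$contrast["mean_other"],
                x$contrast["ratio"]))
  }
  invisible(x)
}

#' Embedding coordinates of a fitted cross-species embedding
#'
#' @param object a [munk()] fit.
#' @param species `"source"`, `"target"`, or `"both"` (rows stacked, with a
#'   `species` attribute removed; row names stay the node ids).
#' @param ... unused.
#' @return coordinate matrix, one row per node.
#' @export
coef.munk <- function(object, species = c("both", "source", "target"), ...) {
  species <- match.arg(species)
  switch(species,
         source = object$C1,
         target = object$C2hat,
         both = rbind(object$C1, object$C2hat))
}

#' Cross-species similarity or dissimilarity scores
#'
#' @param object a [munk()] fit.
#' @param pairs optional two-column matrix/data frame of (source id,
#'   target id) pairs; if omitted the full score matrix is returned.
#' @param type `"similarity"` (inner products) or `"dissimilarity"`
#'   (reciprocals; non-positive similarities become `Inf`).
#' @param ... unused.
#' @return matrix of scores, or a numeric vector when `pairs` is given.
#' @export
predict.munk <- function(object, pairs = NULL,
                         type = c("similarity", "dissimilarity"), ...) {
  type <- match.arg(type)
  S <- object$D12
  if (type == "dissimilarity") S <- to_dissimilarity(S)
  if (is.null(pairs)) return(S)
  pairs <- as.matrix(pairs)
  bad <- !(pairs[, 1L] %in% rownames(S)) | !(pairs[, 2L] %in% colnames(S))
  if (any(bad)) {
    stop_input("pair(s) with unknown node ids, e.g. (",
               pairs[which(bad)[1L], 1L], ", ", pairs[which(bad)[1L], 2L], ")")
  }
  S[cbind(pairs[, 1L], pairs[, 2L])]
}

#' Landmark-constraint residuals
#'
#' The landmark solve requires `C1L %*% t(C2hat) = D2L`; this returns the
#' residual matrix of that constraint (rows = landmarks, columns = target
#' nodes). When the landmark coordinate block has full row rank, residuals
#' are numerically zero.
#'
#' @param object a [munk()] fit.
#' @param ... unused.
#' @return residual matrix.
#' @export
residuals.munk <- function(object, ...) {
  C1L <- object$C1[object$landmarks$source, , drop = FALSE]
  D2L <- object$D2[object$landmarks$target, , drop = FALSE]
  C1L %*% t(object$C2hat) - D2L
}

#' Diagnostic plot of cross-species dissimilarities
#'
#' Plots the distribution of finite cross-species dissimilarity scores for
#' held-out homolog pairs (excluding landmarks) against all other pairs.
#' Homologs concentrating at small dissimilarities indicates that the
#' embedding carries cross-species functional signal.
#'
#' @param x a [munk()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.munk <- function(x, ...) {
  dis <- to_dissimilarity(x$D12)
  lm_src <- x$landmarks$source
  lm_tgt <- x$landmarks$target
  keep_r <- setdiff(rownames(dis), lm_src)
  keep_c <- setdiff(colnames(dis), lm_tgt)
  sub <- dis[keep_r, keep_c, drop = FALSE]
  hom <- x$homologs[x$homologs$source %in% keep_r &
                    x$homologs$target %in% keep_c, , drop = FALSE]
  hv <- sub[cbind(hom$source, hom$target)]
  hv <- hv[is.finite(hv)]
  ov <- sub[is.finite(sub)]
  if (length(hv) == 0L) {
    graphics::hist(log10(ov), main = "Cross-species dissimilarity",
                   xlab = "log10 dissimilarity", ...)
    return(invisible(x))
  }
  dh <- stats::density(log10(hv))
  do <- stats::density(log10(ov))
  graphics::plot(do, col = "grey40", main = "Cross-species dissimilarity",
                 xlab = "log10 dissimilarity",
                 ylim = range(0, dh$y, do$y), ...)
  graphics::lines(dh, col = "firebrick")
  graphics::legend("topright", legend = c("other pairs", "homolog pairs"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
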
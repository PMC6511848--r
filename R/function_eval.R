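# Cross-species functional-similarity evaluation: Resnik semantic
# similarity, Hungarian matching + GO consistency, k-functional similarity
# + AUPR, homolog score contrast, degree-preserving permutation null, and
# multi-species function prediction over a simplex of species weights.

#' Resnik semantic similarity between two genes
#'
#' The information content (IC) of a term is `-log` of the fraction of
#' corpus genes annotated to it (after propagation). The Resnik score of
#' two terms is the maximum IC over their common ancestors, and the score
#' of two genes is the maximum over all pairs of their terms. With
#' ancestor-closed term sets this equals the maximum IC over the
#' intersection of the two genes' closed term sets.
#'
#' @param ann an [ontology_annotation()] supplying the term DAG.
#' @param corpus named list mapping each corpus gene to its (propagated)
#'   term set; defines the IC denominator. For cross-species pairs use the
#'   union corpus of the two species.
#' @param g1,g2 gene identifiers.
#' @return nonnegative scalar, or `NA` if either gene is unannotated.
#' @export
resnik_protein <- function(ann, corpus, g1, g2) {
  anc <- term_ancestors(ann$dag)
  closed <- function(g) {
    terms <- corpus[[g]]
    if (is.null(terms) || length(terms) == 0L) return(NULL)
    unique(unlist(anc[terms], use.names = FALSE))
  }
  t1 <- closed(g1)
  t2 <- closed(g2)
  if (is.null(t1) || is.null(t2)) return(NA_real_)
  common <- intersect(t1, t2)
  if (length(common) == 0L) return(0)
  ic <- term_information_content(ann, corpus)
  max(ic[common], na.rm = TRUE)
}

#' Information content of every term under a gene corpus
#'
#' @inheritParams resnik_protein
#' @return named numeric vector: `-log(n_genes_with_term / n_genes)` for
#'   each term of the DAG, using ancestor-closed gene term sets; terms
#'   annotating no gene get `NA`.
#' @export
term_information_content <- function(ann, corpus) {
  anc <- term_ancestors(ann$dag)
  n <- length(corpus)
  counts <- stats::setNames(numeric(length(ann$dag$terms)), ann$dag$terms)
  for (terms in corpus) {
    closed <- unique(unlist(anc[terms], use.names = FALSE))
    counts[closed] <- counts[closed] + 1
  }
  ic <- -log(counts / n)
  ic[counts == 0] <- NA_real_
  ic
}

#' One-to-one matching of the smaller network into the larger
#'
#' Applies the Hungarian algorithm to a cross-species similarity matrix,
#' maximizing the total matched score. Every node of the smaller side is
#' matched to a distinct node of the larger side.
#'
#' @param scores finite score matrix (rows = source, columns = target).
#' @return data frame with columns `from` (smaller side) and `to` (larger
#'   side) plus attribute `orientation` (`"rows"` or `"cols"`: which side
#'   of `scores` is the smaller, `from`, side).
#' @export
hungarian_match <- function(scores) {
  if (any(!is.finite(scores))) stop_input("scores must be finite for matching")
  flipped <- nrow(scores) > ncol(scores)
  S <- if (flipped) t(scores) else scores
  # solve_LSAP needs nonnegative entries; shifting leaves the argmax intact
  shifted <- S - min(S)
  sol <- clue::solve_LSAP(shifted, maximum = TRUE)
  out <- data.frame(from = rownames(S), to = colnames(S)[as.integer(sol)],
                    stringsAsFactors = FALSE)
  attr(out, "orientation") <- if (flipped) "cols" else "rows"
  class(out) <- c("matching_result", "data.frame")
  out
}

#' Gene Ontology consistency of a matching
#'
#' Mean Jaccard index of the term sets of matched gene pairs. Pairs where
#' both term sets are empty carry no information and are excluded from the
#' mean; pairs with exactly one empty set contribute 0.
#'
#' @param match a [hungarian_match()] result (or any data frame with
#'   columns `from`, `to`).
#' @param terms_from,terms_to named lists mapping gene ids of the two sides
#'   to their (propagated) term sets.
#' @return scalar in \[0, 1\].
#' @export
goc <- function(match, terms_from, terms_to) {
  if (NROW(match) == 0L) stop_input("empty matching")
  jac <- mapply(function(a, b) {
    ta <- terms_from[[a]]
    tb <- terms_to[[b]]
    na <- length(ta); nb <- length(tb)
    if (na == 0L && nb == 0L) return(NA_real_)
    if (na == 0L || nb == 0L) return(0)
    length(intersect(ta, tb)) / length(union(ta, tb))
  }, match$from, match$to)
  if (all(is.na(jac))) stop_input("no matched pair has any annotation")
  mean(jac, na.rm = TRUE)
}

#' k-functional-similarity labels for all cross-species gene pairs
#'
#' A pair is labeled 1 iff some term annotates both genes and that term
#' annotates at most `k` genes in each species.
#'
#' @param terms1,terms2 named lists mapping genes of species 1 / 2 to their
#'   (propagated) term sets.
#' @param k maximum per-species term size for a term to count (default 100).
#' @return binary matrix, rows = genes of species 1, columns = species 2.
#' @export
kfs_labels <- function(terms1, terms2, k = 100) {
  stopifnot(k >= 1)
  all_terms <- sort(unique(c(unlist(terms1, use.names = FALSE),
                             unlist(terms2, use.names = FALSE))))
  inc <- function(tl) {
    M <- matrix(0L, length(tl), length(all_terms),
                dimnames = list(names(tl), all_terms))
    for (g in names(tl)) M[g, tl[[g]]] <- 1L
    M
  }
  M1 <- inc(terms1)
  M2 <- inc(terms2)
  ok <- colSums(M1) <= k & colSums(M2) <= k
  lab <- (M1[, ok, drop = FALSE] %*% t(M2[, ok, drop = FALSE]) > 0) * 1L
  lab
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over the score ranking: thresholds sweep the
#' distinct score values from high to low, tied scores enter together, and
#' the area is the sum of precision times recall increment.
#'
#' @param scores numeric scores, larger = more confidently positive.
#' @param labels binary labels (0/1 or logical) of the same length.
#' @return scalar in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  P <- sum(labels)
  if (P == 0L || P == length(labels)) {
    stop_input("labels must contain both classes")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp_end <- cumsum(rle(s)$lengths)    # last index of each tie group
  tp <- cumsum(l)[grp_end]
  n_pred <- grp_end
  prec <- tp / n_pred
  rec <- tp / P
  sum(prec * diff(c(0, rec)))
}

#' Maximum F1 score of one ranking
#'
#' Sweeps every top-n prefix of the ranking (tied scores, if supplied,
#' enter together) and returns the maximum harmonic mean of precision and
#' recall against the truth set.
#'
#' @param ranked character vector of gene ids, best first.
#' @param truth character vector of true genes.
#' @param scores optional scores aligned with `ranked`, used only to group
#'   ties so a threshold never splits equal scores.
#' @return scalar in \[0, 1\].
#' @export
max_f1 <- function(ranked, truth, scores = NULL) {
  if (length(truth) == 0L) stop_input("empty truth set")
  hit <- as.integer(ranked %in% truth)
  tp <- cumsum(hit)
  n <- seq_along(ranked)
  if (!is.null(scores)) {
    keep <- cumsum(rle(scores)$lengths)
    tp <- tp[keep]; n <- n[keep]
  }
  prec <- tp / n
  rec <- tp / length(truth)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  max(f1)
}

#' Mean maximum F1 over a collection of per-term rankings
#'
#' @param predictions named list: term id -> data frame with columns `gene`
#'   and `score` sorted best-first (as returned by
#'   [multispecies_predict()]), or a ranked character vector.
#' @param truth named list: term id -> character vector of true genes.
#' @return unweighted mean of the per-term maximum F1 scores; terms with an
#'   empty truth set are excluded with a warning.
#' @export
max_f1_over_terms <- function(predictions, truth) {
  terms <- names(predictions)
  if (length(terms) == 0L) stop_input("no terms to evaluate")
  empty <- vapply(terms, function(t) length(truth[[t]]) == 0L, logical(1))
  if (any(empty)) {
    warning(sum(empty), " term(s) with empty truth set excluded", call. = FALSE)
    terms <- terms[!empty]
    if (length(terms) == 0L) stop_input("all truth sets empty")
  }
  vals <- vapply(terms, function(t) {
    p <- predictions[[t]]
    if (is.data.frame(p)) max_f1(p$gene, truth[[t]], p$score)
    else max_f1(p, truth[[t]])
  }, numeric(1))
  mean(vals)
}

#' Homolog versus non-homolog dissimilarity contrast
#'
#' Compares the mean cross-species dissimilarity of homolog pairs with the
#' mean over all other pairs, after removing every pair that involves a
#' landmark gene on either side (landmarks anchor the embedding and would
#' trivially score well). Only finite dissimilarities enter the means.
#'
#' @param dissim dissimilarity matrix from [to_dissimilarity()].
#' @param homologs a [homolog_pairs()] data frame.
#' @param landmarks a `landmark_list`; its genes are excluded.
#' @return named vector `(mean_homolog, mean_other, ratio)` with
#'   `ratio = mean_homolog / mean_other` (< 1 means homologs score closer).
#' @export
homolog_score_contrast <- function(dissim, homologs, landmarks) {
  keep_r <- setdiff(rownames(dissim), landmarks$source)
  keep_c <- setdiff(colnames(dissim), landmarks$target)
  sub <- dissim[keep_r, keep_c, drop = FALSE]
  hom <- homologs[homologs$source %in% keep_r & homologs$target %in% keep_c, ,
                  drop = FALSE]
  if (nrow(hom) == 0L) stop_input("no non-landmark homolog pairs")
  hmask <- matrix(FALSE, nrow(sub), ncol(sub), dimnames = dimnames(sub))
  hmask[cbind(hom$source, hom$target)] <- TRUE
  hv <- sub[hmask & is.finite(sub)]
  ov <- sub[!hmask & is.finite(sub)]
  if (length(hv) == 0L || length(ov) == 0L) {
    stop_input("a contrast group has no finite dissimilarities")
  }
  c(mean_homolog = mean(hv), mean_other = mean(ov),
    ratio = mean(hv) / mean(ov))
}

# mean similarity difference (homolog - other), landmark genes excluded;
# shared by the degree-preserving null test
similarity_contrast_diff <- function(D12, homologs, landmarks) {
  keep_r <- setdiff(rownames(D12), landmarks$source)
  keep_c <- setdiff(colnames(D12), landmarks$target)
  sub <- D12[keep_r, keep_c, drop = FALSE]
  hom <- homologs[homologs$source %in% keep_r & homologs$target %in% keep_c, ,
                  drop = FALSE]
  if (nrow(hom) == 0L) stop_input("no non-landmark homolog pairs")
  hmask <- matrix(FALSE, nrow(sub), ncol(sub), dimnames = dimnames(sub))
  hmask[cbind(hom$source, hom$target)] <- TRUE
  mean(sub[hmask]) - mean(sub[!hmask])
}

#' Degree-preserving permutation test of the homolog contrast
#'
#' Tests whether homolog pairs have higher cross-species similarity than
#' expected from node degrees alone. Both networks are rewired with the
#' configuration model (exact degree sequences, stub matching, then self
#' loops and parallel edges removed), the full embedding pipeline is rerun,
#' and the difference in mean similarity between homolog and other pairs is
#' recorded. The empirical p-value is
#' `(1 + #permutation diffs >= observed) / (n_perm + 1)`.
#'
#' @param net1,net2 preprocessed source and target [ppi_network()]s.
#' @param homologs a [homolog_pairs()] data frame (against `net1`,`net2`).
#' @param landmarks `landmark_list` used for every embedding (held fixed
#'   across permutations so only the wiring changes).
#' @param n_perm number of degree-preserving permutations.
#' @param seed RNG seed.
#' @param lambda diffusion strength passed to the kernel.
#' @return list with `p_value`, `observed` difference and the vector of
#'   `null` differences.
#' @export
degree_null_pvalue <- function(net1, net2, homologs, landmarks,
                               n_perm = 99, seed = NULL, lambda = 0.05) {
  stopifnot(n_perm >= 1)
  run <- function(g1, g2) {
    D1 <- regularized_laplacian(g1, lambda)
    D2 <- regularized_laplacian(g2, lambda)
    C1 <- factorize_kernel(D1)
    C2hat <- embed_target(C1, D2, landmarks)
    similarity_contrast_diff(cross_species_scores(C1, C2hat),
                             homologs, landmarks)
  }
  observed <- run(net1, net2)
  null_diffs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      s1 <- sample.int(.Machine$integer.max, 1L)
      s2 <- sample.int(.Machine$integer.max, 1L)
      r1 <- degree_preserving_randomize(net1, seed = s1)
      r2 <- degree_preserving_randomize(net2, seed = s2)
      tryCatch(run(r1, r2),
               error = function(e) {
                 stop_input("pipeline failed on permutation ", b, ": ",
                            conditionMessage(e))
               })
    }, numeric(1))
  })
  p <- (1 + sum(null_diffs >= observed)) / (n_perm + 1)
  list(p_value = p, observed = observed, null = null_diffs)
}

#' Simplex grid of species weights
#'
#' All nonnegative weight vectors over `d` species with components that are
#' multiples of `step` and sum to one.
#'
#' @param step grid step (e.g. 0.25 yields 15 vectors for 3 species).
#' @param d number of species (default 3).
#' @return matrix with `d` columns, one weight vector per row.
#' @export
simplex_weights <- function(step = 0.25, d = 3L) {
  m <- round(1 / step)
  stopifnot(abs(m * step - 1) < 1e-9)
  grid <- expand.grid(rep(list(0:m), d - 1L))
  keep <- rowSums(grid) <= m
  grid <- as.matrix(grid[keep, , drop = FALSE])
  W <- cbind(grid, m - rowSums(grid)) / m
  colnames(W) <- NULL
  rownames(W) <- NULL
  W
}

#' Rank candidate genes for one term using multiple species
#'
#' Guilt-by-association scoring across species: each candidate gene of the
#' focal species accumulates similarity to every gene annotated with the
#' term, within its own network (via the focal diffusion kernel) and in
#' other species (via cross-species score matrices), combined with a convex
#' weight per species. Genes already annotated with the term in the focal
#' species are seeds and are excluded from the candidate list.
#'
#' @param self_kernel focal-species kernel matrix (genes x genes).
#' @param cross_scores named list of cross-species score matrices, rows =
#'   focal genes, columns = the other species' genes.
#' @param weights named nonnegative weights summing to 1; names are the
#'   focal species' name followed by `names(cross_scores)`.
#' @param annotations named list (same names as `weights`) of gene ->
#'   term-set mappings; the paper-style usage passes specific (unpropagated)
#'   annotations here.
#' @param term term identifier to predict.
#' @param occurrence_range admissible number of focal-species genes
#'   annotated with the term; terms outside the band are skipped with a
#'   warning (default `c(2, 300)`, targeting rare terms).
#' @return data frame with columns `gene`, `score`, sorted by decreasing
#'   score (ties by gene id), or `NULL` if the term is out of band.
#' @export
multispecies_predict <- function(self_kernel, cross_scores, weights,
                                 annotations, term,
                                 occurrence_range = c(2, 300)) {
  sp <- names(weights)
  stopifnot(length(sp) == 1L + length(cross_scores),
            all(names(cross_scores) %in% sp))
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-9) {
    stop_input("weights must be nonnegative and sum to 1")
  }
  focal <- setdiff(sp, names(cross_scores))[1L]
  seeds <- lapply(sp, function(s) {
    ann <- annotations[[s]]
    names(ann)[vapply(ann, function(ts) term %in% ts, logical(1))]
  })
  names(seeds) <- sp
  n_occ <- length(seeds[[focal]])
  if (n_occ < occurrence_range[1L] || n_occ > occurrence_range[2L]) {
    warning("term '", term, "' occurs ", n_occ,
            " times in the focal corpus; outside the admissible band",
            call. = FALSE)
    return(NULL)
  }
  candidates <- setdiff(rownames(self_kernel), seeds[[focal]])
  score <- stats::setNames(numeric(length(candidates)), candidates)
  sf <- intersect(seeds[[focal]], colnames(self_kernel))
  if (weights[focal] > 0 && length(sf) > 0L) {
    score <- score + weights[focal] *
      rowSums(self_kernel[candidates, sf, drop = FALSE])
  }
  for (s in names(cross_scores)) {
    ss <- intersect(seeds[[s]], colnames(cross_scores[[s]]))
    if (weights[s] > 0 && length(ss) > 0L) {
      score <- score + weights[s] *
        rowSums(cross_scores[[s]][candidates, ss, drop = FALSE])
    }
  }
  ord <- order(-score, candidates)
  data.frame(gene = candidates[ord], score = as.numeric(score[ord]),
             stringsAsFactors = FALSE)
}
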
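# Generalized phenolog discovery: cross-species phenotype pairs enriched
# for functionally similar (embedding-close) gene pairs. Functional
# similarity plays the role classical homology played in the original
# phenolog test: target-species phenotype genes are mapped through a
# thresholded cross-species relation into the source universe, and the
# overlap with the source phenotype's genes is scored by a hypergeometric
# upper tail, with a permutation estimate of the false discovery rate.

#' Construct a phenotype -> gene-set map
#'
#' @param records data frame with columns `species`, `phenotype`, `gene`
#'   (one row per association).
#' @return a `phenotype_gene_map`: named list phenotype -> character vector
#'   of genes, with a `species` attribute.
#' @export
phenotype_gene_map <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "phenotype", "gene") %in% names(records)))
  sp <- unique(records$species)
  if (length(sp) != 1L) stop_input("one species per map")
  m <- lapply(split(records$gene, records$phenotype),
              function(g) sort(unique(g)))
  if (any(lengths(m) == 0L)) stop_input("empty phenotype gene set")
  structure(m, species = sp, class = c("phenotype_gene_map", "list"))
}

#' Read a phenotype map from a three-column TSV (species, phenotype, gene)
#' @param path path to the file.
#' @return a [phenotype_gene_map()].
#' @export
read_phenotype_map <- function(path) {
  phenotype_gene_map(read_three_col(path, c("species", "phenotype", "gene")))
}

#' Threshold dissimilarities into a binary functional-similarity relation
#'
#' @param dissim cross-species dissimilarity matrix (source x target).
#' @param tau positive threshold: pairs with dissimilarity `<= tau` are
#'   related. The relation grows monotonically with `tau`. The default
#'   picks a stringent threshold, the `quantile_q`-th quantile of the
#'   finite dissimilarities.
#' @param quantile_q quantile used when `tau` is `NULL` (default 0.001).
#' @return logical source x target matrix.
#' @export
functional_pair_relation <- function(dissim, tau = NULL, quantile_q = 0.001) {
  if (is.null(tau)) {
    tau <- stats::quantile(dissim[is.finite(dissim)], quantile_q, names = FALSE)
  }
  if (tau <= 0) stop_input("tau must be positive")
  rel <- is.finite(dissim) & dissim <= tau
  attr(rel, "tau") <- tau
  rel
}

#' Map a target-species gene set into the source species
#'
#' @param relation logical relation matrix from [functional_pair_relation()].
#' @param geneset_b character vector of target-species genes.
#' @return character vector: source genes related to at least one gene of
#'   `geneset_b`.
#' @export
map_geneset <- function(relation, geneset_b) {
  cols <- intersect(geneset_b, colnames(relation))
  if (length(cols) == 0L) return(character(0))
  sort(rownames(relation)[rowSums(relation[, cols, drop = FALSE]) > 0])
}

#' Hypergeometric overlap test for one phenotype pair
#'
#' @param set_a source-species genes of phenotype A (within the universe).
#' @param mapped_b source-species image of phenotype B's genes under the
#'   functional relation (within the universe).
#' @param universe size of the source gene universe (or the universe gene
#'   vector itself).
#' @return named vector `(overlap, p)`: the overlap count and the upper
#'   tail `P(X >= overlap)` of the hypergeometric with `|mapped_b|`
#'   successes, `universe - |mapped_b|` failures and `|set_a|` draws.
#' @export
phenolog_pvalue <- function(set_a, mapped_b, universe) {
  N <- if (is.numeric(universe) && length(universe) == 1L) universe
       else length(unique(universe))
  ka <- length(unique(set_a))
  kb <- length(unique(mapped_b))
  if (ka > N || kb > N) stop_input("set larger than the universe")
  ov <- length(intersect(set_a, mapped_b))
  p <- stats::phyper(ov - 1, m = kb, n = N - kb, k = ka, lower.tail = FALSE)
  c(overlap = ov, p = p)
}

# all-pairs p-values for two phenotype maps; relation & universe fixed.
# Returns data.frame(phenotype_a, phenotype_b, overlap, pair_count, p).
scan_pvalues <- function(sets_a, sets_b, relation, universe_genes) {
  mapped <- lapply(sets_b, function(gb) {
    intersect(map_geneset(relation, gb), universe_genes)
  })
  N <- length(universe_genes)
  out <- vector("list", length(sets_a) * length(sets_b))
  i <- 0L
  for (pa in names(sets_a)) {
    ga <- intersect(sets_a[[pa]], universe_genes)
    for (pb in names(sets_b)) {
      i <- i + 1L
      mb <- mapped[[pb]]
      ov <- length(intersect(ga, mb))
      p <- stats::phyper(ov - 1, m = length(mb), n = N - length(mb),
                         k = length(ga), lower.tail = FALSE)
      # diagnostic: number of related cross-species gene pairs between the
      # two phenotype gene sets
      cols <- intersect(sets_b[[pb]], colnames(relation))
      pc <- if (length(ga) && length(cols)) {
        sum(relation[ga, cols, drop = FALSE])
      } else 0L
      out[[i]] <- data.frame(phenotype_a = pa, phenotype_b = pb,
                             overlap = ov, pair_count = as.integer(pc),
                             p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Scan all cross-species phenotype pairs for phenologs
#'
#' Computes a hypergeometric overlap p-value for every (phenotype A,
#' phenotype B) pair and estimates false-discovery-rate q-values by
#' rerunning the scan on gene-label-permuted maps: for each observed
#' p-value, q is the mean number of null p-values at or below it per
#' permutation, divided by the observed count (monotonized, capped at 1).
#'
#' @param map_a source-species [phenotype_gene_map()].
#' @param map_b target-species [phenotype_gene_map()].
#' @param relation functional-similarity relation from
#'   [functional_pair_relation()].
#' @param universe source-species gene universe; default: source genes of
#'   the relation that occur in at least one phenotype of `map_a`.
#' @param n_perm number of gene-label permutations (default 100).
#' @param alpha q-value cutoff defining the reported hits (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return a `phenolog_scan`: list with `results` (all pairs with overlap,
#'   related-pair count, p and q, sorted by p) and `hits` (the subset with
#'   `q <= alpha`), plus the parameters used.
#' @export
phenolog_scan <- function(map_a, map_b, relation, universe = NULL,
                          n_perm = 100L, alpha = 0.05, seed = NULL) {
  stopifnot(n_perm >= 1L)
  if (!any(relation)) stop_input("empty functional relation")
  if (is.null(universe)) {
    universe <- intersect(rownames(relation),
                          unique(unlist(map_a, use.names = FALSE)))
  }
  universe <- sort(unique(universe))
  if (length(universe) == 0L) stop_input("empty gene universe")
  sets_a <- lapply(unclass(map_a), function(g) sort(g))
  sets_b <- lapply(unclass(map_b), function(g) sort(g))
  obs <- scan_pvalues(sets_a, sets_b, relation, universe)

  tgt_genes <- colnames(relation)
  null_p <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(b) {
      perm_a <- stats::setNames(sample(universe), universe)
      perm_b <- stats::setNames(sample(tgt_genes), tgt_genes)
      pa <- lapply(sets_a, function(g) {
        g <- intersect(g, universe)
        unname(perm_a[g])
      })
      pb <- lapply(sets_b, function(g) {
        g <- intersect(g, tgt_genes)
        unname(perm_b[g])
      })
      scan_pvalues(pa, pb, relation, universe)$p
    }), use.names = FALSE)
  })

  ord <- order(obs$p, obs$phenotype_a, obs$phenotype_b)
  obs <- obs[ord, , drop = FALSE]
  n_obs <- nrow(obs)
  # empirical FDR at each observed p, then enforce monotonicity in p
  null_sorted <- sort(null_p)
  exp_null <- findInterval(obs$p, null_sorted) / n_perm
  obs_count <- seq_len(n_obs)  # obs sorted by p: count of p_j <= p_i is >= i
  obs_count <- vapply(seq_len(n_obs),
                      function(i) sum(obs$p <= obs$p[i]), numeric(1))
  q <- pmin(1, exp_null / obs_count)
  q <- rev(cummin(rev(q)))
  obs$q <- q
  rownames(obs) <- NULL
  structure(list(results = obs, hits = obs[obs$q <= alpha, , drop = FALSE],
                 alpha = alpha, n_perm = n_perm,
                 tau = attr(relation, "tau"),
                 universe_size = length(universe)),
            class = "phenolog_scan")
}

#' @export
print.phenolog_scan <- function(x, ...) {
  cat(sprintf("Phenolog scan: %d phenotype pairs, universe %d genes, %d permutations\n",
              nrow(x$results), x$universe_size, x$n_perm))
  cat(sprintf("  %d hit(s) at q <= %g\n", nrow(x$hits), x$alpha))
  if (nrow(x$hits) > 0L) print(utils::head(x$hits, 10), row.names = FALSE)
  invisible(x)
}
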
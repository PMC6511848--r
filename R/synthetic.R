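# Seed-deterministic generators for every input the pipeline consumes:
# correlated network pairs with known node correspondence, degree-preserving
# configuration-model nulls, planted pathway-structured synthetic-lethal
# datasets, and toy ontologies / phenotype maps with module-correlated
# annotations.

# iterate LCC + two-core until stable; generators return stable networks so
# downstream preprocessing leaves them (and the recorded truth) unchanged
preprocess_to_fixed_point <- function(net) {
  repeat {
    if (length(net$nodes) == 0L) return(net)
    nxt <- two_core(largest_connected_component(net))
    if (identical(nxt$nodes, net$nodes)) return(nxt)
    net <- nxt
  }
}

#' Generate a correlated pair of networks with known correspondence
#'
#' `net1` is grown by a duplication-divergence process (each new node
#' copies a random existing node's neighbours, keeping each with a fixed
#' retention probability, plus an edge to the copied node), which yields
#' the heavy-tailed degree distributions typical of PPI networks; uniform
#' random edges are then added to reach the requested density. `net2` is a
#' relabeled copy in which a fraction of edges is removed and replaced by
#' random non-edges, emulating interactome divergence between species.
#' Both networks are reduced to a stable two-core of their largest
#' component, and the true node correspondence is recorded.
#'
#' @param n number of nodes grown for `net1`.
#' @param density target edge density of `net1` (default 0.03, mean degree
#'   about 9 at n = 300).
#' @param rewire_fraction fraction of `net2`'s edges replaced by random
#'   non-edges (0 = isomorphic copy, 1 = fully independent wiring).
#' @param seed RNG seed; the whole pair is a deterministic function of it.
#' @param retention duplication-divergence neighbour-retention probability.
#' @param max_attempts regenerate at most this many times if preprocessing
#'   empties a network.
#' @return object of class `synthetic_pair`: list with `net1`, `net2`
#'   ([ppi_network()]s), `truth` (named character vector, source node ->
#'   corresponding target node, restricted to nodes surviving in both) and
#'   `params`.
#' @export
make_network_pair <- function(n, density = 0.03, rewire_fraction = 0.1,
                              seed = NULL, retention = 0.4,
                              max_attempts = 50L) {
  stopifnot(n >= 4, density > 0, density <= 1,
            rewire_fraction >= 0, rewire_fraction <= 1)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      pair <- try(generate_pair_once(n, density, rewire_fraction, retention),
                  silent = TRUE)
      if (!inherits(pair, "try-error")) {
        pair$params <- list(n = n, density = density,
                            rewire_fraction = rewire_fraction, seed = seed,
                            retention = retention)
        return(pair)
      }
    }
    stop_input("could not generate a pair with a nonempty two-core in ",
               max_attempts, " attempts; try a higher density")
  })
}

generate_pair_once <- function(n, density, rewire_fraction, retention) {
  ids <- sprintf("s%04d", seq_len(n))
  # duplication-divergence growth from a seed triangle
  nbr <- vector("list", n)
  add_edge <- function(i, j) {
    nbr[[i]] <<- c(nbr[[i]], j)
    nbr[[j]] <<- c(nbr[[j]], i)
  }
  add_edge(1L, 2L); add_edge(2L, 3L); add_edge(1L, 3L)
  for (v in 4:n) {
    u <- sample.int(v - 1L, 1L)
    kept <- nbr[[u]][stats::runif(length(nbr[[u]])) < retention]
    for (w in unique(kept)) add_edge(v, w)
    add_edge(v, u)  # anchor edge keeps the graph connected
  }
  ei <- unlist(lapply(seq_len(n), function(i) rep(i, length(nbr[[i]]))))
  ej <- unlist(nbr)
  keep <- ei < ej
  edges <- unique(cbind(ei[keep], ej[keep]))
  m_target <- round(density * n * (n - 1) / 2)
  if (nrow(edges) < m_target) {
    have <- paste(edges[, 1L], edges[, 2L])
    need <- m_target - nrow(edges)
    extra <- matrix(integer(0), 0, 2)
    while (nrow(extra) < need) {
      a <- sample.int(n, 2L * need, replace = TRUE)
      b <- sample.int(n, 2L * need, replace = TRUE)
      cand <- cbind(pmin(a, b), pmax(a, b))
      cand <- cand[cand[, 1L] != cand[, 2L], , drop = FALSE]
      key <- paste(cand[, 1L], cand[, 2L])
      ok <- !(key %in% have) & !duplicated(key)
      extra <- rbind(extra, cand[ok, , drop = FALSE])
      have <- c(have, key[ok])
    }
    edges <- rbind(edges, extra[seq_len(need), , drop = FALSE])
  }
  net1 <- ppi_network(cbind(ids[edges[, 1L]], ids[edges[, 2L]]),
                      species = "species1")
  net1 <- preprocess_to_fixed_point(net1)
  if (length(net1$nodes) < 4L) stop("degenerate net1")

  # relabeled copy: truth maps source ids to shuffled target ids
  tgt_ids <- sprintf("t%04d", sample(length(net1$nodes)))
  truth_all <- stats::setNames(tgt_ids, net1$nodes)
  e2 <- cbind(truth_all[net1$edges[, 1L]], truth_all[net1$edges[, 2L]])
  m2 <- nrow(e2)
  n_rw <- round(rewire_fraction * m2)
  if (n_rw > 0L) {
    drop_idx <- sample.int(m2, n_rw)
    kept_keys <- pair_key(e2[-drop_idx, 1L], e2[-drop_idx, 2L])
    nodes2 <- unname(truth_all)
    new_edges <- matrix(character(0), 0, 2)
    have <- kept_keys
    while (nrow(new_edges) < n_rw) {
      a <- sample(nodes2, 2L * n_rw, replace = TRUE)
      b <- sample(nodes2, 2L * n_rw, replace = TRUE)
      ok <- a != b
      key <- pair_key(a[ok], b[ok])
      fresh <- !(key %in% have) & !duplicated(key)
      cand <- canonical_pair(a[ok][fresh], b[ok][fresh])
      new_edges <- rbind(new_edges, cand)
      have <- c(have, key[fresh])
    }
    e2 <- rbind(e2[-drop_idx, , drop = FALSE],
                new_edges[seq_len(n_rw), , drop = FALSE])
  }
  net2 <- ppi_network(e2, species = "species2")
  net2 <- preprocess_to_fixed_point(net2)
  if (length(net2$nodes) < 4L) stop("degenerate net2")

  truth <- truth_all[truth_all %in% net2$nodes]
  truth <- truth[names(truth) %in% net1$nodes]
  if (length(truth) < 2L) stop("no surviving correspondence")
  structure(list(net1 = net1, net2 = net2, truth = truth),
            class = "synthetic_pair")
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf("synthetic_pair: net1 %d nodes / %d edges, net2 %d nodes / %d edges, %d true correspondences\n",
              length(x$net1$nodes), nrow(x$net1$edges),
              length(x$net2$nodes), nrow(x$net2$edges), length(x$truth)))
  invisible(x)
}

#' True correspondences of a synthetic pair as a homolog-pair table
#' @param pair a [make_network_pair()] result.
#' @return data frame with columns `source`, `target`.
#' @export
truth_pairs <- function(pair) {
  data.frame(source = names(pair$truth), target = unname(pair$truth),
             stringsAsFactors = FALSE)
}

#' Degree-preserving randomization of a network
#'
#' Configuration-model rewiring: stubs are matched uniformly at random to
#' realize the exact degree sequence, then self loops and parallel edges
#' are removed, so each node's degree is preserved up to the small losses
#' of that cleanup.
#'
#' @param net a [ppi_network()].
#' @param seed RNG seed.
#' @return a rewired [ppi_network()] over the same node set.
#' @export
degree_preserving_randomize <- function(net, seed = NULL) {
  degs <- network_degree(net)
  with_seed(seed, {
    g <- igraph::sample_degseq(unname(degs), method = "configuration")
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g)
    ppi_network(cbind(net$nodes[el[, 1L]], net$nodes[el[, 2L]]),
                species = net$species, nodes = net$nodes)
  })
}

#' Plant pathway-structured synthetic-lethal interactions
#'
#' Chooses disjoint connected neighbourhoods of `net1` (restricted to
#' nodes with a recorded correspondence) as pathways, wires each up as a
#' cohesive module (protein complexes and tight pathways are dense in real
#' interactomes), and designates consecutive pathway pairs as redundant
#' couples whose members share interaction partners across the couple.
#' Synthetic-lethal pairs are drawn within pathways and between coupled
#' pathways -- mirroring the biology that joint loss is lethal within an
#' essential pathway or across two pathways backing up the same essential
#' function. Additional non-redundant background pathways are planted the
#' same way (without couples), and non-SL pairs are drawn across unrelated
#' pathways, i.e. any two distinct pathways that do not form a redundant
#' couple. The same gene pairs, mapped through the true correspondence,
#' are labeled in both species.
#'
#' The planted module wiring is added to both networks (through the truth
#' map for `net2`, where a `rewire_fraction` share of the planted edges is
#' dropped again as cross-species divergence), so the returned `pair` must
#' be used for downstream embedding.
#'
#' @param pair a [make_network_pair()] result.
#' @param n_pathways number of redundant pathways (must be even;
#'   consecutive pathways form redundant couples). Default 8, i.e. 4
#'   couples.
#' @param pathway_size genes per pathway (default 10).
#' @param n_background number of non-redundant background pathways
#'   (default 12).
#' @param n_per_class number of SL and of non-SL pairs sampled per species
#'   (default 200).
#' @param within_density probability of an edge between two genes of the
#'   same pathway (default 0.6, complex-like cohesion).
#' @param couple_density probability of an edge between genes of coupled
#'   pathways (default 0.3, partner sharing between redundant modules).
#' @param seed RNG seed.
#' @return list with `pair` (the input pair with planted module wiring),
#'   `dataset` (an [sl_dataset()] covering both species), `pathways`
#'   (named list of source-gene vectors; redundant pathways first) and
#'   `couples` (two-column matrix of coupled pathway indices).
#' @export
plant_sl_interactions <- function(pair, n_pathways = 8L, pathway_size = 10L,
                                  n_background = 12L, n_per_class = 200L,
                                  within_density = 0.6, couple_density = 0.3,
                                  seed = NULL) {
  if (n_pathways %% 2L != 0L) stop_input("n_pathways must be even")
  n_total <- n_pathways + n_background
  shared <- names(pair$truth)
  if (n_total * pathway_size > length(shared)) {
    stop_input("not enough corresponding nodes for ", n_total,
               " pathways of size ", pathway_size)
  }
  g1 <- as_igraph_net(pair$net1)
  with_seed(seed, {
    available <- shared
    pathways <- list()
    guard <- 0L
    while (length(pathways) < n_total) {
      guard <- guard + 1L
      if (guard > 500L) stop_input("could not place disjoint connected pathways")
      start <- sample(available, 1L)
      # breadth-first growth through currently-available nodes only
      mem <- start
      frontier <- start
      while (length(mem) < pathway_size && length(frontier) > 0L) {
        nb <- unique(unlist(lapply(frontier, function(v) {
          igraph::neighbors(g1, v)$name
        })))
        nb <- setdiff(intersect(nb, available), mem)
        if (length(nb) == 0L) break
        take <- utils::head(sample(nb), pathway_size - length(mem))
        frontier <- take
        mem <- c(mem, take)
      }
      if (length(mem) < pathway_size) next
      pathways[[length(pathways) + 1L]] <- sort(mem)
      available <- setdiff(available, mem)
    }
    names(pathways) <- sprintf("pw%02d", seq_along(pathways))
    couples <- matrix(seq_len(n_pathways), ncol = 2L, byrow = TRUE)

    # cohesive module wiring, shared partners across each redundant couple
    sample_pairs <- function(pool, prob) {
      pool[stats::runif(nrow(pool)) < prob, , drop = FALSE]
    }
    planted <- do.call(rbind, c(
      lapply(pathways, function(p) {
        sample_pairs(t(utils::combn(p, 2L)), within_density)
      }),
      lapply(seq_len(nrow(couples)), function(r) {
        grid <- as.matrix(expand.grid(pathways[[couples[r, 1L]]],
                                      pathways[[couples[r, 2L]]],
                                      stringsAsFactors = FALSE))
        sample_pairs(grid, couple_density)
      })))
    net1 <- ppi_network(rbind(pair$net1$edges, planted),
                        species = pair$net1$species)
    planted2 <- cbind(unname(pair$truth[planted[, 1L]]),
                      unname(pair$truth[planted[, 2L]]))
    rw <- pair$params$rewire_fraction
    if (!is.null(rw) && rw > 0 && nrow(planted2) > 1L) {
      drop_idx <- sample.int(nrow(planted2), round(rw * nrow(planted2)))
      if (length(drop_idx) > 0L) planted2 <- planted2[-drop_idx, , drop = FALSE]
    }
    net2 <- ppi_network(rbind(pair$net2$edges, planted2),
                        species = pair$net2$species)
    pair$net1 <- net1
    pair$net2 <- net2

    within_pairs <- do.call(rbind, lapply(pathways[seq_len(n_pathways)],
                                          function(p) t(utils::combn(p, 2L))))
    between_pairs <- do.call(rbind, lapply(seq_len(nrow(couples)), function(r) {
      as.matrix(expand.grid(pathways[[couples[r, 1L]]],
                            pathways[[couples[r, 2L]]],
                            stringsAsFactors = FALSE))
    }))
    sl_pool <- rbind(within_pairs, between_pairs)
    # unrelated = distinct pathways that are not a redundant couple
    couple_of <- rep(NA_integer_, n_total)
    couple_of[couples] <- rep(seq_len(nrow(couples)), 2L)
    pw_idx <- rep(seq_along(pathways), lengths(pathways))
    names(pw_idx) <- unlist(pathways)
    all_genes <- unlist(pathways)
    nonsl_pool <- t(utils::combn(all_genes, 2L))
    pi_a <- pw_idx[nonsl_pool[, 1L]]
    pi_b <- pw_idx[nonsl_pool[, 2L]]
    same_couple <- !is.na(couple_of[pi_a]) & !is.na(couple_of[pi_b]) &
      couple_of[pi_a] == couple_of[pi_b]
    nonsl_pool <- nonsl_pool[pi_a != pi_b & !same_couple, , drop = FALSE]

    pick <- function(pool, n) {
      pool[sample.int(nrow(pool), min(n, nrow(pool))), , drop = FALSE]
    }
    sl <- pick(sl_pool, n_per_class)
    nonsl <- pick(nonsl_pool, n_per_class)
    rec <- function(pairs_mat, label) {
      if (nrow(pairs_mat) == 0L) {
        return(data.frame(species = character(0), gene_a = character(0),
                          gene_b = character(0), label = character(0),
                          stringsAsFactors = FALSE))
      }
      rbind(
        data.frame(species = pair$net1$species,
                   gene_a = pairs_mat[, 1L], gene_b = pairs_mat[, 2L],
                   label = label, stringsAsFactors = FALSE),
        data.frame(species = pair$net2$species,
                   gene_a = unname(pair$truth[pairs_mat[, 1L]]),
                   gene_b = unname(pair$truth[pairs_mat[, 2L]]),
                   label = label, stringsAsFactors = FALSE))
    }
    dataset <- sl_dataset(rbind(rec(sl, "SLI"), rec(nonsl, "non-SLI")),
                          provenance = "planted pathway-structured SL")
    list(pair = pair, dataset = dataset, pathways = pathways,
         couples = couples)
  })
}

#' Toy ontology, annotations and phenotype maps over planted modules
#'
#' Builds a small term DAG (a root, two intermediate branches linked by
#' `is_a`, `part_of` and `has_part` relations, and one informative term
#' per module) and annotates every module gene, in both species, with its
#' module's term. Phenotype maps mirror module membership. With zero
#' noise, genes matched through the true correspondence have identical
#' propagated term sets, so ontology-based recovery is possible by
#' construction; `noise` reassigns the given fraction of annotations and
#' phenotype memberships at random.
#'
#' @param pair a [make_network_pair()] result.
#' @param modules named list of source-gene vectors (e.g. the `pathways`
#'   of [plant_sl_interactions()]).
#' @param noise fraction of annotations / phenotype members randomized
#'   (default 0).
#' @param seed RNG seed.
#' @return list with `dag` ([term_dag()]), `annotation`
#'   (an [ontology_annotation()] over both species), `pheno_a`, `pheno_b`
#'   ([phenotype_gene_map()]s for source and target species).
#' @export
make_toy_ontology <- function(pair, modules, noise = 0, seed = NULL) {
  stopifnot(noise >= 0, noise <= 1, length(modules) >= 1L)
  mod_terms <- sprintf("T:mod%02d", seq_along(modules))
  edges <- rbind(
    data.frame(child = "T:process", parent = "T:root", relation = "is_a"),
    data.frame(child = "T:component", parent = "T:root", relation = "part_of"),
    data.frame(child = "T:assembly", parent = "T:component",
               relation = "has_part"),
    data.frame(child = mod_terms,
               parent = ifelse(seq_along(modules) %% 2L == 1L,
                               "T:process", "T:assembly"),
               relation = "is_a"))
  dag <- term_dag(edges)
  sp1 <- pair$net1$species
  sp2 <- pair$net2$species
  with_seed(seed, {
    annotate <- function(genes_by_module, species) {
      g <- unlist(genes_by_module, use.names = FALSE)
      t <- rep(mod_terms, lengths(genes_by_module))
      flip <- stats::runif(length(t)) < noise
      t[flip] <- sample(mod_terms, sum(flip), replace = TRUE)
      data.frame(gene = g, species = species, term = t,
                 stringsAsFactors = FALSE)
    }
    modules2 <- lapply(modules, function(g) unname(pair$truth[g]))
    ann_df <- rbind(annotate(modules, sp1), annotate(modules2, sp2))
    annotation <- ontology_annotation(dag, ann_df)

    pheno <- function(genes_by_module, species, universe) {
      recs <- lapply(seq_along(genes_by_module), function(i) {
        g <- genes_by_module[[i]]
        n_flip <- round(noise * length(g))
        if (n_flip > 0L) {
          g <- c(sample(setdiff(universe, g), n_flip),
                 sample(g, length(g) - n_flip))
        }
        data.frame(species = species,
                   phenotype = sprintf("ph_%s_%02d", species, i),
                   gene = g, stringsAsFactors = FALSE)
      })
      phenotype_gene_map(do.call(rbind, recs))
    }
    list(dag = dag, annotation = annotation,
         pheno_a = pheno(modules, sp1, names(pair$truth)),
         pheno_b = pheno(modules2, sp2, unname(pair$truth)))
  })
}
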
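# Reading, validation and preprocessing of PPI networks, homolog candidate
# pairs, and ontology/annotation inputs.

#' Construct a protein-protein interaction network
#'
#' A `ppi_network` is an undirected, unweighted, simple graph over protein
#' identifiers. Self loops are dropped and parallel edges collapsed on
#' construction; nodes are kept in lexicographic order so that every matrix
#' derived from the network inherits a fixed, reproducible row order.
#'
#' @param edges two-column character matrix or data frame of endpoints, or
#'   `NULL` for an edgeless network.
#' @param species species tag attached to the network (free-form string).
#' @param nodes optional character vector of node identifiers; identifiers
#'   appearing in `edges` are added automatically, so this is only needed to
#'   declare isolated nodes.
#' @return an object of class `ppi_network` with elements `species`,
#'   `nodes` (sorted character vector) and `edges` (m x 2 character matrix,
#'   each row sorted, rows in lexicographic order).
#' @examples
#' net <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
#' network_size(net)
#' @export
ppi_network <- function(edges = NULL, species = "species", nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L) stop_input("edges must have two columns")
    em <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
    em <- em[em[, 1L] != em[, 2L], , drop = FALSE]        # no self loops
    if (nrow(em) > 0L) {
      em <- canonical_pair(em[, 1L], em[, 2L])
      em <- em[!duplicated(paste(em[, 1L], em[, 2L], sep = "\r")), ,
               drop = FALSE]
      em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
    }
  }
  all_nodes <- sort(unique(c(as.character(nodes), as.vector(em))))
  structure(list(species = species, nodes = all_nodes, edges = em),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network '%s': %d nodes, %d edges\n",
              x$species, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes and edges of a network
#' @param net a [ppi_network()].
#' @return named integer vector with elements `nodes` and `edges`.
#' @export
network_size <- function(net) {
  c(nodes = length(net$nodes), edges = nrow(net$edges))
}

# igraph view of a ppi_network; vertex order equals net$nodes.
as_igraph_net <- function(net) {
  g <- igraph::make_empty_graph(n = length(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes)
  if (nrow(net$edges) > 0L) {
    g <- igraph::add_edges(g, rbind(match(net$edges[, 1L], net$nodes),
                                    match(net$edges[, 2L], net$nodes)))
  }
  g
}

#' Node degrees of a network
#' @param net a [ppi_network()].
#' @return named integer vector of degrees in node order.
#' @export
network_degree <- function(net) {
  d <- integer(length(net$nodes))
  names(d) <- net$nodes
  if (nrow(net$edges) > 0L) {
    t1 <- table(factor(net$edges[, 1L], levels = net$nodes))
    t2 <- table(factor(net$edges[, 2L], levels = net$nodes))
    d <- as.integer(t1 + t2)
    names(d) <- net$nodes
  }
  d
}

# Induced subgraph on a subset of node ids.
induced_network <- function(net, keep) {
  keep <- sort(unique(keep))
  em <- net$edges
  em <- em[em[, 1L] %in% keep & em[, 2L] %in% keep, , drop = FALSE]
  ppi_network(em, species = net$species, nodes = keep)
}

#' Read an edge list from a delimited text file
#'
#' Expects two whitespace- or tab-delimited identifier columns. A header
#' line with recognizable column names (`node_a`, `source`, `from`,
#' `gene_a`, ...) is skipped. A third column (e.g. an edge weight) is
#' ignored with a warning: the analysis is unweighted. Self loops and
#' duplicate edges are discarded.
#'
#' @param path path to the edge-list file.
#' @param species_tag species tag for the resulting network.
#' @return a [ppi_network()].
#' @export
read_edge_list <- function(path, species_tag = "species") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_input("empty edge list file: ", path)
  toks <- strsplit(trimws(lines), "[ \t,]+")
  header_names <- c("node_a", "node_b", "source", "target", "from", "to",
                    "gene_a", "gene_b", "protein_a", "protein_b")
  start <- 1L
  if (all(tolower(toks[[1L]][1:2]) %in% header_names)) start <- 2L
  if (start > length(toks)) stop_input("edge list has a header but no data: ", path)
  nf <- vapply(toks[start:length(toks)], length, integer(1))
  if (any(nf < 2L)) {
    bad <- which(nf < 2L)[1L] + start - 1L
    stop_input("malformed edge list line ", bad, " in ", path,
               ": fewer than two fields")
  }
  if (any(nf > 2L)) {
    warning("third column in ", path, " ignored (unweighted analysis)",
            call. = FALSE)
  }
  em <- t(vapply(toks[start:length(toks)], function(x) x[1:2], character(2)))
  ppi_network(em, species = species_tag)
}

#' Largest connected component of a network
#'
#' Ties between equally-sized components are broken in favour of the
#' component containing the lexicographically smallest node identifier.
#'
#' @param net a nonempty [ppi_network()].
#' @return the induced subnetwork on the largest component.
#' @export
largest_connected_component <- function(net) {
  if (length(net$nodes) == 0L) stop_input("empty network")
  comp <- igraph::components(as_igraph_net(net))
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest lexicographic node id among tied components wins
    first_node <- vapply(best, function(ci) min(net$nodes[comp$membership == ci]),
                         character(1))
    best <- best[order(first_node)][1L]
  }
  induced_network(net, net$nodes[comp$membership == best])
}

#' Two-core of a network
#'
#' Iteratively removes nodes of degree < 2 until none remain. Degree-1
#' leaves attached to a common parent are topologically indistinguishable,
#' so they would receive identical diffusion-based scores; the two-core
#' removes this ambiguity. The result may be empty (e.g. for a tree).
#'
#' @param net a [ppi_network()].
#' @return a [ppi_network()], possibly with zero nodes.
#' @export
two_core <- function(net) {
  if (length(net$nodes) == 0L) return(net)
  core <- igraph::coreness(as_igraph_net(net))
  induced_network(net, net$nodes[core >= 2L])
}

#' Standard preprocessing: two-core of the largest connected component
#'
#' Applied once, in this order, before any kernel is computed.
#' @param net a [ppi_network()].
#' @return a [ppi_network()].
#' @export
preprocess_network <- function(net) {
  two_core(largest_connected_component(net))
}

#' Filter homolog candidate pairs against two networks
#'
#' Keeps pairs whose identifiers exist in both (preprocessed) networks,
#' removes duplicates, sorts by source then target identifier, and enforces
#' a one-to-one candidate set by keeping the first occurrence of every
#' identifier in that order.
#'
#' @param pairs two-column matrix or data frame of (source_id, target_id).
#' @param net1,net2 source and target [ppi_network()]s.
#' @return a `homolog_pairs` data frame with columns `source`, `target`.
#' @export
homolog_pairs <- function(pairs, net1, net2) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) < 2L) stop_input("homolog pairs must have two columns")
  df <- data.frame(source = as.character(pairs[, 1L]),
                   target = as.character(pairs[, 2L]),
                   stringsAsFactors = FALSE)
  df <- df[df$source %in% net1$nodes & df$target %in% net2$nodes, , drop = FALSE]
  df <- unique(df)
  df <- df[order(df$source, df$target), , drop = FALSE]
  df <- df[!duplicated(df$source) & !duplicated(df$target), , drop = FALSE]
  if (nrow(df) == 0L) stop_input("no homolog candidate pairs survive network filtering")
  rownames(df) <- NULL
  class(df) <- c("homolog_pairs", "data.frame")
  df
}

#' Read homolog candidate pairs from a two-column TSV
#'
#' @inheritParams read_edge_list
#' @param net1,net2 networks used to filter the pairs (see [homolog_pairs()]).
#' @return a `homolog_pairs` data frame.
#' @export
read_homolog_pairs <- function(path, net1, net2) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_input("empty homolog file: ", path)
  toks <- strsplit(trimws(lines), "[ \t,]+")
  start <- if (all(tolower(toks[[1L]][1:2]) %in%
                   c("source", "target", "source_id", "target_id",
                     "gene_a", "gene_b"))) 2L else 1L
  nf <- vapply(toks[start:length(toks)], length, integer(1))
  if (any(nf < 2L)) {
    stop_input("malformed homolog line ", which(nf < 2L)[1L] + start - 1L,
               " in ", path)
  }
  pm <- t(vapply(toks[start:length(toks)], function(x) x[1:2], character(2)))
  homolog_pairs(pm, net1, net2)
}

## ---------------------------------------------------------------------------
## Ontology DAG and annotations

#' Construct a term DAG
#'
#' @param edges data frame with columns `child`, `parent`, `relation`
#'   (relation in `is_a`, `part_of`, `has_part`), or `NULL`.
#' @param terms character vector of all term identifiers (terms appearing in
#'   `edges` are added automatically).
#' @return an object of class `term_dag`.
#' @export
term_dag <- function(edges = NULL, terms = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  ok_rel <- c("is_a", "part_of", "has_part")
  if (!all(edges$relation %in% ok_rel)) {
    stop_input("unknown relation type(s): ",
               paste(setdiff(unique(edges$relation), ok_rel), collapse = ", "))
  }
  terms <- sort(unique(c(as.character(terms), edges$child, edges$parent)))
  dag <- structure(list(terms = terms, edges = edges), class = "term_dag")
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                       directed = TRUE,
                                       vertices = data.frame(name = terms))
    if (!igraph::is_dag(g)) stop_input("term graph contains a cycle")
  }
  dag
}

# ancestor closure (including the term itself) for every term in the DAG
term_ancestors <- function(dag) {
  anc <- stats::setNames(as.list(dag$terms), dag$terms)
  if (nrow(dag$edges) == 0L) return(anc)
  parents <- split(dag$edges$parent, dag$edges$child)
  # process in topological order child -> parent using igraph
  g <- igraph::graph_from_data_frame(dag$edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = dag$terms))
  # edges run child -> parent; reverse the child-first order so every term's
  # parents are finished before the term itself is processed
  ord <- rev(igraph::topo_sort(g, mode = "out")$name)
  for (t in ord) {
    p <- parents[[t]]
    if (!is.null(p)) {
      anc[[t]] <- sort(unique(c(t, unlist(anc[p], use.names = FALSE))))
    }
  }
  anc
}

#' Read a minimal OBO-format term DAG
#'
#' Understands the `[Term]` stanzas of an OBO file restricted to `id:`,
#' `is_a:` and `relationship: part_of` / `relationship: has_part` lines;
#' everything else is ignored.
#'
#' @param path path to the OBO file.
#' @return a [term_dag()].
#' @export
read_obo <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  in_term <- FALSE
  cur <- NULL
  terms <- character(0)
  ch <- pa <- re <- character(0)
  flush <- function() {
    if (!is.null(cur)) terms <<- c(terms, cur)
  }
  strip_comment <- function(x) trimws(sub("!.*$", "", x))
  for (ln in lines) {
    if (ln == "[Term]") { flush(); in_term <- TRUE; cur <- NULL; next }
    if (grepl("^\\[", ln)) { flush(); in_term <- FALSE; cur <- NULL; next }
    if (!in_term) next
    if (grepl("^id:", ln)) cur <- strip_comment(sub("^id:", "", ln))
    if (grepl("^is_a:", ln)) {
      ch <- c(ch, cur); pa <- c(pa, strip_comment(sub("^is_a:", "", ln)))
      re <- c(re, "is_a")
    }
    if (grepl("^relationship:", ln)) {
      body <- strsplit(strip_comment(sub("^relationship:", "", ln)), "[ \t]+")[[1L]]
      if (length(body) >= 2L && body[1L] %in% c("part_of", "has_part")) {
        ch <- c(ch, cur); pa <- c(pa, body[2L]); re <- c(re, body[1L])
      }
    }
  }
  flush()
  term_dag(data.frame(child = ch, parent = pa, relation = re,
                      stringsAsFactors = FALSE), terms = terms)
}

#' Construct a gene-annotation object over a term DAG
#'
#' @param dag a [term_dag()].
#' @param annotations data frame with columns `gene`, `species`, `term`.
#' @return object of class `ontology_annotation`: the DAG plus a per-species
#'   list of gene -> term-set mappings.
#' @export
ontology_annotation <- function(dag, annotations) {
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "species", "term") %in% names(annotations)))
  missing_terms <- setdiff(unique(annotations$term), dag$terms)
  if (length(missing_terms) > 0L) {
    stop_input("annotated term(s) absent from the DAG: ",
               paste(utils::head(missing_terms, 5), collapse = ", "))
  }
  gene_terms <- lapply(split(annotations, annotations$species), function(d) {
    lapply(split(d$term, d$gene), function(x) sort(unique(x)))
  })
  structure(list(dag = dag, gene_terms = gene_terms, propagated = FALSE),
            class = "ontology_annotation")
}

#' Read a three-column annotation TSV (gene, species, term)
#'
#' @param path path to the annotation file.
#' @param dag the [term_dag()] the terms must belong to.
#' @return an [ontology_annotation()].
#' @export
read_annotations <- function(path, dag) {
  d <- read_three_col(path, c("gene", "species", "term"))
  ontology_annotation(dag, d)
}

# three-column TSV with an optional header line naming the columns
read_three_col <- function(path, cols) {
  first <- readLines(path, n = 1L, warn = FALSE)
  skip <- if (identical(tolower(strsplit(first, "\t")[[1L]]), cols)) 1L else 0L
  utils::read.table(path, header = FALSE, sep = "\t", skip = skip,
                    col.names = cols, colClasses = "character")
}

#' Propagate annotations up the ontology
#'
#' Closes every gene's term set under ancestor traversal along `is_a`,
#' `part_of` and `has_part` edges. Idempotent, and monotone: term sets only
#' grow.
#'
#' @param ann an [ontology_annotation()].
#' @return the propagated [ontology_annotation()].
#' @export
propagate_annotations <- function(ann) {
  stopifnot(inherits(ann, "ontology_annotation"))
  anc <- term_ancestors(ann$dag)
  ann$gene_terms <- lapply(ann$gene_terms, function(sp) {
    lapply(sp, function(terms) {
      sort(unique(unlist(anc[terms], use.names = FALSE)))
    })
  })
  ann$propagated <- TRUE
  ann
}

#' Extract a gene -> term-set mapping for one species
#'
#' @param ann an [ontology_annotation()].
#' @param species species tag.
#' @param propagate close term sets under ancestor traversal first
#'   (default `TRUE`); `FALSE` returns the specific annotations as given.
#' @return named list mapping gene ids to character vectors of terms.
#' @export
gene_term_sets <- function(ann, species, propagate = TRUE) {
  if (propagate && !isTRUE(ann$propagated)) ann <- propagate_annotations(ann)
  out <- ann$gene_terms[[species]]
  if (is.null(out)) stop_input("no annotations for species '", species, "'")
  out
}
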
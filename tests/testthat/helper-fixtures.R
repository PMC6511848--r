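# Shared fixtures, built once per run and cached. Everything is generated
# in code under fixed seeds; no files ship with the tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# small correlated network pair + fit, enough for method-surface tests
fixture_pair60 <- function() {
  fixture("pair60", make_network_pair(n = 60, density = 0.08,
                                      rewire_fraction = 0.1, seed = 1))
}

fixture_fit60 <- function() {
  fixture("fit60", {
    p <- fixture_pair60()
    munk(p$net1, p$net2, truth_pairs(p), n_landmarks = 12, seed = 1)
  })
}

# random connected-ish ER networks for property loops
random_network <- function(n, p_edge, seed, species = "rnd") {
  with_seed(seed, {
    pairs <- t(utils::combn(sprintf("n%03d", seq_len(n)), 2L))
    keep <- stats::runif(nrow(pairs)) < p_edge
    ppi_network(pairs[keep, , drop = FALSE], species = species,
                nodes = sprintf("n%03d", seq_len(n)))
  })
}

with_seed <- munk:::with_seed

# brute-force assignment oracle: maximize total score over all permutations
brute_force_match <- function(S) {
  n <- nrow(S)
  perms <- gtools_permutations(n)
  best <- -Inf
  best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    tot <- sum(S[cbind(seq_len(n), perms[i, ])])
    if (tot > best + 1e-12) {
      best <- tot
      best_perm <- perms[i, ]
    }
  }
  list(total = best, perm = best_perm)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# threshold-sweep AUPR oracle, recomputed from scratch per threshold
sweep_aupr <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  prec <- rec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    called <- scores >= ths[i]
    prec[i] <- sum(labels[called]) / sum(called)
    rec[i] <- sum(labels[called]) / P
  }
  sum(prec * diff(c(0, rec)))
}

# threshold-sweep max-F1 oracle
sweep_max_f1 <- function(scores, labels) {
  labels <- as.logical(labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  best <- 0
  for (t in ths) {
    called <- scores >= t
    tp <- sum(labels & called)
    if (tp == 0) next
    pr <- tp / sum(called)
    rc <- tp / sum(labels)
    best <- max(best, 2 * pr * rc / (pr + rc))
  }
  best
}

# exhaustive hypergeometric upper tail by subset enumeration (universe <= 12)
enumerate_hyper_tail <- function(N, n_success, n_draw, ov) {
  universe <- seq_len(N)
  succ <- seq_len(n_success)
  draws <- utils::combn(N, n_draw)
  hits <- colSums(matrix(draws %in% succ, nrow = n_draw))
  mean(hits >= ov)
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
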
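# Functional-similarity evaluation machinery.

test_that("Resnik gene similarity follows information content", {
  dag <- term_dag(data.frame(child = c("t", "s"), parent = c("s", "root"),
                             relation = "is_a"))
  ann <- ontology_annotation(dag, data.frame(
    gene = paste0("g", 1:8), species = "sp",
    term = c("t", "t", rep("root", 6))))
  corpus <- gene_term_sets(ann, "sp")

  # shared term annotating 2 of 8 corpus genes
  expect_equal(resnik_protein(ann, corpus, "g1", "g2"), -log(0.25),
               tolerance = 1e-12)
  # root annotates everyone: zero information
  expect_equal(resnik_protein(ann, corpus, "g3", "g4"), 0)
  # symmetry and nonnegativity
  expect_equal(resnik_protein(ann, corpus, "g1", "g3"),
               resnik_protein(ann, corpus, "g3", "g1"))
  expect_gte(resnik_protein(ann, corpus, "g1", "g3"), 0)
  # unannotated gene is undefined
  expect_true(is.na(resnik_protein(ann, corpus, "g1", "nope")))

  # identical single-term genes score that term's information content
  ic <- term_information_content(ann, corpus)
  expect_equal(resnik_protein(ann, corpus, "g1", "g1"), unname(ic["t"]))
})

test_that("Hungarian matching equals brute-force enumeration", {
  m <- matrix(c(2, 1, 1, 2), 2, dimnames = list(c("r1", "r2"),
                                                c("c1", "c2")))
  res <- hungarian_match(m)
  expect_equal(res$to, c("c1", "c2"))

  big_diag <- diag(c(9, 8, 7)) + 0.1
  dimnames(big_diag) <- list(paste0("a", 1:3), paste0("b", 1:3))
  expect_equal(hungarian_match(big_diag)$to, paste0("b", 1:3))

  for (s in 1:60) {
    n <- sample(2:5, 1)
    m2 <- sample(2:5, 1)
    S <- with_seed(500 + s, matrix(stats::rnorm(n * m2), n, m2,
                                   dimnames = list(paste0("r", 1:n),
                                                   paste0("c", 1:m2))))
    got <- hungarian_match(S)
    idx <- if (attr(got, "orientation") == "cols") {
      cbind(got$to, got$from)
    } else cbind(got$from, got$to)
    tot <- sum(S[idx])
    # oracle: enumerate injections of the smaller side via subsets
    Sm <- if (nrow(S) <= ncol(S)) S else t(S)
    best <- -Inf
    for (cols in utils::combn(ncol(Sm), nrow(Sm), simplify = FALSE)) {
      bf <- brute_force_match(Sm[, cols, drop = FALSE])
      best <- max(best, bf$total)
    }
    expect_equal(tot, best, tolerance = 1e-10)
  }
  expect_error(hungarian_match(matrix(c(1, Inf), 1)), "finite")
})

test_that("GO consistency averages Jaccard with the fixed empty-set rules", {
  match <- data.frame(from = c("a1", "a2"), to = c("b1", "b2"))
  tf <- list(a1 = c("x", "y"), a2 = c("p"))
  tt <- list(b1 = c("x", "y"), b2 = c("p"))
  expect_equal(goc(match, tf, tt), 1)

  tt2 <- list(b1 = c("q"), b2 = c("r"))
  expect_equal(goc(match, tf, tt2), 0)

  expect_equal(goc(data.frame(from = "a1", to = "b1"),
                   list(a1 = c("a", "b")), list(b1 = c("b", "c"))), 1 / 3)

  # both-empty pairs drop out; one-empty contributes zero
  m3 <- data.frame(from = c("a1", "a2", "a3"), to = c("b1", "b2", "b3"))
  expect_equal(goc(m3, list(a1 = "x", a2 = character(0), a3 = character(0)),
                   list(b1 = "x", b2 = character(0), b3 = "y")),
               mean(c(1, 0)))
  expect_error(goc(m3[0, ], tf, tt), "empty")
})

test_that("k-functional-similarity labels respect the per-species cap", {
  t1 <- list(g1 = "T1", g2 = "T1", g3 = "T2")
  t2 <- list(h1 = "T1", h2 = "T2", h3 = "T2")
  lab <- kfs_labels(t1, t2, k = 100)
  expect_equal(dim(lab), c(3L, 3L))
  # exhaustive expectation: share a term that is rare in both species
  want <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 1))
  expect_equal(unname(lab), want)

  # threshold edge: term too common in one species is disqualified
  t1b <- list(g1 = "T1", g2 = "T1", g3 = "T1")
  labk <- kfs_labels(t1b, t2, k = 2)
  expect_equal(unname(labk[, "h1"]), c(0, 0, 0))
  # symmetry under swapping species
  expect_equal(unname(kfs_labels(t2, t1, 100)), unname(t(lab)))
})

test_that("AUPR matches hand values and a threshold-sweep oracle", {
  expect_equal(aupr(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(aupr(c(4, 3, 2, 1), c(0, 0, 0, 1)), 0.25)
  expect_error(aupr(1:3, c(1, 1, 1)), "both classes")

  for (s in 1:50) {
    n <- sample(8:40, 1)
    sc <- with_seed(600 + s, round(stats::runif(n), 2))  # forces ties
    lb <- with_seed(700 + s, stats::rbinom(n, 1, 0.3))
    if (sum(lb) %in% c(0, n)) next
    expect_equal(aupr(sc, lb), sweep_aupr(sc, lb), tolerance = 1e-12)
  }
})

test_that("maximum F1 matches hand values and a sweep oracle", {
  expect_equal(max_f1(c("a", "b", "c"), "b"), 2 / 3)
  expect_equal(max_f1(c("a", "b"), c("a", "b")), 1)
  for (s in 1:50) {
    n <- sample(8:30, 1)
    sc <- with_seed(800 + s, round(stats::runif(n), 1))
    lb <- with_seed(900 + s, stats::rbinom(n, 1, 0.3)) == 1
    if (!any(lb)) next
    o <- order(-sc)
    ids <- as.character(seq_len(n))
    expect_equal(max_f1(ids[o], ids[lb], scores = sc[o]),
                 sweep_max_f1(sc, lb), tolerance = 1e-12)
  }

  preds <- list(T1 = c("a", "b", "c"), T2 = c("x", "y"))
  expect_equal(max_f1_over_terms(preds, list(T1 = "a", T2 = c("x", "y"))), 1)
  expect_warning(
    out <- max_f1_over_terms(preds, list(T1 = "b", T2 = character(0))),
    "excluded")
  expect_equal(out, 2 / 3)
})

test_that("the homolog contrast compares the two pair groups", {
  dis <- matrix(2, 3, 3, dimnames = list(paste0("s", 1:3), paste0("t", 1:3)))
  dis["s1", "t1"] <- 1
  dis["s2", "t2"] <- 1
  hom <- data.frame(source = c("s1", "s2"), target = c("t1", "t2"))
  lms <- data.frame(source = character(0), target = character(0))
  ct <- homolog_score_contrast(dis, hom, lms)
  expect_equal(unname(ct), c(1, 2, 0.5))

  # identical groups give a ratio near one
  dis2 <- matrix(2, 3, 3, dimnames = dimnames(dis))
  expect_equal(unname(homolog_score_contrast(dis2, hom, lms)["ratio"]), 1)

  # landmark genes are excluded from both groups
  lms2 <- data.frame(source = "s1", target = "t1")
  ct2 <- homolog_score_contrast(dis2, hom, lms2)
  expect_equal(unname(ct2["mean_homolog"]), 2)
  expect_error(homolog_score_contrast(dis, hom[0, ], lms), "homolog")
})

test_that("multi-species prediction reduces to one species at a corner", {
  pair <- fixture_pair60()
  fit <- fixture_fit60()
  genes <- rownames(fit$D1)
  seeds1 <- genes[1:6]
  seeds2 <- colnames(fit$D12)[1:4]
  ann <- list(
    species1 = stats::setNames(rep(list("T1"), 6), seeds1),
    species2 = stats::setNames(rep(list("T1"), 4), seeds2))
  r_corner <- multispecies_predict(fit$D1, list(species2 = fit$D12),
                                   c(species1 = 1, species2 = 0), ann, "T1")
  cand <- setdiff(genes, seeds1)
  sc <- rowSums(fit$D1[cand, seeds1])
  expect_equal(r_corner$gene, cand[order(-sc, cand)])

  # both species contribute under an interior weight
  r_mid <- multispecies_predict(fit$D1, list(species2 = fit$D12),
                                c(species1 = 0.5, species2 = 0.5), ann, "T1")
  expect_false(identical(r_mid$score, r_corner$score))

  expect_warning(
    out <- multispecies_predict(fit$D1, list(species2 = fit$D12),
                                c(species1 = 1, species2 = 0),
                                list(species1 = ann$species1[1],
                                     species2 = ann$species2), "T1"),
    "outside")
  expect_null(out)
  expect_error(multispecies_predict(fit$D1, list(species2 = fit$D12),
                                    c(species1 = 2, species2 = -1), ann,
                                    "T1"), "sum to 1")
})

test_that("the simplex grid enumerates the expected weight vectors", {
  W <- simplex_weights(0.25, 3)
  expect_equal(nrow(W), 15L)
  expect_true(all(abs(rowSums(W) - 1) < 1e-9))
  expect_true(all(W >= 0))
  expect_equal(nrow(simplex_weights(0.05, 3)), choose(22, 2))
})

test_that("permuted cross-species scores do not beat the real ones", {
  pair <- fixture_pair60()
  fit <- fixture_fit60()
  # plant a term on corresponding genes: cross-species signal is real
  tr <- pair$truth[names(pair$truth) %in% rownames(fit$D1) &
                     pair$truth %in% colnames(fit$D12)]
  seeds1 <- names(tr)[1:8]
  seeds2 <- unname(tr[9:16])
  ann <- list(species1 = stats::setNames(rep(list("T1"), 8), seeds1),
              species2 = stats::setNames(rep(list("T1"), 8), seeds2))
  truth1 <- names(tr)[9:16]  # counterparts of the species2 seeds
  w <- c(species1 = 0.5, species2 = 0.5)
  real <- multispecies_predict(fit$D1, list(species2 = fit$D12), w, ann, "T1")
  perm <- with_seed(11, {
    P <- fit$D12[sample(nrow(fit$D12)), ]
    rownames(P) <- rownames(fit$D12)
    multispecies_predict(fit$D1, list(species2 = P), w, ann, "T1")
  })
  f_real <- max_f1(real$gene, truth1, real$score)
  f_perm <- max_f1(perm$gene, truth1, perm$score)
  expect_gte(f_real, f_perm)
})

test_that("degree-null p-values follow the permutation-count formula", {
  pair <- fixture_pair60()
  fit <- fixture_fit60()
  res <- degree_null_pvalue(pair$net1, pair$net2, fit$homologs,
                            fit$landmarks, n_perm = 9, seed = 3)
  expect_equal(res$p_value,
               (1 + sum(res$null >= res$observed)) / 10)
  expect_length(res$null, 9)
  res2 <- degree_null_pvalue(pair$net1, pair$net2, fit$homologs,
                             fit$landmarks, n_perm = 9, seed = 3)
  expect_identical(res$null, res2$null)
})
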
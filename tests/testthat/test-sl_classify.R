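# Synthetic-lethality pair features, negative sampling, CV machinery.

test_that("datasets canonicalize pairs and drop self-pairs and duplicates", {
  ds <- sl_dataset(data.frame(
    species = c("s1", "s1", "s1", "s1"),
    gene_a = c("b", "a", "a", "c"),
    gene_b = c("a", "b", "a", "d"),
    label = c("SLI", "SLI", "SLI", "non-SLI")))
  expect_equal(nrow(ds), 2L)
  expect_equal(ds$gene_a[1], "a")
  expect_error(sl_dataset(data.frame(species = "s", gene_a = "a",
                                     gene_b = "b", label = "yes")),
               "label")
})

test_that("pair features come from the right embedding and are order-invariant", {
  C1 <- matrix(1:6 / 10, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  C2 <- matrix(7:12 / 10, 3, 2, dimnames = list(c("u", "v", "w"), NULL))
  ds <- sl_dataset(data.frame(
    species = c("s1", "s2"),
    gene_a = c("a", "u"), gene_b = c("b", "v"),
    label = c("SLI", "non-SLI")))
  f <- build_pair_features(C1, C2, ds, "s1", "s2")
  expect_equal(unname(f$features[1, ]), unname(C1["a", ] + C1["b", ]))
  expect_equal(unname(f$features[2, ]), unname(C2["u", ] + C2["v", ]))
  expect_equal(ncol(f$features), 2L)

  ds_swapped <- sl_dataset(data.frame(
    species = c("s1", "s2"),
    gene_a = c("b", "v"), gene_b = c("a", "u"),
    label = c("SLI", "non-SLI")))
  f2 <- build_pair_features(C1, C2, ds_swapped, "s1", "s2")
  expect_equal(f$features, f2$features)

  ds_missing <- sl_dataset(data.frame(
    species = c("s1", "s1"), gene_a = c("a", "zz"),
    gene_b = c("b", "c"), label = c("SLI", "SLI")))
  expect_message(f3 <- build_pair_features(C1, C2, ds_missing, "s1", "s2"),
                 "dropped")
  expect_equal(nrow(f3$features), 1L)
})

test_that("negative sampling avoids known interactions deterministically", {
  tri <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  neg <- sample_negatives(tri, rbind(c("a", "b")), 2, seed = 1)
  expect_setequal(paste(neg$gene_a, neg$gene_b), c("a c", "b c"))
  expect_equal(nrow(sample_negatives(tri, rbind(c("a", "b")), 0)), 0L)
  expect_error(sample_negatives(tri, rbind(c("a", "b")), 3, seed = 1),
               "eligible")
  net <- random_network(30, 0.2, seed = 2)
  n1 <- sample_negatives(net, net$edges, 20, seed = 9)
  n2 <- sample_negatives(net, net$edges, 20, seed = 9)
  expect_identical(n1, n2)
  expect_false(any(munk:::pair_key(n1$gene_a, n1$gene_b) %in%
                     munk:::pair_key(net$edges[, 1], net$edges[, 2])))
})

test_that("cross-validation separates a separable planted signal", {
  with_seed(1, {
    n <- 60
    X <- rbind(matrix(stats::rnorm(n * 4, 2), n),
               matrix(stats::rnorm(n * 4, -2), n))
    y <- factor(rep(c("SLI", "non-SLI"), each = n),
                levels = c("non-SLI", "SLI"))
    sp <- rep(rep(c("s1", "s2"), n / 2), 2)
    rep_rf <- cv_evaluate(X, y, sp, "random_forest", seed = 1,
                          tree_grid = 100L)
    expect_true(all(rep_rf$summary$auroc == 1))
    expect_true(all(rep_rf$summary$aupr == 1))
    rep_svm <- cv_evaluate(X, y, sp, "linear_svm", seed = 1)
    expect_true(all(rep_svm$summary$auroc == 1))
    expect_equal(nrow(rep_rf$per_fold), 8L)
  })
})

test_that("cross-validation is reproducible and validates stratification", {
  with_seed(2, {
    X <- matrix(stats::rnorm(80 * 3), 80)
    y <- factor(rep(c("SLI", "non-SLI"), 40), levels = c("non-SLI", "SLI"))
    sp <- rep(c("s1", "s2"), each = 40)
    a <- cv_evaluate(X, y, sp, "random_forest", seed = 4, tree_grid = 50L)
    b <- cv_evaluate(X, y, sp, "random_forest", seed = 4, tree_grid = 50L)
    expect_identical(a$per_fold, b$per_fold)
    expect_error(cv_evaluate(X, y, rep("s1", 80), seed = 1), "species")
    # a species with a single positive cannot be stratified into 4 folds
    y2 <- y
    y2[sp == "s2"] <- "non-SLI"
    y2[which(sp == "s2")[1]] <- "SLI"
    expect_error(cv_evaluate(X, y2, sp, "random_forest", seed = 1,
                             tree_grid = 50L), "stratification")
  })
})

test_that("held-out-gene splits quarantine every pair touching the genes", {
  recs <- expand.grid(gene_a = paste0("g", 1:8), gene_b = paste0("g", 1:8),
                      stringsAsFactors = FALSE)
  recs <- recs[recs$gene_a < recs$gene_b, ]
  ds <- sl_dataset(data.frame(species = "s1", recs,
                              label = rep_len(c("SLI", "non-SLI"),
                                              nrow(recs))))
  sp <- holdout_gene_split(ds, 0.25, seed = 3)
  held <- sp$held_out_genes$s1
  expect_true(all(sp$test$gene_a %in% held | sp$test$gene_b %in% held))
  expect_false(any(sp$train$gene_a %in% held | sp$train$gene_b %in% held))
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(ds))

  for (s in 1:10) {
    spl <- holdout_gene_split(ds, 0.25, seed = s)
    train_genes <- unique(c(spl$train$gene_a, spl$train$gene_b))
    expect_length(intersect(train_genes, spl$held_out_genes$s1), 0)
  }
  expect_error(holdout_gene_split(ds, 0.999, seed = 1), "degenerate")
})

test_that("planted pathway couples enumerate the expected SL candidates", {
  pair <- fixture_pair60()
  planted <- plant_sl_interactions(pair, n_pathways = 2L, pathway_size = 3L,
                                   n_background = 0L, n_per_class = 100L,
                                   seed = 2)
  ds1 <- planted$dataset[planted$dataset$species == "species1", ]
  # 2 * C(3,2) within-pathway pairs + 3 x 3 between the redundant couple
  expect_equal(sum(ds1$label == "SLI"), 2 * 3 + 9)
  keys_sl <- munk:::pair_key(ds1$gene_a[ds1$label == "SLI"],
                             ds1$gene_b[ds1$label == "SLI"])
  keys_non <- munk:::pair_key(ds1$gene_a[ds1$label == "non-SLI"],
                              ds1$gene_b[ds1$label == "non-SLI"])
  expect_length(intersect(keys_sl, keys_non), 0)

  # both species carry the same pairs through the true correspondence
  ds2 <- planted$dataset[planted$dataset$species == "species2", ]
  mapped <- munk:::pair_key(planted$pair$truth[ds1$gene_a],
                            planted$pair$truth[ds1$gene_b])
  expect_setequal(munk:::pair_key(ds2$gene_a, ds2$gene_b), mapped)
})
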
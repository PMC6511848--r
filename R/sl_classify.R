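# Multi-species synthetic-lethality classification on summed pair
# representations: random forests (tree count tuned by nested CV) and
# linear SVMs, evaluated with species-and-label-stratified k-fold CV.

#' Construct a synthetic-lethality dataset
#'
#' @param records data frame with columns `species`, `gene_a`, `gene_b`,
#'   `label` (`"SLI"` / `"non-SLI"`).
#' @param provenance free-form note on where the records came from.
#' @return an `sl_dataset` data frame: self-pairs removed, pairs put in
#'   canonical (sorted) order, duplicates within a species dropped.
#' @export
sl_dataset <- function(records, provenance = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "gene_a", "gene_b", "label") %in% names(records)))
  if (!all(records$label %in% c("SLI", "non-SLI"))) {
    stop_input("labels must be 'SLI' or 'non-SLI'")
  }
  records <- records[records$gene_a != records$gene_b, , drop = FALSE]
  cp <- canonical_pair(records$gene_a, records$gene_b)
  records$gene_a <- cp[, 1L]
  records$gene_b <- cp[, 2L]
  records <- records[!duplicated(paste(records$species, records$gene_a,
                                       records$gene_b, sep = "\r")), ,
                     drop = FALSE]
  rownames(records) <- NULL
  attr(records, "provenance") <- provenance
  class(records) <- c("sl_dataset", "data.frame")
  records
}

#' Pair feature matrix for a synthetic-lethality dataset
#'
#' Each gene pair becomes one k-dimensional row: the sum of the two genes'
#' embedding rows, taken from the source embedding for source-species pairs
#' and from the solved target embedding for target-species pairs. Both
#' species therefore share one feature space. Records with a gene absent
#' from the relevant embedding are dropped with a message.
#'
#' @param C1 source embedding (rows named by gene).
#' @param C2hat target embedding.
#' @param dataset an [sl_dataset()]; its `species` column must contain the
#'   two values given in `source_species` / `target_species`.
#' @param source_species,target_species species tags that map records to
#'   `C1` / `C2hat`.
#' @return list with `features` (matrix), `labels` (factor SLI/non-SLI),
#'   `species` (character vector) and `pairs` (the retained records).
#' @export
build_pair_features <- function(C1, C2hat, dataset,
                                source_species, target_species) {
  emb <- list(C1, C2hat)
  names(emb) <- c(source_species, target_species)
  if (!all(dataset$species %in% names(emb))) {
    stop_input("dataset species must be in {", source_species, ", ",
               target_species, "}")
  }
  keep <- vapply(seq_len(nrow(dataset)), function(r) {
    E <- emb[[dataset$species[r]]]
    dataset$gene_a[r] %in% rownames(E) && dataset$gene_b[r] %in% rownames(E)
  }, logical(1))
  if (any(!keep)) {
    message(sum(!keep), " pair(s) dropped: gene missing from embedding")
  }
  dataset <- dataset[keep, , drop = FALSE]
  if (nrow(dataset) == 0L) stop_input("no pairs left after filtering")
  X <- t(vapply(seq_len(nrow(dataset)), function(r) {
    E <- emb[[dataset$species[r]]]
    E[dataset$gene_a[r], ] + E[dataset$gene_b[r], ]
  }, numeric(ncol(C1))))
  colnames(X) <- paste0("dim", seq_len(ncol(X)))
  list(features = X,
       labels = factor(dataset$label, levels = c("non-SLI", "SLI")),
       species = dataset$species,
       pairs = dataset)
}

#' Sample non-interacting gene pairs
#'
#' Draws `n` distinct unordered node pairs uniformly from the pairs of
#' `net` that are not in the given SLI set (and are not self-pairs).
#'
#' @param net a [ppi_network()] supplying the gene universe.
#' @param sli two-column matrix/data frame of known SLI pairs to avoid.
#' @param n number of pairs to draw.
#' @param seed RNG seed.
#' @return data frame with columns `gene_a`, `gene_b` in canonical order.
#' @export
sample_negatives <- function(net, sli, n, seed = NULL) {
  stopifnot(n >= 0)
  nodes <- net$nodes
  forbidden <- if (NROW(sli) > 0L) {
    sli <- as.matrix(sli)
    pair_key(sli[, 1L], sli[, 2L])
  } else character(0)
  n_total <- choose(length(nodes), 2L)
  n_eligible <- n_total - length(unique(forbidden))
  if (n > n_eligible) {
    stop_input("requested ", n, " negatives but only ", n_eligible,
               " eligible pairs exist")
  }
  if (n == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    if (n_total <= 2e5) {
      all_pairs <- t(utils::combn(nodes, 2L))
      elig <- all_pairs[!(pair_key(all_pairs[, 1L], all_pairs[, 2L]) %in%
                            forbidden), , drop = FALSE]
      pick <- elig[sample.int(nrow(elig), n), , drop = FALSE]
    } else {
      seen <- character(0)
      a <- character(0); b <- character(0)
      while (length(a) < n) {
        i <- sample(nodes, 2L)
        key <- pair_key(i[1L], i[2L])
        if (key %in% forbidden || key %in% seen) next
        seen <- c(seen, key)
        cp <- canonical_pair(i[1L], i[2L])
        a <- c(a, cp[1L]); b <- c(b, cp[2L])
      }
      pick <- cbind(a, b)
    }
    cp <- canonical_pair(pick[, 1L], pick[, 2L])
    data.frame(gene_a = cp[, 1L], gene_b = cp[, 2L], stringsAsFactors = FALSE)
  })
}

# fold assignment stratified jointly by (species, label); deterministic
# under seed. Errors if a fold would miss a class within a species.
stratified_folds <- function(labels, species, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (st in split(seq_along(labels), paste(species, labels))) {
      st <- sample(st)
      fold[st] <- rep_len(seq_len(n_folds), length(st))
    }
  })
  for (f in seq_len(n_folds)) {
    for (sp in unique(species)) {
      test_lab <- labels[fold == f & species == sp]
      if (length(unique(test_lab)) < 2L) {
        stop_input("stratification error: fold ", f, " misses a class for ",
                   sp)
      }
    }
  }
  fold
}

# decision scores on held-out rows for one trained model
fit_and_score <- function(X_tr, y_tr, X_te, model, ntree, seed) {
  if (model == "random_forest") {
    rf <- with_seed(seed, randomForest::randomForest(
      x = X_tr, y = y_tr, ntree = ntree))
    as.numeric(stats::predict(rf, X_te, type = "prob")[, "SLI"])
  } else {
    sv <- with_seed(seed, e1071::svm(
      x = X_tr, y = y_tr, kernel = "linear", scale = FALSE))
    dvm <- attr(stats::predict(sv, X_te, decision.values = TRUE),
                "decision.values")
    dv <- dvm[, 1L]
    # decision-value column "A/B" is positive when favouring class A;
    # orient so larger = more SLI-like
    if (!startsWith(colnames(dvm)[1L], "SLI")) dv <- -dv
    as.numeric(dv)
  }
}

#' Cross-validated synthetic-lethality classification
#'
#' Trains a classifier on pair features from both species simultaneously
#' and evaluates it with `n_folds`-fold cross-validation, stratified
#' jointly by species and label so every fold keeps the species mix and
#' class balance. For the random forest, the tree count is chosen per
#' outer fold by an inner nested cross-validation maximizing held-out
#' AUPR over `tree_grid`. Metrics (AUROC, AUPR, maximum F1) are computed
#' separately per species on the held-out pairs and averaged over folds.
#'
#' @param features numeric feature matrix (one row per pair).
#' @param labels factor with levels `non-SLI`, `SLI` (or coercible).
#' @param species character vector of per-pair species tags.
#' @param model `"random_forest"` or `"linear_svm"`.
#' @param n_folds number of outer folds (default 4).
#' @param seed RNG seed controlling fold assignment and model fits.
#' @param tree_grid candidate tree counts for the nested selection.
#' @param inner_folds inner folds for tree-count selection (default 3).
#' @return an `sl_cv_report`: list with `per_fold` (data frame of per-fold,
#'   per-species metrics and the chosen tree count) and `summary` (fold
#'   averages per species).
#' @export
cv_evaluate <- function(features, labels, species,
                        model = c("random_forest", "linear_svm"),
                        n_folds = 4L, seed = NULL,
                        tree_grid = c(100L, 250L, 500L), inner_folds = 3L) {
  model <- match.arg(model)
  labels <- factor(labels, levels = c("non-SLI", "SLI"))
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(species))
  if (length(unique(species)) < 2L) {
    stop_input("both species must be present")
  }
  fold <- stratified_folds(labels, species, n_folds,
                           seed = if (is.null(seed)) NULL else seed + 1L)
  per_fold <- list()
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    ntree <- NA_integer_
    if (model == "random_forest") {
      if (length(tree_grid) > 1L) {
        inner <- stratified_folds(labels[tr], species[tr], inner_folds,
                                  seed = if (is.null(seed)) NULL
                                         else seed + 100L + f)
        inner_aupr <- vapply(tree_grid, function(nt) {
          mean(vapply(seq_len(inner_folds), function(g) {
            itr <- inner != g
            sc <- fit_and_score(features[tr, , drop = FALSE][itr, , drop = FALSE],
                                labels[tr][itr],
                                features[tr, , drop = FALSE][!itr, , drop = FALSE],
                                model, nt,
                                seed = if (is.null(seed)) NULL
                                       else seed + 1000L + f * 10L + g)
            aupr(sc, labels[tr][!itr] == "SLI")
          }, numeric(1)))
        }, numeric(1))
        ntree <- tree_grid[which.max(inner_aupr)]
      } else {
        ntree <- tree_grid[1L]
      }
    }
    sc <- fit_and_score(features[tr, , drop = FALSE], labels[tr],
                        features[!tr, , drop = FALSE], model, ntree,
                        seed = if (is.null(seed)) NULL else seed + 2000L + f)
    te_species <- species[!tr]
    te_labels <- labels[!tr]
    for (sp in sort(unique(te_species))) {
      m <- te_species == sp
      y <- te_labels[m] == "SLI"
      roc <- suppressMessages(pROC::roc(
        response = factor(y, levels = c(FALSE, TRUE)), predictor = sc[m],
        quiet = TRUE, direction = "<"))
      o <- order(-sc[m])
      ids <- as.character(seq_along(sc[m]))
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        fold = f, species = sp, ntree = ntree,
        auroc = as.numeric(pROC::auc(roc)),
        aupr = aupr(sc[m], y),
        max_f1 = max_f1(ids[o], ids[y], scores = sc[m][o]),
        stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  summ <- do.call(rbind, lapply(split(per_fold, per_fold$species), function(d) {
    data.frame(species = d$species[1L], auroc = mean(d$auroc),
               aupr = mean(d$aupr), max_f1 = mean(d$max_f1),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_fold = per_fold, summary = summ, model = model,
                 n_folds = n_folds),
            class = "sl_cv_report")
}

#' @export
print.sl_cv_report <- function(x, ...) {
  cat(sprintf("Synthetic-lethality classification (%s, %d-fold CV)\n",
              x$model, x$n_folds))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Split a dataset by holding out genes
#'
#' Holds out a fraction of genes per species; every pair touching a
#' held-out gene goes to the test set, pairs with no held-out gene form
#' the training set. This measures generalization to unseen genes rather
#' than unseen pairs.
#'
#' @param dataset an [sl_dataset()].
#' @param fraction fraction of each species' genes to hold out (0 < f < 1).
#' @param seed RNG seed.
#' @return list with `train`, `test` (both `sl_dataset` subsets) and
#'   `held_out_genes` (named list per species).
#' @export
holdout_gene_split <- function(dataset, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  held <- with_seed(seed, {
    lapply(split(dataset, dataset$species), function(d) {
      genes <- sort(unique(c(d$gene_a, d$gene_b)))
      sample(genes, max(1L, ceiling(fraction * length(genes))))
    })
  })
  in_test <- vapply(seq_len(nrow(dataset)), function(r) {
    h <- held[[dataset$species[r]]]
    dataset$gene_a[r] %in% h || dataset$gene_b[r] %in% h
  }, logical(1))
  if (all(in_test) || !any(in_test)) {
    stop_input("degenerate split: empty train or test set")
  }
  train <- dataset[!in_test, , drop = FALSE]
  test <- dataset[in_test, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test, held_out_genes = held)
}
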
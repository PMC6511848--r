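# Kernel factorization, landmark selection, the minimum-norm landmark
# solve, and cross-species scores.

test_that("factorization reconstructs the kernel with deterministic signs", {
  expect_equal(unname(factorize_kernel(diag(3)) %*%
                        t(factorize_kernel(diag(3)))), diag(3))

  edge <- ppi_network(rbind(c("a", "b")))
  K <- regularized_laplacian(edge, 1)
  C <- factorize_kernel(K)
  expect_equal(ncol(C), 2L)
  expect_lt(max(abs(C %*% t(C) - K)), 1e-10)
  # per-column sign: largest-magnitude entry positive
  for (j in seq_len(ncol(C))) expect_gt(C[which.max(abs(C[, j])), j], 0)

  v <- c(3, 1, 2, 0.5)
  K1 <- outer(v, v)
  dimnames(K1) <- list(letters[1:4], letters[1:4])
  expect_equal(ncol(factorize_kernel(K1)), 1L)

  bad <- diag(3); bad[1, 1] <- -1
  expect_error(factorize_kernel(bad), "kernel")
})

test_that("reconstruction error stays tiny on random graphs", {
  for (s in 1:10) {
    n <- sample(10:150, 1)
    net <- random_network(n, 4 / n, seed = 400 + s)
    K <- regularized_laplacian(net, 0.05)
    C <- factorize_kernel(K)
    expect_lt(max(abs(C %*% t(C) - K)), 1e-8)
  }
})

test_that("landmark selection is seeded, bounded and degree-aware", {
  net1 <- random_network(20, 0.3, seed = 5, species = "s1")
  net2 <- random_network(20, 0.3, seed = 6, species = "s2")
  cand <- homolog_pairs(cbind(net1$nodes[1:8], net2$nodes[1:8]), net1, net2)

  all5 <- select_landmarks(cand[1:5, ], 5, "random", seed = 1)
  expect_setequal(paste(all5$source, all5$target),
                  paste(cand$source[1:5], cand$target[1:5]))

  a <- select_landmarks(cand, 4, "random", seed = 9)
  b <- select_landmarks(cand, 4, "random", seed = 9)
  d <- select_landmarks(cand, 4, "random", seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, d))

  expect_error(select_landmarks(cand, 99, "random", seed = 1), "between")

  # a hub pair must come first under the degree strategy
  hub1 <- names(which.max(network_degree(net1)))
  hub2 <- names(which.max(network_degree(net2)))
  cand2 <- homolog_pairs(rbind(cbind(hub1, hub2),
                               cbind(setdiff(net1$nodes, hub1)[1:3],
                                     setdiff(net2$nodes, hub2)[1:3])),
                         net1, net2)
  top <- select_landmarks(cand2, 1, "degree", net1 = net1, net2 = net2)
  expect_equal(top$source, hub1)
})

test_that("the hand-derived single-edge one-landmark solve is reproduced", {
  edge1 <- ppi_network(rbind(c("a", "b")), species = "s1")
  edge2 <- ppi_network(rbind(c("u", "v")), species = "s2")
  D1 <- regularized_laplacian(edge1, 1)
  D2 <- regularized_laplacian(edge2, 1)
  C1 <- factorize_kernel(D1)
  lms <- structure(data.frame(source = "a", target = "u",
                              stringsAsFactors = FALSE),
                   class = c("landmark_list", "data.frame"))
  C2 <- embed_target(C1, D2, lms)
  D12 <- cross_species_scores(C1, C2)
  expect_equal(unname(D12[, ]),
               matrix(c(2 / 3, 1 / 3, 1 / 3, 1 / 6), 2, byrow = TRUE),
               tolerance = 1e-10)

  # independent minimum-norm least-squares oracle for the same system
  C1L <- C1["a", , drop = FALSE]
  oracle <- t(MASS::ginv(C1L) %*% D2["u", , drop = FALSE])
  expect_lt(max(abs(C2 - oracle)), 1e-10)
  expect_error(embed_target(C1, D2, lms[0, ]), "empty")
})

test_that("landmark constraints hold and the solution has minimal norm", {
  pair <- fixture_pair60()
  fit <- fixture_fit60()
  C1L <- fit$C1[fit$landmarks$source, ]
  D2L <- fit$D2[fit$landmarks$target, ]
  expect_equal(qr(C1L)$rank, nrow(C1L))
  expect_lt(max(abs(C1L %*% t(fit$C2hat) - D2L)), 1e-6)

  # adding any null-space component keeps the constraint but adds norm
  sv <- svd(C1L)
  pinv <- sv$v %*% (t(sv$u) / sv$d)
  Pnull <- diag(ncol(C1L)) - pinv %*% C1L
  for (s in 1:3) {
    W <- with_seed(s, matrix(stats::rnorm(ncol(C1L) * nrow(fit$C2hat)),
                             ncol(C1L)))
    pert <- t(fit$C2hat) + Pnull %*% W
    expect_lt(max(abs(C1L %*% pert - D2L)), 1e-6)
    expect_gt(sum(pert^2), sum(fit$C2hat^2) + 1e-8)
  }
})

test_that("scores are invariant to the factorization's orthogonal ambiguity", {
  fit <- fixture_fit60()
  k <- ncol(fit$C1)
  Q <- with_seed(7, qr.Q(qr(matrix(stats::rnorm(k * k), k))))
  C1q <- fit$C1 %*% Q
  C2q <- embed_target(C1q, fit$D2, fit$landmarks)
  D12q <- cross_species_scores(C1q, C2q)
  expect_lt(max(abs(D12q - fit$D12)), 1e-8)
})

test_that("embedding a network into itself reproduces its kernel", {
  net <- preprocess_network(random_network(40, 0.12, seed = 8))
  fit <- munk(net, net, cbind(net$nodes, net$nodes),
              n_landmarks = length(net$nodes), preprocess = FALSE)
  expect_lt(max(abs(fit$D12 - fit$D1)), 1e-8)
})

test_that("dissimilarities invert positive scores and flag the rest", {
  expect_equal(to_dissimilarity(matrix(2))[1, 1], 0.5)
  expect_equal(to_dissimilarity(matrix(0))[1, 1], Inf)
  expect_equal(to_dissimilarity(matrix(-3))[1, 1], Inf)
  S <- with_seed(4, matrix(stats::runif(30, 0.1, 5), 5))
  expect_equal(stats::cor(as.vector(S), as.vector(to_dissimilarity(S)),
                          method = "spearman"), -1)
})

test_that("pair representations sum rows and scores expand bilinearly", {
  C <- rbind(i = c(1, 0), j = c(0, 1), k = c(2, 0), l = c(0, 3))
  expect_equal(unname(pair_representation(C, "i", "j")[1:2]), c(1, 1))
  expect_equal(unname(pair_representation(C, "i", "i")[1:2]), 2 * C["i", ])
  expect_error(pair_representation(C, "i", "zz"), "zz")

  expect_equal(pair_score(c(1, 1), c(1, -1)), 0)
  expect_equal(pair_score(pair_representation(C, "i", "j"),
                          pair_representation(C, "k", "l")), 5)
  expect_error(pair_score(1:3, 1:4), "dimension")

  for (s in 1:20) {
    M <- with_seed(s, matrix(stats::rnorm(8), 4,
                             dimnames = list(letters[1:4], NULL)))
    p <- pair_representation(M, "a", "b")
    q <- pair_representation(M, "c", "d")
    expect_equal(p, pair_representation(M, "b", "a"))
    four <- sum(M["a", ] * M["c", ]) + sum(M["a", ] * M["d", ]) +
      sum(M["b", ] * M["c", ]) + sum(M["b", ] * M["d", ])
    expect_equal(pair_score(p, q), four, tolerance = 1e-10)
  }
})
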
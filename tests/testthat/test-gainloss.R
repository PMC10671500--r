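test_that("birth-death transitions are degenerate at t = 0 and mean-preserving", {
  expect_equal(bd_transition_prob(4, 4, 0.01, 0), 1)
  expect_equal(bd_transition_prob(4, 3, 0.01, 0), 0)
  expect_error(bd_transition_prob(1, 1, -0.1, 1), "lambda")
  expect_error(bd_transition_prob(1, 1, 0.1, -1), "time")
  # the critical process preserves the parent mean
  P <- serpinscape:::bd_matrix(0.004, 40, 120)
  for (i in c(1, 3, 8, 15)) {
    expect_equal(sum(P[i + 1, ] * 0:120), i, tolerance = 1e-6)
  }
  expect_lt(max(abs(rowSums(P[1:31, ]) - 1)), 1e-8)
})

test_that("closed-form transitions match the generator matrix exponential", {
  skip_if_not_installed("Matrix")
  N <- 100
  lam <- 0.02; t <- 40 # lambda * t = 0.8
  G <- matrix(0, N + 1, N + 1)
  for (i in 1:N) {
    G[i + 1, i] <- lam * i
    if (i < N) G[i + 1, i + 2] <- lam * i
  }
  diag(G) <- -rowSums(G)
  Pexp <- as.matrix(Matrix::expm(G * t))
  P <- serpinscape:::bd_matrix(lam, t, N)
  expect_lt(max(abs(P[1:21, 1:21] - Pexp[1:21, 1:21])), 1e-6)
  # long-branch (scaling-and-squaring) path against the same oracle
  P2 <- serpinscape:::bd_matrix(lam, 4 * t, N)
  Pexp2 <- as.matrix(Matrix::expm(G * 4 * t))
  expect_lt(max(abs(P2[1:21, 1:21] - Pexp2[1:21, 1:21])), 1e-6)
})

test_that("two-leaf likelihood equals direct summation over root states", {
  tr <- ape::read.tree(text = "(A:12,B:30);")
  counts <- c(A = 3, B = 6)
  lam <- 0.008
  N <- 12
  ll <- family_likelihood(tr, counts, lam, max_count = N)
  prior <- c(0, rep(1 / N, N))
  direct <- sum(vapply(0:N, function(r) {
    prior[r + 1] * bd_transition_prob(r, 3, lam, 12) *
      bd_transition_prob(r, 6, lam, 30)
  }, numeric(1)))
  expect_equal(ll, log(direct), tolerance = 1e-10)
})

test_that("likelihood is invariant to leaf ordering", {
  tree <- example_species_tree()
  counts <- example_gene_counts()
  l1 <- family_likelihood(tree, counts, 0.003)
  l2 <- family_likelihood(tree, counts[sample(names(counts))], 0.003)
  expect_equal(l1, l2)
})

test_that("identical counts drive lambda to the zero boundary", {
  tr <- ape::read.tree(text = "((A:10,B:10):5,C:15);")
  fit <- fit_lambda(tr, c(A = 4, B = 4, C = 4), max_count = 20)
  expect_true(fit$boundary)
  expect_equal(fit$lambda, 0)
})

test_that("lambda estimates rescale when branch times rescale", {
  tree <- example_species_tree()
  set.seed(61)
  fams <- do.call(rbind, lapply(1:60, function(i) {
    sim_gene_counts(tree, 0.002, root_count = 5, seed = 7000 + i,
                    max_count = 40)$counts
  }))
  fit1 <- fit_lambda(tree, fams, max_count = 40)
  tree2 <- tree
  tree2$edge.length <- tree2$edge.length * 2
  fit2 <- fit_lambda(tree2, fams, max_count = 40)
  expect_equal(fit2$lambda, fit1$lambda / 2, tolerance = 1e-3)
})

test_that("ancestral reconstruction is exact in the no-change limit", {
  tree <- example_species_tree()
  counts <- setNames(rep(26L, length(tree$tip.label)), tree$tip.label)
  anc <- ancestral_counts(tree, counts, lambda = 1e-8)
  expect_true(all(anc$node_counts == 26L))
  expect_true(all(anc$deltas$delta == 0))
  expect_true(all(anc$deltas$label == "0"))
})

test_that("branch deltas telescope from the root to every leaf", {
  s <- sim_gene_counts(example_species_tree(), 0.002, root_count = 10,
                       seed = 99, max_count = 60)
  anc <- ancestral_counts(s$tree, s$counts, 0.002, max_count = 60)
  tr <- anc$tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  for (tip in seq_len(ntip)) {
    # walk up from tip to root, summing deltas
    node <- tip; acc <- 0
    while (node != root) {
      e <- which(tr$edge[, 2] == node)
      acc <- acc + anc$deltas$delta[e]
      node <- tr$edge[e, 1]
    }
    expect_equal(anc$node_counts[root] + acc, unname(s$counts[tip]))
  }
})

test_that("ancestral posterior matches brute-force enumeration on a triple", {
  tr <- ape::read.tree(text = "((A:20,B:20):30,C:50);")
  N <- 10; lam <- 0.01
  counts <- c(A = 3, B = 5, C = 2)
  P50 <- serpinscape:::bd_matrix(lam, 50, N)
  P30 <- serpinscape:::bd_matrix(lam, 30, N)
  P20 <- serpinscape:::bd_matrix(lam, 20, N)
  prior <- c(0, rep(1 / 10, 10))
  post_v <- numeric(N + 1); post_r <- numeric(N + 1)
  for (r in 0:N) {
    for (v in 0:N) {
      pr <- prior[r + 1] * P30[r + 1, v + 1] * P20[v + 1, counts["A"] + 1] *
        P20[v + 1, counts["B"] + 1] * P50[r + 1, counts["C"] + 1]
      post_v[v + 1] <- post_v[v + 1] + pr
      post_r[r + 1] <- post_r[r + 1] + pr
    }
  }
  anc <- ancestral_counts(tr, counts, lam, max_count = N)
  ntip <- 3L
  expect_equal(anc$node_counts[ntip + 1L], which.max(post_r) - 1L)
  expect_equal(anc$node_counts[ntip + 2L], which.max(post_v) - 1L)
})
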
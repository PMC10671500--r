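test_that("p and Poisson distances follow their closed forms", {
  expect_equal(pairwise_distance(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(pairwise_distance(c(a = "AAAA", b = "AAAC"),
                                 model = "p")["a", "b"], 0.25)
  expect_equal(pairwise_distance(c(a = "AAAA", b = "AAAC"))["a", "b"],
               -log(0.75))
  # pairwise deletion: gapped column dropped for that pair only
  expect_equal(pairwise_distance(c(a = "A-AA", b = "AGAC"),
                                 model = "p")["a", "b"], 1 / 3)
  expect_error(pairwise_distance(c(a = "AAAA", b = "CCCC")), "saturates")
  expect_error(pairwise_distance(c(a = "A--A", b = "-CC-")), "no ungapped")
})

test_that("Poisson correction never decreases a distance", {
  set.seed(2)
  for (rep in 1:20) {
    p <- runif(1, 0.01, 0.9)
    expect_gte(-log(1 - p), p)
  }
})

test_that("three-taxon NJ reproduces the three-point formulas", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (5 + 9 - 10) / 2)
  expect_equal(bl[["b"]], (5 + 10 - 9) / 2)
  expect_equal(bl[["c"]], (9 + 10 - 5) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers the generating quartet against least-squares search", {
  set.seed(9)
  for (rep in 1:5) {
    tr <- ape::rtree(4, tip.label = c("t1", "t2", "t3", "t4"))
    tr$edge.length <- runif(nrow(tr$edge), 0.2, 1.5)
    D <- ape::cophenetic.phylo(tr)[c("t1", "t2", "t3", "t4"),
                                   c("t1", "t2", "t3", "t4")]
    splits <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                   list(c(1, 4), c(2, 3)))
    rss <- vapply(splits, function(s) oracle_quartet_rss(D, s), numeric(1))
    best <- splits[[which.min(rss)]]
    nj_tr <- neighbor_joining(D)
    want <- ape::read.tree(text = sprintf(
      "((%s,%s),(%s,%s));",
      paste0("t", best[[1]][1]), paste0("t", best[[1]][2]),
      paste0("t", best[[2]][1]), paste0("t", best[[2]][2])
    ))
    expect_equal(ape::dist.topo(ape::unroot(nj_tr), ape::unroot(want)), 0,
                 ignore_attr = TRUE)
    # additive matrix: branch lengths recovered exactly
    expect_equal(sort(ape::cophenetic.phylo(nj_tr)[rownames(D), colnames(D)]),
                 sort(D), tolerance = 1e-9)
  }
})

test_that("NJ on additive matrices is exact and taxon-order invariant", {
  set.seed(10)
  for (rep in 1:5) {
    tr <- ape::rtree(8)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    D <- ape::cophenetic.phylo(tr)
    nj_tr <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj_tr), 0,
                 ignore_attr = TRUE)
    perm <- sample(rownames(D))
    nj_perm <- neighbor_joining(D[perm, perm])
    expect_equal(sum(nj_perm$edge.length), sum(nj_tr$edge.length),
                 tolerance = 1e-9)
    expect_equal(ape::dist.topo(nj_perm, nj_tr), 0, ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are deterministic given the seed", {
  set.seed(33)
  aln <- setNames(replicate(6, paste(
    sample(c("A", "C", "D", "E"), 120, replace = TRUE), collapse = ""
  )), paste0("s", 1:6))
  t1 <- bootstrap_support(aln, reps = 30, seed = 5)
  t2 <- bootstrap_support(aln, reps = 30, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  expect_error(bootstrap_support(aln, reps = 0), "positive")
})

test_that("diagnostic columns drive clade support to the top", {
  # two 4-taxon clades separated by 200 fixed diagnostic columns
  set.seed(4)
  block1 <- paste(sample(c("A", "C"), 200, replace = TRUE), collapse = "")
  ch <- strsplit(block1, "")[[1]]
  diag_cols <- sample(200, 60)
  ch[diag_cols] <- chartr("AC", "KW", ch[diag_cols])
  block2 <- paste(ch, collapse = "")
  jitter <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), k)
    ch[at] <- sample(c("G", "H", "N", "Q"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  aln <- c(a1 = jitter(block1, 4), a2 = jitter(block1, 4),
           a3 = jitter(block1, 4), a4 = jitter(block1, 4),
           b1 = jitter(block2, 4), b2 = jitter(block2, 4),
           b3 = jitter(block2, 4), b4 = jitter(block2, 4))
  tr <- bootstrap_support(aln, reps = 100, seed = 8)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  # the a|b bipartition must be near-unanimous; it is the deepest split
  expect_true(any(sup >= 95, na.rm = TRUE))
})

test_that("global alignment matches an independent affine-gap DP", {
  ga <- global_align("GATTACA", "GATTACA")
  expect_equal(ga$identity, 100)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  for (pair in list(c("GATTACA", "GCATGCU"), c("MKVLY", "MKLY"),
                    c("WWKEE", "WKE"))) {
    a <- chartr("U", "V", pair[1]); b <- chartr("U", "V", pair[2])
    ga <- global_align(a, b)
    expect_equal(ga$score,
                 oracle_global_align_score(a, b, BLOSUM62, 10, 0.5))
  }
  expect_error(global_align("", "A"), "non-empty")
})
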
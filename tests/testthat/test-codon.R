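test_that("back-translation threads codons through the gapped protein", {
  ca <- back_translate(c(x = "M-K", y = "MLK"),
                       c(x = "ATGAAA", y = "ATGCTGAAA"))
  expect_equal(unclass(ca)["x", ], c("ATG", "---", "AAA"))
  expect_equal(unclass(ca)["y", ], c("ATG", "CTG", "AAA"))
  # trailing stop stripped
  ca2 <- back_translate(c(x = "MK", y = "MK"),
                        c(x = "ATGAAATAA", y = "ATGAAG"))
  expect_equal(ncol(ca2), 2)
  expect_error(
    back_translate(c(x = "MM", y = "MM"), c(x = "ATGAAA", y = "ATGATG")),
    "mismatches protein at residue 2"
  )
  expect_error(
    back_translate(c(x = "MK", y = "MK"), c(x = "ATGTAAAAA", y = "ATGAAG")),
    "internal stop"
  )
})

test_that("translate(back_translate(x)) round-trips on random genes", {
  set.seed(21)
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  for (rep in 1:50) {
    n <- sample(10:40, 1)
    codons <- sample(sense, n, replace = TRUE)
    prot <- paste(gc_tab[codons], collapse = "")
    gapped <- strsplit(prot, "")[[1]]
    at <- sort(sample(n + 1, 3)) # sprinkle gaps
    for (g in rev(at)) gapped <- append(gapped, "-", after = g - 1)
    aln <- c(x = paste(gapped, collapse = ""),
             y = paste(gapped, collapse = ""))
    cds <- setNames(rep(paste(codons, collapse = ""), 2), c("x", "y"))
    ca <- back_translate(aln, cds)
    back <- serpinscape:::translate_codons(unclass(ca)["x", ])
    expect_equal(gsub("-", "", back), prot)
  }
})

test_that("codon alignments reject stop codons and ragged rows", {
  expect_error(codon_alignment(list(a = c("ATG", "TAA"), b = c("ATG", "AAA"))),
               "non-sense codon")
  expect_error(codon_alignment(list(a = "ATGAAA", b = "ATG")), "same number")
})

test_that("Ka/Ks degenerate cases behave as defined", {
  same <- codon_alignment(list(a = rep(c("ATG", "AAA", "CTG"), 5),
                               b = rep(c("ATG", "AAA", "CTG"), 5)))
  kk <- estimate_kaks(same)
  expect_equal(kk$ka, 0)
  expect_equal(kk$ks, 0)
  expect_true(kk$undefined)
  expect_true(is.na(kk$ratio))
  # one synonymous change only
  a <- rep("TTT", 20); b <- a; b[20] <- "TTC"
  kk2 <- estimate_kaks(codon_alignment(list(a = a, b = b)))
  expect_equal(kk2$ka, 0)
  expect_gt(kk2$ks, 0)
  expect_error(estimate_kaks(codon_alignment(list(a = c("ATG", "AAA"),
                                                  b = c("ATG", "AAA")))),
               "minimum")
  expect_error(estimate_kaks(codon_alignment(list(a = rep("---", 12),
                                                  b = rep("---", 12)))),
               "all-gap")
})

test_that("Ka/Ks tracks the simulated omega and correlates with NG86", {
  tr2 <- ape::read.tree(text = "(a:0.3,b:0.3);")
  om <- rep(c(0.2, 0.5, 1, 2), each = 5)
  mine <- numeric(length(om)); oracle <- numeric(length(om))
  for (i in seq_along(om)) {
    sim <- sim_codon_alignment(tr2, list(model = "M0", omega = om[i],
                                         kappa = 2), 300, seed = 600 + i)
    mine[i] <- estimate_kaks(sim$aln)$ratio
    oracle[i] <- oracle_ng86(unclass(sim$aln)["a", ],
                             unclass(sim$aln)["b", ])$ratio
  }
  expect_gte(cor(mine, oracle, method = "spearman"), 0.95)
  # rank order of group means preserved across simulated omega
  means <- tapply(mine, om, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
})

test_that("paralog pairing is within-species and exhaustive", {
  rec <- data.frame(id = c("a1", "a2", "a3", "b1", "b2"),
                    species = c("A", "A", "A", "B", "B"))
  pr <- pair_paralogs(rec)
  expect_equal(nrow(pr), 4)
  expect_equal(sum(pr$species == "A"), 3)
  expect_false(any(substr(pr$id1, 1, 1) != substr(pr$id2, 1, 1)))
  for (n in 2:8) {
    rec_n <- data.frame(id = paste0("g", 1:n), species = "S")
    pr_n <- pair_paralogs(rec_n)
    expect_equal(nrow(pr_n), choose(n, 2))
    expect_equal(anyDuplicated(paste(pr_n$id1, pr_n$id2)), 0L)
  }
})

test_that("rank-sum test uses exact enumeration for small samples", {
  # all 20 assignments of {1..3} vs {10..12}: most extreme ordering both ways
  rs <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_true(rs$exact)
  expect_equal(rs$p_value, 0.1)
  rs_same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(rs_same$p_value, 0.9)
  set.seed(14)
  rs_big <- rank_sum_test(rnorm(50), rnorm(50, mean = 1))
  expect_false(rs_big$exact)
  expect_lt(rs_big$p_value, 0.01)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})
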
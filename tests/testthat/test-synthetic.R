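test_that("generators are deterministic functions of their seed", {
  g1 <- gen_serpin_proteins(20, decoy_fraction = 0.3, seed = 3)
  g2 <- gen_serpin_proteins(20, decoy_fraction = 0.3, seed = 3)
  expect_identical(g1, g2)
  tr <- six_taxon_tree()
  s1 <- sim_codon_alignment(tr, list(model = "M0", omega = 0.5, kappa = 2),
                            40, seed = 4)
  s2 <- sim_codon_alignment(tr, list(model = "M0", omega = 0.5, kappa = 2),
                            40, seed = 4)
  expect_identical(s1, s2)
  tree <- example_species_tree()
  c1 <- sim_gene_counts(tree, 0.002, 6, seed = 5, max_count = 40)
  c2 <- sim_gene_counts(tree, 0.002, 6, seed = 5, max_count = 40)
  expect_identical(c1$counts, c2$counts)
  e1 <- sim_expression(10, c("a", "b"), list(list(size = 10, mean = 3)),
                       seed = 6)
  e2 <- sim_expression(10, c("a", "b"), list(list(size = 10, mean = 3)),
                       seed = 6)
  expect_identical(e1, e2)
  # FASTA bytes identical for identical seeds
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(setNames(g1$records$sequence, g1$records$id), f1)
  write_fasta(setNames(g2$records$sequence, g2$records$id), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("decoy-only output yields zero inhibitory calls", {
  gen <- gen_serpin_proteins(40, decoy_fraction = 1, seed = 8)
  ann <- annotate_records(gen$records)
  expect_equal(sum(ann$inhibitory), 0)
  expect_true(all(gen$truth$decoy))
  expect_error(gen_serpin_proteins(10, class_mix = c(trypsin = 0.7),
                                   seed = 1),
               "proportions")
  expect_error(gen_serpin_proteins(10, decoy_fraction = 1.5), "decoy_fraction")
})

test_that("zero-length trees replicate the root codons everywhere", {
  tr <- six_taxon_tree()
  tr$edge.length[] <- 0
  sim <- sim_codon_alignment(tr, list(model = "M0", omega = 1, kappa = 2),
                             30, seed = 9)
  m <- unclass(sim$aln)
  for (i in 2:nrow(m)) expect_equal(unname(m[i, ]), unname(m[1, ]))
})

test_that("substitution frequency grows with branch length", {
  frac <- vapply(c(0.01, 0.1, 0.5), function(t) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
    sim <- sim_codon_alignment(tr, list(model = "M0", omega = 1, kappa = 2),
                               800, seed = 12)
    m <- unclass(sim$aln)
    mean(m[1, ] != m[2, ])
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("root codon frequencies converge to F3x4", {
  tr <- ape::read.tree(text = "(a:0.01,b:0.01);")
  ntfreq <- matrix(c(.4, .2, .2, .2,
                     .25, .25, .25, .25,
                     .1, .4, .3, .2), 4)
  sim <- sim_codon_alignment(tr, list(model = "M0", omega = 1, kappa = 2),
                             10000, seed = 13, ntfreq = ntfreq)
  ct <- serpinscape:::codon_tables()
  emp <- tabulate(match(unclass(sim$aln)["a", ], ct$codons), 61) / 10000
  expect_lt(max(abs(emp - sim$pi)), 0.012) # ~4 sd of a binomial cell
})

test_that("gene-count simulation respects the critical-process mean", {
  tr <- ape::read.tree(text = "((A:30,B:30):20,C:50);")
  expect_error(sim_gene_counts(tr, -1, 5), "lambda")
  s0 <- sim_gene_counts(tr, 0, 7, seed = 2)
  expect_true(all(s0$node_counts == 7))
  means <- colMeans(do.call(rbind, lapply(1:1000, function(i) {
    sim_gene_counts(tr, 0.003, 5, seed = 20000 + i, max_count = 40)$counts
  })))
  # E[leaf] = root under the critical process; 3 SEs of the sample mean
  se <- sqrt(2 * 0.003 * 50 * 5 / 1000) * 3
  expect_true(all(abs(means - 5) < 3 * max(se, 0.15)))
})

test_that("expression generator validates its block specification", {
  expect_error(sim_expression(10, "s", list(list(size = 4, mean = 1))),
               "sum to n_genes")
  sim <- sim_expression(5, c("s1", "s2"),
                        list(list(size = 5, mean = 3)), noise_sd = 0,
                        seed = 3)
  expect_true(all(sim$fpkm >= 0))
  expect_equal(unname(transform_fpkm(sim$fpkm)[1, ]), c(3, 3))
})

test_that("the packaged family fixture reproduces its tabulated annotation", {
  fx <- serpin_fixture()
  expect_equal(nrow(fx), 26)
  ann <- annotate_records(fx)
  expect_equal(ann$inhibitory, fx$inhibitory == "yes")
  inh <- fx$inhibitory == "yes"
  expect_equal(ann$p1_residue[inh], fx$p1[inh])
  expect_equal(ann$p1p_residue[inh], fx$p1p[inh])
  expect_equal(ann$target_class[inh], fx$target_class[inh])
  # regeneration is deterministic
  expect_identical(serpin_fixture(), fx)
})
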
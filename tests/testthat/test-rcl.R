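test_that("hinge scan finds a planted perfect consensus and ranks it first", {
  seq <- paste0(strrep("M", 330), "EEGTEAAAA", strrep("L", 26), "KS")
  hits <- scan_hinge(seq)
  expect_equal(hits$p17_index[1], 331)
  expect_equal(hits$score[1], 8L)
  expect_true(all(diff(hits$score) <= 0))
})

test_that("hinge scan returns no hits on sequences matching nothing", {
  expect_equal(nrow(scan_hinge(strrep("P", 100))), 0L)
})

test_that("hinge scan rejects sequences too short for an RCL", {
  expect_error(scan_hinge(strrep("A", 39)), "too short")
})

test_that("hinge scan equals exhaustive anchor enumeration on random input", {
  set.seed(42)
  for (rep in 1:10) {
    seq <- paste(sample(names(serpinscape:::AA_RESIDUE_MASS), 400,
                        replace = TRUE), collapse = "")
    got <- scan_hinge(seq)
    want <- oracle_hinge_scan(seq)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(max(got$score), max(want$score))
      # identical (anchor, score) sets
      expect_setequal(paste(got$p17_index, got$score),
                      paste(want$p17_index, want$score))
      # tie-break: top hit is the C-terminal-most maximal anchor
      top <- want$p17_index[want$score == max(want$score)]
      expect_equal(got$p17_index[1], max(top))
    }
  }
})

test_that("annotation places P1 sixteen residues after P17 and calls class", {
  seq <- paste0(strrep("M", 330), "EEGTEAAAA", strrep("L", 20), "KSAAAA")
  ann <- annotate_rcl(seq)
  expect_equal(ann$p1_index, ann$hinge$p17_index + 16L)
  expect_equal(ann$p1p_index, ann$p1_index + 1L)
  expect_true(ann$inhibitory)
  expect_equal(ann$specificity, "chymotrypsin")
})

test_that("degraded hinges and truncated tails are non-inhibitory", {
  set.seed(7)
  # hinge scoring only 3/8 (mimics weakly conserved family members)
  chars <- strsplit(serpinscape:::sample_bg(400), "")[[1]]
  chars <- serpinscape:::plant_degraded_hinge(chars, 350, keep = 3)
  deg <- annotate_rcl(paste(chars, collapse = ""))
  if (!is.null(deg$hinge)) expect_lte(deg$hinge$score, 5)
  expect_false(deg$inhibitory)
  expect_equal(deg$specificity, "none")
  # RCL falls off the end of the sequence
  chars <- strsplit(serpinscape:::sample_bg(276), "")[[1]]
  chars <- serpinscape:::plant_hinge(chars, 268)
  trunc <- annotate_rcl(paste(chars, collapse = ""))
  expect_false(trunc$inhibitory)
})

test_that("specificity classes follow the P1 residue map", {
  expect_equal(classify_specificity("K"), "trypsin")
  expect_equal(classify_specificity("R"), "trypsin")
  expect_equal(classify_specificity("Y"), "chymotrypsin")
  expect_equal(classify_specificity("M"), "elastase")
  expect_equal(classify_specificity("D"), "none")
  expect_error(classify_specificity("B"), "invalid residue")
  expect_error(classify_specificity("KK"), "invalid residue")
})

test_that("molecular weight matches residue-mass arithmetic and is additive", {
  expect_equal(compute_mw("G") * 1000, 75.07, tolerance = 1e-4)
  expect_equal(compute_mw("GG") * 1000, 132.12, tolerance = 1e-4)
  expect_error(compute_mw(""), "non-empty")
  expect_error(compute_mw("GZ"), "unknown residue")
  set.seed(3)
  for (rep in 1:5) {
    s1 <- serpinscape:::sample_bg(30)
    s2 <- serpinscape:::sample_bg(45)
    expect_equal(compute_mw(paste0(s1, s2)) * 1000,
                 compute_mw(s1) * 1000 + compute_mw(s2) * 1000 - 18.0153,
                 tolerance = 1e-9)
  }
})

test_that("pI bisection agrees with closed form and a fine grid search", {
  # no ionizable side chains: midpoint of the terminal pKa values
  expect_equal(compute_pi("GGGG"), 6.1, tolerance = 2e-3)
  expect_gt(compute_pi("RRRR"), 7)
  set.seed(11)
  seqs <- replicate(3, serpinscape:::sample_bg(50))
  grid <- seq(0, 14, by = 5e-4)
  for (s in seqs) {
    chars <- strsplit(s, "")[[1]]
    pk <- serpinscape:::PKA_TABLE
    npos <- table(factor(chars, levels = names(pk$positive)))
    nneg <- table(factor(chars, levels = names(pk$negative)))
    charge <- sapply(grid, function(ph) {
      1 / (1 + 10^(ph - pk$nterm)) +
        sum(npos / (1 + 10^(ph - pk$positive))) -
        1 / (1 + 10^(pk$cterm - ph)) -
        sum(nneg / (1 + 10^(pk$negative - ph)))
    })
    expect_equal(compute_pi(s), grid[which.min(abs(charge))],
                 tolerance = 2e-3)
  }
})

test_that("family summary tallies are exact and order-invariant", {
  rec <- data.frame(
    id = c("a", "b", "c"), chromosome = "chrZ",
    signal_peptide = c("1-18", "NO", "1-20"),
    gene_group = c("A", "A", "B"),
    inhibitory = c(TRUE, TRUE, FALSE)
  )
  rep1 <- summarize_family(rec, chromosome_set = "chrZ")
  expect_equal(rep1$pct_on_chromosome_set, 100)
  expect_equal(rep1$n_inhibitory, 2)
  expect_equal(rep1$n_signal_peptide, 2)
  expect_equal(rep1$group_counts, c(A = 2L, B = 1L))
  rep2 <- summarize_family(rec[c(3, 1, 2), ], chromosome_set = "chrZ")
  expect_equal(rep2[order(names(rep2))], rep1[order(names(rep1))])
  expect_error(summarize_family(rec[0, ]), "no records")
})

test_that("annotation recovers the planted P1 on generator output", {
  gen <- gen_serpin_proteins(60, decoy_fraction = 0, seed = 77)
  ann <- annotate_records(gen$records)
  expect_true(all(ann$inhibitory))
  expect_equal(ann$p1_index, gen$truth$p1_index)
  expect_equal(ann$p1_residue, gen$truth$p1_residue)
  expect_equal(ann$specificity, gen$truth$class)
  expect_equal(ann$p1_index, ann$hinge_index + 16L)
})
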
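# Seeded simulation studies validating each stage against planted truth.
# These drivers define the package's standard validation conditions (tree
# shapes, replicate counts, rates) in one place; the test suite and the
# acceptance script both run them.

#' Four- and six-taxon study trees for codon simulations
#'
#' Balanced trees with moderate divergence (branch lengths in expected
#' substitutions per codon) used by the codon-model validation studies.
#'
#' @param ntaxa 4 or 6.
#' @return A `phylo` tree.
#' @export
codon_study_tree <- function(ntaxa = 4L) {
  txt <- switch(as.character(ntaxa),
    "4" = "((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2);",
    "6" = "(((A:0.3,B:0.3):0.15,(C:0.3,D:0.3):0.15):0.1,(E:0.4,F:0.4):0.1);",
    stop("ntaxa must be 4 or 6")
  )
  ape::read.tree(text = txt)
}

#' Type-I error of the M7-vs-M8 LRT on null data
#'
#' Simulates `reps` alignments under M7 (no positive selection), runs the
#' full M0 -> M7 -> M8 fitting pipeline on each, and scores the fraction of
#' datasets the df = 2 LRT rejects at `alpha`. The boundary null makes the
#' test conservative, so the rate should sit at or below the nominal level.
#'
#' @param reps Number of null replicates (default 100).
#' @param n_sites Codon sites per replicate (default 150).
#' @param alpha Nominal level (default 0.05).
#' @param seed Integer seed.
#' @param p,q,kappa Null M7 simulation parameters.
#' @return List with `rejection_rate`, `reps`, `p_values`, `statistics`.
#' @export
study_m8_type1 <- function(reps = 100L, n_sites = 150L, alpha = 0.05,
                           seed = 1L, p = 0.5, q = 1.5, kappa = 2) {
  tree <- codon_study_tree(4L)
  pvals <- numeric(reps)
  stats <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- sim_codon_alignment(tree, list(model = "M7", p = p, q = q,
                                          kappa = kappa),
                               n_sites, seed = seed * 1000L + r)
    m0 <- fit_site_model(sim$aln, tree, "M0")
    m7 <- fit_site_model(sim$aln, tree, "M7", m0 = m0)
    m8 <- fit_site_model(sim$aln, tree, "M8", m0 = m0, m7 = m7)
    l <- lrt(m7, m8, df = 2)
    pvals[r] <- l$p_value
    stats[r] <- l$statistic
  }
  list(rejection_rate = mean(pvals < alpha), reps = reps,
       p_values = pvals, statistics = stats)
}

#' BEB recovery of planted positively selected sites
#'
#' Simulates one alignment on the six-taxon study tree in which a fraction
#' `p1` of sites evolve at `omega_s` (the rest under a beta background),
#' fits M0/M7/M8, runs [beb_sites()], and scores recall on the planted
#' sites and the false-flag rate on the neutral ones.
#'
#' @param n_sites Codon sites (default 500).
#' @param p1 Planted selected fraction (default 0.05).
#' @param omega_s Planted selected omega (default 5).
#' @param seed Integer seed.
#' @return List with `recall`, `false_rate`, `n_planted`, `beb`, `truth`.
#' @export
study_beb_recovery <- function(n_sites = 500L, p1 = 0.05, omega_s = 5,
                               seed = 1L) {
  tree <- codon_study_tree(6L)
  sim <- sim_codon_alignment(
    tree, list(model = "M8", p0 = 1 - p1, p = 0.5, q = 1.5,
               omega_s = omega_s, kappa = 2),
    n_sites, seed = seed
  )
  m0 <- fit_site_model(sim$aln, tree, "M0")
  m7 <- fit_site_model(sim$aln, tree, "M7", m0 = m0)
  m8 <- fit_site_model(sim$aln, tree, "M8", m0 = m0, m7 = m7)
  bb <- beb_sites(m8)
  planted <- sim$truth$site[sim$truth$omega > 1]
  neutral <- setdiff(bb$site, planted)
  list(recall = mean(bb$pss[planted]),
       false_rate = mean(bb$pss[neutral]),
       n_planted = length(planted), beb = bb, truth = sim$truth,
       m7 = m7, m8 = m8)
}

#' Gain/loss rate recovery on the 14-taxon example tree
#'
#' Simulates `n_families` independent families at rate `lambda` and refits
#' a single shared lambda by maximum likelihood.
#'
#' @param n_families Number of families (default 200).
#' @param lambda True rate (default 0.002 events/gene/My).
#' @param root_count Root family size (default 5).
#' @param seed Integer seed.
#' @return List with `lambda_hat`, `lambda_true`, `relative_error`.
#' @export
study_lambda_recovery <- function(n_families = 200L, lambda = 0.002,
                                  root_count = 5L, seed = 1L) {
  tree <- example_species_tree()
  mx <- max(60L, 8L * root_count)
  cm <- do.call(rbind, lapply(seq_len(n_families), function(i) {
    sim_gene_counts(tree, lambda, root_count, seed = seed * 10000L + i,
                    max_count = mx)$counts
  }))
  fit <- fit_lambda(tree, cm, max_count = mx)
  list(lambda_hat = fit$lambda, lambda_true = lambda,
       relative_error = (fit$lambda - lambda) / lambda)
}

#' Exact ancestral-count recovery on planted birth-death simulations
#'
#' Simulates families with recorded internal states on the 14-taxon example
#' tree and reconstructs them with [ancestral_counts()] at the true lambda.
#' Small families are the informative regime for exact integer recovery
#' (genome-wide birth-death tables are dominated by them); large families
#' carry irreducible posterior spread on deep branches.
#'
#' @param reps Number of replicate families (default 100).
#' @param lambda True rate (default 0.001).
#' @param root_count Root family size (default 3).
#' @param seed Integer seed.
#' @return List with `exact_recovery` (fraction of internal nodes hit
#'   exactly), `sign_agreement` (fraction of branches whose gain/loss sign
#'   matches the planted history), `reps`.
#' @export
study_ancestral_recovery <- function(reps = 100L, lambda = 0.001,
                                     root_count = 3L, seed = 1L) {
  tree <- example_species_tree()
  mx <- max(40L, 8L * root_count)
  hit <- 0L; tot <- 0L; sgn <- 0L; nbr <- 0L
  for (i in seq_len(reps)) {
    s <- sim_gene_counts(tree, lambda, root_count, seed = seed * 10000L + i,
                         max_count = mx)
    anc <- ancestral_counts(s$tree, s$counts, lambda, max_count = mx)
    ntip <- length(s$tree$tip.label)
    idx <- (ntip + 1L):length(s$node_counts)
    hit <- hit + sum(anc$node_counts[idx] == s$node_counts[idx])
    tot <- tot + length(idx)
    true_delta <- s$node_counts[s$tree$edge[, 2]] -
      s$node_counts[s$tree$edge[, 1]]
    sgn <- sgn + sum(sign(anc$deltas$delta) == sign(true_delta))
    nbr <- nbr + length(true_delta)
  }
  list(exact_recovery = hit / tot, sign_agreement = sgn / nbr, reps = reps)
}

#' Neutral-simulation calibration of the Ka/Ks estimator
#'
#' Simulates sequence pairs at omega = 1 (kappa = 2) and averages the
#' estimated Ka/Ks; an unbiased counting estimator should centre on 1.
#'
#' @param n_pairs Number of pairs (default 50).
#' @param n_sites Codons per pair (default 500).
#' @param divergence Total pairwise branch length (default 0.6
#'   substitutions/codon).
#' @param seed Integer seed.
#' @return List with `mean_ratio`, `ratios`.
#' @export
study_neutral_kaks <- function(n_pairs = 50L, n_sites = 500L,
                               divergence = 0.6, seed = 1L) {
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", divergence / 2,
                                      divergence / 2))
  ratios <- vapply(seq_len(n_pairs), function(i) {
    sim <- sim_codon_alignment(tr, list(model = "M0", omega = 1, kappa = 2),
                               n_sites, seed = seed * 1000L + i)
    estimate_kaks(sim$aln)$ratio
  }, numeric(1))
  list(mean_ratio = mean(ratios), ratios = ratios)
}

#' Planted-truth annotation recovery
#'
#' Generates a serpin set with decoys and scores inhibitory recall (with
#' the planted P1 position) and specificity-class agreement.
#'
#' @param n Number of records (default 500).
#' @param decoy_fraction Decoy fraction (default 0.3).
#' @param seed Integer seed.
#' @return List with `inhibitory_recall`, `p1_agreement`,
#'   `specificity_agreement`, `decoy_false_rate`, `n_planted`, `n_decoys`.
#' @export
study_annotation_recovery <- function(n = 500L, decoy_fraction = 0.3,
                                      seed = 1L) {
  gen <- gen_serpin_proteins(n, decoy_fraction = decoy_fraction, seed = seed)
  ann <- annotate_records(gen$records)
  stopifnot(identical(ann$id, gen$truth$id))
  planted <- !gen$truth$decoy
  ok_call <- ann$inhibitory[planted] &
    ann$p1_index[planted] == gen$truth$p1_index[planted]
  list(
    inhibitory_recall = mean(ann$inhibitory[planted]),
    p1_agreement = mean(ok_call),
    specificity_agreement =
      mean(ann$specificity[planted] == gen$truth$class[planted]),
    decoy_false_rate = mean(ann$inhibitory[!planted]),
    n_planted = sum(planted), n_decoys = sum(!planted)
  )
}
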
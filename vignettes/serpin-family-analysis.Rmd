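---
title: "Models and methods behind serpinscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind serpinscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpinscape)
```

serpinscape implements the analysis stages of a genome-scale serpin
(serine protease inhibitor) family study: reactive-center-loop (RCL)
annotation, phylogenetics, molecular-evolution tests, gene-family
gain/loss, isoform assembly and expression clustering. This vignette is
the package's account of the underlying models, the tunable parameters,
the numerical choices, and what the validation studies do and do not
demonstrate.

## RCL annotation

Serpins are ~350-500 residue proteins whose exposed RCL, near the
C-terminus, is cleaved by the target protease between the residues named
P1 and P1' (P-numbering counts N-terminally from the scissile bond:
P17 ... P1 | P1' ...). Inhibitory serpins need the RCL to insert into
beta-sheet A after cleavage, which requires small residues in the
*hinge* (P17-P9). The annotation model scores the classic hinge
consensus

```
P17 [E]   P16 [E/K/R]   P15 [G]   P14 [T/S]   P13 [any]   P12-P9 [A/G/S]
```

at every candidate P17 anchor. P13 is a wildcard, so eight positions are
scored (0-8). Design choices, each surfaced as a parameter:

* **Search window.** The anchor is restricted to `[L - 75, L - 25]`
  (`L` = length): the RCL sits near the carboxyl terminus, and 25-75
  residues leaves room for P17..P1' plus a short tail. Anything outside
  this window (a hinge stranded >60 residues from the tail by a long
  RCL insertion, or a truncated protein whose P1 would fall off the
  end) is not an inhibitory configuration.
* **Inhibitory threshold.** `min_score = 6` of 8. The literature
  describes weakly conserved hinges qualitatively rather than with a
  numeric cutoff; 6/8 cleanly separates a perfect or near-perfect hinge
  from the 3/8-level matches seen in non-inhibitory family members, and
  it is configurable.
* **Tie-breaking.** Equal-scoring anchors resolve to the most
  C-terminal one, the canonical RCL placement.
* **Specificity.** P1 Arg/Lys marks trypsin-like targets; large
  hydrophobics (Leu/Ile/Tyr, extended to Phe/Trp by protease chemistry)
  chymotrypsin; small hydrophobics (Ala/Val/Met, extended to Gly/Ser)
  elastase. Any other P1 residue yields no class, and a record is only
  called inhibitory when a class is assigned.
* **Coordinates** are 1-based inclusive in every user-facing table.

Molecular weight is the sum of average residue masses plus one water;
the isoelectric point solves the Henderson-Hasselbalch net charge for
zero by bisection on pH 0-14 (tolerance 1e-3) with an EMBOSS-style pKa
table declared once in the package constants. Signal peptides are input
metadata (`"1-18"` / `"NO"`), never predicted.

Isoform assembly mirrors the serpin-1 architecture in which shared
exons 1-8 (and a shared terminal exon) combine with one of several
mutually exclusive RCL-encoding ninth exons; each assembled cDNA is
translated and re-annotated, so isoforms can differ in P1 and
specificity.

## Distances, neighbor joining, bootstrap

Pairwise protein distances use pairwise deletion (a gapped column is
dropped for that pair only) and either the raw mismatch proportion `p`
or the Poisson correction `d = -ln(1 - p)`; `p = 1` is reported as a
saturation error rather than an infinite distance. `d >= p` always — the
correction only inflates. Trees come from Saitou-Nei neighbor joining
(delegated to `ape::nj`, the field-standard implementation); negative
branch-length artefacts are clamped to zero and flagged. Bootstrap
support resamples alignment columns with replacement and reports the
percentage of replicate trees containing each internal bipartition of
the full-data tree; runs are bit-reproducible given the seed. Percent
identity from `global_align()` uses alignment columns (gaps included)
as the denominator — the most conservative convention; identity to the
shorter sequence reads higher. Only Poisson/p distances are offered;
maximum-likelihood amino-acid model distances (e.g. JTT) are out of
scope.

## Ka/Ks for paralog pairs

`estimate_kaks()` is a counting estimator in the style of Yang & Nielsen
(2000): kappa (transition/transversion ratio) is estimated from
fourfold-degenerate and nondegenerate positions via a K80 correction;
synonymous/nonsynonymous site totals weight each possible
single-nucleotide change by kappa and the position-specific target
nucleotide frequency; observed differences are apportioned over all
stop-free substitution pathways with equal weights; and each class is
corrected for multiple hits with a K80-style correction from the
transition/transversion split of its own differences (JC fallback when
the logarithms are undefined). `Ks = 0` yields an explicitly undefined
ratio rather than an infinity. The estimator is validated two ways: a
simpler NG86-style oracle (unweighted sites, JC correction) must agree
in rank order (Spearman >= 0.95), and simulation at omega = 1 must
centre the estimated ratio on 1 (the neutral-calibration study uses 50
pairs of 500 codons at a total divergence of 0.6 substitutions/codon —
enough substitutions for stable counting, far from saturation).

Group comparisons use the two-sided Wilcoxon rank-sum test: exact
enumeration for combined n <= 12 without ties, tie-corrected normal
approximation otherwise.

## Codon site models and positive selection

The substitution model is GY94: codon-to-codon rates are zero for
multi-nucleotide changes and otherwise proportional to the target codon
frequency (F3x4, estimated from the alignment with one pseudocount per
nucleotide cell), multiplied by kappa for transitions and by omega for
nonsynonymous changes. All site classes share one scale factor — the
weighted mean rate over classes — so branch lengths are expected
substitutions per codon under the mixture (the simulator uses the same
convention, making parameter-recovery tests exact in expectation).

* **M0** one omega; **M3** three discrete classes; **M7**
  Beta(p, q) in 10 equal-probability categories (category medians);
  **M8** adds a selected class with omega_s >= 1 and weight 1 - p0.
* Branch lengths are estimated under M0 (BFGS on log scale, initialised
  from the input tree) and held fixed for M3/M7/M8 — the standard
  desk-scale economy; kappa is re-estimated within every model.
* Mixture fits use bounded multi-start Nelder-Mead on transformed
  parameters (log for positives, logit for p0, `1 + exp(u)` for
  omega_s); starts are recorded in the fit. M8 always includes a start
  at the M7 optimum with p0 -> 1, so its maximum cannot fall below M7's
  by more than optimizer resolution; `lrt()` clips tiny negative
  differences to zero.
* The likelihood core (eigendecomposition of the
  symmetrised rate matrix + Felsenstein pruning with per-site
  rescaling) is compiled C++; an independent R implementation of the
  same quantities backs the simulator, and both are checked against a
  direct matrix-exponential summation on two-taxon toys.

The M7-vs-M8 LRT uses df = 2; under the null the true parameter sits on
the boundary, so the chi-squared reference is conservative — the
validation study (100 datasets simulated under M7 on a four-taxon tree,
150 codons) checks the empirical size stays at or below ~nominal.
M0-vs-M3 defaults to df = 4 (two extra omegas + two free proportions);
published tables in this field sometimes print p-values consistent with
df = 2 for this comparison, so the df is an explicit argument rather
than hard-wired.

**BEB.** Site detection under M8 uses the Bayes empirical Bayes
construction: a discrete uniform prior grid over (p0, p, q, omega_s) —
10 points per dimension; p0 and omega_s on equal-spaced mid-points of
(0, 1) and (1, 11), p and q log-spaced on [0.05, 5] and [0.05, 20] —
with branch lengths, kappa, codon frequencies and the overall rate
scale fixed at the M8 MLEs. The posterior probability that a site
belongs to the selected class averages over the grid posterior;
sites at posterior >= 0.95 are flagged. Grid sizes are configurable
constants. The planted-truth study (six taxa, 500 codons, 5% of sites
at omega = 5) asks for >= 60% recall with <= 1% false flags — BEB at
this scale is deliberately conservative, and full recall is not
expected.

## Birth-death gene gain/loss

Family-size evolution on a dated (ultrametric, million-year) species
tree follows the critical linear birth-death process: each gene
duplicates and dies at the same rate lambda (events/gene/My), the
single-lambda model of the classic gene-family tools. The transition
probability has a closed-form series in
`alpha = lambda * t / (1 + lambda * t)`; for `lambda * t > 0.8` the
series alternates in sign and cancels catastrophically in floating
point, so long branches are computed by scaling-and-squaring (closed
form at `t / 2^k`, then k matrix squarings — every entry stays
non-negative). Correctness is oracle-checked against the matrix
exponential of the truncated generator.

Likelihoods prune over integer states `0..max_count` (default >= 2x the
largest leaf count; rows near the truncation boundary lose mass, which
only matters if the truncation is inadequate). The root prior is
uniform on `[1, 2 * max leaf count]`; zero is excluded because an
extinct family is unobservable. Other tools condition the root
differently, so absolute likelihoods are not comparable across
implementations, but rate estimates and reconstructions are. lambda is
fitted by golden-section search on `[0, 0.1]`; identical counts
everywhere drive the estimate to the zero boundary, which is returned
with a flag. Ancestral counts are per-node max-marginal posteriors from
an up-down pass (validated against brute-force enumeration on a
three-taxon tree), and branch labels report the signed child-minus-
parent difference ("+2", "-1").

The validation studies use the packaged synthetic 14-taxon chronogram.
Rate recovery simulates 200 families at lambda = 0.002 from a root of 5
genes. Exact ancestral recovery uses root families of 3 genes at lambda
= 0.001: exact integer recovery is the informative statistic in the
small-family regime that dominates genome-wide birth-death tables
(most gene families have a handful of members). For a serpin-sized
family (~28 genes) the per-branch count standard deviation is 2-3 on
deep branches, so no estimator recovers deep nodes exactly much better
than ~40-50% — the package reports the same reconstruction there, and
the sign pattern of gains and losses, which is what such figures
display, remains >= 90% correct. This is an information limit of the
data, not an implementation artefact, and is checked as such.

## Expression clustering

FPKM matrices are transformed as `log2(x + 1)` (exact zeros map to
zero; the transform is strictly monotone and invertible). Genes are
clustered by average-linkage agglomeration on either `1 - Pearson`
correlation between profiles (the default: heatmap subgrouping is about
profile shape) or euclidean distance, cut at a user-supplied k (4 for
developmental stages and 3 for tissues in the motivating study; the
source heatmaps were clustered visually, so exact membership is not
claimed). Group labels are renumbered by decreasing cluster mean so
group 1 is always the highest-expressed subgroup, making the assignment
deterministic and row-order invariant.

## Synthetic data and what passing tests show

Every generator is a deterministic function of its parameters and seed
and returns the planted truth alongside the data:

* `gen_serpin_proteins()` plants a perfect hinge at a recorded anchor
  (uniform background composition — compositional realism is not needed
  by any downstream check) with a P1 residue drawn from a specificity
  mix; decoys carry a degraded hinge (<= 3/8), a truncated tail, or a
  long-RCL insertion. Records are rejection-sampled so the truth labels
  are guaranteed: no decoy hides a chance hinge at or above the
  threshold and no planted record is outscored by a background anchor.
  This is part of the generator's contract — the truth bundle must be
  sufficient to score recovery exactly.
* `sim_codon_alignment()` draws root codons from F3x4 and evolves them
  with exact per-class transition matrices; per-site omega classes are
  recorded.
* `sim_gene_counts()` samples family sizes branch-by-branch from the
  birth-death transition rows, recording internal states.
* `sim_expression()` builds `2^(block mean + noise) - 1` FPKM blocks so
  the transform recovers gaussian structure exactly.
* `serpin_fixture()` regenerates the packaged 26-member family table
  with synthetic stand-in sequences engineered to annotate with the
  tabulated P1/P1' and inhibitory calls; the real appendix sequences
  are not distributed, so sequence-level statistics (Mw, pI) of the
  fixture are not meaningful, while the table-level tallies are exact.

Passing these studies shows the implementations are internally
consistent and recover planted truth under their own model assumptions.
It does not show robustness to real-data violations: alignment error,
recombination, compositional heterogeneity, lineage-specific rates,
expression replicate noise, or genome-assembly artefacts are all
outside the generators.

## Problem sizes and reproducibility

The standard validation runs — chosen to exercise every code path at
desk scale — are: 100 null LRT replicates of 4 taxa x 150 codons; one
BEB study of 6 taxa x 500 codons; 200 birth-death families (rate) and
100 replicates (ancestral counts) on the 14-taxon tree; 50 neutral
pairs of 500 codons; 500 annotation records with 30% decoys. All
randomness flows through explicit integer seeds, and `run_pipeline()`
logs its seed and a config hash so identical configurations reproduce
identical outputs.

## Known limitations

* Hinge scoring is position-independent (no PSSM weighting), matching
  how the consensus is described in the serpin literature.
* F3x4 is the only codon frequency model; branch and branch-site
  models are not implemented.
* The beta discretisation uses category medians; very extreme (p, q)
  make the discretisation coarse at the boundaries.
* Single-lambda birth-death only; no per-branch rates, no error model
  on observed counts, and no "rapidly evolving family" p-values.
* The NJ implementation is `ape`'s; its internal tie-breaking among
  exactly equal Q-criterion pairs is deterministic but not configurable.
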
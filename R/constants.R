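# Internal constant tables: residue masses, pKa values, genetic code.

# Average (isotope-averaged) residue masses in Da; a free peptide adds one
# water (AA_WATER).
AA_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
AA_WATER <- 18.0153

# EMBOSS-style pKa values used by compute_pi(); declared once here.
PKA_TABLE <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

AA_ALPHABET <- names(AA_RESIDUE_MASS)

# P1-residue -> target protease class. The classic trypsin (R/K) and
# chymotrypsin (large hydrophobic) and elastase (small hydrophobic) sets,
# extended to F/W and G/S respectively by protease chemistry.
SPECIFICITY_MAP <- list(
  trypsin      = c("R", "K"),
  chymotrypsin = c("L", "I", "Y", "F", "W"),
  elastase     = c("A", "V", "M", "G", "S")
)

# Hinge consensus P17..P9 relative to the P17 anchor (offset 0). P13 is a
# wildcard and is not scored; eight positions carry residue constraints.
HINGE_CONSENSUS <- list(
  list(offset = 0L, allowed = "E",                 label = "P17"),
  list(offset = 1L, allowed = c("E", "K", "R"),    label = "P16"),
  list(offset = 2L, allowed = "G",                 label = "P15"),
  list(offset = 3L, allowed = c("T", "S"),         label = "P14"),
  list(offset = 5L, allowed = c("A", "G", "S"),    label = "P12"),
  list(offset = 6L, allowed = c("A", "G", "S"),    label = "P11"),
  list(offset = 7L, allowed = c("A", "G", "S"),    label = "P10"),
  list(offset = 8L, allowed = c("A", "G", "S"),    label = "P9")
)

# Offset from the P17 anchor to P1 (P17, P16, ..., P2, P1 spans 17 residues).
P1_OFFSET <- 16L

#' Codon state tables for the 61 sense codons of the universal code
#'
#' Built lazily from [Biostrings::GENETIC_CODE] and cached. Internal.
#'
#' @return list with `codons` (61 strings), `aa` (61 translations), `nt`
#'   (61x3 matrix of nucleotide indices 1-4 for A,C,G,T), and `pairs`, a
#'   matrix of single-nucleotide codon neighbours with columns i, j, pos,
#'   transition (0/1), synonymous (0/1).
#' @noRd
codon_tables <- function() {
  if (!is.null(.ss_cache$codon)) return(.ss_cache$codon)
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)[gc_tab != "*"]
  aa <- unname(gc_tab[codons])
  nts <- c("A", "C", "G", "T")
  nt <- t(vapply(strsplit(codons, ""), function(x) match(x, nts), integer(3)))
  purine <- c(TRUE, FALSE, TRUE, FALSE) # A, G are purines
  n <- length(codons)
  pr <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(nt[i, ] != nt[j, ])
      if (length(diff) != 1L) next
      ts <- purine[nt[i, diff]] == purine[nt[j, diff]]
      pr[[length(pr) + 1L]] <- c(i, j, diff, as.integer(ts),
                                 as.integer(aa[i] == aa[j]))
    }
  }
  pairs <- do.call(rbind, pr)
  colnames(pairs) <- c("i", "j", "pos", "transition", "synonymous")
  .ss_cache$codon <- list(codons = codons, aa = aa, nt = nt, pairs = pairs)
  .ss_cache$codon
}

# F3x4 codon frequencies from a 4 x 3 matrix of position-specific nucleotide
# frequencies (rows A,C,G,T), renormalised over the 61 sense codons.
f3x4_freqs <- function(ntfreq) {
  stopifnot(is.matrix(ntfreq), nrow(ntfreq) == 4L, ncol(ntfreq) == 3L)
  ct <- codon_tables()
  pi0 <- ntfreq[cbind(ct$nt[, 1], 1L)] *
    ntfreq[cbind(ct$nt[, 2], 2L)] *
    ntfreq[cbind(ct$nt[, 3], 3L)]
  pi0 / sum(pi0)
}

# Empirical F3x4 frequencies from a codon alignment (gap codons skipped).
empirical_f3x4 <- function(codon_rows) {
  ct <- codon_tables()
  counts <- matrix(1, 4, 3) # +1 pseudocount per cell
  for (row in codon_rows) {
    keep <- row != "---" & !is.na(row)
    if (!any(keep)) next
    m <- do.call(rbind, strsplit(row[keep], ""))
    for (p in 1:3) {
      tb <- table(factor(m[, p], levels = c("A", "C", "G", "T")))
      counts[, p] <- counts[, p] + as.numeric(tb)
    }
  }
  ntfreq <- sweep(counts, 2, colSums(counts), "/")
  f3x4_freqs(ntfreq)
}
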
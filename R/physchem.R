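#' Theoretical molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da), reported in
#' kDa (display rounding, e.g. to three decimals for family tables, is left
#' to the caller).
#'
#' @param seq Non-empty amino-acid string of standard residues.
#' @return Mass in kDa.
#' @examples
#' compute_mw("G") # 0.0750672 kDa
#' @export
compute_mw <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) ||
      nchar(seq) == 0L) {
    stop("sequence must be a non-empty amino-acid string")
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  }
  (sum(AA_RESIDUE_MASS[chars]) + AA_WATER) / 1000
}

#' Theoretical isoelectric point of a protein
#'
#' Net charge as a function of pH by Henderson-Hasselbalch over the termini
#' and the D, E, C, Y (acidic) and H, K, R (basic) side chains, with the
#' EMBOSS-style pKa table declared in the package constants; the pI is the
#' zero crossing found by bisection on pH 0-14.
#'
#' @param seq Non-empty amino-acid string.
#' @param tol Bisection tolerance in pH units; default 1e-3.
#' @return The pI.
#' @export
compute_pi <- function(seq, tol = 1e-3) {
  seq <- validate_aa_seq(seq)
  chars <- strsplit(seq, "")[[1]]
  npos <- table(factor(chars, levels = names(PKA_TABLE$positive)))
  nneg <- table(factor(chars, levels = names(PKA_TABLE$negative)))
  charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - PKA_TABLE$nterm)) +
      sum(npos / (1 + 10^(ph - PKA_TABLE$positive)))
    neg <- 1 / (1 + 10^(PKA_TABLE$cterm - ph)) +
      sum(nneg / (1 + 10^(PKA_TABLE$negative - ph)))
    pos - neg
  }
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
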
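#' Construct a codon alignment
#'
#' Rows of in-frame codons over the 61 sense codons of the universal code;
#' the gap codon `"---"` is allowed, stop codons are not.
#'
#' @param rows Named list/vector: either in-frame gapped DNA strings (length
#'   a multiple of 3) or character vectors of 3-letter codons.
#' @return Object of class `codon_alignment`: a character matrix of codons,
#'   one row per sequence.
#' @export
codon_alignment <- function(rows) {
  if (is.character(rows)) rows <- as.list(rows)
  if (is.null(names(rows)) || any(names(rows) == "")) {
    stop("codon alignment rows must be named")
  }
  if (anyDuplicated(names(rows))) stop("duplicate ids in codon alignment")
  split_row <- function(r) {
    if (length(r) == 1L && nchar(r[1]) > 3L) {
      if (nchar(r) %% 3L != 0L) {
        stop("row length ", nchar(r), " is not a multiple of 3")
      }
      r <- substring(r, seq(1, nchar(r), 3), seq(3, nchar(r), 3))
    }
    toupper(r)
  }
  rows <- lapply(rows, split_row)
  if (length(unique(lengths(rows))) != 1L) {
    stop("all rows must have the same number of codon sites")
  }
  m <- do.call(rbind, rows)
  ct <- codon_tables()
  bad <- setdiff(unique(as.vector(m)), c(ct$codons, "---"))
  if (length(bad)) {
    stop("non-sense codon(s) in alignment: ", paste(bad, collapse = ", "),
         " (stop codons and ambiguity codes are not allowed)")
  }
  structure(m, class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("Codon alignment: %d sequences x %d sites\n",
              nrow(x), ncol(x)))
  invisible(x)
}

# integer codon states 1..61 (NA = gap) for a codon_alignment
codon_states <- function(caln) {
  ct <- codon_tables()
  m <- matrix(match(as.vector(unclass(caln)), ct$codons),
              nrow = nrow(caln), dimnames = dimnames(caln))
  m
}

# translate one row of codons (gaps -> "-")
translate_codons <- function(codons) {
  ct <- codon_tables()
  aa <- ifelse(codons == "---", "-", ct$aa[match(codons, ct$codons)])
  paste(aa, collapse = "")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Threads each coding sequence through its gapped protein row: every gap
#' column becomes `"---"`, every residue becomes its source codon, order
#' preserved. A trailing stop codon on a CDS is stripped. Each CDS must
#' translate exactly to its ungapped protein row under the standard code.
#'
#' @param protein_aln Alignment as accepted by [as_alignment()].
#' @param cds Named character vector of coding DNA sequences (ids matching
#'   the alignment).
#' @return A [codon_alignment()].
#' @examples
#' back_translate(c(x = "M-K", y = "MLK"),
#'                c(x = "ATGAAA", y = "ATGCTGAAA"))
#' @export
back_translate <- function(protein_aln, cds) {
  protein_aln <- as_alignment(protein_aln)
  missing_ids <- setdiff(names(protein_aln), names(cds))
  if (length(missing_ids)) {
    stop("no CDS for: ", paste(missing_ids, collapse = ", "))
  }
  rows <- lapply(names(protein_aln), function(id) {
    prot <- gsub("-", "", protein_aln[[id]])
    dna <- toupper(cds[[id]])
    if (nchar(dna) %% 3L != 0L) {
      stop(id, ": CDS length is not a multiple of 3")
    }
    codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
    gc_tab <- Biostrings::GENETIC_CODE
    aa <- unname(gc_tab[codons])
    if (any(is.na(aa))) {
      stop(id, ": unrecognised codon at site ", which(is.na(aa))[1])
    }
    if (length(aa) == nchar(prot) + 1L && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (any(aa[-length(aa)] == "*")) {
      stop(id, ": internal stop codon at residue ",
           which(aa == "*")[1])
    }
    if (length(aa) != nchar(prot)) {
      stop(id, ": CDS encodes ", length(aa), " residues but protein row has ",
           nchar(prot))
    }
    if (any(aa == "*")) {
      stop(id, ": stop codon at residue ", which(aa == "*")[1])
    }
    pc <- strsplit(prot, "")[[1]]
    disc <- which(aa != pc)
    if (length(disc)) {
      stop(id, ": CDS translation mismatches protein at residue ", disc[1],
           " (", aa[disc[1]], " vs ", pc[disc[1]], ")")
    }
    out <- rep("---", nchar(protein_aln[[id]]))
    out[strsplit(protein_aln[[id]], "")[[1]] != "-"] <- codons
    out
  })
  names(rows) <- names(protein_aln)
  codon_alignment(rows)
}
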
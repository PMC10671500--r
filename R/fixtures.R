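# Packaged example data: the 26-serpin family table with synthetic stand-in
# sequences, and a synthetic dated 14-taxon species tree with gene counts.

#' The 26-serpin family fixture with synthetic sequences
#'
#' Loads the packaged serpin family metadata (id, length, chromosome, signal
#' peptide, phylogenetic group, predicted P1/P1' and target class) and
#' generates a synthetic stand-in sequence for every record, engineered so
#' that [annotate_records()] reproduces the tabulated P1/P1' residues and
#' inhibitory calls: inhibitory members carry a planted perfect hinge with
#' the tabulated P1/P1'; the four non-inhibitory members carry, as
#' tabulated, a degraded hinge (<= 3/8 consensus positions), a truncated
#' C-terminus (no room for an RCL), or a long-RCL insertion placing the
#' hinge > 60 residues from the tail. Sequences are deterministic in `seed`.
#'
#' @param seed Integer seed; default 9021.
#' @return Data frame with the metadata columns plus `sequence`.
#' @export
serpin_fixture <- function(seed = 9021L) {
  path <- system.file("extdata", "cpom_serpin_metadata_synthetic.tsv",
                      package = "serpinscape")
  meta <- read_serpin_metadata(path)
  with_seed(seed, {
    meta$sequence <- vapply(seq_len(nrow(meta)), function(i) {
      row <- meta[i, ]
      fixture_sequence(row$length, row$inhibitory == "yes", row$decoy_type,
                       row$p1, row$p1p)
    }, character(1))
  })
  meta
}

fixture_sequence <- function(L, inhibitory, decoy_type, p1, p1p,
                             min_score = 6L) {
  for (try in 1:100) {
    chars <- strsplit(sample_bg(L), "")[[1]]
    if (inhibitory) {
      a <- sample((L - 70L):(L - 30L), 1)
      chars <- plant_hinge(chars, a)
      chars[a + P1_OFFSET] <- p1
      chars[a + P1_OFFSET + 1L] <- p1p
      seq <- paste(chars, collapse = "")
      sc <- scan_hinge(seq)
      if (nrow(sc) > 0 && sc$p17_index[1] == a && sc$score[1] == 8L) {
        return(seq)
      }
    } else {
      if (decoy_type == "truncated") {
        a <- L - 8L
        chars <- plant_hinge(chars, a)
      } else if (decoy_type == "long_tail") {
        a <- L - 120L
        chars <- plant_hinge(chars, a)
      } else {
        a <- sample((L - 70L):(L - 30L), 1)
        chars <- plant_degraded_hinge(chars, a, keep = 3L)
      }
      seq <- paste(chars, collapse = "")
      sc <- scan_hinge(seq)
      if (nrow(sc) == 0 || sc$score[1] < min_score) return(seq)
    }
  }
  stop("could not engineer fixture sequence")
}

#' Synthetic dated 14-taxon species tree
#'
#' An ultrametric stand-in chronogram (branch times in My) for thirteen
#' Lepidoptera species plus a dipteran outgroup, shipped as
#' `extdata/species_tree_synthetic.nwk`.
#'
#' @return A `phylo` tree.
#' @export
example_species_tree <- function() {
  read_newick(system.file("extdata", "species_tree_synthetic.nwk",
                          package = "serpinscape"))
}

#' Serpin family sizes for the 14-taxon example tree
#'
#' Published counts where available, synthetic stand-ins elsewhere (see the
#' file header in `extdata/gene_counts_synthetic.tsv`).
#'
#' @return Named integer vector of per-species counts.
#' @export
example_gene_counts <- function() {
  read_gene_counts(system.file("extdata", "gene_counts_synthetic.tsv",
                               package = "serpinscape"))
}
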
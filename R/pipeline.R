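#' Run the serpin analysis pipeline
#'
#' Umbrella driver executing the enabled stages in order — `annotate`
#' (hinge/RCL annotation + family report), `tree` (NJ with bootstrap),
#' `kaks` (within-species paralog Ka/Ks), `sitetest` (M0/M3/M7/M8 + BEB),
#' `gainloss` (birth-death fit + ancestral counts), `express` (transform +
#' cluster) — writing TSV/Newick outputs and a log with the seed and a
#' config hash. Identical config + seed gives identical outputs.
#'
#' @param config Named list. Recognised entries: `proteins` (FASTA path),
#'   `metadata` (TSV path), `chromosome_set`, `alignment` (aligned FASTA),
#'   `bootstrap_reps`, `cds` (FASTA), `codon_tree` (Newick), `species_tree`
#'   (Newick), `gene_counts` (TSV), `expression` (TSV), `k_clusters`,
#'   `hinge_min_score`, `stages` (character vector naming enabled stages;
#'   default: every stage whose inputs are present).
#' @param out_dir Output directory (created).
#' @param seed Integer seed used for every stochastic stage.
#' @return Invisible list of per-stage results; files under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  stopifnot(is.list(config))
  known <- c("proteins", "metadata", "chromosome_set", "alignment",
             "bootstrap_reps", "cds", "codon_tree", "species_tree",
             "gene_counts", "expression", "k_clusters", "hinge_min_score",
             "stages")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  avail <- c(
    annotate = !is.null(config$proteins),
    tree = !is.null(config$alignment),
    kaks = !is.null(config$cds) && !is.null(config$metadata),
    gainloss = !is.null(config$species_tree) && !is.null(config$gene_counts),
    express = !is.null(config$expression)
  )
  stages <- config$stages %||% names(avail)[avail]
  results <- list()

  if ("annotate" %in% stages) {
    seqs <- read_fasta(config$proteins, type = "AA")
    records <- data.frame(id = names(seqs), sequence = unname(seqs))
    if (!is.null(config$metadata)) {
      meta <- read_serpin_metadata(config$metadata)
      records <- merge(records, meta, by = "id", sort = FALSE)
    }
    ann <- annotate_records(records,
                            min_score = config$hinge_min_score %||% 6L)
    write_tsv(ann[, setdiff(names(ann), "sequence")],
              file.path(out_dir, "annotation.tsv"))
    rep <- summarize_family(ann,
                            chromosome_set = config$chromosome_set %||%
                              character())
    rep_df <- data.frame(
      metric = c("n_records", "n_inhibitory", "n_noninhibitory",
                 "n_signal_peptide", "n_chromosomes",
                 "pct_on_chromosome_set"),
      value = c(rep$n_records, rep$n_inhibitory, rep$n_noninhibitory,
                rep$n_signal_peptide, rep$n_chromosomes,
                rep$pct_on_chromosome_set)
    )
    write_tsv(rep_df, file.path(out_dir, "family_report.tsv"))
    results$annotate <- list(annotation = ann, report = rep)
  }

  if ("tree" %in% stages) {
    aln <- as_alignment(read_fasta(config$alignment, type = "AA"))
    tr <- bootstrap_support(aln, reps = config$bootstrap_reps %||% 100L,
                            seed = seed)
    write_newick(tr, file.path(out_dir, "nj_tree.nwk"))
    results$tree <- tr
  }

  if ("kaks" %in% stages) {
    cds <- read_fasta(config$cds, type = "DNA")
    meta <- read_serpin_metadata(config$metadata)
    pairs <- pair_paralogs(meta)
    rows <- lapply(seq_len(nrow(pairs)), function(r) {
      p1 <- pairs$id1[r]; p2 <- pairs$id2[r]
      prot <- vapply(c(p1, p2), function(id) {
        as.character(Biostrings::translate(Biostrings::DNAString(cds[[id]]),
                                           no.init.codon = TRUE))
      }, character(1))
      prot <- sub("\\*$", "", prot)
      ga <- global_align(prot[1], prot[2])
      caln <- back_translate(setNames(c(ga$aligned_a, ga$aligned_b),
                                      c(p1, p2)), cds)
      kk <- estimate_kaks(caln)
      data.frame(species = pairs$species[r], id1 = p1, id2 = p2,
                 ka = kk$ka, ks = kk$ks, ratio = kk$ratio)
    })
    kaks_df <- do.call(rbind, rows)
    write_tsv(kaks_df, file.path(out_dir, "kaks.tsv"))
    results$kaks <- kaks_df
  }

  if ("gainloss" %in% stages) {
    tree <- read_newick(config$species_tree)
    counts <- read_gene_counts(config$gene_counts)
    fit <- fit_lambda(tree, counts)
    anc <- ancestral_counts(tree, counts, fit$lambda)
    tr <- anc$tree
    ntip <- length(tr$tip.label)
    tr$node.label <- as.character(anc$node_counts[(ntip + 1):length(
      anc$node_counts)])
    write_newick(tr, file.path(out_dir, "gainloss_tree.nwk"))
    write_tsv(anc$deltas, file.path(out_dir, "gainloss_branches.tsv"))
    results$gainloss <- list(fit = fit, ancestral = anc)
  }

  if ("express" %in% stages) {
    m <- read_expression(config$expression)
    tm <- transform_fpkm(m)
    k <- config$k_clusters %||% 4L
    grp <- cluster_genes(tm, k = k)
    write_tsv(data.frame(gene = names(grp), group = grp),
              file.path(out_dir, "expression_groups.tsv"))
    write_tsv(cbind(gene = rownames(tm), as.data.frame(tm)),
              file.path(out_dir, "expression_log2.tsv"))
    results$express <- grp
  }

  if (!length(results)) {
    warning("no stages enabled; empty report written to ", out_dir)
  }
  cfg_hash <- sum(utf8ToInt(paste(deparse(config), collapse = "")))
  writeLines(c(
    paste("serpinscape", as.character(utils::packageVersion("serpinscape"))),
    paste("seed", seed),
    paste("config_hash", cfg_hash),
    paste("stages", paste(names(results), collapse = ","))
  ), file.path(out_dir, "run_log.txt"))
  invisible(results)
}
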
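#' Build a gene model with one mutually exclusive exon slot
#'
#' Serpin genes can diversify their RCL by mutually exclusive alternative
#' splicing: a set of shared exons plus several variants of one exon (the
#' RCL-encoding exon), exactly one of which is used per transcript.
#'
#' @param exons Data frame with columns `exon_index` (1-based position of the
#'   exon in the transcript), `variant_flag` (logical; `TRUE` rows are the
#'   alternatives at the exclusive slot), `sequence` (DNA), and optionally
#'   `variant_id` labels for the variant rows.
#' @param gene_id Optional gene label.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(exons, gene_id = "gene") {
  stopifnot(is.data.frame(exons),
            all(c("exon_index", "variant_flag", "sequence") %in% names(exons)))
  exons$sequence <- toupper(exons$sequence)
  bad <- setdiff(unique(unlist(strsplit(exons$sequence, ""))),
                 c("A", "C", "G", "T"))
  if (length(bad)) stop("non-DNA characters in exon sequences: ",
                        paste(bad, collapse = ", "))
  var <- exons[exons$variant_flag, , drop = FALSE]
  shared <- exons[!exons$variant_flag, , drop = FALSE]
  if (nrow(var) < 1L) stop("gene model needs at least one variant exon")
  slot <- unique(var$exon_index)
  if (length(slot) != 1L) {
    stop("all variant exons must share one exon_index (the exclusive slot)")
  }
  all_idx <- sort(c(shared$exon_index, slot))
  if (anyDuplicated(all_idx) ||
      !identical(all_idx, seq_along(all_idx))) {
    stop("exon indices must form a contiguous 1..n series with the variant ",
         "slot inside it")
  }
  if (is.null(var$variant_id) || all(is.na(var$variant_id))) {
    var$variant_id <- LETTERS[seq_len(nrow(var))]
  }
  structure(
    list(gene_id = gene_id,
         shared = shared[order(shared$exon_index), , drop = FALSE],
         variants = var, slot = slot),
    class = "gene_model"
  )
}

#' Assemble isoforms from a mutually exclusive exon model
#'
#' Produces one isoform per variant exon: shared prefix exons + variant +
#' shared suffix exons. When `translate = TRUE` each cDNA is translated
#' (standard code, trailing stop stripped) and annotated with
#' [annotate_rcl()] so isoforms can differ in P1 and specificity.
#'
#' @param model A [gene_model()].
#' @param translate Translate and RCL-annotate each isoform? Default `TRUE`.
#' @param ... Passed to [annotate_rcl()].
#' @return Data frame with one row per isoform: `isoform_id`, `cdna_length`,
#'   `cdna`, and when translated `protein`, `p1_residue`, `specificity`,
#'   `inhibitory`.
#' @export
assemble_isoforms <- function(model, translate = TRUE, ...) {
  stopifnot(inherits(model, "gene_model"))
  pre <- model$shared$sequence[model$shared$exon_index < model$slot]
  post <- model$shared$sequence[model$shared$exon_index > model$slot]
  out <- lapply(seq_len(nrow(model$variants)), function(i) {
    v <- model$variants[i, ]
    cdna <- paste0(paste(pre, collapse = ""), v$sequence,
                   paste(post, collapse = ""))
    row <- data.frame(
      isoform_id = paste0(model$gene_id, v$variant_id),
      cdna_length = nchar(cdna), cdna = cdna
    )
    if (translate) {
      if (nchar(cdna) %% 3L != 0L) {
        stop("isoform ", row$isoform_id, ": cDNA length ", nchar(cdna),
             " is not a multiple of 3 (phase error)")
      }
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(cdna), no.init.codon = TRUE
      ))
      prot <- sub("\\*$", "", prot)
      if (grepl("\\*", prot)) {
        stop("isoform ", row$isoform_id, ": internal stop codon")
      }
      ann <- annotate_rcl(list(id = row$isoform_id, sequence = prot), ...)
      row$protein <- prot
      row$p1_residue <- ann$p1_residue
      row$specificity <- ann$specificity
      row$inhibitory <- ann$inhibitory
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
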
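#' Scan a serpin sequence for hinge-consensus matches
#'
#' Slides the inhibitory-serpin hinge consensus
#' `P17[E]-P16[E/K/R]-P15[G]-P14[T/S]-P13[X]-P12..P9[A/G/S]` along the
#' C-terminal region of a protein and scores every candidate P17 anchor
#' against the eight constrained positions (P13 is a wildcard).
#'
#' The search window restricts the P17 anchor to `[L - 75, L - 25]`
#' (`L` = sequence length): the RCL sits near the carboxyl terminus of the
#' conserved serpin fold, and typical serpins run 350-500 residues. The window
#' is further clipped so the full P17..P1' stretch fits inside the sequence.
#'
#' @param seq Amino-acid string (single-letter codes; `X` tolerated, never
#'   matching a constrained position).
#' @param window Integer length-2 vector: offsets of the anchor window from
#'   the C-terminus, default `c(75, 25)` meaning `[L - 75, L - 25]`.
#' @return A data frame of candidate anchors with score >= 1, one row per
#'   anchor, columns `p17_index` (1-based), `score` (0-8) and logical columns
#'   `P17`, `P16`, `P15`, `P14`, `P12`, `P11`, `P10`, `P9`; sorted by score
#'   (decreasing) then `p17_index` (decreasing, i.e. C-terminal-most first).
#'   Zero rows when no anchor scores at least 1.
#' @examples
#' seq <- paste0(strrep("M", 330), "EEGTEAAAA", strrep("L", 26), "KS")
#' scan_hinge(seq)[1, c("p17_index", "score")]
#' @export
scan_hinge <- function(seq, window = c(75L, 25L)) {
  seq <- validate_aa_seq(seq)
  L <- nchar(seq)
  if (L < 40L) {
    stop("sequence of length ", L, " is too short to carry an RCL")
  }
  chars <- strsplit(seq, "")[[1]]
  lo <- max(1L, L - as.integer(window[1]))
  hi <- min(L - 17L, L - as.integer(window[2]))
  if (hi < lo) {
    return(empty_hinge_frame())
  }
  anchors <- lo:hi
  hits <- vapply(HINGE_CONSENSUS, function(cons) {
    chars[anchors + cons$offset] %in% cons$allowed
  }, logical(length(anchors)))
  hits <- matrix(hits, nrow = length(anchors))
  colnames(hits) <- vapply(HINGE_CONSENSUS, `[[`, "", "label")
  score <- rowSums(hits)
  keep <- score >= 1
  out <- data.frame(p17_index = anchors[keep], score = as.integer(score[keep]))
  out <- cbind(out, as.data.frame(hits[keep, , drop = FALSE]))
  rownames(out) <- NULL
  out[order(-out$score, -out$p17_index), , drop = FALSE]
}

empty_hinge_frame <- function() {
  out <- data.frame(p17_index = integer(), score = integer())
  for (cons in HINGE_CONSENSUS) out[[cons$label]] <- logical()
  out
}

#' Classify target-protease specificity from the P1 residue
#'
#' Arg/Lys at P1 mark trypsin inhibitors; large hydrophobics
#' (Leu/Ile/Tyr/Phe/Trp) chymotrypsin; small hydrophobics
#' (Ala/Val/Met/Gly/Ser) elastase. Any other residue gives `"none"`.
#'
#' @param p1_residue Single standard amino-acid letter.
#' @return One of `"trypsin"`, `"chymotrypsin"`, `"elastase"`, `"none"`.
#' @examples
#' classify_specificity("K") # trypsin
#' classify_specificity("Y") # chymotrypsin
#' @export
classify_specificity <- function(p1_residue) {
  if (length(p1_residue) != 1L || !is.character(p1_residue) ||
      nchar(p1_residue) != 1L || !(p1_residue %in% c(AA_ALPHABET, "X"))) {
    stop("invalid residue: ", deparse(p1_residue))
  }
  for (cls in names(SPECIFICITY_MAP)) {
    if (p1_residue %in% SPECIFICITY_MAP[[cls]]) return(cls)
  }
  "none"
}

#' Annotate the RCL of one serpin record
#'
#' Takes the best [scan_hinge()] match as the hinge, places P1 at
#' `p17_index + 16` and P1' immediately after, and calls the record
#' inhibitory when (i) the hinge scores at least `min_score` of 8, (ii) a P1'
#' residue exists, and (iii) the P1-to-C-terminus tail is no longer than
#' `max_tail` residues (long-RCL insertions, as in degenerate serpins with
#' ~40 extra loop residues, disqualify inhibition). Non-inhibitory records
#' get specificity `"none"`.
#'
#' @param record A list or one-row data frame with at least `id` and
#'   `sequence`; a bare string is also accepted.
#' @param min_score Minimum hinge score (of 8) for an inhibitory call;
#'   default 6.
#' @param max_tail Maximum number of residues from P1 (inclusive) to the
#'   C-terminus; default 60.
#' @param window Passed to [scan_hinge()].
#' @return An object of class `rcl_annotation`: list with `id`, `hinge` (one
#'   row of the scan, or `NULL`), `p1_index`, `p1p_index`, `p1_residue`,
#'   `p1p_residue` (NA when absent), `inhibitory`, `specificity`.
#' @export
annotate_rcl <- function(record, min_score = 6L, max_tail = 60L,
                         window = c(75L, 25L)) {
  if (is.character(record) && length(record) == 1L) {
    record <- list(id = NA_character_, sequence = record)
  }
  seq <- validate_aa_seq(record$sequence)
  L <- nchar(seq)
  ann <- structure(
    list(id = record$id, hinge = NULL,
         p1_index = NA_integer_, p1p_index = NA_integer_,
         p1_residue = NA_character_, p1p_residue = NA_character_,
         inhibitory = FALSE, specificity = "none"),
    class = "rcl_annotation"
  )
  matches <- scan_hinge(seq, window = window)
  if (nrow(matches) == 0L) return(ann)
  best <- matches[1L, , drop = FALSE]
  ann$hinge <- best
  p1 <- best$p17_index + P1_OFFSET
  if (p1 <= L) {
    ann$p1_index <- as.integer(p1)
    ann$p1_residue <- substr(seq, p1, p1)
    if (p1 + 1L <= L) {
      ann$p1p_index <- as.integer(p1 + 1L)
      ann$p1p_residue <- substr(seq, p1 + 1L, p1 + 1L)
    }
  }
  tail_len <- L - p1 + 1L
  if (best$score >= min_score && !is.na(ann$p1p_index) &&
      tail_len <= max_tail) {
    spec <- classify_specificity(ann$p1_residue)
    if (spec != "none") {
      ann$inhibitory <- TRUE
      ann$specificity <- spec
    }
  }
  ann
}

#' @export
print.rcl_annotation <- function(x, ...) {
  cat("RCL annotation", if (!is.na(x$id)) paste0("for ", x$id), "\n")
  if (is.null(x$hinge)) {
    cat("  no hinge-consensus match in the search window\n")
  } else {
    cat(sprintf("  hinge P17 at %d, score %d/8\n",
                x$hinge$p17_index, x$hinge$score))
    cat(sprintf("  P1/P1': %s%s/%s%s\n", x$p1_residue,
                ifelse(is.na(x$p1_index), "", x$p1_index),
                ifelse(is.na(x$p1p_residue), "-", x$p1p_residue),
                ifelse(is.na(x$p1p_index), "", x$p1p_index)))
  }
  cat(sprintf("  inhibitory: %s (%s)\n", x$inhibitory, x$specificity))
  invisible(x)
}

#' Annotate a table of serpin records
#'
#' Vectorised [annotate_rcl()] over a record table, mirroring the columns of
#' a family annotation report (id, P1/P1', target class T/C/E, inhibitory
#' Y/N).
#'
#' @param records Data frame with columns `id` and `sequence`; optional
#'   `species`, `chromosome`, `signal_peptide`, `gene_group` are carried
#'   through.
#' @param ... Passed to [annotate_rcl()].
#' @return Data frame with one row per record: carried metadata plus
#'   `hinge_index`, `hinge_score`, `p1_index`, `p1_residue`, `p1p_residue`,
#'   `specificity`, `target_class` (T/C/E or "-"), `inhibitory`.
#' @export
annotate_records <- function(records, ...) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  anns <- lapply(seq_len(nrow(records)), function(i) {
    annotate_rcl(as.list(records[i, ]), ...)
  })
  meta_cols <- intersect(
    c("id", "species", "chromosome", "signal_peptide", "gene_group"),
    names(records)
  )
  cls_code <- c(trypsin = "T", chymotrypsin = "C", elastase = "E",
                none = "-")
  out <- cbind(
    records[, meta_cols, drop = FALSE],
    data.frame(
      length = nchar(records$sequence),
      hinge_index = vapply(anns, function(a)
        if (is.null(a$hinge)) NA_integer_ else a$hinge$p17_index, integer(1)),
      hinge_score = vapply(anns, function(a)
        if (is.null(a$hinge)) NA_integer_ else a$hinge$score, integer(1)),
      p1_index = vapply(anns, `[[`, integer(1), "p1_index"),
      p1_residue = vapply(anns, `[[`, character(1), "p1_residue"),
      p1p_residue = vapply(anns, `[[`, character(1), "p1p_residue"),
      specificity = vapply(anns, `[[`, character(1), "specificity"),
      inhibitory = vapply(anns, `[[`, logical(1), "inhibitory")
    )
  )
  out$target_class <- unname(cls_code[out$specificity])
  rownames(out) <- NULL
  out
}

#' Summarise an annotated serpin family
#'
#' Tallies inhibitory/non-inhibitory members, signal peptides, chromosome
#' occupancy and phylogenetic groups, and reports the percentage of the
#' family carried by a caller-supplied chromosome set (e.g. the five major
#' serpin-bearing chromosomes).
#'
#' @param records Data frame as returned by [annotate_records()]; the
#'   `inhibitory` column is required, `chromosome` / `signal_peptide` /
#'   `gene_group` are used when present.
#' @param chromosome_set Character vector of chromosome labels for the
#'   percentage; default none.
#' @return An object of class `family_report`: list with `n_records`,
#'   `n_inhibitory`, `n_noninhibitory`, `n_signal_peptide`, `chromosomes`
#'   (named count vector), `n_chromosomes`, `pct_on_chromosome_set` (rounded
#'   to 2 decimals), `group_counts`.
#' @export
summarize_family <- function(records, chromosome_set = character()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no records to summarise")
  stopifnot("inhibitory" %in% names(records))
  n <- nrow(records)
  rep <- list(
    n_records = n,
    n_inhibitory = sum(records$inhibitory),
    n_noninhibitory = sum(!records$inhibitory),
    n_signal_peptide = NA_integer_,
    chromosomes = NULL, n_chromosomes = NA_integer_,
    pct_on_chromosome_set = NA_real_,
    group_counts = NULL
  )
  if ("signal_peptide" %in% names(records)) {
    sp <- records$signal_peptide
    rep$n_signal_peptide <- sum(!is.na(sp) & sp != "" & toupper(sp) != "NO")
  }
  if ("chromosome" %in% names(records)) {
    chr <- records$chromosome[!is.na(records$chromosome) &
                                records$chromosome != ""]
    tab <- table(chr)
    rep$chromosomes <- setNames(as.integer(tab), names(tab))
    rep$n_chromosomes <- length(tab)
    if (length(chromosome_set)) {
      rep$pct_on_chromosome_set <-
        round(100 * sum(records$chromosome %in% chromosome_set) / n, 2)
    }
  }
  if ("gene_group" %in% names(records)) {
    gg <- records$gene_group[!is.na(records$gene_group) &
                               records$gene_group != ""]
    tab <- table(gg)
    rep$group_counts <- setNames(as.integer(tab), names(tab))
  }
  structure(rep, class = "family_report")
}

#' @export
print.family_report <- function(x, ...) {
  cat(sprintf("Serpin family report: %d records\n", x$n_records))
  cat(sprintf("  inhibitory %d / non-inhibitory %d\n",
              x$n_inhibitory, x$n_noninhibitory))
  if (!is.na(x$n_signal_peptide)) {
    cat(sprintf("  with signal peptide: %d\n", x$n_signal_peptide))
  }
  if (!is.null(x$chromosomes)) {
    cat(sprintf("  on %d chromosomes: %s\n", x$n_chromosomes,
                paste(names(x$chromosomes), x$chromosomes,
                      sep = ":", collapse = " ")))
  }
  if (!is.na(x$pct_on_chromosome_set)) {
    cat(sprintf("  %.2f%% on the requested chromosome set\n",
                x$pct_on_chromosome_set))
  }
  if (!is.null(x$group_counts)) {
    cat(sprintf("  groups: %s\n",
                paste(names(x$group_counts), x$group_counts,
                      sep = ":", collapse = " ")))
  }
  invisible(x)
}

validate_aa_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) ||
      nchar(seq) == 0L) {
    stop("sequence must be a non-empty amino-acid string")
  }
  seq <- toupper(seq)
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c(AA_ALPHABET, "X"))
  if (length(bad)) {
    stop("illegal residue(s) in sequence: ", paste(bad, collapse = ", "))
  }
  seq
}
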
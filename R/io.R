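# Readers/writers for FASTA, Newick and the package's TSV dialects.

#' Read a FASTA file
#'
#' Order-preserving, wrap-agnostic parse via Biostrings; duplicate ids and
#' illegal characters are rejected.
#'
#' @param path Readable FASTA file.
#' @param type `"AA"` (default) or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  legal <- if (type == "AA") c(AA_ALPHABET, "X", "-", "*") else
    c("A", "C", "G", "T", "N", "-")
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), legal)
  if (length(bad)) {
    stop("illegal character(s) for ", type, " FASTA: ",
         paste(bad, collapse = ", "))
  }
  setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width; default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' Parses branch lengths and internal labels via [ape::read.tree()], after a
#' structural pre-check that reports the byte offset of the first unbalanced
#' parenthesis or a missing trailing semicolon.
#'
#' @param path Readable Newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt_trim <- trimws(txt)
  if (!nzchar(txt_trim)) stop("empty Newick file: ", path)
  depth <- 0L
  chars <- strsplit(txt_trim, "")[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("unbalanced ')' at offset ", k, " in ", path)
    }
  }
  if (depth != 0L) {
    stop("unbalanced '(' (", depth, " unclosed) in ", path)
  }
  if (!endsWith(txt_trim, ";")) {
    stop("missing trailing semicolon at offset ", nchar(txt_trim), " in ",
         path)
  }
  tr <- tryCatch(ape::read.tree(text = txt_trim),
                 error = function(e) NULL)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  tr
}

#' Write a tree to Newick
#'
#' @param tree `phylo` tree (node labels, e.g. bootstrap supports, are
#'   preserved).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a serpin metadata table
#'
#' TSV with columns `id`, `species`, `chromosome`, `signal_peptide`,
#' `gene_group` (extra columns pass through). `signal_peptide` uses the
#' `"1-18"` / `"NO"` convention.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_serpin_metadata <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#", check.names = FALSE)
  need <- c("id")
  if (!all(need %in% names(df))) {
    stop("metadata must have an 'id' column")
  }
  if (anyDuplicated(df$id)) stop("duplicate ids in metadata")
  df
}

#' Read a gene-count table (species x one family, or several families)
#'
#' @param path TSV with a `species` column and one or more count columns.
#' @return Named integer vector (single count column) or data frame.
#' @export
read_gene_counts <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (!"species" %in% names(df)) stop("counts TSV needs a 'species' column")
  cnt <- setdiff(names(df), "species")
  if (length(cnt) == 1L) {
    setNames(as.integer(df[[cnt]]), df$species)
  } else {
    df
  }
}

#' Read an expression matrix (genes x samples TSV)
#'
#' @param path TSV with gene ids in the first column and a header row of
#'   sample codes.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, row.names = 1)
  as.matrix(df)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
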
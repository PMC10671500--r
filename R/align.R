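#' Validate a protein alignment
#'
#' An alignment is a named character vector of equal-length gapped rows
#' (gap character `-`), at least two rows, unique ids.
#'
#' @param x Named character vector (or list) of aligned sequences.
#' @return The validated named character vector.
#' @export
as_alignment <- function(x) {
  x <- unlist(x)
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("alignment rows must be named")
  }
  if (anyDuplicated(names(x))) stop("duplicate sequence ids in alignment")
  if (length(x) < 2L) stop("alignment needs at least two rows")
  if (length(unique(nchar(x))) != 1L) {
    stop("alignment rows must have equal length")
  }
  toupper(x)
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Pairwise distances under p- or Poisson-corrected models
#'
#' For each pair of rows, gapped positions are removed pairwise (pairwise
#' deletion); `p` is the proportion of mismatching shared columns, and the
#' Poisson-corrected distance is `d = -ln(1 - p)`, the expected number of
#' substitutions per site when changes accumulate as a Poisson process.
#'
#' @param aln Alignment as accepted by [as_alignment()].
#' @param model `"poisson"` (default) or `"p"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @examples
#' pairwise_distance(c(a = "AAAA", b = "AAAC"), model = "p")
#' @export
pairwise_distance <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  aln <- as_alignment(aln)
  m <- aln_matrix(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      ns <- sum(shared)
      if (ns == 0L) {
        stop("sequences ", rownames(m)[i], " and ", rownames(m)[j],
             " share no ungapped columns")
      }
      p <- sum(m[i, shared] != m[j, shared]) / ns
      if (model == "poisson") {
        if (p >= 1) {
          stop("pairwise p = 1 between ", rownames(m)[i], " and ",
               rownames(m)[j], ": Poisson correction saturates")
        }
        D[i, j] <- D[j, i] <- -log(1 - p)
      } else {
        D[i, j] <- D[j, i] <- p
      }
    }
  }
  D
}

#' Needleman-Wunsch global alignment of two protein sequences
#'
#' Wraps [Biostrings::pairwiseAlignment()] with a substitution matrix and
#' affine gap penalties, and reports percent identity with alignment columns
#' (gaps included) as the denominator — the most conservative of the common
#' identity conventions; identity against the shorter sequence or against
#' ungapped columns would read higher.
#'
#' @param a,b Amino-acid strings.
#' @param substitution Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_opening,gap_extension Penalties (positive numbers), defaults
#'   10 and 0.5.
#' @return List with `aligned_a`, `aligned_b` (gapped strings), `score`,
#'   `identity` (percent, 2 decimals).
#' @export
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_opening = 10, gap_extension = 0.5) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L ||
      length(b) != 1L || is.na(a) || is.na(b) ||
      nchar(a) == 0L || nchar(b) == 0L) {
    stop("both sequences must be non-empty strings")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    substitutionMatrix = substitution, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global"
  )
  sa <- as.character(Biostrings::alignedPattern(pa))
  sb <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  ident <- round(100 * sum(ca == cb & ca != "-") / length(ca), 2)
  list(aligned_a = sa, aligned_b = sb,
       score = Biostrings::score(pa), identity = ident)
}
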
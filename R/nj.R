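#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]. On an additive matrix the
#' generating topology and branch lengths are recovered exactly. Negative
#' estimated branch lengths (a known NJ artefact on noisy matrices) are
#' clamped to zero; when that happens the returned tree carries the attribute
#' `clamped = TRUE`.
#'
#' @param D Symmetric distance matrix with unique dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix must carry taxon names")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(D))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Bootstrap support for a neighbor-joining protein tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree under
#' the same distance model for each replicate, and scores every internal
#' bipartition of the full-data tree by the percentage of replicate trees
#' containing it.
#'
#' @param aln Alignment as accepted by [as_alignment()].
#' @param reps Number of replicates (>= 1); 1000 is the conventional choice.
#' @param seed Integer seed; identical seed and reps give bit-identical
#'   supports.
#' @param model Distance model, see [pairwise_distance()].
#' @return The full-data NJ tree (`phylo`) with `node.label` holding support
#'   percentages for internal nodes (root label empty).
#' @export
bootstrap_support <- function(aln, reps, seed = 1L,
                              model = c("poisson", "p")) {
  model <- match.arg(model)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1) {
    stop("reps must be a positive integer")
  }
  reps <- as.integer(reps)
  aln <- as_alignment(aln)
  m <- aln_matrix(aln)
  full <- neighbor_joining(pairwise_distance(aln, model = model))
  boot <- with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rows <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
      neighbor_joining(pairwise_distance(rows, model = model))
    })
  })
  class(boot) <- "multiPhylo"
  counts <- ape::prop.clades(full, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- round(100 * counts / reps, 1)
  full$node.label <- as.character(supports)
  full$node.label[1] <- "" # root of the unrooted representation
  full
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
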
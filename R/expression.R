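#' Log2(FPKM + 1) transform of an expression matrix
#'
#' @param m Numeric matrix (genes x samples) of non-negative FPKM values.
#' @return Matrix of the same shape, `log2(x + 1)`.
#' @export
transform_fpkm <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("expression matrix has missing cells")
  if (any(m < 0)) stop("negative FPKM value(s)")
  log2(m + 1)
}

#' Cluster gene expression profiles into subgroups
#'
#' Agglomerative (average-linkage) clustering of transformed expression
#' rows, cut at `k` groups. Distances are either `1 - Pearson` correlation
#' between gene profiles (shape-based; the default and the usual choice for
#' heatmap subgrouping) or euclidean. Group labels are renumbered by
#' decreasing cluster mean expression, so group 1 is always the
#' highest-expressed subgroup; the assignment is deterministic in the
#' inputs and invariant to gene row order.
#'
#' @param m Transformed (e.g. [transform_fpkm()]) genes x samples matrix
#'   with gene rownames.
#' @param k Number of groups (1..nrow).
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage Agglomeration method; only `"average"` is offered.
#' @return Named integer vector of group labels (1..k) per gene.
#' @export
cluster_genes <- function(m, k, distance = c("pearson", "euclidean"),
                          linkage = "average") {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage, "average")
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("gene rownames required")
  if (k < 1 || k > nrow(m)) {
    stop("k must be between 1 and the number of genes")
  }
  ord <- order(rownames(m)) # row-order invariance
  ms <- m[ord, , drop = FALSE]
  if (k == 1) {
    return(setNames(rep(1L, nrow(m)), rownames(m))[rownames(m)])
  }
  d <- if (distance == "pearson") {
    cc <- suppressWarnings(cor(t(ms)))
    cc[!is.finite(cc)] <- 0 # constant rows: no shape information
    as.dist(1 - cc)
  } else {
    stats::dist(ms)
  }
  hc <- hclust(d, method = linkage)
  grp <- cutree(hc, k = k)
  # renumber by decreasing cluster mean expression
  mu <- tapply(rowMeans(ms), grp, mean)
  ranks <- rank(-mu, ties.method = "first")
  grp <- setNames(as.integer(ranks[as.character(grp)]), rownames(ms))
  grp[rownames(m)]
}
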
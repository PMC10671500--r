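# Birth-death model of gene-family size evolution on a dated species tree.
#
# The critical linear birth-death process (equal per-gene gain and loss rate
# lambda, in events per gene per million years) gives the probability that a
# parent with i genes leaves j descendants after branch time t in closed
# form, with alpha = lambda * t / (1 + lambda * t):
#
#   P(i -> j) = sum_m C(i, m) C(i + j - m - 1, i - 1)
#                 alpha^(i + j - 2m) (1 - 2 alpha)^m
#
# Family likelihoods come from pruning over integer states 0..max_count with
# a uniform root prior on [1, 2 * max leaf count]; ancestral counts are
# max-marginal-posterior states from an up-down pass.

#' Birth-death transition probability for a gene family
#'
#' @param i Parent count (>= 0).
#' @param j Child count (>= 0).
#' @param lambda Per-gene gain/loss rate (events per gene per My), >= 0.
#' @param t Branch time (My), >= 0.
#' @return `P(i -> j)` after time `t` under the critical birth-death process.
#' @examples
#' bd_transition_prob(2, 2, lambda = 0.001, t = 50)
#' @export
bd_transition_prob <- function(i, j, lambda, t) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (t < 0) stop("branch time must be >= 0")
  stopifnot(i >= 0, j >= 0)
  if (lambda * t == 0) return(as.numeric(i == j))
  if (i == 0) return(as.numeric(j == 0))
  alpha <- lambda * t / (1 + lambda * t)
  m <- 0:min(i, j)
  terms <- lchoose(i, m) + lchoose(i + j - m - 1, i - 1) +
    (i + j - 2 * m) * log(alpha) + m * log1p(-2 * alpha)
  # log1p(-2 alpha) is NaN when alpha > 1/2; fall back to signed summation
  if (alpha <= 0.5) {
    sum(exp(terms))
  } else {
    sum(choose(i, m) * choose(i + j - m - 1, i - 1) *
          alpha^(i + j - 2 * m) * (1 - 2 * alpha)^m)
  }
}

# full (max_count+1) x (max_count+1) transition matrix for one branch,
# states 0..max_count. For lambda*t <= 0.8 the closed-form series has only
# non-negative terms and is summed directly; longer branches are handled by
# scaling-and-squaring (closed form at t/2^k, then k matrix squarings),
# which keeps every entry non-negative — the alternating series at
# alpha > 1/2 cancels catastrophically in floating point.
bd_matrix <- function(lambda, t, max_count) {
  n <- max_count + 1L
  P <- matrix(0, n, n)
  if (lambda * t == 0) {
    diag(P) <- 1
    return(P)
  }
  if (lambda * t > 0.8) {
    k <- ceiling(log2(lambda * t / 0.8))
    P <- bd_matrix(lambda, t / 2^k, max_count)
    for (s in seq_len(k)) P <- P %*% P
    return(P)
  }
  alpha <- lambda * t / (1 + lambda * t)
  P[1, 1] <- 1 # zero genes is absorbing
  js <- 0:max_count
  one_m_two_a <- 1 - 2 * alpha
  la2 <- max(log(abs(one_m_two_a)), -745) # avoid 0 * -Inf at alpha = 1/2
  for (i in 1:max_count) {
    m <- 0:i
    J <- matrix(js, length(m), n, byrow = TRUE)
    M <- matrix(m, length(m), n)
    logterm <- lchoose(i, M) + lchoose(i + J - M - 1, i - 1) +
      (i + J - 2 * M) * log(alpha) + M * la2
    sgn <- if (one_m_two_a >= 0) 1 else (-1)^M
    logterm[M > J] <- -Inf
    row <- colSums(exp(logterm) * sgn)
    row[row < 0] <- 0
    P[i + 1L, ] <- row
  }
  P
}

check_dated_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree must carry non-negative branch times")
  }
  tree
}

check_counts <- function(tree, counts) {
  if (is.data.frame(counts)) counts <- setNames(counts$count, counts$species)
  miss <- setdiff(tree$tip.label, names(counts))
  if (length(miss)) {
    stop("missing leaf count(s) for: ", paste(miss, collapse = ", "))
  }
  counts <- counts[tree$tip.label]
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  as.integer(counts)
}

# transition matrices per edge, memoised on (lambda, t, max_count)
bd_edge_mats <- function(tree, lambda, max_count) {
  ts <- tree$edge.length
  uniq <- unique(ts)
  mats <- lapply(uniq, function(t) {
    key <- paste0("bd_", signif(lambda, 12), "_", signif(t, 12), "_",
                  max_count)
    if (is.null(.ss_cache[[key]])) {
      if (length(ls(.ss_cache, pattern = "^bd_")) > 400) {
        rm(list = ls(.ss_cache, pattern = "^bd_"), envir = .ss_cache)
      }
      .ss_cache[[key]] <- bd_matrix(lambda, t, max_count)
    }
    .ss_cache[[key]]
  })
  mats[match(ts, uniq)]
}

#' Log-likelihood of gene counts under the birth-death model
#'
#' Felsenstein pruning over integer family sizes 0..`max_count` on a dated
#' (ultrametric, branch times in My) species tree, with a uniform root prior
#' on `[1, 2 * max(leaf count)]`.
#'
#' @param tree Dated `phylo` tree.
#' @param counts Named vector (or data frame with `species`, `count`) of
#'   non-negative leaf counts; may be a matrix/data.frame of several families
#'   (columns `species`, one row per family) — see `family_matrix`.
#' @param lambda Per-gene gain/loss rate.
#' @param max_count State-space truncation; default
#'   `max(100, 2 * max count)`.
#' @return Total log-likelihood (summed over families when several).
#' @export
family_likelihood <- function(tree, counts, lambda,
                              max_count = NULL) {
  tree <- check_dated_tree(tree)
  cm <- counts_matrix(tree, counts)
  if (is.null(max_count)) max_count <- max(100L, 2L * max(cm))
  if (max_count < 2L * max(cm)) {
    stop("max_count must be at least twice the largest leaf count")
  }
  ll <- bd_pruning(tree, cm, lambda, max_count)
  sum(ll$loglik)
}

# counts -> families x tips integer matrix (tips in tree order)
counts_matrix <- function(tree, counts) {
  if (is.matrix(counts) || (is.data.frame(counts) &&
                            all(tree$tip.label %in% names(counts)))) {
    cm <- as.matrix(counts)[, tree$tip.label, drop = FALSE]
    storage.mode(cm) <- "integer"
    if (any(cm < 0)) stop("counts must be non-negative")
    cm
  } else {
    matrix(check_counts(tree, counts), nrow = 1,
           dimnames = list(NULL, tree$tip.label))
  }
}

# pruning pass: per-family root-state log-likelihood profile
# returns list(loglik (per family), partials, tree, prior)
bd_pruning <- function(tree, cm, lambda, max_count) {
  tree <- ape::reorder.phylo(tree, "postorder")
  mats <- bd_edge_mats(tree, lambda, max_count)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nfam <- nrow(cm)
  n <- max_count + 1L
  # partial[[node]]: n x nfam matrix of conditional likelihoods
  partial <- vector("list", nnode)
  logsc <- matrix(0, 1, nfam)
  for (tip in seq_len(ntip)) {
    L <- matrix(0, n, nfam)
    L[cbind(cm[, tree$tip.label[tip]] + 1L, seq_len(nfam))] <- 1
    partial[[tip]] <- L
  }
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    msg <- mats[[e]] %*% partial[[child]]
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- msg
    } else {
      partial[[parent]] <- partial[[parent]] * msg
      mx <- apply(partial[[parent]], 2, max)
      resc <- which(mx > 0 & mx < 1e-200)
      for (f in resc) {
        partial[[parent]][, f] <- partial[[parent]][, f] / mx[f]
        logsc[1, f] <- logsc[1, f] + log(mx[f])
      }
    }
  }
  root <- ntip + 1L
  prior <- numeric(n)
  hi <- min(2L * max(cm, 1L), max_count)
  prior[(1:hi) + 1L] <- 1 / hi
  lik <- as.vector(prior %*% partial[[root]])
  list(loglik = log(lik) + as.vector(logsc), partial = partial,
       tree = tree, prior = prior, mats = mats, max_count = max_count)
}

#' Maximum-likelihood gain/loss rate for a set of families
#'
#' Golden-section search (via [stats::optimize()]) of the summed family
#' log-likelihood over `lambda` in `[0, lambda_max]`.
#'
#' @param tree Dated `phylo` tree.
#' @param counts One family (named vector) or several (matrix/data frame,
#'   one row per family, columns = species).
#' @param lambda_max Upper search bound; default 0.1 events/gene/My.
#' @param max_count Truncation, as in [family_likelihood()].
#' @return List with `lambda`, `loglik`, `boundary` (`TRUE` when the
#'   optimum sits at the lower boundary, e.g. all counts identical).
#' @export
fit_lambda <- function(tree, counts, lambda_max = 0.1, max_count = NULL) {
  tree <- check_dated_tree(tree)
  cm <- counts_matrix(tree, counts)
  if (is.null(max_count)) max_count <- max(100L, 2L * max(cm))
  obj <- function(l) -sum(bd_pruning(tree, cm, l, max_count)$loglik)
  opt <- optimize(obj, c(0, lambda_max), tol = 1e-6)
  boundary <- opt$minimum < 1e-5
  lam <- if (boundary && obj(0) <= opt$objective) 0 else opt$minimum
  list(lambda = lam, loglik = -obj(lam), boundary = boundary)
}

#' Ancestral family sizes and per-branch gains/losses
#'
#' Max-marginal-posterior integer count at every internal node from an
#' up-down (outside) pass under the birth-death model, plus the signed
#' per-branch deltas (child minus parent; positive = gain, negative = loss).
#'
#' @param tree Dated `phylo` tree.
#' @param counts Named leaf-count vector for one family.
#' @param lambda Gain/loss rate (fitted or supplied).
#' @param max_count Truncation, as in [family_likelihood()].
#' @return List with `node_counts` (counts for all nodes, tips first, in
#'   `ape` node order), `deltas` (per edge of the reordered tree:
#'   `parent`, `child`, `delta`, `label` like `"+2"`/`"-1"`/`"0"`), and
#'   `tree` (the postorder-reordered tree the edges refer to).
#' @export
ancestral_counts <- function(tree, counts, lambda, max_count = NULL) {
  tree <- check_dated_tree(tree)
  cm <- counts_matrix(tree, counts)
  if (nrow(cm) != 1L) stop("ancestral_counts works on one family at a time")
  if (is.null(max_count)) max_count <- max(100L, 2L * max(cm))
  pr <- bd_pruning(tree, cm, lambda, max_count)
  tree <- pr$tree
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  n <- max_count + 1L
  root <- ntip + 1L

  # outside (down) messages: out[[node]] = prior-weighted likelihood of the
  # rest of the tree given the node state
  out <- vector("list", nnode)
  out[[root]] <- matrix(pr$prior, ncol = 1)
  edges <- tree$edge
  for (e in rev(seq_len(nrow(edges)))) { # preorder
    parent <- edges[e, 1]
    child <- edges[e, 2]
    sib_prod <- out[[parent]]
    for (e2 in which(edges[, 1] == parent)) {
      if (edges[e2, 2] == child) next
      sib_prod <- sib_prod * (pr$mats[[e2]] %*% pr$partial[[edges[e2, 2]]])
    }
    out[[child]] <- crossprod(pr$mats[[e]], sib_prod)
  }

  node_counts <- integer(nnode)
  node_counts[seq_len(ntip)] <- cm[1, tree$tip.label]
  for (v in (ntip + 1L):nnode) {
    post <- as.vector(out[[v]]) * as.vector(pr$partial[[v]])
    node_counts[v] <- which.max(post) - 1L
  }
  delta <- node_counts[edges[, 2]] - node_counts[edges[, 1]]
  lab <- ifelse(delta > 0, paste0("+", delta), as.character(delta))
  list(node_counts = node_counts,
       deltas = data.frame(parent = edges[, 1], child = edges[, 2],
                           delta = delta, label = lab),
       tree = tree)
}
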
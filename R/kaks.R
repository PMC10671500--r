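#' Pair paralogous genes within species
#'
#' All unordered within-species pairs of records; cross-species pairs are
#' never formed. This is the pairing used to survey Ka/Ks of a gene family's
#' paralogs inside each genome.
#'
#' @param records Data frame with columns `id` and `species`.
#' @return Data frame with columns `species`, `id1`, `id2`.
#' @export
pair_paralogs <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "species") %in% names(records)))
  out <- lapply(split(records$id, records$species), function(ids) {
    if (length(ids) < 2L) return(NULL)
    cmb <- combn(sort(ids), 2L)
    data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
  })
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) {
    return(data.frame(species = character(), id1 = character(),
                      id2 = character()))
  }
  res <- do.call(rbind, Map(function(sp, df) cbind(species = sp, df),
                            names(out)[keep], out[keep]))
  rownames(res) <- NULL
  res
}

#' YN-style Ka/Ks estimate for a codon-aligned sequence pair
#'
#' Counting-method estimate in the style of Yang & Nielsen (2000):
#' the transition/transversion ratio kappa is estimated from
#' fourfold-degenerate and nondegenerate sites by a K80 correction;
#' synonymous (S) and nonsynonymous (N) site totals weight each possible
#' single-nucleotide change by kappa and by the F3x4 target-nucleotide
#' frequency; observed differences are apportioned over all substitution
#' pathways (stop-free, equally weighted); and the synonymous/nonsynonymous
#' proportions are corrected for multiple hits with a per-class K80
#' correction using the transition/transversion split of the observed
#' differences (falling back to a JC-style correction when the K80
#' logarithms are undefined).
#'
#' @param pair Two-row [codon_alignment()] (or anything `codon_alignment()`
#'   accepts).
#' @param min_sites Minimum shared non-gap codon sites; default 10.
#' @return List with `ka`, `ks`, `ratio` (`NA` with `undefined = TRUE` when
#'   `ks = 0`), `kappa`, `S`, `N`, `Sd`, `Nd`, `n_sites`.
#' @export
estimate_kaks <- function(pair, min_sites = 10L) {
  if (!inherits(pair, "codon_alignment")) pair <- codon_alignment(pair)
  if (nrow(pair) != 2L) stop("estimate_kaks needs exactly two sequences")
  ct <- codon_tables()
  shared <- pair[1, ] != "---" & pair[2, ] != "---"
  if (!any(shared)) stop("all-gap pair: no shared codon sites")
  if (sum(shared) < min_sites) {
    stop("only ", sum(shared), " shared codon sites (minimum ", min_sites, ")")
  }
  c1 <- unclass(pair)[1, shared]
  c2 <- unclass(pair)[2, shared]
  i1 <- match(c1, ct$codons)
  i2 <- match(c2, ct$codons)

  kappa <- estimate_kappa_degenerate(i1, i2, ct)

  # position-specific nucleotide frequencies of the pair (for site weighting)
  ntfreq <- pair_ntfreq(rbind(c1, c2))
  S1 <- count_sites(i1, kappa, ntfreq, ct)
  S2 <- count_sites(i2, kappa, ntfreq, ct)
  S <- (S1 + S2) / 2
  N <- 3 * length(i1) - S

  # observed differences, pathway-averaged, split by substitution type
  d <- c(syn_ts = 0, syn_tv = 0, non_ts = 0, non_tv = 0)
  for (k in seq_along(i1)) {
    if (i1[k] != i2[k]) d <- d + pathway_counts(i1[k], i2[k], ct)
  }
  Sd <- d[["syn_ts"]] + d[["syn_tv"]]
  Nd <- d[["non_ts"]] + d[["non_tv"]]

  ks <- class_distance(d[["syn_ts"]] / S, d[["syn_tv"]] / S)
  ka <- class_distance(d[["non_ts"]] / N, d[["non_tv"]] / N)
  undefined <- ks <= 0
  list(ka = ka, ks = ks,
       ratio = if (undefined) NA_real_ else ka / ks,
       undefined = undefined, kappa = kappa,
       S = S, N = N, Sd = Sd, Nd = Nd, n_sites = length(i1))
}

# K80 distance for one substitution class from ts/tv proportions; JC-style
# fallback when the logs are undefined.
class_distance <- function(P, Q) {
  if (P + Q <= 0) return(0)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 > 0 && w2 > 0) {
    -0.5 * log(w1) - 0.25 * log(w2)
  } else {
    p <- P + Q
    if (p >= 0.749) p <- 0.749
    -3 / 4 * log(1 - 4 * p / 3)
  }
}

# kappa from fourfold-degenerate third positions and nondegenerate positions
# via K80; default 2 when inestimable.
estimate_kappa_degenerate <- function(i1, i2, ct) {
  purine <- c(TRUE, FALSE, TRUE, FALSE)
  # degeneracy class per codon position: number of synonymous alternatives
  deg <- degeneracy_table(ct)
  ts <- tv <- n <- 0
  for (k in seq_along(i1)) {
    for (p in 1:3) {
      d1 <- deg[i1[k], p]
      d2 <- deg[i2[k], p]
      use <- (d1 == 3 && d2 == 3) || (d1 == 0 && d2 == 0)
      if (!use) next
      n <- n + 1
      n1 <- ct$nt[i1[k], p]
      n2 <- ct$nt[i2[k], p]
      if (n1 != n2) {
        if (purine[n1] == purine[n2]) ts <- ts + 1 else tv <- tv + 1
      }
    }
  }
  if (n == 0) return(2)
  P <- ts / n
  Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(2)
  a <- -0.5 * log(w1) + 0.25 * log(w2) # transition rate * t
  b <- -0.25 * log(w2)                 # transversion rate * t (each kind)
  if (b <= 1e-9 || a <= 0) return(2)
  max(a / b, 0.1)
}

# per-codon, per-position count of synonymous single-nt alternatives (0-3)
degeneracy_table <- function(ct) {
  if (!is.null(.ss_cache$degeneracy)) return(.ss_cache$degeneracy)
  n <- length(ct$codons)
  deg <- matrix(0L, n, 3)
  for (r in seq_len(nrow(ct$pairs))) {
    pr <- ct$pairs[r, ]
    if (pr["synonymous"] == 1L) {
      deg[pr["i"], pr["pos"]] <- deg[pr["i"], pr["pos"]] + 1L
    }
  }
  .ss_cache$degeneracy <- deg
  deg
}

# kappa- and frequency-weighted synonymous site count for one sequence
count_sites <- function(idx, kappa, ntfreq, ct) {
  key <- paste0("sites_", signif(kappa, 8), "_",
                paste(signif(ntfreq, 6), collapse = ","))
  if (is.null(.ss_cache[[key]])) {
    purine <- c(TRUE, FALSE, TRUE, FALSE)
    n <- length(ct$codons)
    syn_frac <- matrix(0, n, 3)
    neigh <- ct$pairs
    for (i in seq_len(n)) {
      for (p in 1:3) {
        wsum <- 0
        wsyn <- 0
        for (nt2 in 1:4) {
          if (nt2 == ct$nt[i, p]) next
          trip <- ct$nt[i, ]
          trip[p] <- nt2
          j <- match_codon(trip, ct)
          w <- ifelse(purine[ct$nt[i, p]] == purine[nt2], kappa, 1) *
            ntfreq[nt2, p]
          if (is.na(j)) next # stop codon: not a site
          wsum <- wsum + w
          if (ct$aa[i] == ct$aa[j]) wsyn <- wsyn + w
        }
        syn_frac[i, p] <- if (wsum > 0) wsyn / wsum else 0
      }
    }
    .ss_cache[[key]] <- syn_frac
  }
  syn_frac <- .ss_cache[[key]]
  sum(syn_frac[idx, ])
}

match_codon <- function(trip, ct) {
  hit <- which(ct$nt[, 1] == trip[1] & ct$nt[, 2] == trip[2] &
                 ct$nt[, 3] == trip[3])
  if (length(hit)) hit else NA_integer_
}

# average syn/nonsyn x ts/tv step counts over stop-free substitution
# pathways between two codons (equal path weights)
pathway_counts <- function(i, j, ct) {
  purine <- c(TRUE, FALSE, TRUE, FALSE)
  key <- paste0("path_", i, "_", j)
  if (!is.null(.ss_cache[[key]])) return(.ss_cache[[key]])
  diffs <- which(ct$nt[i, ] != ct$nt[j, ])
  paths <- perms(diffs)
  acc <- matrix(0, 0, 4)
  for (ord in paths) {
    cur <- ct$nt[i, ]
    steps <- c(0, 0, 0, 0)
    ok <- TRUE
    from <- i
    for (p in ord) {
      nxt <- cur
      nxt[p] <- ct$nt[j, p]
      to <- match_codon(nxt, ct)
      if (is.na(to)) { ok <- FALSE; break }
      ts <- purine[cur[p]] == purine[nxt[p]]
      syn <- ct$aa[from] == ct$aa[to]
      kcol <- 1 + (!syn) * 2 + (!ts)
      steps[kcol] <- steps[kcol] + 1
      cur <- nxt
      from <- to
    }
    if (ok) acc <- rbind(acc, steps)
  }
  if (nrow(acc) == 0L) {
    # every pathway passes through a stop; count the direct nucleotide
    # changes as nonsynonymous
    steps <- c(0, 0, 0, 0)
    for (p in diffs) {
      ts <- purine[ct$nt[i, p]] == purine[ct$nt[j, p]]
      steps[3 + (!ts)] <- steps[3 + (!ts)] + 1
    }
    acc <- rbind(acc, steps)
  }
  out <- colMeans(acc)
  names(out) <- c("syn_ts", "syn_tv", "non_ts", "non_tv")
  .ss_cache[[key]] <- out
  out
}

perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (k in seq_along(x)) {
    for (rest in perms(x[-k])) out[[length(out) + 1L]] <- c(x[k], rest)
  }
  out
}

# position-specific nucleotide frequencies of a small codon matrix
pair_ntfreq <- function(codon_mat) {
  counts <- matrix(1, 4, 3)
  m <- do.call(rbind, strsplit(as.vector(codon_mat), ""))
  for (p in 1:3) {
    tb <- table(factor(m[, p], levels = c("A", "C", "G", "T")))
    counts[, p] <- counts[, p] + as.numeric(tb)
  }
  sweep(counts, 2, colSums(counts), "/")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation p-value when the combined sample size is at most 12 and
#' there are no ties; tie-corrected normal approximation (with continuity
#' correction) otherwise. The conventional choice for comparing Ka/Ks
#' distributions between groups of species.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `statistic` (W), `p_value`, `exact` (logical).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12))$p_value # 0.1
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- (length(x) + length(y)) <= 12 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
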
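# Independent brute-force oracles used to validate the package
# implementations. Each is written from the definition, sharing no code
# with the implementation it checks.

# exhaustive hinge scoring: score every anchor in [lo, hi] independently
oracle_hinge_scan <- function(seq, window = c(75, 25)) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  allowed <- list(`0` = "E", `1` = c("E", "K", "R"), `2` = "G",
                  `3` = c("T", "S"), `5` = c("A", "G", "S"),
                  `6` = c("A", "G", "S"), `7` = c("A", "G", "S"),
                  `8` = c("A", "G", "S"))
  lo <- max(1, L - window[1]); hi <- min(L - 17, L - window[2])
  if (hi < lo) return(data.frame(p17_index = integer(), score = integer()))
  res <- do.call(rbind, lapply(lo:hi, function(a) {
    sc <- sum(vapply(names(allowed), function(off) {
      chars[a + as.integer(off)] %in% allowed[[off]]
    }, logical(1)))
    data.frame(p17_index = a, score = sc)
  }))
  res[res$score >= 1, , drop = FALSE]
}

# textbook Needleman-Wunsch with affine-free linear gap penalty is not what
# Biostrings uses; instead score with the same affine scheme by explicit
# 3-state DP (match/insert/delete) over a substitution matrix
oracle_global_align_score <- function(a, b, submat, gap_open, gap_ext) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    Ix[i + 1, 1] <- -gap_open - (i - 1) * gap_ext - gap_ext
  }
  for (j in seq_len(m)) {
    Iy[1, j + 1] <- -gap_open - (j - 1) * gap_ext - gap_ext
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                              Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                              Iy[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# least-squares branch fit of one quartet topology ((A,B),(C,D)) to a
# distance matrix; returns the residual sum of squares
oracle_quartet_rss <- function(D, split) {
  pairs <- t(combn(4, 2))
  path_len <- function(bl, i, j) {
    # bl: 4 tip branches + internal; tips on the same side skip the bridge
    same <- (i %in% split[[1]]) == (j %in% split[[1]])
    bl[i] + bl[j] + if (same) 0 else bl[5]
  }
  rss <- function(bl) {
    sum(vapply(seq_len(nrow(pairs)), function(r) {
      (D[pairs[r, 1], pairs[r, 2]] -
         path_len(bl, pairs[r, 1], pairs[r, 2]))^2
    }, numeric(1)))
  }
  opt <- optim(rep(0.5, 5), function(b) rss(pmax(b, 0)),
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  opt$value
}

# GY94 rate matrix built from first principles for the lnL oracle
oracle_gy94_q <- function(pi, kappa, omega) {
  gc_tab <- Biostrings::GENETIC_CODE
  codons <- names(gc_tab)[gc_tab != "*"]
  n <- length(codons)
  purines <- c("A", "G")
  Q <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- strsplit(codons[i], "")[[1]]; cj <- strsplit(codons[j], "")[[1]]
      d <- which(ci != cj)
      if (length(d) != 1) next
      r <- pi[j]
      if ((ci[d] %in% purines) == (cj[d] %in% purines)) r <- r * kappa
      if (gc_tab[codons[i]] != gc_tab[codons[j]]) r <- r * omega
      Q[i, j] <- r
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# direct two-taxon site log-likelihood: sum_i pi_i P_ij(t), P from
# Matrix::expm (independent matrix-exponential routine)
oracle_two_taxon_loglik <- function(codons1, codons2, pi, kappa, omega, t) {
  Q <- oracle_gy94_q(pi, kappa, omega)
  Q <- Q / (-sum(pi * diag(Q)))
  P <- as.matrix(Matrix::expm(Q * t))
  gc_tab <- Biostrings::GENETIC_CODE
  cods <- names(gc_tab)[gc_tab != "*"]
  i1 <- match(codons1, cods); i2 <- match(codons2, cods)
  sum(log(pi[i1] * P[cbind(i1, i2)]))
}

# NG86 counting oracle: unweighted site counting, equal-weight pathways,
# Jukes-Cantor correction
oracle_ng86 <- function(c1, c2) {
  gc_tab <- Biostrings::GENETIC_CODE
  cods <- names(gc_tab)[gc_tab != "*"]
  syn_frac <- function(codon) {
    ci <- strsplit(codon, "")[[1]]
    sum(vapply(1:3, function(p) {
      alts <- setdiff(c("A", "C", "G", "T"), ci[p])
      muts <- vapply(alts, function(nt) {
        cj <- ci; cj[p] <- nt; paste(cj, collapse = "")
      }, character(1))
      keep <- gc_tab[muts] != "*"
      if (!any(keep)) return(0)
      mean(gc_tab[muts[keep]] == gc_tab[codon])
    }, numeric(1)))
  }
  count_path <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    d <- which(ca != cb)
    if (!length(d)) return(c(0, 0))
    perms <- if (length(d) == 1) list(d) else {
      out <- list()
      rec <- function(pre, rest) {
        if (!length(rest)) out[[length(out) + 1]] <<- pre
        else for (k in seq_along(rest)) rec(c(pre, rest[k]), rest[-k])
      }
      rec(integer(), d); out
    }
    acc <- c(0, 0); np <- 0
    for (ord in perms) {
      cur <- ca; steps <- c(0, 0); ok <- TRUE
      for (p in ord) {
        nxt <- cur; nxt[p] <- cb[p]
        if (gc_tab[paste(nxt, collapse = "")] == "*") { ok <- FALSE; break }
        syn <- gc_tab[paste(cur, collapse = "")] ==
          gc_tab[paste(nxt, collapse = "")]
        steps <- steps + if (syn) c(1, 0) else c(0, 1)
        cur <- nxt
      }
      if (ok) { acc <- acc + steps; np <- np + 1 }
    }
    if (np == 0) c(0, length(d)) else acc / np
  }
  S <- mean(c(sum(vapply(c1, syn_frac, numeric(1))),
              sum(vapply(c2, syn_frac, numeric(1)))))
  N <- 3 * length(c1) - S
  sd_nd <- rowSums(mapply(count_path, c1, c2))
  jc <- function(p) if (p <= 0) 0 else -3 / 4 * log(max(1 - 4 * p / 3, 1e-6))
  ks <- jc(sd_nd[1] / S); ka <- jc(sd_nd[2] / N)
  list(ka = ka, ks = ks, ratio = if (ks > 0) ka / ks else NA_real_)
}

# adjusted Rand index between two labelled partitions
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small balanced 6-taxon tree used by several simulation tests
six_taxon_tree <- function() {
  ape::read.tree(
    text = "(((A:0.3,B:0.3):0.15,(C:0.3,D:0.3):0.15):0.1,(E:0.4,F:0.4):0.1);"
  )
}
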
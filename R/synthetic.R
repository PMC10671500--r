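# Seeded generators for serpin-like proteins, codon alignments, gene counts
# and expression matrices, each returning its planted ground truth so
# downstream recovery can be scored without re-reading generator internals.

sample_bg <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                               collapse = "")

# write a perfect hinge (P17..P9) into chars at anchor a; returns chars
plant_hinge <- function(chars, a) {
  for (cons in HINGE_CONSENSUS) {
    chars[a + cons$offset] <- sample(cons$allowed, 1)
  }
  chars
}

# degrade: exactly `keep` consensus positions satisfied
plant_degraded_hinge <- function(chars, a, keep = 3L) {
  idx <- sample(seq_along(HINGE_CONSENSUS), keep)
  for (k in seq_along(HINGE_CONSENSUS)) {
    cons <- HINGE_CONSENSUS[[k]]
    pool <- if (k %in% idx) cons$allowed else setdiff(AA_ALPHABET,
                                                      cons$allowed)
    chars[a + cons$offset] <- sample(pool, 1)
  }
  chars
}

#' Generate serpin-like proteins with planted hinges and P1 residues
#'
#' Emits proteins of length 345-570 with a perfect hinge consensus planted
#' at a recorded position and a P1 residue drawn from `class_mix`. A
#' `decoy_fraction` of records instead get one of three non-inhibitory
#' defects: a degraded hinge (at most 3/8 consensus positions), a truncated
#' C-terminus (the RCL falls off the end), or a long RCL (the hinge sits
#' more than 60 residues from the P1-bearing tail). Records are
#' rejection-sampled so the planted truth is guaranteed: no decoy carries a
#' spurious hinge at or above `min_score`, and every planted record's best
#' hinge is the planted one — the truth bundle is therefore sufficient to
#' score annotation recovery exactly.
#'
#' @param n Number of records.
#' @param class_mix Named proportions over
#'   `c("trypsin", "chymotrypsin", "elastase")`; default equal.
#' @param decoy_fraction Fraction of decoys in `[0, 1]`; default 0.
#' @param seed Integer seed.
#' @param species Species label for all records.
#' @param min_score Hinge threshold the decoys are guaranteed to stay
#'   under; default 6 (match [annotate_rcl()]).
#' @return List with `records` (data frame `id`, `species`, `sequence`) and
#'   `truth` (data frame `id`, `decoy`, `decoy_type`, `hinge_index`,
#'   `p1_index`, `p1_residue`, `class`), plus `seed` and `params`.
#' @export
gen_serpin_proteins <- function(n, class_mix = NULL, decoy_fraction = 0,
                                seed = 1L, species = "synthetic",
                                min_score = 6L) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(class_mix)) {
    class_mix <- c(trypsin = 1 / 3, chymotrypsin = 1 / 3, elastase = 1 / 3)
  }
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8 ||
      !all(names(class_mix) %in% names(SPECIFICITY_MAP))) {
    stop("class_mix must be named proportions over the specificity classes")
  }
  if (decoy_fraction < 0 || decoy_fraction > 1) {
    stop("decoy_fraction must be in [0, 1]")
  }
  with_seed(seed, {
    n_decoy <- round(n * decoy_fraction)
    is_decoy <- rep(FALSE, n)
    if (n_decoy > 0) is_decoy[sample.int(n, n_decoy)] <- TRUE
    rows <- lapply(seq_len(n), function(i) {
      if (is_decoy[i]) {
        gen_one_decoy(i, min_score)
      } else {
        gen_one_planted(i, class_mix, min_score)
      }
    })
    records <- do.call(rbind, lapply(rows, `[[`, "record"))
    truth <- do.call(rbind, lapply(rows, `[[`, "truth"))
    records$species <- species
    list(records = records[, c("id", "species", "sequence")], truth = truth,
         seed = seed,
         params = list(n = n, class_mix = class_mix,
                       decoy_fraction = decoy_fraction))
  })
}

gen_one_planted <- function(i, class_mix, min_score,
                            len_range = c(345L, 570L)) {
  cls <- sample(names(class_mix), 1, prob = class_mix)
  for (try in 1:50) {
    L <- sample(len_range[1]:len_range[2], 1)
    chars <- strsplit(sample_bg(L), "")[[1]]
    a <- sample((L - 70L):(L - 30L), 1)
    chars <- plant_hinge(chars, a)
    p1 <- sample(SPECIFICITY_MAP[[cls]], 1)
    chars[a + P1_OFFSET] <- p1
    seq <- paste(chars, collapse = "")
    sc <- scan_hinge(seq)
    if (nrow(sc) > 0 && sc$p17_index[1] == a && sc$score[1] == 8L) {
      return(list(
        record = data.frame(id = sprintf("SYN%04d", i), sequence = seq),
        truth = data.frame(id = sprintf("SYN%04d", i), decoy = FALSE,
                           decoy_type = NA_character_, hinge_index = a,
                           p1_index = a + P1_OFFSET, p1_residue = p1,
                           class = cls)
      ))
    }
  }
  stop("failed to plant a unique hinge after 50 tries")
}

gen_one_decoy <- function(i, min_score, len_range = c(345L, 570L)) {
  type <- sample(c("degraded", "truncated", "long_tail"), 1)
  for (try in 1:100) {
    if (type == "truncated") {
      L <- sample(200:300, 1)
      chars <- strsplit(sample_bg(L), "")[[1]]
      a <- L - 8L # hinge fits, P1 beyond the C-terminus
      chars <- plant_hinge(chars, a)
    } else if (type == "long_tail") {
      L <- sample(len_range[1]:len_range[2], 1)
      chars <- strsplit(sample_bg(L), "")[[1]]
      a <- sample((L - 150L):(L - 90L), 1) # tail > 60 residues past P1
      chars <- plant_hinge(chars, a)
      chars[a + P1_OFFSET] <- sample(unlist(SPECIFICITY_MAP), 1)
    } else {
      L <- sample(len_range[1]:len_range[2], 1)
      chars <- strsplit(sample_bg(L), "")[[1]]
      a <- sample((L - 70L):(L - 30L), 1)
      chars <- plant_degraded_hinge(chars, a, keep = 3L)
    }
    seq <- paste(chars, collapse = "")
    sc <- scan_hinge(seq)
    if (nrow(sc) == 0 || sc$score[1] < min_score) {
      return(list(
        record = data.frame(id = sprintf("SYN%04d", i), sequence = seq),
        truth = data.frame(id = sprintf("SYN%04d", i), decoy = TRUE,
                           decoy_type = type, hinge_index = a,
                           p1_index = NA_integer_,
                           p1_residue = NA_character_, class = "none")
      ))
    }
  }
  stop("failed to build a clean decoy after 100 tries")
}

#' Simulate a codon alignment under GY94 site models
#'
#' Draws root codons from F3x4 frequencies and evolves them along the tree
#' with exact per-class transition matrices; each site's omega class is
#' recorded as ground truth. `params` specifies the site-class structure:
#' `list(model = "M0", omega =, kappa =)`,
#' `list(model = "M7", p =, q =, kappa =)`,
#' `list(model = "M8", p0 =, p =, q =, omega_s =, kappa =)`, or an explicit
#' `list(model = "classes", classes = data.frame(omega, weight), kappa =)`.
#' Branch lengths are expected substitutions per codon under the class
#' mixture (the same convention [fit_site_model()] uses).
#'
#' @param tree `phylo` with branch lengths.
#' @param params Site-model spec, see above.
#' @param n_sites Number of codon sites (>= 1).
#' @param seed Integer seed.
#' @param ntfreq Optional 4 x 3 position-specific nucleotide frequency
#'   matrix (rows A,C,G,T) for F3x4; default uniform.
#' @param ncat Beta discretisation for M7/M8; default 10.
#' @return List with `aln` ([codon_alignment()]), `truth` (data frame
#'   `site`, `class`, `omega`), `classes`, `pi`, `seed`.
#' @export
sim_codon_alignment <- function(tree, params, n_sites, seed = 1L,
                                ntfreq = NULL, ncat = 10L) {
  stopifnot(inherits(tree, "phylo"))
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  kappa <- params$kappa %||% 2
  classes <- switch(params$model,
    M0 = data.frame(omega = params$omega, weight = 1),
    M7 = site_class_table("M7", params, ncat),
    M8 = site_class_table("M8", params, ncat),
    classes = params$classes,
    stop("unknown simulation model ", params$model)
  )
  if (is.null(ntfreq)) ntfreq <- matrix(1 / 4, 4, 3)
  pi <- f3x4_freqs(ntfreq)
  ct <- codon_tables()
  rbar <- gy94_scale(pi, kappa, classes$omega, classes$weight)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L

  with_seed(seed, {
    site_class <- sample.int(nrow(classes), n_sites, replace = TRUE,
                             prob = classes$weight)
    states <- matrix(NA_integer_, nnode, n_sites)
    states[root, ] <- sample.int(length(pi), n_sites, replace = TRUE,
                                 prob = pi)
    pmats <- lapply(seq_len(nrow(classes)), function(k) {
      Q <- gy94_q(pi, kappa, classes$omega[k]) / rbar
      lapply(tree$edge.length, function(t) gy94_pmat_cached(pi, Q, t))
    })
    for (e in rev(seq_len(nrow(tree$edge)))) { # preorder: root outwards
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      for (k in unique(site_class)) {
        sites <- which(site_class == k)
        P <- pmats[[k]][[e]]
        for (s in unique(states[parent, sites])) {
          at <- sites[states[parent, sites] == s]
          states[child, at] <- sample.int(length(pi), length(at),
                                          replace = TRUE, prob = P[s, ])
        }
      }
    }
    rows <- lapply(seq_len(ntip), function(tip) ct$codons[states[tip, ]])
    names(rows) <- tree$tip.label
    list(aln = codon_alignment(rows),
         truth = data.frame(site = seq_len(n_sites), class = site_class,
                            omega = classes$omega[site_class]),
         classes = classes, pi = pi, seed = seed)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# P(t) from a pre-scaled Q (symmetric-eigen route, R implementation)
gy94_pmat_cached <- function(pi, Q, t) {
  sq <- sqrt(pi)
  B <- (Q * sq) / rep(sq, each = length(pi))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- sweep(sweep(e$vectors %*% (t(e$vectors) * exp(e$values * t)),
                   1, sq, "/"), 2, sq, "*")
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate gene counts under the birth-death model
#'
#' Samples family sizes branch by branch from [bd_transition_prob()] rows,
#' starting from `root_count`, recording every internal node's state.
#'
#' @param tree Dated `phylo` tree.
#' @param lambda Per-gene gain/loss rate (>= 0).
#' @param root_count Root family size (>= 1).
#' @param seed Integer seed.
#' @param max_count Truncation for the sampling matrices; default
#'   `max(100, 4 * root_count)`.
#' @return List with `counts` (named leaf vector), `node_counts` (all nodes
#'   of the postorder tree), `tree` (reordered), `seed`.
#' @export
sim_gene_counts <- function(tree, lambda, root_count, seed = 1L,
                            max_count = NULL) {
  tree <- check_dated_tree(tree)
  if (lambda < 0) stop("lambda must be >= 0")
  if (root_count < 1) stop("root_count must be >= 1")
  if (is.null(max_count)) max_count <- max(100L, 4L * root_count)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  mats <- bd_edge_mats(tree, lambda, max_count)
  with_seed(seed, {
    node_counts <- integer(nnode)
    node_counts[ntip + 1L] <- root_count
    for (e in rev(seq_len(nrow(tree$edge)))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      p <- mats[[e]][node_counts[parent] + 1L, ]
      node_counts[child] <- sample.int(max_count + 1L, 1, prob = p) - 1L
    }
    counts <- setNames(node_counts[seq_len(ntip)], tree$tip.label)
    list(counts = counts, node_counts = node_counts, tree = tree,
         seed = seed)
  })
}

#' Simulate a block-structured expression matrix
#'
#' FPKM values are `2^(block mean + N(0, noise_sd)) - 1`, floored at zero,
#' so [transform_fpkm()] recovers gaussian blocks exactly.
#'
#' @param n_genes Number of genes.
#' @param sample_labels Character vector of sample (stage/tissue) codes.
#' @param block_spec List of blocks, each `list(size =, mean =)` where
#'   `mean` is a scalar or per-sample vector of log2 means; sizes must sum
#'   to `n_genes`.
#' @param noise_sd Gaussian noise sd on the log2 scale.
#' @param seed Integer seed.
#' @return List with `fpkm` (genes x samples matrix), `labels` (true block
#'   per gene), `seed`.
#' @export
sim_expression <- function(n_genes, sample_labels, block_spec,
                           noise_sd = 0.5, seed = 1L) {
  sizes <- vapply(block_spec, `[[`, numeric(1), "size")
  if (sum(sizes) != n_genes) stop("block sizes must sum to n_genes")
  ns <- length(sample_labels)
  with_seed(seed, {
    rows <- list()
    labels <- integer(0)
    g <- 0L
    for (b in seq_along(block_spec)) {
      mu <- rep(block_spec[[b]]$mean, length.out = ns)
      for (r in seq_len(sizes[b])) {
        g <- g + 1L
        rows[[g]] <- pmax(2^(mu + rnorm(ns, 0, noise_sd)) - 1, 0)
        labels[g] <- b
      }
    }
    fpkm <- do.call(rbind, rows)
    dimnames(fpkm) <- list(sprintf("gene%03d", seq_len(n_genes)),
                           sample_labels)
    list(fpkm = fpkm, labels = setNames(labels, rownames(fpkm)),
         seed = seed)
  })
}

#' Build a serpin gene model with mutually exclusive RCL exons
#'
#' Constructs a synthetic serpin gene in which exons 1-8 and a terminal exon
#' are shared and the ninth exon — encoding the hinge, the RCL and the P1
#' residue — is mutually exclusive, one variant per requested P1 residue.
#' Mirrors the classic serpin-1 architecture where alternative ninth exons
#' swap the inhibitory specificity of the isoforms.
#'
#' @param p1_residues Character vector of P1 residues, one isoform each.
#' @param seed Integer seed for the background sequence.
#' @return A [gene_model()].
#' @export
sim_serpin_gene_model <- function(p1_residues = c("Y", "R", "A"),
                                  seed = 1L) {
  stopifnot(length(p1_residues) >= 1)
  with_seed(seed, {
    nterm <- sample_bg(304) # exons 1-8, 38 aa each
    cterm <- sample_bg(20)  # shared terminal exon
    variants <- vapply(p1_residues, function(p1) {
      chars <- strsplit(sample_bg(30), "")[[1]]
      chars <- plant_hinge(chars, 1L)
      chars[1L + P1_OFFSET] <- p1
      paste(chars, collapse = "")
    }, character(1))
    rt <- function(aa) { # deterministic reverse translation
      gc_tab <- Biostrings::GENETIC_CODE
      vapply(strsplit(aa, "")[[1]], function(a) {
        names(gc_tab)[gc_tab == a][1]
      }, character(1))
    }
    ncod <- rt(nterm)
    splits <- split(seq_along(ncod), cut(seq_along(ncod), 8, labels = FALSE))
    shared <- data.frame(
      exon_index = c(1:8, 10L), variant_flag = FALSE,
      sequence = c(vapply(splits, function(ii)
        paste(ncod[ii], collapse = ""), character(1)),
        paste0(paste(rt(cterm), collapse = ""), "TAA")),
      variant_id = NA_character_
    )
    var <- data.frame(
      exon_index = 9L, variant_flag = TRUE,
      sequence = vapply(variants, function(v)
        paste(rt(v), collapse = ""), character(1)),
      variant_id = LETTERS[seq_along(p1_residues)]
    )
    gene_model(rbind(shared, var), gene_id = "serpin1")
  })
}
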
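# GY94 codon site models M0/M3/M7/M8: fitting, LRTs, NEB/BEB site posteriors.

# ---- rate matrix and transition probabilities (R path; the C++ core in
# src/gy94.cpp is an independent implementation used for fitting speed) ----

gy94_q <- function(pi, kappa, omega) {
  ct <- codon_tables()
  n <- length(pi)
  Q <- matrix(0, n, n)
  pr <- ct$pairs
  rate <- pi[pr[, "j"]] *
    ifelse(pr[, "transition"] == 1L, kappa, 1) *
    ifelse(pr[, "synonymous"] == 1L, 1, omega)
  Q[pr[, c("i", "j")]] <- rate
  diag(Q) <- -rowSums(Q)
  Q
}

# weighted mean rate over classes: the common scale factor so that branch
# lengths are expected substitutions per codon under the mixture
gy94_scale <- function(pi, kappa, omegas, weights) {
  sum(weights * vapply(omegas, function(w) {
    -sum(pi * diag(gy94_q(pi, kappa, w)))
  }, numeric(1)))
}

# transition matrix for one class at branch length t (substitutions/codon
# under the mixture scale rbar)
gy94_pmat <- function(pi, kappa, omega, t, rbar) {
  Q <- gy94_q(pi, kappa, omega) / rbar
  sq <- sqrt(pi)
  B <- (Q * rep(sq, times = length(pi))) / rep(sq, each = length(pi))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- sweep(sweep(e$vectors %*% diag(exp(e$values * t)) %*% t(e$vectors),
                   1, sq, "/"), 2, sq, "*")
  P[P < 0] <- 0
  P
}

# ---- model class grids ----

# equal-probability discretisation of Beta(p, q): category medians
discretize_beta <- function(p, q, ncat = 10L) {
  qbeta((2 * seq_len(ncat) - 1) / (2 * ncat), p, q)
}

site_class_table <- function(model, pars, ncat = 10L) {
  switch(model,
    M0 = data.frame(omega = pars$omega, weight = 1),
    M3 = data.frame(omega = pars$omegas, weight = pars$weights),
    M7 = data.frame(omega = discretize_beta(pars$p, pars$q, ncat),
                    weight = rep(1 / ncat, ncat)),
    M8 = data.frame(
      omega = c(discretize_beta(pars$p, pars$q, ncat), pars$omega_s),
      weight = c(rep(pars$p0 / ncat, ncat), 1 - pars$p0)
    ),
    stop("unknown model ", model)
  )
}

# ---- likelihood plumbing ----

# postorder edge structure for a codon alignment + tree
prep_phylo <- function(caln, tree) {
  stopifnot(inherits(tree, "phylo"))
  ids <- rownames(caln)
  if (!setequal(tree$tip.label, ids)) {
    stop("tree tip labels must match alignment ids")
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  states <- codon_states(caln)[tree$tip.label, , drop = FALSE]
  states[is.na(states)] <- 0L
  list(tree = tree, edge = tree$edge,
       edge_length = tree$edge.length, states = states)
}

# total log-likelihood of a class mixture from the per-class site logliks
mix_loglik <- function(logF, weights) {
  m <- apply(logF, 1, max)
  sum(m + log(as.vector(exp(logF - m) %*% weights)))
}

site_loglik <- function(ph, pi, kappa, classes, edge_length = NULL,
                        rbar = NULL) {
  el <- if (is.null(edge_length)) ph$edge_length else edge_length
  if (!is.null(rbar)) {
    # fixed scale: pre-scale branch lengths by rbar(theta)/rbar_fixed trick
    # is not needed -- the C++ core always scales by the mixture passed in,
    # so emulate a fixed scale by adjusting branch lengths
    own <- gy94_scale(pi, kappa, classes$omega, classes$weight)
    el <- el * own / rbar
  }
  gy94_site_loglik(ph$states, ph$edge, el, pi, kappa,
                   classes$omega, classes$weight, codon_tables()$pairs)
}

# ---- fitting ----

#' Fit a GY94 codon site model
#'
#' Maximum-likelihood fit of the M0 (one-ratio), M3 (three discrete classes),
#' M7 (beta) or M8 (beta plus a selected class with omega >= 1) site models
#' under a GY94 rate matrix with F3x4 codon frequencies, by Felsenstein
#' pruning over sites. Branch lengths are estimated under M0 and then held
#' fixed for the mixture models (pass `m0` to reuse an existing M0 fit);
#' kappa is re-estimated within every model. The beta component is
#' discretised into `ncat` equal-probability categories. Optimisation is a
#' bounded multi-start local search; starts are recorded in the fit.
#'
#' @param aln A [codon_alignment()].
#' @param tree `phylo` tree whose tips match the alignment ids; branch
#'   lengths, if present, seed the M0 branch-length search.
#' @param model One of `"M0"`, `"M3"`, `"M7"`, `"M8"`.
#' @param m0 Optional M0 fit (from this function) supplying fixed branch
#'   lengths for M3/M7/M8.
#' @param ncat Beta discretisation categories (default 10).
#' @param starts Number of optimiser starts for the mixture models.
#' @return Object of class `site_model_fit`: `model`, `lnL`, `params`
#'   (named list), `kappa`, `classes` (omega/weight table), `tree` (with M0
#'   branch lengths), `pi`, `site_posteriors` (sites x classes, empirical
#'   Bayes), `converged`, `starts`.
#' @export
fit_site_model <- function(aln, tree, model = c("M0", "M3", "M7", "M8"),
                           m0 = NULL, m7 = NULL, ncat = 10L, starts = 2L) {
  model <- match.arg(model)
  if (!inherits(aln, "codon_alignment")) aln <- codon_alignment(aln)
  if (nrow(aln) < 2L) stop("need at least two sequences")
  if (model %in% c("M3", "M7", "M8") && nrow(aln) < 3L) {
    stop(model, " needs at least three sequences")
  }
  pi <- empirical_f3x4(split(unclass(aln), row(aln)))
  ph <- prep_phylo(aln, tree)

  if (model == "M0") {
    fit <- fit_m0(ph, pi)
    ph$edge_length <- fit$edge_length
  } else {
    if (is.null(m0)) m0 <- fit_site_model(aln, tree, "M0", ncat = ncat)
    ph$edge_length <- m0$edge_length
    fit <- fit_mixture(ph, pi, model, ncat, starts, m0, m7 = m7)
  }
  classes <- site_class_table(model, fit$params, ncat)
  logF <- site_loglik(ph, pi, fit$kappa, classes)
  post <- exp(logF - apply(logF, 1, max))
  post <- sweep(post * rep(classes$weight, each = nrow(logF)), 1,
                rowSums(post * rep(classes$weight, each = nrow(logF))), "/")
  out_tree <- ph$tree
  out_tree$edge.length <- ph$edge_length
  structure(
    list(model = model, lnL = fit$lnL, params = fit$params,
         kappa = fit$kappa, classes = classes, tree = out_tree,
         edge_length = ph$edge_length, pi = pi,
         site_posteriors = post, converged = fit$converged,
         starts = fit$starts, aln = aln),
    class = "site_model_fit"
  )
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("GY94 site model %s: lnL = %.4f, kappa = %.3f\n",
              x$model, x$lnL, x$kappa))
  pn <- names(x$params)
  cat("  ", paste(pn, vapply(x$params, function(p)
    paste(signif(unlist(p), 5), collapse = ","), ""),
    sep = "=", collapse = "  "), "\n")
  invisible(x)
}

clamp <- function(x, lo = -12, hi = 12) pmin(pmax(x, lo), hi)

fit_m0 <- function(ph, pi) {
  el0 <- ph$edge_length
  if (is.null(el0) || any(!is.finite(el0))) el0 <- rep(0.2, nrow(ph$edge))
  el0 <- pmax(el0, 1e-3)
  par0 <- c(log(2), log(0.3), log(el0))
  obj <- function(par) {
    par <- clamp(par)
    kappa <- exp(par[1]); omega <- exp(par[2]); el <- exp(par[-(1:2)])
    cl <- data.frame(omega = omega, weight = 1)
    -mix_loglik(site_loglik(ph, pi, kappa, cl, edge_length = el), 1)
  }
  opt <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-9))
  par <- clamp(opt$par)
  list(lnL = -opt$value,
       params = list(omega = exp(par[2])),
       kappa = exp(par[1]),
       converged = opt$convergence == 0,
       starts = 1L, edge_length = exp(par[-(1:2)]))
}

fit_mixture <- function(ph, pi, model, ncat, starts, m0, m7 = NULL) {
  ph$edge_length <- m0$edge_length
  make_obj <- function(model) {
    function(par) {
      par <- clamp(par)
      pars <- decode_pars(model, par)
      cl <- site_class_table(model, pars$pars, ncat)
      -mix_loglik(site_loglik(ph, pi, pars$kappa, cl), cl$weight)
    }
  }
  obj <- make_obj(model)
  lk0 <- log(m0$kappa)
  start_list <- switch(model,
    M3 = list(c(lk0, log(c(0.05, 0.3, 1.2)), 0, 0),
              c(lk0, log(rep(m0$params$omega, 3) * c(0.99, 1, 1.01)), 0, 0),
              c(lk0, log(c(0.01, 0.1, 0.8)), 1, -1)),
    M7 = list(c(lk0, log(0.5), log(1.5)),
              c(lk0, log(1), log(4)),
              c(lk0, log(0.2), log(0.8))),
    M8 = list(c(lk0, 2, log(0.5), log(1.5), log(1)),
              c(lk0, 3, log(1), log(4), log(0.3)),
              c(lk0, 1, log(0.3), log(1), log(4)))
  )
  start_list <- start_list[seq_len(min(starts, length(start_list)))]
  if (model == "M8" && !is.null(m7)) {
    # near-null start at the M7 optimum (p0 -> 1, omega_s -> 1) so the M8
    # maximum can never fall below M7's (nesting); replaces one generic start
    start_list <- c(start_list[seq_len(max(1L, length(start_list) - 1L))],
                    list(c(log(m7$kappa), 6.9, log(m7$params$p),
                           log(m7$params$q), log(1e-3))))
  }
  best <- NULL
  for (s in start_list) {
    opt <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-8))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  par <- clamp(best$par)
  dec <- decode_pars(model, par)
  list(lnL = -best$value, params = dec$pars, kappa = dec$kappa,
       converged = best$convergence == 0, starts = length(start_list))
}

decode_pars <- function(model, par) {
  kappa <- exp(par[1])
  rest <- par[-1]
  pars <- switch(model,
    M3 = {
      om <- exp(rest[1:3])
      w <- exp(c(rest[4:5], 0))
      w <- w / sum(w)
      ord <- order(om)
      list(omegas = om[ord], weights = w[ord])
    },
    M7 = list(p = exp(rest[1]), q = exp(rest[2])),
    M8 = list(p0 = 1 / (1 + exp(-rest[1])), p = exp(rest[2]),
              q = exp(rest[3]), omega_s = 1 + exp(rest[4]))
  )
  list(kappa = kappa, pars = pars)
}

# ---- LRT ----

#' Likelihood-ratio test between nested site models
#'
#' `2 * (alt - null)` clipped at zero (optimizer noise can leave a tiny
#' negative difference), compared to the chi-squared upper tail with `df`
#' degrees of freedom, with Bonferroni-adjusted significance over a declared
#' family of comparisons. The M0-vs-M3 comparison conventionally uses df = 4
#' (three omega classes add two omegas and two free proportions); M7-vs-M8
#' uses df = 2.
#'
#' @param null_lnl,alt_lnl Log-likelihoods of the null and alternative fits
#'   (or `site_model_fit` objects).
#' @param df Degrees of freedom (>= 1).
#' @param n_comparisons Bonferroni family size; default 1.
#' @return List with `statistic`, `df`, `p_value`, `significant_5`,
#'   `significant_1` (Bonferroni-adjusted at 5% and 1%).
#' @examples
#' lrt(0, 18.7153 / 2, df = 2)$p_value # 8.63e-05
#' @export
lrt <- function(null_lnl, alt_lnl, df, n_comparisons = 1L) {
  if (inherits(null_lnl, "site_model_fit")) null_lnl <- null_lnl$lnL
  if (inherits(alt_lnl, "site_model_fit")) alt_lnl <- alt_lnl$lnL
  if (!is.numeric(df) || df < 1) stop("df must be >= 1")
  stat <- max(0, 2 * (alt_lnl - null_lnl))
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p,
       significant_5 = p < 0.05 / n_comparisons,
       significant_1 = p < 0.01 / n_comparisons)
}

# ---- BEB ----

#' Bayes empirical Bayes positively selected sites under M8
#'
#' Per-site posterior probability of membership in the selected (omega >= 1)
#' class, integrating over a discrete uniform prior grid on
#' (p0, p, q, omega_s) rather than plugging in the MLEs, per the standard
#' Bayes-empirical-Bayes construction. Branch lengths, kappa, codon
#' frequencies and the overall rate scale are fixed at the M8 MLEs. Sites
#' with posterior >= 0.95 are flagged as positively selected (PSS).
#'
#' @param m8_fit A converged `site_model_fit` with `model == "M8"`.
#' @param grid Points per grid dimension (default 10).
#' @param ncat Beta categories per grid point (default 10).
#' @return Data frame with `site`, `posterior`, `pss`.
#' @export
beb_sites <- function(m8_fit, grid = 10L, ncat = 10L) {
  stopifnot(inherits(m8_fit, "site_model_fit"))
  if (m8_fit$model != "M8") stop("beb_sites needs an M8 fit")
  if (!isTRUE(m8_fit$converged)) {
    stop("M8 fit did not converge; refit before BEB")
  }
  ph <- prep_phylo(m8_fit$aln, m8_fit$tree)
  ph$edge_length <- m8_fit$edge_length
  pi <- m8_fit$pi
  kappa <- m8_fit$kappa
  rbar_fix <- gy94_scale(pi, kappa, m8_fit$classes$omega,
                         m8_fit$classes$weight)

  p0_grid <- (2 * seq_len(grid) - 1) / (2 * grid)
  p_grid <- exp(seq(log(0.05), log(5), length.out = grid))
  q_grid <- exp(seq(log(0.05), log(20), length.out = grid))
  ws_grid <- 1 + (2 * seq_len(grid) - 1) / (2 * grid) * 10

  # log site likelihoods at the selected-class omegas (shared across p,q)
  one <- function(omegas) {
    cl <- data.frame(omega = omegas, weight = rep(1 / length(omegas),
                                                  length(omegas)))
    site_loglik(ph, pi, kappa, cl, rbar = rbar_fix)
  }
  logF_sel <- one(ws_grid) # nsites x grid

  nsites <- ncol(m8_fit$aln)
  n_theta <- grid^3 * grid
  loglik_theta <- numeric(0)
  theta_idx <- list()
  log_mean_bins <- vector("list", grid * grid) # per (p,q)
  pqi <- 0L
  for (ip in seq_len(grid)) {
    for (iq in seq_len(grid)) {
      pqi <- pqi + 1L
      logF_bins <- one(discretize_beta(p_grid[ip], q_grid[iq], ncat))
      mx <- apply(logF_bins, 1, max)
      lmb <- mx + log(rowMeans(exp(logF_bins - mx)))
      log_mean_bins[[pqi]] <- lmb
      for (i0 in seq_len(grid)) {
        for (iw in seq_len(grid)) {
          p0 <- p0_grid[i0]
          lsel <- logF_sel[, iw]
          m <- pmax(lmb, lsel)
          lh <- m + log(p0 * exp(lmb - m) + (1 - p0) * exp(lsel - m))
          loglik_theta <- c(loglik_theta, sum(lh))
          theta_idx[[length(theta_idx) + 1L]] <- c(pqi, i0, iw)
        }
      }
    }
  }
  lw <- loglik_theta - max(loglik_theta)
  post_theta <- exp(lw) / sum(exp(lw))

  post_site <- numeric(nsites)
  for (t in seq_along(post_theta)) {
    if (post_theta[t] < 1e-12) next
    ti <- theta_idx[[t]]
    lmb <- log_mean_bins[[ti[1]]]
    p0 <- p0_grid[ti[2]]
    lsel <- logF_sel[, ti[3]]
    m <- pmax(lmb, lsel)
    denom <- p0 * exp(lmb - m) + (1 - p0) * exp(lsel - m)
    post_site <- post_site +
      post_theta[t] * ((1 - p0) * exp(lsel - m)) / denom
  }
  data.frame(site = seq_len(nsites), posterior = post_site,
             pss = post_site >= 0.95)
}

#' Run the full M0/M3/M7/M8 site-model test battery
#'
#' Fits all four models (branch lengths from M0), performs the M0-vs-M3 and
#' M7-vs-M8 LRTs, and runs BEB site detection on the M8 fit.
#'
#' @param aln A [codon_alignment()].
#' @param tree `phylo` tree matching the alignment.
#' @param df_m0m3,df_m7m8 LRT degrees of freedom (defaults 4 and 2).
#' @param n_comparisons Bonferroni family size for both tests.
#' @param ... Passed to [fit_site_model()].
#' @return List with the four fits, `lrt_m0m3`, `lrt_m7m8`, and `beb`.
#' @export
site_model_tests <- function(aln, tree, df_m0m3 = 4L, df_m7m8 = 2L,
                             n_comparisons = 1L, ...) {
  m0 <- fit_site_model(aln, tree, "M0", ...)
  m3 <- fit_site_model(aln, tree, "M3", m0 = m0, ...)
  m7 <- fit_site_model(aln, tree, "M7", m0 = m0, ...)
  m8 <- fit_site_model(aln, tree, "M8", m0 = m0, m7 = m7, ...)
  list(
    m0 = m0, m3 = m3, m7 = m7, m8 = m8,
    lrt_m0m3 = lrt(m0, m3, df = df_m0m3, n_comparisons = n_comparisons),
    lrt_m7m8 = lrt(m7, m8, df = df_m7m8, n_comparisons = n_comparisons),
    beb = beb_sites(m8)
  )
}
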
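# Maximum-likelihood fitting of the branch-class codon model: all branch
# lengths, a shared kappa, and one omega per branch class, with stationary
# frequencies fixed at their empirical F3x4 estimates. Bounded quasi-Newton
# on log-transformed parameters with deterministic multi-start.

.fit_bounds <- list(t = c(1e-6, 20), kappa = c(0.05, 100), omega = c(1e-6, 50))
.fit_start <- c(t = 0.1, kappa = 2, omega = 0.4)

# run expr with a private RNG stream, leaving the caller's untouched
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# shared objective plumbing: returns function(par) -> negative logL using the
# compiled pruning kernel, par = c(log t[1..E], log kappa, log omega[classes])
make_negloglik <- function(aln, tree, pi) {
  pat <- site_patterns(aln, tree$tip.label)
  po <- tree_edges_postorder(tree)
  classes <- sort(unique(tree$omega_class))
  class_idx <- match(tree$omega_class, classes)[po$perm]
  states <- pat$states
  states[is.na(states)] <- 0L
  msk <- list(single = .code("single_step") * 1,
              ts = .code("is_transition") * 1,
              syn = .code("is_synonymous") * 1)
  E <- length(po$parent)
  K <- length(classes)
  fn <- function(par) {
    tlen <- exp(par[1:E])
    kappa <- exp(par[E + 1])
    omg <- exp(par[E + 1 + seq_len(K)])
    ll <- cpp_loglik(pi, kappa, omg[class_idx], tlen,
                     po$parent, po$child, po$n_tips, po$n_nodes,
                     states, pat$weights, msk$single, msk$ts, msk$syn)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  list(fn = fn, E = E, K = K, classes = classes, po = po)
}

#' Fit the branch-class codon model by maximum likelihood
#'
#' Maximises the pruning log-likelihood over all branch lengths, a shared
#' transition/transversion ratio kappa, and one dN/dS per branch class, with
#' codon frequencies fixed at the alignment's F3x4 estimates. Optimisation
#' uses L-BFGS-B on log-transformed parameters with `n_restarts`
#' deterministically jittered starting points.
#'
#' @param aln A [codon_alignment()] containing a sequence for every tip of
#'   the tree (the six roles C, D, M1, M2, R1, R2 for the default tree).
#' @param tree Tree shape with `omega_class` edge labels; defaults to the
#'   [sextuplet_tree()] with all starting branch lengths at 0.1.
#' @param codon_freqs `"F3x4"` (default) or an explicit 61-vector.
#' @param n_restarts Number of optimisation starts (>= 1).
#' @param control Optimiser settings: `maxit`, `factr` (see
#'   [stats::optim()]), and `jitter_sd` (log-scale SD of restart jitter).
#' @return An object of class `branch_fit`: fitted `params` and `tree`,
#'   `log_likelihood`, `per_branch_dnds` (data.frame with one row per branch:
#'   branch, class, t, dn, ds), `converged`, `n_restarts_used`, and
#'   `at_bound` flags for omegas that ended on a box bound.
#' @export
fit_branch_model <- function(aln, tree = NULL, codon_freqs = "F3x4",
                             n_restarts = 3,
                             control = list(maxit = 500, factr = 1e7,
                                            jitter_sd = 0.5)) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(tree))
    tree <- sextuplet_tree(stats::setNames(rep(.fit_start[["t"]], 9),
                                           c("M1", "R1", "M2", "R2", "C", "D",
                                             "n1", "n2", "n3")))
  pi <- if (identical(codon_freqs, "F3x4")) f3x4_frequencies(aln)
        else { stopifnot(length(codon_freqs) == 61); codon_freqs / sum(codon_freqs) }
  obj <- make_negloglik(aln, tree, pi)
  E <- obj$E; K <- obj$K
  lower <- log(c(rep(.fit_bounds$t[1], E), .fit_bounds$kappa[1],
                 rep(.fit_bounds$omega[1], K)))
  upper <- log(c(rep(.fit_bounds$t[2], E), .fit_bounds$kappa[2],
                 rep(.fit_bounds$omega[2], K)))
  base_start <- log(c(rep(.fit_start[["t"]], E), .fit_start[["kappa"]],
                      rep(.fit_start[["omega"]], K)))
  starts <- with_private_seed(20140728, {
    lapply(seq_len(n_restarts), function(r) {
      if (r == 1) base_start
      else pmin(pmax(base_start + stats::rnorm(E + 1 + K, 0,
                                               control$jitter_sd %||% 0.5),
                     lower), upper)
    })
  })
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, obj$fn, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = control$maxit %||% 500,
                                  factr = control$factr %||% 1e7)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop("optimisation failed in every restart")
  par <- best$par
  tlen <- exp(par[1:E])
  kappa <- exp(par[E + 1])
  omg <- stats::setNames(exp(par[E + 1 + seq_len(K)]), obj$classes)
  at_bound <- omg <= .fit_bounds$omega[1] * 1.0001 |
              omg >= .fit_bounds$omega[2] * 0.9999
  params <- codon_model_params(kappa = kappa, omega_by_class = omg,
                               codon_freqs = pi)
  # write fitted lengths back in original edge order
  fitted_len <- numeric(E)
  fitted_len[obj$po$perm] <- tlen
  tree$edge.length <- fitted_len
  dnds <- t(vapply(seq_len(E), function(e) {
    dn_ds_from_branch(fitted_len[e], omg[[tree$omega_class[e]]], params)
  }, numeric(2)))
  per_branch <- data.frame(
    branch = if (!is.null(tree$edge_name)) tree$edge_name
             else node_names(tree)[tree$edge[, 2]],
    class = tree$omega_class, t = fitted_len,
    dn = dnds[, 1], ds = dnds[, 2], stringsAsFactors = FALSE)
  structure(list(params = params, tree = tree,
                 log_likelihood = -best$value,
                 per_branch_dnds = per_branch,
                 converged = best$convergence == 0,
                 n_restarts_used = length(starts),
                 at_bound = at_bound),
            class = "branch_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.branch_fit <- function(x, ...) {
  cat(sprintf("Branch-class codon model fit: logL = %.4f (%s)\n",
              x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  kappa = %.4g\n", x$params$kappa))
  for (cl in names(x$params$omega_by_class))
    cat(sprintf("  omega[%s] = %.4g%s\n", cl, x$params$omega_by_class[[cl]],
                if (isTRUE(x$at_bound[[cl]])) " (at bound)" else ""))
  invisible(x)
}

# gap-free pattern pairs of two codon sequences
pair_patterns <- function(a, b, labels = c("a", "b")) {
  aln <- codon_alignment(stats::setNames(c(a, b), labels))
  ia <- aln$index[1, ]; ib <- aln$index[2, ]
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stop("no gap-free codon columns shared by the pair")
  key <- paste(ia[ok], ib[ok])
  uk <- unique(key)
  first <- match(uk, key)
  list(sa = ia[ok][first], sb = ib[ok][first],
       w = as.numeric(table(key)[uk]), aln = aln, n_used = sum(ok))
}

#' Pairwise dN/dS by maximum likelihood
#'
#' Fits (t, kappa, omega) on a two-taxon tree under the GY-style model with
#' empirical F3x4 frequencies, then decomposes the fitted divergence into dN
#' and dS via [dn_ds_from_branch()]. Identical sequences return dn = ds = 0
#' with omega undefined (`NA`), as do pairs with no synonymous divergence.
#'
#' @param a,b Nucleotide sequence strings (equal length, in frame), or a
#'   2-sequence [codon_alignment()] as `a`.
#' @param pair Labels for the two sequences.
#' @return Object of class `pairwise_dnds`: `pair`, `dn`, `ds`, `omega`
#'   (NA when ds = 0), `t`, `kappa`, `log_likelihood`, `method = "ML"`.
#' @export
pairwise_dnds_ml <- function(a, b = NULL, pair = c("a", "b")) {
  if (inherits(a, "codon_alignment")) {
    stopifnot(length(a$labels) == 2)
    pair <- a$labels
    b <- a$sequences[[2]]; a <- a$sequences[[1]]
  }
  pp <- pair_patterns(a, b, pair)
  pi <- f3x4_frequencies(pp$aln)
  if (all(pp$sa == pp$sb)) {
    return(structure(list(pair = pair, dn = 0, ds = 0, omega = NA_real_,
                          t = 0, kappa = NA_real_, log_likelihood = NA_real_,
                          n_codons = pp$n_used, method = "ML",
                          saturated = FALSE),
                     class = "pairwise_dnds"))
  }
  msk <- list(single = .code("single_step") * 1,
              ts = .code("is_transition") * 1,
              syn = .code("is_synonymous") * 1)
  fn <- function(par) {
    ll <- cpp_pair_loglik(pi, exp(par[2]), exp(par[3]), exp(par[1]),
                          pp$sa, pp$sb, pp$w, msk$single, msk$ts, msk$syn)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  lower <- log(c(.fit_bounds$t[1], .fit_bounds$kappa[1], .fit_bounds$omega[1]))
  upper <- log(c(.fit_bounds$t[2], .fit_bounds$kappa[2], .fit_bounds$omega[2]))
  res <- stats::optim(log(c(0.1, 2, 0.4)), fn, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e7))
  t_hat <- exp(res$par[1]); kappa <- exp(res$par[2]); omega <- exp(res$par[3])
  params <- codon_model_params(kappa = kappa, omega_by_class = omega,
                               codon_freqs = pi)
  dnds <- dn_ds_from_branch(t_hat, omega, params)
  ds <- dnds[["ds"]]
  structure(list(pair = pair, dn = dnds[["dn"]], ds = ds,
                 omega = if (ds > 0) omega else NA_real_,
                 t = t_hat, kappa = kappa, log_likelihood = -res$value,
                 n_codons = pp$n_used, method = "ML", saturated = FALSE),
            class = "pairwise_dnds")
}

#' @export
print.pairwise_dnds <- function(x, ...) {
  cat(sprintf("%s dN/dS for %s-%s: dn = %.4g, ds = %.4g, omega = %s%s\n",
              x$method, x$pair[1], x$pair[2], x$dn, x$ds,
              if (is.na(x$omega)) "undefined" else sprintf("%.4g", x$omega),
              if (isTRUE(x$saturated)) " [saturated]" else ""))
  invisible(x)
}
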
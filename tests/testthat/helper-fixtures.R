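# Shared fixtures: small trees with omega-class edge labels, random model
# draws, and an enumeration oracle for the pruning likelihood.

# a phylo from newick with one omega class for every edge
make_class_tree <- function(newick, class = "preD") {
  tr <- ape::read.tree(text = newick)
  tr$omega_class <- rep(class, nrow(tr$edge))
  tr
}

# random-but-reproducible model parameters; non-uniform pi available
random_params <- function(seed, uniform_pi = TRUE) {
  set.seed(seed)
  pi <- if (uniform_pi) rep(1 / 61, 61) else {
    w <- stats::runif(61, 0.2, 1.8)
    w / sum(w)
  }
  codon_model_params(kappa = stats::runif(1, 0.5, 6),
                     omega_by_class = c(preD = stats::runif(1, 0.05, 2)),
                     codon_freqs = pi)
}

# random gap-free codon alignment over given labels (not simulated from the
# model; any distribution works for likelihood-identity checks)
random_alignment <- function(labels, n_codons, seed) {
  set.seed(seed)
  seqs <- vapply(labels, function(l) {
    paste(sense_codons()[sample.int(61, n_codons, replace = TRUE)],
          collapse = "")
  }, character(1))
  codon_alignment(seqs)
}

# Brute-force likelihood: sum over all assignments of codon states to the
# internal nodes, multiplying pi at the root and P(t) along every edge.
# Independent of the pruning code path.
enumeration_loglik <- function(aln, tree, params) {
  n_tips <- ape::Ntip(tree)
  n_int <- tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
    om <- params$omega_by_class[[tree$omega_class[e]]]
    transition_probabilities(build_rate_matrix(params, om),
                             tree$edge.length[e], params$codon_freqs)
  })
  root <- n_tips + 1L
  states <- aln$index[tree$tip.label, , drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(1:61), n_int)))
  total <- 0
  for (col in seq_len(ncol(states))) {
    lik <- params$codon_freqs[grid[, 1]]      # root = first internal node
    for (e in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      pa_state <- grid[, pa - n_tips]
      if (ch <= n_tips) {
        s <- states[ch, col]
        if (!is.na(s)) lik <- lik * Ps[[e]][cbind(pa_state, s)]
      } else {
        lik <- lik * Ps[[e]][cbind(pa_state, grid[, ch - n_tips])]
      }
    }
    total <- total + log(sum(lik))
  }
  total
}

# a hand-built branch_fit-like object for delta arithmetic tests
fake_branch_fit <- function(omega, branch_ds = NULL, kappa = 2) {
  params <- codon_model_params(kappa = kappa, omega_by_class = omega)
  bl <- c(M1 = .1, R1 = .1, M2 = .1, R2 = .1, C = .15, D = .15,
          n1 = .05, n2 = .05, n3 = .05)
  tr <- sextuplet_tree(bl)
  per_branch <- data.frame(branch = tr$edge_name, class = tr$omega_class,
                           t = tr$edge.length, stringsAsFactors = FALSE)
  dnds <- t(vapply(seq_len(nrow(per_branch)), function(e)
    dn_ds_from_branch(per_branch$t[e], omega[[per_branch$class[e]]], params),
    numeric(2)))
  per_branch$dn <- dnds[, 1]
  per_branch$ds <- if (is.null(branch_ds)) dnds[, 2] else
    unname(branch_ds[per_branch$branch])
  structure(list(params = params, tree = tr, log_likelihood = -1,
                 per_branch_dnds = per_branch, converged = TRUE,
                 n_restarts_used = 1, at_bound = rep(FALSE, 5)),
            class = "branch_fit")
}

fake_pairwise <- function(omega, ds = 0.2, pair = c("a", "b")) {
  structure(list(pair = pair, dn = omega * ds, ds = ds, omega = omega,
                 t = NA_real_, kappa = 2, log_likelihood = NA_real_,
                 n_codons = 100L, method = "ML", saturated = FALSE),
            class = "pairwise_dnds")
}
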
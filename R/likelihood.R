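# Phylogenetic likelihood of a codon alignment under the branch-class model,
# by Felsenstein pruning over the 61 sense-codon states. Gap codons contribute
# an all-ones partial likelihood (missing data). The model is reversible, so
# the likelihood does not depend on where the pruning is rooted.

# Collapse alignment columns to unique site patterns. Returns a tips x
# n_patterns integer matrix (NA = gap) and pattern weights.
site_patterns <- function(aln, tip_labels) {
  missing_tips <- setdiff(tip_labels, aln$labels)
  if (length(missing_tips))
    stop("alignment lacks sequences for tree tips: ",
         paste(missing_tips, collapse = ", "))
  idx <- aln$index[tip_labels, , drop = FALSE]
  key <- apply(idx, 2, paste, collapse = ",")
  uk <- unique(key)
  pat <- idx[, match(uk, key), drop = FALSE]
  list(states = pat, weights = as.numeric(table(key)[uk]),
       column_pattern = match(key, uk))
}

#' Log-likelihood of a codon alignment on a tree
#'
#' Computes the pruning log-likelihood of an in-frame codon alignment under
#' the GY-style model with one dN/dS class per branch. Columns are collapsed
#' to unique patterns; gap codons are treated as missing data.
#'
#' @param aln A [codon_alignment()] whose labels cover the tree's tips.
#' @param tree A [sextuplet_tree()], or any `ape::phylo` carrying an
#'   `omega_class` character vector parallel to its edges.
#' @param params A [codon_model_params()] supplying kappa, the per-class
#'   omegas (every class used on the tree must be present) and the stationary
#'   codon frequencies.
#' @param per_column If `TRUE`, also return the per-column log-likelihoods.
#' @return The total log-likelihood (a single number), or a list with
#'   elements `log_likelihood` and `by_column` when `per_column = TRUE`.
#' @export
codon_log_likelihood <- function(aln, tree, params, per_column = FALSE) {
  stopifnot(inherits(aln, "codon_alignment"),
            inherits(tree, "phylo"),
            inherits(params, "codon_model_params"))
  if (is.null(tree$omega_class) || length(tree$omega_class) != nrow(tree$edge))
    stop("tree must carry one omega_class label per edge")
  miss <- setdiff(unique(tree$omega_class), names(params$omega_by_class))
  if (length(miss))
    stop("params lack omega for class(es): ", paste(miss, collapse = ", "))
  pat <- site_patterns(aln, tree$tip.label)
  omega_edge <- as.numeric(params$omega_by_class[tree$omega_class])
  colL <- prune_columns(pat$states, tree, tree$edge.length, omega_edge, params)
  total <- sum(colL * pat$weights)
  if (!is.finite(total)) stop("non-finite log-likelihood")
  if (per_column) {
    list(log_likelihood = total, by_column = colL[pat$column_pattern])
  } else total
}

# per-pattern log-likelihoods; omega_edge ordered as tree$edge rows
prune_columns <- function(states, tree, edge_length, omega_edge, params) {
  po <- tree_edges_postorder(tree)
  pi <- params$codon_freqs
  Pcache <- vector("list", length(po$parent))
  for (e in seq_along(po$parent)) {
    orig <- po$perm[e]
    Q <- build_rate_matrix(params, omega_edge[orig])
    Pcache[[e]] <- transition_probabilities(Q, edge_length[orig], pi)
  }
  npat <- ncol(states)
  partial <- vector("list", po$n_nodes)
  for (nd in (po$n_tips + 1L):po$n_nodes) partial[[nd]] <- matrix(1, 61, npat)
  scale_log <- rep(0, npat)
  for (e in seq_along(po$parent)) {
    ch <- po$child[e]
    P <- Pcache[[e]]
    if (ch <= po$n_tips) {
      s <- states[ch, ]
      up <- matrix(1, 61, npat)
      obs <- !is.na(s)
      up[, obs] <- P[, s[obs], drop = FALSE]
    } else {
      L <- partial[[ch]]
      m <- apply(L, 2, max)
      keep <- m > 0
      L[, keep] <- L[, keep, drop = FALSE] / rep(m[keep], each = 61)
      scale_log <- scale_log + ifelse(keep, log(m), -Inf)
      up <- P %*% L
    }
    partial[[po$parent[e]]] <- partial[[po$parent[e]]] * up
  }
  root <- partial[[po$root]]
  log(colSums(pi * root)) + scale_log
}
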
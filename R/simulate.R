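# Codon-sequence simulation along the sextuplet topology with branch-class
# dN/dS regimes, plus the labelled fixtures (multi-duplication families,
# gene-conversion tracts, homology and synteny tables) that the downstream
# stages are validated against. Every generator is seed-deterministic and
# returns machine-readable truth.

#' Default simulation scenario of the sextuplet design
#'
#' Builds a fully specified scenario: the sextuplet tree with branch lengths
#' derived from synonymous-divergence targets, and the true model parameters.
#' The default regime mirrors the headline pattern the analysis is designed
#' to detect: constrained preduplication evolution (omega 0.10), a shared
#' initial postduplication acceleration (omega 0.40 on both internal
#' branches), a copy that stays fast (rpostD1 = 0.25) and a copy that has
#' returned to the preduplication rate (rpostD2 = 0.10), with a paralog
#' synonymous depth of about 0.3. Under these values the true
#' delta_f = 0.15 and delta_s = 0.
#'
#' @param n_codons Number of codon columns to simulate.
#' @param seed Integer seed; fully determines the simulated alignment.
#' @param omega Named numeric of the five true class omegas.
#' @param kappa True transition/transversion ratio.
#' @param paralog_ds Target synonymous divergence between the two paralogs
#'   (summed along the M1-M2 path); recent terminal and initial internal
#'   branches receive 2/3 and 1/3 of it, split evenly.
#' @param outgroup_ds Synonymous depth of each of the C and D branches.
#' @param stem_ds Synonymous depth of the n3-n4 stem branch.
#' @param codon_freqs Stationary codon frequencies (default uniform).
#' @param lineage_tag Cohort label carried into downstream records.
#' @return Object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_codons = 500, seed = 1,
                                omega = c(preD = 0.10, ipostD1 = 0.40,
                                          ipostD2 = 0.40, rpostD1 = 0.25,
                                          rpostD2 = 0.10),
                                kappa = 2.5,
                                paralog_ds = 0.3,
                                outgroup_ds = 0.15,
                                stem_ds = 0.05,
                                codon_freqs = rep(1 / 61, 61),
                                lineage_tag = "synthetic") {
  params <- codon_model_params(kappa = kappa, omega_by_class = omega,
                               codon_freqs = codon_freqs)
  term_ds <- paralog_ds / 3      # each of M1, R1, M2, R2
  int_ds <- paralog_ds / 6       # each of n1, n2
  ds_target <- c(M1 = term_ds, R1 = term_ds, M2 = term_ds, R2 = term_ds,
                 C = outgroup_ds, D = outgroup_ds,
                 n1 = int_ds, n2 = int_ds, n3 = stem_ds)
  bl <- vapply(names(ds_target), function(br) {
    branch_length_for_ds(ds_target[[br]], omega[[class_of_branch(br)]], params)
  }, numeric(1))
  structure(list(tree = sextuplet_tree(bl), params = params,
                 n_codons = as.integer(n_codons), seed = as.integer(seed),
                 branch_ds = ds_target,
                 lineage_tag = lineage_tag),
            class = "simulation_scenario")
}

# simulate child states from parent states through P (vectorised by parent state)
.evolve <- function(parent_states, P) {
  out <- integer(length(parent_states))
  for (s in unique(parent_states)) {
    sel <- parent_states == s
    out[sel] <- sample.int(61, sum(sel), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate a sextuplet codon alignment
#'
#' Draws the root codon states from the stationary frequencies and evolves
#' them along each branch of the scenario's tree by sampling from the
#' branch's transition probabilities under its class omega. The simulation is
#' rooted at the C/D junction n4; by reversibility of the model the rooting
#' choice does not affect the distribution of the tips.
#'
#' @param scenario A [simulation_scenario()].
#' @return A list: `alignment` (the six-tip [codon_alignment()]) and `truth`
#'   (the scenario, with true delta values under `truth$delta`).
#' @export
simulate_sextuplet <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  tr <- scenario$tree; params <- scenario$params
  with_private_seed(scenario$seed, {
    po <- tree_edges_postorder(tr)
    states <- vector("list", po$n_nodes)
    states[[po$root]] <- sample.int(61, scenario$n_codons, replace = TRUE,
                                    prob = params$codon_freqs)
    # preorder: reverse postorder edge sweep
    for (e in rev(seq_along(po$parent))) {
      orig <- po$perm[e]
      Q <- build_rate_matrix(params,
                             params$omega_by_class[[tr$omega_class[orig]]])
      P <- transition_probabilities(Q, tr$edge.length[orig], params$codon_freqs)
      states[[po$child[e]]] <- .evolve(states[[po$parent[e]]], P)
    }
    seqs <- vapply(seq_len(po$n_tips), function(i) codons_to_string(states[[i]]),
                   character(1))
    names(seqs) <- tr$tip.label
    omg <- scenario$params$omega_by_class
    truth <- scenario
    truth$delta <- c(
      delta_f = max(omg[["rpostD1"]], omg[["rpostD2"]]) - omg[["preD"]],
      delta_s = min(omg[["rpostD1"]], omg[["rpostD2"]]) - omg[["preD"]])
    list(alignment = codon_alignment(seqs), truth = truth)
  })
}

#' Simulate a multi-duplication gene family
#'
#' Generates paralogous sequences related by a ladder of nested duplications
#' at the given synonymous depths (smallest = most recent), in one species,
#' as a fixture for family decomposition. Sequences evolve under a single
#' omega regime.
#'
#' @param n_paralogs Number of paralogs (>= 2).
#' @param depths Strictly increasing synonymous depths of the
#'   `n_paralogs - 1` duplication events, most recent first.
#' @param n_codons Codon columns.
#' @param seed Integer seed.
#' @param omega,kappa Model parameters of the family.
#' @return List: `sequences` (named character vector `p1..pk`), `depths`,
#'   `first_pair` (the most recent pair, `c("p1", "p2")`), and `new_member`
#'   (per duplication event, most recent first, the paralog that arose at
#'   that event: the decomposed set of rank r must contain `new_member[r]`;
#'   its partner depends on the random removals).
#' @export
simulate_family <- function(n_paralogs, depths, n_codons = 300, seed = 1,
                            omega = 0.2, kappa = 2.5) {
  stopifnot(n_paralogs >= 2, length(depths) == n_paralogs - 1)
  if (any(diff(depths) <= 0) || anyDuplicated(depths))
    stop("duplication depths must be strictly increasing and distinct")
  params <- codon_model_params(kappa = kappa, omega_by_class = omega)
  with_private_seed(seed, {
    # ladder: the ancestor duplicates at depth[k-1] (deepest) first; the pair
    # (p1, p2) splits last at depths[1]
    pi <- params$codon_freqs
    Q <- build_rate_matrix(params, omega)
    t_of_ds <- function(ds) branch_length_for_ds(ds, omega, params)
    k <- n_paralogs
    root <- sample.int(61, n_codons, replace = TRUE, prob = pi)
    # node at depth d carries the ancestral state of everything younger
    anc <- root
    seqs <- vector("list", k)
    for (ev in rev(seq_len(k - 1))) {          # deepest duplication first
      d <- depths[ev]
      child_d <- if (ev > 1) depths[ev - 1] else 0
      # branch from this duplication node down to paralog p_{ev+1} (tip)
      P_tip <- transition_probabilities(Q, t_of_ds(d), pi)
      seqs[[ev + 1]] <- .evolve(anc, P_tip)
      # branch continuing toward the next (more recent) duplication node
      P_cont <- transition_probabilities(Q, t_of_ds(d - child_d), pi)
      anc <- .evolve(anc, P_cont)
    }
    seqs[[1]] <- anc
    out <- vapply(seqs, codons_to_string, character(1))
    names(out) <- paste0("p", seq_len(k))
    list(sequences = out, depths = depths,
         first_pair = c("p1", "p2"),
         new_member = paste0("p", seq_len(k - 1) + 1))
  })
}

#' Apply a gene-conversion tract between within-species paralogs
#'
#' Replaces the acceptor's codons over a half-open codon-column interval by
#' the donor's, modelling a complete conversion tract - the strongest version
#' of the homogenising signal the paralog-divergence diagnostic screens for.
#'
#' @param aln A [codon_alignment()].
#' @param donor,acceptor Labels of within-species paralogs (M1/M2 or R1/R2,
#'   or any `p*` pair of a family fixture).
#' @param tract Half-open codon interval `c(start, end)`, 0-based.
#' @return The modified [codon_alignment()].
#' @export
apply_gene_conversion <- function(aln, donor, acceptor, tract) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!donor %in% aln$labels || !acceptor %in% aln$labels)
    stop("donor and acceptor must be alignment labels")
  strip <- function(x) sub("[0-9]+$", "", x)
  if (donor == acceptor || strip(donor) != strip(acceptor))
    stop("donor and acceptor must be distinct within-species paralogs")
  start <- tract[1]; end <- tract[2]
  if (start < 0 || end > aln$n_codons || start > end)
    stop("tract must satisfy 0 <= start <= end <= n_codons")
  if (end > start) {
    cols <- (start + 1):end
    aln$index[acceptor, cols] <- aln$index[donor, cols]
    aln$sequences[[acceptor]] <- codons_to_string(aln$index[acceptor, ])
  }
  aln
}

#' Generate a homology-table fixture
#'
#' Emits orthology relations over genomes cow, dog, mouse, rat with a known
#' number of valid sextuplet patterns (dog-cow one-to-one, dog-mouse
#' one-to-many with two mouse paralogs, each mouse gene one-to-one with a rat
#' gene) and of invalid patterns that must not yield sets (dog-cow
#' many-to-many, or a mouse paralog lacking a rat one-to-one ortholog).
#'
#' @param n_valid Number of valid sextuplet patterns.
#' @param n_invalid Number of invalid patterns.
#' @param n_paralogs Mouse paralogs per valid pattern (>= 2); families with
#'   more than two paralogs are left for decomposition.
#' @param seed Integer seed (controls identifier shuffling).
#' @return List: `table` (data.frame with columns gene_id_a, genome_a,
#'   gene_id_b, genome_b, relation) and `truth` (data.frame of planted
#'   patterns: cluster, valid, n_paralogs).
#' @export
make_homology_fixture <- function(n_valid = 10, n_invalid = 5,
                                  n_paralogs = 2, seed = 1) {
  with_private_seed(seed, {
    rows <- list(); truth <- list()
    add <- function(a, ga, b, gb, rel)
      rows[[length(rows) + 1]] <<- data.frame(
        gene_id_a = a, genome_a = ga, gene_id_b = b, genome_b = gb,
        relation = rel, stringsAsFactors = FALSE)
    for (i in seq_len(n_valid)) {
      id <- sprintf("fam%03d", i)
      dog <- paste0(id, "_dog"); cow <- paste0(id, "_cow")
      add(dog, "dog", cow, "cow", "one-to-one")
      for (p in seq_len(n_paralogs)) {
        m <- sprintf("%s_m%d", id, p); r <- sprintf("%s_r%d", id, p)
        add(dog, "dog", m, "mouse", "one-to-many")
        add(m, "mouse", r, "rat", "one-to-one")
      }
      truth[[length(truth) + 1]] <- data.frame(
        cluster = dog, valid = TRUE, n_paralogs = n_paralogs)
    }
    for (i in seq_len(n_invalid)) {
      id <- sprintf("bad%03d", i)
      dog <- paste0(id, "_dog"); cow <- paste0(id, "_cow")
      if (i %% 2 == 0) {
        # dog-cow many-to-many: no set may be emitted
        add(dog, "dog", cow, "cow", "many-to-many")
        for (p in 1:2) {
          m <- sprintf("%s_m%d", id, p); r <- sprintf("%s_r%d", id, p)
          add(dog, "dog", m, "mouse", "one-to-many")
          add(m, "mouse", r, "rat", "one-to-one")
        }
      } else {
        # one mouse paralog lacks a one-to-one rat ortholog
        add(dog, "dog", cow, "cow", "one-to-one")
        add(dog, "dog", paste0(id, "_m1"), "mouse", "one-to-many")
        add(paste0(id, "_m1"), "mouse", paste0(id, "_r1"), "rat", "one-to-one")
        add(dog, "dog", paste0(id, "_m2"), "mouse", "one-to-many")
        add(paste0(id, "_m2"), "mouse", paste0(id, "_r2"), "rat", "one-to-many")
      }
      truth[[length(truth) + 1]] <- data.frame(
        cluster = dog, valid = FALSE, n_paralogs = 2L)
    }
    tab <- do.call(rbind, rows)
    tab <- tab[sample.int(nrow(tab)), ]
    rownames(tab) <- NULL
    list(table = tab, truth = do.call(rbind, truth))
  })
}

#' Generate a synteny-table fixture
#'
#' For each planted duplication, the original copy's flanking neighbours are
#' orthologs of the dog gene's neighbours while the novel copy's are not.
#' Optionally plants tandem pairs (both copies adjacent in one neighbourhood)
#' and unresolvable cases (neither copy's neighbours match).
#'
#' @param n_sets Number of duplication sets.
#' @param window Neighbours recorded per side.
#' @param frac_original_first Fraction of sets (deterministically the first
#'   ones) in which copy 1 is the original.
#' @param n_tandem,n_unresolved Extra planted tandem / unresolvable sets.
#' @param seed Integer seed.
#' @return List: `synteny` (data.frame gene_id, neighbors
#'   (comma-separated, ordered)), `sets` (data.frame set_id, dog, copy1,
#'   copy2), `truth` (data.frame set_id, original ("copy1"/"copy2"/NA),
#'   tandem flag).
#' @export
make_synteny_fixture <- function(n_sets = 26, window = 3,
                                 frac_original_first = 0.5,
                                 n_tandem = 0, n_unresolved = 0, seed = 1) {
  stopifnot(window >= 1)
  with_private_seed(seed, {
    syn <- list(); sets <- list(); truth <- list()
    neigh_ids <- function(stem, n) sprintf("%s_nb%02d", stem, seq_len(n))
    total <- n_sets + n_tandem + n_unresolved
    for (i in seq_len(total)) {
      id <- sprintf("set%03d", i)
      dog <- paste0(id, "_dog")
      c1 <- paste0(id, "_copy1"); c2 <- paste0(id, "_copy2")
      dog_nb <- neigh_ids(paste0(id, "_d"), 2 * window)
      # mouse orthologs of the dog neighbours share the stem with suffix _m
      orth_nb <- paste0(dog_nb, "_m")
      decoy <- neigh_ids(paste0(id, "_x"), 2 * window)
      kind <- if (i <= n_sets) "plain" else if (i <= n_sets + n_tandem)
        "tandem" else "unresolved"
      if (kind == "plain") {
        orig_first <- i <= round(frac_original_first * n_sets)
        orig <- if (orig_first) c1 else c2
        nov <- if (orig_first) c2 else c1
        syn[[length(syn) + 1]] <- data.frame(
          gene_id = c(dog, orig, nov),
          neighbors = c(paste(dog_nb, collapse = ","),
                        paste(orth_nb, collapse = ","),
                        paste(decoy, collapse = ",")),
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          set_id = id, original = if (orig_first) "copy1" else "copy2",
          tandem = FALSE, stringsAsFactors = FALSE)
      } else if (kind == "tandem") {
        # the two copies are adjacent: each appears in the other's window
        base <- orth_nb[seq_len(2 * window - 1)]
        syn[[length(syn) + 1]] <- data.frame(
          gene_id = c(dog, c1, c2),
          neighbors = c(paste(dog_nb, collapse = ","),
                        paste(c(c2, base), collapse = ","),
                        paste(c(c1, base), collapse = ",")),
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          set_id = id, original = NA_character_, tandem = TRUE,
          stringsAsFactors = FALSE)
      } else {
        syn[[length(syn) + 1]] <- data.frame(
          gene_id = c(dog, c1, c2),
          neighbors = c(paste(dog_nb, collapse = ","),
                        paste(decoy, collapse = ","),
                        paste(neigh_ids(paste0(id, "_y"), 2 * window),
                              collapse = ",")),
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          set_id = id, original = NA_character_, tandem = FALSE,
          stringsAsFactors = FALSE)
      }
      sets[[length(sets) + 1]] <- data.frame(
        set_id = id, dog = dog, copy1 = c1, copy2 = c2,
        stringsAsFactors = FALSE)
    }
    list(synteny = do.call(rbind, syn), sets = do.call(rbind, sets),
         truth = do.call(rbind, truth))
  })
}
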
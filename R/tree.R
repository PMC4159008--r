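# The fixed six-taxon study topology (((M1,R1),(M2,R2)),C,D): one gene
# duplication shared by two sister ingroup species (roles M1/M2 and R1/R2)
# with single-copy outgroup orthologs C and D. Represented as an ape "phylo"
# with one omega-class label per edge.

sextuplet_roles <- function() c("C", "D", "M1", "M2", "R1", "R2")

#' Construct the sextuplet tree
#'
#' Builds the fixed topology `(((M1,R1),(M2,R2)),C,D)` with internal nodes
#' n1 = (M1,R1) ancestor, n2 = (M2,R2) ancestor, n3 = duplication node and
#' n4 = the C/D junction (the trifurcating root of the unrooted shape). Each
#' of the nine branches carries an omega-class label: the terminal pairs
#' M1/R1 and M2/R2 are `rpostD1` and `rpostD2`, the internal branches n1-n3
#' and n2-n3 are `ipostD1` and `ipostD2`, and the C, D and n3-n4 stem
#' branches are `preD`.
#'
#' @param branch_lengths Named numeric vector of edge lengths (expected
#'   substitutions per codon, >= 0) keyed by the child end of each edge:
#'   `M1, R1, M2, R2, C, D, n1, n2, n3`.
#' @return Object of classes `sextuplet_tree` and `phylo`, with elements
#'   `omega_class` (one label per edge, ordered as `tree$edge`) and
#'   `edge_name` (child-end name per edge).
#' @examples
#' tr <- sextuplet_tree(c(M1 = .1, R1 = .1, M2 = .1, R2 = .1,
#'                        C = .15, D = .15, n1 = .05, n2 = .05, n3 = .05))
#' @export
sextuplet_tree <- function(branch_lengths) {
  need <- c("M1", "R1", "M2", "R2", "C", "D", "n1", "n2", "n3")
  if (is.null(names(branch_lengths)) || !setequal(names(branch_lengths), need))
    stop("branch_lengths must be named with: ", paste(need, collapse = ", "))
  if (any(!is.finite(branch_lengths)) || any(branch_lengths < 0))
    stop("all branch lengths must be finite and >= 0")
  tr <- ape::read.tree(text = "(((M1,R1),(M2,R2)),C,D);")
  tr$node.label <- c("n4", "n3", "n1", "n2")
  nm <- node_names(tr)
  child <- nm[tr$edge[, 2]]
  tr$edge.length <- as.numeric(branch_lengths[child])
  tr$edge_name <- child
  tr$omega_class <- class_of_branch(child)
  class(tr) <- c("sextuplet_tree", "phylo")
  tr
}

# names for every node id (tips then internals) of a phylo
node_names <- function(tr) {
  n_int <- tr$Nnode
  ints <- if (!is.null(tr$node.label)) tr$node.label else
    paste0("node", seq_len(n_int))
  c(tr$tip.label, ints)
}

# omega class from the child-end name of an edge
class_of_branch <- function(child) {
  cl <- c(M1 = "rpostD1", R1 = "rpostD1", M2 = "rpostD2", R2 = "rpostD2",
          n1 = "ipostD1", n2 = "ipostD2", C = "preD", D = "preD", n3 = "preD")
  unname(cl[child])
}

#' @export
print.sextuplet_tree <- function(x, ...) {
  cat("Sextuplet tree (((M1,R1),(M2,R2)),C,D) with branch classes:\n")
  df <- data.frame(branch = x$edge_name, class = x$omega_class,
                   length = x$edge.length)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Newick string with #k omega-class branch labels
#'
#' Serialises a sextuplet tree in the widely used branch-label dialect where
#' `#k` after a tip or clade marks the branch's omega class, with
#' k = 0..4 for `preD`, `ipostD1`, `ipostD2`, `rpostD1`, `rpostD2`.
#'
#' @param tree A [sextuplet_tree()].
#' @param digits Significant digits for branch lengths.
#' @return A single newick string, terminated by `;`.
#' @export
newick_with_classes <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "sextuplet_tree"))
  k <- match(tree$omega_class, omega_classes()) - 1L
  len <- stats::setNames(tree$edge.length, tree$edge_name)
  kk <- stats::setNames(k, tree$edge_name)
  lab <- function(ch) sprintf(" #%d:%s", kk[[ch]], format(len[[ch]], digits = digits))
  sprintf("(((M1%s,R1%s)%s,(M2%s,R2%s)%s)%s,C%s,D%s);",
          lab("M1"), lab("R1"), lab("n1"), lab("M2"), lab("R2"), lab("n2"),
          lab("n3"), lab("C"), lab("D"))
}

# Edge table view used by the likelihood and the simulator: postorder edges,
# node ids ape-style (tips 1..n, root n+1, ...).
tree_edges_postorder <- function(tr) {
  tp <- ape::reorder.phylo(tr, "postorder")
  ord <- match(paste(tp$edge[, 1], tp$edge[, 2]), paste(tr$edge[, 1], tr$edge[, 2]))
  list(parent = tp$edge[, 1], child = tp$edge[, 2],
       length = tp$edge.length,
       perm = ord,                       # postorder position -> original edge row
       root = ape::Ntip(tr) + 1L,
       n_tips = ape::Ntip(tr), n_nodes = ape::Ntip(tr) + tr$Nnode)
}
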
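# Construction of analysis-ready sextuplet sets from a homology table:
# candidate enumeration from orthology relations, recursive decomposition of
# multi-duplication families by smallest paralog ds, and the synonymous
# divergence filter that removes sets older than the outgroup split.

#' Find candidate sextuplet sets in a homology table
#'
#' A candidate is emitted for every dog gene with a one-to-one cow ortholog
#' and one-to-many orthology to exactly two ingroup (mouse) genes, each of
#' which has a one-to-one rat ortholog. Families with more than two such
#' paralogs are returned separately for [decompose_family()].
#'
#' @param table Data frame with columns `gene_id_a`, `genome_a`, `gene_id_b`,
#'   `genome_b`, `relation` (one-to-one, one-to-many, many-to-many). Rows are
#'   read directionally a -> b; dog-cow and dog-mouse rows must have dog in
#'   column a, mouse-rat rows mouse in column a.
#' @return List: `sets` (data.frame set_id, C, D, M1, M2, R1, R2,
#'   source_cluster, duplication_rank), `families` (list of per-cluster lists
#'   with `dog`, `cow`, `paralogs`, `rat_of` for clusters needing
#'   decomposition), `rejected` (data.frame cluster, reason).
#' @export
find_sextuplets <- function(table) {
  need <- c("gene_id_a", "genome_a", "gene_id_b", "genome_b", "relation")
  if (!all(need %in% names(table)))
    stop("homology table must have columns: ", paste(need, collapse = ", "))
  bad <- !table$relation %in% c("one-to-one", "one-to-many", "many-to-many")
  if (any(bad))
    stop("malformed relation at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  dc <- table[table$genome_a == "dog" & table$genome_b == "cow", ]
  dm <- table[table$genome_a == "dog" & table$genome_b == "mouse", ]
  mr <- table[table$genome_a == "mouse" & table$genome_b == "rat", ]
  sets <- list(); fams <- list(); rej <- list()
  reject <- function(cl, why)
    rej[[length(rej) + 1]] <<- data.frame(cluster = cl, reason = why,
                                          stringsAsFactors = FALSE)
  for (dog in unique(dm$gene_id_a)) {
    cow_rows <- dc[dc$gene_id_a == dog, ]
    if (nrow(cow_rows) != 1 || cow_rows$relation != "one-to-one") {
      reject(dog, "dog-cow not one-to-one")
      next
    }
    paralogs <- dm$gene_id_b[dm$gene_id_a == dog & dm$relation == "one-to-many"]
    if (length(paralogs) < 2) {
      reject(dog, "fewer than two ingroup paralogs")
      next
    }
    rat_of <- vapply(paralogs, function(m) {
      r <- mr[mr$gene_id_a == m & mr$relation == "one-to-one", ]
      if (nrow(r) == 1) r$gene_id_b else NA_character_
    }, character(1))
    keep <- !is.na(rat_of)
    if (sum(keep) < 2) {
      reject(dog, "fewer than two paralogs with one-to-one rat orthologs")
      next
    }
    paralogs <- paralogs[keep]; rat_of <- rat_of[keep]
    if (length(paralogs) == 2) {
      sets[[length(sets) + 1]] <- data.frame(
        set_id = dog, C = cow_rows$gene_id_b, D = dog,
        M1 = paralogs[1], M2 = paralogs[2],
        R1 = rat_of[[1]], R2 = rat_of[[2]],
        source_cluster = dog, duplication_rank = 1L,
        stringsAsFactors = FALSE)
    } else {
      fams[[length(fams) + 1]] <- list(dog = dog, cow = cow_rows$gene_id_b,
                                       paralogs = paralogs, rat_of = rat_of)
    }
  }
  list(sets = if (length(sets)) do.call(rbind, sets) else empty_sets_df(),
       families = fams,
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(cluster = character(), reason = character()))
}

empty_sets_df <- function() {
  data.frame(set_id = character(), C = character(), D = character(),
             M1 = character(), M2 = character(), R1 = character(),
             R2 = character(), source_cluster = character(),
             duplication_rank = integer(), stringsAsFactors = FALSE)
}

#' Decompose a multi-duplication family into single-duplication sets
#'
#' Recursively pairs the two paralogs with the smallest synonymous distance
#' as the most recent duplication, emits a sextuplet set for the pair,
#' removes one member of the pair at random (with its sister-species
#' ortholog), and repeats until one paralog remains. A family of k paralogs
#' yields k - 1 sets. Distance ties are broken lexicographically by the
#' gene-id pair and recorded.
#'
#' @param family List with `dog`, `cow`, `paralogs` (character), `rat_of`
#'   (named character, rat ortholog per paralog).
#' @param ds_matrix Symmetric non-negative matrix of pairwise synonymous
#'   distances among the paralogs (dimnames = paralog ids).
#' @param seed Integer seed scoping this family's random removals, so one
#'   family's draws never perturb another's.
#' @return List: `sets` (data.frame as in [find_sextuplets()], ranked 1 =
#'   most recent), `ties` (character vector describing any broken ties).
#' @export
decompose_family <- function(family, ds_matrix, seed = 1) {
  p <- family$paralogs
  stopifnot(length(p) >= 2, all(p %in% rownames(ds_matrix)),
            all(p %in% colnames(ds_matrix)))
  if (any(ds_matrix[p, p] < 0) ||
      max(abs(ds_matrix[p, p] - t(ds_matrix[p, p]))) > 1e-12)
    stop("ds_matrix must be symmetric and non-negative")
  rat_of <- family$rat_of
  sets <- list(); ties <- character()
  with_private_seed(seed, {
    remaining <- p
    rank <- 1L
    while (length(remaining) > 1) {
      sub <- ds_matrix[remaining, remaining, drop = FALSE]
      pairs <- which(upper.tri(sub), arr.ind = TRUE)
      dvals <- sub[pairs]
      best <- min(dvals)
      cand <- which(dvals <= best)
      if (length(cand) > 1) {
        keys <- apply(pairs[cand, , drop = FALSE], 1, function(ij)
          paste(sort(remaining[ij]), collapse = "|"))
        pick <- cand[order(keys)[1]]
        ties <- c(ties, sprintf("rank %d: ds tie at %.6g broken toward %s",
                                rank, best, keys[order(keys)[1]]))
      } else pick <- cand
      i <- remaining[pairs[pick, 1]]; j <- remaining[pairs[pick, 2]]
      sets[[rank]] <- data.frame(
        set_id = sprintf("%s_dup%d", family$dog, rank),
        C = family$cow, D = family$dog,
        M1 = i, M2 = j, R1 = rat_of[[i]], R2 = rat_of[[j]],
        source_cluster = family$dog, duplication_rank = rank,
        stringsAsFactors = FALSE)
      drop <- sample(c(i, j), 1)
      remaining <- setdiff(remaining, drop)
      rank <- rank + 1L
    }
  })
  list(sets = do.call(rbind, sets), ties = ties)
}

#' Filter sets by pairwise synonymous divergence
#'
#' Removes every set in which any of the five study comparisons (C-D, M1-R1,
#' M2-R2, M1-M2, R1-R2) has ds strictly greater than the threshold; such
#' divergence indicates the apparent duplication predates the outgroup split
#' (typically a gene loss in the dog-cow lineage) or a misassigned ortholog.
#' Sets with a missing ds value are rejected with reason "incomplete". The
#' boundary ds = threshold is retained.
#'
#' @param sets Data frame of sets (must carry `set_id`).
#' @param ds_values Data frame with columns `set_id` and the five comparison
#'   columns `C_D`, `M1_R1`, `M2_R2`, `M1_M2`, `R1_R2` of ds values.
#' @param threshold Rejection threshold on ds (default 1.0, strict `>`).
#' @return List: `retained` (subset of `sets`), `rejected` (data.frame
#'   set_id, reason naming the offending comparison and value).
#' @export
filter_ds <- function(sets, ds_values, threshold = 1.0) {
  comps <- c("C_D", "M1_R1", "M2_R2", "M1_M2", "R1_R2")
  stopifnot(all(c("set_id", comps) %in% names(ds_values)))
  keep <- logical(nrow(sets)); rej <- list()
  for (k in seq_len(nrow(sets))) {
    row <- ds_values[ds_values$set_id == sets$set_id[k], , drop = FALSE]
    if (nrow(row) != 1 || anyNA(row[, comps])) {
      rej[[length(rej) + 1]] <- data.frame(set_id = sets$set_id[k],
                                           reason = "incomplete",
                                           stringsAsFactors = FALSE)
      next
    }
    over <- comps[as.numeric(row[, comps]) > threshold]
    if (length(over)) {
      rej[[length(rej) + 1]] <- data.frame(
        set_id = sets$set_id[k],
        reason = sprintf("ds(%s) = %.4g > %.4g", over[1],
                         row[[over[1]]], threshold),
        stringsAsFactors = FALSE)
    } else keep[k] <- TRUE
  }
  list(retained = sets[keep, , drop = FALSE],
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(set_id = character(), reason = character()))
}
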
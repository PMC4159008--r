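# The delta statistics contrasting pre- and post-duplication rates of
# protein evolution, duplication dating by synonymous divergence, age
# binning, the paralog-divergence gene-conversion diagnostic, synteny-based
# original/novel classification, and the novel-copy-is-fast exact test.

#' Delta statistics from a branch-class ML fit
#'
#' With omega_hat the fitted class values,
#' `delta_f = max(rpostD1, rpostD2) - preD` and
#' `delta_s = min(rpostD1, rpostD2) - preD` contrast the recent rates of the
#' fast and slow copy with the preduplication rate. `delta_if` and `delta_is`
#' are the analogous contrasts for the initial postduplication internal
#' branches, paired with the fast and slow recent copy respectively.
#'
#' @param fit A `branch_fit` from [fit_branch_model()].
#' @param set_id Identifier carried into the record.
#' @param lineage Cohort tag (`"rodent"`, `"primate"` or `"synthetic"`).
#' @return A one-row data.frame (`duplication_record`): set_id, delta_f,
#'   delta_s, delta_if, delta_is, age, fast_copy (1 or 2), method = "ML",
#'   lineage, flagged (TRUE for unconverged fits, which summaries exclude).
#' @export
compute_deltas_ml <- function(fit, set_id = "set", lineage = "synthetic") {
  stopifnot(inherits(fit, "branch_fit"))
  om <- fit$params$omega_by_class
  need <- omega_classes()
  stopifnot(all(need %in% names(om)))
  r1 <- om[["rpostD1"]]; r2 <- om[["rpostD2"]]; pre <- om[["preD"]]
  fast <- if (r1 >= r2) 1L else 2L
  ifast <- om[[paste0("ipostD", fast)]]
  islow <- om[[paste0("ipostD", 3L - fast)]]
  data.frame(set_id = set_id,
             delta_f = max(r1, r2) - pre,
             delta_s = min(r1, r2) - pre,
             delta_if = ifast - pre,
             delta_is = islow - pre,
             age = duplication_age(fit),
             fast_copy = fast,
             method = "ML", lineage = lineage,
             flagged = !isTRUE(fit$converged),
             stringsAsFactors = FALSE)
}

#' Delta statistics from the five pairwise comparisons
#'
#' The pairwise design estimates the preduplication rate as
#' `O = dn/ds(C-D)`, the recent postduplication rates as `P1 = dn/ds(M1-R1)`
#' and `P2 = dn/ds(M2-R2)`, and the duplication age as the mean of
#' `ds(M1-M2)` and `ds(R1-R2)`. Then `delta_f = max(P1, P2) - O` and
#' `delta_s = min(P1, P2) - O`. The internal-branch contrasts are undefined
#' for this method.
#'
#' @param comparisons Named list of `pairwise_dnds` objects with elements
#'   `C_D`, `M1_R1`, `M2_R2`, `M1_M2`, `R1_R2`.
#' @inheritParams compute_deltas_ml
#' @return A one-row `duplication_record` data.frame with method
#'   `"pairwise"`; records with any undefined omega (ds = 0) or saturated
#'   comparison are flagged.
#' @export
compute_deltas_pairwise <- function(comparisons, set_id = "set",
                                    lineage = "synthetic") {
  need <- c("C_D", "M1_R1", "M2_R2", "M1_M2", "R1_R2")
  stopifnot(all(need %in% names(comparisons)))
  O <- comparisons$C_D$omega
  P1 <- comparisons$M1_R1$omega
  P2 <- comparisons$M2_R2$omega
  flagged <- anyNA(c(O, P1, P2)) ||
    any(vapply(comparisons[need], function(x) isTRUE(x$saturated), logical(1)))
  age <- mean(c(comparisons$M1_M2$ds, comparisons$R1_R2$ds))
  fast <- if (isTRUE(P1 >= P2)) 1L else 2L
  data.frame(set_id = set_id,
             delta_f = if (flagged) NA_real_ else max(P1, P2) - O,
             delta_s = if (flagged) NA_real_ else min(P1, P2) - O,
             delta_if = NA_real_, delta_is = NA_real_,
             age = age, fast_copy = if (flagged) NA_integer_ else fast,
             method = "pairwise", lineage = lineage, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Duplication age from synonymous divergence
#'
#' ML method: the mean over the two sister species of the per-branch ds
#' summed along the paths separating the paralogs (M1 to M2 and R1 to R2
#' through n1, n3, n2). Pairwise method: the mean of the pairwise ds(M1-M2)
#' and ds(R1-R2) estimates.
#'
#' @param x A `branch_fit`, or a numeric vector of the two paralog ds values.
#' @return Age in synonymous substitutions per synonymous site.
#' @export
duplication_age <- function(x) {
  if (inherits(x, "branch_fit")) {
    pb <- x$per_branch_dnds
    ds <- stats::setNames(pb$ds, pb$branch)
    path_m <- ds[["M1"]] + ds[["n1"]] + ds[["n2"]] + ds[["M2"]]
    path_r <- ds[["R1"]] + ds[["n1"]] + ds[["n2"]] + ds[["R2"]]
    age <- mean(c(path_m, path_r))
  } else {
    stopifnot(is.numeric(x), length(x) == 2)
    if (anyNA(x) || any(x < 0)) stop("paralog ds values must be non-negative")
    age <- mean(x)
  }
  if (age < 0) stop("negative duplication age")
  age
}

#' Bin duplication records by age
#'
#' @param records Data frame of duplication records.
#' @param bin_edges Strictly increasing numeric vector; bins are half-open
#'   `[lo, hi)`. Default mirrors the study granularity: width 0.1 up to 0.6.
#' @return Data frame (`bin_summary`): bin label, lo, hi, n, mean_delta_f,
#'   mean_delta_s, se_delta_f, se_delta_s (SE = sample SD / sqrt(n),
#'   undefined for n < 2), plus an attribute `n_dropped` counting records
#'   outside all bins. Flagged records are excluded.
#' @export
bin_deltas <- function(records, bin_edges = seq(0, 0.6, by = 0.1)) {
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be strictly increasing")
  rec <- records[!records$flagged & !is.na(records$age), , drop = FALSE]
  idx <- findInterval(rec$age, bin_edges)
  inside <- idx >= 1 & idx < length(bin_edges)
  n_dropped <- sum(!inside)
  rec <- rec[inside, , drop = FALSE]; idx <- idx[inside]
  se <- function(v) if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(seq_len(length(bin_edges) - 1), function(b) {
    v <- rec[idx == b, , drop = FALSE]
    data.frame(bin = sprintf("[%.3g,%.3g)", bin_edges[b], bin_edges[b + 1]),
               lo = bin_edges[b], hi = bin_edges[b + 1], n = nrow(v),
               mean_delta_f = if (nrow(v)) mean(v$delta_f) else NA_real_,
               mean_delta_s = if (nrow(v)) mean(v$delta_s) else NA_real_,
               se_delta_f = se(v$delta_f), se_delta_s = se(v$delta_s),
               mean_age = if (nrow(v)) mean(v$age) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Gene-conversion diagnostic from paralog divergence in sister species
#'
#' Gene conversion homogenises paralogs within one species and so deflates
#' that species' paralog ds below the shared duplication age. The diagnostic
#' correlates ds(M1-M2) with ds(R1-R2) across sets and flags sets in which
#' one species' paralog ds falls below `outlier_frac` times the major-axis
#' prediction from the other species.
#'
#' @param ds_mouse_paralogs,ds_rat_paralogs Paired per-set paralog ds values.
#' @param outlier_frac Flagging threshold (default 0.5).
#' @return List: `r` (Pearson correlation, NA for n < 3), `slope`
#'   (major-axis slope through the origin), `outlier` (logical per set),
#'   `n`.
#' @export
gene_conversion_check <- function(ds_mouse_paralogs, ds_rat_paralogs,
                                  outlier_frac = 0.5) {
  x <- as.numeric(ds_mouse_paralogs); y <- as.numeric(ds_rat_paralogs)
  stopifnot(length(x) == length(y))
  n <- length(x)
  r <- if (n >= 3) stats::cor(x, y) else NA_real_
  # major axis through the origin: first principal direction of (x, y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  slope <- if (sxy == 0) 1 else
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  pred_y <- slope * x
  pred_x <- y / slope
  outlier <- (y < outlier_frac * pred_y) | (x < outlier_frac * pred_x)
  list(r = r, slope = slope, outlier = outlier, n = n)
}

#' Classify original and novel gene copies by synteny
#'
#' The copy whose flanking neighbours (up to `window` per side) include at
#' least `min_matches` orthologs of the dog gene's neighbours occupies the
#' ancestral genomic position and is labelled `original`; the other copy is
#' `novel`. If both or neither copy matches the classification is
#' `unresolved`. Tandem duplicates - paralogs adjacent in the same
#' neighbourhood (each listed among the other's neighbours) - are excluded.
#'
#' Ortholog matching between neighbour identifiers uses `ortholog_map` when
#' given, else the fixture convention that the ingroup ortholog of neighbour
#' `g` is named `g_m`.
#'
#' @param set One row of a sets table with `dog`, `copy1`, `copy2` columns.
#' @param synteny Data frame `gene_id`, `neighbors` (comma-separated ordered
#'   neighbour ids).
#' @param window Neighbours considered per copy (total `2 * window`).
#' @param min_matches Minimum neighbour orthologs required (default 2).
#' @param ortholog_map Optional named character vector mapping dog neighbour
#'   ids to their ingroup ortholog ids.
#' @return Character: `"copy1"` / `"copy2"` (the original), `"unresolved"`,
#'   or `"tandem"`.
#' @export
classify_old_new <- function(set, synteny, window = 3, min_matches = 2,
                             ortholog_map = NULL) {
  nb <- function(g) {
    row <- synteny[synteny$gene_id == g, ]
    if (nrow(row) != 1) return(NULL)
    strsplit(row$neighbors, ",")[[1]]
  }
  dog_nb <- nb(set$dog); nb1 <- nb(set$copy1); nb2 <- nb(set$copy2)
  if (is.null(dog_nb) || is.null(nb1) || is.null(nb2)) return("unresolved")
  nb1 <- utils::head(nb1, 2 * window); nb2 <- utils::head(nb2, 2 * window)
  if (set$copy2 %in% nb1 || set$copy1 %in% nb2) return("tandem")
  expected <- if (is.null(ortholog_map)) paste0(utils::head(dog_nb, 2 * window), "_m")
              else unname(ortholog_map[utils::head(dog_nb, 2 * window)])
  m1 <- sum(nb1 %in% expected); m2 <- sum(nb2 %in% expected)
  hit1 <- m1 >= min_matches; hit2 <- m2 >= min_matches
  if (hit1 && !hit2) "copy1" else if (hit2 && !hit1) "copy2" else "unresolved"
}

#' Exact test that the fast-evolving copy is the novel copy
#'
#' One-sided exact binomial test of the observed count of duplications in
#' which the faster-evolving copy is the relocated (novel) copy, against the
#' null that fast and slow are equally likely to be the novel copy
#' (p = 1/2).
#'
#' @param n_fast_novel Number of duplications where the fast copy is novel.
#' @param n_total Number of classified duplications.
#' @return List: `n_fast_novel`, `n_total`, `fraction`, `p_value`
#'   (one-sided, upper tail).
#' @export
novel_fast_test <- function(n_fast_novel, n_total) {
  stopifnot(n_total >= 1, n_fast_novel >= 0, n_fast_novel <= n_total)
  bt <- stats::binom.test(n_fast_novel, n_total, p = 0.5,
                          alternative = "greater")
  list(n_fast_novel = as.integer(n_fast_novel),
       n_total = as.integer(n_total),
       fraction = n_fast_novel / n_total,
       p_value = bt$p.value)
}

#' Lineage summary of the delta statistics
#'
#' @param records Data frame of duplication records (flagged rows excluded).
#' @return Data frame: lineage, n, mean_delta_f, se_delta_f, mean_delta_s,
#'   se_delta_s. Empty lineages are omitted with a warning.
#' @export
summarize_by_lineage <- function(records) {
  rec <- records[!records$flagged, , drop = FALSE]
  groups <- unique(records$lineage)
  se <- function(v) if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  rows <- lapply(groups, function(g) {
    v <- rec[rec$lineage == g, , drop = FALSE]
    if (nrow(v) == 0) {
      warning("lineage group '", g, "' has no usable records; omitted")
      return(NULL)
    }
    data.frame(lineage = g, n = nrow(v),
               mean_delta_f = mean(v$delta_f), se_delta_f = se(v$delta_f),
               mean_delta_s = mean(v$delta_s), se_delta_s = se(v$delta_s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
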
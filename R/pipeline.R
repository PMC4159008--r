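# End-to-end orchestration: cohort simulation or loading, the five pairwise
# comparisons, the ds filter, branch-model and pairwise delta estimation,
# diagnostics, and TSV/manifest output. Per-set failures are isolated and
# logged; they never abort the cohort.

#' Pipeline configuration
#'
#' @param n_sets Number of sextuplet sets (simulated cohorts).
#' @param n_codons Codon columns per alignment.
#' @param seed Master seed; every stochastic step derives its seed from it.
#' @param methods Estimation paths to run: `"ML"`, `"pairwise"`, or both.
#' @param ds_threshold Rejection threshold of the divergence filter.
#' @param bin_edges Age bin edges for the delta summaries.
#' @param ages Optional vector of target paralog synonymous depths recycled
#'   across sets (age stratification); default uses the scenario default.
#' @param scenario_args Named list of overrides passed to
#'   [simulation_scenario()] (e.g. `omega`, `kappa`).
#' @param synteny_window,synteny_min_matches Synteny classification settings.
#' @param n_restarts Optimiser restarts for the branch-model fits.
#' @param alignments Optional named list of [codon_alignment()] objects to
#'   analyse instead of simulating (names are set ids).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(n_sets = 20, n_codons = 500, seed = 1,
                            methods = c("ML", "pairwise"),
                            ds_threshold = 1.0,
                            bin_edges = seq(0, 0.6, by = 0.1),
                            ages = NULL,
                            scenario_args = list(),
                            synteny_window = 3, synteny_min_matches = 2,
                            n_restarts = 3,
                            alignments = NULL) {
  structure(list(n_sets = n_sets, n_codons = n_codons, seed = as.integer(seed),
                 methods = match.arg(methods, c("ML", "pairwise"),
                                     several.ok = TRUE),
                 ds_threshold = ds_threshold, bin_edges = bin_edges,
                 ages = ages, scenario_args = scenario_args,
                 synteny_window = synteny_window,
                 synteny_min_matches = synteny_min_matches,
                 n_restarts = n_restarts, alignments = alignments),
            class = "run_config")
}

# deterministic per-set seed derived from the master seed (kept < 2^31)
derive_seed <- function(seed, i, salt = 0L) {
  (as.double(seed) * 7919 + i * 104729 + salt * 31) %% 2147483647
}

pairwise_roles <- list(C_D = c("C", "D"), M1_R1 = c("M1", "R1"),
                       M2_R2 = c("M2", "R2"), M1_M2 = c("M1", "M2"),
                       R1_R2 = c("R1", "R2"))

# the five study comparisons of one sextuplet alignment
five_comparisons <- function(aln, method = c("ML", "NG86")) {
  method <- match.arg(method)
  f <- if (method == "ML") pairwise_dnds_ml else ng86_dnds
  lapply(pairwise_roles, function(p)
    f(aln$sequences[[p[1]]], aln$sequences[[p[2]]], pair = p))
}

#' Run the duplication-rate pipeline
#'
#' Executes the full analysis: obtain sextuplet alignments (simulated under
#' the default scenario unless supplied), estimate the five pairwise
#' comparisons, apply the ds filter, fit the branch-class model and/or the
#' pairwise design, compute delta records, age bins, lineage summaries, the
#' gene-conversion diagnostic and - for simulated cohorts - the synteny
#' classification with the novel-copy-is-fast test. Per-set failures are
#' logged and skipped.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, all tables plus a JSON
#'   run manifest are written there.
#' @return A `pipeline_result` list: `records` (all duplication records),
#'   `ds_table`, `retained`, `rejected`, `bins` (per method), `lineage`
#'   (per method), `conversion`, `synteny_truth`, `novel_fast`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # --- stage 1: alignments ---------------------------------------------
  if (is.null(config$alignments)) {
    ages <- config$ages
    alns <- list(); truths <- list()
    for (i in seq_len(config$n_sets)) {
      sa <- config$scenario_args
      sa$n_codons <- config$n_codons
      sa$seed <- derive_seed(config$seed, i)
      if (!is.null(ages)) sa$paralog_ds <- ages[((i - 1) %% length(ages)) + 1]
      sc <- do.call(simulation_scenario, sa)
      sim <- simulate_sextuplet(sc)
      id <- sprintf("set%03d", i)
      alns[[id]] <- sim$alignment
      truths[[id]] <- sim$truth
      note("%s simulate ok (paralog_ds=%.3g)", id, sc$branch_ds[["M1"]] * 3)
    }
  } else {
    alns <- config$alignments
    truths <- NULL
    note("loaded %d supplied alignments", length(alns))
  }

  # --- stage 2: pairwise comparisons + ds filter -----------------------
  comps <- list(); ds_rows <- list()
  for (id in names(alns)) {
    cmp <- tryCatch(five_comparisons(alns[[id]], "ML"), error = function(e) e)
    if (inherits(cmp, "error")) {
      note("%s pairwise FAILED: %s", id, conditionMessage(cmp))
      next
    }
    comps[[id]] <- cmp
    ds_rows[[id]] <- data.frame(
      set_id = id,
      C_D = cmp$C_D$ds, M1_R1 = cmp$M1_R1$ds, M2_R2 = cmp$M2_R2$ds,
      M1_M2 = cmp$M1_M2$ds, R1_R2 = cmp$R1_R2$ds,
      stringsAsFactors = FALSE)
  }
  ds_table <- do.call(rbind, ds_rows)
  sets_df <- data.frame(set_id = names(comps), stringsAsFactors = FALSE)
  filt <- filter_ds(sets_df, ds_table, threshold = config$ds_threshold)
  kept <- filt$retained$set_id
  note("ds filter: %d of %d sets retained", length(kept), nrow(sets_df))

  # --- stage 3: delta records ------------------------------------------
  records <- list()
  for (id in kept) {
    lineage <- if (!is.null(truths)) truths[[id]]$lineage_tag else "unknown"
    if ("pairwise" %in% config$methods) {
      rec <- tryCatch(compute_deltas_pairwise(comps[[id]], id, lineage),
                      error = function(e) e)
      if (inherits(rec, "error")) note("%s pairwise-deltas FAILED: %s", id,
                                       conditionMessage(rec))
      else records[[paste0(id, "_pw")]] <- rec
    }
    if ("ML" %in% config$methods) {
      rec <- tryCatch({
        fit <- fit_branch_model(alns[[id]], n_restarts = config$n_restarts)
        compute_deltas_ml(fit, id, lineage)
      }, error = function(e) e)
      if (inherits(rec, "error")) note("%s ml-deltas FAILED: %s", id,
                                       conditionMessage(rec))
      else records[[paste0(id, "_ml")]] <- rec
    }
  }
  records <- if (length(records)) do.call(rbind, records) else NULL
  if (is.null(records)) {
    note("no surviving sets: empty result")
    return(structure(list(records = NULL, ds_table = ds_table,
                          retained = filt$retained, rejected = filt$rejected,
                          bins = NULL, lineage = NULL, conversion = NULL,
                          synteny_truth = NULL, novel_fast = NULL,
                          log = log_lines, config = config),
                     class = "pipeline_result"))
  }
  rownames(records) <- NULL

  # --- stage 4: summaries + diagnostics --------------------------------
  bins <- lapply(split(records, records$method), bin_deltas,
                 bin_edges = config$bin_edges)
  lineage <- lapply(split(records, records$method), summarize_by_lineage)
  conv <- NULL
  if (length(kept) >= 3) {
    dsk <- ds_table[ds_table$set_id %in% kept, ]
    conv <- gene_conversion_check(dsk$M1_M2, dsk$R1_R2)
    conv$set_id <- dsk$set_id
  }

  synteny_truth <- NULL; nf <- NULL
  if (is.null(config$alignments)) {
    # synthetic cohorts carry a planted synteny fixture keyed to the fast copy
    ml <- records[records$method == "ML" & !records$flagged, , drop = FALSE]
    use <- if (nrow(ml)) ml else records[!records$flagged, , drop = FALSE]
    # plant the original copy on the slow side (copy 2 under the default
    # regime) in most sets, the enrichment the synteny test is built to see
    fx <- make_synteny_fixture(n_sets = length(kept),
                               window = config$synteny_window,
                               frac_original_first = 0.2,
                               seed = derive_seed(config$seed, 0, 7L))
    calls <- vapply(seq_len(nrow(fx$sets)), function(k)
      classify_old_new(fx$sets[k, ], fx$synteny,
                       window = config$synteny_window,
                       min_matches = config$synteny_min_matches),
      character(1))
    synteny_truth <- cbind(fx$truth, call = calls,
                           match = calls == ifelse(is.na(fx$truth$original),
                                                   ifelse(fx$truth$tandem,
                                                          "tandem", "unresolved"),
                                                   fx$truth$original))
    resolved <- calls %in% c("copy1", "copy2")
    if (any(resolved) && nrow(use) > 0) {
      # fast copy per retained set (truth: rpostD1 >= rpostD2 -> copy 1)
      n_use <- min(sum(resolved), nrow(use))
      fastc <- paste0("copy", use$fast_copy[seq_len(n_use)])
      novel <- ifelse(calls[resolved][seq_len(n_use)] == "copy1",
                      "copy2", "copy1")
      nf <- novel_fast_test(sum(fastc == novel), n_use)
    }
  }

  res <- structure(list(records = records, ds_table = ds_table,
                        retained = filt$retained, rejected = filt$rejected,
                        bins = bins, lineage = lineage, conversion = conv,
                        synteny_truth = synteny_truth, novel_fast = nf,
                        truths = truths, log = log_lines, config = config),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_result(res, output_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Duplication-rate pipeline result\n")
  if (is.null(x$records)) { cat("  (no surviving sets)\n"); return(invisible(x)) }
  cat(sprintf("  %d records (%d sets retained, %d rejected)\n",
              nrow(x$records), nrow(x$retained), nrow(x$rejected)))
  for (m in names(x$lineage)) {
    s <- x$lineage[[m]]
    cat(sprintf("  [%s] mean delta_f = %.4g (SE %.2g), mean delta_s = %.4g (SE %.2g)\n",
                m, s$mean_delta_f[1], s$se_delta_f[1],
                s$mean_delta_s[1], s$se_delta_s[1]))
  }
  if (!is.null(x$conversion))
    cat(sprintf("  paralog-ds correlation r = %.3f (%d sets, %d outliers)\n",
                x$conversion$r, x$conversion$n, sum(x$conversion$outlier)))
  if (!is.null(x$novel_fast))
    cat(sprintf("  novel-copy-is-fast: %d/%d, one-sided exact p = %.3g\n",
                x$novel_fast$n_fast_novel, x$novel_fast$n_total,
                x$novel_fast$p_value))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)

#' Write all pipeline tables and the run manifest
#'
#' @param res A `pipeline_result`.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_pipeline_result <- function(res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(output_dir, f)
  if (!is.null(res$records)) write_tsv(res$records, fp("records.tsv"))
  if (!is.null(res$ds_table)) write_tsv(res$ds_table, fp("ds_table.tsv"))
  write_tsv(res$rejected, fp("rejections.tsv"))
  for (m in names(res$bins))
    write_tsv(res$bins[[m]], fp(sprintf("bins_%s.tsv", tolower(m))))
  for (m in names(res$lineage))
    write_tsv(res$lineage[[m]], fp(sprintf("lineage_%s.tsv", tolower(m))))
  if (!is.null(res$conversion))
    write_tsv(data.frame(set_id = res$conversion$set_id,
                         outlier = res$conversion$outlier),
              fp("conversion_outliers.tsv"))
  writeLines(res$log, fp("pipeline.log"))
  cfg <- res$config
  cfg$alignments <- if (is.null(cfg$alignments)) NULL else names(cfg$alignments)
  manifest <- list(config = unclass(cfg),
                   conversion_r = if (!is.null(res$conversion)) res$conversion$r,
                   novel_fast = res$novel_fast,
                   n_records = if (!is.null(res$records)) nrow(res$records) else 0)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(output_dir)
}

#' Write a branch-model fit as TSV
#'
#' One row per branch (branch id, class, t, dn, ds) preceded by `#`-prefixed
#' header lines with kappa, the log-likelihood and the convergence flag.
#'
#' @param fit A `branch_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_branch_fit <- function(fit, path) {
  stopifnot(inherits(fit, "branch_fit"))
  hdr <- sprintf("# kappa=%.10g logL=%.10g converged=%s",
                 fit$params$kappa, fit$log_likelihood, fit$converged)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(fit$per_branch_dnds, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
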
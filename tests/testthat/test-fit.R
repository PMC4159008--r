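# ML fitting of the branch-class model and the pairwise estimators.

test_that("neutral simulation is recovered near omega = 1 in every class", {
  sc <- simulation_scenario(n_codons = 1000, seed = 101,
                            omega = stats::setNames(rep(1, 5), omega_classes()))
  sim <- simulate_sextuplet(sc)
  fit <- fit_branch_model(sim$alignment, n_restarts = 2)
  expect_true(fit$converged)
  for (cl in omega_classes()) {
    expect_gt(fit$params$omega_by_class[[cl]], 0.8)
    expect_lt(fit$params$omega_by_class[[cl]], 1.25)
  }
  # the GY decomposition identity: per-branch dn/ds equals the class omega
  pb <- fit$per_branch_dnds
  ratio <- pb$dn / pb$ds
  expect_lt(max(abs(ratio - fit$params$omega_by_class[pb$class])), 1e-10)
})

test_that("the five-class model never fits worse than the one-class model", {
  for (seed in c(7, 19)) {
    sim <- simulate_sextuplet(simulation_scenario(n_codons = 200, seed = seed))
    fit5 <- fit_branch_model(sim$alignment, n_restarts = 1)
    tr1 <- sim$truth$tree
    tr1$omega_class <- rep("preD", 9)
    fit1 <- fit_branch_model(sim$alignment, tree = tr1, n_restarts = 1)
    expect_gte(fit5$log_likelihood, fit1$log_likelihood - 1e-6)
  }
})

test_that("post-duplication acceleration is detected when simulated", {
  hits <- 0; n_rep <- 10
  for (r in seq_len(n_rep)) {
    sc <- simulation_scenario(n_codons = 300, seed = 4000 + r,
                              omega = c(preD = 0.1, ipostD1 = 0.3,
                                        ipostD2 = 0.3, rpostD1 = 0.3,
                                        rpostD2 = 0.1))
    sim <- simulate_sextuplet(sc)
    fit <- fit_branch_model(sim$alignment, n_restarts = 1)
    om <- fit$params$omega_by_class
    if (om[["rpostD1"]] > om[["preD"]]) hits <- hits + 1
  }
  expect_gte(hits, n_rep - 1)
})

test_that("omega-class bias shrinks as alignments grow", {
  bias_at <- function(n_codons) {
    errs <- vapply(1:2, function(r) {
      sc <- simulation_scenario(n_codons = n_codons, seed = 5000 + r)
      sim <- simulate_sextuplet(sc)
      fit <- fit_branch_model(sim$alignment, n_restarts = 1)
      truth <- sc$params$omega_by_class
      mean(abs(unlist(fit$params$omega_by_class[names(truth)]) -
               unlist(truth)))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(bias_at(2000), bias_at(500))
})

test_that("pairwise ML returns zero divergence for identical sequences and recovers omega", {
  s <- paste(rep("ATGGCTCAT", 20), collapse = "")
  pw0 <- pairwise_dnds_ml(s, s)
  expect_identical(pw0$dn, 0)
  expect_identical(pw0$ds, 0)
  expect_true(is.na(pw0$omega))

  sc <- simulation_scenario(n_codons = 2000, seed = 55,
                            omega = stats::setNames(rep(0.2, 5), omega_classes()),
                            outgroup_ds = 0.1)  # C-D path ds = 0.2
  sim <- simulate_sextuplet(sc)
  pw <- pairwise_dnds_ml(sim$alignment$sequences[["C"]],
                         sim$alignment$sequences[["D"]], pair = c("C", "D"))
  expect_gt(pw$omega, 0.1)
  expect_lt(pw$omega, 0.35)
  # the ML identity dn/ds = omega_hat, exactly
  expect_equal(pw$dn / pw$ds, pw$omega, tolerance = 1e-10)
})

test_that("pairwise ML agrees with the branch-model machinery on a two-taxon tree", {
  sc <- simulation_scenario(n_codons = 400, seed = 77)
  sim <- simulate_sextuplet(sc)
  a <- sim$alignment$sequences[["C"]]; b <- sim$alignment$sequences[["D"]]
  pw <- pairwise_dnds_ml(a, b, pair = c("C", "D"))
  tr <- make_class_tree("(C:0.05,D:0.05);")
  aln2 <- codon_alignment(c(C = a, D = b))
  fit2 <- fit_branch_model(aln2, tree = tr, n_restarts = 1)
  # only the path length between the two tips is identifiable: the pairwise
  # objective evaluated at the tree fit's parameters reproduces its logL
  pp <- dupaccel:::pair_patterns(a, b, c("C", "D"))
  code <- dupaccel:::.code
  ll_path <- dupaccel:::cpp_pair_loglik(
    fit2$params$codon_freqs, fit2$params$kappa,
    fit2$params$omega_by_class[["preD"]],
    sum(fit2$per_branch_dnds$t), pp$sa, pp$sb, pp$w,
    code("single_step") * 1, code("is_transition") * 1,
    code("is_synonymous") * 1)
  expect_lt(abs(ll_path - fit2$log_likelihood), 1e-6)
  # and the two independently optimised routes land on the same maximum
  expect_lt(abs(pw$log_likelihood - fit2$log_likelihood), 1e-3)
  expect_equal(sum(fit2$per_branch_dnds$t), pw$t, tolerance = 1e-2)
})

test_that("gap-only pairwise input is an error", {
  expect_error(pairwise_dnds_ml("ATG---", "---AAA"), "gap-free")
})

test_that("NG86 counting matches construction on hand-built cases", {
  # identical
  ng0 <- ng86_dnds("ATGGCT", "ATGGCT")
  expect_identical(ng0$dn, 0)
  expect_identical(ng0$ds, 0)
  # one synonymous difference in a run of identical codons:
  # GCT -> GCC (Ala), padded so the difference proportion stays small
  pad <- strrep("ATGAAA", 10)
  ng_syn <- ng86_dnds(paste0(pad, "GCT"), paste0(pad, "GCC"))
  expect_identical(ng_syn$dn, 0)
  expect_gt(ng_syn$ds, 0)
  # one nonsynonymous difference: ATG (Met) -> ATA (Ile)
  ng_non <- ng86_dnds(paste0(pad, "ATG"), paste0(pad, "ATA"))
  expect_identical(ng_non$ds, 0)
  expect_gt(ng_non$dn, 0)
  expect_true(is.na(ng_non$omega))
})

test_that("NG86 site counts match the classical values for example codons", {
  svec <- dupaccel:::.ng86_sites()
  cods <- sense_codons()
  # fourfold degenerate third position: 1 synonymous site
  expect_equal(svec[match("GCT", cods)], 1, tolerance = 1e-12)
  # TTT (Phe): only TTC synonymous -> 1/3 site
  expect_equal(svec[match("TTT", cods)], 1 / 3, tolerance = 1e-12)
  # ATG (Met) and TGG (Trp): no synonymous change
  expect_equal(svec[match("ATG", cods)], 0, tolerance = 1e-12)
  expect_equal(svec[match("TGG", cods)], 0, tolerance = 1e-12)
})

test_that("NG86 saturation is flagged, not raised", {
  set.seed(12)
  a <- paste(sense_codons()[sample.int(61, 200, TRUE)], collapse = "")
  b <- paste(sense_codons()[sample.int(61, 200, TRUE)], collapse = "")
  ng <- ng86_dnds(a, b)
  expect_true(is.list(ng))
  expect_true(ng$saturated || (ng$ds < 10 && ng$dn < 10))
})
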
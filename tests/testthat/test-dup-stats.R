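# Delta arithmetic, dating, binning, the gene-conversion diagnostic,
# synteny classification and the exact novelty test.

test_that("delta statistics from a branch fit follow their definitions", {
  fit <- fake_branch_fit(c(preD = 0.15, ipostD1 = 0.40, ipostD2 = 0.20,
                           rpostD1 = 0.30, rpostD2 = 0.10))
  rec <- compute_deltas_ml(fit, set_id = "s1", lineage = "rodent")
  expect_equal(rec$delta_f, 0.30 - 0.15, tolerance = 1e-12)
  expect_equal(rec$delta_s, 0.10 - 0.15, tolerance = 1e-12)
  expect_identical(rec$fast_copy, 1L)
  # the internal contrasts pair with the fast copy's side
  expect_equal(rec$delta_if, 0.40 - 0.15, tolerance = 1e-12)
  expect_equal(rec$delta_is, 0.20 - 0.15, tolerance = 1e-12)
  expect_identical(rec$method, "ML")
  expect_identical(rec$lineage, "rodent")
  expect_false(rec$flagged)
  # identity: delta_f + delta_s = rpostD1 + rpostD2 - 2 preD
  expect_equal(rec$delta_f + rec$delta_s, 0.30 + 0.10 - 2 * 0.15,
               tolerance = 1e-12)
})

test_that("delta statistics are invariant under relabelling the two copies", {
  om <- c(preD = 0.12, ipostD1 = 0.35, ipostD2 = 0.18,
          rpostD1 = 0.28, rpostD2 = 0.09)
  swapped <- c(preD = 0.12, ipostD1 = 0.18, ipostD2 = 0.35,
               rpostD1 = 0.09, rpostD2 = 0.28)
  a <- compute_deltas_ml(fake_branch_fit(om))
  b <- compute_deltas_ml(fake_branch_fit(swapped))
  for (f in c("delta_f", "delta_s", "delta_if", "delta_is"))
    expect_equal(a[[f]], b[[f]], tolerance = 1e-12)
  expect_identical(a$fast_copy, 1L)
  expect_identical(b$fast_copy, 2L)
})

test_that("a rate tie puts both recent contrasts at the same value", {
  rec <- compute_deltas_ml(fake_branch_fit(
    c(preD = 0.1, ipostD1 = 0.2, ipostD2 = 0.2,
      rpostD1 = 0.25, rpostD2 = 0.25)))
  expect_equal(rec$delta_f, rec$delta_s, tolerance = 1e-12)
  expect_identical(rec$fast_copy, 1L)
})

test_that("pairwise delta statistics use the five-comparison design", {
  cmp <- list(C_D = fake_pairwise(0.10, ds = 0.25),
              M1_R1 = fake_pairwise(0.30, ds = 0.10),
              M2_R2 = fake_pairwise(0.12, ds = 0.10),
              M1_M2 = fake_pairwise(0.2, ds = 0.28),
              R1_R2 = fake_pairwise(0.2, ds = 0.32))
  rec <- compute_deltas_pairwise(cmp, set_id = "s9")
  expect_equal(rec$delta_f, 0.30 - 0.10, tolerance = 1e-12)
  expect_equal(rec$delta_s, 0.12 - 0.10, tolerance = 1e-12)
  expect_equal(rec$age, 0.30, tolerance = 1e-12)
  expect_true(is.na(rec$delta_if) && is.na(rec$delta_is))
  expect_identical(rec$method, "pairwise")
  # an undefined omega flags the record instead of propagating NA silently
  cmp$M1_R1 <- fake_pairwise(NA_real_, ds = 0)
  rec2 <- compute_deltas_pairwise(cmp)
  expect_true(rec2$flagged)
  expect_true(is.na(rec2$delta_f))
})

test_that("duplication age averages the two species' paralog paths", {
  expect_equal(duplication_age(c(0.28, 0.32)), 0.30, tolerance = 1e-12)
  expect_error(duplication_age(c(-0.1, 0.2)), "non-negative")
  ds <- c(M1 = 0.05, R1 = 0.07, M2 = 0.06, R2 = 0.08, C = 0.1, D = 0.1,
          n1 = 0.02, n2 = 0.03, n3 = 0.04)
  fit <- fake_branch_fit(c(preD = 0.1, ipostD1 = 0.2, ipostD2 = 0.2,
                           rpostD1 = 0.3, rpostD2 = 0.1), branch_ds = ds)
  # M path: M1 + n1 + n2 + M2 = 0.16; R path: R1 + n1 + n2 + R2 = 0.20
  expect_equal(duplication_age(fit), mean(c(0.16, 0.20)), tolerance = 1e-12)
})

test_that("age bins are half-open with plain mean and SE arithmetic", {
  rec <- data.frame(
    set_id = paste0("s", 1:6),
    delta_f = c(0.10, 0.20, 0.15, 0.40, 0.50, 0.99),
    delta_s = c(0.00, -0.02, 0.02, 0.01, -0.01, 0.99),
    age = c(0.05, 0.09, 0.099999, 0.10, 0.15, 0.65),
    flagged = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  out <- bin_deltas(rec, bin_edges = seq(0, 0.6, by = 0.1))
  expect_identical(out$n, c(3L, 2L, 0L, 0L, 0L, 0L))
  expect_equal(out$mean_delta_f[1], mean(c(0.10, 0.20, 0.15)),
               tolerance = 1e-12)
  expect_equal(out$se_delta_f[1], stats::sd(c(0.10, 0.20, 0.15)) / sqrt(3),
               tolerance = 1e-12)
  # age exactly on an edge joins the upper bin
  expect_equal(out$mean_delta_f[2], mean(c(0.40, 0.50)), tolerance = 1e-12)
  expect_true(is.na(out$se_delta_f[3]))
  # the out-of-range record is counted, not silently lost
  expect_identical(attr(out, "n_dropped"), 1L)
  # flagged records are excluded from summaries
  rec$flagged[2] <- TRUE
  out2 <- bin_deltas(rec, bin_edges = seq(0, 0.6, by = 0.1))
  expect_identical(out2$n[1], 2L)
  expect_error(bin_deltas(rec, bin_edges = c(0, 0.2, 0.2)),
               "strictly increasing")
})

test_that("the gene-conversion diagnostic flags deflated paralog divergence", {
  set.seed(33)
  age <- runif(30, 0.05, 0.6)
  x <- age * exp(rnorm(30, 0, 0.02))
  y <- age * exp(rnorm(30, 0, 0.02))
  clean <- gene_conversion_check(x, y)
  expect_gt(clean$r, 0.99)
  expect_equal(clean$slope, 1, tolerance = 0.1)
  expect_false(any(clean$outlier))
  # exact proportionality: r = 1, slope recovered
  exact <- gene_conversion_check(c(0.1, 0.2, 0.4), c(0.2, 0.4, 0.8))
  expect_equal(exact$r, 1, tolerance = 1e-12)
  expect_equal(exact$slope, 2, tolerance = 1e-10)
  # one converted set: its rat paralog ds collapses far below the trend
  y2 <- y; y2[7] <- y2[7] * 0.1
  conv <- gene_conversion_check(x, y2)
  expect_true(conv$outlier[7])
  expect_identical(sum(conv$outlier), 1L)
  # too few sets for a correlation
  expect_true(is.na(gene_conversion_check(c(0.1, 0.2), c(0.1, 0.2))$r))
})

test_that("synteny classification recovers the planted labels", {
  fx <- make_synteny_fixture(n_sets = 8, window = 3, frac_original_first = 0.5,
                             n_tandem = 2, n_unresolved = 1, seed = 11)
  calls <- vapply(seq_len(nrow(fx$sets)), function(i)
    classify_old_new(fx$sets[i, ], fx$synteny, window = 3, min_matches = 2),
    character(1))
  truth <- ifelse(fx$truth$tandem, "tandem",
                  ifelse(is.na(fx$truth$original), "unresolved",
                         fx$truth$original))
  expect_identical(calls, truth)
})

test_that("a custom ortholog map overrides the suffix convention", {
  fx <- make_synteny_fixture(n_sets = 1, frac_original_first = 1, seed = 2)
  dog_nb <- strsplit(fx$synteny$neighbors[1], ",")[[1]]
  map <- stats::setNames(paste0(dog_nb, "_m"), dog_nb)
  expect_identical(classify_old_new(fx$sets[1, ], fx$synteny,
                                    ortholog_map = map), "copy1")
  # a map pointing at genes absent from both windows leaves it unresolved
  bad <- stats::setNames(paste0(dog_nb, "_zz"), dog_nb)
  expect_identical(classify_old_new(fx$sets[1, ], fx$synteny,
                                    ortholog_map = bad), "unresolved")
})

test_that("a gene missing from the synteny table is unresolved, not an error", {
  fx <- make_synteny_fixture(n_sets = 1, frac_original_first = 1, seed = 4)
  syn <- fx$synteny[fx$synteny$gene_id != fx$sets$copy2[1], , drop = FALSE]
  expect_identical(classify_old_new(fx$sets[1, ], syn), "unresolved")
})

test_that("the exact binomial novelty test matches the closed form", {
  # P(X >= k) for X ~ Binomial(n, 1/2) is sum_{j>=k} C(n, j) / 2^n
  tail_p <- function(k, n) sum(choose(n, k:n)) / 2^n
  expect_equal(novel_fast_test(21, 26)$p_value, 83682 / 2^26,
               tolerance = 1e-12)
  expect_equal(novel_fast_test(26, 26)$p_value, 2^-26, tolerance = 1e-12)
  expect_gt(novel_fast_test(13, 26)$p_value, 0.5)
  for (n in c(5, 11, 26, 30)) for (k in c(0, n %/% 2, n))
    expect_equal(novel_fast_test(k, n)$p_value, tail_p(k, n),
                 tolerance = 1e-12)
  expect_equal(novel_fast_test(21, 26)$fraction, 21 / 26, tolerance = 1e-12)
  expect_error(novel_fast_test(5, 4))
})

test_that("lineage summaries exclude flagged records and warn on empty groups", {
  rec <- rbind(
    compute_deltas_ml(fake_branch_fit(c(preD = 0.1, ipostD1 = 0.3,
                                        ipostD2 = 0.2, rpostD1 = 0.3,
                                        rpostD2 = 0.1)), "a", "rodent"),
    compute_deltas_ml(fake_branch_fit(c(preD = 0.1, ipostD1 = 0.3,
                                        ipostD2 = 0.2, rpostD1 = 0.5,
                                        rpostD2 = 0.1)), "b", "rodent"),
    compute_deltas_ml(fake_branch_fit(c(preD = 0.2, ipostD1 = 0.3,
                                        ipostD2 = 0.2, rpostD1 = 0.4,
                                        rpostD2 = 0.1)), "c", "primate"))
  s <- summarize_by_lineage(rec)
  expect_identical(nrow(s), 2L)
  rod <- s[s$lineage == "rodent", ]
  expect_identical(rod$n, 2L)
  expect_equal(rod$mean_delta_f, mean(c(0.2, 0.4)), tolerance = 1e-12)
  expect_equal(rod$se_delta_f, stats::sd(c(0.2, 0.4)) / sqrt(2),
               tolerance = 1e-12)
  rec$flagged[3] <- TRUE
  expect_warning(s2 <- summarize_by_lineage(rec), "primate")
  expect_identical(s2$lineage, "rodent")
})
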
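# Sextuplet construction, family decomposition and the ds filter.

test_that("find_sextuplets emits exactly the planted valid patterns", {
  fx <- make_homology_fixture(n_valid = 10, n_invalid = 5, seed = 1)
  out <- find_sextuplets(fx$table)
  expect_identical(nrow(out$sets), 10L)
  expect_identical(length(out$families), 0L)
  expect_true(all(out$sets$duplication_rank == 1L))
  # the six roles are present and distinct in every set
  roles <- c("C", "D", "M1", "M2", "R1", "R2")
  for (k in seq_len(nrow(out$sets)))
    expect_identical(anyDuplicated(unlist(out$sets[k, roles])), 0L)
  # invalid clusters are rejected with reasons
  expect_identical(sort(unique(out$rejected$cluster)),
                   sort(fx$truth$cluster[!fx$truth$valid]))
})

test_that("a single valid pattern yields a single set, and broken patterns none", {
  fx1 <- make_homology_fixture(n_valid = 1, n_invalid = 0, seed = 3)
  expect_identical(nrow(find_sextuplets(fx1$table)$sets), 1L)
  # a dog-cow many-to-many cluster and a paralog without a rat one-to-one
  # ortholog both yield nothing
  fx2 <- make_homology_fixture(n_valid = 0, n_invalid = 2, seed = 3)
  out2 <- find_sextuplets(fx2$table)
  expect_identical(nrow(out2$sets), 0L)
  expect_identical(nrow(out2$rejected), 2L)
})

test_that("multi-paralog clusters are routed to decomposition", {
  fx <- make_homology_fixture(n_valid = 3, n_invalid = 0, n_paralogs = 4,
                              seed = 6)
  out <- find_sextuplets(fx$table)
  expect_identical(nrow(out$sets), 0L)
  expect_identical(length(out$families), 3L)
  expect_identical(length(out$families[[1]]$paralogs), 4L)
})

test_that("never emits a set without a one-to-one dog-cow relation", {
  for (seed in 1:5) {
    set.seed(seed)
    fx <- make_homology_fixture(n_valid = sample(0:6, 1),
                                n_invalid = sample(0:6, 1), seed = seed)
    out <- find_sextuplets(fx$table)
    dc <- fx$table[fx$table$genome_a == "dog" & fx$table$genome_b == "cow", ]
    for (dog in out$sets$D)
      expect_identical(dc$relation[dc$gene_id_a == dog], "one-to-one")
  }
})

test_that("malformed relations raise an input error naming the row", {
  fx <- make_homology_fixture(n_valid = 1, n_invalid = 0, seed = 1)
  fx$table$relation[2] <- "friends"
  expect_error(find_sextuplets(fx$table), "row")
})

test_that("decompose_family emits k - 1 ranked sets, most recent pair first", {
  fam <- function(p) list(dog = "dogA", cow = "cowA", paralogs = p,
                          rat_of = stats::setNames(paste0(p, "_r"), p))
  dsm <- function(ids, vals) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[upper.tri(m)] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  # two paralogs: one set
  d2 <- decompose_family(fam(c("a", "b")), dsm(c("a", "b"), 0.2), seed = 1)
  expect_identical(nrow(d2$sets), 1L)
  expect_identical(d2$sets$duplication_rank, 1L)
  # three paralogs with ds (a,b)=0.1, (a,c)=0.4, (b,c)=0.45: first pair (a,b)
  d3 <- decompose_family(fam(c("a", "b", "c")),
                         dsm(c("a", "b", "c"), c(0.1, 0.4, 0.45)), seed = 1)
  expect_identical(sort(c(d3$sets$M1[1], d3$sets$M2[1])), c("a", "b"))
  expect_identical(nrow(d3$sets), 2L)
  # k - 1 sets for arbitrary k
  for (k in c(4, 6)) {
    ids <- letters[1:k]
    set.seed(k)
    vals <- runif(k * (k - 1) / 2, 0.05, 0.9)
    dk <- decompose_family(fam(ids), dsm(ids, vals), seed = 2)
    expect_identical(nrow(dk$sets), as.integer(k - 1))
    expect_identical(dk$sets$duplication_rank, seq_len(k - 1L))
  }
})

test_that("decompose_family recovers the planted order of a simulated family", {
  fam <- simulate_family(4, c(0.08, 0.25, 0.6), n_codons = 400, seed = 17)
  ids <- names(fam$sequences)
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  for (i in 1:3) for (j in (i + 1):4)
    m[i, j] <- m[j, i] <- ng86_dnds(fam$sequences[[ids[i]]],
                                    fam$sequences[[ids[j]]])$ds
  dec <- decompose_family(list(dog = "d", cow = "c", paralogs = ids,
                               rat_of = stats::setNames(paste0(ids, "_r"), ids)),
                          m, seed = 31)
  expect_identical(nrow(dec$sets), 3L)
  expect_identical(sort(c(dec$sets$M1[1], dec$sets$M2[1])), fam$first_pair)
  for (r in 2:3)
    expect_true(fam$new_member[r] %in% c(dec$sets$M1[r], dec$sets$M2[r]))
})

test_that("ds ties are broken lexicographically and logged", {
  fam <- list(dog = "d", cow = "c", paralogs = c("b", "a", "z"),
              rat_of = c(b = "br", a = "ar", z = "zr"))
  m <- matrix(c(0, .1, .1, .1, 0, .1, .1, .1, 0), 3,
              dimnames = list(c("b", "a", "z"), c("b", "a", "z")))
  d <- decompose_family(fam, m, seed = 4)
  expect_gt(length(d$ties), 0)
  expect_identical(sort(c(d$sets$M1[1], d$sets$M2[1])), c("a", "b"))
})

test_that("the removal step is seed-scoped and reproducible", {
  fam <- simulate_family(4, c(0.08, 0.25, 0.6), n_codons = 200, seed = 18)
  ids <- names(fam$sequences)
  m <- matrix(0, 4, 4, dimnames = list(ids, ids))
  for (i in 1:3) for (j in (i + 1):4)
    m[i, j] <- m[j, i] <- ng86_dnds(fam$sequences[[ids[i]]],
                                    fam$sequences[[ids[j]]])$ds
  f <- list(dog = "d", cow = "c", paralogs = ids,
            rat_of = stats::setNames(paste0(ids, "_r"), ids))
  expect_identical(decompose_family(f, m, seed = 7)$sets,
                   decompose_family(f, m, seed = 7)$sets)
})

test_that("the ds filter removes exactly the over-threshold sets, boundary retained", {
  sets <- data.frame(set_id = c("s1", "s2", "s3", "s4"),
                     stringsAsFactors = FALSE)
  dsv <- data.frame(set_id = c("s1", "s2", "s3"),
                    C_D = c(0.3, 0.2, 0.1), M1_R1 = c(0.2, 0.2, 0.2),
                    M2_R2 = c(0.2, 0.2, 0.2), M1_M2 = c(1.2, 1.0, 0),
                    R1_R2 = c(0.4, 0.3, 0), stringsAsFactors = FALSE)
  out <- filter_ds(sets, dsv, threshold = 1.0)
  expect_identical(out$retained$set_id, c("s2", "s3"))
  expect_identical(out$rejected$set_id, c("s1", "s4"))
  expect_match(out$rejected$reason[1], "M1_M2")
  expect_identical(out$rejected$reason[2], "incomplete")
  # idempotent and order-independent
  again <- filter_ds(out$retained, dsv, threshold = 1.0)
  expect_identical(again$retained$set_id, out$retained$set_id)
  perm <- sets[c(3, 1, 4, 2), , drop = FALSE]
  out_perm <- filter_ds(perm, dsv, threshold = 1.0)
  expect_identical(sort(out_perm$retained$set_id), sort(out$retained$set_id))
})
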
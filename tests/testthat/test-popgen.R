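test_that("mutation_steps counts substitutions and gap runs separately", {
  expect_equal(unname(mutation_steps("ACGT", "ACGT")), c(0L, 0L))
  expect_equal(unname(mutation_steps("ACGT", "TCGA")), c(2L, 0L))
  expect_equal(unname(mutation_steps("AC--GT", "ACTTGA")), c(1L, 1L))
  expect_equal(unname(mutation_steps("ANGT", "ACGT")), c(0L, 0L))
  expect_error(mutation_steps("ACG", "ACGT"), "alignment error")
})

test_that("step_matrix equals a brute-force site recount on random sets", {
  set.seed(101)
  hs <- random_hapset(10, 50)
  sm <- suppressWarnings(step_matrix(hs)) # random sets may repeat a sequence
  ids <- names(hs$sequences)
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(sm[ids[i], ids[j]],
                 oracle_subs(hs$sequences[[i]], hs$sequences[[j]]))
  expect_true(isSymmetric(unclass(sm)[, ]))
  expect_true(all(diag(sm) == 0))

  hs2 <- haplotype_set(c(A = "AAA", B = "AAT", C = "ATT"))
  sm2 <- step_matrix(hs2)
  expect_equal(sm2["A", "B"], 1)
  expect_equal(sm2["B", "C"], 1)
  expect_equal(sm2["A", "C"], 2)
  expect_warning(step_matrix(haplotype_set(c(A = "AAA", B = "AAA"))),
                 "duplicate")
})

test_that("gene diversity follows the unbiased estimator", {
  expect_equal(gene_diversity(c(A = 5)), 0)
  expect_equal(gene_diversity(c(A = 1, B = 1)), 1)
  expect_equal(gene_diversity(c(A = 5, B = 5)), 10 / 9 * 0.5)
  expect_true(is.na(gene_diversity(c(A = 1))))
  set.seed(5)
  for (k in 1:20) {
    cnt <- stats::setNames(sample(1:9, 4, replace = TRUE), letters[1:4])
    expect_equal(gene_diversity(cnt), oracle_gene_diversity(cnt))
  }
})

test_that("pairwise FST matches the Hudson-type estimator and oracles", {
  expect_equal(pairwise_fst(c(X = 5), c(Y = 5)), 1)
  expect_equal(pairwise_fst(c(X = 5), c(X = 5)), 0)
  expect_equal(pairwise_fst(c(X = 3, Y = 1), c(X = 1, Y = 3)), 0.2)
  expect_true(is.na(pairwise_fst(c(X = 1), c(X = 5, Y = 2))))
  # self-comparison of a polymorphic sample: the unbiased-within /
  # plain-between estimator gives exactly -1/(n-1), its small-sample bias
  a <- c(X = 4, Y = 3, Z = 2)
  expect_equal(pairwise_fst(a, a), -1 / (sum(a) - 1))
  expect_lte(pairwise_fst(a, a), 0)
  set.seed(17)
  for (k in 1:25) {
    cA <- stats::setNames(sample(0:6, 5, replace = TRUE), letters[1:5])
    cB <- stats::setNames(sample(0:6, 5, replace = TRUE), letters[1:5])
    cA <- cA[cA > 0]; cB <- cB[cB > 0]
    if (sum(cA) < 2 || sum(cB) < 2) next
    expect_equal(pairwise_fst(cA, cB), oracle_fst(cA, cB))
  }
})

test_that("Nei's DA is the 1 - sum sqrt(xy) distance", {
  expect_equal(nei_da(c(A = 1, B = 1), c(A = 1, B = 1)), 0)
  expect_equal(nei_da(c(A = 5), c(B = 5)), 1)
  expect_equal(nei_da(c(A = 10), c(A = 5, B = 5)), 1 - sqrt(0.5))
  set.seed(23)
  for (k in 1:25) {
    cA <- stats::setNames(sample(0:6, 5, replace = TRUE), letters[1:5])
    cB <- stats::setNames(sample(0:6, 5, replace = TRUE), letters[1:5])
    cA <- cA[cA > 0]; cB <- cB[cB > 0]
    if (!sum(cA) || !sum(cB)) next
    expect_equal(nei_da(cA, cB), oracle_da(cA, cB), tolerance = 1e-12)
    expect_equal(nei_da(cA, cB), nei_da(cB, cA))
    expect_gte(nei_da(cA, cB), 0)
    expect_lte(nei_da(cA, cB), 1)
  }
})

test_that("Tajima's D matches hand computation and an independent oracle", {
  t0 <- tajima_d(rep("ACGT", 4))
  expect_true(is.na(t0$D))
  expect_equal(t0$S, 0L)
  expect_equal(t0$pi, 0)

  t1 <- tajima_d(c("AAA", "AAA", "AAT", "AAT"))
  expect_equal(t1$S, 1L)
  expect_equal(t1$pi, 4 / 6)
  a1 <- 1 + 1 / 2 + 1 / 3
  o <- oracle_tajima(c("AAA", "AAA", "AAT", "AAT"))
  expect_equal(t1$D, o$D)
  # sanity on the hand-computed numerator
  expect_equal(t1$pi - t1$S / a1, 4 / 6 - 1 / a1)

  set.seed(31)
  for (k in 1:10) {
    hs <- random_hapset(10, 30)
    seqs <- unname(hs$sequences)
    mine <- tajima_d(seqs)
    theirs <- oracle_tajima(seqs)
    expect_equal(mine$S, theirs$S)
    expect_equal(mine$pi, theirs$pi)
    expect_equal(mine$D, theirs$D)
  }
})

test_that("mismatch distribution enumerates all unordered pairs", {
  mm <- mismatch(c("AAATTT", "AAATTT", "TTTTTT"))
  expect_equal(mm$counts, c(`0` = 1L, `3` = 2L))
  expect_equal(mm$n_pairs, 3L)

  mono <- mismatch(rep("ACGT", 5))
  expect_equal(mono$counts, c(`0` = 10L))
  expect_equal(mismatch_modes(mono), 1L)

  set.seed(37)
  for (k in 1:5) {
    hs <- random_hapset(8, 25)
    seqs <- unname(hs$sequences)
    mm <- mismatch(seqs)
    n <- length(seqs)
    expect_equal(sum(mm$counts), n * (n - 1L) / 2L)
    expect_equal(mm$n_pairs, n * (n - 1L) / 2L)
    # pi equals the mean of the mismatch distribution
    ks <- as.integer(names(mm$counts))
    expect_equal(sum(ks * mm$counts) / mm$n_pairs, tajima_d(seqs)$pi)
  }
})

test_that("geographic distances are great-circle km and symmetric", {
  st <- toy_table(row_def("a", "r", 43, 141, c(A = 1)),
                  row_def("b", "r", 43, 142, c(A = 1)),
                  row_def("c", "r", 43, 141, c(A = 1)))
  km <- geographic_distance(st)
  expect_equal(km["a", "c"], 0)
  expect_equal(km["a", "b"], 81.32, tolerance = 0.001)
  set.seed(41)
  st2 <- toy_table(row_def("p", "r", runif(1, 30, 50), runif(1, 130, 150),
                           c(A = 1)),
                   row_def("q", "r", runif(1, 30, 50), runif(1, 130, 150),
                           c(A = 1)))
  km2 <- geographic_distance(st2)
  expect_equal(km2["p", "q"], km2["q", "p"])
  expect_equal(attr(km2, "kind"), "geographic-km")
})

test_that("pairwise_stat_matrix averages over unordered pairs only", {
  st <- toy_table(row_def("a", "r", 43, 141, c(A = 5)),
                  row_def("b", "r", 44, 141, c(B = 5)),
                  row_def("c", "r", 45, 141, c(A = 5)))
  fst <- pairwise_stat_matrix(st, "fst")
  expect_equal(fst$matrix["a", "b"], 1)
  expect_equal(fst$matrix["a", "c"], 0)
  expect_equal(fst$mean_offdiagonal, mean(c(1, 0, 1)))
})
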
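make_unit <- function(edges) {
  g <- igraph::make_graph(edges, directed = FALSE)
  igraph::E(g)$weight <- 1
  igraph::V(g)$count <- 1
  igraph::V(g)$observed <- 1
  igraph::V(g)$loc_counts <- "{}"
  g
}

test_that("depth map is the unit-step distance from the ancestor", {
  g <- make_unit(c("K", "C", "C", "B", "B", "A"))
  d <- depth_map(g, "K")
  expect_equal(unname(d[c("K", "C", "B", "A")]), 0:3)
  expect_error(depth_map(g, "Z"), "not in network")

  # subdivided weight-3 edge: far endpoint at depth 3
  g2 <- igraph::make_graph(c("K", "A"), directed = FALSE)
  igraph::E(g2)$weight <- 3
  igraph::V(g2)$count <- 1; igraph::V(g2)$observed <- 1
  igraph::V(g2)$loc_counts <- "{}"
  u <- insert_missing(g2)
  expect_equal(unname(depth_map(u, "K")[["A"]]), 3)

  set.seed(12)
  for (k in 1:4) {
    n <- sample(6:10, 1)
    t <- igraph::sample_tree(n, method = "prufer")
    igraph::V(t)$name <- sprintf("h%d", 1:n)
    igraph::E(t)$weight <- 1
    ed <- igraph::ends(t, igraph::E(t))
    mine <- depth_map(t, "h1")
    oracle <- oracle_bfs_depth(ed, "h1")
    expect_equal(unname(mine[names(oracle)]), unname(oracle))
  }
})

test_that("timeline alignment sets all deepest tips to the same final
           slice", {
  single <- list(L1 = stats::setNames(0:3, c("K", "C", "B", "A")))
  tm <- align_timelines(single)
  expect_equal(unname(tm[c("K", "C", "B", "A")]), 1:4)

  west <- stats::setNames(0:6, paste0("w", 0:6))
  east <- stats::setNames(0:5, paste0("e", 0:5))
  tm2 <- align_timelines(list(L1 = west, L2 = east))
  expect_equal(unname(tm2[["w0"]]), 1L)
  expect_equal(unname(tm2[["e0"]]), 2L)
  expect_equal(unname(tm2[["w6"]]), 7L)
  expect_equal(unname(tm2[["e5"]]), 7L)
  expect_equal(attr(tm2, "G"), 6L)

  eq <- align_timelines(list(L1 = stats::setNames(0:2, c("a", "b", "c")),
                             L2 = stats::setNames(0:2, c("x", "y", "z"))))
  expect_equal(unname(eq[["a"]]), 1L)
  expect_equal(unname(eq[["x"]]), 1L)

  # within each lineage, T is depth shifted by a constant (slope 1)
  expect_equal(unname(diff(tm2[paste0("w", 0:6)])), rep(1L, 6))
  expect_equal(unname(diff(tm2[paste0("e", 0:5)])), rep(1L, 6)[1:5])
})

test_that("spread slices partition first appearances and carry the rest", {
  tmap <- structure(c(K = 1L, A = 2L), G = 1L,
                    lineage = c(K = "L1", A = "L1"))
  st <- toy_table(row_def("p", "r", 43, 141, c(K = 3)),
                  row_def("q", "r", 44, 141, c(A = 2, K = 1)))
  tl <- spread_slices(tmap, st)
  expect_equal(length(tl$slices), 2L)
  s1 <- tl$slices[[1]]
  expect_true(all(s1$status == "new"))
  expect_setequal(s1$location[s1$haplotype == "K"], c("p", "q"))
  s2 <- tl$slices[[2]]
  expect_equal(unique(s2$status[s2$haplotype == "K"]), "carried")
  expect_equal(unique(s2$status[s2$haplotype == "A"]), "new")
  # first appearances over all slices = observed haplotypes, once each
  firsts <- unlist(lapply(tl$slices, function(s)
    unique(s$haplotype[s$status == "new"])))
  expect_setequal(firsts, c("K", "A"))
  expect_equal(anyDuplicated(firsts), 0L)

  bad_tmap <- structure(c(K = 1L), G = 0L, lineage = c(K = "L1"))
  expect_error(spread_slices(bad_tmap, st), "consistency error")
})

test_that("projection recovers the founding order of a deterministic
           cascade", {
  sim <- simulate_fixation_cascade(
    sim_params(mode = "fixation-cascade", n_pops_per_front = 6,
               fronts = 2, fixation_prob = 1, sample_size = 8, seed = 14))
  res <- suppressWarnings(phylogeography(
    sim$haps, sim$table,
    analysis_config(mantel_permutations = 99, rng_seed = 14)))
  tl <- res$timeline
  # per front, first-appearance time of a population's haplotype must
  # increase exactly with the true founding order
  tmap <- tl$tmap
  for (fr in c("N", "S")) {
    locs <- names(sim$truth$front)[sim$truth$front == fr]
    ord <- sim$truth$founding_order[locs]
    tt <- tmap[sim$truth$pop_haplotype[locs]]
    expect_equal(unname(stats::cor(ord, tt, method = "spearman")), 1)
  }
  # slice count is 1 + maximum depth
  expect_equal(length(tl$slices), 1L + max(unlist(res$depths)))
})

test_that("rendered maps produce one deterministic file per slice", {
  tmap <- structure(c(K = 1L, A = 2L, B = 3L), G = 2L,
                    lineage = c(K = "L1", A = "L1", B = "L1"))
  st <- toy_table(row_def("p", "r", 43, 141, c(K = 3, B = 1)),
                  row_def("q", "r", 44, 141, c(A = 2)))
  tl <- spread_slices(tmap, st)
  d <- withr::local_tempdir()
  paths <- render_maps(tl, d)
  expect_equal(length(paths), 3L)
  expect_true(all(file.exists(paths)))
  sizes1 <- file.size(paths)
  render_maps(tl, d)
  expect_equal(file.size(paths), sizes1)
})
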
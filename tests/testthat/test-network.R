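unit_tree <- function(edge_pairs, counts = NULL) {
  g <- igraph::make_graph(edge_pairs, directed = FALSE)
  igraph::E(g)$weight <- 1
  ids <- igraph::V(g)$name
  igraph::V(g)$count <- if (is.null(counts)) rep(1, length(ids))
                        else counts[ids]
  igraph::V(g)$observed <- 1
  igraph::V(g)$loc_counts <- "{}"
  g
}

test_that("build_msn includes exactly the union-of-MST edges", {
  d <- dist_matrix(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3),
                   c("A", "B", "C"))
  g <- build_msn(d)
  expect_setequal(edge_keys(g), c("A|B", "B|C"))

  d2 <- dist_matrix(matrix(1, 3, 3) - diag(3), c("A", "B", "C"))
  g2 <- build_msn(d2)
  expect_equal(igraph::ecount(g2), 3L) # equilateral: full loop

  set.seed(7)
  for (k in 1:6) {
    n <- sample(4:6, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- sample(1:4, n * (n - 1) / 2, replace = TRUE)
    m <- m + t(m)
    d <- dist_matrix(m, LETTERS[1:n])
    g <- build_msn(d)
    expect_setequal(edge_keys(g), oracle_msn_edges(d))
  }
})

test_that("some spanning tree inside the MSN attains the minimum weight", {
  set.seed(8)
  n <- 6
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- sample(1:5, n * (n - 1) / 2, replace = TRUE)
  m <- m + t(m)
  d <- dist_matrix(m, LETTERS[1:n])
  g <- build_msn(d)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  full <- igraph::graph_from_adjacency_matrix(unclass(d)[, ],
    mode = "undirected", weighted = TRUE)
  best <- sum(igraph::E(igraph::mst(full))$weight)
  expect_equal(sum(igraph::E(mst)$weight), best)
})

test_that("loop resolution follows frequency, then geography, and keeps
           the graph spanning", {
  d <- dist_matrix(matrix(1, 3, 3) - diag(3), c("A", "B", "C"))
  net <- build_msn(d)
  igraph::V(net)$count <- c(10, 10, 1)
  r <- resolve_loops(net)
  expect_true("A|B" %in% edge_keys(r))
  expect_equal(igraph::ecount(r), 2L)
  expect_equal(igraph::components(r)$no, 1L)

  # equal counts: geography decides; C is sampled far away so its long
  # edge to the distant partner goes
  st <- toy_table(row_def("pA", "r", 43.0, 141, c(A = 5)),
                  row_def("pB", "r", 43.1, 141, c(B = 5)),
                  row_def("pC", "r", 47.5, 141, c(C = 5)))
  net2 <- build_msn(d, st)
  expect_true(all(igraph::V(net2)$count == 5))
  r2 <- resolve_loops(net2, st)
  expect_equal(igraph::ecount(r2), 2L)
  # A and B co-occur nearby; the deleted edge is one of C's
  expect_true("A|B" %in% edge_keys(r2))

  # acyclic input is untouched
  tree <- unit_tree(c("A", "B", "B", "C"))
  expect_equal(edge_keys(resolve_loops(tree)), edge_keys(tree))
})

test_that("loop resolution never disconnects on random loopy instances", {
  set.seed(9)
  for (k in 1:6) {
    n <- sample(5:7, 1)
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- sample(1:3, n * (n - 1) / 2, replace = TRUE)
    m <- m + t(m)
    net <- build_msn(dist_matrix(m, LETTERS[1:n]))
    igraph::V(net)$count <- sample(1:20, n, replace = TRUE)
    r <- resolve_loops(net)
    comp <- igraph::components(r)
    expect_equal(comp$no, igraph::components(net)$no)
    expect_equal(igraph::ecount(r), igraph::vcount(r) - comp$no)
  }
})

test_that("latent insertion preserves all pairwise step distances", {
  g <- unit_tree(c("A", "B"))
  igraph::E(g)$weight <- 3
  u <- insert_missing(g)
  expect_equal(igraph::vcount(u), 4L)
  expect_equal(igraph::ecount(u), 3L)
  expect_true(all(igraph::E(u)$weight == 1))
  expect_equal(sum(igraph::V(u)$observed == 0), 2L)

  # all-unit network: identity
  g2 <- unit_tree(c("A", "B", "B", "C"))
  expect_equal(igraph::vcount(insert_missing(g2)), 3L)

  set.seed(10)
  for (k in 1:5) {
    n <- 6
    # random tree with random integer weights
    pr <- sample(n, n - 2, replace = TRUE)
    d <- matrix(0, n, n)
    g3 <- igraph::sample_tree(n, method = "prufer")
    igraph::V(g3)$name <- LETTERS[1:n]
    igraph::E(g3)$weight <- sample(1:4, n - 1, replace = TRUE)
    igraph::V(g3)$count <- 1
    igraph::V(g3)$observed <- 1
    igraph::V(g3)$loc_counts <- "{}"
    u3 <- insert_missing(g3)
    dist_w <- igraph::distances(g3, weights = igraph::E(g3)$weight)
    dist_u <- igraph::distances(u3, weights = NA)[LETTERS[1:n], LETTERS[1:n]]
    expect_equal(unname(dist_u), unname(dist_w))
  }
})

test_that("lineage splitting cuts edges at the threshold", {
  g <- unit_tree(c("A", "B", "B", "C", "C", "D"))
  igraph::E(g)$weight <- c(1, 7, 1)
  lm <- split_lineages(g, 5)
  expect_equal(length(unique(lm$assignment)), 2L)
  expect_equal(unname(lm$assignment["A"]), unname(lm$assignment["B"]))
  expect_equal(nrow(lm$split_edges), 1L)

  g2 <- unit_tree(c("A", "B", "B", "C"))
  expect_warning(lm2 <- split_lineages(g2, 5), "single lineage")
  expect_equal(length(unique(lm2$assignment)), 1L)

  g3 <- unit_tree(c("A", "B", "B", "C", "C", "D"))
  igraph::E(g3)$weight <- c(7, 1, 9)
  lm3 <- split_lineages(g3, 5)
  expect_equal(length(unique(lm3$assignment)), 3L)
  # largest component gets L1
  expect_equal(unname(lm3$assignment["B"]), "L1")
})

test_that("ancestor inference balances abundance and centrality", {
  star <- unit_tree(c("X", "A", "X", "B", "X", "C", "X", "D"),
                    counts = c(X = 30, A = 1, B = 1, C = 1, D = 1))
  expect_equal(infer_ancestor(star, igraph::V(star)$name), "X")

  path <- unit_tree(c("A", "B", "B", "C", "C", "D", "D", "E"),
                    counts = c(A = 2, B = 2, C = 2, D = 2, E = 2))
  expect_equal(infer_ancestor(path, igraph::V(path)$name), "C")
})

test_that("Templeton-Sing nesting matches the worked path and star cases", {
  path <- unit_tree(c("A", "B", "B", "C", "C", "D", "D", "E"))
  nc <- nest_clades(path)
  lvl1 <- nc$levels[[1]]
  expect_equal(length(lvl1), 2L)
  expect_true(any(vapply(lvl1, function(x) setequal(x, c("A", "B")),
                         logical(1))))
  expect_true(any(vapply(lvl1, function(x) setequal(x, c("C", "D", "E")),
                         logical(1))))

  star <- unit_tree(c("X", "A", "X", "B", "X", "C", "X", "D"))
  expect_equal(length(nest_clades(star)$levels[[1]]), 1L)
})

test_that("every node lies in exactly one clade per nesting level", {
  set.seed(11)
  for (k in 1:5) {
    n <- sample(6:12, 1)
    g <- igraph::sample_tree(n, method = "prufer")
    igraph::V(g)$name <- sprintf("h%02d", 1:n)
    igraph::E(g)$weight <- 1
    igraph::V(g)$count <- 1
    igraph::V(g)$observed <- 1
    igraph::V(g)$loc_counts <- "{}"
    nc <- nest_clades(g)
    for (lvl in nc$levels) {
      members <- unname(unlist(lvl))
      expect_equal(sort(members), sort(igraph::V(g)$name))
      expect_equal(anyDuplicated(members), 0L)
    }
  }
})
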
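# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's own computation paths: direct formulas, exhaustive
# enumeration and brute force only.

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = "")

# a random haplotype set of n sequences of length L (substitutions only)
random_hapset <- function(n, L, mut_per_seq = 3L) {
  root <- strsplit(random_dna(L), "")[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    v <- root
    k <- sample.int(mut_per_seq + 1L, 1L) - 1L
    if (k > 0) for (s in sample.int(L, k))
      v[s] <- sample(setdiff(c("A", "C", "G", "T"), v[s]), 1L)
    paste(v, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("h%02d", seq_len(n))
  haplotype_set(seqs)
}

# brute-force substitution count, written independently (chartr-free)
oracle_subs <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  bases <- utf8ToInt("ACGT")
  sum(av %in% bases & bv %in% bases & av != bv)
}

# direct-formula diversity / FST / DA oracles on frequency vectors
oracle_gene_diversity <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p * p))
}

oracle_fst <- function(cA, cB) {
  ids <- union(names(cA), names(cB))
  fA <- fB <- rep(0, length(ids)); names(fA) <- names(fB) <- ids
  fA[names(cA)] <- cA / sum(cA); fB[names(cB)] <- cB / sum(cB)
  hw <- (oracle_gene_diversity(cA) + oracle_gene_diversity(cB)) / 2
  hb <- 1 - sum(fA * fB)
  if (hb <= 0) 0 else min(1, 1 - hw / hb)
}

oracle_da <- function(cA, cB) {
  ids <- union(names(cA), names(cB))
  fA <- fB <- rep(0, length(ids)); names(fA) <- names(fB) <- ids
  fA[names(cA)] <- cA / sum(cA); fB[names(cB)] <- cB / sum(cB)
  1 - sum(sqrt(fA * fB))
}

# straight-from-formula Tajima's D on a character vector of sequences
oracle_tajima <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  is_base <- function(x) x %in% c("A", "C", "G", "T")
  S <- 0
  for (j in seq_len(ncol(m))) {
    col <- m[, j][is_base(m[, j])]
    if (length(unique(col)) > 1) S <- S + 1
  }
  tot <- 0
  pairs <- utils::combn(n, 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok <- is_base(m[i, ]) & is_base(m[j, ])
    tot <- tot + sum(m[i, ok] != m[j, ok])
  }
  pi <- tot / ncol(pairs)
  if (S == 0 || n < 4) return(list(D = NA_real_, S = S, pi = pi))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(D = (pi - S / a1) / sqrt((c1 / a1) * S +
         (c2 / (a1^2 + a2)) * S * (S - 1)), S = S, pi = pi)
}

# all labelled spanning trees of the complete graph on n nodes via Prufer
# sequences; returns the union of edges over all minimum-weight trees
oracle_msn_edges <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  prufer_to_edges <- function(pr) {
    degree <- rep(1L, n)
    for (x in pr) degree[x] <- degree[x] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    ptr <- 1L
    pr2 <- pr
    for (x in pr2) {
      leaf <- min(which(degree == 1L))
      edges[ptr, ] <- c(leaf, x); ptr <- ptr + 1L
      degree[leaf] <- 0L; degree[x] <- degree[x] - 1L
    }
    rest <- which(degree == 1L)
    edges[ptr, ] <- rest
    edges
  }
  seqs <- if (n == 2) list(integer(0)) else {
    grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 2L))
    lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  }
  best <- Inf; union_edges <- character(0)
  for (pr in seqs) {
    e <- prufer_to_edges(pr)
    w <- sum(d[e])
    keys <- apply(e, 1, function(r)
      paste(sort(labels[r]), collapse = "|"))
    if (w < best - 1e-9) { best <- w; union_edges <- keys }
    else if (abs(w - best) < 1e-9) union_edges <- union(union_edges, keys)
  }
  sort(union_edges)
}

edge_keys <- function(g) {
  e <- igraph::ends(g, igraph::E(g))
  sort(apply(e, 1, function(r) paste(sort(r), collapse = "|")))
}

# exhaustive Mantel p over all n! label permutations, direct cor()
oracle_mantel_exhaustive <- function(mA, mB) {
  n <- nrow(mA)
  lt <- lower.tri(mA)
  r_obs <- cor(mA[lt], mB[lt])
  perms <- perm_all(n)
  rs <- apply(perms, 1, function(p) cor(mA[lt], mB[p, p][lt]))
  list(r = r_obs,
       p_two = mean(abs(rs) >= abs(r_obs) - 1e-12),
       p_greater = mean(rs >= r_obs - 1e-12),
       p_less = mean(rs <= r_obs + 1e-12))
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  smaller <- perm_all(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, smaller + (smaller >= i))
    out <- rbind(out, block)
  }
  out
}

# independent BFS depths on an edge list
oracle_bfs_depth <- function(edges, start) {
  depth <- stats::setNames(Inf, start)
  frontier <- start
  d <- 0
  nodes <- unique(c(edges[, 1], edges[, 2]))
  depth <- stats::setNames(rep(Inf, length(nodes)), nodes)
  depth[start] <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- character(0)
    for (v in frontier) {
      nb <- c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
      nb <- nb[depth[nb] == Inf]
      depth[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  depth
}

# small literal sample table builder
toy_table <- function(..., haps = NULL) {
  rows <- list(...)
  hap_ids <- sort(unique(unlist(lapply(rows, function(r) names(r$counts)))))
  df <- do.call(rbind, lapply(rows, function(r) {
    cnt <- stats::setNames(rep(0, length(hap_ids)), hap_ids)
    cnt[names(r$counts)] <- r$counts
    cbind(data.frame(location = r$loc, region = r$region,
                     lat = r$lat, lon = r$lon, stringsAsFactors = FALSE),
          as.data.frame(as.list(cnt)))
  }))
  names(df) <- c("location", "region", "lat", "lon", hap_ids)
  sample_table(df, haps = haps)
}

row_def <- function(loc, region, lat, lon, counts)
  list(loc = loc, region = region, lat = lat, lon = lon, counts = counts)
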
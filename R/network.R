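#' Build the minimum spanning network over haplotypes
#'
#' The minimum spanning network (MSN) is the union of all minimum spanning
#' trees of the complete graph weighted by mutational steps. An edge
#' (u, v, w) is included exactly when u and v fall in different connected
#' components of the graph restricted to edges of weight strictly less
#' than w; ties in w therefore produce loops.
#'
#' @param steps integer `dist_matrix` of kind "mutation-steps".
#' @param table optional [sample_table()]; when given, per-haplotype total
#'   counts and per-location counts are attached as node attributes.
#' @return An `igraph` graph with vertex attributes `name`, `count`,
#'   `observed` (1/0) and edge attribute `weight`.
#' @export
build_msn <- function(steps, table = NULL) {
  ids <- rownames(steps)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 haplotypes", call. = FALSE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  ut <- which(upper.tri(steps), arr.ind = TRUE)
  w <- steps[upper.tri(steps)]
  ord <- order(w)
  ut <- ut[ord, , drop = FALSE]
  w <- w[ord]
  for (lev in unique(w)) {
    sel <- which(w == lev)
    comp <- igraph::components(g)$membership
    take <- sel[comp[ut[sel, 1L]] != comp[ut[sel, 2L]]]
    if (length(take)) {
      edges <- rbind(ids[ut[take, 1L]], ids[ut[take, 2L]])
      g <- igraph::add_edges(g, as.vector(edges), weight = w[take])
    }
  }
  decorate_network(g, table)
}

# attach count / observed / per-location-count attributes
decorate_network <- function(g, table = NULL) {
  ids <- igraph::V(g)$name
  counts <- stats::setNames(numeric(length(ids)), ids)
  loc_json <- stats::setNames(rep("{}", length(ids)), ids)
  if (!is.null(table)) {
    cnt <- hap_counts(table)
    for (h in intersect(ids, colnames(cnt))) {
      counts[h] <- sum(cnt[, h])
      nz <- cnt[, h][cnt[, h] > 0]
      loc_json[h] <- as.character(jsonlite::toJSON(as.list(nz),
                                                   auto_unbox = TRUE))
    }
  }
  igraph::V(g)$count <- unname(counts)
  igraph::V(g)$observed <- 1
  igraph::V(g)$loc_counts <- unname(loc_json)
  g
}

# edges that currently sit on a cycle = non-bridges
cycle_edges <- function(g) {
  setdiff(seq_len(igraph::ecount(g)), igraph::bridges(g))
}

#' Resolve loops of a minimum spanning network
#'
#' Deterministically reduces the MSN to a spanning tree (per component) by
#' repeatedly deleting one cycle edge, chosen by ordered criteria in the
#' spirit of coalescent expectations for haplotype networks:
#' \enumerate{
#'   \item frequency: delete the cycle edge whose endpoint haplotype
#'     counts sum to the least (edges between common haplotypes are kept);
#'   \item topology: among ties, delete the edge whose endpoint degrees
#'     sum to the least (edges to interior nodes are kept over tip edges);
#'   \item geography: among remaining ties, delete the edge whose endpoint
#'     haplotypes are sampled farthest apart (minimum great-circle
#'     distance over their location pairs; co-occurrence gives 0 km);
#'   \item fallback: delete the lexicographically last edge label.
#' }
#'
#' @param net MSN from [build_msn()].
#' @param table optional [sample_table()] supplying counts and the
#'   geography criterion.
#' @return An acyclic `igraph` network spanning the same nodes.
#' @export
resolve_loops <- function(net, table = NULL) {
  g <- net
  counts <- stats::setNames(igraph::V(g)$count, igraph::V(g)$name)
  geo <- NULL
  if (!is.null(table)) {
    km <- geographic_distance(table)
    cnt <- hap_counts(table)
    geo <- function(u, v) {
      lu <- rownames(cnt)[cnt[, u] > 0]
      lv <- rownames(cnt)[cnt[, v] > 0]
      if (!length(lu) || !length(lv)) return(Inf)
      min(km[lu, lv, drop = FALSE])
    }
  }
  repeat {
    cand <- cycle_edges(g)
    if (!length(cand)) break
    ep <- igraph::ends(g, cand)
    csum <- counts[ep[, 1L]] + counts[ep[, 2L]]
    cand <- cand[csum == min(csum)]
    if (length(cand) > 1L) {
      ep <- igraph::ends(g, cand)
      dsum <- igraph::degree(g, ep[, 1L]) + igraph::degree(g, ep[, 2L])
      cand <- cand[dsum == min(dsum)]
    }
    if (length(cand) > 1L && !is.null(geo)) {
      ep <- igraph::ends(g, cand)
      dist <- mapply(geo, ep[, 1L], ep[, 2L])
      cand <- cand[dist == max(dist)]
    }
    if (length(cand) > 1L) {
      ep <- igraph::ends(g, cand)
      lab <- paste(pmin(ep[, 1L], ep[, 2L]), pmax(ep[, 1L], ep[, 2L]),
                   sep = "|")
      cand <- cand[which.max(rank(lab, ties.method = "first"))]
    }
    g <- igraph::delete_edges(g, cand[1L])
  }
  g
}

#' Insert missing (latent) haplotypes
#'
#' Every edge of weight k > 1 is replaced by a path through k - 1 latent
#' nodes (auto-named m1, m2, ...) with k unit edges, so that graph distance
#' in unit steps equals the original weighted distance exactly. Latent
#' nodes carry count 0 and `observed = 0`.
#'
#' @param net resolved (acyclic) network.
#' @return Unit-step `igraph` network.
#' @export
insert_missing <- function(net) {
  g <- net
  counter <- sum(grepl("^m[0-9]+$", igraph::V(g)$name))
  repeat {
    w <- igraph::E(g)$weight
    heavy <- which(w > 1)
    if (!length(heavy)) break
    e <- heavy[1L]
    ep <- igraph::ends(g, e)
    k <- w[e]
    g <- igraph::delete_edges(g, e)
    chain <- character(k - 1L)
    for (i in seq_len(k - 1L)) {
      counter <- counter + 1L
      chain[i] <- paste0("m", counter)
    }
    g <- igraph::add_vertices(g, k - 1L, name = chain,
                              count = rep(0, k - 1L),
                              observed = rep(0, k - 1L),
                              loc_counts = rep("{}", k - 1L))
    path <- c(ep[1L], chain, ep[2L])
    for (i in seq_len(k))
      g <- igraph::add_edges(g, c(path[i], path[i + 1L]), weight = 1)
  }
  g
}

#' Split deeply divergent lineages
#'
#' Removes every edge of weight >= `min_split_steps` from the resolved
#' (pre-subdivision) network; each remaining component is a lineage.
#' Lineages are labeled "L1", "L2", ... by decreasing size (number of
#' haplotypes, ties broken by total count then by smallest member ID).
#'
#' @param net resolved network with weighted edges (before
#'   [insert_missing()]).
#' @param min_split_steps split threshold in mutational steps.
#' @return List of class `lineage_map`: `assignment` (haplotype -> lineage
#'   label), `ancestors` (empty until [infer_ancestor()] fills it),
#'   `split_edges` (data frame of removed edges).
#' @export
split_lineages <- function(net, min_split_steps = 5L) {
  w <- igraph::E(net)$weight
  cut <- which(w >= min_split_steps)
  if (!length(cut))
    warning("no edge reaches the split threshold; single lineage")
  ep <- igraph::ends(net, cut)
  g <- igraph::delete_edges(net, cut)
  comp <- igraph::components(g)$membership
  ids <- igraph::V(net)$name
  counts <- stats::setNames(igraph::V(net)$count, ids)
  size <- table(comp)
  key <- vapply(names(size), function(k) {
    members <- ids[comp == as.integer(k)]
    sprintf("%06d|%012.1f|%s", length(members),
            sum(counts[members]), min(members))
  }, character(1L))
  ord <- order(key, decreasing = TRUE)
  lab <- stats::setNames(paste0("L", seq_along(ord)), names(size)[ord])
  assignment <- stats::setNames(unname(lab[as.character(comp)]), ids)
  structure(list(assignment = assignment,
                 ancestors = stats::setNames(character(0), character(0)),
                 split_edges = data.frame(from = ep[, 1L], to = ep[, 2L],
                                          weight = w[cut],
                                          stringsAsFactors = FALSE)),
            class = "lineage_map")
}

#' @export
print.lineage_map <- function(x, ...) {
  tab <- table(x$assignment)
  cat("Lineages:", length(tab), "\n")
  for (l in names(tab)) {
    anc <- if (l %in% names(x$ancestors)) x$ancestors[[l]] else "?"
    cat(" ", l, ":", tab[[l]], "haplotypes, ancestor:", anc, "\n")
  }
  invisible(x)
}

#' Infer the ancestral haplotype of a lineage
#'
#' Coalescent reasoning predicts that the oldest extant haplotype is both
#' common and interior in the network. Each observed haplotype h is scored
#' `0.5 * count_h / max(count) + 0.5 * Cmin / C_h`, where `C_h` is the
#' eccentricity of h in the unit-step lineage subgraph and `Cmin` its
#' minimum over the lineage; the highest score wins (ties: larger raw
#' count, then lexicographically smallest ID). Latent nodes are never
#' eligible.
#'
#' @param net unit-step network (after [insert_missing()]).
#' @param lineage character vector of node IDs of one lineage (observed
#'   and latent); or a `lineage_map` plus `label`.
#' @param label when `lineage` is a `lineage_map`, the lineage label.
#' @return The ancestral haplotype ID.
#' @export
infer_ancestor <- function(net, lineage, label = NULL) {
  if (inherits(lineage, "lineage_map")) {
    members <- names(lineage$assignment)[lineage$assignment == label]
  } else members <- lineage
  ids <- igraph::V(net)$name
  # include latent nodes lying inside the lineage's component(s)
  comp <- igraph::components(net)$membership
  target <- unique(comp[match(intersect(members, ids), ids)])
  sub <- igraph::subgraph(net, igraph::V(net)[comp %in% target])
  sids <- igraph::V(sub)$name
  obs <- igraph::V(sub)$observed == 1
  if (!any(obs)) stop("lineage has no observed haplotype", call. = FALSE)
  ecc <- igraph::eccentricity(sub)
  counts <- stats::setNames(igraph::V(sub)$count, sids)
  cand <- sids[obs]
  cmin <- min(ecc[cand])
  cmax <- max(counts[cand])
  score <- 0.5 * (if (cmax > 0) counts[cand] / cmax else 1) +
    0.5 * cmin / ecc[cand]
  ord <- order(-score, -counts[cand], cand)
  cand[ord[1L]]
}

#' Templeton-Sing nested clades
#'
#' Hierarchical nesting of a unit-step haplotype tree (latent nodes
#' included): at each level, tips are united with their adjacent interior
#' node into one-step clades, the procedure moves inward on the remaining
#' tree, and stranded singletons join the adjacent nest with the fewest
#' members (ties resolved toward the lexicographically greater neighbouring
#' clade). Two levels are built.
#'
#' @param net unit-step resolved tree from [insert_missing()].
#' @param levels number of nesting levels to build (default 2).
#' @return List of class `nested_clades`; element `levels` is a list whose
#'   k-th entry is a named list of character vectors giving each level-k
#'   clade's level-0 members.
#' @export
nest_clades <- function(net, levels = 2L) {
  ids <- igraph::V(net)$name
  # current partition: named list cladeName -> level-0 members
  part <- stats::setNames(lapply(ids, identity), ids)
  adj_of <- function(g) g
  g <- net
  out <- vector("list", levels)
  for (lev in seq_len(levels)) {
    if (igraph::vcount(g) <= 1L) {
      nests <- stats::setNames(list(igraph::V(g)$name), paste0(lev, "-1"))
      members <- lapply(nests, function(cl) unlist(part[cl], use.names = FALSE))
      out[[lev]] <- members
      part <- stats::setNames(list(unlist(part, use.names = FALSE)),
                              names(nests))
      g <- igraph::make_empty_graph(1, directed = FALSE)
      igraph::V(g)$name <- names(nests)
      next
    }
    nodes <- igraph::V(g)$name
    allocated <- character(0)
    nests <- list() # list of character vectors of node names
    stranded <- character(0)
    remaining <- nodes
    while (length(remaining)) {
      sub <- igraph::subgraph(g, igraph::V(g)[nodes %in% remaining])
      deg <- igraph::degree(sub)
      snames <- igraph::V(sub)$name
      if (length(remaining) == 1L) {
        stranded <- c(stranded, remaining)
        remaining <- character(0)
        break
      }
      if (length(remaining) == 2L && igraph::ecount(sub) == 1L) {
        nests[[length(nests) + 1L]] <- sort(remaining)
        remaining <- character(0)
        break
      }
      tips <- snames[deg <= 1L]
      lone <- tips[deg[tips] == 0L] # neighbors already allocated
      stranded <- c(stranded, lone)
      tips <- setdiff(tips, lone)
      interiors <- unique(unlist(lapply(tips, function(t)
        igraph::neighbors(sub, t)$name)))
      used <- character(0)
      for (i in sort(interiors)) {
        if (i %in% used) next
        mates <- setdiff(intersect(igraph::neighbors(sub, i)$name, tips),
                         used)
        if (i %in% tips && !length(mates)) next
        nests[[length(nests) + 1L]] <- sort(c(i, mates))
        used <- c(used, i, mates)
      }
      remaining <- setdiff(remaining, c(lone, unlist(nests)))
    }
    # attach stranded singletons to the adjacent nest with fewest members
    for (s in sort(stranded)) {
      nb <- igraph::neighbors(g, s)$name
      host <- which(vapply(nests, function(ns) any(nb %in% ns), logical(1L)))
      if (!length(host)) { nests[[length(nests) + 1L]] <- s; next }
      sizes <- lengths(nests[host])
      host <- host[sizes == min(sizes)]
      if (length(host) > 1L) {
        # tie: join via the lexicographically greater neighbouring clade
        via <- vapply(host, function(hh)
          max(intersect(nb, nests[[hh]])), character(1L))
        host <- host[which.max(rank(via, ties.method = "first"))]
      }
      nests[[host[1L]]] <- sort(c(nests[[host[1L]]], s))
    }
    names(nests) <- paste0(lev, "-", seq_along(nests))
    members <- lapply(nests, function(cl)
      sort(unlist(part[cl], use.names = FALSE)))
    out[[lev]] <- members
    # build the next-level clade graph
    part <- members
    ng <- igraph::make_empty_graph(length(nests), directed = FALSE)
    igraph::V(ng)$name <- names(nests)
    ep <- igraph::ends(g, igraph::E(g))
    owner <- stats::setNames(rep(names(nests), lengths(nests)),
                             unlist(nests))
    for (k in seq_len(nrow(ep))) {
      a <- owner[[ep[k, 1L]]]; b <- owner[[ep[k, 2L]]]
      if (a != b && !igraph::are_adjacent(ng, a, b))
        ng <- igraph::add_edges(ng, c(a, b))
    }
    g <- ng
  }
  structure(list(levels = out), class = "nested_clades")
}

#' @export
print.nested_clades <- function(x, ...) {
  for (lev in seq_along(x$levels)) {
    cat("Level", lev, ":", length(x$levels[[lev]]), "clades\n")
  }
  invisible(x)
}

#' Write / read a mutation network as GraphML
#'
#' Node attributes `count`, `observed` (1/0) and `loc_counts` (JSON map of
#' per-location counts) and the edge attribute `weight` are preserved.
#'
#' @param net `igraph` network.
#' @param path file path.
#' @return `path` invisibly; `read_network` returns the graph.
#' @export
write_network <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  if (!is.null(igraph::vertex_attr(g, "id")) &&
      is.null(igraph::vertex_attr(g, "name")))
    igraph::V(g)$name <- igraph::vertex_attr(g, "id")
  g
}
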
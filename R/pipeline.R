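#' Full phylogeographic analysis of a haplotype dataset
#'
#' Runs the complete inference chain on an aligned haplotype set and a
#' sample table: pooling and sample-size filtering, per-population
#' diversity, pairwise FST / Nei's DA / geographic distance matrices,
#' minimum-spanning-network construction with deterministic loop
#' resolution and latent-haplotype insertion, lineage splitting and
#' per-lineage ancestor inference, Templeton-Sing nesting,
#' isolation-by-distance Mantel tests, Tajima's D and mismatch
#' distributions, stepwise-colonization (Good model) tests, molecular-clock
#' dating of the lineage split, and the time-sliced genealogical spread
#' projection.
#'
#' @param haps a [haplotype_set()].
#' @param table a [sample_table()].
#' @param config an [analysis_config()].
#' @return An object of class `phylogeography`; see the elements described
#'   in Details. Use `print()`, `summary()` and `plot()` on it.
#' @details Elements: `pooled`/`filtered` tables, `pop_stats` data frame,
#'   `steps`, `fst`, `da`, `km` matrices with `mean_fst`/`mean_da`,
#'   `msn`, `network` (resolved), `unit_network`, `lineages`
#'   (`lineage_map` with ancestors), `nested`, `ibd` (overall and per
#'   lineage), `tajima`, `mismatch`, `good` (per-lineage colonization
#'   tests), `clock`, `timeline`, `config`.
#' @export
phylogeography <- function(haps, table, config = analysis_config()) {
  stopifnot(inherits(haps, "haplotype_set"), inherits(table, "sample_table"))
  pooled <- pool_populations(table, config$pooling)
  filtered <- filter_populations(pooled, config$min_sample_size)

  observed <- colnames(hap_counts(pooled))[colSums(hap_counts(pooled)) > 0]
  net_haps <- haplotype_set(haps$sequences[observed])
  steps <- step_matrix(net_haps)

  msn <- build_msn(steps, pooled)
  resolved <- resolve_loops(msn, pooled)
  lineages <- split_lineages(resolved, config$lineage_split_steps)
  unit_full <- insert_missing(resolved)
  nested <- nest_clades(unit_full)

  # per-lineage unit-step forest for depths/ancestors (bridges removed)
  w <- igraph::E(resolved)$weight
  forest <- igraph::delete_edges(resolved,
                                 which(w >= config$lineage_split_steps))
  unit_forest <- insert_missing(forest)

  labs <- sort(unique(lineages$assignment))
  anc <- stats::setNames(character(length(labs)), labs)
  for (l in labs) anc[l] <- infer_ancestor(unit_forest, lineages, l)
  lineages$ancestors <- anc

  # population-level assignment: lineage of the majority of its individuals
  cnt_f <- hap_counts(filtered)
  pop_lineage <- apply(cnt_f, 1L, function(row) {
    per <- tapply(row[row > 0], lineages$assignment[names(row[row > 0])], sum)
    names(per)[which.max(per)]
  })

  h <- apply(cnt_f, 1L, function(row) gene_diversity(row[row > 0]))
  pop_stats <- data.frame(location = filtered$location,
                          region = filtered$region,
                          n = rowSums(cnt_f),
                          n_haplotypes = rowSums(cnt_f > 0),
                          gene_diversity = unname(h),
                          lineage = unname(pop_lineage),
                          stringsAsFactors = FALSE)

  fst <- pairwise_stat_matrix(filtered, "fst")
  da <- pairwise_stat_matrix(filtered, "da")
  km <- geographic_distance(filtered)

  seed <- config$rng_seed
  nperm <- config$mantel_permutations
  ibd <- list()
  if (nrow(filtered) >= 4L)
    ibd$overall <- ibd_test(filtered, haps, nperm = nperm,
                            seed = seed + 10L)
  for (l in labs) {
    locs <- pop_stats$location[pop_stats$lineage == l]
    if (length(locs) >= 4L)
      ibd[[l]] <- ibd_test(filtered, haps, subset = locs, nperm = nperm,
                           seed = seed + 20L + match(l, labs))
  }

  taj <- list(overall = tajima_d(expand_individuals(filtered, haps)))
  mm <- list(overall = mismatch(expand_individuals(filtered, haps)))
  for (l in labs) {
    locs <- pop_stats$location[pop_stats$lineage == l]
    if (length(locs)) {
      sq <- expand_individuals(filtered, haps, locations = locs)
      if (length(sq) >= 4L) taj[[l]] <- tajima_d(sq)
      if (length(sq) >= 2L) mm[[l]] <- mismatch(sq)
    }
  }

  good <- list()
  alt <- if (config$one_sided_good_tests) "less" else "two.sided"
  for (l in labs) {
    locs <- pop_stats$location[pop_stats$lineage == l]
    if (length(locs) < 4L) next
    anc_hap <- anc[[l]]
    cnt_l <- cnt_f[locs, , drop = FALSE]
    anc_loc <- if (anc_hap %in% colnames(cnt_l) &&
                   any(cnt_l[, anc_hap] > 0))
      locs[which.max(cnt_l[, anc_hap])] else locs[1L]
    good[[l]] <- list(
      ancestor_haplotype = anc_hap, ancestor_location = anc_loc,
      n_pops = length(locs),
      pairwise = good_model_pair_test(filtered, haps, lineage = locs,
                                      ancestor_location = anc_loc,
                                      nperm = nperm,
                                      seed = seed + 40L + match(l, labs),
                                      alternative = alt),
      diversity = good_model_diversity_test(filtered, lineage = locs,
                                            ancestor_location = anc_loc))
  }

  clock <- NULL
  if (length(labs) >= 2L) {
    a1 <- names(lineages$assignment)[lineages$assignment == labs[1L]]
    a2 <- names(lineages$assignment)[lineages$assignment == labs[2L]]
    a1 <- intersect(a1, rownames(steps)); a2 <- intersect(a2, rownames(steps))
    cross <- steps[a1, a2, drop = FALSE]
    clock <- list(
      min_split_steps = min(cross),
      mean_cross_steps = mean(cross),
      split = clock_dating(min(cross), haps$length,
                           config$clock_rate_low, config$clock_rate_high),
      mean_divergence_percent = 100 * mean(cross) / haps$length)
  }

  depths <- list()
  for (l in labs) {
    members <- names(lineages$assignment)[lineages$assignment == l]
    dm <- depth_map(unit_forest, anc[[l]])
    depths[[l]] <- dm
  }
  tmap <- align_timelines(depths)
  timeline <- spread_slices(tmap, pooled)

  structure(list(haps = haps, input = table, pooled = pooled,
                 filtered = filtered, pop_stats = pop_stats,
                 steps = steps, fst = fst$matrix, da = da$matrix, km = km,
                 mean_fst = fst$mean_offdiagonal,
                 mean_da = da$mean_offdiagonal,
                 msn = msn, network = resolved, unit_network = unit_full,
                 unit_forest = unit_forest,
                 lineages = lineages, nested = nested, ibd = ibd,
                 tajima = taj, mismatch = mm, good = good, clock = clock,
                 depths = depths, timeline = timeline, config = config),
            class = "phylogeography")
}

#' @export
print.phylogeography <- function(x, ...) {
  cat("Phylogeographic analysis\n")
  cat(sprintf("  %d haplotypes, %d sites; %d locations (%d after n >= %d filter)\n",
              length(x$haps), x$haps$length, nrow(x$pooled),
              nrow(x$filtered), x$config$min_sample_size))
  cat(sprintf("  mean pairwise FST = %.2f, mean Nei's DA = %.2f\n",
              x$mean_fst, x$mean_da))
  tab <- table(x$lineages$assignment)
  cat(sprintf("  %d lineage(s): %s\n", length(tab),
              paste(sprintf("%s (%d haps, ancestor %s)", names(tab), tab,
                            x$lineages$ancestors[names(tab)]),
                    collapse = ", ")))
  if (!is.null(x$clock))
    cat(sprintf("  lineage split: >= %d steps, %.2f%% mean divergence, dated %.1f-%.1f Myr\n",
                x$clock$min_split_steps, x$clock$mean_divergence_percent,
                round(x$clock$mean_divergence_percent / x$config$clock_rate_high, 1),
                round(x$clock$mean_divergence_percent / x$config$clock_rate_low, 1)))
  if (!is.null(x$ibd$overall))
    cat(sprintf("  IBD (overall): r = %.3f, one-sided p = %.3g\n",
                x$ibd$overall$fst_vs_km$r, x$ibd$overall$fst_vs_km$p_value))
  cat(sprintf("  timeline: %d slices\n", length(x$timeline$slices)))
  invisible(x)
}

#' @export
summary.phylogeography <- function(object, ...) {
  print(object)
  cat("\nPer-population statistics:\n")
  print(object$pop_stats, row.names = FALSE)
  cat("\nTajima's D:\n")
  for (nm in names(object$tajima)) {
    cat(" ", nm, ": "); print(object$tajima[[nm]])
  }
  for (nm in names(object$good)) {
    g <- object$good[[nm]]
    cat(sprintf("\nGood-model tests, lineage %s (ancestor %s at %s, %d pops):\n",
                nm, g$ancestor_haplotype, g$ancestor_location, g$n_pops))
    cat("  pairwise DA vs distance-from-ancestor: ")
    print(g$pairwise)
    d <- g$diversity
    if (is.na(d$r)) cat("  diversity test undefined:", d$undefined_reason, "\n")
    else cat(sprintf("  diversity vs distance: r = %.3f (adj r2 = %.4f), p = %.3g\n",
                     d$r, d$adjusted_r_squared, d$p))
  }
  invisible(object)
}

#' @export
plot.phylogeography <- function(x, type = c("network", "ibd", "timeline"),
                                ...) {
  type <- match.arg(type)
  if (type == "network") {
    g <- x$unit_network
    obs <- igraph::V(g)$observed == 1
    set.seed(x$config$rng_seed)
    igraph::plot.igraph(
      g,
      vertex.size = ifelse(obs, pmax(6, 3 * sqrt(igraph::V(g)$count)), 2),
      vertex.color = ifelse(obs, "gold", "black"),
      vertex.label = ifelse(obs, igraph::V(g)$name, NA), ...)
  } else if (type == "ibd") {
    lt <- lower.tri(x$km)
    graphics::plot(x$km[lt], x$fst[lt], xlab = "geographic distance (km)",
                   ylab = "pairwise FST", pch = 1, ...)
  } else plot(x$timeline, ...)
  invisible(x)
}
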
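#' Gene flow estimate from FST
#'
#' Island-model gene flow `M = (1/FST - 1)/4`. M cannot be calculated when
#' FST is zero (or negative, after clamping), in which case `NA` is
#' returned.
#'
#' @param fst FST value(s) in (0, 1\].
#' @return M (vectorized); `NA` where FST <= 0.
#' @export
gene_flow_M <- function(fst) {
  out <- ifelse(fst > 0 & fst <= 1, (1 / fst - 1) / 4, NA_real_)
  unname(out)
}

#' Distances from an assumed ancestral location
#'
#' Great-circle distances (km) from the ancestral population's coordinates
#' to every location of the table.
#'
#' @param table a [sample_table()].
#' @param ancestor_location location ID of the assumed ancestral
#'   population.
#' @return Named numeric vector, location -> km.
#' @export
distance_from_ancestor <- function(table, ancestor_location) {
  i <- match(ancestor_location, table$location)
  if (is.na(i))
    stop("unknown ancestor location: ", ancestor_location, call. = FALSE)
  km <- geographic_distance(table)
  stats::setNames(km[i, ], table$location)
}

#' Stepwise-colonization pair test (Good/Slatkin model)
#'
#' Under serial colonization from an ancestral population, genetic
#' divergence between a pair of populations is predicted to be negatively
#' correlated with the distance of the pair's OLDER member from the
#' ancestral population. For each unordered pair (i, j) the predictor is
#' `min(dist(ancestor, i), dist(ancestor, j))` (optionally the mean) and
#' the response is Nei's DA(i, j); because pairs share populations,
#' significance uses Mantel-style permutation of population labels.
#'
#' @param table a filtered [sample_table()].
#' @param haps companion [haplotype_set()] (interface symmetry).
#' @param lineage optional character vector of location IDs restricting the
#'   test to one lineage's populations.
#' @param ancestor_location assumed ancestral location ID.
#' @param nperm,seed passed to [mantel_test()].
#' @param alternative default "less": the model predicts a negative
#'   correlation.
#' @param pair_distance "min" (the pair's older member) or "mean".
#' @return A [mantel_test()] result, plus attribute `xy` with the
#'   per-pair scatter data.
#' @export
good_model_pair_test <- function(table, haps = NULL, lineage = NULL,
                                 ancestor_location, nperm = 9999L,
                                 seed = 1L, alternative = "less",
                                 pair_distance = c("min", "mean")) {
  pair_distance <- match.arg(pair_distance)
  if (!is.null(lineage)) {
    table <- table[table$location %in% unique(c(lineage, ancestor_location)),
                   , drop = FALSE]
    class(table) <- c("sample_table", "data.frame")
  }
  if (nrow(table) < 4L)
    stop("need at least 4 populations in the lineage", call. = FALSE)
  d <- distance_from_ancestor(table, ancestor_location)
  n <- nrow(table)
  x <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x[i, j] <- if (pair_distance == "min") min(d[i], d[j])
               else (d[i] + d[j]) / 2
  }
  diag(x) <- 0
  dimnames(x) <- list(table$location, table$location)
  y <- pairwise_stat_matrix(table, "da")$matrix
  res <- mantel_test(y, x, nperm = nperm, seed = seed,
                     alternative = alternative)
  lt <- lower.tri(x)
  attr(res, "xy") <- data.frame(distance_km = x[lt], d_a = y[lt])
  res
}

#' Stepwise-colonization diversity test
#'
#' Pearson correlation of per-population unbiased gene diversity against
#' distance from the ancestral location; the model predicts a negative
#' correlation (older populations are more diverse). The two-sided t-test
#' p-value is reported, together with the adjusted r-squared for
#' comparability with small-sample study summaries.
#'
#' @inheritParams good_model_pair_test
#' @return List with `r`, `r_squared`, `adjusted_r_squared`, `p`, `n`, and
#'   the per-population scatter data `xy`; `NA` fields with an
#'   `undefined_reason` when all diversities are equal (e.g. the fully
#'   monomorphic regime).
#' @export
good_model_diversity_test <- function(table, lineage = NULL,
                                      ancestor_location) {
  if (!is.null(lineage)) {
    table <- table[table$location %in% unique(c(lineage, ancestor_location)),
                   , drop = FALSE]
    class(table) <- c("sample_table", "data.frame")
  }
  if (nrow(table) < 4L)
    stop("need at least 4 populations in the lineage", call. = FALSE)
  d <- distance_from_ancestor(table, ancestor_location)
  cnt <- hap_counts(table)
  h <- apply(cnt, 1L, function(row) gene_diversity(row[row > 0]))
  xy <- data.frame(location = table$location, distance_km = unname(d),
                   diversity = unname(h), stringsAsFactors = FALSE)
  if (anyNA(h) || stats::sd(h) == 0) {
    return(list(r = NA_real_, r_squared = NA_real_,
                adjusted_r_squared = NA_real_, p = NA_real_,
                n = nrow(table), xy = xy,
                undefined_reason = "gene diversity constant (or undefined) across populations"))
  }
  ct <- stats::cor.test(d, h, method = "pearson")
  r <- unname(ct$estimate)
  n <- nrow(table)
  list(r = r, r_squared = r^2,
       adjusted_r_squared = 1 - (1 - r^2) * (n - 1) / (n - 2),
       p = ct$p.value, n = n, xy = xy, undefined_reason = NULL)
}

#' Molecular-clock dating from mutational steps
#'
#' Converts a number of substitutions over an alignment of length L into
#' percent sequence divergence and brackets the divergence time with a
#' low/high rate (defaults: the decapod 16S calibration of 0.65-0.88%
#' pairwise divergence per Myr). `t_low` uses the fast rate, `t_high` the
#' slow one. Presentation rounding: percent to 2 decimals, times to 1
#' decimal Myr and 2 significant figures in years.
#'
#' @param steps substitution count (>= 0).
#' @param L alignment length in sites.
#' @param rate_low,rate_high percent divergence per Myr.
#' @return List of class `clock_estimate`.
#' @export
clock_dating <- function(steps, L, rate_low = 0.65, rate_high = 0.88) {
  stopifnot(steps >= 0, L > 0, rate_low < rate_high)
  percent <- 100 * steps / L
  t_low <- percent / rate_high
  t_high <- percent / rate_low
  structure(list(steps = steps, alignment_length = L,
                 percent_divergence = percent,
                 rate_low = rate_low, rate_high = rate_high,
                 t_low_myr = t_low, t_high_myr = t_high,
                 percent_rounded = round(percent, 2),
                 t_low_myr_rounded = round(t_low, 1),
                 t_high_myr_rounded = round(t_high, 1),
                 t_low_yr_rounded = signif(t_low * 1e6, 2),
                 t_high_yr_rounded = signif(t_high * 1e6, 2)),
            class = "clock_estimate")
}

#' @export
print.clock_estimate <- function(x, ...) {
  cat(sprintf(
    "Clock dating: %d steps / %d bp = %.2f%% divergence -> %.1f-%.1f Myr (%s-%s yr) at %.2f-%.2f%%/Myr\n",
    x$steps, x$alignment_length, x$percent_divergence,
    x$t_low_myr_rounded, x$t_high_myr_rounded,
    format(x$t_low_yr_rounded, big.mark = ","),
    format(x$t_high_yr_rounded, big.mark = ","),
    x$rate_low, x$rate_high))
  invisible(x)
}
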
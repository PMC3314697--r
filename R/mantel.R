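#' Mantel test between two distance matrices
#'
#' Pearson correlation over the unordered off-diagonal pairs, with
#' significance from simultaneous row/column permutation of the second
#' matrix. The two-sided p-value is
#' `(count(|r_perm| >= |r_obs|) + 1)/(permutations + 1)`; a one-sided
#' p-value in the direction given by `alternative` is reported alongside.
#' The adjusted r-squared `1 - (1 - r^2)(m - 1)/(m - 2)` (m = number of
#' pairs) is reported because small-sample study summaries are often
#' printed on that scale (it can be negative near r = 0).
#'
#' @param mA,mB square labeled matrices with identical label order.
#' @param nperm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @param alternative "two.sided", "greater" or "less"; selects which
#'   p-value is reported as `p_value` (the other tail and the two-sided p
#'   are always available in the result).
#' @return List of class `mantel_result`: `r`, `r_squared`,
#'   `adjusted_r_squared`, `p_value`, `p_two_sided`, `p_greater`, `p_less`,
#'   `permutations`, `seed`, `alternative`, `m` (number of pairs).
#' @export
mantel_test <- function(mA, mB, nperm = 9999L, seed = 1L,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (nperm < 99L) stop("nperm must be >= 99", call. = FALSE)
  if (!identical(dim(mA), dim(mB)))
    stop("matrices must have identical dimensions", call. = FALSE)
  if (!is.null(rownames(mA)) && !is.null(rownames(mB)) &&
      !identical(rownames(mA), rownames(mB)))
    stop("matrices must have identical label order", call. = FALSE)
  n <- nrow(mA)
  lt <- lower.tri(mA)
  x <- mA[lt]
  m <- n * (n - 1) / 2
  if (stats::sd(x) == 0 || stats::sd(mB[lt]) == 0) {
    return(structure(list(r = NA_real_, r_squared = NA_real_,
                          adjusted_r_squared = NA_real_, p_value = NA_real_,
                          p_two_sided = NA_real_, p_greater = NA_real_,
                          p_less = NA_real_,
                          permutations = as.integer(nperm),
                          seed = as.integer(seed),
                          alternative = alternative, m = m,
                          undefined_reason = "constant distance matrix"),
                     class = "mantel_result"))
  }
  r_obs <- stats::cor(x, mB[lt])
  set.seed(seed)
  r_perm <- vapply(seq_len(nperm), function(k) {
    p <- sample.int(n)
    stats::cor(x, mB[p, p][lt])
  }, numeric(1L))
  eps <- 1e-12
  p_two <- (sum(abs(r_perm) >= abs(r_obs) - eps) + 1) / (nperm + 1)
  p_gr <- (sum(r_perm >= r_obs - eps) + 1) / (nperm + 1)
  p_le <- (sum(r_perm <= r_obs + eps) + 1) / (nperm + 1)
  r2 <- r_obs^2
  structure(list(r = r_obs, r_squared = r2,
                 adjusted_r_squared = 1 - (1 - r2) * (m - 1) / (m - 2),
                 p_value = switch(alternative, two.sided = p_two,
                                  greater = p_gr, less = p_le),
                 p_two_sided = p_two, p_greater = p_gr, p_less = p_le,
                 permutations = as.integer(nperm), seed = as.integer(seed),
                 alternative = alternative, m = m,
                 undefined_reason = NULL),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (is.na(x$r)) {
    cat("Mantel test: undefined (", x$undefined_reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "Mantel test: r = %.4f (r2 = %.4f, adj r2 = %.4f), p = %.4g (%s, %d permutations)\n",
    x$r, x$r_squared, x$adjusted_r_squared, x$p_value, x$alternative,
    x$permutations))
  invisible(x)
}

#' Isolation-by-distance tests
#'
#' Mantel tests of pairwise FST and Nei's DA against great-circle
#' geographic distance over the populations of a sample table, optionally
#' restricted to the populations of one lineage.
#'
#' @param table a filtered [sample_table()] (every population should have
#'   at least 2 individuals so FST is defined).
#' @param haps the companion [haplotype_set()] (unused by the
#'   frequency-based statistics but kept for interface symmetry and
#'   validation).
#' @param subset optional character vector of location IDs (e.g. the
#'   populations assigned to one lineage).
#' @param nperm,seed,alternative passed to [mantel_test()]; the IBD
#'   expectation is a positive correlation, so the default is "greater".
#' @return List with elements `fst_vs_km` and `da_vs_km`
#'   ([mantel_test()] results) plus the matrices used.
#' @export
ibd_test <- function(table, haps = NULL, subset = NULL, nperm = 9999L,
                     seed = 1L, alternative = "greater") {
  if (!is.null(subset)) {
    table <- table[table$location %in% subset, , drop = FALSE]
    class(table) <- c("sample_table", "data.frame")
  }
  if (nrow(table) < 4L)
    stop("need at least 4 populations for an IBD test", call. = FALSE)
  km <- geographic_distance(table)
  fst <- pairwise_stat_matrix(table, "fst")$matrix
  if (anyNA(fst))
    stop("FST undefined for some pairs; filter populations to n >= 2 first",
         call. = FALSE)
  da <- pairwise_stat_matrix(table, "da")$matrix
  list(fst_vs_km = mantel_test(fst, km, nperm, seed, alternative),
       da_vs_km = mantel_test(da, km, nperm, seed + 1L, alternative),
       fst = fst, da = da, km = km)
}
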
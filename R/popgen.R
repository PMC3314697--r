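#' Unbiased gene diversity
#'
#' Nei's unbiased haplotype (gene) diversity
#' \eqn{h = n(1 - \sum p_i^2)/(n-1)}: the probability that two haplotypes
#' sampled without replacement from the population differ.
#'
#' @param counts named non-negative counts per haplotype.
#' @return `h` in \[0, 1\]; `NA` when fewer than 2 individuals.
#' @export
gene_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  unname(n * (1 - sum(p^2)) / (n - 1))
}

#' Pairwise FST from haplotype frequencies
#'
#' Hudson-type frequency-based estimator treating haplotypes as unordered
#' alleles: \eqn{F_{ST} = 1 - H_w/H_b}, where \eqn{H_w} is the mean of the
#' two unbiased within-population heterozygosities and \eqn{H_b = 1 - \sum
#' p_i q_i} is the probability that two haplotypes, one from each
#' population, differ. When \eqn{H_b = 0} (identical monomorphic
#' populations) FST is 0 by convention. Slightly negative estimates are
#' reported as computed; values are capped at 1.
#'
#' @param countsA,countsB named haplotype counts for the two populations.
#' @return FST, or `NA` when either population has fewer than 2 samples.
#' @export
pairwise_fst <- function(countsA, countsB) {
  nA <- sum(countsA); nB <- sum(countsB)
  if (nA < 2 || nB < 2) return(NA_real_)
  ids <- union(names(countsA), names(countsB))
  p <- q <- stats::setNames(numeric(length(ids)), ids)
  p[names(countsA)] <- countsA / nA
  q[names(countsB)] <- countsB / nB
  hA <- nA * (1 - sum(p^2)) / (nA - 1)
  hB <- nB * (1 - sum(q^2)) / (nB - 1)
  Hw <- (hA + hB) / 2
  Hb <- 1 - sum(p * q)
  if (Hb <= 0) return(0)
  min(1, 1 - Hw / Hb)
}

#' Nei's DA distance from haplotype frequencies
#'
#' Single-locus \eqn{D_A = 1 - \sum_i \sqrt{x_i y_i}} over the haplotype
#' frequencies of the two populations; bounded in \[0, 1\], 0 for identical
#' frequency vectors, 1 for disjoint haplotype sets.
#'
#' @inheritParams pairwise_fst
#' @return DA in \[0, 1\].
#' @export
nei_da <- function(countsA, countsB) {
  nA <- sum(countsA); nB <- sum(countsB)
  if (nA < 1 || nB < 1) return(NA_real_)
  ids <- union(names(countsA), names(countsB))
  x <- y <- stats::setNames(numeric(length(ids)), ids)
  x[names(countsA)] <- countsA / nA
  y[names(countsB)] <- countsB / nB
  max(0, min(1, 1 - sum(sqrt(x * y))))
}

#' Population-pairwise statistic matrix over a sample table
#'
#' Computes the full pairwise matrix of FST or Nei's DA from the haplotype
#' counts of every location, together with the mean over unordered pairs
#' (the diagonal excluded).
#'
#' @param table a [sample_table()].
#' @param stat "fst" or "da".
#' @return List with `matrix` (a `dist_matrix`) and `mean_offdiagonal`.
#' @export
pairwise_stat_matrix <- function(table, stat = c("fst", "da")) {
  stat <- match.arg(stat)
  cnt <- hap_counts(table)
  n <- nrow(cnt)
  f <- if (stat == "fst") pairwise_fst else nei_da
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- stats::setNames(cnt[i, ], colnames(cnt))
    cj <- stats::setNames(cnt[j, ], colnames(cnt))
    m[i, j] <- m[j, i] <- f(ci[ci > 0], cj[cj > 0])
  }
  dm <- dist_matrix(m, table$location, if (stat == "fst") "FST" else "D_A")
  list(matrix = dm, mean_offdiagonal = mean(m[upper.tri(m)], na.rm = TRUE))
}

# expand per-location haplotype counts into one sequence per individual
expand_individuals <- function(table, haps, locations = NULL) {
  cnt <- hap_counts(table)
  if (!is.null(locations)) cnt <- cnt[rownames(cnt) %in% locations, ,
                                      drop = FALSE]
  tot <- colSums(cnt)
  unlist(lapply(names(tot)[tot > 0],
                function(h) rep(haps$sequences[[h]], tot[h])))
}

#' Tajima's D
#'
#' The standard neutrality test statistic
#' \eqn{D = (\pi - S/a_1)/\sqrt{e_1 S + e_2 S (S-1)}} with Tajima's (1989)
#' constants. `S` counts segregating sites over substitutions only (sites
#' containing a gap or ambiguity code in any sequence contribute no
#' segregating site there, and such sites are also skipped
#' pairwise-complete in \eqn{\pi}).
#'
#' @param seqs character vector of equal-length aligned sequences, one per
#'   individual.
#' @return List of class `tajima_result` with elements `D` (NA when
#'   undefined), `S`, `pi`, `n` and `undefined_reason`.
#' @export
tajima_d <- function(seqs) {
  n <- length(seqs)
  if (n < 1) stop("no sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment error: sequences differ in length", call. = FALSE)
  uq <- unique(toupper(seqs))
  mult <- as.numeric(table(factor(toupper(seqs), levels = uq)))
  mat <- do.call(rbind, strsplit(uq, "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  S <- sum(apply(mat, 2L, function(col)
    length(unique(col[col %in% bases])) > 1L))
  pi <- 0
  if (n >= 2) {
    d <- 0
    if (length(uq) >= 2L)
      for (i in seq_len(length(uq) - 1L)) for (j in (i + 1L):length(uq)) {
        ok <- mat[i, ] %in% bases & mat[j, ] %in% bases
        d <- d + mult[i] * mult[j] * sum(mat[i, ok] != mat[j, ok])
      }
    pi <- d / (n * (n - 1) / 2)
  }
  res <- list(D = NA_real_, S = as.integer(S), pi = pi, n = as.integer(n),
              undefined_reason = NULL)
  if (n < 4L) res$undefined_reason <- "fewer than 4 sequences"
  else if (S == 0L) res$undefined_reason <- "no segregating sites"
  else {
    i <- seq_len(n - 1L)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    res$D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  class(res) <- "tajima_result"
  res
}

#' @export
print.tajima_result <- function(x, ...) {
  cat("Tajima's D: ",
      if (is.na(x$D)) paste0("undefined (", x$undefined_reason, ")")
      else format(x$D, digits = 4),
      "  [n = ", x$n, ", S = ", x$S, ", pi = ",
      format(x$pi, digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Mismatch distribution
#'
#' Histogram of pairwise substitution differences over all unordered pairs
#' of individuals.
#'
#' @param seqs character vector of aligned sequences, one per individual.
#' @return List of class `mismatch_distribution` with `counts` (named by
#'   difference k) and `n_pairs`.
#' @export
mismatch <- function(seqs) {
  n <- length(seqs)
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  uq <- unique(toupper(seqs))
  mult <- as.numeric(table(factor(toupper(seqs), levels = uq)))
  acc <- numeric(0) # named accumulator: k -> number of pairs
  add <- function(acc, k, w) {
    key <- as.character(k)
    acc[key] <- if (key %in% names(acc)) acc[key] + w else w
    acc
  }
  for (i in seq_along(uq)) {
    if (mult[i] >= 2) acc <- add(acc, 0L, mult[i] * (mult[i] - 1) / 2)
    if (i < length(uq)) for (j in (i + 1L):length(uq)) {
      k <- mutation_steps(uq[i], uq[j])[["substitutions"]]
      acc <- add(acc, k, mult[i] * mult[j])
    }
  }
  acc <- acc[order(as.integer(names(acc)))]
  structure(list(counts = stats::setNames(as.integer(acc), names(acc)),
                 n_pairs = as.integer(n * (n - 1) / 2)),
            class = "mismatch_distribution")
}

#' Number of modes of a mismatch distribution (descriptive)
#'
#' Counts local maxima of the histogram over the full 0..max(k) support;
#' a unimodal distribution is the classic signature of rapid expansion,
#' but no inference is attached here.
#'
#' @param mm a [mismatch()] result.
#' @return Integer mode count.
#' @export
mismatch_modes <- function(mm) {
  k <- as.integer(names(mm$counts))
  full <- stats::setNames(integer(max(k) + 1L), 0:max(k))
  full[as.character(k)] <- mm$counts
  y <- as.numeric(full)
  if (length(y) == 1L) return(1L)
  up <- c(TRUE, diff(y) > 0)
  down <- c(diff(y) < 0, TRUE)
  sum(up & down & y > 0)
}
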
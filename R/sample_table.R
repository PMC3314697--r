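#' Sample table: locations, coordinates and per-haplotype counts
#'
#' A `sample_table` is a data frame with metadata columns `location`,
#' `region`, `lat`, `lon` followed by one non-negative integer count column
#' per haplotype. Every analysis draws its haplotype frequencies from this
#' object; no distances are stored, they are always recomputed downstream.
#'
#' @param df data frame with columns location, region, lat, lon and one
#'   column per haplotype ID.
#' @param haps optional [haplotype_set()] to cross-validate the count
#'   columns against.
#' @return An object of classes `sample_table` and `data.frame`.
#' @export
sample_table <- function(df, haps = NULL) {
  meta <- c("location", "region", "lat", "lon")
  if (!all(meta %in% names(df)))
    stop("sample table must have columns: ", paste(meta, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df <- df[, c(meta, setdiff(names(df), meta)), drop = FALSE]
  hap_cols <- setdiff(names(df), meta)
  if (length(hap_cols) == 0L)
    stop("sample table has no haplotype count columns", call. = FALSE)
  if (anyDuplicated(df$location))
    stop("duplicate location IDs: ",
         paste(unique(df$location[duplicated(df$location)]), collapse = ", "),
         call. = FALSE)
  if (any(df$lat < -90 | df$lat > 90) || any(df$lon < -180 | df$lon > 180))
    stop("coordinates out of range", call. = FALSE)
  cnt <- as.matrix(df[, hap_cols, drop = FALSE])
  if (any(is.na(cnt)) || any(cnt < 0))
    stop("format error: counts must be non-negative numbers", call. = FALSE)
  if (any(cnt != round(cnt)))
    stop("format error: counts must be integers", call. = FALSE)
  tot <- rowSums(cnt)
  if (any(tot < 1))
    stop("format error: all-zero count row(s): ",
         paste(df$location[tot < 1], collapse = ", "), call. = FALSE)
  if (!is.null(haps)) {
    unknown <- setdiff(hap_cols, names(haps$sequences))
    if (length(unknown))
      stop("cross-reference error: haplotype column(s) not in FASTA: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' @export
print.sample_table <- function(x, ...) {
  cnt <- hap_counts(x)
  cat("Sample table:", nrow(x), "locations,", ncol(cnt),
      "haplotype columns,", sum(cnt), "individuals\n")
  NextMethod()
}

#' Extract the location x haplotype count matrix
#'
#' @param table a [sample_table()].
#' @return integer matrix, rows named by location, columns by haplotype ID.
#' @export
hap_counts <- function(table) {
  meta <- c("location", "region", "lat", "lon")
  m <- as.matrix(table[, setdiff(names(table), meta), drop = FALSE])
  rownames(m) <- table$location
  storage.mode(m) <- "double"
  m
}

#' Read a tab-delimited sample table
#'
#' Expects a header `location  region  lat  lon` followed by one column per
#' haplotype ID; the full count matrix is required (zero-count columns are
#' permitted, omitted columns are not).
#'
#' @param path path to the TSV file.
#' @param haps [haplotype_set()] the count columns must belong to.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path, haps) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  sample_table(df, haps = haps)
}

#' Write a sample table as TSV
#'
#' @param table a [sample_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop under-sampled locations
#'
#' Removes rows whose total individual count is below `min_n` (the study
#' convention is to keep locations with at least 5 individuals), preserving
#' row order. Removals are reported via `message()`.
#'
#' @param table a [sample_table()].
#' @param min_n minimum total count per location (>= 1).
#' @return The filtered [sample_table()].
#' @export
filter_populations <- function(table, min_n = 5L) {
  stopifnot(min_n >= 1L)
  tot <- rowSums(hap_counts(table))
  keep <- tot >= min_n
  if (!any(keep))
    stop("degenerate data: no location has >= ", min_n, " individuals",
         call. = FALSE)
  if (any(!keep))
    message("filter_populations: dropped ", sum(!keep), " of ", nrow(table),
            " locations (n < ", min_n, "): ",
            paste(table$location[!keep], collapse = ", "))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Pool locations into combined populations
#'
#' Pooled counts are summed; pooled coordinates are the count-weighted
#' centroid of the member locations; the region label must agree across
#' members. Unmapped locations pass through unchanged. Pooling is applied
#' before any sample-size filter so that adjacent small samples can be
#' retained as one adequately sized population.
#'
#' @param table a [sample_table()].
#' @param pooling named character vector mapping location IDs to pooled IDs
#'   (may be empty or `NULL` for identity).
#' @return A [sample_table()] with pooled rows at the position of each
#'   pool's first member.
#' @export
pool_populations <- function(table, pooling = NULL) {
  if (is.null(pooling) || length(pooling) == 0L) return(table)
  unknown <- setdiff(names(pooling), table$location)
  if (length(unknown))
    stop("pooling refers to unknown location(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  grp <- ifelse(table$location %in% names(pooling),
                unname(pooling[table$location]), table$location)
  cnt <- hap_counts(table)
  tot <- rowSums(cnt)
  first <- !duplicated(grp)
  rows <- lapply(unique(grp), function(g) {
    i <- which(grp == g)
    regions <- unique(table$region[i])
    if (length(regions) > 1L)
      stop("consistency error: pooling '", g, "' spans regions: ",
           paste(regions, collapse = ", "), call. = FALSE)
    w <- tot[i] / sum(tot[i])
    data.frame(location = g, region = regions,
               lat = sum(w * table$lat[i]), lon = sum(w * table$lon[i]),
               stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, rows)
  pooled_cnt <- rowsum(cnt, grp, reorder = FALSE)
  out <- cbind(meta, as.data.frame(pooled_cnt[meta$location, , drop = FALSE]))
  if (nrow(out) < nrow(table))
    message("pool_populations: ", nrow(table), " locations pooled into ",
            nrow(out), " populations")
  sample_table(out)
}
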
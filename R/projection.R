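#' Depth map: unit-step distances from a lineage ancestor
#'
#' Graph distance in unit mutational steps (latent intermediates count)
#' from the ancestral haplotype to every node of its component in the
#' resolved unit-step tree.
#'
#' @param net unit-step resolved network (after [insert_missing()]).
#' @param ancestor ancestral haplotype ID.
#' @return Named integer vector, node -> depth (ancestor = 0).
#' @export
depth_map <- function(net, ancestor) {
  ids <- igraph::V(net)$name
  if (!ancestor %in% ids)
    stop("ancestor not in network: ", ancestor, call. = FALSE)
  d <- igraph::distances(net, v = ancestor, weights = NA)[1L, ]
  d <- d[is.finite(d)]
  stats::setNames(as.integer(d), names(d))
}

#' Align lineage timelines at their most recent tips
#'
#' With G the maximum depth over all lineages, a haplotype at depth
#' `depth(h)` in a lineage of maximum depth D gets time index
#' `T(h) = 1 + G - (D - depth(h))`: the deepest lineage's ancestor appears
#' at T = 1 and every lineage's deepest tip at T = 1 + G, so the most
#' recent tips of all lineages share the final time slice.
#'
#' @param depthmaps named list (one [depth_map()] per lineage).
#' @return Named integer vector haplotype -> T over all lineages, with
#'   attributes `G` (max depth) and `lineage` (node -> lineage label).
#' @export
align_timelines <- function(depthmaps) {
  stopifnot(length(depthmaps) >= 1L)
  G <- max(vapply(depthmaps, max, numeric(1L)))
  tmap <- integer(0)
  lin <- character(0)
  for (lab in names(depthmaps)) {
    dm <- depthmaps[[lab]]
    D <- max(dm)
    tt <- 1L + as.integer(G) - (as.integer(D) - dm)
    tmap <- c(tmap, tt)
    lin <- c(lin, stats::setNames(rep(lab, length(dm)), names(dm)))
  }
  attr(tmap, "G") <- as.integer(G)
  attr(tmap, "lineage") <- lin
  tmap
}

#' Build the time-sliced spread timeline
#'
#' For each time slice T = 1 .. 1 + G, lists the observed haplotypes whose
#' first appearance is T (`status = "new"`) together with all previously
#' appeared haplotypes (`status = "carried"`), each with the sampling
#' locations (and coordinates) where its count is positive. Latent
#' haplotypes advance the clock but never appear in slices.
#'
#' @param tmap aligned time map from [align_timelines()].
#' @param table a [sample_table()].
#' @param lineages named character vector haplotype -> lineage label
#'   (defaults to the `lineage` attribute of `tmap`).
#' @return Object of class `spread_timeline`: list with `slices` (one data
#'   frame per T: haplotype, lineage, status, location, lat, lon) and `G`.
#' @export
spread_slices <- function(tmap, table, lineages = attr(tmap, "lineage")) {
  cnt <- hap_counts(table)
  observed <- colnames(cnt)[colSums(cnt) > 0]
  missing_T <- setdiff(observed, names(tmap))
  if (length(missing_T))
    stop("consistency error: sampled haplotype(s) absent from network: ",
         paste(missing_T, collapse = ", "), call. = FALSE)
  G <- attr(tmap, "G")
  loc <- stats::setNames(seq_len(nrow(table)), table$location)
  slice_of <- function(T) {
    active <- observed[tmap[observed] <= T]
    if (!length(active)) {
      return(data.frame(haplotype = character(0), lineage = character(0),
                        status = character(0), location = character(0),
                        lat = numeric(0), lon = numeric(0),
                        stringsAsFactors = FALSE))
    }
    do.call(rbind, lapply(sort(active), function(h) {
      where <- rownames(cnt)[cnt[, h] > 0]
      data.frame(haplotype = h,
                 lineage = unname(lineages[h]),
                 status = if (tmap[[h]] == T) "new" else "carried",
                 location = where,
                 lat = table$lat[loc[where]],
                 lon = table$lon[loc[where]],
                 stringsAsFactors = FALSE)
    }))
  }
  slices <- lapply(seq_len(1L + G), slice_of)
  names(slices) <- paste0("T", seq_len(1L + G))
  structure(list(slices = slices, G = G, tmap = tmap),
            class = "spread_timeline")
}

#' @export
print.spread_timeline <- function(x, ...) {
  cat("Spread timeline:", length(x$slices), "time slices (G =", x$G, ")\n")
  for (i in seq_along(x$slices)) {
    s <- x$slices[[i]]
    cat(sprintf("  T%d: %d new, %d carried haplotypes\n", i,
                length(unique(s$haplotype[s$status == "new"])),
                length(unique(s$haplotype[s$status == "carried"]))))
  }
  invisible(x)
}

#' Plot one slice of a spread timeline
#'
#' Lat/lon scatter: filled symbols for the first lineage, open for others;
#' "new" appearances are drawn larger with a highlight ring.
#'
#' @param x a `spread_timeline`.
#' @param T slice index (default: last).
#' @param ... passed to [graphics::plot()].
#' @export
plot.spread_timeline <- function(x, T = length(x$slices), ...) {
  s <- x$slices[[T]]
  lins <- sort(unique(attr(x$tmap, "lineage")))
  all_xy <- do.call(rbind, x$slices)
  graphics::plot(all_xy$lon, all_xy$lat, type = "n",
                 xlab = "longitude", ylab = "latitude",
                 main = paste0("T", T), ...)
  if (!nrow(s)) return(invisible(x))
  pch <- ifelse(match(s$lineage, lins) == 1L, 19L, 21L)
  cex <- ifelse(s$status == "new", 1.6, 1.0)
  col <- ifelse(s$status == "new", "goldenrod", "black")
  graphics::points(s$lon, s$lat, pch = pch, cex = cex, col = col,
                   bg = "white")
  invisible(x)
}

#' Render all slices of a spread timeline to image files
#'
#' One PNG per slice (`slice_T01.png`, ...) in `out_dir`.
#'
#' @param tl a `spread_timeline`.
#' @param out_dir output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
render_maps <- function(tl, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  paths <- character(length(tl$slices))
  for (i in seq_along(tl$slices)) {
    paths[i] <- file.path(out_dir, sprintf("slice_T%02d.png", i))
    grDevices::png(paths[i], width = 600, height = 600)
    plot(tl, T = i)
    grDevices::dev.off()
  }
  invisible(paths)
}

#' Write / read a spread timeline as GeoJSON
#'
#' One Point feature per haplotype appearance per location, with
#' properties `T`, `haplotype`, `lineage`, `status` and `location`.
#'
#' @param tl a `spread_timeline`.
#' @param path file path.
#' @return `path` invisibly; `read_timeline` returns a data frame of
#'   features.
#' @export
write_timeline <- function(tl, path) {
  features <- list()
  for (i in seq_along(tl$slices)) {
    s <- tl$slices[[i]]
    for (k in seq_len(nrow(s))) {
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(s$lon[k], s$lat[k])),
        properties = list(T = i, haplotype = s$haplotype[k],
                          lineage = s$lineage[k], status = s$status[k],
                          location = s$location[k]))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  do.call(rbind, lapply(fc$features, function(f)
    data.frame(T = f$properties$T, haplotype = f$properties$haplotype,
               lineage = f$properties$lineage, status = f$properties$status,
               location = f$properties$location,
               lon = f$geometry$coordinates[[1L]],
               lat = f$geometry$coordinates[[2L]],
               stringsAsFactors = FALSE)))
}
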
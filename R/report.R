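# orchestration: simulate / analyze / project / all, with file outputs

config_hash <- function(obj) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

log_line <- function(log_path, ...) {
  if (!is.null(log_path)) cat(paste0(..., "\n"), file = log_path,
                              append = TRUE)
}

#' Run a colonization simulation and write its outputs
#'
#' Writes `haplotypes.fasta`, `samples.tsv` and `truth.json` to `out_dir`.
#'
#' @param p a [sim_params()].
#' @param out_dir output directory.
#' @return The simulation (list `haps`, `table`, `truth`), invisibly.
#' @export
run_simulate <- function(p, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_colonization(p)
  write_haplotype_fasta(sim$haps, file.path(out_dir, "haplotypes.fasta"))
  write_sample_table(sim$table, file.path(out_dir, "samples.tsv"))
  jsonlite::write_json(
    list(origin = sim$truth$origin,
         origins = as.list(sim$truth$origins),
         founding_order = as.list(sim$truth$founding_order),
         colonization_edges = sim$truth$colonization_edges,
         pop_haplotype = as.list(sim$truth$pop_haplotype),
         lineage = as.list(sim$truth$lineage),
         params = unclass(p)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(sim)
}

#' Analyze a haplotype FASTA + sample table and write a report
#'
#' Runs [phylogeography()] and writes `report.json`, `stats.tsv`,
#' `matrices/*.tsv`, `network.graphml` and `run.log` to `out_dir`.
#'
#' @param fasta path to the aligned haplotype FASTA.
#' @param table_path path to the sample-table TSV.
#' @param config an [analysis_config()].
#' @param out_dir output directory (NULL: no files, just the object).
#' @return The `phylogeography` object, invisibly.
#' @export
run_analyze <- function(fasta, table_path, config = analysis_config(),
                        out_dir = NULL) {
  haps <- read_haplotype_fasta(fasta)
  table <- read_sample_table(table_path, haps)
  res <- run_analyze_obj(haps, table, config, out_dir)
  invisible(res)
}

# same as run_analyze but from in-memory objects
run_analyze_obj <- function(haps, table, config = analysis_config(),
                            out_dir = NULL) {
  log_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "matrices"), recursive = TRUE,
               showWarnings = FALSE)
    log_path <- file.path(out_dir, "run.log")
    cat("", file = log_path)
  }
  msgs <- character(0)
  res <- withCallingHandlers(
    phylogeography(haps, table, config),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  for (m in msgs) log_line(log_path, sub("\n$", "", m))
  if (is.null(out_dir)) return(invisible(res))

  utils::write.table(res$pop_stats, file.path(out_dir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(res$steps, file.path(out_dir, "matrices", "steps.tsv"))
  write_matrix(res$fst, file.path(out_dir, "matrices", "fst.tsv"))
  write_matrix(res$da, file.path(out_dir, "matrices", "da.tsv"))
  write_matrix(res$km, file.path(out_dir, "matrices", "km.tsv"))
  write_network(res$unit_network, file.path(out_dir, "network.graphml"))
  jsonlite::write_json(report_payload(res), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_line(log_path, "analysis complete: ", nrow(res$filtered),
           " populations, ", length(unique(res$lineages$assignment)),
           " lineage(s)")
  invisible(res)
}

mantel_payload <- function(m) {
  m[c("r", "r_squared", "adjusted_r_squared", "p_value", "p_two_sided",
      "p_greater", "p_less", "permutations", "seed", "alternative", "m")]
}

report_payload <- function(res) {
  list(
    provenance = list(seed = res$config$rng_seed,
                      config_hash = config_hash(unclass(res$config)),
                      package_version =
                        as.character(utils::packageVersion("haplospread"))),
    n_haplotypes = length(res$haps),
    alignment_length = res$haps$length,
    n_locations = nrow(res$pooled),
    n_filtered = nrow(res$filtered),
    mean_pairwise_fst = res$mean_fst,
    mean_pairwise_da = res$mean_da,
    pop_stats = res$pop_stats,
    lineages = list(assignment = as.list(res$lineages$assignment),
                    ancestors = as.list(res$lineages$ancestors)),
    ibd = lapply(res$ibd, function(t)
      list(fst_vs_km = mantel_payload(t$fst_vs_km),
           da_vs_km = mantel_payload(t$da_vs_km))),
    tajima = lapply(res$tajima, function(t)
      list(D = t$D, S = t$S, pi = t$pi, n = t$n,
           undefined_reason = t$undefined_reason)),
    mismatch = lapply(res$mismatch, function(m)
      list(counts = as.list(m$counts), n_pairs = m$n_pairs,
           modes = mismatch_modes(m))),
    good = lapply(res$good, function(g)
      list(ancestor_haplotype = g$ancestor_haplotype,
           ancestor_location = g$ancestor_location, n_pops = g$n_pops,
           pairwise = mantel_payload(g$pairwise),
           diversity = g$diversity[c("r", "r_squared",
                                     "adjusted_r_squared", "p", "n",
                                     "undefined_reason")])),
    clock = if (is.null(res$clock)) NULL else
      list(min_split_steps = res$clock$min_split_steps,
           mean_divergence_percent = res$clock$mean_divergence_percent,
           split = unclass(res$clock$split)),
    timeline = list(n_slices = length(res$timeline$slices),
                    new_per_slice = vapply(res$timeline$slices, function(s)
                      length(unique(s$haplotype[s$status == "new"])),
                      integer(1L))))
}

#' Write projection outputs (timeline + maps)
#'
#' Writes `timeline.geojson` and `maps/slice_T*.png` for an analyzed
#' dataset.
#'
#' @param res a `phylogeography` object.
#' @param out_dir output directory.
#' @return The `spread_timeline`, invisibly.
#' @export
run_project <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_timeline(res$timeline, file.path(out_dir, "timeline.geojson"))
  render_maps(res$timeline, file.path(out_dir, "maps"))
  invisible(res$timeline)
}

#' Simulate, analyze and project in one call
#'
#' @param p a [sim_params()].
#' @param config an [analysis_config()].
#' @param out_dir output directory.
#' @return List with `sim` and the `phylogeography` result, invisibly.
#' @export
run_all <- function(p, config = analysis_config(), out_dir) {
  sim <- run_simulate(p, out_dir)
  res <- run_analyze_obj(sim$haps, sim$table, config, out_dir)
  run_project(res, out_dir)
  invisible(list(sim = sim, result = res))
}
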
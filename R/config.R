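#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline. Defaults follow the
#' study conventions for a slowly evolving mitochondrial marker in a
#' sedentary species: a minimum of 5 individuals per population, a lineage
#' split at 5 mutational steps, and the decapod 16S clock bracket of
#' 0.65-0.88% pairwise divergence per Myr.
#'
#' @param min_sample_size minimum individuals per population (>= 1).
#' @param pooling named character vector location-ID -> pooled-ID, or NULL.
#' @param lineage_split_steps edges of at least this many mutational steps
#'   separate lineages.
#' @param clock_rate_low,clock_rate_high percent sequence divergence per
#'   Myr bracketing the molecular clock.
#' @param mantel_permutations number of Mantel permutations (>= 99).
#' @param rng_seed integer seed driving all randomized stages.
#' @param one_sided_good_tests logical; report one-sided (negative-tail)
#'   p-values for the directional stepwise-colonization tests.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(min_sample_size = 5L,
                            pooling = NULL,
                            lineage_split_steps = 5L,
                            clock_rate_low = 0.65,
                            clock_rate_high = 0.88,
                            mantel_permutations = 9999L,
                            rng_seed = 1L,
                            one_sided_good_tests = TRUE) {
  if (min_sample_size < 1L) stop("min_sample_size must be >= 1", call. = FALSE)
  if (!(clock_rate_low < clock_rate_high))
    stop("clock_rate_low must be < clock_rate_high", call. = FALSE)
  if (mantel_permutations < 99L)
    stop("mantel_permutations must be >= 99", call. = FALSE)
  structure(list(min_sample_size = as.integer(min_sample_size),
                 pooling = pooling,
                 lineage_split_steps = as.integer(lineage_split_steps),
                 clock_rate_low = clock_rate_low,
                 clock_rate_high = clock_rate_high,
                 mantel_permutations = as.integer(mantel_permutations),
                 rng_seed = as.integer(rng_seed),
                 one_sided_good_tests = isTRUE(one_sided_good_tests)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown top-level keys are ignored (they may belong to the simulation
#' section of a shared config file).
#'
#' @param path YAML file.
#' @return An [analysis_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  args <- y[intersect(names(y), known)]
  if (!is.null(args$pooling)) args$pooling <- unlist(args$pooling)
  do.call(analysis_config, args)
}
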
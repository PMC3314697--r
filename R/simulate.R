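#' Simulation parameters for serial-founder colonization
#'
#' Two generative modes share a 1-D coastline geometry (populations at
#' `coast_step_km` spacing along a meridian):
#' \describe{
#'   \item{fixation-cascade}{each newly founded population copies its
#'     parent's fixed haplotype and, with probability `fixation_prob`,
#'     fixes one new infinite-sites substitution; populations are sampled
#'     monomorphic. One or two colonization fronts extend north/south from
#'     the origin; an optional second lineage (seeded
#'     `lineage_split_steps` substitutions away from the root) colonizes a
#'     disjoint coastline segment.}
#'   \item{good-model}{each population holds `pop_size` lineages evolving
#'     by neutral Wright-Fisher resampling with infinite-sites mutation
#'     (`mutation_rate` expected new mutations per population per
#'     generation); every `generations_between_foundings` generations the
#'     newest population founds the next one by copying its current
#'     frequency spectrum exactly (or via a finite `propagule_size` for
#'     founder-effect experiments); no migration afterwards.}
#' }
#'
#' @param mode "fixation-cascade" or "good-model".
#' @param n_pops_per_front populations per colonization front (mode a) or
#'   total populations in the chain (mode b uses `n_pops`).
#' @param fronts 1 or 2 colonization fronts for the first lineage.
#' @param fixation_prob per-founding probability of fixing one new
#'   substitution (mode a).
#' @param second_n_pops_per_front,second_fronts geometry of the optional
#'   second lineage (mode a; used when `lineage_split_steps > 0`).
#' @param n_pops number of populations in the chain (mode b).
#' @param pop_size Wright-Fisher population size N (mode b).
#' @param mutation_rate expected new mutations per population per
#'   generation (mode b).
#' @param generations_between_foundings generations between successive
#'   foundings (mode b).
#' @param total_generations total simulated generations (mode b; default
#'   `generations_between_foundings * n_pops`).
#' @param propagule_size optional finite founding propagule (mode b);
#'   `NULL` copies the parent frequency spectrum exactly.
#' @param sample_size individuals sampled per population; `NULL` draws
#'   `1 + NegBin(size = 2, mu = 7.5)` per location (mean 8.5, mimicking
#'   uneven field sampling).
#' @param L alignment length in sites; `NULL` picks a mode-appropriate
#'   default large enough for the infinite-sites assumption.
#' @param lineage_split_steps substitutions separating the second lineage's
#'   root from the first (0 = single lineage).
#' @param coast_step_km spacing of populations along the coastline.
#' @param seed integer RNG seed.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(mode = c("fixation-cascade", "good-model"),
                       n_pops_per_front = 5L, fronts = 2L,
                       fixation_prob = 1,
                       second_n_pops_per_front = NULL, second_fronts = 1L,
                       n_pops = 8L, pop_size = 25L, mutation_rate = 0.5,
                       generations_between_foundings = 50L,
                       total_generations = NULL, propagule_size = NULL,
                       sample_size = 10L, L = NULL,
                       lineage_split_steps = 0L, coast_step_km = 15,
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(fronts %in% c(1L, 2L), fixation_prob >= 0, fixation_prob <= 1,
            lineage_split_steps >= 0, coast_step_km > 0)
  if (is.null(second_n_pops_per_front))
    second_n_pops_per_front <- n_pops_per_front
  if (is.null(total_generations))
    total_generations <- generations_between_foundings * n_pops
  if (is.null(L)) {
    L <- if (mode == "fixation-cascade") 490L else {
      lifetimes <- total_generations -
        (seq_len(n_pops) - 1L) * generations_between_foundings
      max(2000L, as.integer(ceiling(4 * mutation_rate * sum(lifetimes))))
    }
  }
  structure(list(mode = mode, n_pops_per_front = as.integer(n_pops_per_front),
                 fronts = as.integer(fronts), fixation_prob = fixation_prob,
                 second_n_pops_per_front = as.integer(second_n_pops_per_front),
                 second_fronts = as.integer(second_fronts),
                 n_pops = as.integer(n_pops), pop_size = as.integer(pop_size),
                 mutation_rate = mutation_rate,
                 generations_between_foundings =
                   as.integer(generations_between_foundings),
                 total_generations = as.integer(total_generations),
                 propagule_size = propagule_size,
                 sample_size = sample_size, L = as.integer(L),
                 lineage_split_steps = as.integer(lineage_split_steps),
                 coast_step_km = coast_step_km, seed = as.integer(seed)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (", x$mode, "), seed ", x$seed, "\n", sep = "")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

# bases cycle A -> C -> G -> T -> A for infinite-sites substitutions
.BASES <- c("A", "C", "G", "T")

mutate_sequence <- function(rootvec, sites) {
  v <- rootvec
  for (s in sites) v[s] <- .BASES[(match(v[s], .BASES)) %% 4L + 1L]
  v
}

draw_sample_sizes <- function(n, sample_size) {
  if (is.null(sample_size)) 1L + stats::rnbinom(n, size = 2, mu = 7.5)
  else rep(as.integer(sample_size), n)
}

# shared site pool: consumes infinite-sites positions without replacement
new_site_pool <- function(L) {
  pool <- sample.int(L)
  i <- 0L
  function(k = 1L) {
    if (i + k > L)
      stop("parameter error: site pool exhausted (increase L)", call. = FALSE)
    out <- pool[(i + 1L):(i + k)]
    i <<- i + k
    out
  }
}

#' Simulate a fixation-cascade colonization
#'
#' See [sim_params()] for the model. Every population is monomorphic for
#' its fixed haplotype; ground truth records the colonization tree,
#' founding order and per-population haplotype.
#'
#' @param p a [sim_params()] with mode "fixation-cascade".
#' @return List with `haps` ([haplotype_set()]), `table`
#'   ([sample_table()]) and `truth` (class `sim_truth`: `origin`,
#'   `origins`, `founding_order`, `colonization_edges`, `pop_haplotype`,
#'   `front`, `lineage`).
#' @export
simulate_fixation_cascade <- function(p) {
  stopifnot(inherits(p, "sim_params"), p$mode == "fixation-cascade")
  set.seed(p$seed)
  rootvec <- sample(.BASES, p$L, replace = TRUE)
  take <- new_site_pool(p$L)

  lineage_plan <- list(list(prefix = "W", fronts = p$fronts,
                            npf = p$n_pops_per_front, lon = 141,
                            lat0 = 43, extra = integer(0)))
  if (p$lineage_split_steps > 0L)
    lineage_plan[[2L]] <- list(prefix = "E", fronts = p$second_fronts,
                               npf = p$second_n_pops_per_front, lon = 143.5,
                               lat0 = 42, extra = take(p$lineage_split_steps))
  step_deg <- p$coast_step_km / 111.195

  pops <- list()       # location -> list(mut = sites, lat, lon, lineage, front, order, parent)
  hap_key <- character(0) # canonical mutation-set key -> haplotype id
  hap_sites <- list()
  hap_id_of <- function(sites) {
    key <- paste(sort(sites), collapse = ",")
    i <- match(key, hap_key)
    if (is.na(i)) {
      hap_key <<- c(hap_key, key)
      hap_sites[[length(hap_key)]] <<- sites
      i <- length(hap_key)
    }
    sprintf("H%02d", i)
  }

  for (plan in lineage_plan) {
    org <- paste0(plan$prefix, "0")
    org_sites <- plan$extra
    pops[[org]] <- list(hap = hap_id_of(org_sites), sites = org_sites,
                        lat = plan$lat0, lon = plan$lon,
                        lineage = plan$prefix, front = "origin",
                        order = 0L, parent = NA_character_)
    fronts <- if (plan$fronts == 2L) c("N", "S") else "N"
    idx <- stats::setNames(rep(0L, length(fronts)), fronts)
    parent <- stats::setNames(rep(org, length(fronts)), fronts)
    parent_sites <- stats::setNames(rep(list(org_sites), length(fronts)),
                                    fronts)
    ord <- 0L
    for (k in seq_len(plan$npf)) for (f in fronts) {
      idx[f] <- idx[f] + 1L
      ord <- ord + 1L
      sites <- parent_sites[[f]]
      if (stats::runif(1L) < p$fixation_prob) sites <- c(sites, take(1L))
      id <- paste0(plan$prefix, f, idx[f])
      pops[[id]] <- list(hap = hap_id_of(sites), sites = sites,
                         lat = plan$lat0 +
                           (if (f == "N") 1 else -1) * idx[f] * step_deg,
                         lon = plan$lon, lineage = plan$prefix, front = f,
                         order = ord, parent = parent[[f]])
      parent[f] <- id
      parent_sites[[f]] <- sites
    }
  }

  locs <- names(pops)
  nss <- draw_sample_sizes(length(locs), p$sample_size)
  hap_ids <- sprintf("H%02d", seq_along(hap_key))
  seqs <- vapply(hap_sites, function(s)
    paste(mutate_sequence(rootvec, s), collapse = ""), character(1L))
  haps <- haplotype_set(stats::setNames(seqs, hap_ids))

  cnt <- matrix(0L, length(locs), length(hap_ids),
                dimnames = list(locs, hap_ids))
  for (i in seq_along(locs)) cnt[i, pops[[locs[i]]]$hap] <- nss[i]
  meta <- data.frame(
    location = locs,
    region = vapply(locs, function(l)
      paste0("R", pops[[l]]$lineage, "_",
             ceiling((pops[[l]]$order + 1L) / 4)), character(1L)),
    lat = vapply(pops, `[[`, numeric(1L), "lat"),
    lon = vapply(pops, `[[`, numeric(1L), "lon"),
    stringsAsFactors = FALSE)
  table <- sample_table(cbind(meta, as.data.frame(cnt)), haps)

  edges <- do.call(rbind, lapply(locs, function(l) {
    pr <- pops[[l]]$parent
    if (is.na(pr)) NULL
    else data.frame(parent = pr, child = l, stringsAsFactors = FALSE)
  }))
  truth <- structure(list(
    origin = paste0(lineage_plan[[1L]]$prefix, "0"),
    origins = stats::setNames(
      vapply(lineage_plan, function(pl) paste0(pl$prefix, "0"),
             character(1L)),
      vapply(lineage_plan, `[[`, character(1L), "prefix")),
    founding_order = vapply(pops, `[[`, integer(1L), "order"),
    colonization_edges = edges,
    pop_haplotype = vapply(pops, `[[`, character(1L), "hap"),
    front = vapply(pops, `[[`, character(1L), "front"),
    lineage = vapply(pops, `[[`, character(1L), "lineage")),
    class = "sim_truth")
  list(haps = haps, table = table, truth = truth)
}

#' Simulate Good's stepwise colonization with Wright-Fisher populations
#'
#' See [sim_params()] for the model. Returns sampled haplotype frequencies
#' per population plus the founding ground truth.
#'
#' @param p a [sim_params()] with mode "good-model".
#' @return Same structure as [simulate_fixation_cascade()].
#' @export
simulate_good_model <- function(p) {
  stopifnot(inherits(p, "sim_params"), p$mode == "good-model")
  set.seed(p$seed)
  rootvec <- sample(.BASES, p$L, replace = TRUE)
  take <- new_site_pool(p$L)
  N <- p$pop_size
  g <- p$generations_between_foundings

  hapsets <- list(integer(0)) # haplotype index -> mutation sites
  pops <- list(rep(1L, N))    # each pop: vector of haplotype indices
  for (t in seq_len(p$total_generations)) {
    k <- length(pops)
    if (k < p$n_pops && t %% g == 0L && (t %/% g) == k) {
      newest <- pops[[k]]
      pops[[k + 1L]] <- if (is.null(p$propagule_size)) newest else {
        prop <- sample(newest, p$propagule_size, replace = TRUE)
        sample(prop, N, replace = TRUE)
      }
    }
    for (j in seq_along(pops)) {
      pop <- pops[[j]][sample.int(N, N, replace = TRUE)]
      nmut <- stats::rpois(1L, p$mutation_rate)
      if (nmut > 0L) for (s in take(nmut)) {
        vic <- sample.int(N, 1L)
        hapsets[[length(hapsets) + 1L]] <- c(hapsets[[pop[vic]]], s)
        pop[vic] <- length(hapsets)
      }
      pops[[j]] <- pop
    }
  }

  nss <- draw_sample_sizes(length(pops), p$sample_size)
  sampled <- lapply(seq_along(pops), function(j) {
    if (nss[j] <= N) sample(pops[[j]], nss[j], replace = FALSE)
    else sample(pops[[j]], nss[j], replace = TRUE)
  })

  used <- sort(unique(unlist(sampled)))
  hap_ids <- sprintf("H%02d", seq_along(used))
  seqs <- vapply(used, function(i)
    paste(mutate_sequence(rootvec, hapsets[[i]]), collapse = ""),
    character(1L))
  haps <- haplotype_set(stats::setNames(seqs, hap_ids))

  locs <- sprintf("P%02d", seq_along(pops))
  step_deg <- p$coast_step_km / 111.195
  cnt <- matrix(0L, length(locs), length(hap_ids),
                dimnames = list(locs, hap_ids))
  for (j in seq_along(pops)) {
    tab <- table(factor(match(sampled[[j]], used), levels = seq_along(used)))
    cnt[j, ] <- as.integer(tab)
  }
  meta <- data.frame(location = locs,
                     region = paste0("R", ceiling(seq_along(locs) / 4)),
                     lat = 43 + (seq_along(locs) - 1L) * step_deg,
                     lon = 141, stringsAsFactors = FALSE)
  table <- sample_table(cbind(meta, as.data.frame(cnt)), haps)

  truth <- structure(list(
    origin = locs[1L],
    origins = stats::setNames(locs[1L], "W"),
    founding_order = stats::setNames(seq_along(locs) - 1L, locs),
    colonization_edges = data.frame(parent = locs[-length(locs)],
                                    child = locs[-1L],
                                    stringsAsFactors = FALSE),
    pop_haplotype = stats::setNames(rep(NA_character_, length(locs)), locs),
    front = stats::setNames(c("origin", rep("N", length(locs) - 1L)), locs),
    lineage = stats::setNames(rep("W", length(locs)), locs)),
    class = "sim_truth")
  list(haps = haps, table = table, truth = truth)
}

#' Dispatch a simulation by mode
#'
#' @param p a [sim_params()].
#' @return See [simulate_fixation_cascade()].
#' @export
simulate_colonization <- function(p) {
  switch(p$mode,
         "fixation-cascade" = simulate_fixation_cascade(p),
         "good-model" = simulate_good_model(p))
}

#' Parameter preset emulating the study-scale dataset shape
#'
#' A fixation-cascade preset chosen to produce roughly 70 locations with a
#' mean of about 8.5 sampled individuals, 45-50 distinct haplotypes, two
#' lineages separated by at least 7 substitutions, and a bidirectional
#' western front plus a northward-expanding eastern segment.
#'
#' @param seed RNG seed.
#' @return A [sim_params()].
#' @export
study_shape_preset <- function(seed = 1L) {
  sim_params(mode = "fixation-cascade",
             n_pops_per_front = 27L, fronts = 2L,
             fixation_prob = 0.65,
             second_n_pops_per_front = 14L, second_fronts = 1L,
             sample_size = NULL, L = 490L,
             lineage_split_steps = 7L, coast_step_km = 12,
             seed = seed)
}
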
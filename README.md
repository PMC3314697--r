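# haplospread

Single-locus phylogeography for strongly structured, sedentary organisms.

`haplospread` implements the analysis chain used to reconstruct range-wide
colonization history from mitochondrial haplotype data when populations are
small, mostly monomorphic, and nearly completely differentiated — the
regime typical of headwater-stream invertebrates such as freshwater
crayfish. It is aimed at population geneticists who have an aligned
haplotype FASTA and a table of per-location haplotype counts with
coordinates, and who want the classic network-based inference chain plus a
time-sliced map projection of haplotype spread, all reproducible from a
single seed.

## What it computes

* **Haplotype networks.** The minimum spanning network (MSN) over
  substitution-step distances — the union of all minimum spanning trees,
  so ties produce loops — followed by deterministic loop resolution using
  ordered frequency / topology (interior vs tip) / geography criteria,
  insertion of missing (unsampled) intermediate haplotypes so every edge
  is one mutation, splitting of deeply divergent lineages, per-lineage
  ancestral-haplotype inference (abundance + network centrality), and
  Templeton–Sing nested clades.
* **Population statistics.** Unbiased gene diversity
  h = n(1 − Σ p²)/(n − 1); pairwise F_ST = 1 − H_w/H_b from haplotype
  frequencies (unbiased within-population heterozygosities, H_b the
  probability that haplotypes drawn one from each population differ);
  Nei's D_A = 1 − Σ√(x·y); Tajima's D; mismatch distributions; haversine
  geographic distances; Mantel tests of isolation-by-distance with
  permutation p-values.
* **Stepwise-colonization (Good/Slatkin) tests.** Under serial founding
  with no subsequent gene flow, divergence between a pair of populations
  should fall with the distance of the pair's *older* member from the
  ancestral population, and gene diversity should fall with distance from
  the ancestor. Both tests are provided (Mantel-style permutation for the
  pair test; Pearson for diversity), plus gene flow M = (1/F_ST − 1)/4.
* **Molecular-clock dating.** Percent divergence = 100·steps/L bracketed
  by a slow/fast rate (default 0.65–0.88 % per Myr, the decapod 16S
  calibration).
* **Time-sliced spread projection.** Haplotypes are assigned relative
  ages from their unit-step depth below the lineage ancestor; lineage
  timelines are aligned at their most recent tips; each time slice T maps
  the locations of newly appearing and carried haplotypes. This is the
  "genealogical spread" visualization that turns a resolved network plus
  coordinates into an ordered colonization movie.
* **Serial-founder simulators.** A fixation-cascade mode (each founding
  fixes at most one new infinite-sites substitution; populations sampled
  monomorphic) and a Wright–Fisher Good-model mode (exact
  frequency-spectrum founding, optional finite propagule), both returning
  full ground truth so every stage of the chain can be validated.

## Worked example

Simulate a study-scale dataset (two lineages, ~70 locations, uneven
sampling) and analyze it:

```r
library(haplospread)

sim <- simulate_fixation_cascade(study_shape_preset(seed = 11))
cfg <- analysis_config(mantel_permutations = 999, rng_seed = 11)
res <- phylogeography(sim$haps, sim$table, cfg)
res
#> Phylogeographic analysis
#>   45 haplotypes, 490 sites; 70 locations (58 after n >= 5 filter)
#>   mean pairwise FST = 0.99, mean Nei's DA = 0.99
#>   2 lineage(s): L1 (34 haps, ancestor H11), L2 (11 haps, ancestor H35)
#>   lineage split: >= 7 steps, 4.18% mean divergence, dated 4.8-6.4 Myr
#>   IBD (overall): r = 0.193, one-sided p = 0.001
#>   timeline: 24 slices
```

Reading this: nearly every location is fixed for a private haplotype, so
mean pairwise F_ST is near 1; the network splits into two lineages at
seven or more mutational steps; isolation-by-distance is weak but
significant (Mantel r = 0.19, p = 0.001 over 999 permutations); and the
projection orders the 45 haplotypes into 24 single-mutation time slices.
Dating the split with the decapod 16S clock:

```r
clock_dating(res$clock$min_split_steps, 490)
#> Clock dating: 7 steps / 490 bp = 1.43% divergence -> 1.6-2.2 Myr
#>   (1,600,000-2,200,000 yr) at 0.65-0.88%/Myr
```

`plot(res, type = "network")`, `plot(res, type = "ibd")` and
`plot(res$timeline, T = 5)` draw the network, the IBD scatter and a
single time-slice map; `run_all(p, cfg, out_dir)` writes the full file
report (FASTA/TSV inputs, `report.json`, matrices, GraphML network,
GeoJSON timeline, per-slice PNG maps). A thin command-line wrapper is
installed at `inst/cli/haplospread.R` with `simulate`, `analyze`,
`project` and `all` subcommands.

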
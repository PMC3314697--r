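Package: haplospread
Title: Haplotype Networks, Stepwise-Colonization Tests and Time-Sliced
    Genealogical Spread Maps for Intraspecific Phylogeography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for range-wide single-locus phylogeography of sedentary
    organisms with strong population structure. Builds minimum spanning
    networks over mtDNA haplotypes, resolves network loops with
    frequency/topology/geography criteria, inserts missing (unsampled)
    intermediate haplotypes, splits deeply divergent lineages and infers
    per-lineage ancestral haplotypes. Computes haplotype-frequency
    population-genetic statistics (unbiased gene diversity, pairwise FST,
    Nei's DA, Tajima's D, mismatch distributions), Mantel tests of
    isolation-by-distance, stepwise-colonization (Good/Slatkin) tests and
    molecular-clock dating, and projects haplotype distributions onto maps
    in time slices of single mutational steps. Includes serial-founder
    colonization simulators (fixation-cascade and Wright-Fisher Good-model
    modes) that provide ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    yaml,
    geosphere,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
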
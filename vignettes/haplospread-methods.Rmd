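---
title: "Methods: haplotype networks, colonization tests and time-sliced spread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype networks, colonization tests and time-sliced spread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplospread)
```

## The setting and the data model

`haplospread` targets single-locus, range-wide phylogeography of
low-dispersal organisms in which most populations are small and fixed for
a private haplotype: between-population differentiation is close to
complete, within-population diversity close to zero, and the haplotype
genealogy is shallow enough that a mutational-step network is an adequate
estimate of it. The data model is deliberately minimal: an aligned
haplotype FASTA (one record per distinct haplotype, identical lengths,
IUPAC DNA plus gaps) and a tab-separated sample table (location, region,
latitude, longitude, then a full matrix of per-haplotype counts). Counts
are the single source of all frequency statistics; coordinates are the
single source of all distances; nothing derived is stored at the boundary.

Two boundary conventions matter downstream. First, pooling of adjacent
locations (e.g. several samples from one river) is applied *before* the
minimum-sample-size filter, so adjacent small samples can survive as one
adequately sized population; pooled coordinates are the count-weighted
centroid and pooling across region labels is an error. Second, the full
count matrix is required — a missing haplotype column is an error rather
than an implicit zero — so that silent column drift between files cannot
corrupt an analysis.

## Distances and frequency statistics

Substitutions are counted at sites where both sequences carry an
unambiguous base; ambiguity codes and N are ignored sitewise; indel
events are maximal runs of sites gapped in exactly one sequence and are
reported separately, never mixed into the step distance (the marker this
chain is designed for is effectively gap-free; the rule exists for
robustness). Tajima's D and the mismatch distribution use
pairwise-complete deletion at gap/ambiguous sites.

Pairwise F_ST is the haplotype-identity (frequency) estimator
1 − H_w/H_b, with H_w the mean of the two *unbiased* within-population
heterozygosities n(1 − Σp²)/(n − 1) and H_b = 1 − Σ p·q. Haplotypes are
treated as unordered alleles — a distance-weighted Φ_ST is deliberately
not used, because in the target regime nearly every population is fixed
and the identity estimator is both sufficient and transparent. Two
consequences are documented rather than hidden: identical monomorphic
populations give F_ST = 0 by convention (H_b = 0), and a population
compared with itself gives exactly −1/(n − 1), the small-sample bias of
mixing an unbiased numerator with a plain denominator. Negative estimates
are reported as computed; only the gene-flow transform
M = (1/F_ST − 1)/4 treats F_ST ≤ 0 as undefined.

Geographic distances are haversine great-circle distances on a 6371 km
sphere. Planar distance on raw degrees is ill-defined across several
hundred kilometres of latitude; at the spatial extent this package
targets the two differ by well under one percent, so the choice is about
well-definedness, not accuracy.

The Mantel test correlates the unordered off-diagonal pairs of two
labelled matrices and permutes row/column labels of the second; the
two-sided p is (#{|r_perm| ≥ |r_obs|} + 1)/(B + 1), with both one-sided
tails also reported. Isolation-by-distance tests default to the
"greater" tail (the IBD prediction is positive), the directional
stepwise-colonization tests to "less". The adjusted
r² = 1 − (1 − r²)(m − 1)/(m − 2) over m pairs is reported alongside the
plain r² because small-sample study summaries are conventionally printed
on that scale — it is the only quantity here that can legitimately be
negative near r = 0.

## Network construction and its deterministic tie-breaks

The minimum spanning network includes edge (u, v, w) exactly when u and v
lie in different components of the graph restricted to edges of weight
strictly below w. This is equivalent to the union of all minimum spanning
trees; equal-weight alternatives therefore appear as loops rather than
being silently broken by input order.

Loop resolution reduces the MSN to a spanning tree by repeatedly deleting
one cycle edge. The coalescent expectations behind the criteria are
qualitative (old, common haplotypes are interior; rare ones are tips;
mutations connect geographically proximate populations), so a total order
was fixed once to make the output reproducible: delete the cycle edge
with (1) the smallest endpoint count sum, then (2) the smallest endpoint
degree sum (tip edges go before interior edges), then (3) the largest
minimal geographic distance between locations carrying the two endpoint
haplotypes (co-occurrence counts as zero), then (4) the lexicographically
last edge label. Any fixed order satisfies determinism; this one deletes
exactly the edges the qualitative criteria disfavour.

Edges of weight k > 1 are then subdivided by k − 1 latent ("missing")
haplotypes so that graph distance equals mutational distance. Lineages
are the components left after removing edges of at least
`lineage_split_steps` (default 5) — the deep split this method targets
separates at 7+ steps while within-lineage gaps stay at a few steps, so
the default sits between those scales and is configurable. The ancestral
haplotype of a lineage maximizes
0.5·(count/max count) + 0.5·(min eccentricity/eccentricity) over observed
nodes; latent nodes are never eligible. Eccentricity (an integer) was
chosen over closeness because its ties are auditable, and the equal
weights encode that abundance and centrality are two cues of the same
rank with no stated relative strength; ties fall back to the larger
count, then the smaller ID. Templeton–Sing nesting unites tips with their
adjacent interior node level by level; a stranded singleton joins the
adjacent nest with fewest members, ties resolved toward the
lexicographically greater neighbouring clade (this reproduces the
standard worked behaviour on a five-node path).

## Stepwise-colonization tests

Under the Good/Slatkin serial-founding model (each new population copies
the newest population's allele frequencies, then evolves in isolation),
the divergence of a population pair is set by the age of its *older*
member, so the pair test regresses D_A(i, j) on
min(d(ancestor, i), d(ancestor, j)) — the mean is available behind a
flag. Because pairs share populations, significance comes from
Mantel-style relabelling, not from treating pairs as independent. The
companion diversity test is an ordinary Pearson correlation of unbiased
gene diversity on distance from the ancestor. Both report the adjusted r²
for comparability; the diversity test flags the fully monomorphic regime
(constant zero diversity) as undefined rather than returning a
meaningless r.

Clock dating converts steps to percent divergence (100·steps/L) and
brackets time with a slow and fast rate in percent per Myr (defaults
0.65 and 0.88, the decapod 16S calibration). Presentation rounding is
part of the contract: percent to two decimals, Myr to one decimal, years
to two significant figures.

## The time-sliced spread projection

Within each lineage, the relative age of a haplotype is its unit-step
depth below the lineage ancestor, latent intermediates included — a
missing haplotype advances the clock exactly one step but never appears
on a map. With G the maximum depth over lineages, a haplotype at depth
`depth(h)` in a lineage of maximum depth D appears at
T(h) = 1 + G − (D − depth(h)). This aligns every lineage's most recent
tip to the final slice 1 + G, so lineages of unequal depth share a
common "now" while the deeper lineage's ancestor defines T = 1. Each
slice lists newly appearing haplotypes and carries all earlier ones, with
every sampling location where the haplotype was observed. Slice maps are
plain latitude/longitude scatters; no basemap is required.

## The simulators, and what passing tests do and do not show

The fixation-cascade mode encodes the regime the analysis chain is built
for: an origin population fixed for a root haplotype; one or two
colonization fronts extending along a 1-D coastline at fixed spacing
(populations every 12–15 km, matching the inter-river scale of the
motivating system); each founding copies the parent's fixed haplotype
and, with probability f, fixes one new infinite-sites substitution; an
optional second lineage seeded s substitutions from the root colonizes a
disjoint segment. Infinite-sites mutation (sites drawn without
replacement) makes step distances equal true mutation counts, so network
recovery can be checked exactly. The study-shape preset (70 locations,
two fronts west, one front east, f = 0.65, s = 7, sample sizes
1 + NegBin(2, 7.5) with mean 8.5) reproduces the gross shape of a
range-wide crayfish survey: ~45 haplotypes, near-total monomorphism,
mean pairwise F_ST near 1, two lineages 7+ steps apart.

The Good-model mode is a forward Wright–Fisher simulation: N haplotype
lineages per population, Poisson(μ) new infinite-sites mutations per
population per generation, a new population founded every g generations
from the newest one by copying its frequency spectrum exactly, no
migration afterwards. μ is parameterized per population (not per
individual) so that θ = 2μ stays O(1) at realistic N; a per-individual
reading at the same numbers would make every sampled individual unique
and all between-population D_A identically 1, leaving the pair test
undefined. An optional finite `propagule_size` replaces the exact
spectrum copy for founder-effect experiments.

Two calibration choices deserve emphasis because they were made once, by
timescale reasoning, and then frozen. The regime-discrimination
experiments use n = 10 populations, N = 100, μ = 0.2, g = 80: the range
of pair divergence times (g … (n−1)·g generations) then straddles the
haplotype-turnover timescale ≈ 1/(1/(2N) + μ/N), so D_A varies smoothly
across pair ages instead of saturating at 1, and the predicted negative
pair-test correlation is detectable. The founder-effect diversity
experiment uses N = 300, μ = 0.5, g = 60 and a propagule of 2, making the
post-bottleneck recovery time comparable to the founding span so that
older populations are visibly more diverse. Under *exact* spectrum
copying the diversity gradient does not exist even in expectation —
every population's heterozygosity follows the same recursion regardless
of age — which is itself the theoretically expected behaviour of the
model, and is why the diversity prediction is only tested with a finite
propagule.

The simulators emulate the statistical structure the analysis assumes:
monomorphism, private haplotypes, stepwise spatial arrangement, a deep
two-lineage split. They do not emulate real-data complications —
recombination (irrelevant for mtDNA), homoplasy at finite sites,
sampling gaps, misidentified locations, secondary contact, or selection.
Passing the recovery experiments therefore shows the chain is correct
and internally consistent under its own assumptions, not that those
assumptions hold for any particular empirical system.

## Numerical conventions and degenerate inputs

Undefined quantities are flagged, not fudged: gene diversity needs n ≥ 2;
F_ST needs both n ≥ 2; Tajima's D is undefined when S = 0 or n < 4 (S and
π are still reported); a constant distance matrix makes a Mantel test
undefined; M is undefined at F_ST ≤ 0; the all-monomorphic regime flags
the diversity test. Duplicate sequences (step distance 0) are allowed
with a warning. All tie-breaks in the network stage are total orders, so
identical inputs yield byte-identical outputs; every randomized stage
(Mantel permutations, simulators) takes an explicit seed, and the file
reports contain no timestamps, so whole runs are reproducible
byte-for-byte.

## Problem sizes used in validation

The automated checks run brute-force oracle comparisons on random
instances of up to 12 haplotypes × 8 populations, exhaustive
spanning-tree enumeration on up to 6 nodes, exhaustive Mantel
enumeration on up to 6 labels, and 50-seed simulation experiments with
11–21 populations (cascade) and 10 populations of N = 100–300
(Wright–Fisher). These sizes were chosen as the smallest at which every
property is non-trivially exercised; all statistics scale comfortably to
study-scale data (dozens of populations, tens of haplotypes) in seconds.

## Known limitations

The F_ST estimator is frequency-based and will differ slightly from
AMOVA variance-component estimators on polymorphic data; mismatch-model
fitting (expansion τ/θ), nested-clade distance inference (Dc/Dn),
statistical-parsimony connection limits and coalescent dating are out of
scope; the geography criterion in loop resolution is one defensible
reading of "resolve by haplotype distributions"; and the projection
assigns ages from network depth alone, which is a relative-rank clock,
not a calibrated one — the per-slice maps order events but do not date
them without the separate rate bracket.
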
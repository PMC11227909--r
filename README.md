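# NicheOverlap

Quantifying multi-dimensional niche overlap and differentiation between
two sympatric species — breeding time, nest site and diet — with
kernel-density overlap indices, permutation null models, and
DNA-metabarcoding diet analysis.

## The problem

Ecologically similar species breeding in the same habitat (here the
motivating system: two secondary cavity-nesting birds, a resident tit and
a migratory flycatcher competing for the same nest boxes) can coexist
stably only if they partition at least one major niche dimension. Testing
that prediction requires a common overlap currency across very different
data types: phenology dates, mixed continuous/categorical nest-site
descriptors, and fecal metabarcoding read counts.

The package's core statistic is the niche overlap index

    NO = 1 − ½ ∫ |f̂_A(x) − f̂_B(x)| dx = ∫ min(f̂_A, f̂_B),

the complement of half the total variation distance between the two
species' utilization distributions (1 = identical niches, 0 = disjoint).
It is estimated by Gaussian KDE for continuous variables
(`continuousOverlap`), by proportional similarity of category frequencies
for categorical variables (`categoricalOverlap`), and by an atom-aware
logit-scale KDE for zero-inflated diet proportions (`proportionOverlap`).
Differentiation is tested against a species-label permutation null
(`nullModelTest`, 1000 relabelings, one-sided for *smaller*-than-chance
overlap), with Holm sequential-Bonferroni adjustment within each
dimension (`sequentialBonferroni`). Composite (per-dimension) and overall
overlaps are means of the member variables (`compositeOverlap`).

Around that core: breeding-time arithmetic on a 1-April Julian scale
(`toJulian`, `breedingPeriod`, `periodOverlapFraction`, `hatchingRate`);
MOTU-table quality filtering and similarity-threshold taxonomy
(`filterCounts`, `assignTaxonomy`); diet metrics (`rra`, `foo`,
`individualRichness`, `levinsBA`, `rarefactionCurve`); Bray–Curtis +
ANOSIM (`brayCurtis`, `anosim`); and a synthetic two-species generator
with analytically known per-variable overlap (`syntheticConfig`,
`generateDataset`) so the whole pipeline is testable without field data.
Count tables live in a `MotuExperiment`, a `SummarizedExperiment`
subclass (MOTUs × samples, species labels in `colData`, taxonomy in
`rowData`).

## Worked example

```r
library(NicheOverlap)

## composite arithmetic on the published per-variable overlaps of the
## motivating tit/flycatcher system
ov <- referenceOverlaps()
compositeOverlap(ov$overlap[ov$dimension == "breeding_time"])$mean
#> [1] 0.44
round(compositeOverlap(ov$overlap)$mean, 3)   # overall, 29 variables
#> [1] 0.763
round(compositeOverlap(ov$overlap)$sd, 3)
#> [1] 0.165

## a full synthetic analysis at study scale
ds <- generateDataset(syntheticConfig(seed = 42))
ds$motu
#> MotuExperiment: 165 MOTUs x 73 samples
#> species: A (n=49), B (n=24)
#> total reads: 1,459,341
res <- nicheOverlapAnalysis(ds$breeding, ds$nestsites, ds$motu,
                            nPerm = 1000, seed = 42, filter = TRUE)
res$composites[, c("dimension", "mean", "sd", "p_raw", "significant")]
#>       dimension  mean     sd    p_raw significant
#> 1 breeding_time 0.214 0.0512 0.000999        TRUE
#> 2     nest_site 0.797 0.0973 0.000999        TRUE
#> 3          diet 0.767 0.1301 0.000999        TRUE
#> 4       overall 0.720 0.2111 0.000999        TRUE

s <- breedingTimeSummary(ds$breeding, "A", "B")
sprintf("co-breeding overlap: %.2f%% (A), %.2f%% (B)",
        s$overlapPctA, s$overlapPctB)
#> [1] "co-breeding overlap: 56.76% (A), 70.00% (B)"
```

The composite lines read: the two synthetic species overlap weakly in
breeding time (0.21; the generator separates their laying peaks by ~30
days), strongly in nest sites and diet (~0.8), and each observed overlap
is smaller than its permutation null (empirical p ≈ 0.001 at 1000
permutations). Per-variable results with null means, raw/adjusted p and
significance flags are in `res$variables`.

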
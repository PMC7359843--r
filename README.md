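# DivergeScan

Population-genomic inference for diploid biallelic SNP panels from
structured population samples — RAD-seq-style data from populations in
paired habitats across two geographic regions. The package is for
population geneticists who need, in one tested toolchain:

- **VCF import and a post-genotyping filter chain** (depth, call rates,
  region-wise heterozygosity excess, relatedness, per-population caps),
- **diversity and differentiation statistics**: Weir–Cockerham FST per SNP,
  pairwise with locus bootstrap, and in sliding windows (200 kb or
  50-SNP/step-5 blocks, top-1% outliers); observed heterozygosity, MAF
  spectra, LD decay and LD-based recent Ne, runs of homozygosity, a
  VanRaden genomic relationship matrix, Hardy–Weinberg tests, and
  FST-vs-recombination enrichment,
- **demographic inference by ABC** over twenty two-population divergence
  models — panmixia (PAN), equilibrium island model (EQ), strict isolation
  (SI), isolation-with-migration (IM), ancient migration (AM), secondary
  contact (SC), each with optional beta-distributed heterogeneity of
  per-locus Ne and migration — simulated with a built-in structured
  coalescent (Rcpp) and summarized by π, Watterson's θ, dxy, net
  divergence Da = dxy − (π₁+π₂)/2, per-locus FST and the Wakeley–Hey site
  classes,
- **redundancy-analysis genome scans** (global and partial RDA with
  permutation tests; 3-SD loading outliers),
- **chromosomal inversion detection** by windowed PCA and local PCA/MDS,
  karyotype assignment, arrangement-stratified FST/π/dxy, and dating via
  T = Da/(2µ),
- **a synthetic study generator** producing VCF + metadata + ground-truth
  JSON so the complete pipeline is testable offline.

The central estimator conventions: FST aggregates Weir–Cockerham variance
components as ratios of sums; migration is scaled as M = 4·N₀·m (Nm =
migrants per generation); times convert to years at 2.3 years per
generation by default.

## Worked example: plant an inversion, find it, date it

```r
library(DivergeScan)
set.seed(5)

st <- makeStudy(studyConfig("inversion"))   # 114 mainland samples, chr3
g  <- st$genotypes
g
#> GenotypeData: 5271 variants x 114 samples
#>   populations: A1D A2D
#>   chromosomes: chr3
#>   missing rate: 0.020

calls <- Filter(function(x) x$status == "called", callInversions(g))
call  <- calls[[1]]
call$region
#> chr3 11820091 - 14620151        (planted truth: 11800001 - 14600000)
call$karyotypes
#> Inversion karyotype call: called
#> inv_hom     het std_hom
#>       4      23      87
#> inverted-arrangement frequency: 0.136 (HWE p = 0.131)

ast <- arrangementStats(g, call$region, call$karyotypes$karyotype,
                        callable_bp = 42000)  # 140 loci x 300 bp
dt  <- dateInversion(ast$da, mu = 1e-8)
c(fst_in = ast$fst_in, fst_out = ast$fst_out, da = ast$da)
#> fst_in = 0.714  fst_out = 0.0047  Da = 0.00388
dt$age_generations
#> age = 194152 generations (446548 years)
```

The scan recovers the planted 2.8-Mb region to within one 100-SNP block,
assigns all 114 karyotypes correctly, and the measured net divergence
(0.0039 against a planted target of 0.0044) dates the arrangement at
~194,000 generations. Differentiation between arrangement homozygotes is
two orders of magnitude higher inside the region (0.71) than outside
(0.005).

The other entry points follow the same pattern: `applyFilters()`,
`pairwiseFst()` / `windowFst()`, `simulateReferenceTable()` +
`abcModelChoice()` / `abcEstimateParams()`, `rdaFit()` / `partialRda()` +
`loadingOutliers()`, and `runPipeline(subcommand, config)` for a
config-driven run (see the methods vignette in `vignettes/`).

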
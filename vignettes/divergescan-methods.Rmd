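---
title: "DivergeScan: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DivergeScan: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DivergeScan)
```

DivergeScan analyses diploid biallelic SNP panels from structured
population samples — the kind produced by RAD sequencing of birds or other
vertebrates sampled across paired habitats in two geographic regions. This
vignette explains the models behind each module, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The genotype container and filter chain

Genotypes live in a `GenotypeData` object (a `RangedSummarizedExperiment`):
a variants-by-samples matrix of ALT-allele dosages (0/1/2/NA), variant
coordinates as 1-based `GRanges`, and the sample sheet (population, region,
habitat, latitude, longitude, altitude) as column data. Window operations
use half-open intervals internally and report 1-based inclusive bounds.

`applyFilters()` applies a standard RAD post-genotyping chain, in order:
per-variant mean depth within [10, 100]; variant call rate ≥ 0.8; removal
of variants with observed heterozygosity ≥ 0.65 *within either region*
(a guard against stacked paralogs — the region-wise formulation means a
variant is dropped as soon as one region shows the excess); sample call
rate ≥ 0.85; removal of one member of each sample pair with genomic
relatedness ≥ 0.35; a random cap of 60 samples per population; and removal
of monomorphic variants. Two choices here were open and are therefore
declared rather than inferred: for a related pair we remove the member
with more missing genotypes (ties broken by sample id, after sorting pairs
by decreasing relatedness), and the population cap samples from the
session RNG so a seed set beforehand makes the run reproducible.

## Differentiation and diversity statistics

Per-SNP FST uses the Weir–Cockerham (1984) variance components *a*, *b*,
*c*; the estimate is *a*/(*a*+*b*+*c*). Genome-wide, per-window and
per-class (autosome vs Z) estimates are ratios of summed components, not
means of ratios — the numerically stable "weighted" form; the window text
statistic is genuinely ambiguous between the two in common usage, and
ratio-of-sums is what VCFtools' windowed FST computes. Bootstrap p-values
for FST > 0 resample loci (default 1,000 replicates). Windows come in two
flavours: 200-kb physical windows, and blocks of 50 SNPs stepping by 5,
which equalizes information content between SNP-dense and SNP-poor
regions. Windows in the top 1% of the window-FST distribution are flagged
as outliers; no further multiplicity correction is applied, matching the
empirical-threshold convention for genome scans.

Relatedness is a VanRaden genomic relationship matrix: dosages centered at
2p, missing values mean-imputed, cross-products scaled by Σ2p(1−p). LD is
composite (dosage-correlation) r², which needs no phasing and matches what
Plink reports for unphased data. The LD-based recent-Ne estimator inverts
E[r²] = 1/(α + 4Nc) per distance bin after subtracting the 1/(2n) sampling
bias, with α = 2 and a constant 1 cM/Mb map by default; each bin dates
roughly t = 1/(2c) generations ago. These defaults are configurable; they
are the package's own, as the tools they emulate do not print theirs.

ROH are maximal homozygous runs (missing genotypes neither break nor count)
of at least 500 kb, segmented to at most 100 SNPs; zero heterozygotes are
tolerated by default (configurable), since only the length and SNP-count
constraints are standard. Group contrasts use a Wilcoxon rank-sum test on
segment lengths.

The Hardy–Weinberg test is the closed-form 1-df Pearson chi-square at the
estimated allele frequency; a fixed allele returns chi-square 0, p = 1 by
definition.

## Coalescent simulator and the twenty divergence models

The simulator (`src/coalescent.cpp`) is a backwards-time structured
coalescent over K demes with piecewise-constant epochs: per-deme sizes, a
backward migration-rate matrix, and a deme relabelling applied on entry to
each epoch (used to merge daughter populations into ancestors). Mutations
are infinite-sites: Poisson on total branch length, placed uniformly on
branches, positions continuous within the locus (a continuous position
guarantees the infinite-sites property that an 85-bp integer grid could
not). Loci are independent and have no intra-locus recombination, which is
the right regime for short RAD loci. No R-level coalescent package is
available in this stack, so the simulator is authored here; its output is
validated in the tests against closed-form neutral expectations (π and
Watterson's θ ≈ 4Nµ within 3 standard errors, E[Da] = 0 under panmixia)
and against monotonicity in migration.

Six base scenarios are supported — PAN (panmixia), EQ (two-deme island
model at equilibrium, no split time), SI (strict isolation after a split),
IM (continuous gene flow after the split), AM (gene flow from the split
until T_am, then isolation), SC (isolation until T_sc, then renewed gene
flow) — each in a homogeneous-Ne or beta-heterogeneous-Ne version, and the
four migration models also in a heterogeneous-migration version: twenty
variants. Migration is parameterized as M = 4·N0·m with M12 the scaled
number of migrants into population 1 from population 2; backward lineage
rates divide by the recipient's 4N. Per-locus heterogeneity multiplies
sizes (or migration) by a Beta(a, b) draw divided by its mean a/(a+b), so
the genome-wide averages stay at their nominal values and the
hyper-parameters remain orthogonal to the scale parameters; draws near
zero emulate barrier loci.

Prior defaults are the package's own (the study pipelines this emulates do
not print theirs): log-uniform Ne in [1e2, 1e6] and T_split in [1e3, 3e6]
generations; T_am and T_sc drawn as uniform fractions of T_split, which
enforces their ordering constraints by construction; M uniform on [0, 40]
with a documented "wide" option [0, 200]; beta hyper-parameters uniform on
[0.1, 10]. Mutation rate defaults to 1e-8 per bp per generation and the
locus length to 85 bp.

`summarizeDataset()` produces the ABC summary vector: per-locus means and
SDs of π per population, Watterson's θ per population, dxy, net divergence
Da = dxy − (π1+π2)/2, a per-locus FST (1 − mean within-π / total π), and
the Wakeley–Hey site classes (private sx1/sx2, shared ss, fixed sf), plus
the across-locus correlation of π1 with π2 — 23 statistics. Within-group π
uses the unbiased n/(n−1) form; dxy is the cross-group mean, so for
literally identical haplotype sets Da is −π/n rather than exactly zero, an
O(1/n) sampling effect the tests account for.

## ABC model choice and parameter estimation

Statistics are standardized by the reference table's median absolute
deviation (robust to the heavy-tailed summaries migration models produce);
rejection keeps the tolerance fraction (default 0.5%, floor 100, fewer
than 50 is an error) nearest in Euclidean distance. Model probabilities
come from a weighted multinomial logistic regression evaluated at the
observed point, with rejection proportions as the documented fallback; a
hierarchical option picks the base scenario family first, then the
heterogeneity variant. Parameter posteriors use the Beaumont local-linear
adjustment with Epanechnikov weights; strictly positive parameters are
regressed on the log scale to stabilize the adjustment. The prior-overlap
diagnostic reports the posterior mass inside the central 50% of the prior:
a posterior equal to the prior sits near 0.5, so values far from 0.5 (by
0.2 or more, the declared rule) flag a genuinely updated posterior.

With unknown original simulation budgets and priors, published posterior
probabilities of specific models are not reproducible quantities; what is
testable is self-consistency, and that is what the acceptance suite
measures: pseudo-observed data from SI (deep split), EQ (M = 4) and PAN
are assigned to the generating scenario in at least 7 of 10 replicates per
class, and the EQ-model Ne lies inside its 95% credible interval in at
least 80% of 20 replicates. These experiments run at desk scale — 300–500
simulations per model, 100 loci of 85 bp, 16 haplotypes per population —
chosen so the whole suite completes in minutes on one CPU; the thresholds
are unchanged from the full-scale formulation.

## RDA genome scan

`rdaFit()`/`partialRda()` wrap vegan's constrained ordination: genotypes
mean-imputed per SNP, numeric predictors standardized, factors coded 0/1
and scaled, exact collinearity dropped with a warning. Sample scores are
the constrained (linear-combination) scores, which is what the explicit
regression-then-eigendecomposition construction yields; an independent
two-step oracle in the tests confirms the equivalence at 1e-10. Global and
marginal significance use permutation tests of the pseudo-F (default
1,000 permutations). Outlier SNPs deviate from the mean loading by more
than 3 SDs on the leading axes — axis 1 by default for a single-predictor
partial RDA, configurable — matching the standard 3-SD convention, which
flags ≈ 0.27% of null Gaussian loadings. LD pruning before ordination
(50-SNP windows, step 5, r² > 0.5 — the VIF-2 equivalent) is available as
`ldPrune()`.

## Inversion detection, karyotyping, dating

The windowed-PCA scan computes PC1 per physical window and clusters the
scores with a one-dimensional Gaussian mixture (EM from a k-means start, k
in 1..3 chosen by BIC on the mixture likelihood — a naive within-SS BIC
degenerately prefers the largest k on continuous scores). A window is
"trimodal" when k = 3 wins, the middle component sits within 25% of the
midpoint of the outer two (the heterozygote expectation), and adjacent
components are separated by at least three times their pooled spreads.
Isolated trimodal windows do occur in clean data wherever a common local
haplotype dominates PC1 — dosage 0/1/2 of a haplotype is genuinely
trimodal — which is why the call does not rest on single windows.

The local-PCA scan summarizes consecutive 100-SNP blocks by the rank-2
eigen-approximation of their sample covariance, normalized to unit
Frobenius norm; block distances (Frobenius) are embedded by classical MDS
and outliers taken at |MDS1 − median| > 3 × mad (the scaled median
absolute deviation — the robust counterpart of the 3-SD rule). The exact
block metric of published local-PCA tools is not printed; the low-rank
covariance distance tests the same structure. `callInversions()` requires
at least three consecutive outlier blocks with a shared MDS1 sign before
karyotyping; this threshold removes isolated local-LD artifacts while
keeping real inversions, which span many blocks.

Karyotypes come from the same 1-D mixture on region-wide PC1: middle
cluster heterozygous, minor outer cluster the inverted homozygote (the
inverted arrangement is taken to be the rarer one — the generator records
true polarity so this assumption is itself testable). If three clusters
are not supported the call is demoted to "candidate" with karyotypes
unassigned. Arrangement-stratified statistics then give FST between
homozygote groups inside vs outside the region, π per karyotype group in
10-kb windows, and dxy between arrangement groups computed from group
allele frequencies (p_x(1−p_y) + p_y(1−p_x) per site — equal to the
haplotype dxy in expectation, which avoids needing phase). With a sparse
RAD panel the per-bp denominator should be the callable sequence, not the
window span; `callable_bp` exposes exactly that. The arrangement age is
T = Da/(2µ) generations (µ = 1e-8 by default) and years at 2.3 years per
generation. UPGMA trees for arrangement groups use average-linkage
`hclust` serialized through ape.

## The synthetic study generator

`makeStudy()` emulates the study design end to end: ten populations named
by region and habitat (mainland "A" / island "B", deciduous "D" /
evergreen "E"), 12 diploids each by default, six synthetic chromosomes
(14, 12, 16, 10, 8 Mb plus a 6-Mb "chrZ" for chromosome-class splits),
300-bp loci every 20 kb, µ = 1e-8. The background history is a single
K-deme coalescent: within-region island-model migration always on
(M_within = 250 total scaled immigration per population), between-region
migration only in the ancient window [T_am, T_split) = [8,000, 50,000)
generations (M_between = 1.5), everything merging into one ancestral deme
(N_anc = 40,000) at T_split; mainland populations have Ne = 50,000, island
15,000. These values were calibrated once, against the study-scale targets
the generator exists to emulate — between-region FST ≈ 0.08 (accepted
band 0.05–0.12), within-region pair FST ≈ 0.003–0.008, island
heterozygosity below mainland — and then frozen; the acceptance script
recomputes the realized values at every run. The 300-bp locus length
(rather than the 85-bp read length) is the desk-scale choice that brings
SNP density to a few per locus at these effective sizes, giving the window
and block machinery realistic occupancy.

The planted inversion is a contiguous chr3 region (11.8–14.6 Mb) in which
each sample's genotypes derive from two arrangement haplotype pools
simulated under strict isolation at depth Da_target/(2µ) with pool sizes
5,000 (inverted) and 50,000 (standard); the ancestral pool size is their
mean, which makes E[Da] equal the target (0.0044) exactly. A sample's two
haplotype slots map to pools according to its karyotype, and that mapping
is fixed across all loci of the region — the arrangement behaves as one
non-recombining locus, which is what local PCA detects. Karyotypes are
drawn at Hardy–Weinberg proportions at the configured regional frequencies
(0.14 mainland, absent on the island); the "inversion" preset instead pins
the karyotype counts to a study-scale sample (4 / 23 / 87 of 114
mainland individuals), because at frequency 0.14 a binomial draw of ~100
samples frequently contains fewer than two inverted homozygotes and the
three-cluster structure every karyotyping method needs is then absent from
the data, not missed by the method. Planted habitat outliers are
frequency shifts (δ = 0.3 between habitats, same base frequency in both
regions) — they test the detection machinery, not selection realism.

What the generator does not emulate: sequencing reads and genotyping
error, recombination-map variation (LD decays by locus independence, not a
map), selection at linked sites, and overlap between plants (colliding
plants are an error, not a merge). Passing tests therefore demonstrate
that the statistical machinery recovers known structure at realistic
magnitudes — not that any particular empirical dataset would yield the
same numbers.

## Pipeline, configuration, reproducibility

`runPipeline(subcommand, config)` wires the modules into the workflow
(simulate-data, filter, stats, scan-fst, scan-rda, abc-simulate, abc-fit,
inversion) from one YAML config; unknown keys are rejected before any
computation, every run writes a `manifest.json` with the resolved config,
seed and package version next to its artifacts, and the same config and
seed reproduce identical outputs. The package is a library first — the
functions, this vignette and the scripts are the interface — with a thin
`inst/scripts/divergescan.R` wrapper for shell use.

## Known limitations

Two populations only in the ABC models (the study generator composes more
demes, but inference contrasts pairs); no intra-locus recombination, so
loci much longer than ~1 kb would violate the model; the LD-based Ne
estimator assumes a constant linear map; the local-PCA block metric is a
reasonable stand-in for published tools rather than a byte-compatible
reimplementation; and ABC posteriors depend on the simulation budget —
at desk scale the credible intervals are honest but wide.
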
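---
title: "Methods: landscape genomics of multi-population SNP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape genomics of multi-population SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `landgen`: what each
stage assumes, which parameters matter and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical decisions a maintainer would otherwise have to reverse-engineer.

## The study design the package encodes

The pipeline targets a common design in invasion and vector biology: tens
of field populations of a highly dispersive insect, genotyped at
genome-wide SNPs from reduced-representation sequencing, with two competing
hypotheses about what structures differentiation between populations —
geographic distance (isolation by distance, IBD) and connectivity to the
human transport networks (shipping, air routes) that carry these insects
between cities. The bundled site tables for *Aedes aegypti* (16
populations) and *Ae. albopictus* (20, of which one divergent
subpopulation is conventionally excluded from landscape models) define the
study geometry: city coordinates, a marine connectivity score (mean
density of commercial shipping tracks within 200 km of the sampling
point, dimensionless ≥ 0) and an aerial score (count of active airline
routes at the city's main airport). The two scores are essentially
uncorrelated across sites (`connectivity_correlation()`), which is what
lets the two networks be tested separately.

## Genotype processing

`filter_snps()` applies the filters in the only order in which per-call
depth bounds are meaningful: calls with read depth outside
`[min_depth, max_depth]` (defaults 3 and 45 reads — below 3 a diploid
genotype cannot be called reliably; above 45 the call likely sits in a
repetitive or paralogous region) are set missing *first*, and only then is
per-locus missingness tallied. The missingness rule is a strict
"< `max_missing`" (default 0.20): a locus missing in exactly 20% of calls
is dropped. `population_coverage_filter()` is inclusive the other way
("at least" 75% called in *every* population). These boundary readings
follow the filtering conventions of the study design verbatim. The depth
bounds are interpreted per call, not per locus mean: the lower bound
guards individual genotype calls, which is a per-call property.

Missing calls are completed by `impute_missing()` — per-locus modal dosage,
ties to the lower dosage — purely so PCA/DAPC have complete input. This is
deliberately *not* a phasing-based imputation; it preserves the modal
structure of each locus and nothing more, is deterministic, and the
pipeline logs it as a deviation whenever it runs.

## Kinship and pruning

`king_kinship()` implements the KING-robust between-family estimator,

$$\phi = \frac{N_{het,het} - 2N_{opp.hom}}{N_{het}(i) + N_{het}(j)},$$

chosen because it needs no allele-frequency estimates and is the standard
tool for SNP panels with uneven population structure. First-order kin
(full sibs, parent–offspring) have expectation φ = 0.25; the pruning
threshold default 0.177 = 2^−2.5 is the conventional midpoint between the
first- and second-degree expectations. `prune_kin()` then removes, while
any within-population pair exceeds the threshold, the implicated sample
with the most missing data — ties broken toward the lexicographically
later sample id, a rule chosen only to make runs reproducible — and caps
every population at 18 genotypes the same way.

## Balanced subsampling and the statistics

All population-level statistics run over `balanced_subsample()`
replicates: 10 replicates, each drawing with replacement *k* genotypes per
population, *k* defaulting to the minimum population size (five in the
reference design). Equal *k* is what makes F′_ST, heterozygosity and
allele-frequency spectra comparable across populations of unequal sample
size.

Two estimator caveats are worth stating plainly. First, the multi-locus
plug-in G_ST (ratio of sums over loci) carries a positive O(1/n) sampling
bias, so small-*k* subsamples slightly overestimate differentiation; the
estimates remain comparable *across* populations at fixed *k*, which is
what the balanced design uses them for. Second, π is averaged over the
loci present in the matrix — invariant sites do not survive SNP calling —
so it is a relative diversity measure, not an absolute per-base one.

Replicate summaries use the standard t interval, mean ± t₀.₉₇₅,ᵣ₋₁·sd/√r.
A percentile option exists (`method = "percentile"`) for statistics with
visibly skewed replicate distributions. Negative multi-locus G_ST values
(sampling noise around zero differentiation) are reported as computed;
`clamp = TRUE` clamps at zero for display.

The folded allele frequency spectrum (`folded_afs()`) requires the same
number of called diploids at every locus so the minor-allele-frequency
bins {0, 1/2k, …, 0.5} are exact; it refuses ragged input rather than
silently pooling approximate bins (impute or subsample first). Bin 0 is
the monomorphic proportion.

## Cluster detection

`find_clusters()` scans K = 1…K_max with k-means (best of `n_starts`
restarts, default 100 — a desk-scale stand-in for an effectively unlimited
iteration budget) and scores each partition with explicit formulas,
BIC = n·ln(WSS/n) + K·ln(n) and AIC = n·ln(WSS/n) + 2K, reporting raw WSS
so any other criterion can be recomputed. AIC penalises less, so the
AIC-chosen K is never below the BIC-chosen K.

One property of these criteria deserves a warning. Splitting a true
Gaussian cluster multiplies its WSS by roughly (1 − 0.64/d) in *d*
dimensions, independent of scale, so in very low-dimensional score spaces
the likelihood gain from over-splitting always beats the ln(n) penalty and
the scan overfits K. In realistic DAPC score spaces (tens of retained PCs)
the per-axis share is small and the criteria behave; the package's cluster
recovery tests therefore simulate blobs in 30 dimensions, and
`pca_reduce()` retains the smallest number of PCs explaining ≥ 90% of
variance, capped at a third of the sample count.

`dapc_assign()` fits linear discriminant axes to the scanned clusters and
assigns by nearest centroid in discriminant space, with
inverse-squared-distance membership weights: a sample on a centroid gets
probability ~1, a sample equidistant between two centroids ~0.5/0.5.

## The landscape stage

Pairwise predictor matrices are built by `geo_distance_matrix()`
(haversine on a 6371-km sphere; the source coordinates are city-scale, so
a spheroid refinement would be false precision) and
`connectivity_matrix()` (pairwise mean of the two populations' scores,
own score on the diagonal). Connectivity matrices enter PCNM exactly as
built even though a high entry means "well connected", not "far apart":
the ordination only needs a basis spanning the pairwise structure, and the
sign of the association is recovered separately by `directionality()`.

`pcnm_basis()` follows the classical recipe: truncate at the longest
minimum-spanning-tree edge (the smallest threshold keeping the graph
connected), replace larger entries by 4t, Gower-double-centre −D²/2,
eigendecompose, and keep axes with eigenvalue > 1e−8 × the largest.
With a threshold beyond the largest distance this reduces to classical
PCoA and reconstructs Euclidean inputs to machine precision — the
package's reference test for the transform.

`dbrda()` is a from-scratch constrained ordination equivalent to
`capscale`-style dbRDA on the real (positive-eigenvalue) principal
coordinates: negative eigenvalues of non-Euclidean F′_ST matrices are
dropped, matching the default behaviour of the field's reference
implementation, with no Lingoes/Cailliez correction. Conditioning
residualises both response scores and predictors on the condition axes by
least squares. pseudo-F uses df_model = number of predictor axes and
df_residual = n − 1 − df_model − n_condition. The permutation test is
Freedman–Lane: rows of the residualised scores are permuted and
re-residualised on the condition axes, and P = (1 + #{F* ≥ F}) / (1 + n_perm)
— exact by construction, which the test suite confirms by the uniformity
of null P-values. Screening (`select_significant_axes()`) runs one
single-axis dbRDA per spatial eigenvector at the same permutation budget
and keeps axes with P < 0.01; the selected geographic axes condition the
connectivity models.

`directionality()` z-score-normalises the upper-triangle entries of the
response and predictor matrices and reports the OLS slope. Pairwise
entries are not independent, so this is an effect direction, not a test —
significance always comes from the permutation machinery. z-scoring (not
min–max) was chosen so the slope is a standardised coefficient.

## The synthetic-data generator

`simulate_snp_data()` is a statistical emulator, not a demographic model.
Per locus, an ancestral frequency is drawn (uniform MAF on [0.05, 0.5] by
default; `maf_law = "neutral"` gives the 1/x, rare-allele-heavy shape of a
neutral spectrum), and population deviations on the logit scale follow a
multivariate normal with covariance σ²·exp(−d_eff/ρ) plus per-population
extra drift variance on the diagonal, where effective distance
d_eff = d_geo / (1 + γ·c̄) shrinks with pairwise mean connectivity.
Individuals are Binomial(2, p) draws; missingness is uniform at rate *m*;
depths are negative binomial (mean 20, dispersion 8, typical of
reduced-representation coverage). Planted full-sib pairs are produced by
Mendelian segregation from two parents drawn at the population's
frequencies. Defaults mirror the reference design: the bundled site
tables, five genotypes per population, σ = 1, ρ = half the landscape
diameter, γ = 0.

What it emulates: differentiation increasing with
connectivity-modulated distance; drift/bottleneck distortion of the
folded AFS; realistic missingness, depth and kin contamination. What it
does not: linkage, selection, coalescent genealogies, temporal sampling,
or ascertainment of SNPs from read data. Passing tests therefore show the
*statistical machinery* behaves as designed — they cannot certify
behaviour under demographic histories the emulator does not represent.

Two generator notes. The exponential kernel on shrunk (non-metric)
effective distances need not be positive definite; the generator lifts
the spectrum by the smallest sufficient diagonal constant and says so.
And the bottleneck AFS signature — fewer rare alleles, more
intermediate-frequency minor alleles — only emerges from a rare-heavy
ancestral spectrum: under a flat ancestral MAF law, drift pushes mass to
the extremes and the intermediate bins *lose* mass, so bottleneck
emulation should use `maf_law = "neutral"`.

## Statistical properties, verified and not

The acceptance machinery (`scripts/acceptance.R`, and the test suite's
end-to-end file) recomputes at every run: the connectivity-score
regressions on the bundled tables; the landscape model dimensions (the
PCNM axis counts of the geographic and connectivity bases); the two-deme
F′_ST closed form; permutation type-I error over 2,000 null draws;
IBD power and directionality over 200 simulations at σ = 1; the
connectivity power curve over γ ∈ {0, 5, 20} (100 runs each, conditioned
on screened geographic axes); KING recovery of planted full sibs and
their removal by pruning; and BIC cluster-number recovery over 40 blob
simulations. Problem sizes (500-locus simulations, 199 permutations per
simulated test, 9,999 only where a single P-value is the product) are the
package's chosen desk scale: large enough that each property is measured
well inside its tolerance, small enough to run routinely.

## Known limitations

- **Near-saturated connectivity models have little power.** A full PCNM
  basis of a connectivity matrix can use most of the available degrees of
  freedom (e.g. 12 predictor axes for 16 populations), so the null
  expectation of the model R² is already df_model/(n−1) and only very
  concentrated effects move the pseudo-F. In the generator's
  connectivity-driven regime the rejection rate rises with γ but stays
  modest; the directionality slope is the more sensitive indicator of the
  connectivity signal. This is a property of the design itself, worth
  keeping in mind when interpreting non-significant connectivity models
  on real data.
- **Plug-in F′_ST bias.** Small balanced subsamples overestimate absolute
  differentiation (positive O(1/n) bias); comparisons across populations
  at fixed k are unaffected.
- **Imputation is modal, not genealogical**; downstream analyses that
  need phased or probabilistically imputed genotypes should substitute a
  dedicated tool before the PCA stage.
- **π excludes invariant sites** and is comparable only within a marker
  panel.
- **Coordinates are city-level**; distances below ~20 km are below the
  design's spatial resolution.
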
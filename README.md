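# landgen

Landscape population genomics of invasive *Aedes* mosquitoes — a tested,
reusable R pipeline for asking how genome-wide differentiation between
populations is structured by geography and by connectivity to human
transport networks.

`landgen` is aimed at population geneticists working with reduced-
representation SNP panels (e.g. ddRAD) sampled from many field populations,
in study systems where dispersal is a mix of short-range movement and
long-range, human-mediated transport. It re-implements, end to end, the
analysis design used for Indo-Pacific *Aedes aegypti* and *Ae. albopictus*:
filter SNP genotypes, prune close kin, equalise sample sizes by balanced
resampling, estimate differentiation and diversity, detect genetic
clusters, and test landscape hypotheses with constrained ordination.

## What it computes

**Pairwise differentiation.** Hedrick's standardised F′_ST between each
population pair. Per locus, with plug-in alt-allele frequencies
*p_A*, *p_B*:

    H_S = (2 p_A (1 − p_A) + 2 p_B (1 − p_B)) / 2
    H_T = 2 p̄ (1 − p̄),   p̄ = (p_A + p_B) / 2

loci combine as a ratio of sums, G_ST = (ΣH_T − ΣH_S) / ΣH_T, and the
two-deme standardisation F′_ST = G_ST (1 + H̄_S) / (1 − H̄_S) rescales G_ST
by its maximum attainable value given the within-population
heterozygosity, so values are comparable across marker panels of different
diversity.

**Balanced subsampling.** Uneven sample sizes bias comparative statistics,
so every statistic is computed over replicate datasets in which each
population contributes exactly *k* genotypes drawn with replacement
(*k* = the minimum population size), summarised as mean and 95% t-interval.

**Kin pruning.** KING-robust kinship φ for every pair; within each
population, members of first-order pairs (φ ≥ 0.177) are removed greedily
in order of missing data, and populations are capped at 18 genotypes.

**Cluster detection.** PCA reduction of the imputed dosage matrix, k-means
over K = 1…K_max with BIC = n·ln(WSS/n) + K·ln(n) (and AIC), then linear
discriminant assignment of individuals to the chosen clusters.

**Landscape hypothesis tests.** Distance-based redundancy analysis
(dbRDA): the F′_ST matrix is ordinated by principal coordinates and
regressed on PCNM spatial eigenvectors of either the great-circle distance
matrix or a pairwise transport-connectivity matrix (the mean of the two
populations' shipping-density or airline-route scores). Marginal
significance comes from a Freedman–Lane permutation test of the pseudo-F;
conditioning on the geographic axes significant at P < 0.01 separates
connectivity effects from isolation by distance. Because principal
coordinates lose sign, a separate regression of normalised pairwise F′_ST
on the normalised predictor recovers the direction of each association.

**Synthetic data.** A seedable logit-normal spatial generator produces
multi-population diploid SNP matrices whose differentiation grows with
effective distance d_geo / (1 + γ·c̄) — γ sets how strongly pairwise
connectivity c̄ short-circuits geography — with optional extra drift
(bottleneck signatures in the folded allele frequency spectrum), missing
calls, read depths and planted full-sib pairs. Every analysis module is
validated against it.

## Worked example

Simulate an isolation-by-distance study on the bundled 16-population
*Ae. aegypti* landscape (city coordinates plus marine/aerial connectivity
scores), then run the full pipeline from one config:

```r
library(landgen)
config <- list(
  simulate  = list(sites = "aegypti", n_ind = 8, n_loci = 600, sigma = 1,
                   missing_rate = 0.05, seed = 1),
  filter    = list(max_missing = 0.20, min_depth = 3, max_depth = 45,
                   pop_coverage = 0.75),
  subsample = list(n_reps = 10, seed = 2),
  dapc      = list(K_max = 10, n_starts = 50, seed = 3),
  landscape = list(n_perm = 9999, seed = 4)
)
report <- run_pipeline(config)
report
#> landgen run report — stages: simulate -> filter -> prune -> stats -> dapc -> landscape
#> mean pairwise F'ST over 16 populations: 0.2000
#> cluster scan: K(BIC) = 3, K(AIC) = 10
#> landscape dbRDAs:
#>                   term Df SumOfSquares         F      P
#>  Geographical distance  9    0.2442673 2.4601572 0.0001
#>    Marine connectivity 12    0.1725891 0.9993154 0.5973
#>    Aerial connectivity 11    0.1584559 1.0069309 0.5471
report$landscape$directionality
#>        geo     marine     aerial
#>  0.8728978  0.1053195 -0.1296948
```

The report reads as a landscape-genomic result: differentiation is
significantly structured by geographic distance (pseudo-F = 2.46 on the 9
spatial eigenvectors, permutation P = 1e-4) and the association is
positive (slope 0.87 on normalised pairwise values — farther pairs are
more differentiated), while neither transport network explains residual
structure in this geography-only simulation. `mean_fst_to_others(report$fst,
"Taiwan")` style summaries, per-population diversity (`report$diversity`)
and the per-pair subsample confidence intervals (`report$fst_summary`) are
all in the report.

A thin command-line wrapper ships in `inst/cli/landgen.R`
(`Rscript landgen.R run --config study.yaml`).

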
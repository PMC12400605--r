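# adaptscape

Landscape-genomics scans for environmental adaptation in crop germplasm.

`adaptscape` is an R toolkit for asking where, in the genome of a structured
germplasm collection, allele frequencies have diverged more than shared
population history explains — and whether that divergence tracks the
environments the material was traditionally grown in. It targets panels of
largely inbred accessions (selfing crops such as soybean) grouped into
regional populations along an environmental gradient.

## The model

Populations share an ancestry encoded in a P×P allele-frequency covariance
matrix **Ω**: for SNP *j* with ancestral frequency π<sub>j</sub>, the vector
of population frequencies α<sub>j</sub> is modelled as a truncated Gaussian
with mean π<sub>j</sub>**1** and covariance π<sub>j</sub>(1−π<sub>j</sub>)Ω.
On top of this null the package computes, per SNP:

- **XtX** = z′Ω̂⁻¹z with z the standardized frequencies — a SNP-specific
  F<sub>ST</sub> analogue corrected for population structure, approximately
  χ²(P−1) under neutrality. Significance is calibrated empirically with
  pseudo-observed data (PODs): neutral SNPs simulated from the fitted model
  and scored identically; the 99% quantile of the null sample is the
  threshold.
- **Bayes factors (deciban)** for association with a standardized population
  covariate c\* (here: the first two principal components of the growing
  regions' environments). After whitening with Ω̂<sup>−1/2</sup>, the slope
  prior β ~ N(0, τ²) gives the closed form
  BF = (1 + τ²S<sub>xx</sub>)<sup>−1/2</sup>
  exp(½ τ²S<sub>xy</sub>² / (1 + τ²S<sub>xx</sub>)), reported as
  10·log₁₀BF; 10 dB is "strong", 20 dB "decisive" support.

Downstream stages turn scores into biology: significant SNPs closer than
50 kb merge into adaptation-signature regions (±5 kb padding), signature
peaks are screened for long-range linkage disequilibrium networks
(r² above 3× the interchromosomal background, clusters spanning ≥5 Mb or
multiple chromosomes), local haplotypes are clustered into blocks whose
group frequencies are compared along the latitudinal gradient and against
cultivar panels, and regions are annotated with gene models, hypergeometric
GO enrichment and Monte-Carlo gene-set overlap tests.

A built-in synthetic-data generator produces covariance-structured
frequencies, inbred genotypes and mosaic haplotype panels with a truth
ledger, so the entire pipeline is testable without external data.

## Worked example

```r
library(adaptscape)

# 1. environmental covariates: PCA of the six-region climate table
pca <- env_pca(china_region_env())
pca
#> Environmental PCA: 6 regions x 11 variables
#>   variance explained (%): PC1 74.5, PC2 23.1, PC3 1.2, PC4 1.1
#>   scores:
#>      PC1    PC2
#> 1 -3.883  1.763
#> 2 -2.027  0.780
#> ...
#> 6  4.238  0.626
```

The six growing regions order themselves along PC1 from the cool,
short-season north (region 1, score −3.88) to the warm subtropical south
(region 6, score +4.24); PC1 and PC2 together capture 97.6% of the
environmental variance, so two covariates summarize the gradient.

```r
# 2. a synthetic six-population panel with planted signals
cfg <- sim_config(n_snps = 5000, seed = 42)   # defaults: P=6, 50 lines/pop
fr  <- simulate_frequencies(cfg)
gen <- simulate_genotypes(fr)

# 3. the scan: Omega, XtX, POD threshold, Bayes factors
cts <- population_allele_counts(gen, maf_floor = 0.01)
cov <- scan_covariates(pca, k = 2,
                       group_to_region = setNames(as.character(1:6),
                                                  paste0("pop", 1:6)))
fit <- gea_scan(cts, cov, n_pod = 1e5, seed = 43)
fit
#> Genome scan: 4996 SNPs, 6 populations
#>   XtX threshold (POD 99%): 18.034  (62 SNPs pass)
#>   bf_pc1 > 10 dB: 36 SNPs
#>   bf_pc2 > 10 dB: 3 SNPs
```

62 of 4,996 SNPs exceed the POD-calibrated XtX threshold (the generator
planted 1% differentiated loci), and 36 SNPs show strong association with
the first environmental PC. `plot(fit)` draws the Manhattan track.

```r
# 4. adaptation signatures: merge passing SNPs < 50 kb apart, pad ±5 kb
sig <- call_signatures(fit$scores, "xtx", fit$pod,
                       chrom_lengths = setNames(cfg$chrom_layout$length,
                                                cfg$chrom_layout$chrom))
head(as.data.frame(sig), 3)
#>   chrom    start      end peak_pos peak_value n_snps_supporting
#> 1 Chr01 47097273 47107273 47102273   27.77                   1
#> 2 Chr02 33708724 33718724 33713724   26.66                   1
#> 3 Chr03 13887024 13897024 13892024   20.42                   1
```

`run_pipeline()` chains all stages (two overlapping scan scenarios, region
calling, scenario overlap, LD networks, truth-ledger precision/recall) and
writes TSV/BED/JSON outputs; `overlap_sets()`, `build_ld_network()`,
`blocks_in_region()`, `assign_groups()`, `go_enrichment()` and friends
expose each stage individually.

## Limitations

- The Ω estimator is a mean-centered moment estimator: the component of
  covariance shared by all populations is absorbed into the per-SNP
  ancestral frequency and is not separately identifiable. POD calibration
  uses the same centering, so thresholds remain self-consistent.
- Dosage-based r² equals haplotype r² only for inbred material; the LD
  stage is not designed for heterozygous panels.
- The haplotype-block stage uses a transparent greedy Hamming-distance
  clustering, not a re-implementation of any specific block-detection
  heuristic.

See the vignette (`vignettes/landscape-scan.Rmd`) for the full methods
account, parameter guidance and design rationale.
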
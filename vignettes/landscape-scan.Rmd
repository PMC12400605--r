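---
title: "Covariance-aware landscape genomics: models, parameters and design"
author: "adaptscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance-aware landscape genomics: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscape)
```

## The problem

Genebank collections of selfing crops preserve landraces that evolved under
strong local selection along environmental gradients. Grouping accessions
into regional populations and scanning allele frequencies for (i) excess
differentiation between groups and (ii) association with environmental
covariates can localize the genomic regions behind that adaptation. Both
questions are confounded by shared population history: groups that split
recently covary in allele frequency everywhere in the genome, and a scan
that ignores this covariance mistakes drift for selection. `adaptscape`
implements the covariance-corrected version of both scans, together with
the stages that turn per-SNP scores into regions, LD networks, haplotype
comparisons and gene-level annotation.

## The null model and its two statistics

For SNP $j$, let $\pi_j$ be the ancestral allele frequency and
$\alpha_j \in (0,1)^P$ the frequencies in $P$ populations. The working null
is

$$\alpha_j \sim \mathcal{N}\!\big(\pi_j \mathbf{1},\;
  \pi_j(1-\pi_j)\,\Omega\big), \quad \text{truncated to } (0,1)^P ,$$

with $\Omega$ a $P \times P$ covariance matrix capturing shared history.
Observed data are binomial draws from $\alpha_j$ at the per-population
sample sizes (inbred accessions count as single haplotypes: the two alleles
of a fully selfed line are copies, not observations).

**Estimating $\Omega$.** `estimate_omega()` is a moment estimator with
shrinkage. Starting from $\Omega = I$ it alternates (twice by default):
a per-SNP GLS estimate of the ancestral frequency,
$\hat\pi_j = (\mathbf{1}'\Omega^{-1} p_j)/(\mathbf{1}'\Omega^{-1}\mathbf{1})$;
standardization $z_j = (p_j - \hat\pi_j)/\sqrt{\hat\pi_j(1-\hat\pi_j)}$;
and the shrunk sample covariance
$\hat\Omega = (1-\delta)\,J^{-1}\sum_j z_j z_j' + \delta\,
\mathrm{diag}(\cdot)$ with $\delta = 0.05$, which guarantees positive
definiteness. SNPs whose $\hat\pi_j$ leaves $(10^{-3}, 1-10^{-3})$ are
excluded from estimation (they carry no stable standardization) but are
still scored.

An identifiability point worth stating plainly: because $\pi_j$ is
estimated per SNP by a mean, any covariance component shared by *all*
populations is absorbed into $\hat\pi_j$ and cannot appear in
$\hat\Omega$. The estimator is consistent for the *centered* covariance
$A\,\Omega\,A'$ with $A = I - \mathbf{1}w'/(w'\mathbf{1})$, not for
$\Omega$ itself. This costs nothing downstream: XtX, the Bayes factors and
the POD calibration all operate on the same centered scale, so the null is
self-consistent. It does mean $\hat\Omega$ should not be read as an
absolute co-ancestry matrix.

**XtX.** `xtx_scan()` computes $X^tX_j = z_j' \hat\Omega^{-1} z_j$ through
one Cholesky factorization reused across SNPs. With GLS centering the
neutral distribution is approximately $\chi^2(P-1)$ — one degree of freedom
is spent on $\hat\pi_j$.

**POD calibration.** Rather than trusting the asymptotic reference,
`pod_threshold()` simulates pseudo-observed data from the fitted model
(ancestral frequencies resampled from the empirical $\hat\pi$ distribution,
truncated-Gaussian frequencies, binomial sampling at the observed sample
sizes), scores them identically — including re-estimating $\hat\pi$ per POD
SNP — and takes the empirical 99% quantile (type-7 interpolation) of
100,000 null SNPs as the threshold. In the regime where truncation is rare
(drift scale up to a few percent) the threshold sits at the
$\chi^2(P-1)$ 0.99 quantile; the calibration's value is that it also tracks
the finite-sample inflation that binomial noise and truncation introduce.
At sample sizes of 50 per population the empirical threshold runs 15–20%
above the asymptotic value, which is exactly why the empirical route is the
default.

**Association Bayes factors.** `bf_scan()` fits, per SNP, the whitened
linear model $y_j = \beta\, x + e$ with $y_j = \hat\Omega^{-1/2} z_j$,
$x = \hat\Omega^{-1/2} c^*$, $e \sim \mathcal{N}(0, I)$, and the slope
prior $\beta \sim \mathcal{N}(0, \tau^2)$. The marginal-likelihood ratio
against $\beta = 0$ has the closed form

$$\mathrm{BF}_j = (1 + \tau^2 S_{xx})^{-1/2}
  \exp\!\left(\tfrac{1}{2}\,
  \frac{\tau^2 S_{xy}^2}{1 + \tau^2 S_{xx}}\right),$$

reported in deciban ($10\log_{10}$). The default prior scale sets the prior
effect variance to one tenth of the standardized-frequency variance,
$\tau^2 = 0.1\,\overline{\mathrm{diag}(\hat\Omega)}$ — large enough not to
strangle realistic effects, small enough that the Occam penalty
$-5\log_{10}(1+\tau^2 S_{xx})$ keeps null SNPs negative. The closed form is
verified against brute-force numerical integration in the test suite
(100 random instances, relative tolerance $10^{-6}$).

**Covariates.** `env_pca()` runs the standardized PCA of the region ×
environmental-variable table: columns centered and scaled with the
*population* divisor $R$, eigendecomposition of the correlation matrix,
scores on unit-norm eigenvectors. Under this convention eigenvalues sum to
the number of variables and $\frac{1}{R}\sum \mathrm{score}^2_k =
\lambda_k$ exactly — the self-consistency check the shipped six-region
table passes to $10^{-10}$. PCA signs are arbitrary, so orientation is
fixed by named loadings (PC1: vegetative-phase mean temperature positive;
PC2: reproductive-phase accumulated temperature negative), both
configurable. `scan_covariates()` maps populations to their region scores
and standardizes with divisor $P$; `bf_scan()` refuses covariates that are
not standardized, because $\tau$ is calibrated on that scale.

**Environmental variables from monthly climate.**
`derive_region_variables()` aggregates per-cell monthly climate values into
the 11 region variables: latitude plus, for the vegetative and reproductive
windows, day-weighted mean temperature, accumulated temperature, mean
diurnal range, prorated precipitation and mean radiation. Accumulated
temperature is month-resolution: months whose regional mean is at least
15 °C contribute (days inside window) × (monthly mean); colder months
contribute nothing. Partial months are prorated by days. Grids are consumed
as plain data frames of per-cell monthly values; cells are averaged
unweighted (no harvested-area weighting — a deliberate, documented choice;
the pre-built region table is the primary interface).

## From scores to regions and networks

- `call_signatures()`: passing SNPs on a chromosome merge while consecutive
  gaps are strictly below 50 kb (a gap of exactly 50 kb splits); boundaries
  are the outermost passing SNPs ±5 kb, clipped to the chromosome; the peak
  is the maximal passing SNP, ties to the smallest position. Coordinates
  are 1-based inclusive throughout; a true BED export (0-based half-open)
  is provided separately.
- `overlap_sets()`: regions overlap iff they share at least one bp
  (closed-interval convention: [1,10] and [10,20] overlap). The Venn
  "overlap" cell is the smaller side's matched count, so cells sum
  consistently.
- `background_ld()`: mean r² over random interchromosomal pairs
  (MAF ≥ 5%), plus the unlinked-pair reference statistic defined as the
  square of the type-7 95th percentile of $\sqrt{r^2}$. Both are reported
  because the two background definitions differ and the 3× network
  threshold must name its base: the default base is the mean, configurable
  to the percentile statistic.
- `build_ld_network()`: edges where r² exceeds 3× background; clusters are
  connected components (the simplest deterministic rule; a config hook
  exists for community detection). Reported clusters must look like
  long-range structure: an interchromosomal edge or an intra-chromosomal
  span of at least 5 Mb. Raising the threshold can only refine the
  partition — a property the tests assert.
- `permutation_ld_test()`: two-sided permutation t-test on cube-root
  transformed r² (the transform symmetrizes the skewed r² distribution),
  p-value with add-one smoothing, floor $1/(n_{perm}+1)$.
- `ld_prune()`: greedy left-to-right sliding windows of 10 SNPs capped at
  500 kb; in a high-LD pair the lower-MAF member is dropped, ties drop the
  larger position. Deterministic and idempotent.

## Haplotype blocks and group comparisons

`blocks_in_region()` clusters the local haplotypes of an inbred panel by
greedy consensus: take the most frequent remaining haplotype string (ties:
lexicographically smallest), absorb haplotypes within Hamming distance 1,
emit if the cluster holds at least 5% of the panel, pool the rest as
"other". This is a deliberately transparent stand-in for heuristic
block-detection software: all downstream use — per-group frequencies
(`block_frequencies()`, columns sum to 1), latitudinal-gradient
correlations (`gradient_correlation()`, constant rows flagged undefined
rather than NaN), and cultivar representation flags
(`representation_report()`: "underrepresented" when a block dominating the
northern source groups at ≥0.5 falls below 5% in a cultivar panel;
"selected" at ≥0.9 near-fixation) — depends only on block membership, not
on any particular block heuristic. Cultivar haplotypes are projected onto
the source panel's consensus sequences (`assign_to_blocks()`) rather than
re-blocked jointly, matching the direction of the comparison.

## Annotation

`assign_groups()` applies the ancestry-threshold rules: an accession joins
a group at ≥80% ancestry; the northeastern groups subdivide by maturity
rating (MG 000–0 → region 1, I → region 2, II–III → region 3, with region 1
existing only in the scenario-A group), the Yellow-River group maps to
region 4, and the southern group splits by province (middle–lower Yangtze
vs lower subtropical). The rules live in an editable CSV
(`inst/extdata/germplasm_rules.csv`), not in code. Every accession is
either assigned or carries a reason code — a totality property the tests
exercise on randomized inputs.

`genes_in_signatures()` intersects gene models (GFF3 via `ape::read.gff`)
with regions under the shared-bp convention; `go_enrichment()` is the
one-sided hypergeometric upper tail with Benjamini–Hochberg control;
`gene_overlap_mc()` draws random query-sized gene subsets to give the null
expectation of an overlap with a target set (its mean is checked against
the analytic $n\,m/N$ in the tests). `high_impact_variants()` consumes an
effect-annotated VCF (HIGH/MODERATE/LOW/MODIFIER impact classes in an INFO
field) — the package does not predict variant effects itself.

## The synthetic-data generator

`simulate_frequencies()` draws $\pi_j$ uniform on (0.05, 0.95) by default,
then $\alpha_j$ from the Gaussian model above, *clipped* (not resampled) to
$(10^{-4}, 1-10^{-4})$ — clipping keeps the generator fast, deterministic
and in the spirit of the truncated model. Planted signals:

- *differentiated* loci scale the covariance, $\Omega \to \lambda\Omega$
  ($\lambda = 5$ by default for 1% of loci);
- *associated* loci shift frequencies linearly along the standardized
  covariate, $\alpha_j \mathrel{+}= \beta_j c^*$ with
  $\beta_j = s_j\sqrt{\pi_j(1-\pi_j)}$, i.e. $s_j$ is the slope on the
  standardized-frequency scale. Default $|s_j| \sim U(0.5, 1)$, random
  sign, 1% of loci — a spread of effect sizes above the detection-relevant
  floor rather than a single point mass.

Defaults describe the study conditions the package is tested under: six
populations on the real latitudes of the six growing regions,
compound-symmetry $\Omega$ with drift scale 0.05 and correlation 0.25
(moderate regional drift with shared history along the gradient), 50
inbred lines per population, 20,000 SNPs on 20 chromosomes of 50 Mb.

Two honest caveats about the generator. First, clipping attenuates planted
signals: a locus planted at slope $s$ realizes a smaller slope in the
frequencies it actually carries (roughly half the nominal value beyond the
clip region at these defaults), so recovery rates are quoted against the
*realized* slope — the association present in the data — computed by
per-locus regression of standardized frequencies on $c^*$. Second, at
drift scales approaching 1 the truncation dominates and the realized
covariance falls far below the nominal $\Omega$; covariance-recovery
checks therefore run at small drift scales where the truncated model
matches its nominal parameters. Neither caveat affects the scan itself,
whose calibration is empirical.

What the generator does *not* emulate: linkage between scan SNPs
(frequencies are drawn independently per SNP; local LD exists only in the
separate haplotype-panel generator), site-frequency-spectrum realism,
demography beyond the $\Omega$ abstraction, recombination maps, or
missingness. Passing tests therefore demonstrate correctness of the
machinery and calibration under the model's own assumptions — not
performance on real genotype panels.

`simulate_genotypes()` draws inbred dosages ($2\times$Bernoulli at full
selfing; two correlated alleles at partial selfing).
`simulate_haplotype_panel()` builds mosaic haplotypes from founders via a
Markov copy process with per-bp switch hazard $1/\text{block\_len\_mean}$
(switch probability $1-e^{-d/L}$ across a gap of $d$ bp) plus per-site
mutation; founder weights per population set up the latitudinal block
gradient. `write_dataset()` emits VCF + CSV bundles that round-trip
bit-identically through `load_vcf_dosages()`.

## Detection operating characteristics

Two facts about the default conditions, computed by the acceptance script
and worth knowing before interpreting recovery rates:

- A variance-inflation signal of $\lambda$ has XtX distributed roughly
  $\lambda\,\chi^2(P-1)$, so even with perfect calibration the detection
  rate at the 99% null quantile is bounded by
  $P(\chi^2_5 > q_{0.99}(\chi^2_5)/\lambda)$ — about 0.70 at $\lambda = 5$,
  before sampling noise and truncation, and near 0.3 at the default sample
  sizes. Variance-scaling differentiation is intrinsically hard to detect
  at a 1% false-positive budget; the measured rate is reported as is.
- Association detection at 10 dB reaches ≈95% for loci whose realized
  standardized slope is at least 0.5, while neutral loci exceed 10 dB at
  well under 1%.

## Numerical and degenerate-input policy

Quantiles are type-7 throughout. All stochastic operations take explicit
seeds and are byte-reproducible. Frequencies are kept strictly inside
$(10^{-4}, 1-10^{-4})$; ancestral-frequency estimates outside
$(10^{-3}, 1-10^{-3})$ are excluded from $\Omega$ estimation with a
warning. Constant covariates, constant PCA columns, monomorphic SNPs in LD
sets, empty groups, unsorted score tables, internally overlapping region
sets and mismatched run SNP sets are all rejected with named errors rather
than propagated. Tie-breaks are deterministic everywhere (peak: smallest
position; pruning: larger position dropped; block consensus:
lexicographically smallest).

Problem sizes in the test suite are chosen to make each check sharp but
quick: covariance recovery at 40–50k SNPs, POD calibration at 100k PODs
with 20k neutral test SNPs, recovery rates on the full default dataset
(20k SNPs, 300 lines), pipeline integration at 3k SNPs. The full suite and
the acceptance script each run in well under a minute of compute for the
scan stages.

## Known limitations

- $\hat\Omega$ is centered (see above); absolute co-ancestry is not
  identified.
- The closed-form Bayes factor uses a single global $\tau$, not a prior
  grid; rankings are insensitive to $\tau$ over a wide range but the dB
  scale shifts with it.
- Replicate "runs" of the deterministic scan differ only through POD seeds;
  run consolidation exists for protocol parity and for callers that
  introduce genuine run-to-run variation.
- Dosage r² assumes inbred material; no EM haplotype-frequency estimation
  for heterozygous panels.
- The block clustering is order-independent and deterministic but makes no
  claim of equivalence to any specific published block-detection heuristic.
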
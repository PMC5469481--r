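---
title: "Mismatch-rate relatedness inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mismatch-rate relatedness inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinmatch)
```

kinmatch finds duplicate samples and close relatives in SNP genotype
collections by comparing pairs of samples over a fixed panel of fingerprint
SNPs and working directly with two mismatch-rate statistics, without
estimating identity-by-descent (IBD) probabilities or kinship coefficients
per pair. This vignette describes the statistical model, the algorithms, the
tunable parameters, and the choices made where the design was open.

## The fingerprint panel

Genotype datasets produced on different arrays or sequencing assays share no
universal SNP set, and the DNA strand reported for a SNP can differ between
assays. The panel therefore admits only SNPs that are:

* present on most genotyping platforms (default at least 80%),
* bi-allelic with both alleles among A/C/G/T,
* common (minor allele frequency above 0.17), so most samples are
  informative at most SNPs,
* at least 50 kb from any other panel SNP on the same chromosome, so panel
  genotypes are approximately independent (`select_panel()` enforces this
  greedily left-to-right by position),
* non-complementary (no A/T, no G/C): for an A/G SNP, a dataset reporting
  T/C is unambiguously the other strand, so genotypes can be reconciled
  without knowing strand orientation (`harmonize_alleles()`).

The reference panel size is S = 10,000 autosomal SNPs. Each sample's
genotypes over the panel are packed two bits per SNP into paired 64-bit
words (`00` hom-allele1, `01` het, `10` hom-allele2, `11` missing), chosen
so that "missing" is `hi AND lo` and "homozygous" is `NOT lo`; the pairwise
counting kernel then needs only a handful of bitwise operations and
popcounts per 64 SNPs. Pad bits beyond S are set to missing so popcounts
need no length masking.

## The two statistics

For a sample pair compared at the jointly genotyped panel SNPs:

* **AGMR** (all genotype mismatch rate) is the fraction of compared SNPs at
  which the genotypes differ, i.e. with IBS state $I < 2$.
* **HGMR** (homozygous genotype mismatch rate) restricts to SNPs where both
  samples are homozygous and reports the fraction with *different*
  homozygotes: $\mathrm{HGMR} = N_{DO} / (N_{DO} + N_{SO})$.

Under a homogeneous random-mating population in Hardy–Weinberg equilibrium,
the conditional IBS distribution given the IBD state $Z$ at a SNP with
allele frequency $p$ is a simple polynomial table (`p_ibs_given_ibd()`), and
each relationship class has a fixed IBD profile $P(Z=0,1,2)$: identical
(0,0,1), parent-offspring (0,1,0), full siblings (¼,½,¼), second degree
(½,½,0), third degree (¾,¼,0), unrelated (1,0,0).

Averaging over allele frequencies uniform on (0.1, 0.9) — a reasonable
stand-in for a common-SNP panel — gives the expected values the package
uses as anchors (`expectation_table()`): expected AGMR 0 / 0.39 / 0.33 /
0.47 / 0.50 / 0.54 and expected HGMR 0 / 0 / 0.0454 / 0.1040 / 0.1594 /
0.2172 for ID/PO/FS/D2/D3/UN respectively. HGMR is exactly zero for
parent-offspring pairs (a parent and child always share an allele, so
different homozygotes are impossible without genotyping error), which is
what makes HGMR much sharper than IBS0-based statistics for separating full
siblings from second-degree relatives. The predicted standard deviation of
HGMR treats $N_{DO}$ as binomial over S SNPs
(`sd_hgmr()`); at S = 10,000 it is about 0.003–0.007.

All uniform-interval expectations are evaluated with a 16-node
Gauss–Legendre rule on (0.1, 0.9): every integrand is a polynomial of
degree at most four, so the rule is exact (not an approximation), fast, and
free of quadrature-resolution choices.

## Finding identical pairs

Three scanners, in increasing cleverness:

* `naive_scan()` compares every pair over the full panel, $O(n^2 S)$; it is
  the exhaustive reference the other two are tested against.
* `quadratic_scan()` screens each pair on the first m = 64 jointly
  genotyped SNPs (accumulated in 64-SNP words, so "at least 64 non-missing,
  word-aligned" — this can only reduce the miss rate) and abandons the pair
  once k = 8 mismatches are seen. Because the screen needs a *fixed* number
  of comparisons per pair, the scan is $O(n^2)$ in sample count. Survivors
  are verified over the full panel, so the reported set has no false
  positives by construction. For a true duplicate pair with per-genotype
  error rate $\varepsilon$, the probability of being screened out is the
  binomial tail $P(X \ge k)$, $X \sim \mathrm{Bin}(m, \varepsilon)$
  (`quadratic_fn_rate()`); at $\varepsilon = 1\%$ this is below $10^{-5}$,
  and an unrelated pair survives the screen with probability below
  $10^{-8}$ (`quadratic_fp_rate()`).
* `subquadratic_scan()` sorts: each round draws m = 20 SNPs from the
  low-missingness pool, codes each sample's genotypes at them into one
  integer, sorts the keys ($O(n \log n)$), and takes equal adjacent keys as
  putative duplicates, verified over the full panel. A pair is found in a
  round only if all m drawn SNPs are non-missing and concordant, so the
  per-round sensitivity is $e^{-m\delta}$ for per-SNP missing-or-mismatch
  rate $\delta$, and the loop stops after c = 10 consecutive rounds without
  a new confirmed pair. It is the right tool only when missingness is low.

Reported identical pairs use an AGMR cutoff of 0.20 — far above the
error-driven AGMR of true duplicates (typically below 0.05) and far below
the full-sibling expectation of 0.33.

Open details resolved here: the sort-key pool is the lowest-missing-rate
20% of panel SNPs (at least 10m SNPs), keeping missing-key exclusions rare
while preserving round-to-round diversity; samples with a missing genotype
among the drawn SNPs get a sentinel key and sit out that round; equal-key
runs longer than two yield all within-run pairs so duplicate clusters are
found whole; the scan seed is an explicit argument (default 0) so runs are
reproducible, and unions over reruns can only grow the result set.

## Classifying close relationships

Identical pairs are removed by the AGMR cutoff and unrelated or remotely
related pairs by an HGMR cutoff; the remaining pairs are assigned one of
PO/FS/D2/D3 by maximum posterior probability under per-class densities of
the joint (HGMR, AGMR) value (`classify_pairs()`):

* FS, D2, D3: a bivariate normal with correlation $\rho$ (mismatch counts
  are sums over many near-independent SNPs, so the statistics are
  approximately jointly normal);
* PO: HGMR is *not* normal — it is zero but for genotyping error — so it
  gets an exponential density $k e^{-kx}$, independent of a normal AGMR.

The default parameters (`default_model()`) are empirical values estimated
from a very large reference collection of submitter-reported relative
pairs; means are stored as fractions (e.g. FS: HGMR 0.0486 ± 0.0102, AGMR
0.3359 ± 0.0232, ρ = 0.784). `fit_model()` re-estimates them from labelled
pairs of the dataset at hand, which is preferable whenever a few dozen
labelled pairs per class exist, because real cohorts show broader spreads
than the homogeneous-population prediction. Equal class priors are the
default; posteriors are reported so downstream QC can threshold on
confidence.

Choices the references leave open, fixed here:

* `hgmr_unrelated_cutoff` defaults to the midpoint of the analytic D3 and
  UN expectations (≈ 0.188) — symmetric exclusion between the most distant
  modelled class and unrelated pairs. It is a parameter, not dogma: at
  small panel sizes the HGMR spread grows and the cutoff should grow with
  it.
* The exponential rate defaults to $k = 1/0.0004 = 2500$ (the reciprocal of
  the reference PO mean HGMR); accuracy is insensitive to k over a wide
  range because PO pairs are far from every other class in HGMR. Fitted
  k is the moment estimate $1/\bar{x}$, capped at $10^5$ when a cohort has
  all-zero PO HGMRs (a degenerate but possible error-free input).
* Posterior ties break toward the closer relationship (PO > FS > D2 > D3);
  a probability-zero event in the continuous model, but observed rates are
  rational numbers.
* Pairs whose four class densities all underflow (far from every class)
  are labelled UN rather than forced into the nearest class.
* `decision_boundaries()` works in log-density space, so boundary contours
  are exact even in far tails where the densities underflow.

## Pedigree concordance QC

`ped_graph()` validates a PED-style table (cycles, duplicate IDs, missing
parents), `ped_kinship()` implements the standard kinship recursion
(founders unrelated and non-inbred), and `expected_relationship()` maps
structure to class: sample map or MZ annotation → ID; parent edge → PO;
both parents shared → FS; otherwise φ = 1/8 → D2 and φ = 1/16 → D3.
Compound relationships (e.g. double first cousins) are classified by total
kinship; inbreeding is out of scope throughout. MZ twins must be annotated
explicitly because PED columns cannot express them. `qc_report()` then
reconciles genotype predictions with the reported pedigree into five
categories (confirmed, type_mismatch, unreported_related,
reported_but_unrelated, duplicate_unreported) and flags reported-identical
pairs whose AGMR sits near the full-sibling expectation (probably DZ twins
reported as MZ) or near the unrelated expectation (probable mix-up).

## The simulator, and what passing its tests does and does not show

`simulate_cohort()` generates founders under HWE at per-SNP frequencies
drawn once from the frequency model (default uniform 0.1–0.9), creates
offspring by Mendelian gene dropping independently across SNPs, plants
duplicates, and applies genotyping error (replace with one of the other two
genotypes, uniformly), random missingness, and optional per-dataset
platform masks. Duplicates copy the *observed* genotypes of their source
and then receive fresh error, so a planted duplicate pair's realized
mismatch rate equals `error_rate` exactly — the same ε that parameterizes
the screen error formulas, which keeps simulation and theory aligned.

The simulator deliberately embodies the same assumptions as the analytic
model: one homogeneous random-mating population, independent SNPs, no LD,
no population structure or admixture, errors independent across genotypes.
Tests passing on its output therefore validate the *implementation* of the
method and its internal consistency with the closed forms; they do not
demonstrate robustness to stratified populations, correlated genotyping
artifacts, or assay batch effects, which real data have. The empirical
reference parameters in `default_model()` are broader than the
homogeneous-model predictions for exactly that reason.

## Problem sizes and numerical conventions

The shipped tests and validation runs use sizes chosen to exercise every
regime while remaining quick on a laptop: kernel checks on 10,000-SNP
fixtures; scanner-equivalence runs at 1,000 samples × 10,000 SNPs with
ε = 0.005 and 0.5% missingness (well inside the regime where all three
scanners provably agree); per-round sensitivity at 500 planted duplicate
pairs × 8 rounds for δ ∈ {0.005, 0.01, 0.02}; classifier end-to-end runs on
30 ten-member first-cousin-template families (300 samples, 930 labelled
pairs covering PO/FS/D2/D3) at S = 10,000. Monte-Carlo assertions use 3-standard-error bands around the
closed forms (plus the explicit $(1-\delta)^m$ vs $e^{-m\delta}$ gap where
the Poisson approximation is the stated reference).

Conventions: rates are fractions internally and in every function argument
(reports may print percentages); genotype codes count copies of allele 2;
coordinates are 1-based (PLINK convention); HGMR with an empty denominator
is `NA` and such pairs are never classified as related; pairs with fewer
than 64 jointly genotyped SNPs are flagged incomparable; monomorphic or
"0"-allele dataset columns are treated as incompatible with the panel and
encoded missing; marker matching across datasets prefers rsID with a
chromosome+position fallback, because positions shift between genome
assemblies.

## Known limitations

* No population-structure handling: in admixed cohorts the unrelated HGMR
  distribution shifts and broadens, and cutoffs calibrated on a homogeneous
  model will misbehave. Fit the model on labelled pairs from the cohort
  itself where possible.
* Relationships beyond third degree are all "unrelated" by design.
* Inbreeding violates both the IBD profiles and the kinship-to-class map.
* The sub-quadratic scanner loses sensitivity quickly as missingness rises;
  the quadratic scanner is the robust default.
* HGMR-based classification needs enough jointly homozygous SNPs; panels
  far smaller than 10,000 SNPs widen every distribution (the `S` argument
  of `sd_hgmr()` quantifies this).
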
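---
title: "Methods: covariate-adjusted two-locus epistasis scans for quantitative traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covariate-adjusted two-locus epistasis scans for quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-locus genome-wide association scans miss genetic signal that only
appears when two loci act jointly. For a continuous outcome such as the
cerebrospinal-fluid concentration of hyperphosphorylated tau — a biomarker
of Alzheimer's-type neurodegeneration — an exhaustive two-locus scan asks,
for every unordered pair of SNPs, whether the product of the two additive
genotype codes explains phenotypic variance beyond the two main effects
and the clinical covariates. `epiqt` implements that scan, the quality
control around it, the variance bookkeeping used to interpret hits, and
the gene-level annotation of significant pairs, together with a synthetic
cohort generator so every stage can be exercised and calibrated without
access to restricted patient-level data.

## The statistical model

For subjects $i = 1, \dots, n$ with additive genotype codes
$g_{1}, g_{2} \in \{0, 1, 2\}$ (copies of the A1 allele) the two nested
models are

$$y_i = \alpha_0 + \alpha_1 g_{1i} + \alpha_2 g_{2i}
      + \mathbf{c}_i^\top \boldsymbol\gamma + \varepsilon_i,$$

$$y_i = \alpha_0 + \alpha_1 g_{1i} + \alpha_2 g_{2i}
      + \alpha_{12}\, g_{1i} g_{2i}
      + \mathbf{c}_i^\top \boldsymbol\gamma + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2),$$

where $\mathbf{c}_i$ holds age in years, a 0/1 gender code, and four
indicator columns for clinical diagnostic status (CN, SMC, EMCI, LMCI, AD;
CN is the reference). The full design has $k = 10$ columns. The
interaction is tested by the nested-model F statistic

$$F = \frac{\mathrm{RSS}_{\text{reduced}} - \mathrm{RSS}_{\text{full}}}
           {\mathrm{RSS}_{\text{full}} / (n_{\text{used}} - 10)}
  \sim F(1,\, n_{\text{used}} - 10) \text{ under } H_0\!: \alpha_{12} = 0,$$

which with a single added term equals the squared t statistic of
$\hat\alpha_{12}$. Each pair is fit on its own complete-case subset
($n_{\text{used}}$ subjects with both genotypes, phenotype and covariates
observed); no imputation is performed, so results are exactly
reproducible from the input files.

Diagnostic status is encoded as unordered indicators rather than an
ordinal score: the five groups are categories whose phenotype means need
not be monotone, and indicator coding never understates the covariate
contribution that the interaction must beat. This choice is recorded in
the run manifest.

## The blocked scan

All $m(m-1)/2$ pairs are evaluated exactly once. The implementation
pre-residualises the phenotype and every genotype column against the
covariate block (one QR factorisation of the $n \times 7$ intercept +
covariate matrix), caches the Gram matrix of the residualised genotypes,
and then sweeps blocks of product columns with dense matrix algebra. By
the Frisch–Waugh–Lovell theorem the resulting F statistic is identical to
refitting both models from scratch per pair; the test suite verifies
agreement with an explicit normal-equation solver at $10^{-8}$ relative
tolerance on F over a complete 60-SNP panel. `block_size` only bounds the
size of temporary matrices — it never changes any reported number.

Three situations leave the fast path. Pairs involving a genotype column
with missing entries are refit singly so the complete-case subset is
honoured. Pairs whose two-SNP residual Gram matrix is near-singular
(relative determinant below $10^{-12}$), or whose residualised product
column has squared norm below $10^{-10}$ of the raw product's, are refit
with pivoted QR and flagged: a collinear interaction column (a constant
SNP, perfect LD) yields `rank_deficient` with $p = 1$ by convention, and
complete-case subsets of ten or fewer subjects yield `insufficient_df`
with `NA` statistics. Flagged pairs are reported, never silently dropped.

The significance threshold is configurable; the default is Bonferroni at
family-wise level 0.05 over the number of tests actually performed. The
threshold used, the encoding choices, and all counts go into the run
manifest.

## Variance partition

For reported pairs the phenotypic variance is decomposed hierarchically
with three nested fits on the pair's complete-case subset: covariates
only; plus the two main effects; plus the interaction. Each $R^2$ is
$1 - \mathrm{RSS}/\mathrm{TSS}$ and the two increments are successive
differences, so the components sum to the full-model $R^2$ identically
(asserted to $10^{-10}$). Plain rather than adjusted $R^2$ is used — at
several hundred subjects and one to two added terms the difference is in
the fourth decimal, and unadjusted $R^2$ matches the convention of the
general-linear-model software these tables are usually produced with. The
scan and the partition use the same design, so
$F = \Delta R^2_{\text{int}} \big/ \frac{1 - R^2_{\text{full}}}{n - 10}$
holds exactly; the suite asserts it at $10^{-8}$ relative.

Top tables are ranked by $\Delta R^2_{\text{int}}$ descending with ties
broken by ascending interaction p-value.

## Quality control

Variant filters run in a fixed order with a per-stage audit trail:
chromosomes 1–22 only, SNP call rate $\ge 0.95$, minor allele frequency
$\ge 0.05$, and Hardy–Weinberg exact p $\ge 10^{-6}$; all thresholds are
inclusive. Subject filters remove an optional external exclusion list
(e.g. ancestry outliers identified by dedicated tools, which are out of
scope here), subjects with call rate $< 0.90$, and subjects lacking a
phenotype or any covariate. Variant statistics are computed on whatever
subject set is present, so the intended order is subjects first, variants
second — the pipeline does exactly that.

The HWE test is the plain (not mid-p) two-sided exact test conditional on
allele counts, computed by the standard outward recurrence from the modal
heterozygote count. Configurations mathematically tied with the observed
table can differ in their last floating-point bits, so tail membership
uses a $1 + 10^{-10}$ relative guard; the suite checks exact agreement
with an independent log-factorial enumeration for every genotype table
with up to 50 subjects.

Phenotype handling assumes one baseline record per subject (duplicates
are an error, not averaged) and offers three transforms: natural log
(default — CSF concentrations are positive and right-skewed), rank-based
inverse normal, or none. No outlier exclusion is applied: a
"normality" phenotype-QC rule without a stated algorithm is better served
by an explicit, recorded transform than by silent trimming.

## The synthetic cohort generator

The generator is the package's stand-in for access-restricted
patient-level cohorts and is fixed at one set of reference conditions:
860 subjects by default; diagnostic
groups drawn with probabilities (201, 84, 251, 209, 115)/860; age uniform
on 55–90 years; gender Bernoulli(0.5); covariates jointly explaining 9.3%
of phenotype variance; MAF uniform on [0.05, 0.5] with genotypes drawn as
two independent allele copies, hence exact HWE proportions. The 9.3%
covariate share is split age/gender/cds as 0.35/0.05/0.60 — diagnosis
dominates a tau biomarker, age matters, gender is minor; the split is a
modelling choice the generator records, not an estimate.

Planted effects are scaled analytically. A centred genotype with allele
frequency $p$ has variance $2p(1-p)$; the centred product of two
independent HWE genotypes, $(g_1 - 2p_1)(g_2 - 2p_2)$, has variance
$4 p_1 (1-p_1)\, p_2 (1-p_2)$ and is uncorrelated with both main-effect
columns, so a target variance fraction $f$ yields the coefficient
$\sqrt{f / \mathrm{var}}$ and the hierarchical $\Delta R^2_{\text{int}}$
converges to $f$. Gaussian noise absorbs the remaining variance so the
latent phenotype has unit variance; the reported concentration is
$\exp(\log 25 + 0.35 \cdot \text{latent})$ pg/mL, which the default log
transform maps back to an exactly linear model. All coefficients and
component variances are stored as a truth record.

What the generator does *not* emulate: realistic allele-frequency spectra,
population structure, genotyping batch effects, and LD beyond an optional
within-block autoregressive mode used to exercise rank-deficiency
handling. Passing tests therefore demonstrate the statistical machinery —
calibration under the null, unbiased recovery of planted effects at a
realistic cohort scale — not robustness to confounding that real cohorts
carry.

A small-sample note used by the recovery checks: the raw
$\Delta R^2$ of one added regressor has expectation
$f + (1 - R^2_{\text{full}})/(n - k)$ under the model — about 0.001 at
$n = 860$ — so parameter-recovery comparisons subtract that one-degree
chance contribution before comparing with the planted fraction.

## Gene mapping and network overlap

A SNP inside one or more gene bodies (internal coordinates are 1-based
inclusive; BED input is converted at the boundary, in one place) maps to
all containing genes; otherwise it maps to the nearest gene whose
boundary lies within 100 kb, inclusive at exactly 100,000 bp, with
distance ties kept. An `all_in_window` mode returns every gene in range
instead — both readings of a "±100 kb offset" rule are defensible, so both
are provided and the choice is a recorded parameter. Significant SNP
pairs expand to the cross-product of their gene lists; gene pairs are
unordered and deduplicated with supporting SNP pairs accumulated. Pairs
whose SNPs map only to one common gene are reported as intragenic, and
pairs with an unmapped SNP are listed separately; neither enters the
gene-pair counts. Disease-relatedness is a user-supplied gene list
(three-way categorisation: both / one / neither member in the list), and
network support is a user-supplied undirected edge list matched
case-sensitively after whitespace trimming — web enrichment services are
deliberately out of scope so runs are reproducible offline.

## Problem sizes and numerical choices

The shipped tests run the oracle comparison on a 200-subject × 60-SNP
panel (1,770 pairs), null calibration on 10,000 disjoint pairs at
$n = 500$, and parameter recovery on 200 replicates of an 860-subject,
102-SNP panel with the planted pair at 5.6% interaction variance — sizes
chosen so the full suite exercises every code path at the reference subject
scale while completing on a laptop. Exact PLINK round-trips, inclusive QC
boundaries, and the 100 kb mapping boundary are asserted bitwise or at
printed precision. Degenerate inputs (zero-variance phenotype, empty
panels, monomorphic SNPs, all-missing columns) raise typed errors or
flags rather than propagating NaNs.

## Known limitations

The scan is dense and single-machine: every pair is evaluated, so runtime
grows quadratically in the number of SNPs, and genome-scale panels
(hundreds of thousands of SNPs) need the blocked computation distributed
or accelerated, which is out of scope. Logistic (case-control) epistasis,
three-way interactions, LD pruning, imputation, relatedness checks and
ancestry estimation are not provided. The gene-pair categorisation is
only as good as the supplied gene list and edge list; no enrichment
statistics are computed.
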
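---
title: "Extra-binomial association testing for pooled case-control sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extra-binomial association testing for pooled case-control sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooldisp)
library(dplyr)
```

## The problem

Pooled DNA sequencing mixes the DNA of many subjects into a handful of
libraries before sequencing, so a case-control study observes only per-pool
allele read counts `y_ij` out of depths `R_ij` (SNP `i`, pool `j`), never
individual genotypes. Testing whether the major-allele frequency differs
between case and control chromosomes from such counts is harder than it
looks, because the counts are *over-dispersed* relative to a binomial in
`R_ij`:

* a pool physically contains only `s` distinct chromosomes (`2 x` persons
  per pool), so no amount of sequencing can make a pool worth more than `s`
  binomial observations;
* DNA capture, library construction and PCR contribute very unevenly across
  persons and pools, so the pool-level allele frequency itself varies from
  pool to pool far beyond the `1/s` chromosome-sampling floor;
* base-calling errors add further noise, and correcting their expectation
  adds variance of its own.

A test that prices a pool at its read depth — the binomial model behind
Fisher's exact test on estimated chromosome counts — therefore understates
the variance and rejects far too often.

## The three tests

**Fisher baseline** ([fisher_test()]). Within each group the major-allele
frequency is the unweighted mean of per-pool read frequencies over valid
pools; frequencies are converted to allele counts out of
`s x (number of valid pools)` chromosomes (rounded, ties to even) and the
2x2 allele-by-group table is tested with a two-sided Fisher's exact test.
Before this test only, pools must pass a chromosome-coverage filter: pool
`j` is used only if its depth gives more than 80% probability of covering
at least `k = 80` of the `s` chromosomes, computed exactly from the
occupancy distribution of `R` uniform reads on `s` chromosomes
([coverage_probability()], a dynamic program over reads).

**EB1** ([eb1_test()]), the classical quasi-likelihood comparator. The
pool-level frequency is a latent variable with mean `p_i` and variance
`phi_i p_i (1 - p_i)`, giving `Var(y_ij) = R p (1-p) [1 + (R-1) phi_i]`.
The logistic model (intercept + case/control factor) is fitted by
iteratively re-weighted least squares with weights `1/[1 + phi (R-1)]`,
`phi_i` updated by the moment equation that matches the weighted Pearson
chi-square to its leverage-corrected expectation and floored at zero
(initialised at 0, tolerance 1e-8, at most 50 iterations). The test
statistic is the increase in the weighted Pearson chi-square when the
case-control factor is deleted, referred to chi-square with 1 df. Its
weakness is that `phi_i` must be estimated per SNP from only `n` pools
(20 here), which is hopeless for rare variants; SNPs with zero minor
counts in either group are excluded outright.

**EB2** ([fit_dispersion()] + [eb2_test()]), the method this package is
built around. Instead of one dispersion per SNP, two *global* parameters
`a` and `b` shared by all SNPs scale the variance:

    Var(y_ij) = R_ij p_i (1 - p_i) [ a + b (R_ij - 1) / s ].

Pure two-stage sampling (s chromosomes into the pool, then reads off those
chromosomes) gives `a = b = 1`; experimental noise moves both. Writing
`R*_ij = R_ij / [a + b (R_ij - 1)/s]` turns the law back into a binomial
variance with the *adjusted depth* `R*` — the number of ideal binomial
observations the pool is actually worth. For each SNP the normalized
dispersion statistic

    z_i = sum_j R_ij (p_ij - p_ig(j))^2 / [ p_i (1 - p_i) (n_i - 2) ]

(deviations of pool frequencies about their depth-weighted group means,
overall pooled frequency `p_i` in the denominator, `n_i - 2` residual
degrees of freedom after the two group means) has expectation `a + b x_i`,
where the depth regressor `x_i` reduces to `(R - 1)/s` when all pools have
equal depth; in general the package uses the exact form
`x_i = [(sum_j R_ij - sum_g sum_{j in g} R_ij^2 / R_g+) / (n_i - 2) - 1]/s`,
which keeps the regression unbiased under arbitrary depth profiles.
Ordinary least squares of `z_i` on `x_i` across all usable SNPs (pooled
frequency strictly inside (0,1), at least 4 informative pools) yields `a`
as intercept and `b` as slope. The test then sums adjusted allele counts
`p_ij R*_ij` and `(1 - p_ij) R*_ij` over case and control pools into a 2x2
table and applies a Pearson chi-square with 1 df, no continuity
correction — the entries are model-adjusted quantities, not raw counts, so
fractional values are expected and correct.

## Pre-test filtering

`filter_pipeline()` reproduces the screening a pooled study applies before
any testing:

1. **Minimum depth** (default 8): summed depth per group must reach the
   threshold (a per-pool mode is available).
2. **MAF partition** (default threshold 0.05, boundary counted as common):
   common variants are accepted as real without further screening.
3. **Random-error screen** for the rare remainder: under a pure-error null
   the minor reads scatter across pools in proportion to depth, whereas a
   genuine rare variant concentrates in the few carrier pools. The Pearson
   statistic of minor counts against depth-proportional expectation is
   referred either to a Monte-Carlo multinomial null (default, 10,000
   resamples, adaptive early stop) or to its asymptotic chi-square tail.
   A SNP is called true if its p-value beats `0.05 / n_tests` (Bonferroni
   over the rare candidates screened) *and* some pool has more than two
   minor reads.

The Monte-Carlo tail has granularity `1/(n_perm + 1)`; once the candidate
count approaches `alpha x n_perm` no SNP can clear Bonferroni, so the
function warns and the large simulation study uses the chi-square tail,
which is accurate in that study's read-count regime (hundreds of minor
reads across 20 pools) and has no floor.

## Sequencing-error correction

`estimate_error_rates()` estimates one error rate per ordered base
substitution (12 classes) as alt-reads over total reads summed across all
positions *not* called as SNPs; `correct_counts()` inverts the expectation
`E[y_obs] = y (1 - e_Mm) + (R - y) e_mM` to give the unbiased corrected
count `y* = (y_obs - R e_mM) / (1 - e_Mm - e_mM)`, clamped to `[0, R]` and
left real-valued (the chi-square machinery accepts fractional counts;
Fisher works on rounded chromosome counts anyway). Rates below `1e-8` are
treated as zero. The correction is unbiased by construction but inflates
variance by `1/(1 - e_Mm - e_mM)^2` — a price EB2 absorbs into its fitted
variance law while Fisher's fixed binomial assumption cannot. Because
estimated rates are themselves uncertain, `correct_counts()` takes a
`rate_scale` multiplier for sensitivity analysis: re-running with the rates
halved and doubled shows whether findings survive misspecification of the
error model.

## The simulator

`simulate_dataset()` generates the package's study conditions: 500 cases
and 500 controls in 20 pools of 50 (so `s = 100`), three truth classes
(null with MAF 0, neutral with equal case/control MAF over a grid from
0.005 to 0.5, disease with case MAF derived from control MAF under a
multiplicative per-allele relative risk, default 1.5 — the exact-odds form
`q rr / (q rr + 1 - q)`, whose implied allele odds ratio is exactly `rr`),
and a symmetric per-read error rate from 0 to 5%.

Per SNP, pool and person: genotype `~ Bin(2, q_group)`; read depth from a
gamma, rounded half-up, zeros allowed; minor reads `~ Bin(depth, g/2)`;
each read flips allele with the error probability. Pool counts are
per-person sums. The per-person depth gamma has shape 0.1265 and scale
`7.709 x` nominal coverage, calibrated so that at the default 40x the
per-person depth has mean 39 and variance 12,026. This distribution is
extremely right-skewed — about half the persons contribute no reads at a
given position, and pool depths (mean 1950) vary with a CV of ~40% — which
is deliberate: uneven capture and amplification are what create the large
between-pool frequency variance seen in real pooled 454 data, where depth
variance is extreme especially at low MAF. Under these conditions a
2000-read pool carries the information of roughly 11 chromosomes, and a
variance-blind binomial analysis is not mildly but grossly anti-
conservative. The two-stage person-level structure (genotypes, then
person-weighted reads) is what produces both the `1/s` floor and the
depth-linked extra variance that the EB2 law `a + b (R-1)/s` captures.

What the generator does *not* emulate: linkage disequilibrium between SNPs
(all SNPs independent), allele-specific PCR amplification bias,
position- or quality-dependent error rates, and indels or multi-allelic
sites. Passing tests on this generator therefore says nothing about
robustness to those phenomena on real data.

## The simulation study

`run_simulation_study()` runs the *blinded* pipeline per replicate exactly
as it would run on real data: orient, depth filter, MAF partition, error
screen (Bonferroni denominator = number of rare candidates in that
replicate), error-rate estimation from the screened-out positions, count
correction of survivors, then the requested tests (coverage filter on the
Fisher path only). Rejection rates among neutral SNPs estimate Type-1
error and among disease SNPs estimate power, per method x error rate x
control-MAF bin with binomial standard errors.

Under the default conditions at `alpha = 0.05`, Fisher's observed Type-1
error reaches about nine times the nominal level (worst across the MAF
grid and error rates 0-5%), while EB2 stays near the level and is
conservative for rare SNPs (MAF below ~0.02), where its adjusted table
holds only a handful of effective counts. EB2 does retain a mild residual
inflation (roughly 1.2-1.8x in the worst common-MAF bins): replacing the
fitted `(a, b)` with oracle values does not remove it, so it is not an
estimation artifact but a property of applying a 1-df chi-square to sums
of heavy-tailed pool contributions worth ~11 effective chromosomes each.
It shrinks as pools or coverage grow.

### Problem sizes

The package's evaluation runs the study at 201 replicates (67 per error
rate in {0, 0.01, 0.05}) of 1,860-SNP datasets (100 null, 1,600 neutral —
200 per MAF bin — and 160 disease SNPs). Replicate *size* is kept near the
full design's 2,100 SNPs on purpose: the dispersion regression is the one
component that degrades when a dataset carries too few SNPs (the per-SNP
statistic `z_i` is heavy-tailed, so fits on a few hundred SNPs are noisy
and mildly biased), and scaling down the replicate count instead preserves
the method's operating characteristics. The error screen inside the study
uses the chi-square tail for the granularity reason above.

## Q-Q diagnostics

`qq_summary()` converts p-values to observed chi-square(1) quantiles via
the inverse survival function (`pvalues_to_chisq()`; `p = 1 -> 0`;
underflowed zeros are capped at the smallest positive double and counted),
sorts them against expected quantiles at the deterministic plotting
positions `k/(m+1)`, and reports the regression-through-the-origin slope —
the genomic-inflation convention, equal to 1 for calibrated p-values and
scale-equivariant under inflation of the underlying statistics. The 95%
concentration band is pointwise, from Beta(k, m+1-k) order-statistic
quantiles of uniforms mapped to the chi-square scale; it is not a
simultaneous band, so ~5% of points fall outside even under the null.
Deterministic plotting positions are used instead of drawing random
expected quantiles, which would make the diagnostic itself noisy.

## Numerical choices and degenerate inputs

* Major-allele orientation: the allele with the larger total read count
  over all pools; exact ties go to the reference allele, making
  [orient_major_allele()] deterministic and idempotent. Only bi-allelic
  SNVs are accepted; anything else is rejected at validation.
* A missing pool at a SNP is encoded as depth 0 and kept in the table;
  depth-0 pools are dropped inside each test, never silently from the data.
* Fisher's chromosome counts round ties-to-even; a SNP with no valid pool
  in one group is `excluded` (status column), as is an EB1 SNP with zero
  minor counts in a group. Non-convergent EB1 fits are flagged
  `degenerate` with their iteration count.
* EB1's Pearson chi-square is not the quantity its IRLS maximizes, so
  deleting the case-control factor can *lower* it by a small amount in
  near-null data; the reported statistic floors at zero (p = 1).
* A fitted variance law can be non-positive at unusual depths (e.g. a
  negative slope from a noisy fit): such pools are dropped for that SNP
  with a message, and a SNP losing an entire group is excluded.
* The EB2 chi-square uses no Yates correction: the adjusted table is a
  model quantity, not a discrete count table.
* Error correction clamps to `[0, depth]` and flags clamped pools; rates
  below 1e-8 are zero.
* All simulation randomness flows from one integer seed; study replicates
  use arithmetic substreams of it so each replicate is independently
  reproducible.

## Limitations

* The global variance law is linear in depth with one intercept and one
  slope for all SNPs. Additive error noise scales like `1/[p(1-p)]` on the
  dispersion-statistic scale, so under high error rates the single law
  slightly over-corrects rare SNPs (conservative) and under-corrects
  common ones; this is intrinsic to the two-parameter design.
* The Fisher baseline is included for comparison, not recommendation; its
  calibration depends entirely on pools being worth their nominal `s`
  chromosomes.
* EB1's per-SNP dispersion is unidentifiable for rare variants with 20
  pools; its exclusion rule removes exactly the SNPs a rare-variant study
  cares most about.
* p-values are reported raw, matching the diagnostic-driven analysis
  style; `add_bh()` appends a Benjamini-Hochberg column when per-SNP
  decisions are needed.
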
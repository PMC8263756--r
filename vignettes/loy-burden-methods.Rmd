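---
title: "Methods: rare-variant burden analysis of mosaic loss of Y"
author: "loyburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant burden analysis of mosaic loss of Y}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loyburden)
```

# The phenotype: a composite quantitative LOY score

Mosaic loss of the Y chromosome (LOY) is the most common somatic mosaicism
in men: a clone of blood cells lacking Y expands with age. Two array-based
proxies are in wide use — the median log2 R ratio of probes in the
male-specific region of Y (mLRR-Y; more negative means more loss) and a
dichotomous call from allelic imbalance in the pseudo-autosomal region
(PAR-LOY), accompanied by an estimate of the affected cell fraction
(AF-LOY). The two derive from non-overlapping regions of Y, so each carries
information the other lacks. The composite score used throughout this
package is

$$\mathrm{PARLOYq} = \mathrm{PARLOY} + 3\,\mathrm{AFLOY} - 3\,\mathrm{mLRRY},$$

cropped to $[0,2]$ (`compute_par_loyq()`). The weights $\pm 3$ are fixed
constants of the score's definition, not tunable parameters; the intent is
to up-weight men whose clone occupies a larger cell fraction. Missing
inputs propagate to a missing score. `compare_measures()` quantifies the
power gain of one measure over another by the $t$ statistics of
univariable regressions on age and ever-smoking (measures standardised to
unit variance first, so statistics are scale-free) and, at supplied variant
dosages, by the median per-variant chi-square improvement.

# Quality control of exome genotypes

Genotype-level QC computes the allelic balance of each heterozygous call
at an on-target bi-allelic site, $\mathrm{ABratio} = AD_{alt} /
(AD_{ref} + AD_{alt})$, and sets the call to missing when
$\mathrm{ABratio} \le 0.25$ or $\ge 0.8$ (boundaries inclusive). Site-level
missingness is computed **after** this exclusion; the opposite order is
defensible but would let imbalanced calls mask a site's true missingness,
so the stricter convention is used.

Three site filters then apply, with strict inequalities exactly as their
definitions read:

* filter 1 — genotype missingness $> 5\%$;
* filter 2 — maximum read depth (DP) over **called** genotypes $< 10$;
* filter 3 — more than $20\%$ of **called** genotypes with GQ $< 20$
  (missing calls carry no GQ, so they are excluded from the denominator).

A site failing any filter is excluded. QUAL and the INFO AQ field are
summarised per site but never filtered on. DP/GQ/ABratio summaries use
linear interpolation between order statistics (`stats::quantile` type 7) —
the estimator is fixed so that independent recounts reproduce the metrics
bit for bit. Multi-allelic records are split positionally into per-ALT
variants (no left-normalisation); ABratio QC applies only to bi-allelic
sites, per its definition.

# Burden sets

Annotations arrive as a VEP-style table with one row per variant-gene
transcript; `most_severe()` keeps the highest-ranked consequence per
variant-gene pair using the frozen severity table
(`consequence_severity_table()`), with unknown terms warned about and
ranked last. Impact classes: HIGH covers frameshift, transcript ablation
and amplification, splice acceptor/donor, stop lost/gained, plus both
`start_lost` (conventional) and `start_gained` (a phrasing that sometimes
appears for the same event) — both map to HIGH. MODERATE covers missense,
inframe insertion/deletion and protein-altering variants.

A variant qualifies for a gene's burden set when its most severe
consequence matches the model (loss-of-function = HIGH; moderate =
MODERATE, never HIGH) and its MAF, computed on the analysis sample set, is
below 0.5% — strict `<` for the primary burden model, with `<=` exposed as
an option because set-based pipelines commonly quote the threshold
inclusively. The carrier indicator is 1 for one-or-more rare alleles, 0
for observed non-carriers, and missing only for individuals missing at
every qualifying variant (missing at some but carrying another still
counts as a carrier: the observation is sufficient). Exclusion rules
(`multi_allelic`, `indel`, `non_HC_loftee`, explicit keys) remove variants,
not individuals; excluding moderate-model *individuals* who also carry a
LoF allele is a stricter alternative not implemented here.

# Association testing

`fit_null()` fits the covariate-only model once per trait (least squares
for quantitative traits, IRLS logistic regression for dichotomous ones)
and exposes residuals and variance weights so gene-level tests are score
tests against a fixed null. The default covariate set is age, genotyping
chip and ten principal components, with age², sex or anything else
available through the covariate table. Mixed models (GRM-based) are out of
scope: on the unrelated simulated cohorts the generator produces,
fixed-effects regression with PCs coincides with them in expectation. This
is the package's single largest deviation from biobank-scale practice and
the main caveat when transferring conclusions to real, related cohorts.

Per gene the scan computes:

* **Burden**: the carrier indicator added to the design; Wald beta/SE (OR
  for binomial) are the reported effects, while the p-value entering the
  scan and the omnibus is the score test's, which remains calibrated at
  low carrier counts where the Wald statistic does not.
* **SKAT**: $Q = \sum_j w_j^2 (g_j^\top r)^2$ with $r$ the null response
  residuals; the null distribution is the matching mixture of
  $\chi^2_1$ variables with eigenvalues from the weighted,
  covariate-projected genotype covariance.
* **ACAT-V**: Cauchy combination $T = \sum_j w_j \tan\{(0.5-p_j)\pi\} /
  \sum_j w_j$, $p = 0.5 - \arctan(T)/\pi$, over per-variant score tests.
  Ultra-rare variants (MAC $\le$ 10) have no valid single-variant
  asymptotic p-value and are first collapsed into one burden component, as
  the aggregated Cauchy test prescribes.
* **Omnibus**: equal-weight Cauchy combination of the defined component
  p-values.

Weights default to 1; CADD Phred scores can be supplied instead
(`weights = "cadd"`). No MAF-based Beta weights are used anywhere. Results
are ranked by omnibus p with ties broken by gene id, and flagged
significant strictly below the exome-wide threshold (default
$1.6\times10^{-6}$, configurable).

## Small-sample calibration for dichotomous traits

At desk scale (cohorts of a few thousand, variants with MAC $\le 20$,
trait prevalence around 7%) normal-theory approximations are measurably
miscalibrated: the normal score test is skew-blind, the chi-square mixture
misses the discreteness of sparse binary scores, and the analytic Cauchy
combination inherits and amplifies both. The package therefore uses the
remedies standard in the rare-variant literature:

* binomial score tests switch to a saddlepoint approximation of the exact
  Bernoulli score distribution once the normal-scale statistic exceeds
  0.5 (the smooth normal approximation is kept at the centre, where
  skewness is immaterial);
* the binomial SKAT p-value is referred to a parametric bootstrap of the
  fitted null model (2,000 centred Bernoulli residual draws, cached on the
  null object and generated from a fixed internal stream so results are
  deterministic and the caller's RNG state is untouched), with a
  moment-matched chi-square extension beyond the bootstrap's resolved
  range;
* in `exome_scan()` the binomial ACAT-V and omnibus statistics are
  referred to the same bootstrap draws (conditional Monte-Carlo with
  mid-rank ties), which respects both discreteness and the dependence
  between component tests; the analytic combination takes over in the far
  tail, where it is accurate.

Under the null at $n = 2{,}000$ with 500 genes these choices keep the
empirical type-I error of all four tests inside the 95% binomial band at
$\alpha = 0.05$ and their p-values consistent with uniformity, for both
trait families — the acceptance suite recomputes exactly this.

## The mixture-of-chi-squares tail

`mixture_chisq_tail()` computes $P(\sum_k \lambda_k \chi^2_{1,k} > q)$.
Equal eigenvalues reduce exactly to a scaled chi-square and are evaluated
in closed form. General spectra use characteristic-function inversion
(Imhof's integral), integrated blockwise over the integrand's oscillation
period with repeated averaging of the alternating partial sums — plain
adaptive quadrature over $(0,\infty)$ fails to converge on these
oscillatory integrands. Accuracy against exact two-eigenvalue convolutions
is on the order of $10^{-8}$. When the accelerated sum still cannot
resolve the tail (very small p with heavy cancellation), a Liu-type
four-moment chi-square approximation takes over with a warning and the
method used is recorded in the output.

Logistic separation in effect estimation falls back to Firth's penalised
likelihood (damped Newton with a hat-diagonal-corrected score), flagged in
the output rather than failing; the confounding check reports
likelihood-ratio p-values because quasi-separation collapses Wald
statistics exactly in the situations the check is meant to catch.

# Sensitivity analyses

`leave_one_out()` rebuilds the set without each variant in turn (carrier
indicators recomputed) and reruns the configured tests next to the
full-set reference row; re-inserting a variant reproduces the reference
exactly. `subset_analysis()` re-tests under the standard robustness
schemes — no multi-allelic sites, no indels, LOFTEE high-confidence only.
`confounding_check()` regresses carrier status on each PC separately.
`phenome_scan()` runs the burden test across a declared trait panel with
per-trait family, transformation (none, log, or rank-inverse-normal with
the Blom offset) and optional BMI adjustment; the bundled
`default_trait_config()` is an illustrative 17-trait metabolic panel —
real analyses should substitute the study's own panel and transformations.

On retention thresholds in leave-one-out: with 40 carriers and a 0.93 SD
effect, dropping the 10-carrier frameshift leaves an expected burden
$z \approx 5.2$ against the $4.80$ an exome-wide threshold demands, so
even a true, robust signal retains exome-wide significance after the worst
drop in only ~60% of replicates — a power fact, not evidence that one
variant drives the signal. The acceptance suite therefore judges
leave-one-out retention at nominal significance (every drop $p < 0.05$),
which is also how sensitivity analyses are read in practice.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes so
the whole pipeline is testable without access-controlled data.

**Cohort and latent clone.** Age uniform over 40–70 years; ever-smoking
prevalence 45% (typical of older male biobank volunteers); genotyping chip
a balanced binary; PCs independent standard normals. Clone presence is
logistic in age and smoking: baseline prevalence 5% at the age midpoint
(the typical array-detected LOY call rate), log-odds 1.0 per decade of age
and 0.4 for ever-smokers (odds ratios ~2.7/decade and ~1.5, in line with
the established epidemiology of LOY), with an optional carrier term so a
planted gene can raise clone risk. Given presence the cell fraction is
Beta(1, 8) at the youngest age, with the first shape parameter doubling
across the age range (clones expand with time), so the latent fraction
increases with age both through prevalence and conditionally.

**Array measures.** Each man gets 25 Y-probe log2 R ratios, Gaussian with
SD 0.14 around $\log_2(1 - f/2)$ at cell fraction $f$ (cells without Y
contribute no Y intensity). The PAR-LOY caller detects a clone with
sensitivity $\mathrm{logit}^{-1}\{(f - 0.10)/0.03\}$ — near-certain
detection above ~15% cell fraction, rare below 5% — and a 0.2%
false-positive rate; AF-LOY is the clamped noisy fraction for called men
and exactly 0 otherwise by default (the `af_loy_noncall = "estimate"`
flag exposes the alternative convention in which an estimate is returned
even without a call).

**Exome.** One contiguous interval per gene with unique variant
positions; background minor-allele counts follow a $1/k$ spectrum up to
MAC 20; 10% indels; 5% multi-allelic sites (positional second ALT); 3% of
sites planted off-target. Depth is Poisson(30); GQ is a noisy
deterministic function of DP floored at 21 outside plants, so the planted
filter-3 sites are exactly the sites with low-GQ calls; heterozygous AD is
binomial given DP but truncated strictly inside (0.25, 0.8), so the
planted imbalanced calls are exactly the recoverable ones — these
truncations trade a little realism for an exact, machine-checkable truth
sidecar, which is what the QC tests need. QUAL and AQ are integers in
[20, 99] drawn from a right-skewed Beta with mean ~45. Planted carrier
genes follow the configured spectrum (one multi-carrier frameshift
insertion plus doubletons and singletons, all carried by distinct
individuals); carrier sites receive no QC plants or missingness so carrier
truth is exact, and up to three singleton carrier variants sit at
multi-allelic sites so exclusion schemes bite.

**Phenotypes.** The quantitative trait is age and smoking effects plus
standard normal noise, standardised to unit SD in non-carriers, plus the
carrier effect — so planted effects are in non-carrier SD units exactly.
The binary trait is logistic with the intercept calibrated numerically so
the expected non-carrier prevalence matches the target (default 7.1%),
age log-odds 0.5 per decade, and carrier log-odds $\log(\mathrm{OR})$.

**What it does not emulate**: linkage disequilibrium and haplotype
structure, read-level sequencing error, relatedness and population
structure beyond independent PCs, sample-level QC failures, and transcript
-level annotation complexity beyond multiple rows per variant. Passing
tests therefore demonstrate the statistical machinery under the assumed
generative structure, not robustness to those real-data complications —
in particular the fixed-effects replacement for mixed models is exact here
by construction.

**Determinism.** One user-facing seed; each stage draws from its own
derived stream, so identical config + seed reproduce byte-identical VCFs
and tables, and the carrier assignment (`draw_carriers()`) is shared
between the cohort and exome generators.

# Problem sizes and numerical conventions

The test and acceptance suites run at deliberately modest sizes chosen to
make the statistical checks sharp rather than large: QC recounts on a
1,000-site × 500-sample VCF; null calibration at $n = 2{,}000$ with 500
genes per trait family; leave-one-out robustness over 100 replicates at
$n = 2{,}500$; parameter recovery at $n = 20{,}000$ with 60 (tests) or 200
(acceptance script) replicates. p-values are floored at $10^{-300}$; the
Cauchy combination substitutes $1/(p\pi)$ for $\tan\{(0.5-p)\pi\}$ below
$10^{-15}$; p-values of exactly 0 are clipped with a warning; results are
sorted by omnibus p with gene-id tie-breaks for reproducibility. The
dichotomous LOY-call recovery scenario uses a 5% baseline call rate; the
T2D-like scenario uses the 7.1% population prevalence with ~64 carriers
and the quantitative scenario 40 carriers in 20,000 — the published study
conditions the generator is built to reproduce. At such carrier counts the
plain logistic MLE's finite-sample mean sits a few percent below the
generating log-odds (visible even in a covariate-free fit); effects are
nevertheless estimated by plain logistic regression because that is the
method the reported effect sizes are defined by.
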
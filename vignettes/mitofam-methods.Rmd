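---
title: "Models and methods behind mitofam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitofam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofam)
```

`mitofam` analyzes mitochondrial heteroplasmy, mtDNA content and their
inter-generational transmission in matched family designs. This vignette
documents the statistical models, the concrete numerical choices made where
conventions differ, the synthetic-data generator used for calibration, and
the limits of what the packaged tests demonstrate.

## The calling model

Input is a per-site pileup over the 16,569-bp mitochondrial coordinate
system: strand-split allele counts, mean Phred base quality (BAQ) per
allele, and the fraction of site bases with BAQ ≥ 30. The pipeline begins
*after* alignment; the format assumes the producer already applied
read-level screens (MAPQ ≥ 20, BAQ ≥ 30, mismatch and proper-pair filters,
with the D-loop proper-pair exception handled upstream because the molecule
is circular).

A site yields a heteroplasmy call when all of the following hold:

| filter | default | unit/meaning |
|---|---|---|
| unique-read depth | > 500 | reads; ultradeep floor for 1.5% VAF work |
| base-quality profile | > 70% of bases BAQ ≥ 30 | site trustworthiness |
| masked regions | m.302–316, m.512–526, m.16184–16193 | homopolymeric stretches |
| minor-allele count | ≥ 5 | absolute evidence floor |
| likelihood score | > 5 | log10 likelihood-ratio units |
| strand concordance | P ≥ 1e-4, minor allele on both strands | exact conditional test |
| VAF floor | ≥ 1.5% | defense against co-aligning nuclear mtDNA segments (NUMTs) |

**The likelihood score.** The score is the log10 ratio of a two-component
mixture ("true heteroplasmy at the observed fraction") against an
errors-only null. With per-base error probability $e_i = 10^{-BAQ_i/10}$ and
$\hat p = k/n$, a minor-allele base contributes
$\hat p(1-e_i) + (1-\hat p)e_i/3$ under the alternative and $e_i/3$ under
the null; major bases contribute $(1-\hat p)(1-e_i) + \hat p e_i/3$ versus
$1-e_i$. Errors are spread uniformly over the three non-reference bases — a
maximum-entropy default in the absence of a substitution-specific error
profile. The exact functional form behind a BAQ-based score is a
convention choice; this one is pinned, documented, and monotone in the
minor count, and the threshold of 5 is used as-is. Borderline calls could
shift under a different concretization; nothing downstream depends on
borderline behavior. The score is clamped at zero: at $k=0$ the models
coincide, and $\hat p = k/n$ is a plug-in rather than the mixture MLE, so
tiny negative values are truncated rather than reported.

**Strand concordance.** Two-sided exact conditional (hypergeometric)
probability, defined as the total probability of tables with point
probability at most that of the observed table — the convention
`fisher.test` implements; conventions differ, so this one is stated. An
all-zero table passes with P = 1.

**Consensus mode.** For barcode-tagged capture data, reads sharing a
molecular barcode are merged per site under a uniform prior over the four
bases with per-read Phred likelihoods; the consensus base is the posterior
mode and its quality the Phred-scaled posterior error. Posterior ties emit
`N` and are excluded from counts — the conservative choice. Two filters
replace the strand test (consensus reads have no meaningful strand split):
per call, the variant fraction among multi-read consensus reads must be
comparable to the single-read fraction (exact test P ≥ 1e-4 and less than a
5-fold drop); per site, if more than half of a batch's variants fail that
check, the site is flagged low-quality and all its calls are removed. The
">50% of variants" tally is computed per analysis batch (the unit the
function sees); computing it per study would only differ if batches have
very few variants per site.

**Sharing and origin.** A variant is shared with another sample when its
fraction there is ≥ 0.2% among > 500 reads and the exact binomial upper
tail at the error rate (default 1e-3, the BAQ-30 bound; site-specific rates
may be supplied) is below 1e-3. Depth ≤ 500 yields *indeterminate*,
deliberately distinct from *not shared*. A child call shared with any
maternal-lineage member is inherited, otherwise de novo; "maternal lineage"
includes the other child in quartet designs, because a variant present in
the sibling must have passed through the mother even if her blood fraction
is undetectable. The same test rescues *secondary* heteroplasmies: maternal
variants below the primary VAF floor still count as transmitted when the
sharing test passes.

**Detection power** is exact binomial arithmetic: the critical count is the
smallest $k$ with $P(\mathrm{Bin}(n,e) \ge k) \le \alpha$ and power is the
alternative's upper tail there. No normal approximation is used; at
per-base error 2e-4 the relevant counts are single digits where the normal
approximation is poor. When $p \le e$ the same formula returns at most the
achieved size, a property the tests assert.

## mtDNA content and mtCNz

The depth-ratio estimator is $2 \times$ the mean over the 22 autosomes of
(mtDNA depth / chromosome coverage), each chromosome's coverage being the
mean over 100-kb windows (50-kb step) with more than 80% of sites covered —
windows in deletions or alignment gaps drop out rather than biasing the
denominator. The capture-data estimator is the analogous ratio of mean
per-probe consensus-read counts, with probes whose annealing regions
overlap polymorphisms segregating in ≥ 0.2% of batch samples masked out.

mtCNz is the standardized residual of child content regressed by OLS on age
(gestational age for cord blood) and parental-mean (or maternal) content.
Children with missing age receive the cohort mean before fitting. The
regression is fit once on the full child set and never refit per subgroup,
so stratified analyses share one scale. Tertiles (T1 = low) are cut at the
1/3 and 2/3 empirical quantiles of all pooled children — cases and controls
together, since splitting the reference set would make tertile membership
depend on the analysis subset; fully degenerate input falls back to stable
input order with a warning.

## Pathogenicity

The pathogenicity z-score is the rank-based inverse-normal transform
$z_i = \Phi^{-1}((r_i - 0.5)/m)$ over the universe of all $3 \times$
(category positions) possible nucleotide changes — CADD-like raw scores for
OXPHOS genes, MitoTIP-like raw scores for tRNA genes. Ties share the mean
rank; the half-offset convention is stated because the transform's offset
is not standardized. The transform is invariant to monotone rescaling of
raw scores, which is the property that makes z-scores from different
predictors comparable.

Predicted-pathogenic (PP) classification reads the predictor battery
per-applicability: nonsynonymous OXPHOS changes require *all* of CADD
Phred > 15, PolyPhen-2 possibly/probably damaging, and MutPred > 0.6; tRNA
changes require MitoTIP raw > 12.66. Any-of readings would be vacuous,
since protein predictors do not exist for tRNA variants and vice versa. A
confirmed mitochondrial-disorder mutation overrides prediction unless
marked benign; in either route the population frequency must be ≤ 0.05%,
taken as the *maximum* across reference panels — the stricter reading when
several panels are available. rRNA and D-loop variants carry no z-score and
can be PP only via the confirmed-mutation route. Missing required scores
yield an indeterminate flag, distinct from a negative call. Variants in
gene overlaps report every membership, and downstream counting dedupes by
the most severe consequence (OXPHOS > tRNA > rest); how the original
analyses resolved overlaps is not recoverable, so the package keeps all
memberships visible.

## Selection and transmission

Two tests of purifying selection are provided. The one-sample t test asks
whether a heteroplasmy set's mean z deviates from 0 (the universe median).
The resampling test draws, without replacement within each
(gene category × transition/transversion) stratum, `B = 1e5` change sets
matching the observed composition exactly, and reports
$(1 + \#\{\bar z_b \le \bar z_{obs}\})/(B+1)$ — the +1 smoothing keeps the
probability valid at finite B, and the lower tail is the default because
purifying selection is the directional hypothesis (a two-sided variant
doubles the smaller tail). Strata are matched *jointly* on category and
transition status: matching them only marginally would let the resamples
trade tRNA transversions for OXPHOS transitions, changing the null.

The transmission model is a logistic regression of the transmitted
indicator of maternal heteroplasmies on the pathogenicity z-score with
gene-class, maternal-VAF and child-sex covariates; since z is on the SD
scale, the exponentiated coefficient is the transmission odds ratio per SD
of pathogenicity. Complete separation is flagged and the interval reported
unbounded rather than silently trusted. Maternal-age effects on de novo
counts use ordinary linear regression with an optional group × age
interaction (slope heterogeneity) and paternal-age covariate. The mutation
rate estimator is deliberately plain — total de novo counts over (children
× callable sites), with an explicit, default-off detectability divisor —
because detectability corrections depend on depth and VAF-floor specifics
that belong to the study, not the package; it is validated by simulation
round-trip only.

## The association layer

Within-family effects use conditional logistic regression
(`survival::clogit`) on family strata; for one binary exposure in 1:1
pairs this equals the discordant-pair ratio, which the tests exploit as a
closed-form oracle. Unmatched analyses use ML logistic models with optional
interaction terms and likelihood-ratio comparison of nested models. The
carrying rule is design-specific: a quartet child carries a PP heteroplasmy
if its fraction exceeds the sibling's at that site; a dyad child if the
fraction increased relative to the mother. Missing parental ages are
imputed with the group mean.

Fixed-effect meta-analysis back-calculates each stratum's log-OR standard
error from its printed 95% CI as $(\ln hi - \ln lo)/(2 \times 1.959964)$ —
assuming symmetric Wald intervals on the log scale, the only reading that
reproduces published combined estimates from printed per-cohort rows — then
combines with inverse-variance weights, reporting Cochran's Q (χ², k−1 df)
and $I^2 = \max(0, (Q-(k-1))/Q)$. The population-attributable risk is
$p_0(OR-1)/(1+p_0(OR-1))$ with $p_0$ the family-adjusted exposure
prevalence among controls; its CI resamples whole matched units (families)
1,000 times, recomputing prevalence and the discordant-pair OR each time.
"Family-adjusted prevalence" itself is pinned as the comparator-rule
exposure proportion with a family bootstrap for the SEM — the published
analyses name the quantity without defining it, so this definition is the
package's own and is stated here. Nominal two-sided P values are reported
throughout; no hidden multiplicity correction is applied.

## The synthetic cohort generator

The generator exists so that every layer can be calibrated against known
truth. Its defaults are the study conditions the analysis assumes, chosen
once: a 0.02% per-base error floor with mean BAQ 33 and 90% of bases at
Q30+; depth 4,000 ± 900 (negative-binomial); a germline bottleneck of 30
segregating units; transmission odds 0.64 per SD of pathogenicity z;
disease odds 1.5 for PP carriage with a 1.65× extra multiplier in the
low-content tertile and 0.7 per SD of content; content heritability 0.65
with ~1.2 copies/year age decline around a mean of 160 copies per diploid
genome; ~1.5 heteroplasmies per parent.

Mechanism choices, where the source data constrain direction but not form:

* **Bottleneck**: single-generation binomial resampling of N units at the
  maternal fraction — the minimal mechanism that produces VAF drift, loss
  and fixation. N = 1 gives fixation-or-loss, as it must.
* **Selection acts on the transmission probability**, not the transmitted
  fraction: the odds of surviving the bottleneck are multiplied by
  0.64 per SD of z. This mirrors how selection is *measured* (a
  transmission odds ratio), so the logistic readout is estimating exactly
  the parameter the generator set.
* **De novo events** are Poisson with mean linear in maternal age
  (the ~12,800 unmasked OXPHOS/tRNA sites × µ at the reference age of 30,
  plus 0.012
  events/year); positions are drawn from the unmasked OXPHOS/tRNA change
  universe with weights $\exp(c \cdot (age-30) \cdot z)$, giving the
  age-dependent pathogenicity shift in location (the source data report
  direction only; c = 0.02/year is a configurable magnitude).
* **µ defaults to 2e-5 per site per generation**, chosen to give a
  realistic ~0.3 detectable de novo heteroplasmies per child. Published
  per-site rates an order of magnitude lower are *detectability-corrected*
  estimates; the generator parameterizes the detectable-event rate
  directly, and `mutation_rate()`'s correction factor is the user's
  explicit input.
* **Content** decomposes additively: parental genetic values
  $a \sim N(0, h^2)$, environment $N(0, 1-h^2)$, child genetic value =
  midparent mean + Mendelian noise $N(0, h^2/2)$. This yields
  midparent-offspring slope $h^2$ and parent-child correlation $h^2/2
  \approx 0.33$, the moderate correlation regime family studies report.
* **Phenotype**: in quartets, exactly one of the two children is designated
  the proband with probability proportional to its disease odds —
  retrospective ascertainment of one affected child per family, under
  which conditional logistic regression consistently estimates the
  configured odds ratios. Dyads draw independent Bernoulli outcomes around
  a 15% baseline.
* **Error injection** is strand-symmetric by default; a `strand_bias_frac`
  knob pushes error mass onto one strand to exercise the strand filter.
  A `vaf_overdispersion` knob adds Beta noise around true fractions; the
  replicate variability of real capture data conflates capture and
  sequencing noise, and the generator deliberately exposes one knob rather
  than pretending to decompose sources it cannot identify.

Determinism: the seed fully determines output, and each family consumes an
independent derived stream, so enlarging the cohort leaves earlier families
byte-identical. The generator does **not** emulate: alignment artifacts,
NUMT co-alignment structure (the VAF floor is carried as a filter, not
re-derived), haplogroup structure beyond an ancestry label, indels, or any
nuclear genetics. Consequently, passing tests demonstrate that the
*statistics* behave as designed under the stated mechanisms — not that the
filters would perform identically against real alignment pathologies.

## Problem sizes and calibration checks

The packaged checks run at sizes chosen to give tight Monte-Carlo bounds on
one CPU: parameter recovery uses 2,000 quartet families (disease-OR
recovery runs with the interaction and content effects disabled, so the
marginal carriage effect *is* the configured 1.5 — the standard way to
validate an estimator against a single known parameter); error control uses
100 error-only genome pileups at depth 2,000; sensitivity uses 300 clean
truth heteroplasmies at VAF 5–40%; type-I calibration uses 250–1,000
replicates per test with acceptance bands of ±2 Monte-Carlo SE around 5%;
the resampling test is checked for exact agreement with full stratified
enumeration on a 20-entry universe. The recovery checks assert 95% CI
coverage of the configured values, so each has a ~5% false-alarm rate by
construction; seeds are fixed to keep runs reproducible.

## Known limitations

* The likelihood-score form is a documented concretization; a different
  BAQ-based score could shift borderline calls.
* The consensus-mode content estimator is a ratio estimator with probe
  masking; capture-efficiency modeling beyond masking is out of scope, as
  is GC or mappability correction of nuclear depth.
* Conditional logistic support is limited to within-family strata as
  `clogit` handles them; bespoke exact methods for large sparse strata are
  not included.
* The packaged reference sequence is synthetic (with the standard gene
  map); real analyses should supply an rCRS FASTA. Consequence annotation
  depends on the supplied sequence's codons, not on a packaged truth.
* Score tables are consumed as supplied; no live database access, no
  recomputation of CADD/PolyPhen-2/MutPred/MitoTIP.
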
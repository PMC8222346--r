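---
title: "Models and methods: Walsh-encoded landscapes, variance partitions, and greedy adaptive walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiwalsh)
```

# The data model

Everything downstream consumes a *landscape table*: long-format replicate
activity records keyed by (genotype bitstring over `L` biallelic sites,
environment label, replicate index). Bit `i` refers to the `i`-th entry of
the table's site labels, `0` meaning ancestral and `1` derived; the default
labels are the five active-site positions `72, 193, 258, 271, 273` of the
motivating enzyme system, ordered by sequence position. Activities are
nonnegative reals — in the motivating assays, substrate-hydrolysis rates in
nM/s normalized to culture OD. Normalization is treated as part of the
measurement, not of this analysis, so activities are expected to arrive
already normalized.

Zero activities are legal: below-detection wells are a fact of plate
assays. Every operation that needs a ratio or a logarithm applies a
*detection floor*, by default the smallest positive activity in the table
times $10^{-2}$, and flags each value it floors. The floor is configurable
and flooring can be disabled, in which case logging a zero is an explicit
error rather than a silent `-Inf`.

The package validates rather than assumes completeness: `completeness()`
reports missing genotype-by-environment cells and per-cell replicate
counts, and operations whose algebra requires the full factorial
(orthogonality, background enumeration, walks) refuse incomplete
environments by name instead of producing biased estimates.

# Genotype and environment encodings

Site `i` of a genotype is encoded $u_i = \pm 1$ (ancestral $-1$, derived
$+1$), and a site subset $T$ by the product $\prod_{i \in T} u_i$. On a
complete balanced factorial these columns are mutually orthogonal and each
non-intercept column sums to zero, which yields the properties the whole
analysis leans on:

* the intercept is the grand mean of the (transformed) response, so every
  coefficient reads as a deviation from the mean;
* coefficients at different orders are estimated independently, so
  sequential $R^2$ increments are nonnegative and do not depend on the
  order in which same-order terms enter;
* the full-order coefficients equal the Walsh–Hadamard transform of the
  cell means scaled by $2^{-L}$ (verified in the tests against a
  brute-force subset-enumeration transform for $L \le 5$).

Categorical environments get Hadamard contrast coordinates: the rows of the
order-$E$ Sylvester Hadamard matrix with the constant column removed,
assigned in the order the labels appear. Each label's coordinate vector has
self dot product $E-1$, any two distinct labels have dot product $-1$, and
every dimension sums to zero over labels. The magnitude of one
environment's effect is the dot product of its coordinates with the fitted
environment coefficients; which label maps to which Hadamard row is
arbitrary, and these magnitudes are invariant to that assignment, which is
why the package simply follows label order. When $E$ is not a power of two
the Sylvester construction does not exist and the encoding falls back to
sum-to-zero contrasts — the zero-sum centering survives, the equal pairwise
dot products do not; this is a documented deviation, not an error.

A `design_spec` nominally allows genetic orders 1..`L`; order 0 is also
accepted so that the environment-only model (activity explained by
environment coordinates alone) can be expressed in the same machinery.

# Response transform

The models regress the response by OLS. The default transform is `log10`
with the detection floor applied first, because activities in this kind of
assay span orders of magnitude, effects are naturally discussed as fold
changes, and replicate scatter scales with signal; `identity` is available
by configuration for data where additive noise is the better description.
Neither choice is hard-coded into the statistics: every fitting function
takes the transform from its `design_spec`, and walks deliberately use raw
mean activities, since greedy ranking is invariant under monotone
transforms.

Fits operate on replicate rows by default, so $R^2 < 1$ even at full order
(the full-order model interpolates cell means, not replicates). A
`aggregate = "means"` switch fits cell means instead; that mode gives the
exact-interpolation identity used by the Walsh-transform tests.

# Fit statistics and nested comparisons

To make nested comparisons reproducible bit-for-bit, the statistics are
pinned exactly: $R^2 = 1 - RSS/TSS$ (defined as 0 for a constant response);
adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-p)$ with $p$ counting all columns
including the intercept; Gaussian maximum-likelihood log-likelihood
$-\tfrac{n}{2}(\log(2\pi\,RSS/n) + 1)$. The likelihood-ratio statistic for
nested models is $2(\ell_{high} - \ell_{low})$ against $\chi^2$ with
$p_{high}-p_{low}$ degrees of freedom. A zero-residual fit has divergent
Gaussian likelihood; the comparison then reports an `Inf` sentinel with a
`zero_residual` flag and p-value 0 rather than pretending a finite
statistic. Rank-deficient designs (typically from missing cells) abort with
the collinear terms named.

The sequential variance partition fits genetic-only models of order
$1..L$ per environment and reports the $R^2$ increments. Per-environment
partitions are the default because the motivating analysis describes its
supplementary partition per environment; a pooled fit with environment and
interaction columns can be built directly with `build_design` when a single
decomposition across environments is wanted.

# Effect statistics

The effect of deriving site $s$ in a background $b$ (one of the $2^{L-1}$
genotypes with $s$ ancestral) is, on the default log scale,
$\log_{10}(\bar{A}_{b+s}/\bar{A}_b)$ — antisymmetric under direction
reversal, with raw-fold and identity scales available. From these
background effects derive the averaged and conditional summaries: the
average effect (equal to twice the first-order Walsh coefficient on a
balanced design), conditional effects given another site's state (the
unconditional average is the mean of the two conditional values, and the
derived-minus-ancestral difference of conditional effects is four times the
pairwise Walsh coefficient on a noiseless landscape), pairwise epistatic
coefficients (the order-2 fit's second-order terms), cross-environment
regressions of the concatenated $L \cdot 2^{L-1}$ background effects
(conservation of epistasis between environments), and the correlation of a
site's effect with the number of substitutions already fixed elsewhere.

Two conventions here were genuinely open and are configuration, not
doctrine: the correlation statistic defaults to Pearson with Spearman as an
option, and the multiple-testing correction across the environment family
defaults to Benjamini–Hochberg with Bonferroni available. Points whose
numerator or denominator was floored are excluded from regressions by
default and counted in the output rather than silently included.

# The greedy walk

The walk implements strong directional selection: from the current
genotype, consider all $L$ single-mutation neighbors *including
back-mutations*, and fix the one with the greatest improvement in mean
activity "as long as the change is not negative". Three edge cases required
decisions:

* **Zero improvement.** "Not negative" includes zero, so zero-delta steps
  are permitted; they are forced ambiguous (the data cannot order the two
  genotypes), and a no-revisit guard halts the walk rather than cycling on
  a plateau, classifying the endpoint `stalled_no_improvement`.
* **Ties.** Two equally best neighbors break deterministically to the
  lowest site index, with all tied candidates recorded in the step
  metadata.
* **Stop rule versus ambiguity.** A step's ambiguity never blocks it — the
  walk stops only when no non-negative move exists — and the endpoint's
  confidence is reported separately: `strict_optimum` when every neighbor's
  replicate span lies entirely below the endpoint's, `tentative_optimum`
  otherwise. This keeps the step rule and the stop rule from conflicting
  when an endpoint's neighbors overlap it.

Ambiguity compares closed replicate spans $[\min, \max]$, the literal
reading of "span of replicate measurements"; a `mean_sd` rule
(mean $\pm$ one standard deviation) is offered as an alternative since
reasonable analysts differ, and the two can disagree. Shrinking replicate
noise can only remove ambiguity, never create it — a property the tests
assert by contracting replicates toward their cell means.

Optimum enumeration is exhaustive and independent of the walk: a local
optimum beats all $L$ neighbors on means, the global optimum is the maximum
mean (exact ties are all reported and flagged), and each walk endpoint is
classified `reached_global`, `stranded_local`, or `stalled` against that
enumeration.

# The synthetic generator

`generate_landscape()` builds a complete factorial whose cell log10-mean is
a planted Walsh expansion — baseline, per-environment offsets, and explicit
or randomly drawn coefficients per order, shared across environments or
environment-specific (the latter planting $G \times E$ and
$G \times G \times E$ structure) — plus Gaussian replicate noise on the
log10 scale. Multiplicative noise is the default because replicate scatter
in activity assays scales with signal; an additive option exists for
identity-transform testing. Generation is a pure function of
(specification, seed).

`generate_study_mimic()` instantiates the motivating design: $2^5$
genotypes $\times$ 8 metal labels $\times$ 3 replicates (768 records). Its
planted plan is fixed, chosen once so that first-order terms carry roughly
70% of the variance in cell log-means, pairwise terms roughly 25%, orders
3–5 a few percent, and the default replicate noise ($\sigma = 0.2$ log10
units) about 5%; site 271 is deleterious alone and rescued late by synergy
with 258 and 273, the pairwise terms form a chain of synergies that keeps
the all-derived genotype both the global optimum and the greedy
destination in seven environments, and `Cd` carries a sign-flipped
258×271 interaction strong enough to move its global optimum to `11101`.
Because the Walsh columns are orthonormal after scaling, the per-order
variance shares implied by any planted plan are available in closed form
(`planted_variance_shares()`), which is the oracle for the recovery tests.

What the generator does *not* emulate: assay-specific artifacts
(plate-position effects, batch drift, heteroskedasticity beyond the
multiplicative model), below-detection censoring, pipetting outliers, and
any mechanistic relationship between metals and catalysis. Passing
recovery tests on this generator therefore demonstrates the statistical
machinery is correct under its stated noise model, not that real assay data
satisfy that model.

# Problem sizes and numerical tolerances

The shipped tests compare full-order OLS to the brute-force Walsh
transform on 200 random landscapes across $L \le 5$ at $10^{-9}$; run
1,000 random noiseless walks against exhaustive optimum enumeration; check
planted-share recovery at $10^{-6}$ on the noiseless mimic; and measure
coefficient recovery within three standard errors across 300 noisy
mimic draws (expected fraction 99.7% under Gaussian theory, asserted at
99%). Simulation-based property tests (power of the order-2 LRT, decay of
cross-environment $R^2$ with planted $G \times G \times E$ variance,
type-I control of the adjusted correlations, RMSE scaling with
$\sigma/\sqrt{n}$) use 40–300 seeds each — enough that their Monte Carlo
error is small against the asserted margins. The LRT power check plants its
interaction at twice the $3\sigma/\sqrt{n}$ detectability threshold
(noncentrality $\approx 36$ on 10 degrees of freedom), where rejection
at $p < 0.05$ in at least 95% of draws follows analytically; at exactly
the threshold the power of a 10-df test is far lower, so that marginal
case is not asserted.

# Limitations

* Plain OLS only: no regularization, no mixed models, no Bayesian
  variants; replicates are treated as exchangeable.
* The nested sequential partition makes highest-order estimates
  conservative by construction — variance is credited to the lowest order
  that can absorb it.
* The walk model is deterministic greedy selection; it does not model
  fixation probabilities, clonal interference, or mutation bias.
* Hadamard environment coordinates require $E$ a power of two for the
  equal-angle geometry; other $E$ fall back to ordinary sum-to-zero
  contrasts.
* Sites are abstract biallelic loci: there is no sequence-level
  representation, and site labels are opaque identifiers.
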
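---
title: "AMMI stability analysis and doubled-haploid gene effects: models and methods"
author: "ammistab maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AMMI stability analysis and doubled-haploid gene effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ammistab)
```

## The problem

Multi-environment trials of crop genotypes routinely show
genotype-by-environment (GE) interaction: the ranking of genotypes
changes across years or locations, so a genotype's mean performance
alone is a poor selection criterion. `ammistab` implements the
fixed-effects AMMI analysis of such trials — additive main effects plus
a multiplicative (SVD) decomposition of the interaction — together with
the AMMI stability value (ASV), the genotype selection index (GSI), and
quantile-method estimation of total additive and additive-by-additive
(epistatic) gene effects in doubled-haploid (DH) populations. The
worked example throughout is the embedded `barleyTKW()` trial: 32
spring barley genotypes (two parents and 30 DH lines) scored for
1000-kernel weight (grams) over six years at one location, three
replicates per plot, stored as the published 2-decimal cell means.

## The AMMI model

For a balanced table of cell means $y_{ge}$ (genotype $g = 1..G$,
environment $e = 1..E$, each mean over $r$ replicates),

$$y_{ge} = \mu + \alpha_g + \beta_e +
  \sum_{n=1}^{N} \lambda_n \gamma_{gn} \delta_{en} + Q_{ge},$$

with zero-sum main effects, $\lambda_n$ the singular values of the
doubly-centred interaction matrix
$Z_{ge} = y_{ge} - \bar y_{g\cdot} - \bar y_{\cdot e} + \bar y_{\cdot\cdot}$,
$\gamma$ and $\delta$ orthonormal score vectors, and $Q_{ge}$ the
residual left by the $N$ retained axes. With all
$M = \min(G-1, E-1)$ axes the reconstruction is exact, which is one of
the package's standing test invariants, alongside conservation of the
interaction sum of squares across axes.

Assumptions worth spelling out: the design is balanced and complete
(the package refuses unbalanced input rather than imputing — AMMI
imputation schemes are a separate topic), effects are fixed, and the
plot errors are i.i.d. normal. Mixed-model (REML/BLUP) alternatives
are deliberately out of scope.

### Scaling, signs and ties

Published AMMI tables rarely state the score scaling. `ammiDecompose()`
uses *symmetric* scaling, $\sqrt{\lambda_n}\,\gamma_{gn}$ and
$\sqrt{\lambda_n}\,\delta_{en}$, so each side's per-axis sum of squares
equals $\lambda_n$. On the embedded trial this reproduces the published
score magnitudes (e.g. environment-2012 IPCA1 $\approx 3.87$), which is
how the choice was validated. SVD signs are arbitrary; each axis is
flipped so its largest-magnitude environment score is positive. ASV,
GSI and all sums of squares are invariant to this choice; comparisons
against published scores are made on magnitudes or after a single
global sign alignment per axis. Axes are ordered by decreasing
$\lambda$; exact ties (a measure-zero event in real data) keep the
underlying SVD order after the sign convention, which makes the output
deterministic.

A degenerate, exactly additive table (zero interaction) yields all
$\lambda_n = 0$; axis percentages are then reported as 0 with a
warning. When the interaction is numerically rank-1 the ASV weight
$SS_1/SS_2$ is undefined and `asv()` stops with a clear message rather
than dividing by a round-off value (the guard treats
$SS_2 < 10^{-12}\,SS_1$ as zero).

### ANOVA scales and axis tests

All sums of squares are reported on the replicate-total scale (means
SS times $r$), the convention of published trial ANOVA tables; $r$
travels with the `GEMatrix`. From replicate-level records
(`anovaTwoWay()`, built on `lm`/`anova`) the pooled error stratum is
estimated from the data; from means-only input the user supplies an
externally published error mean square (`anovaFromMeans(ge, errorMS,
errorDf)`), 26.4 g² on 372 df for the embedded trial.

Each multiplicative axis is tested by the Gollob approximation: axis
$n$ carries $G + E - 1 - 2n$ degrees of freedom — exactly the
free-parameter count of extending a rank-$(n-1)$ doubly-centred matrix
to rank $n$, which the test suite verifies combinatorially — and
$F_n = MS_n / MS_{error}$. Gollob tests are anticonservative relative
to resampling alternatives (FGH, bootstrap); those are out of scope,
and retained-axis counts are always user-overridable (default: axes
with Gollob $p < 0.05$ when an error term exists, else the biplot
minimum of 2).

Percentage-of-total columns are computed from the table's own rows.
For the embedded trial the published percentages imply an additional
unlisted stratum (most plausibly blocks) of roughly 1,000 g²; since
that stratum is not recoverable from the printed means, the package
reports percentages over the listed rows and the numeric SS values are
the quantities checked against the source.

## Stability: ASV and GSI

$$\mathrm{ASV}_g = \sqrt{\left[\frac{SS_{IPCA1}}{SS_{IPCA2}}
  \mathrm{IPCA1}_g\right]^2 + \mathrm{IPCA2}_g^2}$$

is the weighted distance of genotype $g$ from the origin of the first
two interaction axes; the weight compensates for axis 1 carrying more
of the interaction SS. Exactly two axes enter, even when more are
significant — that is the statistic's definition. The SS ratio is
invariant to $r$, so means-only input is safe. GSI adds the rank of
the genotype mean (1 = best) to the rank of ASV (1 = most stable);
ties get average ranks, so GSI can be non-integer under ties (the
convention the package documents because the source is silent).

```{r stability}
ge <- barleyTKW()
dec <- ammiDecompose(ge)
head(as.data.frame(stabilityReport(dec, ge)), 3)
```

Near-ties deserve a caution: two genotypes of the embedded trial have
ASVs about 0.001 apart, and the 2-decimal rounding of the published
cell means is enough to swap their ASV ranks (and hence shift both
GSIs by one) relative to the source's unrounded analysis. All other
ranks agree.

## Quantile-method gene effects in DH populations

DH lines are fully homozygous, so dominance deviations are impossible
and line means expose additive and additive-by-additive effects
directly. The estimators need the groups of *extreme* lines — those
carrying, in theory, only trait-decreasing or only trait-increasing
alleles. `extremeLines()` takes the lines at or below the 0.03 and at
or above the 0.97 empirical quantile of the line means (the probability
defaults carried over from the method's calibration study; both are
user-settable). The empirical quantile uses linear interpolation of
order statistics (R's default type 7) — the source does not state a
convention, but with 30 lines all interpolating conventions that
include the observed extremes give the same singleton groups here, and
this choice reproduces the published effect grid exactly. Then

$$\hat a_{DH} = \tfrac12(\bar L_{max} - \bar L_{min}), \qquad
  \hat{aa}_{DH} = \tfrac12(\bar L_{max} + \bar L_{min}) - \bar L,
  \qquad \hat a_{Parents} = \tfrac12(P_1 - P_2),$$

with $P_1$ the better parent *in that context* (each year, or the
multi-year mean, decides its own better parent). Subset analyses
(hulled / hull-less seed types) re-identify extremes within the
subset; parents never enter DH groups. Cross-environment analyses use
the row means of the cell-mean matrix.

```{r genetics}
eff <- geneticEffects(ge, errorMS = 26.4, errorDf = 372)
geneticEffectsTable(eff)[1:3, ]
```

### Significance tests — an interpretation, flagged as such

The source literature for the $F_a = MS_a/MS_e$, $F_{aa} =
MS_{aa}/MS_e$ tests does not print the mean-square constructions.
`effectTests()` treats each effect as a single-df linear contrast of
line means: with contrast coefficients $c_i$ over means of $n_{obs}$
plots each, $MS = \hat\theta^2 / (\sum_i c_i^2 / n_{obs})$, referred to
$F(1, df_e)$. This is a documented interpretation, not a reproduction:
the replicate-level error of the original trial is not recoverable
from printed means, so the package's stars on the embedded data are
illustrative. Two caveats follow from the construction itself. First,
the contrast coefficients treat group membership as fixed. Under the
genetic model this is reasonable — membership reflects which alleles a
line carries — but when the extremes are *selected from noisy data*,
the selection inflates the statistic, and the test is anticonservative
under a pure-noise null. The package's calibration check therefore
fixes membership a priori (where the test holds its 5% size exactly);
users should read significance on data-selected extremes with that in
mind. Second, for the cross-environment context the per-mean
observation count is $rE$, treating year effects as fixed, consistent
with the fixed-effects analysis throughout.

## The simulators, and what passing tests do not show

`simulateAMMITrial()` generates plot values from the AMMI model
itself: chosen or drawn zero-sum main effects, $K$ planted singular
values with random orthonormal score vectors built orthogonal to the
all-ones vector (so simulated data satisfy the double-centring
identities exactly), and i.i.d. normal plot error. It is seeded and
byte-reproducible. `simulateDHPopulation()` draws $\pm 1$ allele
vectors per line, builds genotypic values additively plus optional
pairwise additive-by-additive terms, and can plant the all-plus and
all-minus lines that the extreme-line estimators presuppose. It is an
idealisation consistent with the estimators' assumptions — test
scaffolding, not a biological claim: there is no linkage, no
recombination, no marker structure, and allele effects are
exchangeable across loci.

Consequently, green simulation tests demonstrate internal consistency
(estimators recover what the generative model plants; error mean
squares are recovered at the trial's scale; the noiseless limits are
exact) — they do not demonstrate robustness to field realities the
generator omits: spatial trends, unbalanced or missing plots,
non-normal error, outlier years, or genuine linkage disequilibrium
among loci.

Problem sizes used by the checks were chosen to mirror the embedded
study where that matters and to keep everything desk-scale otherwise:
error-MS recovery runs 500 trials at the study's own 32 x 6 x 3
design with error variance 26.4 g²; leading-singular-value recovery
runs 200 trials at the same design; the fixed-contrast size check uses
2,000 pure-noise populations of 30 lines x 3 replicates.

## Known limitations

* Balanced, complete designs only; no imputation, no incomplete
  blocks, no spatial models, single trait.
* Fixed-effects inference only; no REML/BLUP, no GGE biplot, no
  cross-validation axis selection.
* The embedded trial stores published 2-decimal means, so every
  comparison against the source carries that rounding floor (about
  0.005 g on a mean, ~0.002 on scores, and up to ~0.002 g² relative on
  sums of squares); two environment scores printed in the source are
  internally inconsistent with its own table and are excluded from
  comparisons.
* Stability statistics use exactly the first two axes; trials whose
  interaction is effectively rank-1 are rejected rather than silently
  re-weighted.
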
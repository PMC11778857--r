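---
title: "Models and methods behind MetaMutualism"
author: "MetaMutualism authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind MetaMutualism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetaMutualism)
```

## The system

MetaMutualism studies a synthetic obligate mutualism built from engineered
budding-yeast strains. Four adenine over-producers (AdeOPs) release adenine
and require lysine; four lysine over-producers (LysOPs) release lysine and
require adenine. In medium lacking both amino acids, neither guild can grow
without the other, so the community is an obligate cross-feeding loop. A
ninth strain, a lysine *cheater*, consumes lysine without releasing
anything and pays no over-production cost. If the cheater competitively
excludes every AdeOP, the adenine supply vanishes and the whole community
is doomed: the persistence of the mutualism hinges on keeping at least one
member of each producer guild alive.

The package asks whether *directed dispersal* — reintroducing a strain
into wells where it is nearly extinct, from wells where it thrives —
rescues such communities. The full pipeline simulates a plate-based
meta-community under serial transfer, applies the weekly rescue protocol,
and analyses the resulting ordinal scoring tables: Hill-number alpha
diversity, Bray–Curtis beta diversity with a richness-preserving null
model, NMDS ordination, persistence/collapse summaries, and permutation
inference for treatment and trend effects.

## The experimental design being emulated

`buildLayout()` constructs the default design: two 48-well plates per
community type, six blank wells per plate for contamination monitoring, and
the remaining 42 wells split into 21 *isolated* and 21 *dispersal-allowed*
communities — 168 experimental communities in total, 84 mutualist-only and
84 exploited. Every community starts at a total density of 0.1 OD600:
mutualist-only wells receive 0.0125 OD of each of the 8 mutualists;
exploited wells receive 0.01 OD of each mutualist plus 0.02 OD of the
cheater (AdeOP : LysOP : cheater = 2 : 2 : 1). Which physical well gets
which role is a seeded uniform shuffle; well positions carry no meaning in
the downstream analysis, so whether blanks are interleaved or grouped is
irrelevant to inference.

Cultures are diluted 1:10 into fresh medium every 48 h. A scored "week" is
three 48-h batches (the 48-h cadence does not divide a calendar week
evenly; three batches per week is the package's convention,
`transfersPerWeek` in the configuration). At the end of each week, 10 µl of
every well is plated on selective agar and each strain is scored on the
ordinal scale *strong / weak / very weak / micro / gone*. The experiment
runs 8 weeks; analyses default to Week 7 as the endpoint
(`finalWeek` option) because the final week's transfer round truncates the
last batch cycle.

## The batch-culture model

The simulator (`stepBatch()`, `serialTransfer()`, `runExperiment()`) is a
minimal Monod consumer–resource batch model, integrated with a fixed-step
Euler scheme. For strain $i$ with required resource $R$ (lysine for AdeOPs
and the cheater, adenine for LysOPs), cell number $N_i$ and resource pools
evolve as

$$
\frac{dN_i}{dt} = \mu_{\max} (1 - c_i)\, \frac{R}{K_i + R}
  \left(1 - \frac{N_{\mathrm{tot}}}{N_{\mathrm{cap}}}\right) N_i
  \;-\; m_i N_i \,\mathbb{1}[R < \theta K_i],
$$

with resource consumption $1/Y$ units per new cell and, for producers,
release of $y_g$ units per new cell (growth-coupled over-production),
$y_d$ units per cell lost to starvation death (lysis returns the
intracellular pool to the medium), and a constitutive leak $\lambda$ per
cell per hour. Growth in a step is rescaled whenever it would overdraw a
resource pool, so pools and densities stay non-negative by construction.

Three structural terms deserve comment, because a strictly growth-coupled
release model cannot reproduce the system's qualitative behaviour:

* **Constitutive leak.** Fresh medium contains neither amino acid, so with
  growth-coupled release alone the obligate loop can never start (each
  guild waits for the other). Over-producer strains release their product
  regardless of growth; a small leak term bootstraps the loop.
* **Carrying capacity.** Amino-acid exchange cannot lift the glucose
  ceiling of the medium; without a shared logistic cap the leak term makes
  the loop amplify without bound.
* **Death-linked release.** Starving producer cells lyse and return their
  amino-acid stores to the medium. Without this term, a well that tips
  into resource deficit crashes wholesale at dilution speed
  (about $-\ln 10$ per batch, $\approx 7$ natural-log units per week),
  faster than a weekly rescue protocol can possibly act; with it, declines
  are graded and strain-by-strain, which is what plate-scored data show.

The cheater's advantage has two faces, both parameterized: it pays no
over-production cost ($c = 0$ versus $c = 0.18$ for mutualists) and it
handles lysine scarcity better — a lower starvation death rate
(0.005 h⁻¹ versus 0.03 h⁻¹) and a lower half-saturation constant
(`cheaterK` = 0.4 versus 1), i.e. it scavenges scarce lysine more
efficiently. The scavenging advantage matters structurally: it lets the
cheater squeeze the AdeOPs out strain by strain while LysOPs and the
cheater itself remain scorable, instead of starving whole wells at once.

### Stochasticity

Three noise sources act, each at a biologically distinct point:

1. **Environmental jitter** (`sigmaEnv`, default 0.5): each (well, strain,
   batch) draws an i.i.d. lognormal factor on its growth rate. This stands
   in for the minor phenotypic variation and micro-environmental
   fluctuation that make near-equivalent strains drift apart. It is i.i.d.
   across strains, so within-guild exchangeability holds exactly: which of
   the four AdeOPs is lost first is uniform over replicates (a property
   test checks this with a chi-square test over several hundred simulated
   wells). Setting `sigmaEnv = 0` recovers a model whose only noise is
   demographic.
2. **Transfer thinning**: the cells carried into fresh medium are a Poisson
   draw with mean `dilution × N`. Extinction is therefore absorbing —
   Poisson(0) = 0 — and the last phase of every extinction is genuinely
   demographic.
3. **Plating**: weekly colony counts are Poisson in the plated volume, so
   scored "gone" can flicker at the detection boundary even while a few
   cells persist in the well; true extinction is absorbing, observed
   extinction is an estimate.

### Demographic scale

Densities are tracked as cell numbers with a configurable conversion of
`cellsPerOD` = 2×10⁵ cells ml⁻¹ per 1.0 OD600 — deliberately about two
orders of magnitude below a physical yeast culture. This is a scaled-down
demographic rendering: it places the Poisson extinction boundary and the
10-µl plate counts on scales where both are resolvable in a simulation of
a few seconds, while every analysed statistic (scores, diversities,
dissimilarities, proportions) depends only on abundance ratios. The
conversion is a single configuration entry for users who want a different
scale.

### Calibration of the defaults

The growth, cost and noise defaults were chosen once, by exploratory
simulation, so that the generator sits in the regime the synthetic system
is known to occupy: all strains present at Week 2 with several near
extinction; random within-guild species loss accumulating in isolated
mutualist-only wells; cheater-driven exclusion of AdeOPs followed by
whole-community collapse in isolated exploited wells, while dispersal keeps
exploited communities alive; and faster beta-diversity divergence among
isolated than among dispersal-allowed communities. At the defaults,
isolated exploited communities collapse in roughly a third of wells by
the end of the 8-week run and dispersal-allowed ones about three times
less often — the
directional structure
is robust (it holds in ≈19/20 replicate experiments), though the absolute
collapse proportions are milder than a wet system with stronger cheaters
would show. These are the study conditions for all stochastic tests; they
are not tuned per test.

## The directed-dispersal protocol

From the Week-2 scoring onward (when low-density strains first appear),
each weekly scoring triggers the rescue algorithm in dispersal-allowed
wells only:

* **Sinks** (`findSinks()`): any (well, strain) with 1–19 colonies — the
  "very weak, below 20 colonies" extinction trajectory. Strains already at
  0 colonies are *not* rescue-eligible (reintroduction targets strains
  that are going extinct, not gone); the `rescueExtinct` flag flips this.
* **Sources** (`findSource()`): a uniformly random dispersal-allowed well
  of the *same plate* where the strain scores strong; if none exists the
  event is skipped and logged.
* **Inoculum** (`applyDispersal()`): 10 % of the average strain density in
  the sink right after the next transfer. "Average" is taken over the
  strains actually present (density > 0) — an average over all panel
  strains would be diluted by extinct ones; the `meanOverPresent` flag
  switches to the all-strain mean. The cheater participates in dispersal
  like any other strain (it can be excluded by filtering the event log).
* **Recovery** (`checkRecovery()`): the event counts as recovered when the
  strain scores strong in the sink two days (one batch) later.

## From ordinal scores to diversity

The weekly scores are ordinal; diversity needs numbers. The default map is
geometric — gone 0, micro 1, very weak 10, weak 100, strong 1000 —
reflecting that successive tiers correspond to roughly tenfold density
bands. Any strictly increasing map with gone = 0 is accepted, and
`scoreSensitivity()` recomputes alpha and beta diversity under alternative
maps and reports Spearman rank correlations with the default, so users can
check that conclusions do not hinge on the choice (rank correlations are
high for geometric variants; a linear map reweights tiers more
aggressively). Colony counts can be used directly instead
(`source = "count"`).

Alpha diversity is the Hill number of order $q$; the analyses use $q = 1$,
the exponential of Shannon entropy (natural log — Hill numbers are
base-invariant), i.e. the effective number of common strains.
A collapsed community has no defined Hill diversity; in group comparisons
it is coded as 0 effective species, which keeps group means defined and
reflects the biology.

Beta diversity is abundance-based Bray–Curtis,
$\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, computed with `vegan::vegdist`
behind `pairwiseBeta()`; collapsed communities are excluded from pairwise
comparisons with a logged note. NMDS (`runNMDS()`) wraps
`vegan::metaMDS`/`monoMDS`: 2-D, weak (ties-averaged) monotone regression,
random restarts with the best stress-1 solution reported, seeded.

## The null model and standardized effect sizes

To separate deterministic from stochastic assembly, observed beta
diversity is compared to a randomization null (`randomizeMatrix()`,
`sesBeta()`). The scheme fixes, for every community independently, its
richness and its multiset of nonzero abundances — hence its alpha
diversity — and redraws *which* strains carry those abundances uniformly
from the pool. This is the weakest constraint that isolates beta-diversity
structure: if strain identities are interchangeable (random species loss),
the observed dissimilarities should look like the null's. The standardized
effect size is

$$\mathrm{SES} = (\mathrm{mean}_{obs} - \mathrm{mean}_{null}) /
  \mathrm{s.d.}_{null}$$

over 1000 randomizations by default, reported both for the mean pairwise
dissimilarity and per community pair (each pair against its own null
distribution). A more constrained alternative (quantitative swap
preserving strain totals and fill, via vegan's `swap_count`) is available
as `method = "swap"` for sensitivity.

Self-calibration: on data generated *by the null itself* the mean SES must
sit near 0 and about 5 % of per-pair SES values outside ±1.96. The
acceptance suite runs this with 200 self-null datasets of 20 communities ×
8 strains at 1000 randomizations each.

Per-pair SES values are tested against 0 with both a one-sample t-type
test and a Wilcoxon signed-rank test (`sesTest()`); both are reported
because both are common in this role, the rank test being the conservative
default for skewed SES distributions. Degenerate inputs (constant values,
n = 2) are flagged rather than silently trusted.

## Permutation inference in place of mixed models

Treatment and trend effects in plate experiments are classically analysed
with (Bayesian) GLMMs carrying plate and pair random effects. This package
deliberately substitutes design-respecting permutation tests: the targets
of inference — group differences and trend signs — are preserved, the
tests are exact under exchangeability, dependency-light, and directly
testable for calibration. This is a methodological substitution, not a
reproduction of any particular mixed-model fit.

* `alphaComparison()`: difference in mean alpha between treatments, with
  treatment labels shuffled *within plates* — the stratification plays the
  role of the plate random effect. If a plate carries one treatment only,
  it falls back to a global shuffle with a warning.
* `betaTrend()`: least-squares slope of pairwise beta diversity on week,
  with week labels permuted *within each pair-ID block* — preserving the
  dependence of repeated measures on the same community pair, the role of
  a pair-ID random effect. P-values are two-sided,
  $(\mathrm{hits}+1)/(n_{perm}+1)$.

Both tests are calibrated: under their simulated nulls (1000 replicates,
199 permutations each) the type-I error at nominal 0.05 falls in
[0.03, 0.07] — the acceptance suite checks exactly this.

## Persistence and the headline checks

`persistenceCurve()` tabulates, per week × community type × treatment, the
proportion of communities retaining each number of strains; a community is
collapsed when every strain is gone. The alternative *functional* notion —
an exploited community is doomed once all four AdeOPs are gone, even
though other strains linger a few transfers — is available as
`collapse = "functional"`.

`headlineSigns()` condenses one simulated experiment into the three
directional findings the pipeline exists to test: (a) by the end of the
experiment, isolated exploited communities have collapsed more often than
dispersal-allowed ones (which stay near
zero); (b) Week-7 alpha diversity is higher under dispersal in both
community types; (c) beta diversity among isolated mutualist-only
communities diverges faster over time than among dispersal-allowed ones.
The acceptance suite asserts each sign in at least 18 of 20 replicate
simulated experiments. At the calibrated defaults the dispersal-allowed
beta trend, while several-fold flatter than the isolated one, remains
slightly positive (some strain loss escapes rescue between weekly
checks), so its permutation p-value is often small; the assertion is the
slope ordering, not a zero slope.

## Numerical choices

* Euler integration at `dt` = 0.1 h; a test compares one batch against an
  independently coded reference integrator at `dt` = 0.005 h and requires
  agreement within 5 %.
* Per-step growth is rescaled when a resource pool would be overdrawn;
  pools and densities are clipped at 0 (mass error at most one step's
  flux).
* Degenerate inputs are flagged, not guessed: all-zero communities give
  `NA` diversity; `sd_null` = 0 gives an undefined SES with a warning;
  all-equal dissimilarity matrices return a non-converged NMDS fit.
* Problem sizes in the test and acceptance suites — 20 replicate
  experiments for the sign checks, 200 self-null datasets, 1000
  calibration replicates, several hundred wells for the exchangeability
  test — were chosen as the smallest sizes at which the checked
  probabilities are estimated with comfortably sub-threshold standard
  errors.

## What the generator does and does not emulate

The simulator reproduces the *statistical structure* the analysis chain
assumes: ordinal weekly scores with detection noise, random within-guild
loss, across-well heterogeneity that makes sources available where sinks
appear, cheater-driven exclusion, obligate collapse, and a rescue effect
of directed dispersal. It does not emulate: evolution of the strains
(competitiveness or cheating resistance), contamination of blanks, plate
position effects, medium chemistry beyond two resource pools, within-well
spatial structure, or the two-day YPD outgrowth of source strains before
reintroduction (treated as an instantaneous inoculum of the computed
size). Passing the suite therefore shows that the *analysis chain* behaves
correctly on data with this structure — not that the growth model is a
quantitative fit to any particular wet system; absolute collapse
proportions, recovery rates and event counts are expected to differ from
wet data.

## Reproducibility

Every stochastic entry point takes a seed and restores the caller's RNG
state; `runExperiment()` is bit-reproducible given (layout, parameters,
seed), and every CLI output directory carries a manifest with the
configuration, its MD5 hash and the seed needed to regenerate the run.
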
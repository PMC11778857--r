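# MetaMutualism

Simulation and analysis of directed dispersal in exploited microbial
mutualisms.

`MetaMutualism` is for community ecologists and microbial-ecology
modellers who work with synthetic cross-feeding communities under serial
transfer. It provides, as one tested pipeline:

* a stochastic consumer–resource simulator of obligate adenine/lysine
  cross-feeding yeast communities (4 adenine over-producers, 4 lysine
  over-producers, 1 lysine cheater) grown in 48-well plates with 1:10
  transfers every 48 h and weekly ordinal plate scoring
  (*strong / weak / very weak / micro / gone*);
* the directed source-to-sink dispersal (rescue) algorithm: strains at
  1–19 colonies in a dispersal-allowed well receive 10 % of the mean
  present-strain density from a same-plate well where they are strong,
  with recovery assessed two days later;
* the analysis chain for the resulting observation tables.

The statistics at the core are

* alpha diversity as Hill numbers,
  $^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}$, with
  $^1D = \exp(-\sum_i p_i \ln p_i)$ (effective number of common strains);
* abundance-based Bray–Curtis dissimilarity
  $d(x, y) = \sum_i |x_i - y_i| \,/\, \sum_i (x_i + y_i)$, with 2-D NMDS
  ordination (Kruskal stress-1, monotone regression, random restarts);
* a richness-preserving null model (per community: richness and abundance
  multiset fixed, strain identities redrawn) with standardized effect
  sizes $\mathrm{SES} = (\mathrm{mean}_{obs} -
  \mathrm{mean}_{null})/\mathrm{s.d.}_{null}$ over 1000 randomizations;
* persistence/collapse summaries and design-respecting permutation tests:
  plate-stratified label shuffles for treatment effects on alpha
  diversity, and pair-ID-blocked week shuffles for beta-diversity-over-time
  trends.

The methods vignette (`vignettes/metamutualism-methods.Rmd`) documents the
growth model, the stochasticity, the dispersal protocol and every design
decision in detail.

## Worked example

Simulate the default design (168 experimental communities: 84
mutualist-only, 84 exploited; half isolated, half dispersal-allowed) for
8 weeks under the directed-dispersal policy, then extract the three
headline comparisons at the Week-7 endpoint:

```r
library(MetaMutualism)

lay <- buildLayout(seed = 1)
exp <- runExperiment(lay, policy = "directed", seed = 1)
exp
#> MutualismExperiment: 8 scored weeks, 192 wells, policy = directed
#>    13824 observation records, 1127 dispersal events (seed 1)

hs <- headlineSigns(exp, finalWeek = 7, nPerm = 199, seed = 1)
round(hs$collapse, 3)          # exploited communities collapsed by week 8
#> dispersal_allowed          isolated
#>             0.119             0.286
lapply(hs$alpha, round, 2)     # mean Hill q=1 alpha at week 7
#> $exploited
#> dispersal_allowed          isolated
#>              4.08              3.35
#> $mutualist_only
#> dispersal_allowed          isolated
#>              5.20              4.13
round(hs$slopes, 4)            # beta-diversity change per week
#>          isolated dispersal_allowed
#>            0.0325            0.0062
```

Reading these numbers: isolated exploited communities collapse well over
twice as often as dispersal-allowed ones (28.6 % vs 11.9 %); dispersal
raises the
effective number of strains at Week 7 in both community types (4.08 vs
3.35 effective strains in exploited communities); and beta diversity among
isolated communities drifts upward five times faster than among
dispersal-allowed ones (0.033 vs 0.006 Bray–Curtis units per week) — the
rescue effect homogenizes the meta-community.

The null model asks whether community assemblages differ from random
strain occupancy with the same richness structure:

```r
m   <- abundanceMatrix(exp, week = 7)
iso <- attr(m, "community_type") == "mutualist_only" &
       attr(m, "treatment") == "isolated"
sesBeta(m[iso & rowSums(m) > 0, ], nRand = 1000, seed = 1)
#> SESResult: mean_obs = 0.5183, mean_null = 0.5693, sd_null = 0.0066
#>   SES = -7.7513 over 1000 randomizations (861 pairs)
```

Here observed assemblages are *more* similar than the null expects
(negative SES): in the simulated system every surviving community keeps
the same deterministic backbone (both producer guilds), a structure the
identity-shuffling null does not condition on.

A full analysis — alpha tests, persistence curves, per-treatment trends,
SES and NMDS — is one call (`analyzeExperiment(exp)`), and the same
pipeline runs from the shell via the launcher in `exec/`:

```sh
exec/metamutualism simulate --seed 1 --out run1
exec/metamutualism analyze --obs run1/observations.csv \
    --layout run1/layout.csv --seed 1 --out run1/analysis
exec/metamutualism report --obs run1/observations.csv \
    --layout run1/layout.csv --seed 1 --out run1
```

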
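Package: MetaMutualism
Title: Simulation and Analysis of Dispersal in Exploited Microbial Mutualisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how directed dispersal affects the persistence
    and stability of obligate cross-feeding microbial communities exploited by
    a cheater. Provides a stochastic consumer-resource simulator of
    adenine/lysine over-producing yeast communities under 48-hour serial
    transfer with weekly ordinal plate scoring, a directed source-to-sink
    dispersal (rescue) algorithm, Hill-number alpha diversity, Bray-Curtis
    beta diversity with a richness-preserving null model and standardized
    effect sizes, nonmetric multidimensional scaling, persistence/collapse
    summaries, and stratified permutation inference for treatment and trend
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    vegan,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
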
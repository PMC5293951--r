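Package: mutdiv
Title: From Mutation Rate to Diversification Rate: Fixation, Incompatibility
    and Lineage Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative chain linking per-generation mutation
    rates to macroevolutionary diversification rates. Implements Wright-Fisher
    simulation of allele frequencies under deterministic demographic change and
    the general fixation-probability formula for time-varying effective
    population size, with exact absorbing-Markov-chain and Kimura closed-form
    references; substitution-rate, dN/dS and Kr/Kc predictions across
    demographic scenarios; Dobzhansky-Muller incompatibility accumulation on a
    holey adaptive landscape (snowball condition, interbreeding probability,
    geometric waiting time to reproductive isolation); and an event-driven
    lineage simulator that maps waiting times to isolation, secondary contact
    and complete reproductive isolation onto reconstructed phylogenies with
    Newick output and diversification-rate summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
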
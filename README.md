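# mutdiv

**From mutation rate to diversification rate: Wright–Fisher fixation,
incompatibility accumulation, and lineage simulation.**

Comparative studies keep finding that lineages with faster molecular
evolution are more species-rich. `mutdiv` is for researchers in molecular
evolution and macroevolution who want that observation as runnable,
testable quantitative machinery rather than a verbal argument. It
implements each link of the chain:

1. **Mutation → substitution.** The fixation probability of a new mutation
   under deterministic demographic change,

   *P*<sub>fix</sub> = (1 − E[e^(−4*N*<sub>e</sub>*s* *X*(*T*))]) / (1 − e^(−4*N*<sub>e</sub>*s*)),

   evaluated by Wright–Fisher Monte Carlo (`fixation_probability()`), with
   Kimura's constant-size closed form and an exact absorbing-Markov-chain
   solver (`exact_matrix_fixation()`) as built-in references. From it:
   substitution rates (2*N*<sub>e</sub>*u* *P*<sub>fix</sub>), dN/dS and
   Kr/Kc predictions across demographic scenarios
   (`substitution_rate_grid()`). The neutral substitution rate stays equal
   to *u* *N*<sub>e</sub>/*N* no matter how the population grows or
   shrinks — the package's central invariance.

2. **Substitution → reproductive isolation.** Dobzhansky–Muller
   incompatibilities on a holey adaptive landscape: linear (ε*d*) versus
   snowball (ε*d*(*d*−1)/2) accumulation, the ε < ln *L*/*L* snowball
   condition, the (1−ε)^*d* interbreeding probability, and the geometric
   waiting time of 1/ε substitutions to complete isolation
   (`landscape_model()`, `ri_substitution_distribution()`,
   `fit_epsilon_and_exponent()`).

3. **Reproductive isolation → diversification.** An event-driven lineage
   simulator over the waiting times to isolation (*T*<sub>I</sub>),
   secondary contact (*T*<sub>S</sub>) and complete RI (*T*<sub>R</sub>),
   with fusion, reinforcement and extinction outcomes at contact;
   reconstruction of the molecular phylogeny the true history implies
   (`simulate_history()`, `reconstruct_tree()`, Newick output via `ape`);
   and a sweep coupling *T*<sub>R</sub> = *k*/*u* to the mutation rate
   (`sweep_mutation_rate()`).

## Worked example

```r
library(mutdiv)

# a population crashing to 10% of its size over 200 generations
prof <- demography_profile(n0 = 1000, ratio = 0.1, duration = 200)

# slightly deleterious mutations fix far more easily in the crash ...
f_del <- fixation_probability(-0.001, prof, n_replicates = 100000, seed = 7)
f_del
#> Fixation probability: 0.000364334 (method: monte_carlo, MC std. error 2.58e-05)

# ... while the neutral substitution rate stays pinned to the mutation rate
f_neu <- fixation_probability(0, prof, n_replicates = 100000, seed = 8,
                              method = "monte_carlo")
substitution_rate(1e-8, prof, f_neu)
#> Substitution rate: 9.894e-09 (u = 1e-08, ln(rate/u) = -0.0107)   # ~0

# dN/dS rises toward 1 in the declining population (relaxed drift barrier)
f_del$p_fix / f_neu$p_fix                  # 0.736 under decline
dnds_ratio(demography_profile(1000))       # 0.075 at constant N = 1000

# time to speciation if 1 in 50 substitutions is incompatible
expected_time_to_ri(0.02, substitution_rate(1e-8, prof, f_neu)$substitution_rate)
#> [1] 5053567819   # generations: ~50 substitutions / (neutral rate ~ u)

# a lineage history in which isolation always completes RI: the
# reconstructed phylogeny doubles every t_i generations ...
p <- regime_parameters(t_i = 100, t_s = 1e6, t_r = 50,
                       timing_mode = "fixed", total_time = 450)
tr <- reconstruct_tree(simulate_history(p, seed = 1))
ape::write.tree(tr)
#> ((((L1:50,L9:50):100,(L5:50,L10:50):100):100,...):100;   # 16 tips

# ... and the branching-based speciation-rate estimate reads off 1/t_i
unlist(diversification_estimate(tr)[c("lambda", "n_tips", "crown_age")])
#>    lambda    n_tips crown_age
#>  0.007922   16.0000  350.0000    # ln(16)/350 ~ 1/t_i = 0.01
```

Interpretation: in the declining population the deleterious class fixes at
73.6% of the neutral rate (versus 7.5% at constant size 1000) while the
neutral log rate-ratio sits at −0.011 ± 0.026 — indistinguishable from 0.
With ε = 0.02 and neutral divergence at the mutation rate, complete RI
takes on the order of 50/*u* generations, and when RI completes before
secondary contact the phylogeny's internode lengths equal the isolation
interval exactly.

## Command line

A thin CLI over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mutdiv.R", package = "mutdiv"))')
Rscript $CLI grid      --seed 1 --out out/            # scenario x Ne x s table
Rscript $CLI landscape --epsilon 0.02 --out out/      # holey-landscape report
Rscript $CLI lineages  --config regime.yml --out out/ # trees.nwk + event log
Rscript $CLI fixtures  --kind snowball_table --out out/
```

All subcommands are byte-reproducible under `--seed`, validate before
writing anything, and leave a manifest TSV beside their outputs.

## Documentation

The methods vignette
(`vignettes/mutation-to-diversification.Rmd`) documents the three model
layers, every tunable parameter with its default and rationale, the
numerical choices (tolerances, tie-breaks, seed derivation), the sweep
study conditions, and what the synthetic data can and cannot establish
about real systems.
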
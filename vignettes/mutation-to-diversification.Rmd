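---
title: "From mutation rate to diversification rate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From mutation rate to diversification rate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutdiv)
set.seed(1)
```

`mutdiv` implements, as tested simulation and closed-form code, the causal
chain that comparative studies invoke when they correlate genome-wide
mutation rates with species richness: mutations become substitutions at a
rate set by fixation probabilities; substitutions accumulate
incompatibilities between isolated populations; incompatibilities complete
reproductive isolation (RI); and the tempo of RI relative to population
isolation and secondary contact determines what a reconstructed phylogeny —
and hence a diversification-rate estimate — can see. This vignette documents
the three model layers, the parameters that matter, the numerical choices,
and what the simulations do and do not establish.

## 1. Fixation under changing population size

A new mutation in a diploid population of census size $N$ starts at
frequency $x_0 = 1/2N$. Its frequency evolves by Wright–Fisher binomial
resampling with genic selection: with current frequency $x$ and selection
coefficient $s$, the sampling probability for the next generation of $2N'$
gene copies is

$$p^\* = \frac{x(1+s)}{1+xs},$$

with 0 and 1 absorbing. The probability that the mutation eventually fixes
when the population changes size deterministically over $T$ generations and
is constant thereafter is

$$P_{fix} \;=\; \frac{1 - E\left[e^{-4N_e s X(T)}\right]}{1 - e^{-4N_e s}},$$

where $X(T)$ is the (random) frequency at the end of the change and $N_e$
is the *final* effective size. The logic: after $T$ the population is
constant, so conditioning on $X(T)$ reduces the problem to Kimura's
constant-size formula, and $P_{fix}$ is its expectation over $X(T)$.
`fixation_probability()` evaluates the expectation by Monte-Carlo
simulation of replicate trajectories (`simulate_frequency_at_T()`); the
default replicate count is 500,000, and the standard error is propagated
from the replicate mean of $e^{-4N_e s X(T)}$ (the map is linear, so the
delta method is exact).

Three special branches avoid degenerate numerics:

* $s = 0$ makes the formula $0/0$; the neutral limit $P_{fix} = E[X(T)]$
  is used instead, which by the martingale property of neutral resampling
  equals $x_0$.
* Constant-size profiles return Kimura's closed form
  $(1 - e^{-4N_e s x_0})/(1 - e^{-4N_e s})$ directly (no simulation),
  computed through `expm1` so that tiny exponents do not lose precision.
* For small populations ($2N \le 200$), `exact_matrix_fixation()` solves
  the absorbing Markov chain on allele counts by a dense linear solve —
  the exact reference against which both the Monte-Carlo and closed-form
  routes are tested.

Demography is a `demography_profile(n0, ratio, duration, shape,
ne_over_n)`: census size interpolates from `n0` to `round(n0 * ratio)` over
`duration` generations, linearly by default (exponential optionally —
the endpoints and durations are what is specified; the interpolation
between them is a modelling choice). Sizes are rounded to integers and a
trajectory that dips below 2 individuals is rejected. `ne_over_n` ties
effective to census size with a constant factor (default 1).

The standard scenario set used throughout (`standard_scenarios()`) is:
constant size; growth to 1.9× over 20 (fast) or 200 (slow) generations;
decline to 0.1× over 20 or 200 generations.

### Substitution rates and rate ratios

The long-run substitution rate is the mutational input times the fixation
probability, $2 N_e u P_{fix}$, with $N_e$ taken at the mutation's origin.
For neutral mutations this collapses to $u N_e/N$ — equal to the mutation
rate itself whenever $N_e = N$, *regardless of demographic history*. That
invariance is the package's headline reproduction: the log rate-to-mutation
ratio for the neutral class stays at 0 across all five demographic
scenarios, within Monte-Carlo error.

Rate-ratio predictions follow as fixation-probability ratios at matched
demography: `dnds_ratio()` uses $s = -0.001$ (slightly deleterious,
non-synonymous proxy) over $s = 0$; `krkc_ratio()` uses $s = -0.01$
(radical) over $s = -0.001$ (conservative). Both lie in $(0, 1]$ for the
negative-$s$ classes and decline with $N_e$, the radical/conservative
contrast much faster — so across a population-size gradient the
radical-to-conservative ratio is the more sensitive diagnostic, while
dN/dS can look nearly flat in the same range.

`substitution_rate_grid()` sweeps scenario × size × selection class and
reports everything in one tidy table. Each cell draws its seed from the
master seed by a Lehmer-generator split (`derive_seeds()`), so any cell can
be recomputed alone.

## 2. Incompatibilities on a holey landscape

Between two populations separated by $d$ substitutions, each substitution
is incompatible with the other population's background with probability
$\varepsilon$. Two accumulation laws are implemented
(`incompatibility_count()`):

* *pairwise linear*: incompatible alleles come in functional pairs, and the
  expected count is $\varepsilon d$;
* *snowball*: every derived allele can conflict with every other, giving
  $\varepsilon d(d-1)/2$ — quadratic growth.

With $L$ mutational targets, a genotype has $L(1-\varepsilon)$ expected
viable one-substitution steps (`expected_paths()`); quadratic accumulation
is sustainable only when $\varepsilon < \ln L / L$
(`snowball_condition()`), so genomes with more targets need a smaller
per-substitution risk.

Under the simplest RI trigger — any one incompatible substitution causes
complete RI — the isolating substitution index is geometric:
$P(k) = (1-\varepsilon)^{k-1}\varepsilon$, mean $1/\varepsilon$
substitutions, and the probability that populations still interbreed at
divergence $d$ is the survival function $(1-\varepsilon)^d$. Dividing
$1/\varepsilon$ by the per-pair substitution rate converts it to
generations (`expected_time_to_ri()`); with neutral divergence the
substitution rate is the mutation rate, which is the coupling the lineage
simulator exploits. Because the calculation starts the clock at zero
divergence and ignores standing variation, it should be read as an upper
bound on the expected time.

### Estimating $\varepsilon$ and the accumulation exponent

`fit_epsilon_and_exponent()` fits the power law $\text{count} = a d^b$ by
least squares on the log scale (zero counts dropped; a Poisson-regression
engine with log link is available for tables with many zeros, and keeps
them). The exponent $b$ is the continuous measure of how much faster than
linear incompatibilities accumulate; $\varepsilon$ is recovered from $a$
under the declared law ($a = \varepsilon$ pairwise, $a = \varepsilon/2$
snowball). One subtlety is deliberate: the exact snowball expectation
$\varepsilon d(d-1)/2$ is *not* a pure power of $d$, and its fitted
log–log slope over $d = 10..100$ is about 2.03, not 2. The fixture
generator (`make_incompatibility_table()`) therefore offers both the exact
pair-count form (`form = "pairs"`, the default, used by the fixtures CLI)
and the asymptotic power-law form (`form = "power_law"`), which is the
right input for exact parameter-recovery checks of the regression itself.

## 3. Lineages, trees and diversification

`simulate_history()` runs an event-driven birth–merge–extinction process
governed by three waiting times:

| parameter | meaning | units |
|---|---|---|
| `t_i` | expected wait between population-isolating events, per lineage | generations |
| `t_s` | expected wait from a split to secondary contact of the pair | generations |
| `t_r` | expected time for a pair to complete RI | generations |

Waits are exponential by default (`timing_mode = "exponential"`) or
deterministic (`"fixed"`); the deterministic mode is what makes the
sharp regime signatures exactly checkable. `t_r` can instead be *coupled*
to molecular evolution: the isolating substitution count $k$ is drawn from
the geometric distribution above and $T_R = k/u$, with $u$ the neutral
per-pair substitution (mutation) rate.

Every split schedules a contact time and an RI time for the sister pair.
If RI completes first, later contact is inconsequential — the pair are
species. If contact arrives first, the outcome is sampled from
`contact_outcomes`: **fuse** (the pair merges back into one lineage; the
period of isolation leaves no trace and divergence restarts from zero),
**reinforce** (selection against unfit hybrids completes RI on the spot),
or **extinction** of one or both populations through wasted reproductive
effort. The defaults (0.5, 0.25, 0.05, remainder fuse) are free parameters
of the model, not estimates. Contact is pairwise between the two sides of
a split; spatial arrangement (a middle population touching two neighbours)
is not modelled. The simulation stops at `total_time`; a `max_lineages`
cap marks the history `truncated` rather than erroring.

`classify_regime()` names the qualitative outcomes: `isolation_completes_ri`
($t_s \ge t_r$), `fusion_latest_split_only` ($t_r/t_s \ge$ `far_factor`,
$t_i \ge t_s$), `chained_isolation` ($t_r/t_s \ge$ `far_factor`,
$t_i < t_s$), and `partial_ri_contact` otherwise. "Much greater" has no
canonical cutoff; `far_factor = 10` is the documented default and is
configurable. Ties go to the first-listed label at each comparison.

### Tree reconstruction

`reconstruct_tree()` builds the phylogeny a perfectly accurate molecular
analysis would recover at an observation time: tips are the populations
then extant; each isolating event whose two descendant branches both lead
to extant populations is a node at the split time. Fusion erases history —
when a pair merges, the merged lineage inherits the fused partner's
children (their divergence dates from their own splits, which is what the
sequences would record) and the collapsed split is never a node. Splits
whose descendants all died are pruned. Trees are ultrametric at the
observation time; the stem from time 0 to the first visible split is kept
as the `root.edge`. A split occurring exactly at the observation time is
not yet observable (strict inequality), which keeps all branch lengths
positive. Newick serialization uses 15 significant digits so trees
round-trip through standard readers to within $10^{-9}$.

Two consequences are worth stating because the tests rely on them:

* In the RI-first regime with fixed timing, every internal edge equals
  `t_i` exactly, and lineages double every `t_i` generations.
* In the fast-fusion regime (`t_s < t_i`, RI far away, fusion certain),
  the reconstructed tree has exactly two tips whose split is the *latest*
  isolating event — provided the observation falls before that pair's
  contact, i.e. `total_time mod t_i < t_s` under fixed timing; observing
  just after a fusion shows a single unbroken lineage instead.

### Diversification rate, and which age to divide by

`diversification_estimate()` uses the pure-birth estimator
$\hat\lambda = \ln(n)/\text{age}$, robust at small $n$. Two age
conventions are provided. `age = "crown"` (default) divides by the time
since the first visible split — the only age available when all you have
is a reconstructed tree, and the convention under which the Yule-regime
estimate is consistent with $1/t_i$. `age = "stem"` divides by the full
history length (crown age plus root edge).

`sweep_mutation_rate()` uses the stem convention, for a reason that an
early design iteration made vivid: the crown age is *endogenous* to the
RI-versus-contact race being swept. When fusion erases early splits, low
mutation rates produce both fewer tips and younger crowns, and
$\ln(n)/\text{crown}$ turns out to be nearly invariant to $u$ — the two
effects cancel almost exactly. Measured against the fixed observation
window, the rate cleanly tracks the tip count, which is the quantity the
mutation rate actually drives. Single-survivor histories contribute
$\hat\lambda = 0$; histories with no survivors are excluded.

### Sweep study conditions

The packaged mutation-rate sweep uses, and its tests freeze, the following
conditions: $t_i = 3000$, $t_s = 12000$ (environment-driven contact,
independent of $u$), observation window 15,000 generations, lineage cap
256, exponential timing, contact before RI always fusing
(reinforcement and extinction off, so the RI-versus-contact race alone
decides speciation — the mechanism under test), $\varepsilon = 0.05$, and
five mutation rates spanning $10^{-3}$ to $10^{-2}$ (a 10× range), 500
histories each. With these values the per-split probability that RI beats
contact, $E[e^{-T_R/t_s}]$, rises from about 0.37 to about 0.86 across the
grid — large enough that the mean rate over 500 histories orders the five
mutation rates correctly with high probability, small enough that no part
of the grid is saturated. These sizes also keep the sweep under a minute
of CPU; they are stated here so results can be reproduced exactly.

```{r sweep-example, eval = FALSE}
base <- regime_parameters(
  t_i = 3000, t_s = 12000, t_r = 1, timing_mode = "exponential",
  contact_outcomes = c(reinforce = 0, extinct_one = 0, extinct_both = 0),
  total_time = 15000, max_lineages = 256)
sweep_mutation_rate(10^seq(-3, -2, length.out = 5), epsilon = 0.05,
                    base, n_histories = 500, seed = 1)
```

## What the synthetic data does and does not show

The generators emulate the *study conditions* of the theory: deterministic
demography with a single selection coefficient per mutation class;
divergence as a clean substitution count with one constant $\varepsilon$;
isolation, contact and RI as memoryless (or fixed) waits homogeneous over
lineages and time. Real data violate most of this — selection coefficients
are drawn from continuous distributions, $\varepsilon$ differs across
substitution classes and lineage pairs, waiting times drift with
environment and geography, phylogenies are estimated with error rather
than read off the true history, and standing variation shortens real RI
times. Passing tests therefore establish that the implementation agrees
with the mathematics it encodes, and that the qualitative orderings
(deleterious fixation faster under decline; snowball dominating pairwise;
diversification rising with mutation rate when contact is
environment-driven) follow from those assumptions — not that any
particular empirical system obeys them.

## Numerical choices and limitations

* Census sizes are rounded to integers, floored at 2 by validation.
* Replicate counts in tests are scaled to 20,000–100,000 (against 3-SE
  tolerances) so the suite runs in minutes; the 500,000-replicate default
  remains for production use.
* Monte-Carlo vs closed-form agreement at constant size is tested on
  profiles held constant for 50 generations, so the simulated $X(T)$
  genuinely varies; at that horizon the discrete-chain vs diffusion bias
  is far inside the Monte-Carlo error at the tested sizes.
* The event queue is a simple scan (adequate to a few thousand events per
  history); per-lineage split times are strictly increasing, and
  same-time events on different lineages are processed in insertion
  order, so fixed-timing histories are deterministic.
* Seeds: every grid cell, history and sweep point derives its own seed
  from the master seed via a Lehmer (MINSTD) stream; all derived seeds
  stay below $2^{31}-1$.
* Not modelled: dominance, linked selection, diffusion-equation solvers,
  sequence evolution on branches, phylogenetic inference error, spatial
  structure, standing genetic variation, selection-accelerated RI (noted
  in the literature as reducing RI time in proportion to $N_e s$; left
  for future work rather than guessed at).
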
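---
title: "Simulating and inferring gene-for-gene coevolution from paired polymorphism data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and inferring gene-for-gene coevolution from paired polymorphism data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfgcoal)
```

## The model

`gfgcoal` simulates antagonistic coevolution between a haploid host and a
haploid parasite at one bi-allelic functional locus per species, under a
gene-for-gene (GFG) infection matrix: one parasite allele (INF) infects every
host, one host allele (res) is susceptible to every parasite, and resistant
hosts (RES) block only non-infective (ninf) parasites. Each discrete host
generation contains two parasite infection cycles with auto-infection (a
parasite re-infects the host it was produced on), so a host infected in the
first cycle stays infected.

Three costs drive the dynamics:

* `s` — cost of infection, paid by a host infected in the first cycle; a
  resistant host that resists the first cycle but receives an infective
  parasite in the second cycle pays the reduced cost `s/2`.
* `c_H` — constitutive cost of carrying RES.
* `c_P` — constitutive cost of carrying INF.

`gfg_step()` implements the resulting one-generation recursions for the
frequencies `R` of RES hosts and `a1` of INF parasites (with the
within-generation second-cycle frequency `a2`). Coevolutionary cycling
requires `s > c_H`; otherwise the susceptible allele fixes and the locus pair
is effectively neutral, which is why very small infection costs are
indistinguishable from neutrality downstream.

The internal equilibrium has the closed form (`gfg_equilibrium()`, with
`s1 = s`, `s2 = s/2`)

$$\hat a = \frac{s_2 + s_1 - \sqrt{(s_2+s_1)^2 - 4 s_2 (s_1 - c_H)}}{2 s_2 (1 - c_H)},
\qquad \hat R = \frac{c_P}{2 - c_P - \hat a},$$

so the parasite equilibrium depends only on the host-side costs (`s`, `c_H`)
and the host equilibrium is driven by the parasite-side cost `c_P`. The
algebraic identity `R_hat * (2 - c_P - a_hat) = c_P` is exact and is tested to
1e-12. The closed form is an approximation to the centre of the coevolutionary
cycles: comparing it with 30,000-generation numerical iteration
(`gfg_iterate()`, started at `R0 = a0 = 0.2`), the infective-allele component
agrees to about 0.05 across the trench-warfare region of the cost grid
(`c_H` in {0.05, 0.1}, `c_P` in {0.1, 0.3}, `s` up to 0.6), while the
host component degrades to gaps of 0.05–0.09 at `c_P = 0.3` with `s >= 0.4`.
That gap is a property of the approximation itself, not of the iteration, and
the corresponding check in the acceptance suite reports it honestly rather
than hiding it. Because cycles may persist, `equilibrium_from_trajectory()`
averages the last 10% of generations instead of taking the terminal point,
which would alias the cycle phase.

## Forward simulation

`simulate_frequency_path()` produces a stochastic allele-frequency path over
`g_max` host generations. Each generation applies, in order:

1. the deterministic recursions (infinite-population expectation),
2. binomial drift: the next allele count is `Binomial(N, freq)` in each
   species at its constant haploid size,
3. recurrent functional mutation: `Binomial` counts of individuals switching
   into and out of the allele class at per-individual rates
   (`mu_Rtor = mu_rtoR = mu_ntoI = mu_Iton = 1e-5` by default).

Mutation is applied after drift as integer switch counts rather than a
deterministic expectation, keeping the state integer-valued and matching the
per-individual interpretation of the rates. The parasite is drifted and
mutated once per host generation, on the carried first-cycle frequency
`a_{g+1,1}`; the second-cycle value is deterministic within the generation.
The recorded path entry is the post-drift, post-mutation count at the start of
each generation — exactly the quantity the backward pass consumes.

One genuinely degenerate corner exists: RES fixed while INF is absent, where
no parasite can reproduce. The deterministic `gfg_step()` raises an explicit
domain error there (the recursion is 0/0). The stochastic simulator instead
carries the frequencies over unchanged — population sizes are constant by
assumption, `R = 1` is the limit of the host recursion as the susceptible
frequency vanishes, and recurrent mutation re-seeds both alleles. Without this
continuation, long arms-race simulations at moderate-to-high `s` would abort
whenever drift loses INF and RES subsequently fixes, a state that genuinely
occurs on the way to the recurrent-sweep regime.

Defaults mirror the study conditions: initial frequencies `R0 = a0 = 0.2`,
`g_max = max(3 N_H, 3 N_P)` generations (long enough for sweep and
balancing-selection signatures to establish), and replicate histories derived
from a master seed via per-replicate child seeds
(`simulate_history_replicates()`), so every replicate is independently
replayable.

## Backward simulation: the conditioned structured coalescent

`simulate_genealogy()` builds the genealogy of `n` sampled haplotypes (drawn
hypergeometrically from the final composition, `assign_sample_classes()`)
backward through the recorded path. Lineages belong to two allelic classes
whose sizes are the recorded integer counts (counts, not frequencies, so there
is no rounding ambiguity). Per generation, every lineage picks a parent
uniformly within its class in the previous generation; identical picks merge.
These are true Wright-Fisher mechanics: simultaneous and multiple mergers
happen automatically when a class bottlenecks, with no special cases. A
lineage's parent sits in the other class with probability
`min(1, mu_fwd * X_other(g-1) / X_own(g))` — the backward shadow of forward
functional mutation, in analogy to gene flow in a two-deme structured
coalescent — and with probability one when its own class is empty in the
previous generation (the origin of the allele: the last lineage migrates to
the other class, which is how recurrent selective sweeps are stitched to the
forward path). Older than the path, all surviving lineages are exchangeable
and coalesce as a discrete-time Kingman process at size `N`, simulated with
geometric waiting times.

The whole backward pass runs in discrete generations rather than rescaled
continuous time: it is exact for the model, costs O(`g_max`) per replicate,
and avoids any time-scaling convention. One backward step is taken per host
generation for both species, matching the resolution of the recorded path;
the parasite's two infection cycles are not resolved within a generation
(the forward model also carries only the per-host-generation state).

Neutral mutations are placed by `drop_mutations()` under the infinite-sites
model: `Poisson(branch length in generations * L * mu_site)` per branch,
uniform positions on [0, 1) in the ms convention. The locus length
(`L = 2500` bp) and the site rate (`mu_site = 1e-7`) enter only through their
product, giving `theta = 2 N L mu_site` (= 5 at `N = 10000`). The neutral
(non-coevolving) model uses the same machinery without conditioning
(`simulate_neutral_snp()`).

## Summary statistics

Each replicate is summarised by 17 statistics (`pair_sumstats()`), all based
on the unfolded site frequency spectrum: per species the number of
segregating sites S, Watterson's `theta_W`, nucleotide diversity `pi`,
Tajima's D, Fu and Li's D and F (unfolded, with the derived singleton class
as the external-branch count), Fay and Wu's `theta_H` and the normalised H
statistic (standardised `pi - theta_L`); plus one cross-species statistic,
the pairwise Manhattan distance (PMD) between the two spectra. Haplotype and
LD statistics are deliberately absent.

Two conventions matter:

* A monomorphic sample (S = 0) returns all eight statistics as 0 rather than
  `NA`, so the average over `r` replicates is always defined — arms-race
  regimes do produce monomorphic samples, and dropping them would bias the
  replicate mean.
* PMD is computed on proportion-normalised spectra,
  `sum_i |xi_Hi / S_H - xi_Pi / S_P|`, with a monomorphic species
  contributing a zero vector. Proportions keep PMD a pure shape contrast
  (bounded by 2, comparable across population sizes) instead of yet another
  theta estimator; the exact normalisation is isolated in
  `pairwise_manhattan_distance()` so an alternative convention is a one-line
  swap.

The ABC datapoint is the elementwise mean of the 17 statistics over `r`
replicate histories (`replicate_average()`), emulating data from repeated
experiments or several equivalent natural populations; averaging integrates
out the drift-driven variability of single histories.

## ABC inference

`scenario_prior()` encodes the two designs: scenario 1 draws
`s ~ U(0.1, 0.9)` and `N_H, N_P ~ logU(2000, 40000)` with known costs
`c_H = 0.05`, `c_P = 0.1`; scenario 2 fixes `N_H = N_P = 10000` and draws all
three costs (`s ~ U(0.1, 0.9)`, `c_H, c_P ~ U(0.01, 0.35)`). The matched
neutral models share the population-size priors (scenario 1) or have no free
parameter (scenario 2). `build_reference_table()` simulates both models'
entries, each itself an `r`-replicate average — the same averaging as the
pseudo-observed data, so reference entries and observations are exchangeable
objects.

Model choice (`model_choice()`) standardises every statistic by its median
absolute deviation over the pooled two-model table, retains the
`ceiling(tolerance * rows)` entries closest in Euclidean distance (1% by
default), and reports each model's share among them. Zero-MAD columns are
dropped with a warning. `cross_validate()` wraps this in leave-one-out
validation and reports the false negative rate (coevolving pairs classified
neutral) and false positive rate (neutral pairs classified coevolving); exact
posterior ties — unavoidable when the retained count is small — are broken by
a fair coin so neither rate is systematically inflated.

Parameter estimation (`estimate_parameters()`) uses the coevolution entries
only: rejection by unnormalised Euclidean distance on the chosen statistic
subset (all 17, host-only 8, or parasite-only 8 — the cross-species PMD only
enters the joint set), then a local-linear regression adjustment of each
retained parameter to the observed statistics, Gaussian kernel smoothing with
width 0.01 on the parameter scale normalised to its prior range, clamping to
the prior support, and the marginal posterior median (computed as the exact
median of the Gaussian mixture). Population sizes are handled on the log
scale throughout, consistent with their log-uniform priors. The adjustment is
a plain unweighted local-linear fit isolated behind this one function; a
weighted or general-linear-model variant can be swapped in without touching
the rest of the pipeline. Constant statistic columns are dropped from the
regression with a warning, falling back to pure rejection if none remain.

## Numerical and design choices

* Double precision with explicit guards against denominators below 1e-300;
  no exact rational arithmetic is needed (the recursions are well
  conditioned away from the degenerate corner).
* Fixation thresholds for classifying dynamics: integer count 0 or N on
  stochastic paths, frequency beyond `1/(2N)` on deterministic trajectories,
  so matched runs get identical labels (`classify_dynamics()`).
* The within-class pairwise coalescence probability is realised by uniform
  parent choice (probability `1/X` per pair), not by a rate approximation.
* Ties in model choice are broken randomly (see above); `which.max` would
  silently favour whichever model is listed first.
* All randomness flows through R's RNG, including the compiled simulators,
  so a single `set.seed()` (or the `seed` fields of the settings objects)
  reproduces any result bit-identically.

## What the generator emulates, and what it does not

The synthetic data emulate SNP samples (50 haploid individuals per species)
at a single non-recombining 2500-bp coevolutionary locus with polarised
ancestral/derived states, under constant population sizes and a strict GFG
interaction with two auto-infection cycles. Real data add complications the
generator deliberately omits: intra-locus recombination, mis-polarised sites,
demographic change and eco-evolutionary feedback on population sizes,
more-than-two-allele interactions, allo-infection, and more than two parasite
generations per host generation. The forward update is pluggable (the
deterministic step is a single function), so alternative within-generation
parasite dynamics can be added, but none are implemented here. Passing tests
therefore demonstrate correctness of the simulator and inference machinery
under the stated model, not robustness of the inference to violations of it.

## Problem sizes used by the test suite and acceptance script

The published experiment runs ~100,000 reference simulations per model with
`r = 30` replicate histories each (population sizes around 10,000 and
`g_max = 3N` generations). The package reproduces that design at reduced
sizes chosen once as desk-scale defaults: reference tables of a few hundred
entries per model, leave-one-out validation of ~100 entries per model,
45-POD recovery grids, and scaled population sizes in pure unit tests. With
1% rejection on a pooled table of ~600 rows, only ~6 neighbours are retained,
so cross-validation error rates are substantially noisier and higher than the
full-scale study's (a nearest-neighbour classifier loses accuracy roughly
with the log of the reference density); the corresponding checks therefore
assert wide Monte-Carlo bands and orderings (more replicates help, accuracy
decays with the cost of infection) rather than the full-scale rates. The
full-scale experiment is available through `run_experiment()` unchanged — the
`g_max` override and all sizes are recorded in the run manifest so a reduced
run can never be mistaken for a full one.

## Known limitations

* The closed-form equilibrium degrades for large `c_P` (see above); use the
  iterated equilibrium when precision matters.
* Fu and Li's and Zeng's statistics assume correct polarisation; the
  simulator provides it by construction, real data may not.
* The neutral Kingman tail treats lineages as exchangeable beyond the
  simulated history, i.e. the functional alleles are assumed selectively
  equivalent older than `g_max` generations.
* The discrete-generation backward pass is exact but O(`g_max`) per
  replicate; very large populations make reference tables expensive
  (the cost is dominated by `g_max = 3N`).
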
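---
title: "The pairsim model: sexual selection, pair bonds, and a closed resource economy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pairsim model: sexual selection, pair bonds, and a closed resource economy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsim)
```

pairsim is an agent-based simulator built to study a single question:
can female mate choice, together with a pair-bond mechanism, trigger and
maintain sympatric speciation in a population that shares one habitat?
This vignette documents the model, its assumptions, every tunable that
matters, and the limits of what the shipped experiments can show.

## The model

**Environment.** Agents live on a connected, undirected graph of nodes
(default: a 4 x 4 torus grid). Space plays exactly one role: an agent
sees, and can therefore pair with, only agents in its own node. Agents
and bonded pairs migrate along edges. Space carries no fitness
information; the "ecological niches" live in *genetic* space.

**Genotype.** Each agent carries a real 2-vector $x$ and a positive
2-vector $\sigma$. For males, $x$ encodes displayed traits; for females,
mating preferences; for both, $x$ is the point at which the fitness
landscape is evaluated. $\sigma$ holds per-coordinate mutation standard
deviations that co-evolve with $x$ (self-adaptation).

**Fitness landscapes.** Four classic multimodal minimization surfaces
(Michalewicz with $m = 10$, Rastrigin, Schwefel, Waves), each on its
standard 2-D domain box. Local minima act as niches. Two typesetting
ambiguities in circulating statements of these benchmarks are resolved
as follows: Schwefel is implemented with the $\sin\sqrt{|x_i|}$ kernel
(the variant with irregularly spaced optima; the known global minimum
$f(420.9687, 420.9687) = -837.9658$ is a test anchor), and the Waves
surface uses the grouping

$$f(x) = -(0.3 x_1)^3 - x_2^2 - 4.5\,x_2^2 x_1 x_2
  - 4.7 \cos(3 x_1 - x_2^2(2 + x_1))\,\sin(2.5 \pi x_1),$$

kept in one function (`waves_function`) as the single point of change
should a different grouping be preferred. Out-of-domain offspring are
clamped to the box edge — the simplest rule that preserves determinism
and the domain invariant (no resampling, no reflection).

**Resource economy and selection.** A fixed total of resource circulates
between an environment pool and the agents; nothing is created or
destroyed, and every test audits this conservation. Selection is
decentralized: each step the environment releases `dispense_rate` of its
pool to agents in proportion to quality weights

$$w_i \propto (\max_j f_j - f_i) + \varepsilon\,(\max_j f_j - \min_j f_j + 1),$$

a linear rescale against the current worst (raw proportionality is
ill-defined for minimization surfaces with negative values) plus a floor
that keeps every weight positive. The floor coefficient used by the
engine (`selection_eps`, default 0.03) sets the income gradient between
niches; the exported `quality_weights()` defaults to a harsher 0.01 for
standalone use. Dispensing is global by default — the environment
evaluates the whole population, and nodes only limit the field of view —
with a `per_node` variant available (pool split equally over occupied
nodes first). In calibration runs the per-node variant drives all
conditions to a single niche, because within-node rescaled weights are
winner-take-all in mixed nodes, so the global form is the default.

Every agent pays a flat upkeep each step (`upkeep` of the nominal
per-capita share, `total_resource / initial_population`). An agent that
cannot cover its upkeep starves and dies that step, returning what it
holds to the pool. This combination — flat cost, proportional income —
is what makes selection lethal: a cost proportional to an agent's own
holding can never outrun income and leaves destitute agents immortal,
freezing the population. Death also occurs at a hard floor
(`death_floor_frac` of the share).

**Reproduction, mate choice, pairs.** An agent is ready to reproduce
when its resource is at least `min_rep_res` (0.5) of the nominal share.
Each step, every ready unpaired female surveys the ready unpaired males
in her node and picks one with probability proportional to
$1/(1 + d)$, where $d$ is the Euclidean distance between her preference
vector and his trait vector; with sexual selection disabled the choice
is uniform. The two form a pair: they migrate together and reproduce —
two offspring per brood, at most one brood per step, only when both are
ready — until the pair is older than `max_pair_age` or a member dies.
`max_pair_age = 0` means pairs dissolve right after their first
reproduction opportunity (serial re-pairing); `max_pair_age >= steps`
means lifelong bonds.

Searching is the costly activity that pair bonds avoid: every step an
unpaired ready agent searches, it pays an absolute cost (`mig_cost` of
the nominal share, capped by its holding), settled after the mating
episode so that a search that succeeds still permits reproduction that
step. A searcher that finds no partner moves to a random neighbouring
node (paying the proportional migration cost) to look elsewhere. The
cost is absolute rather than proportional because roaming takes the same
effort whether the agent is rich or poor — which is exactly what makes
repeated searching lethal for agents in low-income niches, and pair
persistence valuable. An optional `search_success < 1` makes the search
also consume steps; the default leaves it neutral.

Reproduction transfers `female_rep_cost` (0.4) of the mother's and
`male_rep_cost` (0.2) of the father's current resource to the brood,
split equally between the two children — reproduction is costlier for
females, the asymmetry from which sexual selection derives. Each brood
is one daughter and one son by default (`offspring_sex_rule = "coin"`
switches to independent fair coins).

**Variation.** Offspring genotypes come from intermediate recombination
(per-coordinate uniform convex mixing of both $x$ and $\sigma$) with
probability `rec_prob` (0.8), otherwise a copy of one parent; then, with
probability `mut_prob` (0.1), a two-stage self-adaptive mutation:
$\sigma_i' = \sigma_i \exp(\tau_0 \xi + \tau \xi_i)$ with
$\tau_0 = 1/\sqrt{2n}$, $\tau = 1/\sqrt{2\sqrt{n}}$ (the standard
recommendations; $n = 2$), followed by $x_i' = x_i + \sigma_i' \xi_{x,i}$
using the fresh $\sigma'$. The exponential form keeps $\sigma$ positive
forever. Whether $\sigma$ should be recombined even when $x$
recombination is skipped is not settled by theory; here the two are
coupled (a copy copies both). Founders start with $\sigma$ at
`init_sigma_frac` (10%) of each domain width, giving initial mutation
steps commensurate with the landscape scale.

**Scheduling.** One step executes, in fixed order: (a) aging and upkeep
(starvation marked), (b) dispensing, (c) pair aging and dissolution, (d)
mate choice and pair formation (females in seeded random order within
each node), (e) reproduction of ready pairs in formation order, then
settlement of search costs, (f) migration — unsuccessful searchers, then
spontaneous movers (probability `move_prob` per step for unpaired
non-searchers and for pairs), (g) death cleanup. All randomness flows
through one RNG stream seeded once per run, so identical configurations
and seeds give bit-identical snapshots and CSVs.

## Diversity statistics

Species abundances are converted to *true diversities* (Hill numbers)
$^qD = (\sum_i p_i^q)^{1/(1-q)}$, reported at orders 0 (richness), 0.5
(rare-species weighted), 1 (the exponential of Shannon entropy, taken as
the limit), and 2 (common-species weighted). Equal abundances give the
species count at every order, and the doubling property holds exactly;
both are tested. Centroid-distance diversity — the mean Euclidean
distance of genotypes from their mean — is the scalar tracked in the
pair-persistence experiments.

Species are detected in genetic space only (the $x$ columns) by
Euclidean k-medoids (PAM via the cluster package; an exact acceleration,
`pamonce = 3`, plus seeded random restarts on instances up to 100 points
where the BUILD start can land in a poor basin — tiny-instance optima
are verified against exhaustive medoid search in the tests). The number
of clusters is chosen pamk-style: $k = 2..10$ scored by mean silhouette
width, with fallback to a single species when the best score is below
0.5. That floor was measured, not guessed: a structureless Gaussian or
uniform blob scores 0.30–0.45 under k-medoids (so a lower floor
manufactures species out of noise), while genuinely separated groups
score well above 0.5. Labels are canonicalized by decreasing cluster
size with coordinate tie-breaks, so they are invariant to input order.

## The shipped experiments and what they show

`run_controls()` crosses sexual selection on/off with pair persistence
on/off under shared seeds; `run_sweep()` replicates runs over a grid of
`max_pair_age` values. The scaled study conditions are 150 founders,
1000 resource units, and 3000 steps for the pairing contrast — chosen
because at this population size the contrast between lifelong pairs and
immediate dissolution is at its clearest there: at 2000 steps the
no-pairing arm has typically not yet declined, while towards 5000 steps
genetic drift erodes even the protected arm (small populations lose
diversity to drift quickly, which is also why the no-mechanism control
is run to 5000 steps, where its collapse to a single tight cluster —
final centroid distance well under 0.3 against a unit niche spacing —
is essentially complete). Full-scale runs (200 founders, 5000 steps)
are the `sim_config()` defaults.

Three patterns are asserted, all ordinal and replicate-majority based,
never point values: (a) selection plus lifelong pairing on Rastrigin
ends with at least two detected species in at least 4 of 5 replicates;
(b) final-epoch centroid distance is higher with persistent pairs than
with `max_pair_age = 0` in at least 4 of 5 seed-matched run pairs; (c)
with both mechanisms off, the late-run population concentrates into one
cluster in a majority of replicates. Pattern (b) is the most fragile:
across 25 calibration seeds its per-seed win rate is about 0.68, so a
5-seed set clears the 4-of-5 bar only somewhat more often than not. The
root cause is the deliberately mild choice law $1/(1+d)$ — bounded,
scale-tolerant, never zero (so a trickle of gene flow between nascent
species always remains) — which yields assortment too weak for permanent
reproductive isolation; both arms drift toward competitive exclusion and
the comparison contrasts their collapse times. A steeper choice
function or a niche-specific resource economy would stabilize
coexistence outright, at the price of changing the model's contracts.

**What the generator does not emulate.** Genotypes are 2-D; there is no
age-related senescence, no overlapping broods per step, no male-male
competition or courtship dynamics, no heterogeneous node capacities, and
the environment is static. Passing the shipped experiments shows the
mechanisms interact as described *within this model*; it is not evidence
about any natural population.

## Numerical and degenerate-input choices

Resource transfers are written as exact paired debits/credits, so the
conservation audit holds to floating-point rounding (relative drift
around 1e-13 over 5000 steps, tested against a 1e-6 tolerance). Hill
numbers treat $|q - 1| < 10^{-9}$ as the $q = 1$ limit and drop
zero-abundance classes ($0 \log 0 = 0$). Empty populations yield valid
states and NA diversity reports; single or fully duplicated point sets
yield the trivial one-species partition; `k` equal to the number of
points yields the zero-cost all-medoid partition (handled outside
cluster::pam, which requires $k < n$). Mate choice with one candidate
short-circuits without consuming randomness. Clustering inside
`diversity_report()` strides down to at most 2000 points; centroid
distance always uses every agent. PAM restarts run under a private,
data-derived seed and restore the caller's RNG state, so analysis never
perturbs simulation replay.

## A worked micro-example

```{r example}
cfg <- sim_config(landscape = "rastrigin", initial_population = 100,
                  total_resource = 500, steps = 600,
                  snapshot_every = 300, seed = 7)
res <- run_simulation(cfg)
res$diversity[, c("step", "n_agents", "n_species", "D0", "D1",
                  "centroid_distance")]
```

The columns mirror the per-snapshot report: population size, detected
species, Hill numbers, and centroid-distance diversity; the same values
flow into the CSVs written by `write_run_csv()` and the command-line
front end in `inst/cli/pairsim`.
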
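# pairsim

An agent-based simulator of **sexual selection and pair formation** in a
closed ecosystem, built to study whether female mate choice over
heritable male traits — together with a pair-bond mechanism — can
trigger **sympatric speciation** and maintain population diversity, plus
the analysis layer used to measure it: **Hill-number (true diversity)
statistics**, centroid-distance diversity, and **k-medoid species
detection**.

## Who this is for

Evolutionary ecologists and artificial-life researchers who want a
small, fully reproducible sandbox for mate-choice-driven speciation:
every run is seeded, every unit of "resource" is conserved, and every
analysis statistic has an exact or brute-force-verified definition.

## The model in brief

Agents of two sexes live on a torus grid of nodes over a multimodal
fitness landscape (Michalewicz, Rastrigin, Schwefel or Waves; local
minima act as ecological niches). A genotype is a pair
⟨x, σ⟩ ∈ ℝ² × ℝ²₊ — trait/preference coordinates plus self-adaptive
mutation deviations. A fixed resource total circulates between an
environment pool and the agents; the environment dispenses it in
proportion to quality weights
w_i ∝ (max_j f_j − f_i) + ε·(max_j f_j − min_j f_j + 1) on the
minimization surface f, agents pay a flat upkeep, and an agent that
cannot pay starves — selection is entirely decentralized.

A ready female chooses among ready males in her node with probability
∝ 1/(1 + d), d the Euclidean distance between her preferences and his
displayed traits. The couple forms a pair that co-migrates and
reproduces (two offspring per brood; intermediate recombination, then
log-normal self-adaptive mutation σᵢ′ = σᵢ·exp(τ₀ξ + τξᵢ),
xᵢ′ = xᵢ + σᵢ′ξᵢ) until the pair exceeds `max_pair_age` or a member
dies. Searching for a partner costs resource every step it goes on;
members of a pair never search — that economy is what makes pair bonds
matter. Reproduction costs the female 40% and the male 20% of their
holdings, transferred to the brood.

Diversity of a snapshot is reported as Hill numbers
**D_q = (Σ p_iᵠ)^{1/(1−q)}** at q ∈ {0, 0.5, 1, 2} over species
abundances from a pamk-style detector (Euclidean PAM, k chosen by mean
silhouette width), together with the mean distance of genotypes from
the population centroid.

## A worked example

```r
library(pairsim)

p <- c(0.5, 0.25, 0.125, 0.125)
shannon_entropy(p, base = 2)   # 1.75 bits
hill_numbers(p)                # D0 = 4, D0.5 = 3.664, D1 = 3.364, D2 = 2.909

cfg <- experiment_config("rastrigin", seed = 1)  # 150 founders, 3000 steps
res <- run_simulation(cfg)
res
#> <sim_result: rastrigin, 3000 steps, seed 1>
#>   final: N = 280 agents, 7 species, D0 = 7, D1 = 5.15, centroid distance = 0.755
res$diversity[, c("step", "n_agents", "n_species", "D0", "D1", "centroid_distance")]
#>   step n_agents n_species D0   D1 centroid_distance
#> 1    0      150         1  1 1.00             1.810
#> 2  500      266         1  1 1.00             1.413
#> 3 1000      274        10 10 8.45             1.183
#> 4 1500      271        10 10 8.34             1.025
#> 5 2000      285        10 10 6.93             0.892
#> 6 2500      285        10 10 6.37             0.835
#> 7 3000      280         7  7 5.15             0.755
```

Reading it: the uniformly scattered founders (centroid distance 1.81)
condense within ~1000 steps into reproductively isolated clusters
sitting in distinct Rastrigin niches — the species detector finds up to
10 of them, with an effective number of common species (D1) around 6–8 —
and with lifelong pairs most species persist to the end of the run.
Setting `pairing = FALSE` (pairs dissolve immediately after
reproducing) or `sexual_selection = FALSE` (uniform mate choice)
degrades or destroys this pattern; `run_controls()` runs the full 2 × 2
and `run_sweep()` replicates a `max_pair_age` grid into a tidy table.

A command-line front end is included at `inst/cli/pairsim`
(`run`, `analyze`, `sweep` subcommands over YAML configs).

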
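# mutatorsim

An ab initio multiscale simulator of mutator dynamics in stressed asexual
populations. Fitness and mutation rate are not postulated: they are computed
from the physics of each cell's proteins — lattice folding stability,
rigid-body docking thermodynamics, and law-of-mass-action cytoplasmic
equilibria — so that the rise and fall of mutator phenotypes under
heat-shock, stationary-phase and starvation stress emerges from sequence
level events.

## The model in one page

Each organism carries 4 genes of 81 nt encoding 27-mer proteins that fold on
the 3×3×3 cubic lattice (103,346 maximally compact conformations up to cube
rotations and chain reversal; production runs use a sampled subset).
Contact energies are the Miyazawa–Jernigan (1996) residue-pair table.

* **Stability** — P_nat = exp(−E0/T) / Σ_c exp(−E_c/T), the Boltzmann weight
  of the lowest-energy conformation.
* **Binding** — two cube proteins dock in 144 rigid modes (6 faces × 6
  faces × 4 rotations); P_int is the probability of the lowest-energy mode,
  and the binding constant K_ij = exp(−(E_int − Ē_modes)/T) enters the
  mass-action equations F_i = C_i / (1 + Σ_j K_ij F_j), with heterodimers
  F_ij = K_ij F_i F_j and homodimers F_ii = K_ii F_i²/2.
* **Fitness** — genes 1–3 control replication:
  b = b0 · G1 · G23 / (1 + σ (ΣC_i − C0)²), clamped to [0,1], where
  G1 = F₁ P_nat¹ and G23 = F₂₃ P_int²³ P_nat² P_nat³.
* **Mutation rate** — gene 4 is a mismatch-repair (MMR) prototype whose
  functional homodimer concentration G44 = F₄₄ P_int⁴⁴ (P_nat⁴)² sets
  m = m_min + (m_max − m_min)·max(0, 1 − G44/G_ref); a *mutator* has
  m > 0.01 (wild type: 10⁻⁴).
* **Dynamics** — discrete time; per step each cell may fluctuate its
  expression levels (probability r per gene, multiplicative Normal(0, 0.1)
  noise, epigenetically heritable), dies with probability d = 0.005, divides
  with probability b (two daughters, Poisson(m) substitutions per gene;
  destabilized or truncated products are lethal), and excess organisms are
  culled at random above the carrying capacity (chemostat regime).
* **Stress** — at t_apply exactly one parameter changes: T 0.85 → 1.00
  (heat shock), b0 → b0/3 (stationary phase), or C0 0.4 → 0.04 (starvation).

Seed genomes are designed by Metropolis Monte Carlo in sequence space
(genes 1–3 stable; gene 4 stable *and* strongly homodimerizing), then b0 and
G_ref are calibrated so the seed population starts at b = d with wild-type
mutation rate.

## A worked example

```r
library(mutatorsim)

full <- enumerate_compact_conformations()
full
#> <conformation_set> 103346 compact 3x3x3 lattice conformations

set <- sample_structure_set(full, 1000, rng_seed = 11)
em  <- energy_model()            # T = 0.85, MJ contact energies

fold(strrep("L", 27), set, em)   # a homopolymer: fully degenerate
#> <protein_state> native 1  E0 = -206.36  P_nat = 0.001

cfg <- run_config(cap = 300, n_seed = 100, t_max = 3000, n_struct = 1000,
                  seed = 5, record_every = 500)
run <- run_evolution(cfg, structure_set = set)
run
#> <evolution_run> 3000 steps, 300 cells, final mean b = 0.988  mutator freq = 0.0133

tidy(run)[, c("t", "n", "mean_b", "mutator_freq", "mean_C4", "mean_pnat4")]
#>      t   n mean_b mutator_freq mean_C4 mean_pnat4
#> 1    0 100 0.0050       0.0000  0.1000      0.899
#> 2  500 104 0.0046       0.4712  0.0950      0.899
#> 3 1000 300 0.0433       0.8667  0.0815      0.879
#> 4 1500 300 0.9880       0.1467  0.1119      0.920
#> 5 2000 300 0.9963       0.0667  0.1056      0.917
#> 6 2500 300 0.9883       0.0267  0.1215      0.920
#> 7 3000 300 0.9881       0.0133  0.1157      0.921
```

Read the trajectory top to bottom: the population seeds at the
birth–death balance (b = d = 0.005, no mutators). Expression noise in the
MMR gene supplies mutators (frequency 0.47 by step 500, transiently fixing
at 0.87), the hypermutating population discovers beneficial
replication-gene mutations and fitness jumps from 0.005 to ≈0.99, and a
stabilizing MMR mutation then returns the population to a non-mutator state
(frequency back to ~1–7%, the persistent constitutive-mutator fraction) —
second-order selection in miniature. `glance(run)` summarizes the endpoint,
`autoplot(run)` draws the population/fitness/frequency panels, and
`classify_transitions(run)` attributes each mutator fixation and loss to an
environmental change (Env), a gene-4 mutation (Mut) or epigenetic
stochastic switching (SS).

Stress experiments use the same machinery (`protocol = "heat_shock"`,
`"stationary_phase"`, `"starvation"`); `run_competition()` races
fluctuating against non-fluctuating lineages, and `run_constant_fitness()`
is the drift control in which fitness is fixed and only the supply/purging
balance of mutators remains. Configurations reproducing the full-scale
published ensembles (capacity 5000, 10,000-structure sets, stress at
t = 20000, 100 runs) ship in `inst/extdata/config_full_*.yaml`; they are
cluster-scale experiments, not desktop runs. A thin command-line front end
with verbs `enumerate`, `design`, `run`, `compete`, `drift` and `analyze`
is installed as `exec/mutatorsim`.

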
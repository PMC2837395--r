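---
title: "From lattice proteins to mutator dynamics: the model behind mutatorsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From lattice proteins to mutator dynamics: the model behind mutatorsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mutatorsim` is an ab initio evolutionary simulator: the fitness and the
mutation rate of every model cell are computed from the physics of its
proteins rather than postulated. This vignette describes the model layer by
layer, the parameters that matter, the numerical choices made, and what the
package's tests do and do not establish.

## The cell model

Each organism carries four genes of 81 nucleotides, translated with the
standard genetic code into 27-mer proteins that fold on the 3x3x3 cubic
lattice. Genes 1-3 are replication-controlling genes (RCGs): protein 1
functions as a monomer, proteins 2 and 3 as a heterodimer. Gene 4 encodes a
mismatch-repair (MMR) protein, functional as a homodimer, which sets the
replication fidelity.

**Folding.** A maximally compact conformation is a self-avoiding chain
visiting all 27 cube sites; there are exactly 103,346 of them once
conformations related by a proper cube rotation and/or chain reversal are
identified (mirror images are counted as distinct; this convention is the
one that reproduces the published count). Each conformation has exactly 28
non-bonded nearest-neighbour contacts, scored with the Miyazawa-Jernigan
(1996) residue-residue contact energies shipped as a plain-text matrix.
The native state is the energy minimum over the structure set and its
thermal stability is the Boltzmann probability
P_nat = exp(-E0/T) / sum_c exp(-E_c/T). Production runs use a uniformly
sampled representative subset (10,000 structures at full scale) in place of
the complete enumeration.

**Docking.** Two cube proteins can dock rigidly in 6 x 6 x 4 = 144 modes
(either face of each partner, 4 in-plane rotations; reflections are not
extra modes). A mode's energy is the sum of contact energies over its 9
interface residue pairs, read off the two native conformations. P_int is
the Boltzmann probability of the lowest-energy mode among the 144.

**Binding constants and the mass-action equilibrium.** The binding constant
entering the law of mass action is, by default,

K_ij = exp( -(E_int_min - mean_modes E) / T ),

the native-mode constant measured relative to the pair's nonspecific
docking baseline. The choice deserves a comment, because it was genuinely
open. Tying K to the absolute minimum energy, K = exp(-E_int_min/T), gives
K ~ 1e15-1e25 with this contact potential: all protein is then locked in
dimers, free-monomer fractions are ~1e-9, and calibrating the base growth
rate against the death rate yields b0 ~ 1e9 — orders of magnitude away from
the reference value of 707.445 and incompatible with functional monomer
fractions of order one. The baseline-relative form gives K ~ 1-1e3,
partial dimerization, and seed calibrations of a few hundred. Both the
absolute (`"min_energy"`) and mode-summed (`"mode_sum"`) forms remain
available through the `k_form` switch.

Free monomer concentrations solve F_i = C_i / (1 + sum_j K_ij F_j), with
heterodimers F_ij = K_ij F_i F_j and homodimers F_ii = K_ii F_i^2 / 2. The
1/2 is the homodimer symmetry number; it is the only convention under which
the fixed-point equation, the textbook one-species quadratic, and mass
conservation C_i = F_i + 2 F_ii + sum_{j != i} F_ij hold simultaneously,
and the test suite asserts all three.

**Fitness and mutation rate.** The division probability per time step is

b = b0 * G1 * G23 / (1 + sigma * (sum_i C_i - C0)^2), clamped to [0, 1],

with G1 = F_1 P_nat^1 (functional monomers of protein 1) and
G23 = F_23 P_int^23 P_nat^2 P_nat^3 (functional 2-3 heterodimers). The
quadratic penalty prices protein overproduction. The mutation rate per gene
per replication falls linearly with the functional MMR dimer concentration
G44 = F_44 P_int^44 (P_nat^4)^2:

m = m_min + (m_max - m_min) * max(0, 1 - G44 / G_ref),

so a cell with the reference MMR capacity mutates at the wild-type rate
1e-4 and a cell with no functional dimers at m_max = 0.1. A *mutator* is a
cell with m > 0.01 (strict).

## Population dynamics

Time advances in discrete steps. Within a step, each cell (1) may fluctuate
each gene's total concentration with probability r (multiplicative noise,
eta ~ Normal(0, 0.1), floored at 1e-6 — concentrations are epigenetically
heritable but noisy); (2) has its equilibrium and rates refreshed if
anything changed; (3) dies with probability d; (4) divides with probability
b, the mother being replaced by two daughters that inherit her
concentrations and acquire Poisson(m) substitutions per gene; a daughter
whose mutated protein falls below the stability threshold theta_nat = 0.6,
or carries an in-frame stop codon, is lethal and discarded. (5) If the
population exceeds the carrying capacity, uniformly random culling restores
it (the chemostat regime). The within-step order
(fluctuate, death, division, culling) is fixed; nothing in the model pins
it down, and at the neutral balance point b = d the tests verify the
expected population change is zero, which is the statistic the order could
most easily bias.

Every mutation, fluctuation, stress application and mutator-status flip is
logged. Flips record their proximal cause: `Env` when triggered by the
stress-step parameter change, `Mut` when coincident with a gene-4
substitution at replication, `SS` when coincident with a logged fluctuation
of the MMR gene's production level, and `unattributed` otherwise (e.g. a
flip driven by competition after a fluctuation of another gene's
concentration). Population-level transitions are frequency crossings of 0.5
with hysteresis — the frequency must first have been below 0.25 (for a rise)
or above 0.75 (for a fall) — and take the majority cause of the flips in the
arming window, with precedence Env > Mut > SS on ties. Falls are never
attributed to Env. The hysteresis rule is a package choice; no crossing
definition is inherited from the literature, and without it the
classification chatters around 0.5.

## Seed design and calibration

Seed genomes are designed, not sampled: Metropolis Monte Carlo in sequence
space (single-residue proposals, geometrically annealed selection
temperature) drives each designated native structure — drawn uniformly at
random from the structure set — to be the unique energy minimum with
P_nat >= 0.85; gene 4 additionally must form a homodimer with
P_int >= 0.8. Back-translation uses uniformly random synonymous codons.
RCG-RCG interactions are left undesigned, so seed populations start poorly
adapted.

The design thresholds are deliberately near the stability and binding
optimum attainable on the structure set, not just above the lethality cut.
The reference MMR capacity G_ref is calibrated to the seed cell, and
adapted populations ratchet their MMR margin upward (a mutator episode
costs viable offspring, so extra G44 margin is selected). If the seed is
anchored far below the optimum, that ratchet leaves adapted populations
with G44 far above G_ref and a temperature jump can no longer push them
over the mutator threshold — the heat-shock phenomenology disappears.
Anchoring the seed near the optimum keeps the adapted state close to
G_ref, which is also where the published pre-stress stabilities (~0.83) and
homodimer binding probabilities (~0.8) sit.

b0 is calibrated per seed genome so the initial birth rate equals the death
rate d = 0.005; the published 707.445 is one instance of this calibration,
and the calibrated values produced here are of the same order. The three
stress protocols each change exactly one parameter at t_apply: temperature
0.85 -> 1.00 (heat shock), b0 -> b0/3 (stationary phase), C0 -> C0/10
(starvation).

## What the generator emulates, and what it does not

The design module plus the population initializer are the package's
synthetic-data generator: they produce the study conditions (clonal seed
populations of designed genomes at equal per-gene concentrations C0/4,
wild-type rates by construction). Real proteins are not 27-mers on a cube;
the lattice representation preserves the qualitative couplings that drive
the science — stability and binding respond to the same mutations,
temperature destabilizes both, and expression noise propagates through a
shared equilibrium — but not real folding kinetics, real contact orders, or
crowding corrections to mass action. Passing tests therefore support the
model's internal consistency and the published qualitative phenomenology,
not quantitative predictions for any organism.

## Numerical choices

- Fixed-point LMA iteration stops when every F_i changes by less than 0.1%
  (configurable); plain iteration switches to 0.5-damped after 100 sweeps,
  which cannot change the fixed point. The vectorized population solver
  damps from the start and iterates to half the tolerance.
- Energy ties in folding break to the lowest conformation index; designed
  sequences are required to have a strictly unique minimum.
- Concentrations are floored at 1e-6 after fluctuation; the mass-action
  equations need C >= 0 and the noise model does not otherwise exclude
  negative draws.
- Lethality is assessed on mutated genes only: stability loss *by a
  mutation* is lethal; a stable cell does not die merely because the
  temperature rose.
- In local fitness landscapes, lethal mutants are assigned x = -1 (complete
  fitness loss) rather than excluded, and synonymous draws are rejected and
  redrawn. Total concentrations are held fixed, so x isolates the
  protein-level effect.
- Master seed -> per-component child seeds (structure sampling, design,
  dynamics), so components can be re-run independently and every run is
  exactly reproducible from (config, seed).

## Problem sizes used by the test suite

The published ensembles (100 runs, 5000-cell capacity, 25,000+ steps,
10,000 structures) are cluster-scale; the shipped
`inst/extdata/config_full_*.yaml` files reproduce them verbatim. The test
suite runs the same machinery at desk scale, chosen once: carrying capacity
300, seed populations of 100, 1000-structure sets, 3,000-3,500 steps, and
10-12 replicates per condition. At this scale the qualitative claims are
reproducible (no mutator fixation and stalled adaptation without expression
noise; mutator frequency falling with growth rate under constant fitness;
environmental causes dominating heat-shock transitions and stochastic
switching dominating starvation transitions), while the published
percentages of Table-1-style cause counts are not expected to transfer —
they are properties of the full-scale ensemble.

## Known limitations

- The mass-action treatment is mean-field; no crowding corrections, no
  complexes beyond dimers, and no dimer-of-dimers MMR tetramer.
- Horizontal gene transfer, indels, recombination and regulatory-region
  mutations are out of scope.
- At desk scale the fitness trajectory of a single run is strongly
  genome-dependent (the calibrated b0 varies by orders of magnitude across
  designed seeds); ensemble statements in the tests pool replicates for
  this reason.
- Event logs record full provenance (divisions, deaths, culls) only when
  `log_divisions = TRUE`; the default trims them to state-changing events
  to keep long runs in memory.
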
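---
title: "Simulating prebiotic polymer evolution under wet-dry cycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating prebiotic polymer evolution under wet-dry cycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`usrsim` simulates a population of informational polymers living on a
periodic square lattice of surface "reaction domains", driven by regular
hydration-dehydration cycles. Two monomer species, A and B, are present in
equal, finite, strictly conserved total amounts; every polymer has fixed
length $L$ (default 20) and carries $L/2$ residues of each species. Because
composition is fixed, a unique sequence need not be stored explicitly: each
lineage (species) is identified by an integer ID assigned in order of first
appearance. Sequence space is vast relative to what any run explores, so
spontaneously assembled polymers are always treated as novel sequences, and
mutation and recombination are deliberately outside the model.

Each cycle has two phases.

**Dry phase** (duration `dry_duration`). Sites are diffusively isolated and
evolve independently by the exact stochastic simulation algorithm (SSA).
Two channels exist at a site with $A$ and $B$ free monomers:

* spontaneous assembly, propensity $a_s = k_s A B$, which consumes $L/2$ of
  each monomer species and creates one polymer of a brand-new lineage;
* universal sequence replication (USR), propensity
  $a_r = k_r A B \sum_i T_i$, where $T_i$ is the number of *available
  templates* of lineage $i$. The $AB$ nucleation factor models dimer
  formation as the rate-limiting step, so replication speed depends on local
  resources; $k_r$ itself is sequence-independent -- the intrinsic fitness
  landscape is flat.

Both channels are gated: no event can fire at a site holding fewer than
$L/2$ monomers of either species, because a full-length polymer cannot be
built there. Template sequestration enforces *at most one copy per template
per cycle*: a replication decrements the lineage's available-template count,
and neither the fresh copy nor a newly assembled polymer becomes an eligible
template until the next dry phase (the duplex does not dissociate until the
next hydration).

**Wet phase** (duration `wet_duration`). Sites couple diffusively and
polymers can act. Stochastic channels, with propensities refreshed after
every event: hydrolysis $k_h n$ (all-or-none; the $L/2 + L/2$ monomers
return to the *same* site, the localized recycling that feeds cluster
formation), polymer hopping $d_p n$ to a uniformly chosen 4-neighbour, and
-- for functional synthetase lineages -- catalysis $k_{cat}\, p\!A \cdot
n_{enz}$ converting one unit of a proto-monomer pool into the corresponding
free monomer on the same site. Monomer and proto-monomer transport is
coarse-grained as mass-action hopping,
$\dot X_x = (d_m/4)\sum_{y\sim x} X_y - d_m X_x$, making monomer fields
real-valued while every kinetic event still moves integer quanta.

## Numerical scheme

The wet phase is a hybrid: rare events ride on a deterministically
diffusing monomer background. The implementation advances the fields to the
exact time of every rare event, using the *exact* spectral propagator of
the periodic-lattice Laplacian (the generator is circulant, so the 2-D FFT
diagonalizes it; field mass is conserved to machine precision and the
matrix-exponential solution is reproduced to better than $10^{-6}$).
Hydrolysis and hopping propensities depend only on polymer counts, so their
SSA treatment is exact. The catalysis propensity reads the diffusing
proto-monomer field; while a catalysis channel is active the exponential
waiting times are additionally capped at `wet_substep` (default 0.01
cycles), the usual piecewise-constant-propensity window, and the process
law converges to the exact coupled law as `wet_substep` $\to 0$. A polymer
drained to a fractional proto-pool transfers $\min(1, p\!A)$ so the pool
empties exactly without going negative.

Two bookkeeping invariants are asserted continuously: each element's ledger
(free + $L/2\cdot$polymers + proto) is constant to $10^{-6}$ relative over
any run, and the tracker's per-lineage counts always agree with the spatial
polymer table. Dry-phase sites consume independent RNG substreams drawn
from the master stream at each phase start, so per-site outcomes are
independent of site processing order, and a run is bit-reproducible from
`(params, seed)`.

The `oracle_simulate()` engine is a fully stochastic reference: integer
monomer counts, every monomer hop a stochastic event at rate $d_m$. When no
catalysis channel is active, no wet-phase propensity reads a monomer count,
so monomer walks are independent of the polymer process and are sampled
exactly (Poisson hop counts, uniform steps; monomers released mid-phase
walk only their remaining time) -- an exact-law decomposition, not an
approximation; with catalysis the oracle falls back to full event-by-event
SSA. `compare_hybrid_to_oracle()` runs matched ensembles of both engines
and compares end-of-run distributions of total population, extant species
and average local diversity by two-sample rank tests.

## Metrics

Sampled once per cycle, at the end of the wet phase (the sampling point is
a package convention): total population; extant species; average species
population (total/extant); exploration rate (new lineage IDs that cycle);
and average local diversity, the per-site Shannon entropy
$-\sum_i p_i \ln p_i$ of lineage counts (natural log, unnormalized),
averaged over **all** sites with empty sites contributing zero. Species
lifetime is the number of contiguous cycles in which at least one copy
existed; the extinction cycle is recorded as the first cycle *without* a
copy, so lifetime = extinction − birth and a polymer that dies in its birth
cycle has lifetime 1. In the no-replication limit this makes the mean
lifetime exactly the geometric $1/(1-e^{-k_h \cdot \mathrm{wet}})$, which
the test suite verifies to 2%. Window statistics use only lineages whose
extinction falls inside the window; still-extant (censored) lineages are
excluded from means and reported as a count -- unbiased for the closed
population and explicit about censoring. `cluster_map()` labels 4-connected
components of the polymer density grid under periodic wrap.

## Parameters and the default regime

| parameter | default | meaning |
|---|---|---|
| `lattice_side` | 16 | sites per edge, periodic |
| `polymer_length` | 20 | residues; $L/2$ of each species |
| `k_s` | 1e-4 | spontaneous assembly, per $AB$ per cycle |
| `k_r` | 5e-4 | replication, per $AB\cdot$template per cycle |
| `k_h` | 0.1 | hydrolysis, per polymer per cycle |
| `k_cat` | 10 | catalysis, per proto-monomer per enzyme |
| `d_m`, `d_p` | 1, 0.01 | monomer / polymer hopping, sites per cycle |
| `init_A`, `init_B` | 60, 60 | monomers per site at start |

The kinetic defaults place the system deliberately in the
*propensity-limited* regime. At quasi-steady state, replication balances
hydrolysis where $k_r \bar A \bar B \approx 1 - e^{-k_h}$, i.e.
$\bar A \bar B \approx 190$ per site: free monomers equilibrate at ~14-20
per site, *above* the assembly gate of $L/2 = 10$. Here replication is
probability-limited and local resource levels multiply a lineage's
replication odds -- which is what makes a monomer synthetase selectable: a
site held at $A \approx 60$ replicates its residents several times faster
than the background. Had we chosen $k_h/k_r$ an order of magnitude smaller,
free monomers would pin *at* the gate; replication then becomes
quantum-limited (each 10-monomer parcel of the scarce species is consumed
by whichever template wins a share-weighted lottery, regardless of
propensity magnitude), a synthetase's resource fountain confers no local
advantage, and functional selection collapses -- inconsistent with the
selection behaviour this model family is built to exhibit. `k_cat`'s
default is saturating: one enzyme converts $\ge 99\%$ of its site's
proto-pool within one wet phase, so enzyme impact is limited by diffusive
access to the proto-resource, not by chemistry. `k_s` is set well below
`k_r` so spontaneous nucleation is the rarer channel, sustaining a few new
sequences per cycle at steady state on a 16x16 lattice.

With these defaults a 16x16 run reaches dynamic kinetic stability within
~100 cycles: total population plateaus (~70-80% of monomer mass bound)
while lineage composition keeps turning over and new sequences keep
appearing -- the exploration-with-propagation compromise at the heart of
the model.

## The functional-selection experiment

`functional_experiment()` follows the inoculation protocol: run a
nonfunctional base simulation to the insertion cycle; add 60 proto-monomers
per site (a previously untapped resource); insert a single flagged polymer
as a spontaneous-assembly event at a site drawn proportionally to
$k_s A B$ among gated sites; continue until the flagged lineage dies (or a
cap). Each replicate also runs a matched nonfunctional control from the
same checkpoint at the same site, and a background arm with no inoculation.
The reduced-scale study conditions are a 12x12 lattice, insertion at cycle
250, a 1200-cycle survival cap and 25 replicates per arm. Because enzyme
and control arms are matched by construction, lifetimes are compared by a
paired one-sided signed-rank test. Establishment from a single copy is an
extinction-prone branching race (roughly half of inoculations die before
replicating, in both arms); the synthetase's advantage appears in the
established tail, so mean-population ratios at this lattice size
underestimate what larger surfaces (longer-lived fountains, larger
proto-reservoirs) would show.

## What the generator emulates, and what it does not

All inputs are synthetic and config-driven; the initial condition is the
homogeneous monomer bath the model prescribes. The simulations emulate:
closed-mass recycling chemistry, environment-driven phase alternation,
spatially localized feedback, and flat-fitness replication. They do not
emulate: explicit base sequences (composition is fixed at 1:1 by design,
as the dynamical attractor), replication error or recombination, variable
polymer lengths (a config knob `polymer_length` exists but length is fixed
within a run), polymer-polymer interactions beyond resource competition, or
any chemistry of the proto-monomer other than conversion. Passing tests
therefore demonstrate the model's internal dynamics, not properties of any
real polymer chemistry.

## Problem sizes and numerical conventions

The packaged tests and the acceptance script run at desk scale, chosen as
the package's own study sizes: 16x16 lattices and 500 cycles for
steady-state characterization, 4x4/100 cycles with 200 replicates per
engine for hybrid-oracle equivalence, 12x12 for selection experiments,
20,000-30,000 replicates for the closed-form lifetime checks, ensembles of
5-25 for directional comparisons. Degenerate inputs are defined, not
rejected: a 1x1 lattice is the well-mixed limit (hops are no-ops, the
diffusion propagator is the identity), zero rate constants silently
disable their channels, and `n_cycles = 0` returns the initial state with
an empty history. Ties in site/lineage selection cannot occur (continuous
propensities); rank tests use the normal approximation throughout.

## Known limitations

The hybrid engine's monomer fields carry no demographic noise. Real
integer monomer counts occasionally fluctuate below the assembly gate,
which slightly throttles the exact process, while the hybrid's smooth
fields do not: on a 4x4 lattice after 100 cycles this produces a measured
~1-2% excess in the hybrid's mean total population (detectable with
200-replicate ensembles; extant-species and diversity distributions are
indistinguishable, and the two engines are statistically identical when
transport is disabled). On very small lattices where this matters, the
oracle is the better engine. Performance is
adequate for desk-scale studies (a 16x16, 500-cycle run takes seconds);
publication-scale sweeps would want a compiled engine. The event log grows
linearly with events and is off by default. Checkpoints store real-valued
fields to 17 significant digits, which is lossless for integer-valued
quantities but not bit-exact for arbitrary reals.
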
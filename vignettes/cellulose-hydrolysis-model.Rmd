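---
title: "A lattice event model of enzymatic cellulose hydrolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lattice event model of enzymatic cellulose hydrolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CellulaseSim)
```

# The model

`CellulaseSim` simulates the degradation of the surface layer of a
crystalline cellulose (Iβ) slab by individually tracked cellulase
particles. The substrate is a two-dimensional grid: `nChains` parallel
glucan chains of identical degree of polymerization (DP), nonreducing ends
(NE) at column 0 and reducing ends (RE) at column DP − 1, consistent with
the parallel-chain packing of cellulose Iβ. Within a chain, neighbouring
glucose units are joined by β-1,4 glycosidic bonds (indexed by their left
unit); between vertically adjacent chains each unit pair is joined by one
*effective* inter-chain hydrogen bond. Real cellulose carries several
hydrogen bonds per glucose pair; collapsing them into one bookkeeping unit
matches the per-pair counting used in the processive-step time and the
endo hydrogen-bond phase below, and only the product
`t_hbbreak · nrHb` (or the rate `k_hbbreak`) is physically meaningful.

Each glucose unit carries a small set of state flags: soluble or part of
the lattice, chain-end type, coverage by a bound enzyme, and locking by a
processive enzyme that has reserved the units ahead of itself. At most one
enzyme covers any unit; locked units are not binding sites and their bonds
cannot be cut by other enzymes.

**Solubilization rule.** Whenever a cleavage leaves a maximal
glycosidically connected fragment shorter than 4 units, the fragment
dissolves immediately: its units lose all flags and incident bonds, and
one glucose (G1), cellobiose (G2) or cellotriose (G3) molecule is tallied.
Dissolved sugars are inert — none of the modelled enzymes attacks soluble
oligomers, so the conversion counts `(G1 + 2·G2 + 3·G3) / N₀`.

## Endo-cellulase (EG I-like)

An endo site is a 9-column window on a middle chain with its two flanking
chains. Availability requires the nine middle-chain units to be part of
the lattice and the 12 *core* units — the central four columns of the
window on the three chains — to be uncovered and unlocked. A bound endo
covers only its core. The catalytic bond sits centrally, between the 2nd
and 3rd core units, following the picture of a four-subsite binding groove
with the catalytic centre in the middle. After adsorption the enzyme

1. fast-desorbs (`k_offfast`) if the catalytic bond is already cut,
2. otherwise breaks the intact hydrogen bonds between its covered units
   one at a time, each break an exponential race of `k_hbbreak` against
   desorption at `k_off` (so the expected breaking time is proportional to
   the number of bonds),
3. then hydrolyzes the catalytic bond in a `k_gly` vs `k_off` race, and
4. after a cleavage always desorbs, with an Exp(`k_off`) delay.

One visit therefore cuts at most one bond. With the reference rates the
productive fraction of ready-stage visits is
`k_gly / (k_gly + k_off) = 0.35/0.45 = 7/9`.

**Short-fragment anchors.** The 9-column footprint rule alone cannot
degrade an isolated fragment of 4–8 units (no nine consecutive lattice
columns remain), which would leave a residue of undegradable islands and
make 100 % conversion unreachable. Mirroring the edge-chain convention —
footprints truncate where the lattice ends — every maximal connected
fragment of 4 to 8 units contributes one additional anchor whose 4-unit
core is centred on the fragment. Pristine-sheet site counts are unchanged
(a 5 × 5000 sheet has 5 × 4992 = 24 960 anchors), and complete hydrolysis
becomes reachable for every configuration.

## Exo-cellulases (CBH I / CBH II-like)

Exo-R binds free reducing ends and processes toward the NE; exo-N is its
mirror image. The catalytic tunnel holds nine sugars with two product
binding sites, so an adsorption site is a free chain end whose nine
terminal units are in the lattice with all eight intervening bonds intact,
and whose up-to-27 footprint units are uncovered and unlocked. Adsorption
breaks all hydrogen bonds between covered units instantaneously.

Each processive cycle then decides, in order:

1. **Continuity** — if the covered middle-chain units are no longer a
   contiguous intact run (the tunnel has advanced over a cut made by
   another enzyme), desorb with rate `k_offfast`; a chain consumed to
   nothing releases the enzyme at `k_off`.
2. **Voluntary desorption** — with probability α per cycle, desorb at
   `k_off`.
3. **Spatial conditions** — the two columns ahead of the tunnel are
   examined. If the first ahead unit exists and is part of the lattice,
   the six ahead units (two columns × three chains, where present) must
   be free of other enzymes, otherwise the enzyme waits `t_stay` and
   re-enters the cycle (with a fresh α draw). If free, the ahead units are
   locked and a step is scheduled after
   `t_process = t_move + t_hbbreak · nrHb`, with `nrHb` the intact
   hydrogen bonds incident to the locked units. If the column immediately
   ahead is dissolved but the next one is not (a one-column hole), the
   enzyme desorbs at `k_off`.
4. **Step execution** — the active-site bond (between the 2nd and 3rd
   units from the processed end) is cut, releasing the terminal cellobiose;
   the tunnel advances two columns, covering the locked units and breaking
   the hydrogen bonds under itself; the fragment rule dissolves any short
   trailing remnant (a 4-unit remnant yields a second cellobiose).

**Chain ends.** When the tunnel reaches the end of its fragment the
covered region simply shrinks with the remaining tail and processing
continues until the fragment is consumed; on an even-DP pristine chain an
exo-R therefore releases cellobiose exclusively and reaches full
conversion. This is a deliberate resolution of an ambiguity: a strict
"desorb at the chain end" reading strands a tunnel-length remnant at every
chain end and makes exo-only runs livelock on re-adsorption, while
processing the tail keeps the enzyme's constant-speed product release and
gives clean termination. Internal cuts still interrupt processivity
through the continuity check, and holes through the spatial check, so the
mechanisms that generate endo–exo synergy are unaffected.

## Time evolution

The engine is an asynchronous discrete-event loop. Each bound enzyme has
exactly one pending event; each species with free particles has one
pending adsorption event drawn from its propensity

&nbsp;&nbsp;&nbsp;&nbsp;`a = k_on · n_free · n_sites / (N_A · V)`,

mass-action in both the free-enzyme and the available-site count — the
form that reproduces adsorption-equilibrium scaling, loading saturation
and the volume dependence of hydrolysis. `V = S·d` with
`S = N₀/2 · A_G2` (`A_G2 = 5.512 × 10⁻¹⁹ m²` per cellobiose) held fixed at
its initial value, and `d` a configurable slab thickness of order 1 µm.
Waiting times are exponential (Gillespie direct method); on firing, an
adsorption event picks one free particle and one available site uniformly
at random. The run stops at the degradation threshold (default 100 %
conversion), when nothing can happen any more (no bound enzyme, no
positive propensity), or at a configurable hard wall `t_max` (default
infinite) that guards pathological configurations such as two opposing
processive enzymes with α = 0 waiting on each other forever.

# Parameters

| Parameter | Endo | Exo-R / Exo-N | Units | Meaning |
|---|---|---|---|---|
| `kOn` | 100 | 10⁴ | (s·M)⁻¹ | adsorption rate constant |
| `kOff` | 0.1 | 10 | s⁻¹ | desorption rate constant |
| `kOffFast` | 1 | 100 | s⁻¹ | fast desorption (always 10 × `kOff`) |
| `kGly` | 0.35 | 0.0846 | s⁻¹ | glycosidic hydrolysis rate |
| `kHbBreak` | 10¹² | — | s⁻¹ | single hydrogen-bond breaking |
| `tMove` | — | 12 | s | cleave-and-slide step (`round(1/kGly)`) |
| `tStay` | — | 12 | s | waiting time when blocked |
| `tHbBreak` | — | 10⁻¹² | s | per hydrogen bond during a step |
| `alpha` | — | 0.1 | — | voluntary desorption probability/cycle |
| MW | 52 500 | 63 500 | g/mol | molecular weight |

The adsorption/desorption pairs keep the adsorption equilibrium constant
at 10³ M⁻¹; the endo hydrolysis rate is five-fold the exo rate. Soluble
sugar masses use `n × 162.1406 + 18.0153` g/mol (anhydroglucose plus one
water of hydrolysis), which reproduces the glucose weight 180.156 g/mol
for the monomer.

# What the generated substrate does and does not emulate

A run configuration fully defines the substrate, so all inputs are
synthetic. The default sheet — five chains of 4000–5000 units — matches
the surface layer of a cellulose microfibril in width and a typical
bacterial-cellulose DP. The `broken_fraction` option pre-cleaves an exact,
deterministically rounded number of uniformly chosen bonds (binomial
per-bond sampling would blur replicate comparisons) and applies the
solubilization rule once, emulating the pre-existing irregularities of
real crystals that remove the lag phase of perfectly crystalline sheets.

The model deliberately omits: multi-layer (3-D) crystals, so every bond is
solvent-exposed from the start and hydrolysis is faster than in a real
crystal; amorphous regions and chain-length heterogeneity; enzyme surface
diffusion; a distinct decrystallization step; hydrogen-bond reformation
(the `allow_hbond_reform` hook exists but only the default off state is
implemented); β-glucosidase chemistry (soluble sugars are terminal
products); and length-dependent adsorption affinity. Passing tests
therefore validate the discrete mechanism and its statistics, not
quantitative agreement with any particular experimental substrate.

# Numerical and design notes

* **Determinism.** Every random draw — event delays, site and particle
  choices, hydrogen-bond selection, α draws — comes from R's RNG in a
  fixed order, so `set.seed()` makes runs bit-reproducible.
  `simulateHydrolysis` seeds replica *i* with `seed + i − 1`.
  Simultaneous events are almost surely absent; equal-time pending events
  resolve in species order, then agent order.
* **Site bookkeeping.** Available-site counts are recomputed by a full
  lattice scan, lazily: a scan runs after at most 64 availability-changing
  events (8 when any species' cached count falls below 256, so that small
  counts — e.g. the handful of free chain ends — stay accurate), whenever
  an adsorption event needs a site, and always before the engine declares
  the system exhausted, which makes termination exact. A site drawn from
  the cached list is re-validated against the current lattice and redrawn
  if stale.
* **Trajectory sampling.** Observables are sampled on a fixed grid
  (default 60 s) between events — the state is piecewise constant — plus a
  final row at termination; exact first-passage times are recorded at
  every whole per-cent of conversion, so conversion-time readouts do not
  depend on the grid. Grid emission is capped at 2 × 10⁵ rows to keep
  pathological waiting times from exhausting memory.
* **Degenerate inputs.** Zero-enzyme runs (explicitly allowed via
  `allow_zero_enzymes`) terminate at time 0 with the pre-cleaved soluble
  fraction; a fully dissolved sheet reports zero mass and site densities;
  `t_max` bounds every run.
* **Open choices.** Where the mechanism admitted more than one reading we
  fixed: the endo core centred in its window (columns 3–6 of 0–8); the α
  draw once per exo cycle, after the continuity check and before the
  spatial conditions, with a fresh draw after each wait; exo desorption at
  chain ends replaced by tail processing (above); `nrHb` counting bonds
  incident to the locked units only, bonds further afield being broken at
  coverage time; and hydrolysis volumes `d = 1 µm` by default with
  `d = 3 µm` in the fixed-total-concentration mixture sweeps so that a
  2 µM total maps to 25 particles and every exo:endo ratio on the sweep
  grid is a distinct whole-particle split.

# Problem sizes

The test suite exercises full-scale sheets (5 × 5000 units) for the
acceptance-level checks — complete endo-only conversions, mixture ratio
sweeps at 25 particles, exo-only linearity — and smaller lattices
(hundreds of units) for stepwise mechanistic checks, the 3 × 9
first-cleavage Markov-chain oracle (1200 repetitions against the
closed-form expectation), a 10⁴-sample Kolmogorov–Smirnov check of
desorption delays, and brute-force site-enumeration oracles on sheets up
to 5 × 50. A full 5 × 5000 endo-only conversion executes a few hundred
thousand events.

# Known limitations

Single-layer substrate and perfect initial crystallinity make absolute
hydrolysis times faster than experiment; the inert-oligomer assumption
overstates cellotriose relative to glucose at completion; the effective
one-bond-per-pair hydrogen-bond network means `kHbBreak`/`tHbBreak` are
effective, not molecular, constants; and enzyme transport is purely
through the well-mixed solution phase (no surface diffusion), which
lengthens the lag phase of perfect crystals.
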
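# CellulaseSim

Event-driven stochastic simulation of crystalline-cellulose hydrolysis by
endo- and exo-cellulases on an explicit two-dimensional glucan-chain
lattice.

## The problem

Enzymatic saccharification of cellulose is a heterogeneous surface
reaction: endoglucanases (EG I-like) bind at random interior sites of the
crystal surface and hydrolyze internal β-1,4 glycosidic bonds, creating new
chain ends, while processive cellobiohydrolases (CBH I/CBH II-like) thread
a free chain end through their catalytic tunnel and peel off cellobiose
unit by unit. Bulk rate equations cannot represent the spatial effects that
dominate this chemistry — enzyme crowding, surface heterogeneity, the
hydrogen-bond network that holds chains in the crystal, and the endo–exo
synergy that arises because endo-generated chain ends feed the processive
enzymes. `CellulaseSim` is for modellers and enzymologists who want those
effects explicit: every glucose unit, bond and enzyme particle is tracked
individually.

## The model

The substrate is the surface layer of a cellulose Iβ crystal: `n` parallel
glucan chains of equal degree of polymerization, nonreducing ends at column
0. Each glucose unit carries state flags (soluble, chain-end type, covered
by / locked for an enzyme); units are linked by intra-chain glycosidic
bonds and one effective inter-chain hydrogen bond per vertically adjacent
pair. Any connected fragment shorter than 4 units dissolves instantly as
glucose, cellobiose or cellotriose, which are inert thereafter.

Enzyme particles are explicit agents following per-particle state machines:

* **Endo-cellulase** — adsorbs to an available 9-column, 3-chain footprint
  (propensity `a = k_on · n_free · n_sites / (N_A V)`, Gillespie direct
  method), breaks the hydrogen bonds under its 4-unit catalytic core one at
  a time (rate `k_hbbreak`, racing desorption `k_off`), hydrolyzes the
  central glycosidic bond (`k_gly` vs `k_off`), and desorbs.
* **Exo-cellulase** — binds a free reducing (exo-R) or nonreducing (exo-N)
  end, instantly breaks the hydrogen bonds under its footprint, then runs a
  cleave-and-slide cycle: each step takes
  `t_process = t_move + t_hbbreak · nrHb` and releases one cellobiose. It
  waits `t_stay` when blocked by another enzyme, desorbs voluntarily with
  probability α per cycle, and desorbs fast (`k_offfast`) when the chain
  under its tunnel is discontinuous.

All waiting times are exponential except the deterministic processive step;
a single master event queue (one pending event per bound enzyme plus one
adsorption clock per species) advances continuous time asynchronously.
Reference parameters: endo `k_on = 100 (s·M)⁻¹`, `k_off = 0.1 s⁻¹`,
`k_gly = 0.35 s⁻¹`, `k_hbbreak = 10¹² s⁻¹`; exo `k_on = 10⁴ (s·M)⁻¹`,
`k_off = 10 s⁻¹`, `t_move = t_stay = 12 s`, `t_hbbreak = 10⁻¹² s`,
`α = 0.1`; `k_offfast = 10 · k_off`. The reaction volume is `V = S·d` with
`S` the sheet area (5.512 × 10⁻¹⁹ m² per cellobiose unit) and `d ≈ 1 µm`.

## Worked example

A 1 µM + 1 µM endo/exo-R mixture on a 5 × 5000-unit sheet, run to 50 %
conversion:

```r
library(CellulaseSim)
set.seed(1)
sheet <- celluloseSheet(5, 5000)
sys <- hydrolysisSystem(sheet, list(endoCellulase(concentration = 1e-6),
                                    exoCellulase("R", concentration = 1e-6)))
sys
#> HydrolysisSystem: 5 x 5000 lattice, t = 0 s, conversion 0.0000
#>   volume 6.89e-18 L (d = 1e-06 m)
#>   endo : 0 bound / 4 free, 24960 available sites, a = 2.406 s^-1
#>   exoR : 0 bound / 4 free, 5 available sites, a = 0.0482 s^-1

run <- runHydrolysis(sys, threshold = 0.5)
run$firstPassage["p50"]
#>      p50
#> 14589.08
run$tally
#>   G1   G2   G3
#>  338 5260  548
sugarConcentrations(run$tally, systemVolume(sys))
#>         sugar count      molar_M    mass_gL
#> 1     glucose   338 8.146041e-05 0.01467557
#> 2  cellobiose  5260 1.267697e-03 0.43392840
#> 3 cellotriose   548 1.320719e-04 0.06662197
```

The mixture reaches 50 % conversion after about 4.1 simulated hours.
Cellobiose dominates the soluble sugars because every processive step
releases one cellobiose and endo cuts near existing cuts release short
oligomers; the 2.4 s⁻¹ initial endo adsorption propensity against 0.05 s⁻¹
for exo-R reflects the scarcity of free chain ends (5 reducing ends on a
pristine sheet vs ~25 000 interior endo sites) — the origin of endo–exo
synergy.

Ready-made experiments (endo-only and exo-only time courses, loading
sweeps, imperfect-crystal lag-phase runs, synergy, exo:endo ratio
optimization, volume and substrate-size sensitivity) are available through
`presetConfig()` / `runPreset()`, and a thin command-line front end lives
in `inst/scripts/cellulase-sim.R`:

```sh
Rscript inst/scripts/cellulase-sim.R preset fig12_synergy --out runs/
```

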
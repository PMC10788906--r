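# holehopr

Trajectory analysis and electron-transfer theory for tryptophan-to-tryptophan
hole hopping in photosensitized proteins.

## What this is for

In Re-labeled azurins and similar systems, a photogenerated hole at the
chromophore migrates toward the buried redox center through tryptophan
relays. The critical elementary step is a hop between two adjacent indoles —
here labeled W124 (hole = state CS1) and W122 (hole = state CS2). Whether and
when that hop happens is controlled by the environment: fluctuations of the
electrostatic potential at the two indoles drive their diabatic states to
degeneracy, water reorganizes around the cationic indole, and the chromophore
toggles between "in" and "out" rotamers that gate the preceding step.

`holehopr` gives a simulation analyst the complete toolchain for
characterizing this step from trajectory data:

* **I/O and data model** — PDB topologies with fragment maps and charge
  sidecars (via `bio3d`), multi-frame XYZ trajectories with `t=<fs>` comment
  times, per-fragment charge/spin/coupling CSV series.
* **Geometry** — shortest heavy-atom contacts, centroid distances, ring-plane
  angles, and in/out conformer classification with hysteresis.
* **Solvation** — proximal water assignment (each water belongs solely to its
  closest residue), proximal g(r) with Monte-Carlo shell volumes, coordination
  numbers, and donor–water–water–acceptor hydrogen-bond bridge detection.
* **Electrostatics** — potentials averaged over scaled van der Waals surfaces
  of the indoles, partitioned by source (solvent / protein / reduced
  sensitizer / selected residues), and potential-times-charge stabilization
  energies.
* **ET detection** — CS1/DELOC/CS2/BACK_ET state labeling, onset detection by
  charge-equality interpolation, reactive/unreactive/back-ET outcome
  classification, delocalization and occupancy-equilibrium statistics, and
  lagged potential-to-charge correlation.
* **Theory** — Marcus barriers, the strong-coupling correction
  `H_ab − H_ab′²/λ`, Landau–Zener adiabaticity `2πγ =
  π^{3/2}⟨H_ab²⟩/(hν_eff√(λk_BT))`, and rate/lifetime estimates.
* **Synthetic generator** — a seeded two-state diabatic model (OU energy gap
  with telegraph mean switching) that emits topologies, trajectories, charge
  series, and ground-truth labels for testing every estimator above.

Everything is tibble-first and pipe-friendly; result objects carry
`tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

Generate a synthetic system with one forced CS1→CS2 conversion near 900 fs,
detect the hop, and evaluate the theory block:

```r
library(holehopr)

cfg <- synthetic_config(n_frames = 2000, n_waters = 60, seed = 42,
                        forced_switch_time = 900)
sys <- generate_system(cfg)

outcome <- classify_outcome(sys$series)
glance(outcome)
#> # A tibble: 1 × 4
#>   verdict  n_events onset_fs deloc_fraction
#>   <chr>       <int>    <dbl>          <dbl>
#> 1 reactive        1     958.          0.114
```

The trajectory is classified `reactive`: the hole crossed over (the first
time the two indole charges were equal) at 958 fs — the OU gap needs some
50 fs after the 900 fs mean switch to actually reach degeneracy — and in the
CS2 segment the hole remains 11% delocalized onto W124, the expected minority
share at the generator's operating point.

Conformer occupancies come from the chromophore–W124 contact distance:

```r
g <- geometry_series(sys$trajectory, sys$topology)
classify_conformers(dplyr::filter(g, pair == "dmp-W124")$d_min)$occupancy
#>    in   out
#> 0.929 0.071
```

The theory layer reproduces the step's printed energetics from its inputs
(λ = 800 meV, ΔG = +11 meV, H_ab = 40 meV at the crossing, H_ab′ = 10 meV
near the CS1 minimum):

```r
et_parameters(lambda = 800, delta_g = 11, h_ab = 40, h_ab_min = 10,
              nu_n = 1e10, activation_factor = 1.2e-3)
#> Electron-transfer theory report
#>   lambda = 800 meV, deltaG = 11 meV, T = 298 K
#>   Marcus barrier:            205.54 meV
#>   Coupling-corrected barrier: 165.66 meV
#>   nu_eff at 2*pi*gamma = 1:  1.5e+13 s^-1 (period 66.5 fs)
#>   rate = 1.2e+07 s^-1, lifetime = 83.3 ns
```

Quoted to the nearest 10 meV these are the familiar 210 meV (Marcus) and
170 meV (coupling-corrected) barriers; with the nuclear frequency bounded by
(100 ps)⁻¹ the predicted lifetime bound is 83 ns.

For an end-to-end run (geometry → potentials → detection → solvation →
theory, with CSV/JSON artifacts) use `run_pipeline()`:

```r
res <- run_pipeline(list(synthetic = list(n_frames = 500, seed = 1),
                         out_dir = "run1"))
```

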
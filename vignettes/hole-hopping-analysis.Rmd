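---
title: "Analyzing tryptophan hole hopping: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing tryptophan hole hopping: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(holehopr)
library(dplyr)
```

## The problem

In photosensitized redox proteins such as Re-labeled azurins, an oxidizing
equivalent ("hole") created at a metal-diimine chromophore can migrate to the
protein surface through a chain of tryptophan residues. The elementary step
this package is built around is a hop between two adjacent tryptophan
indoles, here called W124 and W122: the charge-separated state with the hole
on W124 is CS1, the state with the hole on W122 is CS2, and near-equal
sharing is DELOC. The questions the analysis answers are the ones a
simulation study of such a step asks:

* How close are the chromophore and the indoles, and does the chromophore
  rotamer ("in" versus "out") gate the chemistry?
* When does the hole actually move, and what fraction of trajectories
  complete the hop, stall, or lose the hole to recombination (back-ET)?
* Does the electrostatic potential of the environment (solvent and protein)
  *drive* the hop — i.e., do potential fluctuations precede charge
  fluctuations?
* How is the cationic indole solvated, and do water bridges form around it?
* Given the step's energetics, what barrier and rate does electron-transfer
  theory predict?

`holehopr` implements the full chain: data model and file I/O, geometry and
conformer analysis, partitioned surface electrostatics, proximal solvation
statistics, hydrogen-bond bridge detection, ET event detection and outcome
classification, and the Marcus/Landau-Zener theory layer. Because real
QM/MM/MD data for such systems are not generally redistributable, the
package ships a first-class synthetic generator that emulates the
statistical structure of those trajectories with known ground truth; all
statistical guarantees of the analysis layer are tested against it.

## The two-state diabatic model

The generator and the detection layer share one physical picture: a hole
distributed over two sites with diabatic energy gap $\Delta E(t)$ (positive
when the hole prefers W124) and electronic coupling $H_{ab}(t) \ge 0$. The
ground state of the $2 \times 2$ Hamiltonian with diagonal
$\pm \Delta E / 2$ and off-diagonal $H_{ab}$ puts a fraction

$$ f_{124} = \tfrac12\!\left(1 + \frac{\Delta E}{\sqrt{\Delta E^2 +
4 H_{ab}^2}}\right) $$

of the hole on W124. Two consequences the tests lean on:

* $\Delta E = 0$ gives perfect delocalization ($f = 1/2$) regardless of the
  coupling, so the "first time the two indole charges are equal" is exactly
  a zero crossing of the gap;
* a minority fraction of 0.10 occurs at $|\Delta E| = \sqrt{2.56/0.36}\,
  H_{ab} \approx 2.667\,H_{ab}$, which is where the generator's CS2
  conditions are placed so that CS2 is partially (about 10%) delocalized,
  as reported for such systems.

The gap itself is modeled as an Ornstein–Uhlenbeck (OU) process whose mean
switches between a CS1-biased and a CS2-biased value by a two-state
telegraph process. The OU choice is a modeling decision, not something the
underlying physics pins down: what is known is that the gap is driven by
quasi-continuous environmental (electrostatic) fluctuations with a finite
correlation time, which OU captures with the fewest parameters. The exact
discretization ($x_{t+dt} = \mu + (x_t - \mu)e^{-dt/\tau} +
\sigma\sqrt{1 - e^{-2dt/\tau}}\,\xi$) makes the stationary variance exactly
$\sigma^2$ at any step size, which is what the variance-recovery test
asserts.

### Generator defaults and what they emulate

| Parameter | Default | Why |
|---|---|---|
| `dt` | 1 fs | typical QM/MM/MD analysis spacing |
| `tau_gap` | 100 fs | sub-ps environmental correlation |
| `sigma_gap` | 50 meV | thermal-scale gap fluctuations ($\approx 2 k_B T$) |
| `gap_mean_cs1` | +300 meV | strongly localized CS1 (~2% minority) |
| `gap_mean_cs2` | $-2.667 \times$ CS2 coupling | the 10% minority operating point |
| `coupling_mean` / `coupling_mean_cs2` | 40 / 100 meV | coupling rises on approach to and inside the ET region |
| `k_cs1_cs2` / `k_cs2_cs1` | 0.65e-3 / 1.0e-3 fs$^{-1}$ | equilibrium ratio 0.65, the experimentally inferred CS1/CS2 constant |
| `k_in_out` / `k_out_in` | 0.37e-3 / 0.63e-3 fs$^{-1}$ | 63% "in" occupancy |
| `lag_fs` | 5 fs | potential fluctuations precede charge response by a few fs |
| `dmp_charge` | $-0.45$ e | diimine share of the reduced sensitizer |
| `n_waters`, `box_edge` | 100, 30 Å | enough solvent for solvation statistics without periodic images |

Couplings are log-normal (couplings are positive and right-skewed) around a
state-dependent median, and in the full geometric generator they are
additionally modulated by $e^{-2\,\delta d}$ where $\delta d$ is a smoothed
displacement of W122 along the inter-indole axis — the same displacement
applied to the coordinates — giving the negative coupling–distance
correlation seen in such data. The charge response uses the gap *delayed*
by `lag_fs`, so the injected driver-to-charge lag is a known ground truth
the lag estimator must recover.

What the generator does **not** emulate: real force-field energetics,
water orientational structure and explicit hydrogen-bond dynamics (the
water bias is a centroid-directed drift with solute-clash rejection, which
produces realistic *occupancy* statistics but not realistic water
*orientations*), periodic boundary conditions, and any electronic-structure
detail beyond the two-state model. Tests passing on generator output
therefore certify the *estimators* — not force fields, and not the real
protein.

## Geometry and conformers

Contact distances are minima over heavy-atom pairs; center-to-center
distances use unweighted heavy-atom centroids; ring-plane angles come from
a principal-axis fit (the plane normal is the axis of least variance),
folded to [0°, 90°]. Plane–plane angles were chosen over long-axis angles
for the inter-indole orientation; for near-planar fragments the plane
normal is the better-conditioned quantity.

Conformer classification thresholds the chromophore–W124 contact distance
at 5.0 Å with a ±0.3 Å hysteresis band. The two poses sit near 3.4 Å ("in")
and 6.5–7 Å ("out"), so the threshold lies midway where neither pose
dwells; the hysteresis suppresses spurious switch counting from thermal
jitter without changing occupancies (a property test asserts hysteresis
never increases the switch count). The first frame takes the nearest side
of the threshold.

## Proximal solvation

Every water (located at its oxygen) is assigned *solely* to the residue
whose nearest heavy atom is closest, ties to the first-listed residue. The
proximal radial distribution function normalizes shell counts by the
volume of the proximal shell — the set of points whose nearest solute
heavy atom belongs to the residue at that distance — estimated by
rejection (Monte-Carlo) sampling of the simulation box with a caller-fixed
seed. This estimator is exact in expectation for arbitrary residue shapes,
at the cost of sampling noise $\propto 1/\sqrt{N_{MC} \cdot
V_{shell}/V_{box}}$: very thin or deeply buried shells are noisy, which is
why the uniform-water oracle test asserts the 2% band on shells with
adequate volume (r ≥ 3 Å at 1.5 Å bin width) and a loose sanity band
elsewhere. Coordination numbers integrate raw assigned counts (not g(r)),
so summed over residues at infinite cutoff they recover the exact water
count — a conservation law the tests check per frame.

## Surface electrostatics

Potentials are evaluated on scaled van der Waals surfaces of the indoles:
Fibonacci-lattice points (seeded random rotation, deterministic per seed)
on spheres of radius $2.0 \times r_{vdW}$ around each heavy atom, with
points inside any sibling sphere removed. The scale factor 2.0 probes the
near-solvent region just outside contact; it is exposed in configuration
because reasonable studies may prefer 1.4–2.5. The potential is the
unweighted mean over surviving points of $k_e \sum_i q_i / d_i$
($k_e = 14.399645$ V·Å/e), linear in charges, with sources partitioned
into solvent, the reduced sensitizer, the labeled segment, Q107, and the
remaining protein; both indoles are always excluded from the sources. The
additivity of the partition (components sum to the total at every frame)
is enforced by construction and asserted to $10^{-9}$ V. Electrostatic
stabilization energies are plain $\sum_f \phi_{ext}(f)\, q_f$ dot
products, in eV.

A note on thresholds: in reactive trajectories of the real system the ET
region is entered when $\Delta\phi$ reaches about +1.1 V. That number is
dataset-specific — it depends on charge sets, surface definition, and
scale factor — so the package reports $\Delta\phi$ at onset rather than
hard-coding a universal threshold.

## ET detection

The hole fraction $f = q_{124}/(q_{124}+q_{122})$ is defined only while
the summed indole charge stays above `hole_floor` (default 0.5 e); below
it the hole has recombined and frames are labeled BACK_ET. Labels use
`f_hi = 0.8`: CS1 at $f \ge 0.8$, CS2 at $f \le 0.2$, DELOC between. No
universal thresholds exist for these labels; 0.8 was chosen once so that
the described regimes — strongly localized CS1 (~2% minority), ~10%
delocalized CS2, and a genuinely shared DELOC band — map to distinct
labels, and the thresholds are exposed in configuration. Sensitivity is
observable rather than hidden: `label_states()` takes `f_hi` directly.

The ET onset is the first time the two indole charges are equal, located
by linear interpolation of $q_{124} - q_{122}$ between bracketing frames;
crossing direction distinguishes forward from reverse events. An outcome
is `back_ET` if a sustained (≥ `min_cs2_dwell`, default 200 fs) BACK_ET
segment exists, else `reactive` if a forward onset is followed by a
sustained CS2 segment, else `unreactive`. The 200 fs dwell is an
operational definition of "sustained" sitting below the 500–1000 fs ET
regions such trajectories exhibit but far above single-frame noise.

Lagged correlation of two series uses Pearson correlation of
$x(t-\tau)$ against $y(t)$ on a lag grid (default ±50 fs at the native
step); a positive best lag means $x$ precedes $y$. Applied to the
potential driver and the charge difference it recovers the generator's
injected lag exactly at grid resolution.

## Theory layer

With $\lambda$ the reorganization energy and $\Delta G$ the driving force
(both meV), the Marcus barrier is $(\lambda + \Delta G)^2 / 4\lambda$.
For strong coupling the barrier is lowered by $H_{ab} - H_{ab}'^2 /
\lambda$ ($H_{ab}$ at the crossing, $H_{ab}'$ near the reactant minimum),
floored at zero. Adiabaticity is quantified by
$2\pi\gamma = \pi^{3/2} \langle H_{ab}^2 \rangle / (h \nu_{eff}
\sqrt{\lambda k_B T})$; the inverse problem (the $\nu_{eff}$ giving
$2\pi\gamma = 1$) marks the nuclear frequency below which the transfer is
adiabatic. Rates follow $k = \nu_N e^{-\Delta G^\ddagger / k_B T}$, with
an entry point accepting a pre-computed activation factor for
reproducing quoted numbers whose exact temperature convention is not
stated. The default temperature is 298 K; the unit-adiabaticity frequency
moves by under 2% across 293–310 K, so this choice is not load-bearing.

```{r theory}
rep <- et_parameters(lambda = 800, delta_g = 11, h_ab = 40, h_ab_min = 10,
                     nu_n = 1e10, activation_factor = 1.2e-3)
tidy(rep)
```

Quoted to the nearest 10 meV (half-up — the convention used for barrier
round-offs in this literature), the barriers above read 210 and 170 meV,
and the lifetime bound is 83 ns.

## Numerical choices and degenerate inputs

* All distances Å, times fs, charges e, potentials V, fragment energies
  eV, theory energies meV; constants live in one exported list.
* Zero-gap, zero-coupling input to the two-state model returns exact
  sharing (0.5) rather than NaN.
* Collinear fragments have no plane: an error, not a silent zero. Plane
  fits reject fragments whose second principal variance is numerically
  zero.
* A source atom within $10^{-6}$ Å of a mesh point raises a degeneracy
  error naming the atom rather than returning a huge potential.
* Ties in proximal assignment go to the first-listed residue —
  deterministic and documented rather than arbitrary.
* All stochastic estimators (surface meshes, shell volumes, the
  generator) take explicit seeds, save and restore the global RNG state,
  and are byte-reproducible for a fixed configuration.

## Problem sizes used in the shipped checks

The test suite runs the statistical guarantees at: $10^5$ steps for
OU-variance and occupancy-equilibrium recovery, $10^5$ Monte-Carlo samples
per frame (300 frames, 660 waters) for the uniform-water g(r) oracle, a
30-trajectory ensemble (3000 frames each) for onset/verdict recovery, and
3000-frame runs for lag recovery and delocalization. These sizes were
chosen so each check's sampling error sits several-fold below its
tolerance band (error budgets are in the comments of the corresponding
tests); the full suite completes in well under a minute on one core.

## Known limitations

* No periodic-boundary minimum-image handling: the generator's box is
  larger than any analysis cutoff, and file-based input is assumed
  whole-molecule imaged.
* The H-bond bridge search enumerates at most two intervening waters and
  uses a single geometric criterion (donor–acceptor distance ≤ 3.5 Å,
  donor–H···acceptor angle ≥ 120°, both configurable); display-style
  cutoffs (e.g. 3.2 Å) can be set but are not defaults.
* One charge track per source: per-frame fragment charges come from the
  series file, static atomic charges from the topology sidecar, and the
  package does not attempt to reconcile population-analysis charges with
  force-field charges when both are present.
* The theory layer is equilibrium Marcus/Landau–Zener; nonequilibrium
  (solvent-control/Sumi–Marcus) models are out of scope.
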
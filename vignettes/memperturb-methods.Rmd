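---
title: "Methods: membrane perturbation analysis for permeation-enhancer trajectories"
author: "memperturb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: membrane perturbation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memperturb)
```

# Scope and model system

`memperturb` analyses molecular-dynamics trajectories of planar
phospholipid bilayers doped with intestinal permeation enhancers (PEs) —
small amphiphiles such as caprylate, caprate, laurate, SNAC or sucrose
monolaurate that are co-formulated with peptide drugs to increase
epithelial permeability. The reference system is a POPC bilayer with 64
lipids per leaflet in a periodic box of roughly 6.60 x 6.60 x 9.35 nm,
simulated near body temperature (310.15 K), with PEs inserted into one
leaflet (the model of the apical epithelial face) at 5--35% of the
leaflet's lipid count (3--22 molecules; `peCountFromPercent()`).

The package implements the downstream analysis only. It does not run
molecular dynamics; trajectories come from an MD engine as multi-frame
GRO or PDB files (binary formats are out of scope behind a documented
reader seam), and umbrella-sampling windows come as plain-text
time/coordinate sample files. Units are nm, ns and kcal/mol throughout.

# Event detection

## The classification rule

A PE belongs to a leaflet while its reference site is within `r_expel` =
0.9 nm (minimum image) of any of that leaflet's POPC phosphate atoms.
Beyond that distance from both leaflets it is in water; when both
leaflets' cutoffs are satisfied, the nearer leaflet wins. The distance
rule is evaluated against both leaflets by default
(`expel_both_leaflets`); a flag restricts it to the initial leaflet,
since the criterion as usually phrased is ambiguous on this point.

The anchor atom for the distance is the PE polar-head heavy atom
(carboxylate carbon for fatty acids; configurable through the
`pe_reference` role pattern), because no single convention exists for
which atom anchors the cutoff.

## The state machine

`detectEvents()` runs a debounced state machine per PE over the
per-frame classification:

* A new state must persist `debounce_frames` (default 5) consecutive
  frames to commit. This prevents a molecule oscillating at the 0.9 nm
  shell from generating spurious event pairs.
* A committed transition to water is an **expulsion**.
* A committed arrival in the other leaflet is a **flip-flop** only if
  the unwrapped z-path actually traversed the bilayer interior and
  never wandered more than half a box height from the membrane centre.
* If the unwrapped path did exceed half a box height, the molecule
  left through a periodic z-face and re-entered on the other side; such
  an arrival is a **pbc_crossing_as_expulsion** — counted with
  expulsions and never as a flip-flop, since nothing traversed the
  bilayer interior.
* Re-entry after an expulsion is tracked in the occupancy series (the
  remaining-in-leaflet count dips and recovers) but does not erase the
  expulsion event: expulsion counts are cumulative.

One subtlety required a refinement beyond the plain three-state rule: a
molecule in the middle of a genuine flip is transiently more than
0.9 nm from *both* phosphate planes, which the distance rule alone calls
"water". `detectEvents()` therefore distinguishes exterior water from
the bilayer interior (|z - z_center| less than one leaflet thickness)
and treats interior frames as transit that extends the previous
committed state. Without this, every slow flip would be miscounted as an
expulsion followed by an insertion. The public `classifyState()` keeps
the plain three-state contract.

z-unwrapping accumulates minimum-image per-frame displacements. The
periodic-boundary discriminator is "unwrapped |z - z_center| exceeds
box_z/2 anywhere on the excursion" rather than the net displacement
between commit frames: the net displacement is blunted by the two
cutoff depths and can fall just short of box_z/2 for a genuine crossing
(we observed exactly this on scripted trajectories).

# Structural metrics

* **Area per lipid**: box_x * box_y / 64. The divisor is the leaflet's
  POPC count; inserted PEs never enter the denominator.
* **Thickness**: phosphate-plane (P--P) separation. `global` mode is the
  difference of leaflet mean phosphate z; `local` mode averages, per
  lipid, the distance to the mean z of its k = 6 laterally nearest
  opposite-leaflet phosphates (a neighbourhood-based local thickness in
  the spirit of published local-thickness algorithms, without their full
  normal-field machinery). Both are provided because published
  thickness numbers rarely state which variant was used. Leaflet
  thickness is half the P--P value.
* **Membrane centre**: midpoint of the two leaflet mean phosphate z.
* **PE depth** d: |z_com(PE heavy atoms) - z_center| with minimum-image
  handling, the standard insertion-depth coordinate.

# Order parameters

The deuterium order parameter of a C--H bond against the bilayer normal
is S_CD = <(3 cos^2 theta - 1)/2>: 1 for perfect alignment, -0.5 for
bonds in the membrane plane, 0 for an isotropic distribution. The
normal is fixed to +z; the membranes analysed here are planar and
z-normal, so no instantaneous-normal estimation is attempted.

When explicit hydrogens are absent (united-atom or synthetic chains),
C--H directions are reconstructed from adjacent-carbon geometry: at
carbon n the two hydrogens lie in the plane spanned by the inverse
bisector of the C(n-1)--C(n)--C(n+1) bonds and the bond-plane normal, at
half the tetrahedral H--C--H angle from the bisector. For an ideal
all-trans chain along z this construction gives exactly S_CD = -0.5 at
every interior carbon, which the tests exploit as a closed-form oracle.
Chains must zigzag — for exactly colinear carbons the construction is
undefined and the package raises an error rather than guessing.

Profiles default to the sn-1 chain (the chain usually plotted), with
sn-2 available. `peOrderParameter()` applies the same estimator to the
PE chains and reports a species mean with the standard deviation over
molecules.

# Lateral diffusion

`lateralDiffusion()` computes the in-plane mean squared displacement
over all sliding time origins using the FFT autocorrelation algorithm
(verified against the brute-force definition in the tests), after
removing the per-leaflet centre-of-mass drift — leaflets carrying PEs
can drift laterally, which contaminates the MSD. The 2-D Einstein
relation gives D_L = slope/4 from an ordinary least-squares fit of
MSD(tau).

Two windows matter and both are configurable: the maximum lag defaults
to one tenth of the series length (longer lags average too few origins
to be useful), and the fit uses lags between 10% and 90% of that
maximum, discarding the short-lag regime and the noisy tail. The
original analyses do not state their fit protocol; these defaults
mirror common practice of the standard MSD tools.

# Water permeation and fractional interactions

Water permeation is counted as the number of distinct water molecules
whose oxygen lies within `r_water` = 0.5 nm (minimum image) of any atom
of the terminal-tail region — the last three carbons of both acyl
chains plus their hydrogens when present — normalised per lipid
(n = 128) and reported as mean +/- sd over frames.

Fractional interactions quantify mixing in the PE-bearing leaflet. Two
molecules are in contact when their headgroup sites (phosphate for
POPC, the reference atom for PEs) are closer than 0.9 nm; multiple
atomic contacts of a pair count once. Raw pair counts C_ij are averaged
over frames first and then normalised (the averaging order is a
documented package choice), corrected for abundance by the number of
possible pairs — N_i N_j between species, N_i (N_i - 1)/2 within — and
row-normalised. This normalisation provably yields 0.5 in every cell
for an ideal two-component mixture, the calibration point the field
uses. Only molecules assigned to the PE-bearing leaflet at each frame
(via the event module's state) enter the matrix.

# Umbrella sampling and the partition ratio

## WHAM

`whamSolve()` iterates the standard weighted-histogram equations on a
uniform half-open bin grid until the window free energies move by less
than `wham_tol` (1e-6 kcal/mol; F initialised to zero, iteration cap
1e5, deterministic given inputs). The PMF is G = -RT ln P, shifted so
its mean over the water reference zone (distance from centre >= 2.3 nm
by default — beyond the 1.95 nm leaflet plus headgroups — or any
configured interval) is zero.

Two numerical choices deserve note:

* **Bias factor per bin.** The harmonic bias is not evaluated at the
  bin centre but integrated analytically over the bin (an erf
  expression). With stiff springs the bias varies by several RT across
  a bin and the centre-point approximation visibly distorts the tails.
* **Bin width.** The default is 0.01 nm. With the conventional stiff
  pull spring (about 240 kcal/mol/nm^2, i.e. 1000 kJ/mol/nm^2) we
  measured a systematic ~0.2 kcal/mol washout of well depths at
  0.05 nm bins; 0.01 nm bins converge to the true potential and match
  the resolution the standard WHAM tools default to.

Bins visited fewer than `pmf_min_count` = 150 times are flagged poorly
sampled (the per-bin statistical uncertainty of G is about RT/sqrt(n),
so 150 counts keep it near 0.05 kcal/mol); `extractDeltaG()` searches
the membrane zone for the minimum over well-sampled bins only.

## Partition ratio conventions

`partitionRatio()` converts the free-energy difference between the
membrane-interior minimum and water (Delta G = G(minimum) - G(water),
negative when the interior is favourable) into the outside/inside
concentration ratio. Two conventions are implemented:

* `"paper"` (default): Co/Ci = exp(Delta G / (ln 10 * R * T)).
* `"boltzmann"`: Co/Ci = exp(Delta G / (R T)), the textbook form.

The default reproduces the published ratio table exactly (all six
values within 0.01 at T = 310.15 K with R = 1.9872e-3 kcal/mol/K),
which the textbook form does not — e.g. for Delta G = -2.21 kcal/mol it
gives 0.21 versus Boltzmann's 0.03. Whether the extra ln 10 in the
source is a deliberate log10 convention or a slip cannot be determined
from the text; both forms are exposed and neither intent is asserted.
Reproduction work should use `"paper"`; new analyses should choose
deliberately.

`aggregateReplicates()` averages replicate PMFs pointwise and reports
the sample standard deviation (n - 1 denominator), matching
mean-and-sd error-band plotting.

# The synthetic-data module

Every pipeline input can be generated with known ground truth, so all
stages are testable with no MD engine and no download:

* `makeBilayerTrajectory()` places the two phosphate planes 1.95 nm
  either side of the box-z midpoint (the pure-POPC leaflet
  half-thickness) in a 6.60 x 6.60 x 9.35 nm box, with terminal tail
  carbons as inward vertical zigzags, waters outside the membrane slab,
  and PEs following scripted piecewise-linear z-paths (stay, expel,
  flip-flop, boundary-cross, expel-and-re-enter) with small lateral
  jitter. Piecewise-linear paths make commit frames unambiguous for
  precision/recall tests. Ground truth (events, remaining series,
  scripted interior-water counts) is emitted alongside and verified by
  an independent re-scan of the z-paths (`rescanRemaining()`).
* `makeBrownianWalkers()` draws 2-D Gaussian steps of variance 2 D dt.
* `makeOrientationEnsemble()` produces aligned, in-plane, isotropic and
  fixed-cone bond-vector sets with closed-form order parameters.
* `makeUmbrellaSamples()` draws exact Boltzmann samples of a tabulated
  potential under harmonic biases by inverse-CDF lookup on a fine grid
  (20001 points by default). The CDF is midpoint-corrected: a plain
  cumulative sum places each cell's mass at its right edge, shifting
  every sample by half a cell against its bias centre, which tilts the
  window free-energy ladder by k * delta * spacing per window — a
  0.16 kcal/mol end-to-end artefact at default settings before the
  correction.
* `makeLatticeMixture()` builds ideal or segregated two-species planar
  configurations at membrane-like density (0.65 nm^2 per molecule).

What the generator does **not** emulate: real lipid dynamics
(positions are static apart from jitter), undulations, realistic chain
conformations, solvent structure, or any force field. Passing tests
therefore demonstrate that the estimators are correct on inputs whose
answer is known — not that any MD-derived observable (expulsion
fractions, APL shifts, thickness changes, PMF minima locations) is
reproduced; those require the original 500 ns simulations.

# Problem sizes used in the checks

The test suite and acceptance checks run at sizes chosen to keep
statistical error comfortably inside each tolerance while remaining
desk-scale: 20 umbrella windows x 5e4 samples for potential recovery,
512 walkers x 1e4 steps for diffusion (recovery well within 5%), 1000 +
1000 molecules for the ideal-mixing calibration, 22-PE bilayers of
60--80 frames for event fidelity.

# Degenerate inputs and tie-breaks

* Leaflet membership ties (inside both cutoffs) resolve to the nearer
  leaflet, deterministically.
* Colinear chain carbons error out of C--H reconstruction.
* Windows with no shared populated bins abort WHAM with a
  non-overlap error; hitting the iteration cap returns the partial
  profile flagged `converged = FALSE` with a warning.
* An empty water reference zone falls back to zeroing the profile
  minimum.
* A species absent from a mixture drops out of the fraction matrix.
* POPC leaflet assignment is asserted constant across frames (lipid
  flip-flop is absent in these systems); a change raises a warning.

# Known limitations

* The GRO reader assumes fixed-column, concatenated frames with
  constant atom count; XTC/TRR are not read (documented seam:
  `readTrajectory()` dispatches on extension).
* No autocorrelation/statistical-inefficiency correction in WHAM;
  samples are treated as independent, appropriate for the synthetic
  generator and a documented approximation for real window data.
* One-dimensional reaction coordinates only.
* The mM conversion (`peConcentration()`) uses a fixed bulk water
  molecular volume of 0.030 nm^3 and is informational.
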
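---
title: "Methods: orientation descriptors, bootstrap uncertainty and two-state dynamics for pentamer trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientation descriptors, bootstrap uncertainty and two-state dynamics for pentamer trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentadyn)
```

`pentadyn` analyzes molecular-dynamics trajectories of the phospholamban
(PLN) pentamer and similar bitopic membrane proteins. This vignette is the
package's account of its methods: the models and their assumptions, the
parameters that matter, the numerical choices, and the limits of what the
synthetic validation can show.

## The system and its descriptors

The PLN monomer has four structural domains, fixed throughout the package
by `domain_definitions()`: the cytoplasmic helix Ia (residues 1–16), a
β-turn hinge (17–22), and the transmembrane helices Ib (23–30) and II
(31–52). The transmembrane portion is anchored in the bilayer; the
cytoplasmic helix is the mobile element whose orientation distinguishes the
two known pentamer architectures — the extended ("R"-state, bellflower)
form with cytoplasmic helices pointing away from the membrane, and the bent
("L"-state, pinwheel) form with them lying near the membrane plane.

Two scalar descriptors per chain and frame capture this:

- **θ (degrees)** — the angle between the cytoplasmic-domain line and the
  bilayer *plane*: θ = 90° − arccos(|**u** · **n**|). The absolute value
  makes θ independent of the sign conventions of both the domain axis
  **u** and the membrane normal **n**, so θ ∈ [0°, 90°].
- **d (Å)** — the distance of the cytoplasmic-domain Cα centroid from the
  bilayer midplane along the normal.

Three design choices here were genuinely open and are worth recording:

1. **θ is measured against the plane, not the normal.** The extended-state
   population mean near 41° describes a helix leaning away from the
   membrane surface; under the complement convention the same geometry
   would read ~49° and the extended/bent ordering of the two states would
   invert. The plane convention is the one consistent with "extended"
   being the *larger* angle.
2. **The domain axis is the line through the Cα atoms of residues 1 and
   16** — the first and last residues of the domain — not a fitted helix
   axis. This is the simplest reproducible rule and is robust to partial
   unfolding of the helix middle. A least-squares principal-axis variant
   is available (`axis_mode = "lsq"` in `orientation_series()`) for
   sensitivity analysis; on an ideal helix the two differ by a few degrees
   because the end-to-end vector of a helix is not parallel to its axis.
3. **d is referenced to the bilayer midplane**, which is independent of
   lipid composition and leaflet asymmetry. (A headgroup-plane reference
   would differ by the leaflet half-thickness, ~19 Å for POPC.)

Per-chain series are computed separately; the pentamer-level series is the
per-frame mean over chains (`aggregate_orientation()`). Averaging is the
natural condensation when the chains are exchangeable, and it reduces the
per-frame measurement noise by √5; all segmentation and bootstrap results
in the package's own experiments use the chain-mean series.

## Membrane frame estimation

With lipid reference atoms (phosphate positions or stand-ins spanning both
leaflets), `estimate_membrane_frame()` fits each leaflet by a least-squares
plane and returns the sign-aligned mean normal, the midpoint of the leaflet
centroids, and half their separation along the normal. Leaflet membership
is decided by a deterministic two-means split (initialized at the range
endpoints — no RNG) along the best-separating principal axis, then refined
once along the fitted normal. Degenerate (collinear) leaflets are an error,
as is a reference set of fewer than six atoms. Without lipid references the
declared fallback is normal = +z and midplane through the origin, the
convention in which most membrane simulations are built.

For trajectories the frame can be re-estimated per frame (default), or
estimated once from the first frame (`per_frame_membrane = FALSE`) when
the reference atoms are known to be static — the case for the synthetic
bilayer, where the single estimate is exact and ~40× cheaper.

No periodic-boundary unwrapping is attempted: inputs are assumed
whole-molecule, because unwrapping policy is MD-engine-specific.

## Superposition metrics

`kabsch_superpose()` is the standard SVD solution of the least-squares
rigid superposition problem with the reflection guard (the smallest
singular direction is sign-flipped when the raw optimum is improper), so
the returned rotation always has determinant +1. It refuses collinear point
sets, where the rotation is not identifiable.

`rmsd_series()` superposes every frame onto the reference over the fit
selection (default: all Cα) and reports the RMSD over the measured
selection. The reference defaults to the first frame of the trajectory —
the "deviation from the initial structure" convention — and can be any
external model. The pentamer default fits all 260 Cα jointly; per-chain
analyses just pass per-chain index sets.

`rmsf_profile()` uses the iterative mean-structure procedure: superpose all
frames onto the current mean, recompute the mean, repeat until the mean
moves by less than 1 Å × 10⁻⁶ (at most 20 iterations; convergence is
typically 3–4). This removes the reference-choice bias of first-frame
RMSF. One property of rigid-body fitting worth remembering when reading
profiles: localized motion leaks slightly into all other atoms through the
six fitted degrees of freedom, at a level ~√(6/3N) of the moving atom's
amplitude, so "static" atoms show a small floor rather than exactly zero.

For isotropic Gaussian displacement of variance σ² per coordinate both the
mean RMSD and the RMSF converge to σ√3; the test suite checks this
closed form within 5% at 2000 frames.

## Bootstrap uncertainty

Orientation series are strongly autocorrelated, so naive standard errors
are optimistic. `block_bootstrap()` implements the moving-block bootstrap:
each resampled dataset draws ⌈L/b⌉ contiguous blocks of b frames with
replacement and truncates to length L; the summary (mean, SD, percentile
CI) describes the distribution of resample means. Defaults: b = frames
spanning 1 ns, 1000 resamples, 95% percentile CI. One nanosecond comfortably
exceeds the sub-nanosecond orientational correlation times of the domain
motion modelled here, which is the condition for the block SD to be an
honest standard error.

Because published "mean ± value" tables rarely state which spread they
print, the summary carries three: `sd` (the resample SD — the headline
standard error), `series_sd` (the plain time-series SD, which measures the
width of the population, not the uncertainty of its mean), and — from the
two-level scheme — `between_trajectory_sd`.

`multi_trajectory_summary()` is the estimator for repeated independent
simulations: trajectories are resampled with replacement, then blocks
within each, and each resampled dataset's statistic is the mean of its
per-trajectory blocked means. This propagates between-run spread, which
dominates when runs are short relative to slow conformational exchange. A
single series falls back to the within-trajectory bootstrap and records a
warning in the result.

All resampling is driven by an explicit integer seed, restored-state
local RNG, and is bit-reproducible; the seed is echoed in every summary.

Known calibration properties, verified in the test suite: on iid series the
resample SD matches σ/√L within 15%; on AR(1) series with autocorrelation
time τ, blocks of b ≥ 5τ reproduce the analytic standard error within 25%
while b = 1 underestimates it; empirical 95% CI coverage on iid data sits
in [0.90, 0.99]. Percentile CIs of a mean with b a small multiple of τ
genuinely undercover somewhat (true coverage ≈ 92% in the package's own
experiments) — a known property of the method, not a defect of the
implementation; practitioners who need sharper calibration should increase
b toward 10τ at the cost of fewer blocks.

## Two-state segmentation

`classify_states()` labels frames by a hysteresis rule: switch to
*extended* at θ ≥ θ_up, to *bent* at θ ≤ θ_down, otherwise keep the
previous label; frames before the first crossing are *undecided*. The dead
band suppresses chatter when θ fluctuates near a single boundary. Defaults
θ_up = 35°, θ_down = 28°: these bracket 30° — the convergence zone of the
phosphorylated systems — and separate the extended (≈41°) and bent (≈23°)
population means by roughly symmetric margins (≈0.7 population SDs each).
No published threshold defines the states, so these are this package's
choice, fully configurable, and reports should treat them as such.

`detect_transitions()` then merges label runs shorter than `min_dwell_ps`
(default 1 ns, matching the bootstrap block scale) into their flanking
state, shortest first, and reports transitions at the first frame of each
surviving run. Dwell times use the start-to-next-start convention, so
per-state dwell times plus the undecided prefix sum exactly to the series
duration. θ alone drives classification; d is reported alongside as
corroborating evidence, not as a second classifier.

## The synthetic generator

`generate_synthetic()` builds Cα-only pentamer pseudo-trajectories in
which the analysis answer is *planted*, making every stage testable
closed-loop without MD output:

- Per chain, the state s(t) follows a continuous-time two-state Markov
  chain (exact exponential waiting times, recorded as ground truth);
  θ(t) and d(t) follow Ornstein–Uhlenbeck processes relaxing toward the
  active state's well with the state's stationary SD. The OU update uses
  the exact discretization, so statistics are correct at any frame spacing.
- The cytoplasmic helix (ideal geometry: 2.3 Å radius, 1.5 Å rise,
  100°/residue) is re-oriented every frame so that its residue-1→16 Cα
  line has *exactly* the planted tilt, and translated so the domain
  centroid sits *exactly* at the planted midplane distance. The
  transmembrane helix is held rigid ("clamped") across frames — a
  30-residue ideal helix spans 43.5 Å and necessarily protrudes beyond a
  38-Å bilayer, as the real TM domain does; what matters for the analyses
  is that it is immobile up to noise. The hinge interpolates between the
  segments. Chains are arranged with C5 symmetry; isotropic Gaussian noise
  (default 0.5 Å per coordinate) is added to every protein atom.
- The virtual bilayer is an 8×8 grid of phosphate stand-in pseudo-atoms
  per leaflet at z = ±19 Å (typical POPC half-thickness), chain `"X"`.

Default well parameters are the population values of the system the
package targets: extended θ 41.19 ± 8.46°, d 30.00 ± 1.19 Å; bent θ
23.40 ± 7.46°, d 33.72 ± 2.40 Å. The d SDs mirror the printed spreads of
the corresponding distance populations. The `"phosphorylated"` regime
switches to the near-degenerate wells observed after Ser16 phosphorylation
(θ 30.87 ± 9.93° and 27.37 ± 9.05°; d 32 and 37 Å) — phosphorylation is a
parameter regime here, not chemistry. Remaining free parameters, chosen
once as realistic values and not revisited: OU relaxation time 0.2 ns (a
sub-nanosecond orientational correlation time), switching rates 0.05/ns
each way (mean dwell 20 ns, the scale of the transitions the detector
exists for), 40 000 frames at 1 ps (a 40-ns production run). For planted
transition experiments, `forced_switch_ns` toggles every chain
deterministically at given times instead of stochastic switching.

What the generator does *not* emulate — and hence what green tests do not
show about real data: no force field or energetics, no side chains, no
lipid diffusion or membrane undulation (the bilayer is flat and static),
no inter-chain coupling (chains switch independently unless forced), no
drift or aging in the dynamics (the planted process is stationary within
each state), and Gaussian measurement noise only. Real trajectories break
several of these (undulating reference planes, correlated chains,
non-Markovian kinetics); the package's estimators are exercised against
the idealization, which validates the *computation*, not the physics.

## Problem sizes and numerical choices

The package's own experiments (test suite and the acceptance script) use
40-ns series sampled every 10 ps (4000 frames, 5 chains) for recovery and
detection studies, 400-ns runs for the phosphorylated-regime long-run
comparison, 50-replicate batteries for CI-coverage estimates, and
2000-frame Monte-Carlo checks of the σ√3 closed forms. Geometry oracles are
exact to 10⁻⁶; Kabsch is checked against a quaternion-search brute force to
10⁻⁶ and against bio3d's least-squares fit; file round-trips are checked at
the PDB's three-decimal precision (0.02° on recovered angles).

Other numerical conventions: unit-vector checks at 10⁻⁶; coincident axis
endpoints (< 10⁻⁶ Å) and collinear point sets are errors, not warnings;
θ is clamped into [0.5°, 89.5°] inside the generator so planted paths stay
in the descriptor's range; tie-breaks in dwell merging absorb the shortest
run first, and a short *first* run merges forward. Degenerate inputs
(empty selections, all-undecided segmentations, single-frame RMSF) raise
classed errors (`selection_error`, `insufficient_data_error`, ...) rather
than returning NA.

## Limitations

- The descriptors assume a planar bilayer; curved or undulating membranes
  need a local frame estimate the package does not provide.
- The hysteresis classifier is threshold-based by design; systems with
  genuinely intermediate states need more than two labels (no hidden-Markov
  fitting here).
- The two-level bootstrap treats trajectories as exchangeable; systematic
  differences between runs (different starting structures) belong in a
  fixed-effect comparison, for which `compare_systems()` gives differences
  with quadrature-propagated SDs.
- Percentile block-bootstrap CIs undercover mildly at b ≈ 5τ (see above).
- SERCA binding, phosphate chemistry and free energies are outside the
  package's scope: "extended"/"bent" are geometric labels, and the
  phosphorylated regime is a parameterization, not a mechanism.
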
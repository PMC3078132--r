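# pentadyn

Trajectory descriptors and two-state conformational dynamics for
membrane-protein pentamers, built around the phospholamban (PLN) system.

## The scientific problem

PLN is a 52-residue bitopic membrane protein whose pentamer regulates the
SERCA Ca²⁺ pump. Its transmembrane helix (domains Ib/II, residues 23–52)
sits in the bilayer, while the short cytoplasmic helix (domain Ia, residues
1–16) swings between two conformations: an **extended ("R", bellflower-like)
state** pointing away from the membrane and a **bent ("L", pinwheel-like)
state** lying near the membrane plane. Which state the cytoplasmic domain
occupies — and how often it interconverts — matters because only the
extended conformation is positioned to engage SERCA.

Molecular-dynamics trajectories of such systems are routinely summarized by
a small set of descriptors. `pentadyn` implements that analysis stack as a
reusable, fully tested pipeline:

- **Tilt angle θ** — the angle between the cytoplasmic-domain line (the Cα
  of residue 1 to the Cα of residue 16) and the bilayer *plane*:
  θ = 90° − arccos(|**u** · **n**|), with **u** the unit domain axis and
  **n** the bilayer normal. θ = 0° lies in the membrane plane, θ = 90° is
  perpendicular to it.
- **Membrane distance d** — the projection of the cytoplasmic-domain Cα
  centroid onto the bilayer normal, measured from the midplane:
  d = |**n** · (**c** − **p₀**)|.
- **RMSD/RMSF** — Kabsch (SVD) superposition, per-frame RMS deviation from
  the initial (or a supplied) structure, and per-residue RMS fluctuation
  about the iteratively refined time-average structure.
- **Moving-block bootstrap** — percentile confidence intervals for means of
  autocorrelated θ/d series (contiguous blocks resampled with replacement),
  plus a two-level scheme that resamples whole trajectories, then blocks,
  when several independent simulations are pooled.
- **Two-state segmentation** — hysteresis thresholds (switch to extended at
  θ ≥ 35°, to bent at θ ≤ 28°, by default) with dwell-time filtering,
  transition detection, and state occupancies.
- **Synthetic generator** — coarse-grained Cα pentamer pseudo-trajectories
  with planted ground truth: the cytoplasmic tilt follows a two-state
  Markov-switching Ornstein–Uhlenbeck process between configurable wells,
  inside a virtual bilayer marked by lipid reference pseudo-atoms. Every
  pipeline stage is validated closed-loop against what was planted.

Input formats: multi-model PDB, XYZ, and (via bio3d) DCD with a PDB
topology. Outputs are tidy TSV and JSON.

## Worked example

Generate a 40-ns synthetic pentamer (frames every 10 ps) whose cytoplasmic
domain starts extended (well: θ 41.19 ± 8.46°, d 30.00 ± 1.19 Å) and is
forced to switch to the bent well at 21 ns, then analyze it:

```r
library(pentadyn)

cfg <- synthetic_config(n_frames = 4000, dt_ps = 10,
                        forced_switch_ns = 21, seed = 42)
sim <- generate_synthetic(cfg)

lip <- lipid_reference_indices(sim$trajectory)
series <- lapply(LETTERS[1:5], function(ch)
  orientation_series(sim$trajectory, ch, lipid_ref = lip,
                     per_frame_membrane = FALSE))
pent <- aggregate_orientation(series)   # per-frame mean over the 5 chains
pent
#> <OrientationSeries> chain mean, 4000 frames: theta 32.52 +/- 9.56 deg, d 31.79 +/- 2.07 A

# uncertainty of the pre-switch tilt mean (1-ns blocks)
block_bootstrap(pent$theta[pent$times < 21000],
                n_resamples = 1000, block_length = 100, seed = 1)
#> <BootstrapSummary> mean 40.85 +/- 0.508 (resample SD), 95% CI [39.87, 41.78], 1000 resamples, block 100

seg <- segment_states(pent$theta, pent$times)
seg$transitions
#>   time_ps     from   to
#> 1   21140 extended bent
round(occupancy(seg), 3)
#> extended     bent
#>    0.528    0.472
```

The pre-switch bootstrap mean (40.85°, CI [39.87, 41.78]) recovers the
planted extended well of 41.19°, and the hysteresis segmentation locates
the planted 21-ns transition at 21.14 ns — inside the 1-ns dwell
resolution. The whole pipeline (plus RMSD/RMSF and report files) runs from
one config via `run_pipeline(run_config(...))`, or from a shell through
`inst/scripts/analyze`.

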
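---
title: "Image-guided microinjection: models, simulation and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-guided microinjection: models, simulation and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microinjectr)
```

`microinjectr` implements the computational core of a robotic workflow for
microinjecting single cells — apical progenitors and newborn neurons — in
organotypic slices of the embryonic telencephalon, together with the
quantifications used to characterise such a platform: yield as a function of
pressure and depth, lineage and zone distributions of injected cells,
gap-junction dye-coupling clusters, and exact nonparametric statistics. No
hardware is required: a simulated manipulator, pressure chain and camera
stand behind the same contracts the physical devices would satisfy.

## The calibration model

The pipette is steered by a three-axis micromanipulator while the scene is
observed through a camera. Calibration estimates the linear map $M$ (2×3,
px/µm) from manipulator displacements $(\Delta x, \Delta y, \Delta z)$ to
image displacements $(\Delta u, \Delta v)$:

$$
\begin{pmatrix}\Delta u\\ \Delta v\end{pmatrix}
= s\begin{pmatrix}\cos\theta & -\sin\theta\\ \sin\theta & \cos\theta\end{pmatrix}
\begin{pmatrix}\Delta x\\ \Delta y\end{pmatrix},
$$

where $s$ is the optical scale in px/µm and $\theta$ the rotation between
the camera axes and the manipulator axes — the key parameter of the
pixel-to-stage transformation. The z (focus) column of $M$ is nominally zero
and retained only as a diagnostic.

`estimate_transform()` fits $M$ by ordinary least squares on the stacked
system built from annotate–move–annotate displacement pairs. OLS is the
minimal estimator consistent with that procedure; with two or more
linearly independent in-plane moves it is exact on noiseless data, and with
annotation noise it is the maximum-likelihood fit under i.i.d. Gaussian
click error. $\theta$ is extracted by the two-argument arctangent of the
fitted x column and reported in $(-\pi, \pi]$; $s$ is the mean of the two
in-plane column norms. Near-collinear calibration moves (condition number
above $10^8$) abort with an explicit calibration-failure error rather than
returning an unstable fit; if no move has z support the z column is set to
zero. Targeting (`pixel_to_stage()`) inverts only the in-plane 2×2 block and
leaves focus untouched; the forward/inverse round trip is exact to well
below $10^{-6}$ px.

Image coordinates are 0-based with u increasing rightward and v downward
(origin top-left), and sub-pixel annotation is allowed. Positioning accuracy
is summarised per manipulator axis as the mean ± sd of the absolute error in
µm, the form in which such platforms report accuracy. Under i.i.d. Gaussian
annotation noise of σ per coordinate the expected per-axis absolute error is
$\sigma\sqrt{2/\pi}$, which the simulation tests recover.

## Trajectory planning

The user draws the injection path as a pixel polyline along the tissue edge
and states on which side of the travel direction the tissue interior lies.
`resample_path()` converts the polyline to stage coordinates and places
sites at arclengths $0, s, 2s, \dots$ up to the total length, so a straight
300 µm edge at 30 µm spacing yields 11 sites. Surface tangents come from
central differences on the resampled points (one-sided at the ends); the
interior normal is the tangent rotated 90° toward the interior side. The
normal estimator is a package choice — any reasonable local estimator gives
the same sites on the smooth edges encountered in practice.

The pipette axis at a site is tilted from the local normal by the approach
angle, within the plane spanned by the normal and the travel direction
(`injection_axis()`). Each site expands into exactly three motion commands —
approach (the surface point pulled back by `pullout_um` along the axis),
inject (the surface point advanced by the axial depth), retract — with the
line pressure constant across the whole plan and command times accumulated
from distance/speed plus the optional dwell. Sites are visited in path
order; no reordering is attempted.

Depth is interpreted *axially*, i.e. along the pipette axis, so the
perpendicular depth below the surface is $d\cos\alpha$ for approach angle
$\alpha$. At the standard 45° approach, axial depths of 15 and 25 µm
correspond to 10.6 and 17.7 µm — 11 and 18 after integer rounding. Note a
discrepancy in the source data for this protocol: the printed perpendicular
depth for a 10 µm axial advance is 5 µm, while the cosine geometry gives
7.07 µm. The package implements the geometric form and does not hard-code
the printed 5.

For basal-surface neuron targeting, `injection_parameters(depth_range_um =
c(10, 35))` draws each site's axial depth uniformly from the range instead
of using a fixed depth.

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `pressure_mbar` | 75 | mbar | optimum of the pressure sweep; ≤ 250 (electronic regulator range) |
| `depth_um` | 10 | µm (axial) | optimum of the depth sweep |
| `spacing_um` | 30 | µm | separates injections so coupled clusters stay identifiable |
| `pullout_um` | 20 | µm | fully clears the tissue between sites |
| `approach_angle_deg` | 45 | degrees from the surface normal | apical-progenitor protocol |
| `speed_um_s` | 1000 | µm/s | fast sweep; lower it to emulate realistic attempt rates |
| `dwell_s` | 0 | s | no in-tissue hold by default; exposed in the configuration |

## Simulated hardware

The pressure chain models house pressure (~2,400 mbar) downregulated
mechanically to a fixed 340 mbar, an electronic regulator spanning 0–250
mbar, and a solenoid valve: delivered pressure equals the electronic
setpoint while the valve is open and 0 otherwise, and a request outside
0–250 mbar raises a range error naming the regulator limit. Regulator and
valve dynamics (rise time, overshoot) are modelled as instantaneous because
no time constants are available; nothing in the planner depends on them.

The manipulator moves in straight lines at constant speed and arrives
bit-exactly at the commanded target (no drift model), with symmetric
±10,000 µm travel limits per axis. The virtual tissue is a static surface
polyline — tissue deformation under the pipette is not modelled — with a
cell table on its interior side, and `depth_in_tissue()` returns the signed
perpendicular distance to the surface (positive inside).

`render_frame()` draws what the camera would see: background 30, tissue
interior 80, a 160-intensity band within 2 px of the projected surface, and
a Gaussian tip blob of amplitude 200 and σ = 2 px, on an 8-bit scale with
optional additive Gaussian noise. The intensity levels are arbitrary but
fixed for reproducibility. Ground truth (tip pixel, projected surface) is
embedded losslessly so the image loop can be tested: `frame_centroid()`
masks the annotated edge band (its location is user-drawn, hence known),
box-smooths, and takes an intensity-weighted centroid around the peak,
recovering the tip to ~0.1 px noiseless and well under 2 px at noise σ = 50.

## The stochastic outcome model

Success of an attempt is a Bernoulli draw whose probability comes from a
lookup table over (pressure, axial depth). Two presets encode the measured
sweeps: the depth sweep at 75 mbar (10/15/25 µm → 0.68/0.22/0.11), which is
the default, and the pressure sweep at 10 µm depth (75/100/125 mbar →
0.35/0.35/0.08). The two tables disagree at (75 mbar, 10 µm) — 68% vs 35% —
because they come from different slices and batches; the package keeps them
as separate presets and does not average them. Lookup is nearest-neighbour
by default (no interpolation is claimed by the measurements); bilinear
interpolation over a complete grid is available by configuration.

`run_session()` executes a plan site by site, with per-attempt timestamps
taken from the motion schedule, so attempt rates *emerge* from geometry and
speed rather than being set directly: with 30 µm spacing, 20 µm pullout and
10 µm depth each attempt covers ~90 µm of travel, and a 54 µm/s sweep gives
~36 attempts/min, the regime of the robotic benchmark. Sessions are
deterministic under a fixed seed, and `summarize_sessions()` reports
per-group mean ± sd of success percentage, attempts/min and successes/min
with each slice weighted equally (the convention of per-slice mean ± sd
reporting; whether the original aggregation weighted slices by attempts is
not stated).

## Quantification of cell tables

* `bin_distances()` uses the standard nine half-open bins of nucleus
  distance from the ventricular surface (0 to <20 µm through 140 to <160 µm,
  then ≥160), exhaustive and mutually exclusive over $[0, \infty)$.
* `zone_distribution()` and `marker_fraction()` report percentages over
  known-status cells only, with nearest-integer forms alongside raw
  fractions, matching how marker panels with differing n are reported.
  When zones are absent, `assign_zones()` derives them from distance
  thresholds (VZ < 100 µm ≤ SVZ < 160 ≤ CP) — a stand-in for histological
  scoring.
* `find_coupled_clusters()` groups junction-permeable-dye cells into
  clusters by connecting cells within `max_link_um` of each other
  (equivalently: single-linkage clustering cut at `max_link_um`, computed as
  neighbour-graph components via a sorted sweep and union–find so that
  10,000-cell tables need no n×n distance matrix). Each cluster is assigned
  to its unique impermeable-dye (injected) member; clusters with several
  injected members are flagged as uniqueness violations, never silently
  merged, and permeable cells with no injected neighbour are returned as
  orphans. The default cutoff of 15 µm is half the 30 µm injection spacing,
  so neighbouring injections cannot merge; no linkage radius is stated by
  the protocol, making this a package choice.
* `colocalization_success()` scores a nucleus as injected when the dye mask
  covers at least half of it (threshold configurable), mirroring the
  dye/DAPI co-localization criterion.

## Statistics from first principles

`rank_sum_exact()` computes the Wilcoxon rank-sum (Mann–Whitney U) test by
full enumeration of all $\binom{n_1+n_2}{n_1}$ assignments of the pooled
mid-ranks whenever that count is at most $2\times10^5$ (worst-case runtime
well under a second); beyond the cap it falls back to the tie-corrected,
continuity-corrected normal approximation, which agrees with enumeration to
within 0.01 absolute p at $n_1=n_2=10$. For completely separated samples
the minimal one-sided p is $1/\binom{n_1+n_2}{n_1}$: 1/126 ≈ 0.0079 at
4 vs 5 and 1/252 ≈ 0.004 at 5 vs 5. The two-sided p is
$\min(1, 2\min(p_\text{less}, p_\text{greater}))$ — a convention the
source leaves unstated.

`ks_normality()` is the one-sample Kolmogorov–Smirnov pre-test against the
standard normal after z-scoring, with the asymptotic Kolmogorov p-value.
Because mean and sd are estimated from the data, omitting the Lilliefors
correction makes the test anti-conservative; the plain KS form is kept
deliberately since that is the named pre-test, and the limitation is
documented here.

## What the synthetic data emulates — and what it does not

The generators are pure functions of (parameters, seed).

* `generate_tissue()`: a line or sine apical surface with cells anchored by
  an apical process, nucleus depths uniform on 5–150 µm (the real depth
  distribution over the cell cycle is non-uniform; uniform is a declared
  stand-in), and Tbr2 positivity at 30% in the VZ.
* `generate_coupling_table()`: injected cells 30 µm apart carrying both
  dyes; with probability 1/3 a cluster of size 2–8 (P(2) = 0.55, P(3) = 0.2,
  P(4) = 0.1, P(5..8) = 0.0375 each — only "majority two-cell, range 2–8" is
  constrained; the rest of the mass is a configurable package choice) whose
  partners carry the permeable dye only and sit within 7 µm, below the
  15 µm linkage cutoff while inter-cluster gaps stay ≥ 16 µm; apical
  contact with probability 0.98 for coupled cells. The generated partition
  is therefore recoverable exactly, which the tests verify, and cluster
  statistics on large tables recover the generative parameters within
  3 standard errors.
* `generate_lineage_table()`: multinomial zone draws against the occupancy
  targets 100/0/0, 31/59/10 and 23/31/47 percent (VZ/SVZ/CP at 0/24/48 h),
  with distances drawn inside the zone's band so zone and distance are
  consistent by construction.
* `make_benchmark_fixtures()` writes deterministic CSVs encoding the
  count-derived benchmarks (attempt logs 110/314, 65/185, 23/287, 111/163,
  37/170, 19/169; 8/17 RFP; 4/46 Tbr2-positive coupled cells; two fully
  separated rate tables). Counts not directly published are the smallest
  integers consistent with the published percentages and are tagged as
  derived in the bundle's manifest.

Passing tests on these generators show that the algorithms are correct under
the stated generative assumptions; they do not show robustness to what real
slices add — tissue deformation under the pipette, pipette clogging, uneven
illumination, z-resolution limits of confocal scoring, or non-uniform
interkinetic nuclear migration.

## Numerical choices and degenerate inputs

* Calibration refuses rank-deficient input (condition number > $10^8$).
* Resampling keeps the first site exactly at the path start; a spacing
  longer than the path leaves a single site.
* Ties in the rank-sum enumeration use mid-ranks; p-value comparisons use a
  $10^{-9}$ slack so floating-point rank sums never drop an equal case.
* A constant sample is a degenerate input to the KS test and errors.
* `sd` is reported as 0 for n = 1, matching the mean ± sd convention.
* Percentages are reported both raw and rounded to the nearest integer.

## Problem sizes used by the test-suite

The suites use sizes chosen to make binomial/multinomial standard errors
informative while keeping the default run fast: 1,000 targets for the
positioning-error Monte Carlo, 163 and 1,000 attempts for outcome-model
calibration, 10,000-cell tables for Tbr2 and coupling parameter recovery,
2,000 null replicates for the super-uniformity of the exact p-value, and
100 random tables for the cluster-partition oracle equivalence.

## Reproducing a full run

```{r, eval = FALSE}
path <- annotated_path(tibble::tibble(u_px = c(0, 300), v_px = c(0, 0)))
transform <- make_transform(theta = 0, scale = 1)
plan <- plan_trajectory(path, injection_parameters(), transform)
log <- run_session(plan, depth_yield_model(), seed = 1)
glance(log)
```

The command-line interface (`inst/cli/microinject`) exposes the same
pipeline as `calibrate`, `plan`, `simulate`, `analyze`, `stats compare` and
`genfix` subcommands, each writing a manifest with the resolved options and
seed so any run can be replayed byte-identically.
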
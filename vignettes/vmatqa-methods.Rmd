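---
title: "Models and methods in vmatqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in vmatqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatqa)
```

# The problem

Knowledge-based planning (KBP) systems push organ-at-risk dose objectives
toward the best values achieved in a library of prior patients. Plans
optimized against such aggressive objectives tend to be more modulated:
more monitor units (MU), smaller and more irregular MLC apertures, faster
leaf travel. Modulation in turn degrades deliverability — the agreement
between the dose the treatment planning system (TPS) computes and the dose
the machine actually delivers, quantified in patient-specific QA by the
gamma passing rate (GPR) against a detector-array measurement. `vmatqa`
implements the full measurement chain for studying this trade-off on
prostate VMAT plans, along with a synthetic cohort generator so that every
stage can be exercised, tested and benchmarked without clinical data.

# Plan model

A `vmat_plan` is a list of arcs; an arc an ordered list of control points
(gantry angle, cumulative meterset weight in [0, 1], per-pair leaf-bank
positions, jaws). Coordinates follow IEC 61217 beam-limiting-device
conventions: leaves travel along X, pairs stack along Y, bank A is the
negative-X bank, and a closed pair has `bank_a == bank_b` (never a
negative gap). Gantry-angle differences are always the shortest signed arc
modulo 360°, so a 359° → 3° transition is 4°. The default head is 80 pairs
of 5 mm leaves (a 160-leaf MLC). Jaws are stored per control point; the
generator keeps them fixed per arc, since nothing in the emulated study
says whether they track the aperture.

`validate_plan()` returns violations as *data* (a data frame naming arc,
control point and leaf), not exceptions: structural checks (weight
monotonicity and endpoints, bank ordering, jaw sanity) plus the mechanical
leaf-speed constraint |Δposition|/|Δgantry| ≤ 7 mm/deg by default.

DICOM RT Plan support is deliberately minimal: explicit-VR little-endian
files, beam/control-point/MLC/jaw/meterset attributes, fraction-group
metersets and the target prescription dose. Written files are for
interchange and round-trip testing only — they are not deliverable
treatment plans. The portable JSON plan schema (`vmatqa-plan/1`) is
lossless and versioned.

# Complexity metrics

All four metrics operate on the in-jaw leaf pairs, where a pair counts as
in-jaw when its Y-band overlaps the Y jaws by more than 0.5 mm — a
tolerance that avoids knife-edge ambiguity at jaw boundaries.

**MU/Gy** — total MU divided by the prescription dose per fraction, so
plans with different prescriptions compare on one scale.

**MCS** — per control point, the leaf-sequence variability is
`LSV = Π_banks Σ_{n=1}^{N-1} (pos_max − |p_n − p_{n+1}|) / ((N−1) pos_max)`
with `pos_max` the spread of that bank's in-jaw positions; a bank with
zero spread contributes 1 (zero variability) by convention. The
aperture-area variability AAV is the ratio of the summed in-jaw gaps to
the gaps of the arc's maximal aperture (each leaf at its extreme position
over all control points of the arc; a zero denominator also yields 1).
The arc score averages adjacent control points weighted by the meterset
delivered between them,
`MCS = Σ_i ((AAV_i + AAV_{i+1})/2)((LSV_i + LSV_{i+1})/2) W_i`,
and the plan value is the MU-weighted mean over arcs. A static, fully
open arc scores exactly 1. Note that a *dynamic* conformal arc tracking
an ellipsoidal target scores well below 1 (≈ 0.7 for this generator's
anatomies) because the aperture area legitimately varies with gantry
angle; MCS = 1 is a property of static deliveries only.

**EM** — per control point, the aperture boundary is decomposed into
leaf-end edges (2 × leaf width per open pair) and leaf-side edges: the
symmetric-difference length of adjacent in-jaw open intervals, plus the
full gap lengths bordering closed pairs or the top/bottom of the open
region. `EM_cp = (C₁·L_end + C₂·L_side)/A_cp` with the conventional
scaling C₁ = 0, C₂ = 1, so only side edge counts at defaults (making the
choice of full versus jaw-clipped width for the end edges moot). Control
points are weighted by `(ΔW_left + ΔW_right)/2` (endpoints take their
single adjacent interval). A zero-area aperture with nonzero weight is
degenerate: it is dropped with a warning and the remaining weights are
renormalized, keeping EM a weighted mean — the alternative (leaving the
weight mass out) would silently shrink the metric.

**LM** — for each transition, the mean over in-jaw leaves of both banks
of |Δposition|/|Δgantry|; the plan value is the unweighted mean of the
per-transition means pooled over arcs. Whether the underlying definition
pools all leaf-transitions or averages per-transition means is ambiguous
in the literature; the two agree exactly when the in-jaw count is
constant, which holds for this generator (fixed jaws per arc). A zero
gantry increment between control points with distinct leaf positions has
no defined speed and raises an error.

# Gamma analysis

For each reference point above the low-dose threshold,
`γ = min over evaluated positions of sqrt(r²/Δd² + δ²/ΔD²)`. Conventions,
following detector-array QA practice:

- The **reference** plane is the measurement (fixed detector sites, never
  interpolated); the **evaluated** plane is the computed dose,
  interpolated bilinearly.
- The **global normalization dose** defaults to the reference maximum
  (`either_max` is available as an option; the underlying description —
  "the maximum dose in either distribution" — is ambiguous).
- The **threshold** (default 10%) is always taken relative to the global
  normalization dose, also under local normalization, so the analyzed
  point set does not change between normalization modes.
- The minimization searches a lattice of spacing `dta/20` out to radius
  `gamma_cap × dta` (cap 2 by default); offsets are visited in order of
  increasing distance and the search stops once the distance term alone
  exceeds the running minimum, which keeps the fine lattice cheap (the
  C++ loop typically touches a handful of offsets per passing point).
  The lattice must be this fine because near a steep dose gradient the
  per-point minimum behaves like |linear| in the offset: a `dta/5`
  lattice can overestimate γ by several tenths, while `dta/20` holds the
  discretization error below 0.01 — the equivalence the brute-force
  oracle (`brute_force_gamma`, an independent plain-R exhaustive search)
  asserts in the tests.
- γ values at the cap are reported as the cap; the boundary γ = 1 counts
  as passing.
- `align_planes()` grid-searches rigid shifts (±3 mm, 0.5 mm steps by
  default) maximizing the GPR, with ties broken by smallest shift
  magnitude then lexicographically — a documented substitute for the
  proprietary "calculated shift" feature of commercial QA software.

`tg218_presets()` returns the seven criteria used in the emulated study
(3%/3, 2%/2, 1%/1 mm × global/local, and 3%/2 mm global), all at the 10%
threshold, annotated with the TG-218 universal tolerance (95%) and action
(90%) limits.

# DVH metrics

Cumulative DVHs use uniform bins (default 0.1 Gy; 0.01 Gy where a 0.01 Gy
post-condition matters, as in D95 renormalization). `D_x` is read off the
cumulative curve with linear interpolation as the largest dose at which
the curve still reaches x% volume — so for a two-voxel {60, 80} Gy
structure, D50 = 80 Gy and D100 = 60 Gy. Dmin/Dmax/Dmean come from voxel
values directly, not the curve. The homogeneity index defaults to the
ICRU 83 form `(D2 − D98)/D50` and the conformity index to the ICRU 62
style prescription-isodose-volume over PTV-volume ratio; both alternative
forms are switchable, since the emulated study cites only "ICRU
definitions" — the chosen forms reproduce its printed magnitudes (~0.05
and ~1.4). Masks are binary at the dose-grid resolution (4 mm default);
fractional voxel membership is not modelled.

# OVH and KBP prediction

The signed distance field is an exact Euclidean transform on voxel
centers (separable lower-envelope algorithm in C++): positive outside the
target, negative inside, with a target surface voxel at ≈ 0 (inside
distances are offset by one voxel so the boundary layer sits at zero).
"Within the treatment fields" is realized as a superior–inferior slab
from the jaw Y-extent projected at isocenter — for coplanar full arcs the
lateral extent is rotationally swept, so only z is restricted — and both
the numerator and denominator of the overlap fraction use in-field voxels
only. The OVH is tabulated on a 1 mm lattice by default with linear
interpolation for the inverse lookup.

The prediction rule: for each OAR and volume level, an entry is eligible
when its OVH distance at that level is no larger than the query's (its
geometry at least as unfavorable), and the prediction is the lowest dose
achieved at that level among all eligible clinical *and* Pareto entries;
with no eligible entry the nearest-distance entry is used and flagged.
Two consequences the tests assert: growing the database can only lower
predictions, and a query identical to a database entry is bounded by its
own achieved dose. A caveat on leave-one-out evaluation: once the patient
itself is removed, the minimum over *harder*-geometry entries is only
guaranteed to bound the held-out dose when some eligible entry actually
achieved no more than it — in a cohort where achieved dose decreases
smoothly with OVH distance this is frequently, but not always, the case.

# The synthetic world

The generator states the emulated study conditions as defaults: 31
patients, two coplanar 360° arcs at 4° control-point spacing (91 control
points each), a 7 mm/deg leaf-speed limit, 38 × 2 Gy fractionation (so
"95% of the PTV receives 76 Gy" is a meaningful normalization), three
measured replicates per plan, and a uniform 7 mm detector grid over
26 × 26 cm (the real device's diagonal lattice is out of scope).
Anatomies are ellipsoidal PTVs with an anterior-superior bladder and a
posterior, z-elongated rectum inside a body cylinder on a 4 mm lattice,
with OAR–PTV surface separations drawn from [−12, 4] mm (negative =
overlap).

**Modulation model.** The conformal beam's-eye-view aperture is narrowed
into a sweeping leaf window: the half-width shrinks with the modulation
dial (down to ~30–50% at dial 1) while the window center sweeps fully
across — and slightly beyond — the outline a few times per arc with leaf-
and arc-specific phases, plus band-limited irregularity fields (up to ~22
cycles per arc, ~12 per bank). The full crossing matters: it keeps target
coverage near-uniform (every point is built from moving window edges, as
real optimizers produce), where a center-anchored sweep would leave the
aperture core permanently exposed and pile up a hot spot that distorts
global-normalization gamma comparisons. MU grows linearly with the dial
(380 + 310·dial, times a target-size factor and 5% replan noise),
emulating the MU-for-aperture trade. The sweep overshoot ramps in over
dial ∈ [0, 0.3] so dial 0 is exactly a static-aperture conformal arc per
gantry angle. Reference plans draw their dial from [0.15, 0.40],
KBP-style re-plans from [0.55, 0.85].

**Dose surrogate.** Fluence accumulation (aperture indicator × meterset
weight × beam MU, back-projected per gantry angle) convolved with a 3 mm
Gaussian penumbra and scaled by a fixed output calibration. It is linear
in MU and deterministic given the plan. It is *not* a physics engine: no
transmission, tongue-and-groove, output factors, spectrum or scatter.

**Measurement model.** The delivered plane differs from the computed one
by three deterministic MLC error terms plus stochastic ones:
static per-leaf calibration offsets ~ N(0, 0.5 mm) drawn once from a
machine-level calibration seed (shared by every plan and replicate, like
a real machine's state); a servo lag of 0.4° of gantry rotation, making
each leaf's position error proportional to its speed; and a
continuous-delivery surrogate that renders the delivered fluence with
subdivided, linearly interpolated control points, so the computed
4°-resolution plane carries the TPS's discretization error. On top come
1.5% proportional noise (the only thing distinguishing replicates) and an
optional rigid setup shift (0 by default). The three MLC terms are what
couple complexity to deliverability: relative fluence error scales
roughly as (offset + lag × leaf speed)/gap width, so narrow, fast,
irregular apertures measure worse — the mechanism the cohort-level sign
structure tests rely on.

**What a green test establishes — and what it does not.** The suite
asserts *directional and statistical* structure: metrics monotone in the
modulation dial, GPR monotone in planted error magnitude, and the
31-patient two-arm cohort separating significantly in all four complexity
metrics and all seven gamma criteria with the studied signs. Absolute
values are realistic in order of magnitude (MU ≈ 450 vs 600, LM ≈ 0.5 vs
1.0 mm/deg, GPRs in the high-80s to 100%) but are *not* clinical
predictions: MCS and EM levels sit roughly a factor ~2 from typical
clinical tables because the sweeping-window world is more uniformly
modulated than optimizer output, and gamma failure rates depend directly
on the chosen error magnitudes. Nothing here validates a TPS, a machine
or a detector.

# Numerical choices and degenerate inputs

- Seeds: everything derives deterministically from (spec, seed) through a
  integer mixing function kept below 2³¹; there is no hidden global
  state, and regenerating a cohort reproduces it bit-for-bit.
- Gamma: subgrid `dta/20`, cap 2, oracle lattice `dta/20` within the cap
  radius; no extrapolation outside the evaluated plane (offsets falling
  outside are skipped by both paths).
- Leaf-speed clamping in the generator is sequential (each control point
  is pulled within ±28 mm of its predecessor, then pair ordering is
  restored by collapsing crossings to the midpoint, which provably
  respects the same bound).
- Wilcoxon: zero differences are dropped (the original treatment); the
  exact null is used for n ≤ 25 without ties in |d|, otherwise the normal
  approximation with continuity correction. Identical arms short-circuit
  to p = 1; a constant nonzero shift routes through the sign machinery
  rather than erroring in the t-test.
- No multiple-testing correction is applied by default, matching the
  per-test α = 0.05 reporting convention of the emulated study design.
- Pearson complexity–GPR correlations pool both arms by default (n = 62);
  per-arm correlation is available via `correlation_arms`.

# Known limitations

- DICOM support is explicit-VR little-endian RT Plan only; RT Dose and
  RT Struct are out of scope (dose planes/grids and masks use the
  documented portable CSV/JSON formats).
- The dose surrogate and error model are stated worlds for exercising the
  analysis machinery, not validated physics.
- Binary masks at 4 mm without fractional membership bias small-structure
  DVH metrics; the synthetic anatomies are large enough for this not to
  matter in the tests.
- The shift-alignment search optimizes GPR directly and is O(shifts ×
  gamma); for routine cohort work with a zero planted shift it is off.
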
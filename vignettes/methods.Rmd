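---
title: "Methods: tracking, phase calling and trajectory analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking, phase calling and trajectory analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
`fuccitrack`, the assumptions behind them, the tunable parameters and
their defaults, and the choices made where the design was genuinely open.
It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The pipeline at a glance

A movie is a calibrated image stack (`T × H × W` grayscale or
`T × H × W × 3` RGB) with a pixel size (µm/px) and a frame interval
(min). Calibration is supplied by the user, never parsed from TIFF
metadata: vendor metadata dialects are too inconsistent to trust, and a
wrong silent default corrupts every downstream unit. Pixel coordinates
are 0-based with pixel centres at integers (`x` = column, `y` = row);
frame numbers are 1-based, in memory and in every exported table.

Tracking proceeds cell by cell, frame by frame: segment a local window,
link by minimum distance, apply any scripted event, repeat. This mirrors
a supervised workflow in which a user watches one cell at a time and
intervenes when the tracker goes wrong — with the intervention stream
replaced by machine-readable event tables, so a "supervised" analysis is
replayable bit for bit.

## Nucleus detection

Two segmentation routes are provided, selected per run.

**CLAHE + Otsu.** The frame (or window) is min–max normalised,
equalised by contrast-limited adaptive histogram equalisation, binarised
at Otsu's threshold, and connected components of at least `min_area_px`
pixels (default 9 px — about the smallest plausible nucleus cross
section at 10–20× magnification, and an effective hot-pixel filter)
become detections. CLAHE tiles are at least 32 px on a side with the
grid capped at 8 × 8: tiles comparable in size to a nucleus distort
region shapes and break translation invariance, which the test suite
checks explicitly. Images narrower than 64 px (typical tracking windows)
skip the adaptive step entirely and fall through to plain Otsu — at that
scale a single nucleus dominates the histogram and global thresholding
is both sufficient and exactly shift-invariant. The contrast limit
`clahe_clip` (default 0.01 of the tile histogram) is exposed but rarely
worth touching.

**Watershed.** Intensity is treated as topography: bright nucleus pixels
are high elevations, and touching nuclei that merge into one
above-threshold region are split along the watershed ridge between their
peaks. The image is lightly smoothed (Gaussian, σ = 1 px) before
flooding so that pixel noise does not nucleate spurious catchment
basins, and maxima shallower than `h_minima` (default 0.05 of the
dynamic range) are merged — the standard guard against
over-segmentation. The tests include a fixture of two blobs 8 px apart
that thresholding reports as one region and the watershed correctly
reports as two.

**Positioning.** A detection's position is the *unweighted* centre of
mass of its binary region. Intensity weighting was considered and
rejected: the binarised pipeline treats all above-threshold pixels as
equally "nucleus", and the unweighted centroid is what the
translation-equivariance property holds for exactly. On noise-free
Gaussian-blob fixtures both routes localise to well under 1 px.

## Frame-to-frame linking

Each tracked cell carries a square search window (side =
`roi_fraction` × the shorter image side, default 0.25) centred on its
last position; only that crop is segmented, which bounds the cost per
cell per frame and suppresses distractors far from the cell. The
detection minimising the Euclidean distance to the last position becomes
the new position, **provided** the distance is at most `gate_px`. The
gate defaults to half the window side; exceeding it flags the track
`lost` rather than force-linking, the headless analogue of pausing
automated tracking for a correction. Ties (exactly equidistant
detections) resolve in row-major scan order — smallest `y`, then `x` — an
arbitrary but deterministic rule.

Scripted events:

* A **correction** at frame *f* overrides the position: snapped to the
  nearest detected centroid when `use_center_of_mass` is set (the right
  choice when the nucleus is visible but the tracker drifted), else the
  given point verbatim (for nuclei too dim to segment). Frame *f* is
  recorded, and `correction_rate()` reports corrected frames over track
  length.
* A **division** at frame *f* closes the track (`division_frame = f`)
  and seeds one daughter track per given position at frame *f* + 1.
  Lineage ids append `.1`, `.2`, … to the parent id, so the id encodes
  the full ancestry and `generation()` is simply the number of
  separators. More than two daughters are accepted — multipolar
  divisions occur in transformed lines.

Root cells are seeded only on the first frame (matching the supervised
workflow this emulates); root and daughter seeds snap to the nearest
in-gate detection when one exists, since a click on a nucleus means the
nucleus, not the click's sub-pixel location.

The five-category partition (all / dividing / non-dividing / daughter /
dividing daughter) follows from `division_frame` and `parent_id` alone.
Two identities are enforced by property tests across random simulated
lineages: dividing ∪ non-dividing = all (disjoint), and dividing
daughters = daughters ∩ dividers.

## FUCCI phase calling

Per frame, each channel's raw signal is its mean over a disk centred on
the tracked position. The disk diameter should not exceed the cell
diameter (contamination by neighbours is the main failure mode) and can
be set per cell. Signals are then min–max normalised per cell over its
own time series: FUCCI reporters oscillate over the cycle, so each
channel of a cell that completes a cycle visits both its floor and its
peak, and per-cell normalisation removes expression-level differences
between cells. A constant channel maps to all zeros. The normalisation
window is the whole trace (not sliding): traces that do not span a full
cycle will distort, which is why validation evaluates cells observed
birth-to-division. A 3-frame median pre-filter is available but off by
default — at the default noise scale it changes nothing, and it blurs
genuine transitions.

**Two-channel rule** (Cdt1-red / Geminin-green; thresholds MS, MGSS,
MRSS, all defaulting to 0.1). Cdt1 peaks in G1 and declines through S;
Geminin accumulates through S and G2. Hence: red-only → G1, both → S,
green-only → G2M, neither above MS → Unknown. Precedence is Unknown,
then S, then G1, then G2M, so the both-high state is claimed by S before
either single-channel phase can claim it. Raising MGSS can only shrink
the S-labelled set — a monotonicity property the tests assert on random
traces.

**Three-channel rule** (PCNA-red / Geminin-green / PIP-blue; MGBr-G1 =
0.5, MGBr-G2 = 0.7, MBS-G2 = 0.1). The PIP degron is degraded during
replication, so blue is high in G1 and G2 but low in S, while Geminin is
high in S and G2; PCNA is carried in the trace but unused by the rule.
With ρ = ĝ/(b̂ + ε): ρ ≤ MGBr-G1 → G1; ρ ≥ MGBr-G2 with b̂ ≥ MBS-G2 →
G2M; otherwise S. The blue floor MBS-G2 prevents S frames (blue near
zero, ratio numerically huge) from leaking into G2M. ε = 10⁻⁶ guards
the division; it is far below any meaningful normalised signal, so it
never changes a call.

Mitosis is not separated from G2 (the reporters cannot distinguish
them), and the phase caller never smooths or enforces phase ordering —
scripted corrections (`correct_phase()`, closed 1-based ranges) are the
supported way to fix isolated miscalls.

## Trajectory analytics

For a track of *n* positions with pixel size *s* and interval Δt:
trajectory time *T* = (*n* − 1)Δt/60 h, total distance *D* = Σ step
lengths × *s*, displacement *L* = first-to-last distance × *s*,
directionality *L*/*D* (NA for *D* = 0, excluded from summaries), mean
speed *D*/*T*, instantaneous speeds v_t per step. Two identities are
property-tested to numerical precision: *L* ≤ *D*, and mean(v)·*T* = *D*.

**Doubling times.** Each dividing daughter cell — born at a division and
dividing itself — spans exactly one cycle, so its lifetime is a direct
doubling-time measurement. Summaries report mean, sd, median and mode;
the mode of a continuous quantity is taken as the midpoint of the
tallest histogram bin with bin width equal to one frame interval (the
measurement's native resolution).

**Daughter-pair heterogeneity.** Sibling pairs are compared on their
measures only when both daughters were observed at least
`min_trajectory_time_h` (default 10 h) and differ in observation time by
at most `max_pair_time_diff_h` (default 3 h) — short or unbalanced
observations make the comparison meaningless. Multi-daughter divisions
contribute all unordered sibling pairs. **Division synchrony** compares
absolute division times across pairs in which both daughters divide.

**Per-phase dynamics.** A step from frame *t* to *t* + 1 is attributed
to the phase of frame *t* (the phase the cell was in when it moved).
Per-phase directionality is computed on the sub-path of positions
carrying that label.

**Terminal speed jump.** A dividing cell is flagged when some step in
the final hour before division, starting in a G2M-labelled frame,
satisfies both: v ≥ 2.5 × the mean instantaneous speed over the final
2 h, and v ≥ 3 × each existing temporally adjacent step speed. Two
interpretation choices were open. "Neighbour" speeds are the temporally
adjacent steps (t − 1, t + 1) where they exist: the criterion is stated
per cell, so spatial neighbours (other cells) cannot be meant. The
baseline mean is a pure 2 h time window and *includes* the candidate
step: nothing in the criterion's statement excludes it, and including it
makes the test strictly harder to pass, which is the conservative
reading. The detector provably never fires on constant-speed tracks
(v = baseline < 2.5 × baseline), which the tests check across baselines.

## Evaluation against reference annotations

Tracks are matched to reference cells by nearest position at the track's
birth frame, with a uniqueness check — two tracks claiming the same
reference cell is an error, not a silent merge. Errors are reported
axis-wise (|Δx|, |Δy| in µm, mean ± sd per axis and pooled) rather than
as Euclidean distances, matching how tracking accuracy is conventionally
tabulated, plus the maximum absolute difference in pixels and a flag for
exceeding 20 px. Reference annotations arrive as coordinate tables; a
converter (`masks_to_reference()`) reduces labelled-mask stacks (16-bit
label images, 0 = background) to that form by per-label centroids.

## The synthetic generator

`simulate_lineage()` draws ground-truth trajectories, divisions and
phase labels; `simulate_movie()` renders them. Defaults are fixed to the
RPE-like imaging regime: 0.65 µm/px, 10 min/frame, mean speed 9.3 µm/h,
cycle length ~ Normal(21.5 h, 4.8 h) truncated positive, phase fractions
G1/S/G2M = 0.22/0.59/0.19. These numbers are the conditions the package
is validated under, not tuning knobs.

* **Motion** is a persistent random walk: per frame the heading gains a
  wrapped-normal increment with sd (1 − persistence)·π (default
  persistence 0.5) and the step length is normal around the calibrated
  mean step. Purely Brownian motion would under-represent the
  directional persistence real cells show at 10-min sampling
  (directionality ratios around 0.1–0.2 over a day); the persistent
  walk reproduces that regime. Cells reflect off a margin of 4σ so
  nuclei stay renderable.
* **Rendering**: isotropic Gaussian blobs (σ = 3 px, peak 180 on the
  8-bit scale) plus additive Gaussian noise (sd 3), quantised per frame
  (which also keeps peak memory at about one copy of the stack).
* **Divisions** replace one blob by two offset 1.5σ in opposite
  directions — enough to exercise the division/seeding machinery, with
  no attempt to model mitotic morphology.
* **FUCCI programmes** are piecewise-linear in the position *u* within
  each phase. Two-channel: red 1 in G1, declining 1 → 0.2 across S,
  0.05 in G2M; green 0.05 in G1, rising 0.3 → 0.9 across S, 1 in G2M.
  Three-channel: blue 1 / 0.05 / 1 across G1/S/G2M, green 0.05, rising
  0.4 → 0.9, then 1; red constant 0.5. The level jumps at phase
  boundaries are deliberate: the reporters' degradation switches are
  fast on the 10-min sampling grid, and the jump keeps every
  within-phase signal comfortably clear of the calling thresholds after
  per-cell normalisation.
* **Jump injection** rescales one ground-truth step in the last hour of
  G2M (shifting subsequent positions so all other step vectors are
  unchanged) to 1.25 × the larger of the two criterion bounds, solved
  in closed form with the baseline's dependence on the injected step
  accounted for. Injected jumps therefore satisfy the criterion by
  construction, making 100% detector recall a meaningful requirement.

What the generator does **not** emulate: background structure and
illumination gradients, photobleaching, cell–cell contact and collision,
mitotic rounding, segmentation-scale shape variation, or imaging
artefacts. Passing tests therefore demonstrate the correctness of the
algorithms under clean, known conditions — not robustness to every
failure mode of real microscopy, which is what the scripted-correction
machinery exists to absorb.

## Validation problem sizes

The acceptance checks run at sizes chosen to make their statistics
meaningful while staying comfortably reproducible on a laptop-class
single core: tracking recovery on 10 cells × 100 frames (512² px);
category identities over 200 random lineages; phase recovery on 50-cell
two- and three-channel movies (320² px, 210 frames, slow-moving cells so
signal purity isolates the phase rules from tracking); measure
identities on 1000 random tracks; doubling-time recovery from cycle
lengths ~ Normal(24 h, 3 h) with ~100 dividing daughters. For the
doubling-time check the movie spans 60 h with founders starting at age
0: long enough that second-generation divisions are essentially never
right-censored, short enough that third-generation divisions (whose
censoring would bias the sample) cannot occur. The phase-recovery movies
instead start founders at age 0 and evaluate cells observed
birth-to-division, so every evaluated trace spans one full cycle and the
per-cell normalisation is well posed.

## Known limitations

* Linking is greedy per cell, not a global assignment: two tracked cells
  can in principle claim the same detection. The per-cell search window
  plus scripted corrections are the intended remedy, as in the
  supervised workflow this reproduces.
* Automatic division detection is out of scope by design; divisions are
  scripted events.
* Phase calling assumes the trace spans a full cycle (see above); for
  partial traces the thresholds act on a distorted scale.
* The XLSX writer is deliberately minimal (inline strings, no styling);
  it exists so the two-sheet result workbooks open in standard tools,
  with CSV mirrors as the primary machine interface.
* Cells can only be seeded on the first frame; cells entering the field
  later are not tracked, which depresses population-level recall on
  dense reference datasets exactly as it does in the supervised tool
  this emulates.
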
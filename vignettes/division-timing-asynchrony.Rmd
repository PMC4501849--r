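---
title: "Quantifying division-timing asynchrony in C. elegans embryonic lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying division-timing asynchrony in C. elegans embryonic lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

*C. elegans* embryogenesis is invariant: every wild-type embryo executes the
same binary pedigree of Sulston-named cell divisions on a tight schedule.
Automated lineaging of 3D time-lapse recordings yields, per embryo, one row
per nucleus per 1.5-minute frame with the cell's name and position. From such
tables this package quantifies **cell cycle length** (birth to division, in
minutes) and the **asynchrony of division between sister cells (ADS)** — the
absolute difference of the two daughters' cycle lengths — and supports a
high-content RNAi screen for genes whose depletion collapses specific
asynchronies, inflates timing variance (a buffering/capacitor phenotype), or
displaces cells and division axes.

The screen logic is:

1. build a multi-embryo wild-type reference of per-pair ADS distributions;
2. monitor the pairs whose mean wild-type ADS exceeds 5 minutes;
3. per perturbed gene, flag a replicate for a pair when its ADS is uncensored,
   reduced by at least 50% relative to the wild-type mean, below that mean,
   and outside the normal-model confidence interval (two-sided tail
   probability below 0.05 or 0.01);
4. call the gene a hit for the pair when at least two replicates agree at the
   same level.

## Timing model and censoring

Frames are 1-based; a cell's lifetime is the inclusive frame interval from
its first to its last observation, and its division is timestamped at its
daughters' birth frame (mother's last frame + 1). Cycle length is
`(daughters' birth frame − own birth frame) × Δt` with `Δt = 1.5` min.

Timings are censored, never dropped silently, with explicit reasons:

* `early-round-excluded` — AB, P1, ABa, ABp, EMS, P2: imaging starts at the
  two- to four-cell stage, so the first two division rounds are not observed
  from birth;
* `not-observed-from-birth` — any other cell already present at the first
  frame;
* `undivided-at-cutoff` — no division before the analysis cutoff, which is
  the frame at which the embryo first reaches 350 cells (or the last curated
  frame if never reached);
* `dead` — cells on the recording's death list.

An ADS is censored whenever either daughter's cycle is. All ADS statistics
are invariant to frame renumbering and to daughter order; a uniform slowdown
multiplies every cycle and ADS by the same factor.

## The wild-type reference

For each pair with at least `min_n = 8` uncensored ADS values, the reference
stores the mean, SD, and a D'Agostino K² omnibus normality test (skewness
and kurtosis z-statistics squared and summed, chi-square with 2 df). The
screen's tail probabilities always use the normal model; the normality flag
is persisted so reports can caveat non-normal pairs rather than excluding
them. `min_n = 8` is the smallest sample the K² approximation tolerates. No
multiple-testing correction is applied across pairs — the screen is a
prioritization tool and the two-replicate rule is the specificity control;
this is stated in reports rather than silently "fixed".

Pairs with small true asynchrony have folded (half-normal-like) ADS
distributions, so their K² pass rate is intrinsically low; the monitored
(large-ADS) pairs are effectively Gaussian and pass at the nominal rate.

## Buffering (capacitor) detection

Per generation of a lineage (default AB), deviations of each embryo's cycle
lengths from the wild-type per-cell means are compared by a one-sided
two-sample F-test of Var(perturbed) > Var(wild type); the gene is flagged
when the minimum per-generation p falls below 0.01. Two numerical choices
matter and are defaults with literal-reading switches:

* **Leave-one-out wild-type means** (`loo_wt = TRUE`). With the pooled mean,
  each wild-type embryo's own value deflates the wild-type dispersion
  (E[F] ≈ (1+1/n)/(1−1/n)), which at a 20-embryo cohort inflates the 1%
  flag rate to ~6%. Leave-one-out restores the nominal level (measured 1.2%
  over 1000 simulations, Kolmogorov–Smirnov uniformity p = 0.86).
* **Per-embryo speed normalization** (`speed_normalize = TRUE`). Each
  embryo's cycles are rescaled by the median ratio to the wild-type means
  before deviations are formed. Embryo-to-embryo global pace variation
  otherwise enters all cells of an embryo coherently; with three replicates
  that component has almost no degrees of freedom, and the F-test — which
  assumes independent deviations — mistakes ordinary pace spread for a
  dispersion phenotype (null minimum p-values down to 1e-7 in full
  simulations). The screen's QC (below) removes gross slowdowns, but the
  few-percent residual variation is enough to corrupt the test.

The F-test runs on signed deviations; `absolute = TRUE` tests absolute
deviations instead for a literal reading of "dispersion". Note that a pure
mean-shift phenotype confined to a few cells of a generation (e.g. a
collapsed asynchrony) also widens the pooled deviations and can trigger the
flag: the detector responds to any excess deviation from the wild-type
schedule, not exclusively to symmetric variance inflation.

## Quality control

A perturbed recording fails QC when it has fewer than 300 cells at its last
editable frame, or — if the recording extends to frame 240 — when it never
reached 350 cells by frame 240. The second clause is applied only to
recordings long enough for it to be evaluable; earlier-terminated curations
are judged by the 300-cell clause alone. A gene whose replicates all fail QC
is reported `unscreenable` rather than scored.

## Spatial statistics

**Axis normalization.** At the last four-cell frame, the A-P direction is
the ABa-to-P2 line and the second axis is the ABp-to-EMS line
orthogonalized against A-P; the third axis completes a right-handed frame.
We keep the conventional screen labels (A-P, L-R, D-V) for these axes even
though at the four-cell stage the ABp/EMS axis is anatomically
dorso-ventral. Positions are translated to the four-cell centroid, rotated,
and each axis affinely mapped so the embryo's global min/max over all
frames lands on [−1, 1]. The scaling extent is global per embryo — per-frame
scaling would make trajectories discontinuous.

**Positional deviation** uses the scaled coordinates: the perturbed cell's
distance to the wild-type centroid at the cell's last frame, referred to the
upper tail of a normal fitted to the wild-type distances.

**Division angles** use rotated-but-unscaled coordinates: the anisotropic
[−1, 1] scaling would distort angles. The angle of the daughter-separation
vector to each reference plane (AP-LR, AP-DV, LR-DV) is
`asin(|v·n|/|v|)` with `n` the plane normal, in [0°, 90°]. Angle deviations
Box–Cox-transform the wild-type sample (λ by profile maximum likelihood on
[−5, 5], tolerance 1e-6; angles clamped to ≥ 0.1° to satisfy positivity),
remove outliers beyond 3 SD in a single pass *after* fitting λ (the fit is
not repeated), record K² normality, and score the perturbed angle by its
two-sided normal tail.

λ is well identified only when the sample's coefficient of variation is
appreciable: for a sample with CV ≈ 0.1 (e.g. mean 50, SD 5, n = 91) the
MLE's sampling SD is ≈ 0.87 regardless of implementation, so point recovery
of λ is meaningful only for strongly dispersed samples.

## The synthetic embryo generator

The generator stands in for curated recordings; its defaults are the study
conditions and are not tuned per analysis.

| parameter | default | meaning |
|---|---|---|
| `rounds` | 9 | generations simulated; ~480 concurrent cells, so the 350-cell stage falls mid-way through the last round, as in real curation |
| baseline μ(g) | 15…60 min | per-generation mean cycle length, widening with generation as in the real embryo |
| designated pairs | 12, offsets 8–40 min | asynchronous sister pairs (P3 largest, 40 min, the soma/germline D–P4 split), spanning founders and the three fate categories |
| generic offset | 1 min | small anterior/left/dorsal-first asynchrony for all other pairs |
| `sigma0`, `kappa` | 0.8, 0.25 min | per-cell cycle SD σ(g) = σ0 + κ·g, reproducing the increasing generation-SD trend |
| `rho` | 0.04 | SD of a shared per-embryo speed factor; gives between-embryo cycle-length correlations of ~0.91–0.95 without per-cell correlation |
| `Δt` | 1.5 min | frame quantization, round-half-up on cumulative division times, daughters forced ≥ 1 frame after the mother — reproducing the ±1-frame ADS noise floor |
| ellipsoid | 26 × 13 × 13 µm | 2:1:1 embryo; daughters placed at parent ± half a shrinking separation along the division axis plus isotropic jitter |
| marker | MSaa + ABalpa sublineages, level 1000 | tissue-marker intensity with background noise |
| curation | 350 cells + 10 frames, cap 240 | overshoot mirrors curating "up to approximately" the 350-cell stage |

Perturbations compose: per-pair `ads_factor` (0 collapses the offset),
global `slowdown`, `variance_inflation` (per founder or global), arrest (by
frame or cell count), subtree `position_shift` (normalized units),
`angle_rotation` of a division, and marker `expression_knockout`.

What the generator does **not** emulate: cell migration (positions are
static per cell), cell death, mis-naming/curation errors, founder-specific
cycle programs (the E lineage's slow intestinal cycles), egg-shell
compression, or intensity bleed-through. Passing tests therefore demonstrate
that the statistics behave correctly under the assumed noise structure, not
that real recordings satisfy those assumptions.

Two property checks deliberately switch off the shared speed factor
(`rho = 0`): per-cell SD recovery against σ(g), and the flat-profile check at
κ = 0 — the shared factor adds a generation-dependent variance term
(ρ·μ(g))² that is not part of σ(c) and would otherwise confound both.

## Problem sizes

The test suite and acceptance script use: a 91-embryo wild-type cohort for
reference recovery; 12-embryo cohorts for cross-module checks; 200-iteration
Monte Carlo for screen detection and buffering power; 1000 iterations for
the buffering null level; 100 seeds for the Box–Cox and K² calibrations;
and a 20 wild-type + 8-gene × 3-replicate panel for the analysis workflow.
These sizes give Monte Carlo standard errors comfortably inside the asserted
tolerances while keeping a full run in minutes on one CPU.

## Known limitations

* The normal model is applied to all monitored pairs regardless of the K²
  outcome (flagged, not excluded), mirroring screen practice.
* The buffering F-test pools cells within a generation; residual within-
  embryo correlation beyond the global speed factor would inflate its tails.
* Positional deviation reduces three coordinates to a centroid distance; a
  direction-specific shift smaller than the radial spread is invisible.
* `mother_of`/`daughters_of` accept any syntactically valid Sulston string;
  they do not know which divisions actually occur in the worm beyond the
  founder table.
* The death-list convention (a per-recording list of cell names censored for
  timing) is this package's own; curation pipelines encode deaths in
  different ways and should be mapped onto it on import.
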
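---
title: "Dose prediction and rectal-spacer stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose prediction and rectal-spacer stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decision problem

Rectal spacers are surgically inserted between the prostate and the anterior
rectal wall to pull the rectum out of the high-dose region of prostate
radiotherapy. Because insertion is invasive and not universally funded, a
centre needs to decide *per patient* whether the expected rectal dose — and
hence the expected late toxicity — justifies the procedure. The conventional
route to that answer is a full treatment plan, which takes days of planner
time. `spacerstrat` implements the alternative: predict the 3D dose
distribution directly from the delineated anatomy with a convolutional
network, extract the rectal dose-volume histogram (DVH) from the prediction,
convert it to late-toxicity risk with the Lyman-Kutcher-Burman (LKB) model,
and stratify the patient as high or low risk for spacer insertion — all
within seconds of contouring.

Because the clinical plans and contours behind the original study cannot be
distributed, the package ships a seeded synthetic pelvic-phantom and
analytic-plan simulator that reproduces the *statistical structure* of such
a cohort. Every experiment in the package (tests, the acceptance script, the
worked examples) runs end to end on this simulator.

## The phantom and plan simulator

`phantom_spec()` / `generate_phantom()` build a voxelised pelvis on a grid
with axes (x, y, z) = (left-right, anterior-to-posterior, cranio-caudal):

* a prostate ellipsoid (CTV60) whose volume is drawn from N(42.3, 15.7) cc,
  truncated at 2.5 SD — the prostate-volume distribution of a dose-escalated
  cohort;
* two superior-posterior lobes standing in for the seminal vesicles
  (prostate + lobes = CTV53); the original study gives no phantom geometry,
  so the lobe shape is our choice;
* a rectum: a gently meandering, tapered tube posterior to the prostate,
  volume N(69.3, 19.7) cc, separated from the gland by a per-phantom gap of
  0.5-4.5 mm;
* a bladder ellipsoid anterior-superior, N(150, 35) cc;
* six boost lesions (DILs) in posterior-weighted peripheral-zone sectors at
  angles -100..100 degrees (jittered per phantom), log-normal volumes with
  median 3.1 cc truncated to 1-9 cc.

Margins follow the dose-escalation planning convention: PTV60 = prostate +
5 mm, PTV53 = CTV53 + 9 mm, CTV68 = DIL + 3 mm cropped to the gland,
PTV68 = CTV68 + 2 mm. Because the grid is deliberately coarse (4 x 4 x 7 mm
at desk scale), the targets are built from *continuous* distance fields
rather than voxel-mask dilations: a 2 mm margin is meaningful even when it
is half a voxel. Across seeds this construction keeps all PTV68 volumes
inside the clinically reported 3.0-31.7 cc range.

`simulate_plan_dose()` replaces the commercial treatment planning system
with an analytic surrogate. Each prescription target contributes its plateau
inside the target and a normalized sigmoidal fall-off with distance outside
it; the three contributions (68 / 60 / 53 Gy levels) combine by voxelwise
maximum. Two refinements give the surrogate the features that matter for
this method:

* a rectal sparing term `1 - w * exp(-d_rectum / 8 mm)` multiplies the
  fall-off (never the in-target plateau), bowing the isodoses concavely
  around the rectum exactly as an optimiser that is told to spare it would;
  `w` is a per-phantom "planning style" in U(0.25, 0.40);
* the fall-off metric counts cranio-caudal millimetres 1.6 times, because
  arc plans collapse much faster along the beam-edge direction than
  in-plane.

A smooth seeded noise field (SD 0.1 Gy) emulates plan-to-plan variability.
The 60 and 53 Gy plateaus sit 1 Gy above prescription so the coverage
objectives hold with margin under that noise, while the boost plateau is
exactly 68 Gy so the PTV68 median lands at 68 +/- noise. Every emitted plan
is verified by direct voxel count against the planning objectives
(>= 95% of PTV60 at 60 Gy, >= 95% of PTV53 at 53 Gy, PTV68 median within
68 +/- 0.3 Gy); a plan that cannot meet them raises an error naming the
failed objective.

What the simulator does *not* emulate: CT intensities (the method uses only
masks), realistic rectal wall deformation or filling changes, femoral-head
anatomy, inter-planner variability beyond the sparing-weight and noise
terms, and the skewed, occasionally multi-focal shapes of clinical lesions.
A network that performs well here has been shown to learn the
anatomy-to-dose mapping of this family of plans — not to be ready for
clinical data.

## Preprocessing

`resample_dose()` interpolates dose onto a target grid with separable
third-order (natural cubic) splines, clamping negative overshoot to zero.
`crop_to_input()` cuts the fixed network volume — 128 x 128 x 64 voxels at
full scale, 32 x 32 x 16 in the desk-scale configuration used throughout the
tests — centred left-right on the PTV53 centre of mass and cranio-caudally
on the rectal centre of mass (non-integer centres floored), and placed
anterior-posteriorly so that the *entire* rectum is inside the window, as
anterior as that constraint allows so the targets stay in view. Rectum
containment is a hard assertion on every call; windows that overrun the
source grid are zero-padded with a warning. The crop offset is recorded so
predictions can be pasted back into the source grid (`uncrop()`).

Dose is normalized by the maximum voxel dose over the training cohort
(`norm_constant_from_cohort()`). The constant is stored inside the trained
model and reused verbatim at prediction time; we deliberately never
recompute it from a validation or test cohort, so a checkpoint is
self-contained and reproducible.

## The network

`build_network()` constructs a hierarchically densely connected 3D U-Net:
within each resolution level, each 3 x 3 x 3 convolution's output (the
"growth" feature maps) is concatenated onto the running feature stack;
across levels, the expansive path concatenates *all* same-resolution feature
maps from the contracting path. Downsampling is 2x max-pooling, upsampling
is trilinear interpolation followed by convolution, every convolution is
followed by a rectified linear unit, and a final 1 x 1 x 1 linear
convolution emits the single dose channel. At full scale (five levels,
128 x 128 x 64 input) the bottleneck is 8 x 8 x 4. The per-level feature
counts are not prescribed by the source architecture's description, so the
growth rate is configuration; the desk-scale preset uses three levels and
growth 4 (about 10k parameters).

The forward and backward passes are implemented in the package itself
(im2col + BLAS GEMM convolutions in compiled code, with the data gradient
computed as a forward convolution with axis-flipped kernels). The backward
pass is verified against central finite differences in the test suite —
agreement to ~1e-6 relative — which is the strongest correctness oracle
available for hand-written backpropagation.

Training (`train_network()`) minimises voxelwise mean squared error with
Adam. The full-scale schedule is the reference one (learning rate 1e-4,
200 epochs); the desk-scale preset uses learning rate 1e-3 for 25-40 epochs,
chosen because the desk-scale problem is ~500x smaller and converges
correspondingly faster. Training is bit-deterministic given the seed
(single-threaded BLAS assumed; loss histories are asserted identical across
reruns in the tests). `loocv()` provides the leave-one-patient-out harness:
folds are grouped by patient so that no boost plan of a held-out patient
ever enters its training fold, and the fold manifests record every split.

## DVH, EQD2, gEUD, and LKB risk

`compute_dvh()` counts voxels: `v(d)` is the percentage of structure voxels
receiving at least `d`, on a fixed 0.1 Gy binning (configurable). The
differential form attributes the mass between cumulative bin edges
`[d_j, d_{j+1})` to the lower edge — exact whenever doses align with edges,
biased low by less than one bin otherwise. `dvh_metric()` answers `VdGy`,
`Dv%`, `Dmax` and `Dmean` queries, the first two by linear interpolation.
`Dmax` is the true maximum voxel dose, not a near-max percentile.

`eqd2_transform()` applies the linear-quadratic fractionation correction per
DVH bin, `EQD2 = D (d + a/b) / (2 + a/b)` with `d = D / n_fractions` and
`a/b = 3` Gy for late rectal effects. The number of fractions is not part of
the toxicity parameter sets, so it is explicit configuration (default 20,
the dose-escalation schedule); risk estimates should always be quoted with
the scheme used.

`geud()` reduces a DVH to the generalized equivalent uniform dose
`(sum_i v_i d_i^(1/n))^n`, computed in log space so that strongly serial
exponents (`1/n` up to 1000) neither overflow nor lose the hot tail; it
equals the mean dose at `n = 1` and approaches the maximum as `n -> 0`.
`lkb_ntcp()` is the probit `Phi((gEUD - TD50) / (m TD50))`. Two presets are
shipped: grade-2 late rectal bleeding (TD50 = 97.7 Gy, m = 0.27, n = 0.085 —
a serial endpoint driven by the hottest rectal subvolume) and late fecal
incontinence (TD50 = 105 Gy, m = 0.43, n = 1 — a parallel endpoint driven by
the mean). `risk()` composes the three steps; on simulated cohorts the
bleeding risks land in the low single-digit percent range, overlapping the
3.3-10.4% band reported for the clinical cohort.

## Evaluation and stratification

`dvh_error_profile()` summarises signed prediction errors
(predicted - planned, so positive = over-prediction) per DVH parameter with
IQR boxes and Tukey whiskers. `isodose_dsc()` computes Dice overlap of
supra-threshold voxel sets at the six reporting isodoses (24.6, 32.4, 40.8,
48.6, 60, 68 Gy); levels whose ground-truth isodose touches the sampled
volume boundary are excluded and logged, since their overlap would be
truncated. `bland_altman()` reports mean bias and 95% limits of agreement
(mean +/- 1.96 SD, sample SD — the n-1 flavour, documented because the
convention is often left implicit).

`check_constraints()` implements tolerance-table stratification: a plan is
high risk if any rectal `VdGy` *strictly* exceeds its tolerance; exact
equality passes. The shipped table is an Onjukka-style two-level (optimal /
mandatory) set at the six reporting doses, with the top optimal entry at
0.2% rather than 0% for practical planning reasons; the threshold values
are calibrated once to the simulator so that roughly 60% of plans exceed
optimal and 20-25% exceed mandatory constraints, with failures concentrated
at the two highest doses — the same regime as the clinical cohort. The table
is explicitly user-overridable (YAML round-trip via
`read_constraint_table()`). Risk-threshold stratification uses an inclusive
threshold (risk >= threshold is high risk), and `threshold_sweep()` traces
stratification agreement across thresholds. Confusion metrics treat
"exceeds tolerance / high risk" as the positive class; metrics with empty
denominators are flagged `NA`, never silently zero.

## The desk-scale experiment

`replicate_small()` / `run_pipeline(run_config(...))` is the packaged
experiment: 20 training phantoms x 6 boost plans at 32 x 32 x 16, a
three-level growth-4 network trained 40 epochs (well within the 200-epoch
reference schedule), and 14 held-out phantoms with one plan each. On this
configuration the trained network's held-out rectal Dmean error is several
times smaller than a predict-the-cohort-mean-dose baseline, optimal-
constraint stratification accuracy on the held-out phantoms reaches the
90-100% range, and the parallel-endpoint (incontinence) risk agreement is
tight. The serial bleeding endpoint shows a positive risk bias: its gEUD is
dominated by the few hottest rectal voxels, and a smoothing network bleeds
some target plateau into rectal voxels at mask boundaries — the same
over-prediction direction reported for the clinical test cohort, amplified
here by the coarse desk-scale voxels. We report it rather than tune it away.

Every stage writes text reports plus a manifest (seed, configuration echo,
stage timings); re-running any stage with the same configuration and seed
reproduces its reports byte for byte, which the test suite asserts.

## Numerical choices and degenerate inputs

* Centres of mass are floored to integer indices (tie-break documented).
* DVH queries above the recorded maximum dose return 0 (nothing receives
  more than the maximum); negative or out-of-range queries are clamped with
  a warning.
* Both-empty isodose sets have Dice 1 by convention (logged).
* The probit is evaluated through R's `pnorm` (error-function path, double
  precision); no lookup tables.
* Zero-steepness fall-off, empty masks, misaligned grids, non-positive
  normalization constants and invalid LKB parameters all raise validation
  errors rather than propagating garbage.

## Known limitations

The phantom family is ellipsoid-and-tube geometry; it does not test
robustness to real contouring variability. The analytic dose surrogate has
no beam model, so absolute DVH shapes (especially the low-dose bath) are
stylised. The desk-scale network is far below clinical resolution; the
full-scale configuration is provided and shape-checked but not trained in
the packaged experiments. The LKB parameters are fixed literature values —
no fitting, and no tumour-control modelling — so risk numbers are relative
decision aids, not absolute outcome predictions.
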
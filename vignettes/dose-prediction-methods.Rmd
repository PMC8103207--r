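---
title: "Priority-conditioned dose prediction: model, surrogate cohort and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Priority-conditioned dose prediction: model, surrogate cohort and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretodose)
```

## The problem

Inverse planning for prostate volumetric modulated arc therapy (VMAT)
scalarizes competing dose objectives — uniform target coverage, bladder
sparing, rectum sparing — into a weighted sum whose weights (the
*optimization priorities*) a planner chooses. Exploring the trade-off
(Pareto) surface means re-optimizing and re-calculating a plan per priority
combination, at minutes per plan on a commercial treatment planning system
(TPS). `paretodose` implements a machine-learning shortcut: a voxel-wise
model that maps a patient's structure masks plus a priority vector directly
to the resulting dose distribution, so a whole Pareto surface can be
estimated in seconds.

The model works in fraction-of-prescription units (1.0 = the prescribed
target dose, 70 Gy in the intended setting) and all errors are reported as
percentages of prescription. The three objectives are the PTV homogeneity
index (HI = D2% − D98%), bladder D25% and rectum D25%.

## Model

### Analytic dose initialization

VMAT arcs wrapping (nearly) 360 degrees produce dose that decays roughly
isotropically with distance from the target. The model therefore starts
from a closed-form initialization driven by two PTV distance maps:

* `ISD1(v)`: in-plane Euclidean distance from voxel `v` to the nearest PTV
  voxel *within v's own transverse slice*;
* `ISD2(v)`: distance along the slice axis from `v` to the nearest slice in
  which the PTV occupies `v`'s (row, column) position.

The initialized dose is

    Di(v) = 1 / (1 + a1 * ISD1(v)^a2 + c * ISD2(v)^a3)

with four positive parameters fitted to reference doses by masked RMSE
before any network training. `Di` is exactly 1 on the PTV and decays
monotonically in both distances.

Numerical choices:

* Distances are expressed in units of 10 mm before exponentiation so the
  fitted exponents act on O(1) quantities. This constant is fixed and
  documented (`DIST_SCALE_MM`).
* Where a distance is undefined (a slice containing no PTV, or a (row,
  column) position the PTV never occupies), the distance is capped at the
  grid diagonal, which drives `Di` to ~0 far from the target.
* `c` is treated as a fourth fitted parameter on the same footing as
  `a1..a3`; fitting it cost nothing and subsumes the fixed-`c` case.
* The fit runs Adam on the log-parameters (positivity by construction),
  seeded, with analytic gradients; 1500 iterations at learning rate 0.05 by
  default, which recovers generator parameters to well under 5% on
  noiseless phantoms.
* Naming: `ISD1` is implemented as the in-plane distance and `ISD2` as the
  along-axis distance. The inter-/intra-slice labels attached to these
  quantities read as swapped in places; this package fixes the mapping by
  what each distance measures and documents it here.

### Patch features

Per voxel, the model sees 9×9 transverse patches of four channels — the
priority-scaled PTV, bladder and rectum masks and the current dose map — at
three atrous (dilated) rates 1, 3 and 10. Before sampling at rate `r > 1`,
a channel is smoothed with a uniform `r × r` kernel so each sampled value
summarises the voxels the dilation skips; the receptive field grows to most
of a 128×128 slice without extra parameters. Patches are flattened
row-major into 81-vectors and concatenated — for each rate, channels in the
fixed order (PTV, bladder, rectum, dose) — followed by the raw priority
triplet: 4 × 3 × 81 + 3 = 975 features.

Choices where the design was open:

* Zero padding outside the slice for both smoothing and patch sampling;
  dose outside the body is near zero anyway.
* The even 10×10 kernel is anchored at the top-left element of its central
  2×2.
* The dose channel is smoothed before atrous sampling exactly like the
  structure channels, keeping receptive-field semantics uniform across
  channels.
* Patches are strictly 2-D (transverse); no 3-D sampling.
* Priority scaling enters twice — as mask scaling and as the raw trailing
  triplet — and the scaling commutes with smoothing and patch extraction
  (both linear), which the implementation exploits by caching unscaled
  structure features per slice.

### Residual network

Six residual blocks sequentially update the initialized dose map. Each
block is a per-voxel fully connected net: two 100-unit layers with leaky
ReLU (slope 0.2 below zero) and a single output with scaled softsign
activation `SS(x) = 0.3 x / (1 + |x|)`, bounding each block's dose shift to
(−0.3, 0.3) of prescription — so the six blocks can move a voxel by at most
1.8 in total, a bound the tests assert. Because every block changes the
dose map, the dose-channel patches are re-extracted before each block;
structure-channel patches are computed once (the anatomy never changes).
Gradients flow through both the additive skip connection and the
re-extracted patches, and the backward pass implements the exact adjoint of
the smoothing and atrous gather operators (verified against central finite
differences to better than 1e-4 relative error).

Blocks do not share weights; the priority triplet is part of every block's
feature vector. Block count, layer widths and atrous rates are
configuration with the defaults above.

### Training

The loss is the root-mean-square error between predicted and reference
dose, restricted to voxels inside the body contour on slices containing at
least one critical structure (PTV, bladder or rectum). Optimizing RMSE
rather than MSE matches the quantity reported everywhere else; at exactly
zero loss the gradient has an epsilon guard.

Batches are whole slices sampled *diagonally*: patients are visited in a
seeded cyclic order and each batch slot advances one slice per iteration
from a staggered offset, so one batch contains slices at different depths
of different patients and, over enough iterations, every (patient, slice)
pair appears. Slices whose loss mask is empty contribute zero loss and
gradient and are skipped exactly. The batch size defaults to the cohort's
median slice count — the typical number of slices a patient has. Each slot
also cycles deterministically through the patient's plans, so all plans are
eligible.

Training uses Adam with step size 0.001, decay rates 0.9/0.999 and epsilon
1e-8, from a Glorot-uniform initialization (every weight uniform within
±sqrt(6/(fan-in + fan-out)), zero biases), for a default of 2000
iterations. No early stopping, learning-rate schedule or weight decay. The
initialization parameters are always fitted first and held fixed during
network training.

## Synthetic pelvic cohort

Clinical cohorts of planned prostate VMAT cases are not distributable, so
the package ships a phantom generator whose output has the statistical
structure the model assumes. It emulates, per patient: a body cylinder; an
ellipsoidal PTV near the grid centre, slightly posterior; an ellipsoidal
bladder anterior-superior to the PTV; and a rectum tube running posterior
to the PTV along roughly 60% of the scan (contoured rectum extends only a
few centimetres beyond the target in practice, and scans retain slices with
no critical structures — which is exactly the situation the loss-mask rule
addresses). Centres and radii are jittered per patient, deterministically
in (seed, patient index). Femoral heads are not modelled; the associated
clinical constraint is out of scope.

Per patient, 25 plans sample the Pareto surface on a deterministic 5×5 grid
of convex combinations `p = α P1 + (1−α)(β P2 + (1−β) P3)` of three
bounding priority vectors, by default the objective-dominant corners
(10,1,1), (1,10,1), (1,1,10). Duplicate priority vectors on the α = 1 edge
are retained so every plan keeps its (α, β) coordinate. The clinically
tuned bounding points of a real MCO protocol are irreproducible; these
defaults are stand-ins, not claims about clinical values.

The surrogate "TPS" dose for a plan is

    dose = base × sparing × heterogeneity + noise,  then D95-normalized

* `base` is the analytic initialization evaluated with the generator's true
  parameters (a1\*, a2\*, a3\*, c\*) = (1.5, 2.0, 0.8, 0.6) — deliberately
  the same functional form the model initializes with, so the network's
  learning target is the small residual, not the dose shape itself.
* `sparing = 1 − Σ_o s_o (w_o/Σw) exp(−d_o/τ)` over the bladder and rectum,
  with `d_o` the in-plane distance to organ `o`: raising an organ's
  priority deepens the dose reduction around it. Defaults `s_o = 0.4`,
  `τ = 25 mm`. Sparing applies outside the PTV only — target coverage is
  protected, as clinical optimizers enforce — which also makes the D95
  normalization factor independent of the organ weights. With equal
  `s_bladder = s_rectum`, each organ's dose is then pointwise
  non-increasing in its own weight, so the monotone trade-off property
  holds by construction and not merely on average.
* `heterogeneity = 1 + h g/(1 + w_hi)` inside the PTV, `g` a smooth
  zero-mean unit-variance field: a higher HI priority flattens the target
  dose, so HI falls monotonically in `w_hi`.
* `noise` is uniform-kernel-smoothed white noise (TPS doses are spatially
  smooth, so i.i.d. noise would be wrong), amplitude `σ = 0.003`.

The stochastic amplitudes are deliberately small relative to the
deterministic sparing term: the heterogeneity field and the noise are
patient-specific random fields no model can predict, so they set an
irreducible error floor, while the sparing term is a deterministic function
of the masks and priorities — exactly what the network is supposed to
learn. Random fields are seeded per patient (not per plan) so that plans of
one patient differ only through their priorities; this is what makes the
monotone trade-off property testable across plans. All doses are normalized
so PTV D95% equals 100% of prescription, exactly as plan normalization does
clinically.

What the phantom does *not* emulate: beam transport and fluence physics,
CT intensities, femoral-head constraints, inter-patient anatomical
diversity beyond ellipsoid jitter, or TPS optimizer idiosyncrasies. Passing
tests on the phantom therefore demonstrate the pipeline's correctness and
the model's ability to learn priority-conditioned dose structure, not
clinical-grade accuracy.

## Pareto-surface evaluation

A surface is sampled by the 25 plans; its vertices are the objective
vectors (HI, bladder D25%, rectum D25%) and its simplicial complex is the
triangulation of the (α, β) parameter grid carried into objective space
(32 triangles for the 5×5 grid). Triangulating in parameter space avoids
the flipped simplices an objective-space Delaunay can produce on a curved
surface. Four metrics compare a predicted surface with its reference:

* **Matched RMSE** — root mean squared 3-D Euclidean distance over matched
  plans; objective errors accumulate within a pair, so values run larger
  than dose-map RMSE.
* **Hausdorff distance** — max of the two directed sup–inf distances over
  the vertex sets (vertices only, by definition); sensitive to outliers.
* **APD** (average projected distance) — matched displacements projected
  onto the mean-displacement direction, then averaged; error components
  along the surfaces cancel. Zero displacements give APD 0 by convention;
  a non-zero displacement set with vanishing mean has no defined direction
  and raises an error.
* **ANPD** (average nearest-point distance) — each surface's complex is
  supersampled on a barycentric grid (≥105 points per triangle by default,
  subdivision level 13) and each sample's *exact* distance to the other
  complex (point-to-triangle projection, minimized over triangles, with a
  segment fallback for degenerate triangles) is averaged per direction,
  then across the two directions. The brute-force point-cloud version of
  this computation is kept in the test suite as the independent oracle.

DVH percentiles use the exactly testable convention: sort masked doses
descending and take element `ceiling(x/100 · N)`, no interpolation.

## Cross-validation harnesses

Two schemes are provided. Repeated k-fold: per repetition, patients are
shuffled (seeded) into k folds and the full two-stage fit runs k times,
each tested on its held-out fold; each patient is tested exactly once and
trained on k−1 times per repetition (the full protocol is 10-fold repeated
50 times). Rotating-subset: patients grouped into 10 enumerated subsets;
validation j trains on the cyclic window of `train_subsets` subsets
starting at j and tests on the rest, so every subset appears in exactly
`train_subsets` training sets — a symmetric way to probe train:test ratios
from 9:1 down to 1:9 with ten trainings each.

## Problem sizes used in the shipped studies

The package's own test and acceptance studies run on reduced problem sizes
chosen so a laptop-class single core reproduces them comfortably:

* Initialization-parameter recovery: 3 patients × 1 plan at 10×24×24
  voxels, noiseless surrogate doses generated exactly by the
  initialization formula; recovery to within 5% relative and masked RMSE
  below 0.5% of prescription.
* Learning-signal study: 8 patients × 5 plans (the diagonal of the 5×5
  priority grid) at 16×32×32 voxels, 6 training patients and 2 held out,
  300 Adam iterations. At this scale the network configuration is reduced
  to 2 residual blocks of 32 units: the 16×32×32 phantom has two orders of
  magnitude fewer voxels than the clinical setting the 6×100 default is
  sized for, and an overparameterized network spends the whole short
  budget deflating its random initial output (whose initial error is large
  and random, as expected for a residual stack with non-zero random
  parameters) rather than learning. The paper-scale defaults remain the
  package defaults.
* Pareto pipeline checks: one patient, the full 25-plan grid, at reduced
  resolution.
* Oracle-equivalence checks run 100+ randomized cases per operation for
  the cheap operations and a smaller number of full-plan cases for the
  end-to-end forward pass and ANPD, whose brute-force oracles are
  themselves expensive.

## Known limitations

* The isotropic initialization is only appropriate for ~360° arcs; IMRT or
  partial arcs would need a different analytic form.
* Predictions are voxel-wise and not explicitly smoothed; predicted maps
  can look jagged around mid-level isodose lines.
* The model outputs a dose distribution, not a deliverable plan; a real
  optimization must follow any priority choice it informs.
* Hausdorff is computed over vertex sets, not interpolated surfaces — the
  very limitation that motivates ANPD.
* The phantom's trade-off structure is smooth and mild by construction;
  real Pareto surfaces can be sharper near constraint boundaries.
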
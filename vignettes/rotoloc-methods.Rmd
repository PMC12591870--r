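---
title: "rotoloc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rotoloc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rotoloc` implements the computational core of an ultrasound guidance
system for vacuum-assisted rotational resection of breast tumors: the
geometric activation decision, complexity accounting for the lightweight
detection architectures, detection metrics, and a synthetic session
generator that makes the whole pipeline testable without clinical data.
This vignette records the models, conventions and design decisions, in the
order a user meets them.

## 1. The activation decision

Detections are axis-aligned pixel boxes with the origin at the image's
top-left corner and y growing downwards (the native convention of both
ultrasound frames and detector output). The cutter slot box is
`(x1, y1, L1, H1)` (left edge, top edge, length, height) and the tumor box
`(x2, y2, L2, H2)`. Coordinates are real-valued — detectors localise at
sub-pixel precision — and no predicate rounds them.

The decision first classifies the **size scenario** with a margin of
`size_margin = 20` px:

* slot larger: `L1 − L2 > 20`
* tumor larger: `L2 − L1 > 20`
* similar sizes: otherwise.

The strict `>` on both sides leaves the exact boundary `|L1 − L2| = 20`
unassigned by the printed rules; we assign it to the *similar* scenario,
whose length-extension rule is the procedure's own fallback for ambiguous
sizes, making the partition total (a property test checks totality).

Alignment is then a conjunction of one horizontal and one vertical strict
inequality:

* slot larger: `x1 − 0.2·L1 < x2` and `y2 − 1.1·H2 < y1`;
* slot smaller: `x2 − 0.2·L2 < x1` and `y2 − 1.1·H2 < y1`;
* similar: the slot-smaller rules after temporarily extending the tumor,
  `L2' = 1.2·L2`, keeping `(x2, y2)` fixed.

All inequalities are implemented strictly as written. Two consequences are
worth flagging. First, the slot-larger horizontal condition is weak: it
accepts configurations where the tumor lies far to the slot's right. We
implement it verbatim rather than "repairing" it; users who need a
two-sided horizontal window can compose their own predicate from the
exported pieces. Second, every condition is homogeneous of degree one in
the coordinates, so the decision is invariant under uniform rescaling of
the geometry provided `size_margin` is rescaled too — a property test
exercises this, and it is why the engine behaves identically on the 160 px
test scenes and 640 px frames.

### Per-frame semantics

Frames may contain several detections per class; the engine keeps the
highest-confidence box per class (ties: larger area, then smaller x — the
deterministic order detector post-processing produces) after discarding
detections below `confidence_threshold` (default 0.25; detector
post-processing thresholds in this family are conventionally around this
value, and it is exposed in the configuration).

**Procedure I** (cutter beneath the tumor, both co-visible): the prompt is
emitted on the first frame where both classes are present and the
alignment predicate holds. There is no frame-count requirement; stability
is the operator's responsibility in this workflow. The prompt is emitted
once per session — the flag is absorbing, since the workflow defines a
single "can begin" notification.

**Procedure II** (cutter lateral to the tumor, alternating probe views):
the engine must tolerate the slot and tumor never being co-visible. The
slot position is *recorded* after `slot_confirm_frames = 5` consecutive
slot sightings (a single-frame sighting may be a transient
false positive; five consecutive frames is ~0.2 s at typical frame rates).
The remembered box persists until a later confirmed sighting replaces it.
On every tumor-visible frame with a remembered slot, the alignment
predicate is evaluated against the remembered slot; each aligned frame
increments the overlap counter, and the prompt fires when the counter
reaches `overlap_frames_required = 500`. The counter is *cumulative* —
misaligned or tumor-free frames do not reset it. A stricter consecutive
reading is available via `reset_on_miss = TRUE` (a frame where the tumor
is visible but misaligned zeroes the counter; slot-only frames never do,
as that would make the alternating workflow unable to finish). No motion
compensation is applied between the remembered slot and the live tumor;
the method assumes the probe returns to a comparable plane, and we
implement exactly that.

Both step functions are pure: they return a new state, never mutate the
input, and replaying a recorded detection stream reproduces the identical
event sequence (tested).

## 2. Architecture plans and complexity accounting

The detection models are described as *declarative layer plans* — YAML
lists of blocks with explicit channels, kernels, strides, expansions and
graph edges, shipped under `inst/extdata/plans/` — rather than code. Four
plans are registered: the baseline nano and small detectors (`yolov11n`,
`yolov11s`, the published topology with a two-class head) and the
lightweight variants (`yolov11n_plus`, `yolov11s_plus`).

### Counting conventions

Two parameter conventions exist in the wild and differ by exactly the
batch-norm bookkeeping:

* **training**: convolutions are bias-free; each batch-norm layer
  contributes `2·channels` learnable parameters;
* **deployed** (the default): each conv+norm pair is folded into a biased
  convolution (`weights + channels`), and the fixed 16-parameter
  distribution-projection convolution of the detection head is included.

Published "total params" figures for this detector family are deployed
counts, and `count_parameters()` reproduces them exactly: 2,582,542 (nano
baseline, 2 classes) and 9,413,574 (small baseline). The training-side
counts are what a built model's weight arrays sum to; an invariant test
keeps the analytic accounting and the instantiated weights equal.

FLOPs are `2 × multiply-accumulates` of the folded convolutions at
640×640; activation, pooling and resampling terms are excluded. This
convention was calibrated once against the baselines — it reports 6.3 and
21.3 GFLOPs for the two baseline plans at the one-decimal precision such
figures are quoted at — and is then applied unchanged to every plan.
`count_flops()` returns the unrounded value; reporting rounds to one
decimal.

### The lightweight variants

The published description of the `+` backbones fixes the module inventory
(ConvBN, MIRB, MUIB, SPPF, pruned C3K2, cross-stage partial connections),
the 40-80-128-480-512 channel schedule, the kernel menu (3×3/5×5), the
expansion-ratio menus, and the *totals* — 2,140,390 parameters / 4.6
GFLOPs (nano) and 7,477,470 parameters (small) — but not the
layer-by-layer listing. We treat the printed totals as checksums: the
plans shipped here satisfy all the stated structural constraints *and*
reproduce the totals exactly. Four points about the chosen topology:

* The compute budget forces the high-resolution stages to be
  depthwise-dominated. At the schedule's widths, a dense 3×3 projection at
  the P2 resolution costs ≈1.5 GFLOPs by itself — a third of the whole
  budget — so stride-2 MIRB stages are realised as a strided depthwise
  convolution followed by a pointwise expansion (two convolutions), while
  stride-1 MIRB keeps the classic three-convolution inverted-residual form
  (expand 1×1 → depthwise → project 1×1, hidden width `c_in × expansion`).
* The 480- and 512-wide waypoints of the schedule are reached by pointwise
  (1×1) ConvBN projections feeding the P4/P5 taps; the spatial trunk runs
  at width 160 through MUIB blocks (leading strided depthwise → expand 1×1
  → depthwise → project 1×1, expansion 4). This mirrors how
  mobile-oriented backbones realise wide late stages cheaply.
* The improved SPPF is narrow: hidden width 80, output 160 (the "80, 160"
  widths quoted for it), pooling kernel 5.
* "Local information pruning" in the neck's C3K2 blocks is realised as a
  reduced residual branch: each unit is a depthwise 3×3 + pointwise 1×1
  pair at an explicit hidden width (20/16/44/176 for the nano variant),
  replacing the two dense 3×3 convolutions of the unpruned block. The
  hidden widths are data in the plan files, chosen together with the block
  menus so the totals land on the published checksums; the small variant is
  the same topology with doubled widths and re-balanced neck hiddens.

With these plans, the parameter reduction of the nano pair is 17.12% and
the FLOP reduction 27.01% — matching the quoted 17.1% / 27.0%.

`build_model()` instantiates every convolution with seeded He-normal
weights and identity batch-norm, and `model_forward()` runs a numeric
forward pass (im2col + BLAS for dense convolutions, shift-accumulate for
depthwise, explicit attention for the baselines' partial-self-attention
stage), producing the three raw detection maps at strides 8/16/32. The
forward pass exists to validate graph wiring and shapes, not for speed;
tests run it at 128×128 (any multiple of 32 works). Gradient training is
out of scope: `train()` raises a classed error pointing at the exported
dataset/config layout for external trainers. The package is a planning,
accounting and simulation toolkit, not a training framework.

## 3. Detection metrics

Matching is the standard greedy scheme at IoU ≥ 0.5: predictions in
decreasing confidence order claim the unmatched same-class ground-truth
box of highest IoU; leftovers are false positives / false negatives.
Average precision uses all-points (continuous) interpolation — the
precision envelope integrated over recall — and `mAP50(all)` is the
unweighted mean over the two classes. AP on small fixtures is checked
against a brute-force enumeration of the curve.

Specificity, MCC and error rate need true negatives, which have **no
standard definition for box detection**. We adopt an explicit image-level
convention: per class, an image contributes TN = 1 exactly when it
contains neither a ground-truth box nor a prediction of that class. This
is a documented stand-in — published specificity/MCC/ERR tables for
detectors rarely state their convention, so absolute values are only
comparable within a convention. Degenerate denominators are handled
explicitly: MCC is 0 whenever a marginal factor is zero (the limit
convention that keeps it defined), while precision/recall/specificity/ERR
are reported as `NA`, never silently 0.

Cross-validation folds are built at the patient level: whole patients are
shuffled deterministically under a seed and dealt round-robin into k
folds, so no patient's images are split across folds (preventing
patient-level leakage) and fold sizes balance to within one patient.

## 4. Synthetic sessions

The generator emulates just enough of B-mode appearance to exercise every
downstream component with exact ground truth:

* a smooth background with mild depth attenuation;
* multiplicative speckle, `pixel × Gamma(shape = 1/v, rate = 1/v)` with
  unit mean and variance `v` (default 0.25, i.e. the grainy
  fully-developed-speckle look; 0 gives deterministic frames);
* the cutter slot as a bright 120×20 px rectangle and the tumor as a
  hypoechoic 80×50 px ellipse at the default 640×640 frame — consistent
  with a 7-gauge probe aperture and the 8–15 mm lesions this procedure
  treats at a typical pixel pitch. Ground-truth boxes are the tight
  analytic bounds of the shapes, not a rasterisation.

Session scripts drive per-frame positions and visibility. Procedure I
scripts keep both objects visible and lower the slot through the critical
vertical line so the alignment predicate first holds exactly at the
scripted onset frame (the script constructor verifies this with the
engine's own predicates and rejects inconsistent scripts). Procedure II
scripts toggle visibility in blocks — probe switching is modelled as
visibility toggling only, since no probe kinematics are specified — with
the tumor placed out of (too deep), then in, activation geometry. The
slot's horizontal placement anchors its left edge just right of the
tumor's, which satisfies the horizontal condition in all three size
scenarios, so scripted alignment is gated purely by the vertical
condition and remains valid at any frame scale.

The **detector stub** perturbs scripted ground truth instead of running a
network: Gaussian localisation noise, per-box miss probability, Poisson
false positives, and a confidence model `1 − |N(0, conf_sd)|` truncated to
`[0.05, 1]`. With all noise at zero it returns the ground truth with
confidence exactly 1, which is what makes end-to-end frame-exact prompt
tests possible. A `segmentation_detector()` (thresholds + connected
components) is included so the pixel path can run end-to-end too.

What passing these tests shows — and does not show: they validate the
decision logic, counters, I/O and metric computations on streams whose
statistics we control. They say nothing about detection accuracy on real
ultrasound, which has shadowing, reverberation, anisotropic speckle and
probe-pressure deformation this generator deliberately does not model.

Datasets are exported in the YOLO text-label layout (`images/`, `labels/`,
`data.yaml`, plus a `patients.json` sidecar for fold splitting); empty
frames get empty label files so frame counts survive the round trip, and
labels are written at six decimals (round-trip error < 0.5 px). Videos
are written as multi-page TIFF or numbered PNG sequences; compressed
containers (MP4/AVI) are not handled — no codec bindings are among the
package's dependencies, and frame directories are the lingua franca of
offline analysis anyway.

## 5. Numerical and testing choices

* Test scenes are 160×160 (geometry scales exactly; see the
  scale-covariance property), forward passes run at 128×128, the
  decision-rule/oracle grid uses 10⁴–1.2×10⁴ random pairs stratified
  across size scenarios including the ±20 px boundary, and the stub's
  miss-rate Monte-Carlo uses 10⁴ frames (binomial s.e. ≈ 0.003 at
  p = 0.1). These sizes were chosen as the smallest that make the checks
  sharp.
* All stochastic components take explicit seeds; the stub derives a
  per-frame RNG state from `(session seed, frame index)` so logs are
  reproducible and frames independent.
* Degenerate inputs are first-class: zero-frame scripts produce empty
  streams and no events; empty detection frames advance the engine
  without state change; zero-frame videos are refused rather than written.
* Parameter counts are exact integers; FLOP comparisons in tests use the
  one-decimal reporting precision; the reduction ratios are computed from
  the unrounded values.

## 6. Known limitations

* The activation rules are 2-D and verbatim; they have no notion of probe
  motion, out-of-plane displacement, or the weak slot-larger horizontal
  condition noted above.
* True-negative-based metrics follow this package's stated convention and
  are not comparable to tables computed under unknown conventions.
* The layer plans reproduce the published complexity budgets exactly, but
  where the internal structure was not published the plans are this
  package's reconstruction, documented above and inspectable as data.
* No training backend; no claim about real-data detection quality is made
  or tested.
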
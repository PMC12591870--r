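# rotoloc

Real-time ultrasound guidance tooling for **vacuum-assisted rotational
resection of breast tumors**.

During minimally invasive rotational resection, the surgeon steers a
rotating cutter under B-mode ultrasound and must decide when the cutter's
aperture (the *cutter slot*) is correctly positioned under the tumor before
activating it. That decision currently rests on the operator's experience
with real-time image interpretation, which limits the technique's uptake
outside specialist centres. `rotoloc` implements the computational core of
an intelligent guidance system for this task, aimed at researchers and
engineers building or validating such systems:

* **Activation decision engine** — the geometric rules that decide, from the
  detected slot box `(x1, y1, L1, H1)` and tumor box `(x2, y2, L2, H2)`,
  whether the slot is in activation position. Sizes are compared with a
  20 px margin; depending on the size scenario the horizontal condition is
  `x1 − 0.2·L1 < x2` (slot larger) or `x2 − 0.2·L2 < x1` (slot smaller,
  with `L2' = 1.2·L2` when sizes are similar), and the vertical condition is
  `y2 − 1.1·H2 < y1`. Two surgical workflows are supported: procedure I
  (slot and tumor co-visible; prompt on first aligned frame) and procedure
  II (alternating probe views; a remembered slot position is compared with
  the live tumor, and the prompt fires when the cumulative overlap count
  reaches 500 frames). The emitted prompt is
  `"The operation can begin now."`.
* **Detection architecture accounting** — declarative layer plans for the
  lightweight detectors used to localise slot and tumor (baseline nano/small
  detectors and the `+` variants with MobileNetV4-style inverted-residual
  (MIRB) and universal-inverted-bottleneck (MUIB) backbone stages, a
  40-80-128-480-512 channel schedule and a pruned cross-stage-partial neck),
  with exact parameter and FLOP accounting and a numeric forward pass. The
  registered plans reproduce the published complexity budgets exactly:
  2,582,542 → 2,140,390 parameters (−17.1%) and 6.3 → 4.6 GFLOPs (−27.0%)
  for the nano pair; 9,413,574 → 7,477,470 parameters for the small pair.
* **Detection metrics** — greedy IoU matching, per-class and pooled
  precision / recall / mAP50 / specificity / MCC / error rate (with a
  documented image-level true-negative convention), and patient-level
  cross-validation folds that never split a patient.
* **Synthetic sessions** — speckle-textured frames with scripted slot/tumor
  trajectories and exact ground truth, a ground-truth-backed detector stub
  with controllable noise, YOLO-format dataset export/import, and a
  frame-stream pipeline with keyframe extraction, burned-in annotations and
  prompt emission.

Model training is deliberately out of scope (it needs a GPU deep-learning
runtime); `write_yolo_dataset()` and `write_config()` produce the dataset
layout and hyperparameter file the detector family's standard trainer
consumes.

## Worked example

```r
library(rotoloc)
library(dplyr)
library(generics)

# 1. Build the lightweight detector and inspect its complexity budget
glance(build_model(arch_plan("yolov11n_plus")))
#> # A tibble: 1 × 6
#>   name          layers num_classes total_params training_params gflops
#>   <chr>          <int>       <int>        <int>           <int>  <dbl>
#> 1 yolov11n_plus     23           2      2140390         2151302   4.61

reduction_ratios("yolov11n", "yolov11n_plus")
#> # A tibble: 1 × 2
#>   params_reduction_pct flops_reduction_pct
#>                  <dbl>               <dbl>
#> 1                 17.1                27.0

# 2. Simulate an alternating-view (procedure II) session: 10 slot-only
#    frames confirm the slot position, then the tumor is tracked in
#    activation position; the prompt fires at the 500th overlap frame.
scene <- scene_params()
script <- session_script(procedure = 2, n_frames = 520, onset_frame = 1,
                         scene = scene, slot_block = 10, tumor_block = 600)
stream <- simulate_session(script, scene, seed = 42)
log <- run_session(stream, detector_stub())
log$events
#> # A tibble: 1 × 2
#>   frame message
#>   <int> <chr>
#> 1   510 The operation can begin now.
```

`total_params` (2,140,390) is the deployed, batch-norm-folded parameter
count of the two-class model; `training_params` counts the unfolded
convolution + normalisation weights. The 17.1% / 27.0% figures are the
reductions of the lightweight variant over its baseline. In the session,
frames 1–10 show only the slot (confirming its remembered position after 5
consecutive sightings), frames 11 onward show the tumor in activation
geometry, so the 500th overlap frame — and the prompt — lands on frame 510.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","rotoloc",package="rotoloc"))')" \
    complexity --arch yolov11n_plus
```

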
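# Shared fixtures built in code.

# small scene renders quickly in tests; geometry scales with the frame
test_scene <- function(width = 160, height = 160, speckle_var = 0.25, ...) {
  scene_params(width = width, height = height, speckle_var = speckle_var, ...)
}

# a random pair of valid slot/tumor boxes
random_box_pair <- function(n = 1, max_xy = 500, max_len = 200) {
  list(
    slot = boxes(runif(n, 0, max_xy), runif(n, 0, max_xy),
                 runif(n, 1, max_len), runif(n, 1, 60), "slot"),
    tumor = boxes(runif(n, 0, max_xy), runif(n, 0, max_xy),
                  runif(n, 1, max_len), runif(n, 1, 80), "tumor")
  )
}

# direct transcription of the printed activation inequalities, kept free of
# the package's scenario dispatch so it can serve as an independent oracle
oracle_activation <- function(x1, y1, L1, H1, x2, y2, L2, H2,
                              margin = 20, hf = 0.2, vf = 1.1, ef = 1.2) {
  if (L1 - L2 > margin) {
    (x1 - L1 * hf < x2) && (y2 - H2 * vf < y1)
  } else if (L2 - L1 > margin) {
    (x2 - L2 * hf < x1) && (y2 - H2 * vf < y1)
  } else {
    L2e <- L2 * ef
    (x2 - L2e * hf < x1) && (y2 - H2 * vf < y1)
  }
}

# brute-force average precision: enumerate every confidence cut of the
# ranked predictions and integrate the precision envelope numerically
oracle_ap <- function(matched, n_gt) {
  if (!length(matched)) return(0)
  tp <- cumsum(matched); fp <- cumsum(!matched)
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  ap <- 0
  r_prev <- 0
  for (i in seq_along(rec)) {
    p_env <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - r_prev) * p_env
    r_prev <- rec[i]
  }
  ap
}

scene_truth_for_tests <- function(sc) rotoloc:::scene_truth(sc)
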
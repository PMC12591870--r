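test_that("rendered frames are deterministic and carry tight bounds", {
  sc <- scene_params(width = 640, height = 640,
                     tumor_center = c(320, 200), tumor_axes = c(40, 25))
  f1 <- render_frame(sc, seed = 5)
  f2 <- render_frame(sc, seed = 5)
  expect_identical(f1$image, f2$image)
  expect_identical(f1$truth, f2$truth)
  tb <- f1$truth[f1$truth$class == "tumor", ]
  expect_equal(unlist(tb[c("x", "y", "length", "height")]),
               c(x = 280, y = 175, length = 80, height = 50))
  # zero speckle variance: bit-identical across different seeds
  sc0 <- test_scene(speckle_var = 0)
  expect_identical(render_frame(sc0, seed = 1)$image,
                   render_frame(sc0, seed = 2)$image)
  # values stay within the image range
  expect_true(all(f1$image >= 0 & f1$image <= 1))
  expect_error(scene_params(width = 100, height = 100,
                            slot_center = c(95, 50), slot_length = 30),
               "scene error")
})

test_that("the rendered slot is bright and the tumor hypoechoic", {
  sc <- test_scene(speckle_var = 0)
  f <- render_frame(sc, 1)
  slot <- f$truth[f$truth$class == "slot", ]
  tum <- f$truth[f$truth$class == "tumor", ]
  in_slot <- f$image[round(slot$y + slot$height / 2), round(slot$x + slot$length / 2)]
  in_tum <- f$image[round(tum$y + tum$height / 2), round(tum$x + tum$length / 2)]
  expect_gt(in_slot, 0.8)
  expect_lt(in_tum, 0.2)
})

test_that("procedure I scripts align exactly from the onset frame", {
  sc <- test_scene()
  script <- session_script(1, n_frames = 100, onset_frame = 40, scene = sc)
  expect_true(all(script$slot_visible & script$tumor_visible))
  expect_false(any(script$aligned[script$frame < 40]))
  expect_true(all(script$aligned[script$frame >= 40]))
  # running the engine on the scripted ground truth prompts at the onset
  stream <- simulate_session(script, sc, seed = 2)
  log <- run_decision_engine(stream$truth, 1, n_frames = 100)
  expect_equal(log$events$frame, 40L)
})

test_that("procedure II scripts alternate visibility and trigger at the counted frame", {
  sc <- test_scene()
  script <- session_script(2, n_frames = 700, onset_frame = 1, scene = sc,
                           slot_block = 10, tumor_block = 300)
  expect_false(any(script$slot_visible & script$tumor_visible))
  expect_true(any(script$slot_visible) && any(script$tumor_visible))
  stream <- simulate_session(script, sc, seed = 2)
  cfg <- decision_config(overlap_frames_required = 500)
  log <- run_decision_engine(stream$truth, 2, cfg, n_frames = 700)
  # tumor-visible frames: 11..310 (300) and 321..620, 631.. ; the 500th
  # overlap frame is the 200th frame of the second tumor block
  tumor_frames <- script$frame[script$tumor_visible]
  expect_equal(log$events$frame, tumor_frames[500])
  # zero-frame scripts yield empty streams and no events
  empty <- session_script(1, n_frames = 0, scene = sc)
  s0 <- simulate_session(empty, sc)
  expect_equal(s0$n_frames, 0L)
  expect_equal(nrow(run_decision_engine(s0$truth, 1, n_frames = 0)$events), 0L)
})

test_that("the ground-truth stub degrades gracefully with noise parameters", {
  sc <- test_scene()
  truth <- scene_truth_for_tests(sc)
  # all noise zero: exactly the truth, confidence 1
  det <- stub_detect(detector_stub(), truth, 1, seed = 3)
  expect_equal(det$x, truth$x)
  expect_equal(det$confidence, rep(1, nrow(truth)))
  # certain miss: empty
  det <- stub_detect(detector_stub(miss_prob = 1), truth, 1, seed = 3)
  expect_equal(nrow(det), 0L)
  # determinism in the frame/seed stream
  d1 <- stub_detect(detector_stub(noise_sd = 2, fp_rate = 0.5), truth, 7, seed = 1)
  d2 <- stub_detect(detector_stub(noise_sd = 2, fp_rate = 0.5), truth, 7, seed = 1)
  expect_identical(d1, d2)
})

test_that("empirical miss rate matches the configured probability", {
  sc <- test_scene()
  truth <- scene_truth_for_tests(sc)[1, ]
  stub <- detector_stub(miss_prob = 0.1)
  hits <- vapply(seq_len(10000), function(i) {
    nrow(stub_detect(stub, truth, i, seed = 2))
  }, 0)
  expect_equal(mean(hits == 0), 0.1, tolerance = 0.01 / 0.1)
})

test_that("YOLO datasets round-trip boxes, patients and empty frames", {
  dir <- withr::local_tempdir()
  sc <- test_scene(speckle_var = 0.1)
  s1 <- simulate_session(session_script(1, 6, 3, scene = sc), sc, seed = 1)
  s2 <- simulate_session(session_script(2, 6, 2, scene = sc,
                                        slot_block = 3, tumor_block = 3),
                         sc, seed = 2)
  man <- write_yolo_dataset(list(s1, s2), dir, patients = c("PA", "PB"))
  expect_equal(nrow(man$index), 12)
  expect_true(all(file.exists(man$index$path)))
  # every frame has a label file, even frames with no visible object
  expect_true(all(file.exists(man$index$label_path)))
  back <- read_yolo_dataset(dir)
  expect_setequal(unique(back$images$patient), c("PA", "PB"))
  joined <- dplyr::inner_join(
    back$truth,
    dplyr::mutate(s1$truth, image = sprintf("s01_f%04d", frame)),
    by = c("image", "class"))
  expect_gt(nrow(joined), 0)
  expect_true(all(abs(joined$x.x - joined$x.y) < 0.5))
  expect_true(all(abs(joined$length.x - joined$length.y) < 0.5))
  # the written label line for a known box matches the normalisation
  b <- boxes(280, 175, 80, 50, "tumor")
  lab <- boxes_to_yolo(b, 640, 640)
  line <- sprintf("%d %.6f %.6f %.6f %.6f", lab$class_id, lab$xc, lab$yc,
                  lab$w, lab$h)
  expect_equal(line, "1 0.500000 0.312500 0.125000 0.078125")
})
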
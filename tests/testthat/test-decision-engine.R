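sb <- function(x, y, L, H) boxes(x, y, L, H, "slot")
tb <- function(x, y, L, H) boxes(x, y, L, H, "tumor")

test_that("size scenario partitions length differences with the boundary in 'similar'", {
  expect_equal(size_scenario(sb(0, 0, 100, 30), tb(0, 0, 60, 40)), "slot_larger")
  expect_equal(size_scenario(sb(0, 0, 60, 30), tb(0, 0, 100, 40)), "tumor_larger")
  expect_equal(size_scenario(sb(0, 0, 100, 30), tb(0, 0, 90, 40)), "similar")
  # boundary |L1 - L2| == 20 belongs to the similar-size fallback
  expect_equal(size_scenario(sb(0, 0, 100, 30), tb(0, 0, 80, 40)), "similar")
  expect_equal(size_scenario(sb(0, 0, 80, 30), tb(0, 0, 100, 40)), "similar")
  expect_error(size_scenario(tb(0, 0, 10, 10), tb(0, 0, 10, 10)), "slot")
})

test_that("slot-larger alignment follows the printed inequalities strictly", {
  expect_true(aligned_slot_larger(sb(200, 150, 100, 30), tb(190, 140, 60, 40)))
  expect_false(aligned_slot_larger(sb(200, 50, 100, 30), tb(190, 140, 60, 40)))
  expect_true(aligned_slot_larger(sb(0, 1e6, 1, 1), tb(1e6, 0, 1, 1)))
  # equality violates the strict inequality: x1 - 0.2 L1 == x2
  # (vertical condition holds here, so the horizontal tie is decisive)
  expect_false(aligned_slot_larger(sb(100, 150, 100, 30), tb(80, 100, 60, 40)))
})

test_that("slot-smaller alignment reverses the horizontal comparison", {
  expect_true(aligned_slot_smaller(sb(300, 120, 40, 20), tb(290, 100, 80, 50)))
  expect_false(aligned_slot_smaller(sb(100, 120, 40, 20), tb(290, 100, 80, 50)))
  expect_true(aligned_slot_smaller(sb(0, 0, 50, 50), tb(0, 0, 50, 50)))
})

test_that("tumor extension scales length only and keeps the input unchanged", {
  t0 <- tb(50, 60, 100, 40)
  t1 <- extend_tumor(t0)
  expect_equal(t1$length, 120)
  expect_equal(t1[c("x", "y", "height")], t0[c("x", "y", "height")])
  expect_equal(t0$length, 100)  # copy semantics
  expect_equal(extend_tumor(t0, decision_config(extension_factor = 1))$length, 100)
  expect_equal(extend_tumor(tb(0, 0, 0.5, 1))$length, 0.6)  # no rounding
})

test_that("activation dispatch agrees with direct inequality evaluation on a large grid", {
  set.seed(42)
  n <- 12000
  x1 <- runif(n, 0, 600); y1 <- runif(n, 0, 600)
  L1 <- runif(n, 1, 250); H1 <- runif(n, 1, 60)
  x2 <- runif(n, 0, 600); y2 <- runif(n, 0, 600)
  # force coverage of all three scenarios, including near-boundary sizes
  L2 <- pmax(0.5, L1 + sample(c(-40, -21, -20, -19, 0, 19, 20, 21, 40), n,
                              replace = TRUE) + runif(n, -5, 5))
  H2 <- runif(n, 1, 90)
  got <- is_activation_position(boxes(x1, y1, L1, H1, "slot"),
                                boxes(x2, y2, L2, H2, "tumor"))
  want <- vapply(seq_len(n), function(i) {
    oracle_activation(x1[i], y1[i], L1[i], H1[i], x2[i], y2[i], L2[i], H2[i])
  }, logical(1))
  expect_identical(got, want)
})

test_that("similar-size dispatch applies the extended-length rules", {
  slot <- sb(300, 120, 100, 30)
  tumor <- tb(290, 100, 95, 50)
  expect_equal(size_scenario(slot, tumor), "similar")
  expect_true(is_activation_position(slot, tumor))
  # vertical failure is decisive in every scenario
  for (L2 in c(60, 95, 160)) {
    expect_false(is_activation_position(sb(300, 10, 100, 30),
                                        tb(290, 300, L2, 50)))
  }
})

test_that("the activation predicate is scale-covariant", {
  set.seed(11)
  for (i in 1:200) {
    p <- random_box_pair()
    base <- is_activation_position(p$slot, p$tumor)
    for (s in c(0.25, 3, 17.5)) {
      scaled <- lapply(p, function(b)
        dplyr::mutate(b, x = x * s, y = y * s,
                      length = length * s, height = height * s))
      cfg <- decision_config(size_margin = 20 * s)
      expect_identical(
        is_activation_position(scaled$slot, scaled$tumor, cfg), base)
    }
  }
})

test_that("size scenario is total over random length pairs", {
  set.seed(5)
  L1 <- runif(500, 0.1, 300); L2 <- runif(500, 0.1, 300)
  scen <- size_scenario(boxes(0, 0, L1, 10, "slot"),
                        boxes(0, 0, L2, 10, "tumor"))
  expect_true(all(scen %in% c("slot_larger", "tumor_larger", "similar")))
  expect_equal(length(scen), 500)
})

test_that("procedure I prompts immediately on the first aligned co-visible frame", {
  aligned <- dplyr::bind_rows(sb(200, 150, 100, 30), tb(190, 140, 60, 40))
  st <- activation_state(1)
  # tumor alone: unchanged, no prompt
  r <- decision_step(st, tb(190, 140, 60, 40), 1)
  expect_null(r$event)
  expect_false(r$state$prompt_emitted)
  # both present and aligned: prompt now
  r <- decision_step(r$state, aligned, 2)
  expect_equal(r$event$frame, 2L)
  expect_equal(r$event$message, "The operation can begin now.")
  # absorbing: no second prompt
  r2 <- decision_step(r$state, aligned, 3)
  expect_null(r2$event)
  expect_true(r2$state$prompt_emitted)
})

test_that("frame indices must strictly increase", {
  st <- activation_state(1)
  r <- decision_step(st, sb(1, 1, 10, 10), 5)
  expect_error(decision_step(r$state, sb(1, 1, 10, 10), 5), "stream-order")
  expect_error(decision_step(r$state, sb(1, 1, 10, 10), 4), "stream-order")
})

test_that("procedure II requires slot confirmation, then counts cumulative overlap", {
  cfg <- decision_config(overlap_frames_required = 10, slot_confirm_frames = 3)
  slot <- sb(200, 150, 100, 30)
  tumor <- tb(190, 140, 60, 40)
  st <- activation_state(2)
  f <- 0L
  # two sightings only: not confirmed, tumor frames do not count
  for (i in 1:2) { r <- decision_step(st, slot, f <- f + 1L, cfg); st <- r$state }
  r <- decision_step(st, tumor, f <- f + 1L, cfg); st <- r$state
  expect_equal(st$overlap_count, 0L)
  expect_null(st$remembered_slot)
  # three consecutive sightings confirm the slot
  for (i in 1:3) { r <- decision_step(st, slot, f <- f + 1L, cfg); st <- r$state }
  expect_false(is.null(st$remembered_slot))
  # overlap frames accumulate across interruptions (cumulative counter)
  for (i in 1:6) { r <- decision_step(st, tumor, f <- f + 1L, cfg); st <- r$state }
  expect_equal(st$overlap_count, 6L)
  for (i in 1:4) {  # tumor absent: counter holds
    r <- decision_step(st, boxes(numeric(), numeric(), numeric(), numeric(),
                                 character()), f <- f + 1L, cfg)
    st <- r$state
  }
  expect_equal(st$overlap_count, 6L)
  ev <- NULL
  for (i in 1:4) {
    r <- decision_step(st, tumor, f <- f + 1L, cfg); st <- r$state
    if (!is.null(r$event)) ev <- r$event
  }
  expect_equal(st$overlap_count, 10L)
  expect_equal(ev$frame, f)
})

test_that("degenerate threshold of one overlap frame prompts immediately", {
  cfg <- decision_config(overlap_frames_required = 1, slot_confirm_frames = 1)
  st <- activation_state(2)
  r <- decision_step(st, sb(200, 150, 100, 30), 1, cfg)
  r <- decision_step(r$state, tb(190, 140, 60, 40), 2, cfg)
  expect_equal(r$event$frame, 2L)
})

test_that("interrupted overlap still prompts at the required cumulative count", {
  # 300 overlap frames, 100 non-overlap frames, 200 overlap frames:
  # prompt fires on the 600th frame overall (the 500th overlap frame)
  cfg <- decision_config(slot_confirm_frames = 1)
  slot <- sb(200, 150, 100, 30)
  aligned <- tb(190, 140, 60, 40)
  misaligned <- tb(190, 400, 60, 40)  # too deep: vertical condition fails
  det <- dplyr::bind_rows(
    dplyr::mutate(slot, frame = 1L),
    purrr::map_dfr(2:301, ~dplyr::mutate(aligned, frame = .x)),
    purrr::map_dfr(302:401, ~dplyr::mutate(misaligned, frame = .x)),
    purrr::map_dfr(402:601, ~dplyr::mutate(aligned, frame = .x))
  )
  log <- run_decision_engine(det, procedure = 2, cfg)
  expect_equal(nrow(log$events), 1L)
  expect_equal(log$events$frame, 601L)  # frame 1 was the slot sighting
  # under the stricter consecutive reading the same stream needs more frames
  log2 <- run_decision_engine(det, procedure = 2,
                              decision_config(slot_confirm_frames = 1,
                                              reset_on_miss = TRUE))
  expect_equal(nrow(log2$events), 0L)
})

test_that("overlap counters are monotone and the prompt flag absorbing", {
  set.seed(9)
  scene <- test_scene()
  script <- session_script(2, n_frames = 120, onset_frame = 40, scene = scene,
                           slot_block = 10, tumor_block = 30)
  stream <- simulate_session(script, scene, seed = 1)
  cfg <- decision_config(overlap_frames_required = 25)
  log <- run_decision_engine(stream$truth, 2, cfg, n_frames = 120)
  oc <- log$trace$overlap_count
  expect_true(all(diff(oc) >= 0))
  pe <- log$trace$prompt_emitted
  expect_true(all(diff(as.integer(pe)) >= 0))
  expect_lte(nrow(log$events), 1L)
})

test_that("replaying a detection stream reproduces identical events", {
  scene <- test_scene()
  script <- session_script(1, n_frames = 60, onset_frame = 30, scene = scene)
  stream <- simulate_session(script, scene, seed = 3)
  l1 <- run_decision_engine(stream$truth, 1, n_frames = 60)
  l2 <- run_decision_engine(stream$truth, 1, n_frames = 60)
  expect_identical(l1$events, l2$events)
  expect_identical(l1$trace, l2$trace)
})

test_that("multiple detections per class reduce to the highest-confidence box", {
  # a low-confidence aligned slot must lose to a high-confidence misaligned one
  good <- dplyr::mutate(sb(200, 150, 100, 30), confidence = 0.4)
  bad <- dplyr::mutate(sb(200, 10, 100, 30), confidence = 0.9)
  tum <- tb(190, 140, 60, 40)
  st <- activation_state(1)
  r <- decision_step(st, dplyr::bind_rows(good, bad, tum), 1)
  expect_null(r$event)
  # with equal confidence the larger box wins deterministically
  tie1 <- dplyr::mutate(sb(200, 150, 100, 30), confidence = 0.8)
  tie2 <- dplyr::mutate(sb(200, 10, 100, 29), confidence = 0.8)
  r2 <- decision_step(activation_state(1), dplyr::bind_rows(tie2, tie1, tum), 1)
  expect_equal(r2$event$frame, 1L)
})
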
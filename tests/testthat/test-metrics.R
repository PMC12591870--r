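one_img <- function(b, image = "img1") dplyr::mutate(b, image = image)

test_that("greedy matching produces the expected confusion counts", {
  gt <- one_img(boxes(10, 10, 50, 40, "tumor"))
  # exact duplicate prediction: a single true positive
  m <- match_detections(one_img(boxes(10, 10, 50, 40, "tumor", 0.9)), gt)
  expect_equal(unlist(m$counts[m$counts$class == "tumor", c("tp", "fp", "fn")]),
               c(tp = 1, fp = 0, fn = 0))
  # disjoint boxes: one FP and one FN
  m <- match_detections(one_img(boxes(300, 300, 50, 40, "tumor", 0.9)), gt)
  expect_equal(unlist(m$counts[m$counts$class == "tumor", c("tp", "fp", "fn")]),
               c(tp = 1 - 1, fp = 1, fn = 1))
  # two predictions over one ground truth: greedy one-to-one keeps one TP
  m <- match_detections(
    one_img(boxes(c(10, 12), c(10, 12), c(50, 50), c(40, 40), "tumor",
                  c(0.9, 0.8))), gt)
  expect_equal(unlist(m$counts[m$counts$class == "tumor", c("tp", "fp", "fn")]),
               c(tp = 1, fp = 1, fn = 0))
  # ground truth is matched at most once and TP+FN equals the truth count
  expect_equal(sum(m$counts$tp + m$counts$fn), nrow(gt))
  expect_error(match_detections(gt, gt, iou_threshold = 1.2), "between 0 and 1")
})

test_that("true negatives follow the image-level absence convention", {
  gt <- dplyr::bind_rows(one_img(boxes(10, 10, 50, 40, "tumor"), "a"))
  pred <- one_img(boxes(10, 10, 50, 40, "tumor", 0.9), "a")
  m <- match_detections(pred, gt, images = c("a", "b", "c"))
  # images b and c contain neither truth nor predictions of either class
  expect_equal(m$counts$tn[m$counts$class == "tumor"], 2)
  expect_equal(m$counts$tn[m$counts$class == "slot"], 3)
})

test_that("average precision matches a hand-enumerated curve", {
  gt <- dplyr::bind_rows(
    one_img(boxes(0, 0, 50, 50, "tumor"), "a"),
    one_img(boxes(200, 200, 50, 50, "tumor"), "b")
  )
  # ranked TP (0.9), FP (0.8), TP (0.7)
  pred <- dplyr::bind_rows(
    one_img(boxes(0, 0, 50, 50, "tumor", 0.9), "a"),
    one_img(boxes(400, 0, 50, 50, "tumor", 0.8), "a"),
    one_img(boxes(200, 200, 50, 50, "tumor", 0.7), "b")
  )
  # hand enumeration: recall steps 0.5 (p=1) and 1.0 (envelope p=2/3)
  expect_equal(average_precision_50(pred, gt, "tumor"),
               0.5 * 1 + 0.5 * (2 / 3))
  # perfect detector and silent detector
  expect_equal(average_precision_50(dplyr::mutate(gt, confidence = 1), gt,
                                    "tumor"), 1)
  expect_equal(average_precision_50(gt[0, ], gt, "tumor"), 0)
  expect_error(average_precision_50(pred, gt, "slot"), "undefined metric")
})

test_that("average precision agrees with brute-force enumeration on small fixtures", {
  set.seed(31)
  for (rep in 1:25) {
    n_gt <- sample(1:3, 1)
    gt <- dplyr::bind_rows(lapply(seq_len(n_gt), function(i) {
      one_img(boxes(runif(1, 0, 400), runif(1, 0, 400), 50, 50, "tumor"),
              sample(c("a", "b"), 1))
    }))
    n_p <- sample(1:5, 1)
    pred <- dplyr::bind_rows(lapply(seq_len(n_p), function(i) {
      src <- gt[sample(n_gt, 1), ]
      jit <- runif(1, 0, 60)
      one_img(boxes(src$x + jit, src$y, 50, 50, "tumor", runif(1, 0.1, 1)),
              src$image)
    }))
    got <- average_precision_50(pred, gt, "tumor")
    m <- match_detections(pred, gt)
    ranked <- dplyr::arrange(m$predictions, dplyr::desc(confidence))
    expect_equal(got, oracle_ap(ranked$matched, n_gt))
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("removing a false positive never decreases average precision", {
  set.seed(13)
  gt <- dplyr::bind_rows(
    one_img(boxes(0, 0, 50, 50, "tumor"), "a"),
    one_img(boxes(200, 200, 50, 50, "tumor"), "b"))
  pred <- dplyr::bind_rows(
    one_img(boxes(2, 2, 50, 50, "tumor", 0.8), "a"),
    one_img(boxes(400, 400, 40, 40, "tumor", 0.95), "a"),  # a false positive
    one_img(boxes(201, 199, 50, 50, "tumor", 0.6), "b"))
  with_fp <- average_precision_50(pred, gt, "tumor")
  without_fp <- average_precision_50(pred[-2, ], gt, "tumor")
  expect_gte(without_fp, with_fp)
})

test_that("confusion metrics implement the tabulated formulas", {
  cm <- confusion_metrics(tibble::tibble(class = "tumor", tp = 3, fp = 1,
                                         fn = 1, tn = 5))
  row <- cm[cm$class == "tumor", ]
  expect_equal(row$precision, 0.75)
  expect_equal(row$recall, 0.75)
  expect_equal(row$specificity, 5 / 6)
  expect_equal(row$err, 0.2)
  expect_equal(row$mcc, (3 * 5 - 1 * 1) / sqrt(4 * 4 * 6 * 6))
  # perfect classification
  perfect <- confusion_metrics(tibble::tibble(class = "slot", tp = 7, fp = 0,
                                              fn = 0, tn = 7))
  expect_equal(perfect$mcc[1], 1)
  # fully degenerate counts: MCC 0, ratio metrics undefined (NA), not 0
  degen <- confusion_metrics(tibble::tibble(class = "slot", tp = 0, fp = 0,
                                            fn = 0, tn = 0))
  expect_equal(degen$mcc[1], 0)
  expect_true(is.na(degen$precision[1]))
  expect_true(is.na(degen$recall[1]))
  expect_error(confusion_metrics(tibble::tibble(class = "slot", tp = -1,
                                                fp = 0, fn = 0, tn = 0)),
               "non-negative")
})

test_that("MCC is invariant under swapping positives with negatives", {
  set.seed(77)
  for (i in 1:50) {
    cts <- as.list(sample(0:30, 4, replace = TRUE))
    names(cts) <- c("tp", "fp", "fn", "tn")
    a <- confusion_metrics(tibble::tibble(class = "slot", !!!cts))$mcc[1]
    b <- confusion_metrics(tibble::tibble(class = "slot", tp = cts$tn,
                                          fp = cts$fn, fn = cts$fp,
                                          tn = cts$tp))$mcc[1]
    expect_equal(a, b)
  }
})

test_that("patient folds never split a patient and balance within one", {
  imgs <- tibble::tibble(
    image = sprintf("im%03d", 1:60),
    patient = rep(sprintf("P%02d", 1:12), each = 5)
  )
  f <- patient_fold_split(imgs, k = 3, seed = 4)
  per_patient <- dplyr::summarise(dplyr::group_by(f, patient),
                                  nf = dplyr::n_distinct(fold))
  expect_true(all(per_patient$nf == 1))
  by_fold <- dplyr::summarise(dplyr::group_by(f, fold),
                              np = dplyr::n_distinct(patient))
  expect_lte(diff(range(by_fold$np)), 1)
  # deterministic under the seed, different under another
  expect_identical(f, patient_fold_split(imgs, k = 3, seed = 4))
  expect_error(patient_fold_split(imgs, k = 13), "exceeds")
  # uneven patient counts still balance within one
  imgs2 <- tibble::tibble(image = sprintf("j%02d", 1:14),
                          patient = rep(sprintf("Q%d", 1:7), each = 2))
  f2 <- patient_fold_split(imgs2, k = 3, seed = 9)
  by_fold2 <- dplyr::summarise(dplyr::group_by(f2, fold),
                               np = dplyr::n_distinct(patient))
  expect_lte(diff(range(by_fold2$np)), 1)
})
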
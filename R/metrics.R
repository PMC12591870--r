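#' Match predicted boxes against ground truth
#'
#' Standard greedy one-to-one matching per image and class: predictions are
#' visited in decreasing confidence order and matched to the still-unmatched
#' ground-truth box of the same class with the highest IoU at or above the
#' threshold. Unmatched predictions are false positives; unmatched ground
#' truths are false negatives.
#'
#' True negatives have no natural definition for box detection. To support
#' specificity, Matthews correlation and error rate, this package adopts an
#' image-level convention: per class, an image contributes `TN = 1` when it
#' contains neither a ground-truth box nor a prediction of that class, and 0
#' otherwise. This is a documented stand-in, not a community standard;
#' compare such metrics only across results computed with the same
#' convention.
#'
#' @param pred Tibble of predictions: `image`, `class`, `x`, `y`, `length`,
#'   `height`, `confidence`.
#' @param truth Tibble of ground truth: `image`, `class`, `x`, `y`, `length`,
#'   `height`.
#' @param iou_threshold IoU threshold in (0, 1), default 0.5.
#' @param images Optional character vector of all image ids in the evaluated
#'   set (needed so images empty in both `pred` and `truth` count towards
#'   true negatives); defaults to ids present in either table.
#' @return A `match_result`: list with `counts` (per class: `tp`, `fp`, `fn`,
#'   `tn`), `matches` (per matched pair: `image`, `class`, `confidence`,
#'   `iou`) and `predictions` (each prediction flagged as matched or not).
#' @export
match_detections <- function(pred, truth, iou_threshold = 0.5, images = NULL) {
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop("iou_threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  images <- images %||% union(unique(pred$image), unique(truth$image))
  pred <- dplyr::arrange(pred, dplyr::desc(.data$confidence))
  matches <- list()
  matched_pred <- logical(nrow(pred))
  truth$.matched <- FALSE
  for (i in seq_len(nrow(pred))) {
    p <- pred[i, ]
    cand <- which(truth$image == p$image & truth$class == p$class &
                    !truth$.matched)
    if (!length(cand)) next
    ious <- box_iou(p[rep(1, length(cand)), ], truth[cand, ])
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      gi <- cand[best]
      truth$.matched[gi] <- TRUE
      matched_pred[i] <- TRUE
      matches[[length(matches) + 1]] <- tibble::tibble(
        image = p$image, class = p$class,
        confidence = p$confidence, iou = ious[best], truth_row = gi
      )
    }
  }
  matches <- if (length(matches)) dplyr::bind_rows(matches) else
    tibble::tibble(image = character(), class = character(),
                   confidence = numeric(), iou = numeric(),
                   truth_row = integer())
  counts <- lapply(box_classes, function(cl) {
    tp <- sum(matches$class == cl)
    fp <- sum(pred$class == cl) - tp
    fn <- sum(truth$class == cl) - tp
    tn <- sum(vapply(images, function(im) {
      !any(truth$image == im & truth$class == cl) &&
        !any(pred$image == im & pred$class == cl)
    }, logical(1)))
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = tn)
  })
  structure(
    list(
      counts = dplyr::bind_rows(counts),
      matches = matches,
      predictions = dplyr::mutate(pred, matched = matched_pred),
      truth_n = table(factor(truth$class, levels = box_classes)),
      iou_threshold = iou_threshold
    ),
    class = "match_result"
  )
}

#' Average precision at IoU 0.5 for one class
#'
#' Area under the precision-recall curve using all-points (continuous)
#' interpolation: precision is replaced by its running maximum from the
#' right (the precision envelope) and integrated over recall.
#'
#' @inheritParams match_detections
#' @param class `"slot"` or `"tumor"`.
#' @return AP in `[0, 1]`.
#' @export
average_precision_50 <- function(pred, truth, class,
                                 iou_threshold = 0.5) {
  n_gt <- sum(truth$class == class)
  if (n_gt == 0) {
    stop(sprintf("undefined metric: no ground-truth boxes of class '%s'", class),
         call. = FALSE)
  }
  m <- match_detections(pred, truth, iou_threshold)
  p <- m$predictions[m$predictions$class == class, , drop = FALSE]
  if (nrow(p) == 0) return(0)
  p <- dplyr::arrange(p, dplyr::desc(.data$confidence))
  tp <- cumsum(p$matched)
  fp <- cumsum(!p$matched)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # precision envelope, integrated over recall
  penv <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * penv)
}

#' Confusion-count metrics for detection results
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, error rate `(FP+FN)/(TP+TN+FP+FN)` and the Matthews
#' correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` per class and
#' pooled over classes. MCC is 0 whenever any marginal factor is zero;
#' ratio metrics with a zero denominator are reported as `NA` (undefined),
#' never silently as 0.
#'
#' @param m A [match_detections()] result, or a tibble with columns `class`,
#'   `tp`, `fp`, `fn`, `tn`.
#' @return Tibble with one row per class plus a pooled `"all"` row.
#' @export
confusion_metrics <- function(m) {
  counts <- if (inherits(m, "match_result")) m$counts else tibble::as_tibble(m)
  stopifnot(all(c("class", "tp", "fp", "fn", "tn") %in% names(counts)))
  if (any(counts$tp < 0 | counts$fp < 0 | counts$fn < 0 | counts$tn < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  pooled <- dplyr::summarise(counts, class = "all",
                             tp = sum(.data$tp), fp = sum(.data$fp),
                             fn = sum(.data$fn), tn = sum(.data$tn))
  dplyr::bind_rows(counts, pooled) |>
    dplyr::mutate(
      precision = ratio_or_na(.data$tp, .data$tp + .data$fp),
      recall = ratio_or_na(.data$tp, .data$tp + .data$fn),
      specificity = ratio_or_na(.data$tn, .data$tn + .data$fp),
      err = ratio_or_na(.data$fp + .data$fn,
                        .data$tp + .data$tn + .data$fp + .data$fn),
      mcc = mcc_safe(.data$tp, .data$fp, .data$fn, .data$tn)
    )
}

ratio_or_na <- function(num, den) ifelse(den > 0, num / den, NA_real_)

mcc_safe <- function(tp, fp, fn, tn) {
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  ifelse(denom2 > 0, (tp * tn - fp * fn) / sqrt(denom2), 0)
}

#' Full detection evaluation report
#'
#' Per-class and pooled precision, recall, specificity, error rate, Matthews
#' correlation (from the confusion counts at the IoU threshold) and mAP50
#' (per class AP; pooled value is the unweighted class mean).
#'
#' @inheritParams match_detections
#' @return A `metrics_report` tibble (rows: slot, tumor, all).
#' @export
detection_report <- function(pred, truth, iou_threshold = 0.5, images = NULL) {
  m <- match_detections(pred, truth, iou_threshold, images)
  cm <- confusion_metrics(m)
  ap <- vapply(box_classes, function(cl) {
    if (sum(truth$class == cl) == 0) NA_real_ else
      average_precision_50(pred, truth, cl, iou_threshold)
  }, 0)
  cm$map50 <- c(ap, mean(ap, na.rm = TRUE))
  structure(cm, class = c("metrics_report", class(cm)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.match_result <- function(object, ...) {
  p <- object$predictions |>
    dplyr::group_by(.data$class) |>
    dplyr::arrange(dplyr::desc(.data$confidence), .by_group = TRUE) |>
    dplyr::mutate(
      recall = cumsum(.data$matched) / as.numeric(object$truth_n[.data$class[1]]),
      precision = cumsum(.data$matched) / dplyr::row_number()
    )
  ggplot2::ggplot(p, ggplot2::aes(x = .data$recall, y = .data$precision,
                                  colour = .data$class)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = "Precision-recall", x = "recall", y = "precision")
}

#' Patient-level cross-validation folds
#'
#' Assigns whole patients to folds so that no patient's images are split
#' across folds (preventing patient-level leakage), with fold sizes balanced
#' by patient count to within one. Deterministic given `seed`.
#'
#' @param images Tibble with columns `image` (unique ids) and `patient`.
#' @param k Number of folds (default 3); must not exceed the number of
#'   distinct patients.
#' @param seed Integer seed controlling the patient shuffle.
#' @return The input tibble with an integer `fold` column added.
#' @export
patient_fold_split <- function(images, k = 3, seed = 1L) {
  stopifnot(all(c("image", "patient") %in% names(images)))
  if (anyDuplicated(images$image)) {
    stop("image ids must be unique", call. = FALSE)
  }
  patients <- sort(unique(as.character(images$patient)))
  if (k > length(patients)) {
    stop(sprintf("k = %d exceeds the number of distinct patients (%d)",
                 k, length(patients)), call. = FALSE)
  }
  shuffled <- withr_seed(seed, sample(patients))
  fold_of <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  dplyr::mutate(images, fold = unname(fold_of[as.character(.data$patient)]))
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}
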
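#' Build a tibble of detection boxes
#'
#' Boxes use image pixel coordinates with the origin at the top-left corner
#' and y increasing downwards. A box is stored as its left edge `x`, top edge
#' `y`, horizontal extent `length` and vertical extent `height`, together with
#' the object class (`"slot"` for the cutter slot, `"tumor"` for the lesion)
#' and a detection confidence in `[0, 1]`. Coordinates are real-valued:
#' detector output is sub-pixel and no rounding happens inside any predicate.
#'
#' @param x,y Left and top edge, pixels (non-negative).
#' @param length,height Horizontal and vertical extent, pixels (positive).
#' @param class Character, `"slot"` or `"tumor"` (recycled).
#' @param confidence Detection confidence in `[0, 1]` (recycled, default 1).
#' @return A tibble with columns `class`, `x`, `y`, `length`, `height`,
#'   `confidence`.
#' @examples
#' boxes(x = 200, y = 150, length = 100, height = 30, class = "slot")
#' @export
boxes <- function(x, y, length, height, class, confidence = 1) {
  out <- tibble::tibble(
    class = as.character(class),
    x = as.numeric(x), y = as.numeric(y),
    length = as.numeric(length), height = as.numeric(height),
    confidence = as.numeric(confidence)
  )
  validate_boxes(out)
  out
}

box_classes <- c("slot", "tumor")

validate_boxes <- function(b, arg = "boxes") {
  needed <- c("class", "x", "y", "length", "height")
  missing <- setdiff(needed, names(b))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", arg,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(b) == 0) return(invisible(b))
  if (any(!b$class %in% box_classes)) {
    stop(sprintf("%s$class must be one of %s", arg,
                 paste(box_classes, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(b$x)) || any(!is.finite(b$y)) ||
      any(!is.finite(b$length)) || any(!is.finite(b$height))) {
    stop(sprintf("%s has non-finite geometry", arg), call. = FALSE)
  }
  if (any(b$length <= 0) || any(b$height <= 0)) {
    stop(sprintf("invalid geometry in %s: length and height must be positive", arg),
         call. = FALSE)
  }
  if (any(b$x < 0) || any(b$y < 0)) {
    stop(sprintf("invalid geometry in %s: x and y must be non-negative", arg),
         call. = FALSE)
  }
  if ("confidence" %in% names(b) &&
      (any(b$confidence < 0) || any(b$confidence > 1))) {
    stop(sprintf("%s$confidence must lie in [0, 1]", arg), call. = FALSE)
  }
  invisible(b)
}

#' Intersection-over-union of paired boxes
#'
#' Vectorised over rows: row i of `a` is compared with row i of `b`.
#'
#' @param a,b Box tibbles (see [boxes()]) with the same number of rows.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x + a$length, b$x + b$length) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$height, b$y + b$height) - pmax(a$y, b$y))
  inter <- ix * iy
  union <- a$length * a$height + b$length * b$height - inter
  ifelse(union > 0, inter / union, 0)
}

# class ids used in YOLO label files: 0 = cutter slot, 1 = tumor
class_to_id <- function(class) match(class, box_classes) - 1L
id_to_class <- function(id) box_classes[id + 1L]

#' Convert pixel boxes to normalised YOLO label rows
#'
#' YOLO text labels store `class x_center y_center width height` with all
#' geometry normalised by the image size. Class id 0 is the cutter slot,
#' class id 1 the tumor.
#'
#' @param b Box tibble.
#' @param width,height Image size in pixels.
#' @return Tibble with columns `class_id`, `xc`, `yc`, `w`, `h` (normalised).
#' @export
boxes_to_yolo <- function(b, width, height) {
  validate_boxes(b)
  tibble::tibble(
    class_id = class_to_id(b$class),
    xc = (b$x + b$length / 2) / width,
    yc = (b$y + b$height / 2) / height,
    w = b$length / width,
    h = b$height / height
  )
}

#' Convert normalised YOLO label rows back to pixel boxes
#'
#' @param labels Tibble as produced by [boxes_to_yolo()].
#' @param width,height Image size in pixels.
#' @param confidence Confidence to attach (default 1).
#' @return Box tibble.
#' @export
yolo_to_boxes <- function(labels, width, height, confidence = 1) {
  if (nrow(labels) == 0) {
    return(boxes(numeric(), numeric(), numeric(), numeric(), character()))
  }
  boxes(
    x = labels$xc * width - labels$w * width / 2,
    y = labels$yc * height - labels$h * height / 2,
    length = labels$w * width,
    height = labels$h * height,
    class = id_to_class(labels$class_id),
    confidence = confidence
  )
}

# Highest-confidence box per class; ties broken by larger area, then lower x.
# Standard detector post-processing used before the decision rules.
select_best_per_class <- function(b) {
  if (nrow(b) == 0) return(b)
  b |>
    dplyr::mutate(.area = .data$length * .data$height) |>
    dplyr::arrange(.data$class, dplyr::desc(.data$confidence),
                   dplyr::desc(.data$.area), .data$x) |>
    dplyr::distinct(.data$class, .keep_all = TRUE) |>
    dplyr::select(-".area")
}
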
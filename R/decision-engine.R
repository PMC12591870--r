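#' Thresholds for the cutter-slot activation decision
#'
#' The activation decision compares the cutter-slot box (left edge `x1`, top
#' edge `y1`, length `L1`, height `H1`) with the tumor box (`x2`, `y2`, `L2`,
#' `H2`). Its thresholds are:
#'
#' * `size_margin` (pixels): the two objects count as similar-sized when
#'   `|L1 - L2|` does not exceed this margin (default 20 px).
#' * `horizontal_factor`: fraction of the reference length used as horizontal
#'   slack, `x1 - L1 * 0.2 < x2` (slot-larger) or `x2 - L2 * 0.2 < x1`
#'   (slot-smaller).
#' * `vertical_factor`: vertical overlap condition `y2 - H2 * 1.1 < y1`.
#' * `extension_factor`: in the similar-size case the tumor length is
#'   temporarily extended, `L2' = L2 * 1.2`, before applying the slot-smaller
#'   rules.
#' * `overlap_frames_required`: in the alternating-view workflow
#'   (procedure II) the prompt fires when the cumulative count of overlap
#'   frames reaches this value (default 500).
#' * `slot_confirm_frames`: consecutive slot sightings required before the
#'   slot position is recorded in procedure II (default 5).
#' * `reset_on_miss`: if `TRUE`, a frame in which the tumor is visible but
#'   not aligned resets the overlap counter (stricter, consecutive reading);
#'   default `FALSE`, i.e. the counter is cumulative.
#' * `confidence_threshold`: detections below this confidence are discarded
#'   before the decision rules (default 0.25).
#'
#' @param size_margin Pixels, non-negative.
#' @param horizontal_factor,vertical_factor,extension_factor Positive factors.
#' @param overlap_frames_required Frames, at least 1.
#' @param slot_confirm_frames Frames, at least 1.
#' @param reset_on_miss Logical.
#' @param confidence_threshold Confidence cut in `[0, 1]`.
#' @param prompt_message Text of the emitted prompt.
#' @return A list with class `"decision_config"`.
#' @examples
#' cfg <- decision_config()
#' cfg$size_margin
#' @export
decision_config <- function(size_margin = 20,
                            horizontal_factor = 0.2,
                            vertical_factor = 1.1,
                            extension_factor = 1.2,
                            overlap_frames_required = 500,
                            slot_confirm_frames = 5,
                            reset_on_miss = FALSE,
                            confidence_threshold = 0.25,
                            prompt_message = "The operation can begin now.") {
  stopifnot(
    size_margin >= 0,
    horizontal_factor > 0, vertical_factor > 0, extension_factor > 0,
    overlap_frames_required >= 1, slot_confirm_frames >= 1,
    confidence_threshold >= 0, confidence_threshold <= 1
  )
  structure(
    list(
      size_margin = size_margin,
      horizontal_factor = horizontal_factor,
      vertical_factor = vertical_factor,
      extension_factor = extension_factor,
      overlap_frames_required = as.integer(overlap_frames_required),
      slot_confirm_frames = as.integer(slot_confirm_frames),
      reset_on_miss = isTRUE(reset_on_miss),
      confidence_threshold = confidence_threshold,
      prompt_message = prompt_message
    ),
    class = "decision_config"
  )
}

check_roles <- function(slot, tumor) {
  if (nrow(slot) && any(slot$class != "slot")) {
    stop("`slot` must contain cutter-slot boxes (class \"slot\")", call. = FALSE)
  }
  if (nrow(tumor) && any(tumor$class != "tumor")) {
    stop("`tumor` must contain tumor boxes (class \"tumor\")", call. = FALSE)
  }
}

#' Classify the relative size of cutter slot and tumor
#'
#' Partitions every pair of lengths into one of three scenarios:
#' `"slot_larger"` when `L1 - L2 > size_margin`, `"tumor_larger"` when
#' `L2 - L1 > size_margin`, and `"similar"` otherwise. The boundary
#' `|L1 - L2| == size_margin` falls into `"similar"`, whose
#' length-extension rule is the procedure's own fallback for ambiguous
#' sizes, so the partition is total.
#'
#' @param slot,tumor Box tibbles with equal row counts (vectorised row-wise).
#' @param cfg A [decision_config()].
#' @return Character vector: `"slot_larger"`, `"tumor_larger"` or `"similar"`.
#' @examples
#' size_scenario(boxes(0, 0, 100, 30, "slot"), boxes(0, 0, 60, 40, "tumor"))
#' @export
size_scenario <- function(slot, tumor, cfg = decision_config()) {
  validate_boxes(slot, "slot"); validate_boxes(tumor, "tumor")
  check_roles(slot, tumor)
  d <- slot$length - tumor$length
  dplyr::case_when(
    d > cfg$size_margin ~ "slot_larger",
    -d > cfg$size_margin ~ "tumor_larger",
    .default = "similar"
  )
}

#' Alignment test when the cutter slot is larger than the tumor
#'
#' Scenario (a): horizontal condition `x1 - L1 * horizontal_factor < x2` and
#' vertical condition `y2 - H2 * vertical_factor < y1`, both strict. The
#' slot then horizontally covers the tumor's left side and vertically
#' overlaps it.
#'
#' @inheritParams size_scenario
#' @return Logical vector.
#' @export
aligned_slot_larger <- function(slot, tumor, cfg = decision_config()) {
  validate_boxes(slot, "slot"); validate_boxes(tumor, "tumor")
  (slot$x - slot$length * cfg$horizontal_factor < tumor$x) &
    (tumor$y - tumor$height * cfg$vertical_factor < slot$y)
}

#' Alignment test when the cutter slot is smaller than the tumor
#'
#' Scenario (b): the horizontal comparison is reversed,
#' `x2 - L2 * horizontal_factor < x1`, so the tumor falls within the
#' cutter's horizontal range; the vertical condition is unchanged.
#'
#' @inheritParams size_scenario
#' @return Logical vector.
#' @export
aligned_slot_smaller <- function(slot, tumor, cfg = decision_config()) {
  validate_boxes(slot, "slot"); validate_boxes(tumor, "tumor")
  (tumor$x - tumor$length * cfg$horizontal_factor < slot$x) &
    (tumor$y - tumor$height * cfg$vertical_factor < slot$y)
}

#' Temporarily extend the tumor length for the similar-size scenario
#'
#' Returns a copy of the tumor boxes with `length` multiplied by
#' `cfg$extension_factor` (default 1.2), keeping the top-left corner and all
#' other fields unchanged. Lengths are real-valued; no rounding is applied.
#'
#' @param tumor Box tibble.
#' @param cfg A [decision_config()].
#' @return Box tibble with extended lengths.
#' @examples
#' extend_tumor(boxes(50, 60, 100, 40, "tumor"))$length  # 120
#' @export
extend_tumor <- function(tumor, cfg = decision_config()) {
  validate_boxes(tumor, "tumor")
  dplyr::mutate(tumor, length = .data$length * cfg$extension_factor)
}

#' Is the cutter slot correctly positioned for activation?
#'
#' Dispatches on [size_scenario()]: scenario (a) applies
#' [aligned_slot_larger()], scenario (b) applies [aligned_slot_smaller()],
#' and the similar-size scenario applies the scenario (b) rules after
#' [extend_tumor()].
#'
#' @param slot,tumor Box tibbles with equal row counts (vectorised row-wise);
#'   `slot` rows must have class `"slot"` and `tumor` rows class `"tumor"`.
#' @param cfg A [decision_config()].
#' @return Logical vector.
#' @examples
#' slot <- boxes(200, 150, 100, 30, "slot")
#' tumor <- boxes(190, 140, 60, 40, "tumor")
#' is_activation_position(slot, tumor)
#' @export
is_activation_position <- function(slot, tumor, cfg = decision_config()) {
  validate_boxes(slot, "slot"); validate_boxes(tumor, "tumor")
  check_roles(slot, tumor)
  scen <- size_scenario(slot, tumor, cfg)
  ext <- extend_tumor(tumor, cfg)
  dplyr::case_when(
    scen == "slot_larger" ~ aligned_slot_larger(slot, tumor, cfg),
    scen == "tumor_larger" ~ aligned_slot_smaller(slot, tumor, cfg),
    .default = aligned_slot_smaller(slot, ext, cfg)
  )
}

#' Fresh activation-decision state
#'
#' @param procedure 1 (co-visible workflow) or 2 (alternating-view workflow).
#' @return A list with class `"activation_state"`: cumulative `overlap_count`,
#'   the `remembered_slot` box (procedure II), the current
#'   `slot_sighting_streak`, the absorbing `prompt_emitted` flag and
#'   `last_frame_index`.
#' @export
activation_state <- function(procedure = 1) {
  procedure <- as.integer(procedure)
  stopifnot(procedure %in% c(1L, 2L))
  structure(
    list(
      procedure = procedure,
      overlap_count = 0L,
      remembered_slot = NULL,
      slot_sighting_streak = 0L,
      prompt_emitted = FALSE,
      last_frame_index = -Inf
    ),
    class = "activation_state"
  )
}

new_prompt <- function(frame_index, cfg) {
  tibble::tibble(frame = as.integer(frame_index), message = cfg$prompt_message)
}

#' Advance the activation decision by one frame
#'
#' Pure function: returns a new state plus at most one prompt event; the
#' input state is not modified. Detections are filtered by
#' `cfg$confidence_threshold` and reduced to the highest-confidence box per
#' class (ties: larger area, then lower x) before the geometric rules run.
#'
#' In procedure I the prompt fires on the first frame in which both objects
#' are visible and [is_activation_position()] holds. In procedure II a slot
#' position is first confirmed over `cfg$slot_confirm_frames` consecutive
#' slot sightings; afterwards every tumor-visible frame is tested against the
#' remembered slot and the prompt fires when the cumulative overlap count
#' reaches `cfg$overlap_frames_required`. The prompt is emitted once per
#' session; the flag never reverts.
#'
#' @param state An [activation_state()].
#' @param detections Box tibble for this frame (possibly empty).
#' @param frame_index Integer, strictly increasing across calls.
#' @param cfg A [decision_config()].
#' @return List with elements `state` (updated) and `event` (one-row prompt
#'   tibble, or `NULL`).
#' @export
decision_step <- function(state, detections, frame_index,
                          cfg = decision_config()) {
  stopifnot(inherits(state, "activation_state"))
  if (frame_index <= state$last_frame_index) {
    stop(sprintf(
      "stream-order error: frame index %s does not increase (last was %s)",
      frame_index, state$last_frame_index), call. = FALSE)
  }
  validate_boxes(detections, "detections")
  state$last_frame_index <- frame_index
  det <- detections[detections$confidence >= cfg$confidence_threshold, ,
                    drop = FALSE]
  det <- select_best_per_class(det)
  slot <- det[det$class == "slot", , drop = FALSE]
  tumor <- det[det$class == "tumor", , drop = FALSE]

  event <- NULL
  if (state$procedure == 1L) {
    if (nrow(slot) == 1 && nrow(tumor) == 1 &&
        is_activation_position(slot, tumor, cfg) && !state$prompt_emitted) {
      state$prompt_emitted <- TRUE
      event <- new_prompt(frame_index, cfg)
    }
  } else {
    # track the slot: require consecutive sightings before trusting it
    if (nrow(slot) == 1) {
      state$slot_sighting_streak <- state$slot_sighting_streak + 1L
      if (state$slot_sighting_streak >= cfg$slot_confirm_frames) {
        state$remembered_slot <- slot
      }
    } else {
      state$slot_sighting_streak <- 0L
    }
    if (nrow(tumor) == 1 && !is.null(state$remembered_slot)) {
      if (is_activation_position(state$remembered_slot, tumor, cfg)) {
        state$overlap_count <- state$overlap_count + 1L
      } else if (cfg$reset_on_miss) {
        state$overlap_count <- 0L
      }
      if (state$overlap_count >= cfg$overlap_frames_required &&
          !state$prompt_emitted) {
        state$prompt_emitted <- TRUE
        event <- new_prompt(frame_index, cfg)
      }
    }
  }
  list(state = state, event = event)
}

#' Run the activation decision over a detection stream
#'
#' @param detections Tibble with one row per detection: columns `frame`,
#'   `class`, `x`, `y`, `length`, `height`, `confidence`. Frames absent from
#'   the table are treated as empty; supply `n_frames` to extend the stream
#'   past the last detection.
#' @param procedure 1 or 2.
#' @param cfg A [decision_config()].
#' @param n_frames Total number of frames (default: max frame index present).
#' @return A list with class `"decision_log"`: `events` (prompt tibble),
#'   `trace` (per-frame `frame`, `overlap_count`, `prompt_emitted`),
#'   `state` (final), `procedure`, `config`.
#' @examples
#' det <- dplyr::bind_rows(
#'   boxes(200, 150, 100, 30, "slot"),
#'   boxes(190, 140, 60, 40, "tumor")
#' )
#' det$frame <- 1L
#' run_decision_engine(det, procedure = 1)$events
#' @export
run_decision_engine <- function(detections, procedure = 1,
                                cfg = decision_config(), n_frames = NULL) {
  if (!"frame" %in% names(detections)) {
    stop("`detections` needs a `frame` column", call. = FALSE)
  }
  frames <- if (is.null(n_frames)) {
    if (nrow(detections)) max(detections$frame) else 0L
  } else n_frames
  state <- activation_state(procedure)
  events <- list()
  trace <- vector("list", frames)
  by_frame <- split(detections, factor(detections$frame, levels = seq_len(frames)))
  for (i in seq_len(frames)) {
    det <- by_frame[[i]]
    res <- decision_step(state, det, i, cfg)
    state <- res$state
    if (!is.null(res$event)) events[[length(events) + 1]] <- res$event
    trace[[i]] <- tibble::tibble(
      frame = i,
      overlap_count = state$overlap_count,
      prompt_emitted = state$prompt_emitted
    )
  }
  structure(
    list(
      events = if (length(events)) dplyr::bind_rows(events) else
        tibble::tibble(frame = integer(), message = character()),
      trace = dplyr::bind_rows(trace),
      state = state,
      procedure = as.integer(procedure),
      config = cfg
    ),
    class = "decision_log"
  )
}

#' @export
print.decision_log <- function(x, ...) {
  cat(sprintf("<decision_log> procedure %s, %d frames, %d prompt event(s)\n",
              c("I", "II")[x$procedure], nrow(x$trace), nrow(x$events)))
  if (nrow(x$events)) {
    cat(sprintf("  prompt at frame %d: \"%s\"\n",
                x$events$frame[1], x$events$message[1]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.decision_log <- function(x, ...) x$trace

#' @exportS3Method generics::glance
glance.decision_log <- function(x, ...) {
  tibble::tibble(
    procedure = x$procedure,
    frames = nrow(x$trace),
    overlap_count = x$state$overlap_count,
    prompt_emitted = x$state$prompt_emitted,
    prompt_frame = if (nrow(x$events)) x$events$frame[1] else NA_integer_
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.decision_log <- function(object, ...) {
  p <- ggplot2::ggplot(object$trace,
                       ggplot2::aes(x = .data$frame, y = .data$overlap_count)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "frame", y = "cumulative overlap frames",
                  title = sprintf("Activation decision, procedure %s",
                                  c("I", "II")[object$procedure]))
  if (nrow(object$events)) {
    p <- p + ggplot2::geom_vline(xintercept = object$events$frame,
                                 linetype = "dashed", colour = "red")
  }
  p
}
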
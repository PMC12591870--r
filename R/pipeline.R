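#' Extract keyframes by uniform temporal sampling
#'
#' Samples one frame every `interval` seconds starting at t = 0 (so a 95 s
#' stream at a 10 s interval yields the 10 frames at t = 0, 10, ..., 90).
#' Used to thin surgical recordings into a manageable annotation set.
#'
#' @param source A `rotoloc_stream`, or a directory of numbered image frames
#'   (PNG), or a numeric vector of frame timestamps in seconds.
#' @param interval Sampling interval in seconds (> 0), default 10.
#' @param fps Frame rate used to assign timestamps when the source does not
#'   carry any (default 25).
#' @param out_dir Optional directory; selected frames are written there as
#'   PNG files named by their timestamp.
#' @return Tibble with columns `frame` (1-based index), `time` (seconds) and,
#'   when frames were written, `path`.
#' @export
extract_keyframes <- function(source, interval = 10, fps = 25, out_dir = NULL) {
  if (interval <= 0) stop("interval must be > 0", call. = FALSE)
  if (inherits(source, "rotoloc_stream")) {
    times <- (seq_len(source$n_frames) - 1) / fps
    get_image <- function(i) stream_frame(source, i)$image
  } else if (is.character(source) && length(source) == 1 && dir.exists(source)) {
    files <- sort(dir(source, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("I/O error: no frames found in ", source,
                             call. = FALSE)
    times <- (seq_along(files) - 1) / fps
    get_image <- function(i) png::readPNG(files[i])
  } else if (is.numeric(source)) {
    times <- source
    get_image <- NULL
  } else {
    stop("I/O error: unreadable stream source", call. = FALSE)
  }
  if (!length(times)) {
    return(tibble::tibble(frame = integer(), time = numeric()))
  }
  # first frame at or after each multiple of the interval
  marks <- seq(0, max(times), by = interval)
  idx <- vapply(marks, function(m) which(times >= m)[1], 0L)
  idx <- unique(idx[!is.na(idx)])
  out <- tibble::tibble(frame = idx, time = times[idx])
  if (!is.null(out_dir) && !is.null(get_image)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$path <- vapply(seq_len(nrow(out)), function(r) {
      p <- file.path(out_dir, sprintf("t%07.2fs.png", out$time[r]))
      png::writePNG(get_image(out$frame[r]), p)
      p
    }, "")
  }
  out
}

#' Run the real-time guidance loop over a frame stream
#'
#' For each frame: obtain detections from the detector, filter by the
#' confidence threshold, reduce to the best box per class, advance the
#' activation decision, and record the outcome. The loop is single-threaded
#' and frame-ordered; the resulting log replays deterministically.
#'
#' @param stream A [simulate_session()] stream.
#' @param detector Either a [detector_stub()] (run against the stream's
#'   ground truth) or a function `function(image, frame_index)` returning a
#'   box tibble (run against rendered pixels).
#' @param procedure 1 or 2 (default: the stream script's procedure).
#' @param cfg A [decision_config()].
#' @return A `session_log`: list with `frames` (per-frame summary),
#'   `events` (prompt events with frame and message), `detections` (all
#'   retained detections, replayable through [run_decision_engine()]),
#'   `procedure`, `config` and `seed`.
#' @export
run_session <- function(stream, detector = detector_stub(),
                        procedure = NULL, cfg = decision_config()) {
  stopifnot(inherits(stream, "rotoloc_stream"))
  procedure <- procedure %||% attr(stream$script, "procedure")
  state <- activation_state(procedure)
  events <- list(); det_rows <- list(); frames <- vector("list", stream$n_frames)
  truth_by_frame <- split(stream$truth,
                          factor(stream$truth$frame, levels = seq_len(stream$n_frames)))
  for (i in seq_len(stream$n_frames)) {
    det <- if (inherits(detector, "detector_stub")) {
      tr <- truth_by_frame[[i]]
      if (is.null(tr)) tr <- stream$truth[0, ]
      stub_detect(detector, dplyr::select(tr, -dplyr::any_of("frame")), i,
                  seed = stream$seed,
                  frame_size = c(stream$scene$width, stream$scene$height))
    } else if (is.function(detector)) {
      detector(stream_frame(stream, i)$image, i)
    } else {
      stop("detector must be a detector_stub or a function", call. = FALSE)
    }
    ok <- tryCatch({ validate_boxes(det, "detections"); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) {
      stop(sprintf("detector error at frame %d: %s", i, conditionMessage(ok)),
           call. = FALSE)
    }
    res <- decision_step(state, det, i, cfg)
    state <- res$state
    if (!is.null(res$event)) events[[length(events) + 1]] <- res$event
    if (nrow(det)) {
      det$frame <- i
      det_rows[[length(det_rows) + 1]] <- det
    }
    frames[[i]] <- tibble::tibble(
      frame = i, n_detections = nrow(det),
      overlap_count = state$overlap_count,
      prompt_emitted = state$prompt_emitted
    )
  }
  structure(
    list(
      frames = dplyr::bind_rows(frames),
      events = if (length(events)) dplyr::bind_rows(events) else
        tibble::tibble(frame = integer(), message = character()),
      detections = if (length(det_rows)) dplyr::bind_rows(det_rows) else
        tibble::tibble(frame = integer(), class = character(), x = numeric(),
                       y = numeric(), length = numeric(), height = numeric(),
                       confidence = numeric()),
      procedure = as.integer(procedure),
      config = cfg,
      seed = stream$seed
    ),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> procedure %s, %d frames, %d prompt event(s)\n",
              c("I", "II")[x$procedure], nrow(x$frames), nrow(x$events)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.session_log <- function(x, ...) x$frames

#' @exportS3Method generics::glance
glance.session_log <- function(x, ...) {
  tibble::tibble(
    procedure = x$procedure, frames = nrow(x$frames),
    detections = nrow(x$detections),
    prompt_frame = if (nrow(x$events)) x$events$frame[1] else NA_integer_
  )
}

#' Replay a recorded session log through the decision engine
#'
#' Re-derives the prompt events offline from the logged detections; by the
#' engine's purity this must reproduce the live events exactly.
#'
#' @param log A [run_session()] log.
#' @return The events tibble of the replay.
#' @export
replay_session <- function(log) {
  stopifnot(inherits(log, "session_log"))
  run_decision_engine(log$detections, log$procedure, log$config,
                      n_frames = nrow(log$frames))$events
}

#' Burn detection annotations into a frame
#'
#' Draws class-coloured rectangles (green for the cutter slot, red for the
#' tumor) with confidence text, and — once the prompt has been emitted — a
#' banner with the prompt message. Returns a new RGB array; the input is
#' not modified. Boxes partly outside the image are clamped.
#'
#' @param image Grayscale matrix or `(H, W, 3)` array in `[0, 1]`.
#' @param detections Box tibble.
#' @param state An [activation_state()] (or `NULL`); the banner is drawn
#'   when `state$prompt_emitted` is `TRUE`.
#' @param cfg A [decision_config()] supplying the banner text.
#' @return `(H, W, 3)` array.
#' @export
annotate_frame <- function(image, detections, state = NULL,
                           cfg = decision_config()) {
  img <- if (is.matrix(image)) {
    array(rep(image, 3), c(dim(image), 3))
  } else image
  H <- dim(img)[1]; W <- dim(img)[2]
  cols <- list(slot = c(0.1, 0.9, 0.2), tumor = c(0.95, 0.15, 0.15))
  if (nrow(detections)) validate_boxes(detections)
  for (i in seq_len(nrow(detections))) {
    b <- detections[i, ]
    x0 <- clamp(round(b$x), 1, W); x1 <- clamp(round(b$x + b$length), 1, W)
    y0 <- clamp(round(b$y), 1, H); y1 <- clamp(round(b$y + b$height), 1, H)
    colr <- cols[[b$class]]
    for (k in 1:3) {
      img[y0:y1, c(x0, x1), k] <- colr[k]
      img[c(y0, y1), x0:x1, k] <- colr[k]
    }
    img <- draw_text(img, sprintf("%s %.2f", b$class, b$confidence),
                     x = x0, y = max(1, y0 - 9), colour = colr)
  }
  if (!is.null(state) && isTRUE(state$prompt_emitted)) {
    band <- seq_len(min(14, H))
    img[band, , ] <- img[band, , ] * 0.2
    img <- draw_text(img, cfg$prompt_message, x = 4, y = 4,
                     colour = c(1, 1, 0.2))
  }
  img
}

#' Write an annotated session as a video file
#'
#' Renders every frame of the stream, burns in the detections recorded in
#' the log plus the prompt banner, and writes the sequence either as a
#' multi-page TIFF (path ending in `.tif`/`.tiff`) or as a numbered PNG
#' sequence (path treated as a directory). The output has exactly one page
#' or file per stream frame.
#'
#' @param log A [run_session()] log.
#' @param stream The stream the log was produced from.
#' @param path Output `.tiff` file or directory.
#' @return `path`, invisibly.
#' @export
write_session_video <- function(log, stream, path) {
  stopifnot(inherits(log, "session_log"), inherits(stream, "rotoloc_stream"))
  n <- nrow(log$frames)
  if (n == 0) stop("I/O error: refusing to write a zero-frame video",
                   call. = FALSE)
  prompt_frame <- if (nrow(log$events)) log$events$frame[1] else Inf
  det_by_frame <- split(log$detections,
                        factor(log$detections$frame, levels = seq_len(n)))
  render1 <- function(i) {
    st <- activation_state(log$procedure)
    st$prompt_emitted <- i >= prompt_frame
    det <- det_by_frame[[i]]
    if (is.null(det)) det <- log$detections[0, ]
    annotate_frame(stream_frame(stream, i)$image, det, st, log$config)
  }
  if (grepl("\\.tiff?$", path)) {
    tiff::writeTIFF(lapply(seq_len(n), render1), path)
  } else {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      png::writePNG(render1(i), file.path(path, sprintf("frame%05d.png", i)))
    }
  }
  invisible(path)
}

#' A simple image-processing detector for synthetic frames
#'
#' Thresholds the frame into bright (slot-like) and dark (tumor-like)
#' regions, extracts connected components, and returns their bounding boxes
#' with a confidence given by the component's fill ratio. No learning is
#' involved; it exists so the whole pixel pipeline can run end-to-end
#' without a neural detector.
#'
#' @param bright Threshold above which pixels count as slot echo.
#' @param dark Threshold below which pixels count as tumor interior.
#' @param min_area Minimum component area in pixels.
#' @return A detector function usable with [run_session()].
#' @export
segmentation_detector <- function(bright = 0.65, dark = 0.15, min_area = 60) {
  function(image, frame_index) {
    det <- list(
      components_to_boxes(image >= bright, "slot", min_area),
      components_to_boxes(image <= dark, "tumor", min_area)
    )
    dplyr::bind_rows(det)
  }
}

# connected components (4-neighbour) via two-pass labelling with union-find
components_to_boxes <- function(mask, class, min_area) {
  H <- nrow(mask); W <- ncol(mask)
  labels <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j]) next
    up <- if (i > 1) labels[i - 1, j] else 0L
    lf <- if (j > 1) labels[i, j - 1] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; labels[i, j] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      parent[max(ru, rl)] <- min(ru, rl)
      labels[i, j] <- min(ru, rl)
    } else {
      labels[i, j] <- max(up, lf)
    }
  }
  if (nxt == 0L) {
    return(boxes(numeric(), numeric(), numeric(), numeric(), character()))
  }
  roots <- vapply(seq_len(nxt), find, 0L)
  idx <- which(labels > 0L, arr.ind = TRUE)
  comp <- roots[labels[labels > 0L]]
  out <- list()
  for (r in unique(comp)) {
    sel <- idx[comp == r, , drop = FALSE]
    if (nrow(sel) < min_area) next
    x0 <- min(sel[, 2]) - 1; x1 <- max(sel[, 2])
    y0 <- min(sel[, 1]) - 1; y1 <- max(sel[, 1])
    fill <- nrow(sel) / ((x1 - x0) * (y1 - y0))
    out[[length(out) + 1]] <- boxes(x0, y0, x1 - x0, y1 - y0, class,
                                    confidence = clamp(fill, 0.05, 1))
  }
  if (length(out)) dplyr::bind_rows(out) else
    boxes(numeric(), numeric(), numeric(), numeric(), character())
}
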
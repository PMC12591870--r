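#' Load a declarative architecture layer plan
#'
#' Layer plans are inspectable data: a YAML list of blocks (kind, output
#' channels, kernel, stride, expansion, hidden widths, graph edges) shipped
#' under `inst/extdata/plans/`. Four plans are registered: the published
#' baseline detectors `yolov11n` and `yolov11s`, and the lightweight
#' `yolov11n_plus` / `yolov11s_plus` variants whose backbones use inverted
#' residual (MIRB) and universal inverted bottleneck (MUIB) stages with a
#' 40-80-128-480-512 channel schedule and a pruned cross-stage-partial neck.
#'
#' @param name Registry name (`"yolov11n"`, `"yolov11s"`, `"yolov11n_plus"`,
#'   `"yolov11s_plus"`) or a path to a plan YAML file.
#' @param num_classes Number of detection classes (default: value stored in
#'   the plan; 2 for cutter slot + tumor).
#' @param input_size Input image side in pixels (default from plan, 640).
#' @return An `arch_plan` object: list with `name`, `num_classes`,
#'   `input_size` and `layers`.
#' @examples
#' plan <- arch_plan("yolov11n_plus")
#' length(plan$layers)
#' @export
arch_plan <- function(name, num_classes = NULL, input_size = NULL) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", "plans", paste0(name, ".yaml"), package = "rotoloc")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("unknown architecture '%s'; registered plans: %s",
                 name, paste(arch_names(), collapse = ", ")), call. = FALSE)
  }
  spec <- yaml::read_yaml(path)
  plan <- structure(
    list(
      name = spec$name,
      num_classes = as.integer(num_classes %||% spec$num_classes %||% 2),
      input_size = as.integer(input_size %||% spec$input_size %||% 640),
      layers = spec$layers
    ),
    class = "arch_plan"
  )
  if (plan$num_classes < 1) stop("num_classes must be >= 1", call. = FALSE)
  plan
}

#' Names of the registered architecture plans
#' @return Character vector.
#' @export
arch_names <- function() {
  sub("\\.yaml$", "",
      dir(system.file("extdata", "plans", package = "rotoloc"),
          pattern = "\\.yaml$"))
}

# Resolve a plan into primitive convolution records: walk the layer graph,
# propagate channel counts and spatial sizes, expand each block.
resolve_plan <- function(plan, input_size = NULL) {
  input_size <- input_size %||% plan$input_size
  layers <- plan$layers
  n <- length(layers)
  out_c <- integer(n); out_h <- numeric(n); out_w <- numeric(n)
  recs <- vector("list", n)
  get_src <- function(from, i) {
    idx <- ifelse(from < 0, i + from, from + 1)   # layer ids are 0-based
    if (any(idx < 1 | idx >= i + 1)) {
      stop(sprintf("construction error at layer %d: unresolvable source", i - 1),
           call. = FALSE)
    }
    idx
  }
  for (i in seq_len(n)) {
    ly <- layers[[i]]
    kind <- ly$kind
    from <- unlist(ly$from %||% -1L)
    if (kind == "concat") {
      src <- get_src(from, i)
      hs <- out_h[src]; ws <- out_w[src]
      if (length(unique(hs)) != 1 || length(unique(ws)) != 1) {
        stop(sprintf("construction error at layer %d (concat): spatial mismatch",
                     i - 1), call. = FALSE)
      }
      out_c[i] <- sum(out_c[src]); out_h[i] <- hs[1]; out_w[i] <- ws[1]
      recs[[i]] <- conv_rec(integer(), integer())
    } else if (kind == "detect") {
      src <- get_src(from, i)
      ex <- expand_detect(out_c[src], plan$num_classes, out_h[src], out_w[src])
      recs[[i]] <- ex$recs
      out_c[i] <- NA_integer_; out_h[i] <- NA; out_w[i] <- NA
    } else {
      src <- if (i == 1) NA_integer_ else get_src(from[1], i)
      c_in <- if (i == 1) 3L else out_c[src]
      h_in <- if (i == 1) input_size else out_h[src]
      w_in <- if (i == 1) input_size else out_w[src]
      ex <- expand_block(ly, c_in, h_in, w_in)
      recs[[i]] <- ex$recs
      out_c[i] <- ex$c_out; out_h[i] <- ex$h; out_w[i] <- ex$w
    }
  }
  rec_tbl <- dplyr::bind_rows(
    lapply(seq_len(n), function(i) {
      r <- recs[[i]]
      if (nrow(r)) r$layer <- i - 1L
      r
    })
  )
  list(records = rec_tbl, out_c = out_c, out_h = out_h, out_w = out_w)
}

detect_layer_index <- function(plan) {
  which(vapply(plan$layers, function(l) l$kind == "detect", logical(1)))
}

#' Count the parameters of a model or plan
#'
#' Under the default `"deployed"` convention batch-norm layers are folded
#' into their convolutions (weights + bias) and the fixed 16-parameter
#' distribution-projection convolution of the detection head is included;
#' this is the convention in which total model sizes are reported for this
#' detector family. The `"training"` convention counts bias-free convolution
#' weights plus `2 * channels` per batch-norm layer and equals the number of
#' weight values held by a built model.
#'
#' @param x An `arch_plan`, a `rotoloc_model`, or a registry name.
#' @param convention `"deployed"` or `"training"`.
#' @return Integer parameter count.
#' @examples
#' count_parameters("yolov11n_plus")
#' @export
count_parameters <- function(x, convention = c("deployed", "training")) {
  convention <- match.arg(convention)
  plan <- as_arch_plan(x)
  res <- resolve_plan(plan)
  as.integer(round(rec_params(res$records, convention))) + 16L  # + DFL
}

#' Count the floating-point operations of a model or plan
#'
#' FLOPs are computed as 2 x multiply-accumulates of the batch-norm-folded
#' convolutions at the given input size; activation, pooling and resampling
#' terms are not counted. This convention reproduces the published complexity
#' figures of the baseline detectors at one-decimal precision.
#'
#' @inheritParams count_parameters
#' @param input_size Image side in pixels (default: plan's, 640).
#' @return FLOPs in billions (GFLOPs), unrounded.
#' @examples
#' round(count_flops("yolov11n"), 1)
#' @export
count_flops <- function(x, input_size = NULL) {
  plan <- as_arch_plan(x)
  if (!is.null(input_size) && input_size <= 0) {
    stop("input_size must be positive", call. = FALSE)
  }
  res <- resolve_plan(plan, input_size)
  rec_flops(res$records) / 1e9
}

as_arch_plan <- function(x) {
  if (inherits(x, "arch_plan")) return(x)
  if (inherits(x, "rotoloc_model")) return(x$plan)
  if (is.character(x) && length(x) == 1) return(arch_plan(x))
  stop("expected an arch_plan, rotoloc_model, or architecture name",
       call. = FALSE)
}

#' Per-layer complexity accounting
#'
#' @inheritParams count_parameters
#' @param input_size Image side in pixels for the FLOP column.
#' @return A `complexity_report`: tibble with one row per layer (`layer`,
#'   `kind`, `params`, `gflops`) plus attributes `total_params` (deployed
#'   convention, incl. the fixed head projection) and `gflops`.
#' @examples
#' complexity_report("yolov11n_plus")
#' @export
complexity_report <- function(x, input_size = NULL) {
  plan <- as_arch_plan(x)
  res <- resolve_plan(plan, input_size)
  kinds <- vapply(plan$layers, `[[`, "", "kind")
  per <- res$records |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(
      params = as.integer(round(sum(.data$c1 / .data$g * .data$c2 * .data$k^2 +
                                      ifelse(.data$bn | .data$bias, .data$c2, 0)))),
      gflops = sum(2 * .data$c1 / .data$g * .data$c2 * .data$k^2 *
                     .data$h * .data$w) / 1e9,
      .groups = "drop"
    )
  all_layers <- tibble::tibble(layer = seq_along(kinds) - 1L, kind = kinds)
  per <- dplyr::left_join(all_layers, per, by = "layer") |>
    dplyr::mutate(params = dplyr::coalesce(.data$params, 0L),
                  gflops = dplyr::coalesce(.data$gflops, 0))
  # fixed distribution-projection parameters belong to the detect layer
  di <- detect_layer_index(plan) - 1L
  per$params[per$layer == di] <- per$params[per$layer == di] + 16L
  structure(per,
            class = c("complexity_report", class(per)),
            name = plan$name,
            total_params = sum(per$params),
            gflops = sum(per$gflops))
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("<complexity_report> %s: %s parameters, %.1f GFLOPs\n",
              attr(x, "name"), format(attr(x, "total_params"), big.mark = ","),
              attr(x, "gflops")))
  NextMethod()
}

#' @exportS3Method generics::glance
glance.complexity_report <- function(x, ...) {
  tibble::tibble(name = attr(x, "name"),
                 total_params = attr(x, "total_params"),
                 gflops = attr(x, "gflops"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.complexity_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$layer),
                                       y = .data$params, fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "layer", y = "parameters (deployed)",
                  title = attr(object, "name"))
}

#' Parameter and FLOP reduction of a lightweight variant over its baseline
#'
#' @param base,variant Plans, models or registry names.
#' @return Tibble with the percentage reductions
#'   `100 * (1 - variant / base)` for parameters and FLOPs.
#' @examples
#' reduction_ratios("yolov11n", "yolov11n_plus")
#' @export
reduction_ratios <- function(base, variant) {
  pb <- count_parameters(base); pv <- count_parameters(variant)
  fb <- count_flops(base); fv <- count_flops(variant)
  tibble::tibble(
    params_reduction_pct = 100 * (1 - pv / pb),
    flops_reduction_pct = 100 * (1 - fv / fb)
  )
}

#' Build an executable model from a layer plan
#'
#' Instantiates every convolution with deterministically seeded He-normal
#' weights and identity batch-norm parameters. The returned model carries the
#' resolved layer graph and can run a numeric forward pass
#' ([model_forward()]) producing the three detection feature maps at strides
#' 8, 16 and 32.
#'
#' @param plan An `arch_plan` (or registry name).
#' @param seed Integer seed for weight initialisation.
#' @return A `rotoloc_model`.
#' @examples
#' m <- build_model(arch_plan("yolov11n_plus"))
#' count_parameters(m)
#' @export
build_model <- function(plan, seed = 0L) {
  plan <- as_arch_plan(plan)
  res <- resolve_plan(plan)
  recs <- res$records
  set.seed(seed)
  weights <- lapply(seq_len(nrow(recs)), function(i) {
    r <- recs[i, ]
    fan_in <- r$c1 / r$g * r$k^2
    W <- matrix(stats::rnorm(r$c2 * fan_in, sd = sqrt(2 / fan_in)),
                nrow = r$c2)
    out <- list(W = W)
    if (r$bn) {
      out$gamma <- rep(1, r$c2); out$beta <- rep(0, r$c2)
    } else if (r$bias) {
      out$bias <- rep(0, r$c2)
    }
    out
  })
  structure(
    list(plan = plan, records = recs, weights = weights,
         out_c = res$out_c, out_h = res$out_h, out_w = res$out_w, seed = seed),
    class = "rotoloc_model"
  )
}

#' @export
print.rotoloc_model <- function(x, ...) {
  cat(sprintf(
    "<rotoloc_model> %s: %d layers, %s parameters (deployed), %.1f GFLOPs @ %d\n",
    x$plan$name, length(x$plan$layers),
    format(count_parameters(x), big.mark = ","), count_flops(x),
    x$plan$input_size))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rotoloc_model <- function(x, ...) {
  rep <- complexity_report(x$plan)
  tibble::as_tibble(rep)
}

#' @exportS3Method generics::glance
glance.rotoloc_model <- function(x, ...) {
  tibble::tibble(
    name = x$plan$name,
    layers = length(x$plan$layers),
    num_classes = x$plan$num_classes,
    total_params = count_parameters(x),
    training_params = count_parameters(x, "training"),
    gflops = count_flops(x)
  )
}

# number of weight values actually held by a built model (training view)
model_weight_count <- function(model) {
  as.integer(sum(vapply(model$weights, function(wl) {
    sum(vapply(wl, length, 0L))
  }, 0))) + 16L  # fixed distribution-projection convolution
}
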
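# Block-level definitions for the detection architectures.
#
# Every block expands to an ordered list of primitive convolution records.
# A record holds: c1, c2, k, g (groups), stride, bn (followed by a batch-norm
# layer), bias (raw convolution bias), act (SiLU applied), and the output
# spatial size (h, w). Parameter and FLOP accounting, weight instantiation
# and the numeric forward pass all consume the same records in the same
# order, so the three views cannot drift apart.
#
# Counting conventions:
#  * training:  conv weights (bias-free) + 2*channels per batch-norm layer
#  * deployed:  batch-norm folded into the convolution, i.e. weights + bias
# FLOPs are 2 x multiply-accumulates of the folded convolutions at the given
# input size; activation, pooling and resampling terms are not counted.

conv_rec <- function(c1, c2, k = 1, g = 1, stride = 1, bn = TRUE, bias = FALSE,
                     act = TRUE, h = NA_real_, w = NA_real_) {
  tibble::tibble(c1 = c1, c2 = c2, k = k, g = g, stride = stride,
                 bn = bn, bias = bias, act = act, h = h, w = w)
}

rec_params <- function(rec, convention = "deployed") {
  wts <- rec$c1 / rec$g * rec$c2 * rec$k^2
  extra <- if (convention == "training") {
    ifelse(rec$bn, 2 * rec$c2, ifelse(rec$bias, rec$c2, 0))
  } else {
    ifelse(rec$bn | rec$bias, rec$c2, 0)
  }
  sum(wts + extra)
}

rec_flops <- function(rec) {
  sum(2 * rec$c1 / rec$g * rec$c2 * rec$k^2 * rec$h * rec$w)
}

# ---- block expanders -------------------------------------------------------
# Each expander returns list(recs, c_out, h, w). `h`, `w` are input dims.

down <- function(x, s) ceiling(x / s)

expand_conv_bn <- function(c1, out, kernel, stride, h, w) {
  h2 <- down(h, stride); w2 <- down(w, stride)
  list(recs = conv_rec(c1, out, kernel, stride = stride, h = h2, w = w2),
       c_out = out, h = h2, w = w2)
}

# Stride-1 inverted residual: expand 1x1 (c1 -> c1*e), depthwise kxk,
# project 1x1 -> out; residual connection when c1 == out.
# Stride-2 form: strided depthwise kxk on the input followed by a pointwise
# expansion c1 -> out (the projection is fused into the expansion).
expand_mirb <- function(c1, out, kernel, stride, expansion, h, w) {
  if (stride == 1) {
    hd <- c1 * expansion
    recs <- dplyr::bind_rows(
      conv_rec(c1, hd, 1, h = h, w = w),
      conv_rec(hd, hd, kernel, g = hd, h = h, w = w),
      conv_rec(hd, out, 1, h = h, w = w)
    )
    list(recs = recs, c_out = out, h = h, w = w)
  } else {
    h2 <- down(h, stride); w2 <- down(w, stride)
    recs <- dplyr::bind_rows(
      conv_rec(c1, c1, kernel, g = c1, stride = stride, h = h2, w = w2),
      conv_rec(c1, out, 1, h = h2, w = w2)
    )
    list(recs = recs, c_out = out, h = h2, w = w2)
  }
}

# Universal inverted bottleneck: leading depthwise (carries the stride),
# expand 1x1 (c1 -> c1*e), mid depthwise, project 1x1 -> out.
expand_muib <- function(c1, out, kernel, stride, expansion, h, w) {
  hd <- c1 * expansion
  h2 <- down(h, stride); w2 <- down(w, stride)
  recs <- dplyr::bind_rows(
    conv_rec(c1, c1, kernel, g = c1, stride = stride, h = h2, w = w2),
    conv_rec(c1, hd, 1, h = h2, w = w2),
    conv_rec(hd, hd, kernel, g = hd, h = h2, w = w2),
    conv_rec(hd, out, 1, h = h2, w = w2)
  )
  list(recs = recs, c_out = out, h = h2, w = w2)
}

expand_sppf <- function(c1, out, hidden, h, w) {
  recs <- dplyr::bind_rows(
    conv_rec(c1, hidden, 1, h = h, w = w),
    conv_rec(4 * hidden, out, 1, h = h, w = w)
  )
  list(recs = recs, c_out = out, h = h, w = w)
}

expand_bottleneck <- function(c1, c2, e, k1, k2, h, w) {
  cm <- floor(c2 * e)
  dplyr::bind_rows(
    conv_rec(c1, cm, k1, h = h, w = w),
    conv_rec(cm, c2, k2, h = h, w = w)
  )
}

expand_c3k <- function(c1, c2, n, e, k, h, w) {
  cm <- floor(c2 * e)
  recs <- dplyr::bind_rows(
    conv_rec(c1, cm, 1, h = h, w = w),
    conv_rec(c1, cm, 1, h = h, w = w),
    conv_rec(2 * cm, c2, 1, h = h, w = w)
  )
  for (i in seq_len(n)) {
    recs <- dplyr::bind_rows(recs, expand_bottleneck(cm, cm, 1, k, k, h, w))
  }
  recs
}

# Cross-stage-partial block. Unpruned: n standard bottlenecks (or C3k
# sub-blocks when c3k = TRUE) at hidden width floor(out * e). Pruned
# ("local information pruning"): the residual branch of each unit is reduced
# to a depthwise 3x3 + pointwise 1x1 pair at an explicit hidden width.
expand_c3k2 <- function(c1, out, n = 1, e = 0.5, c3k = FALSE, pruned = FALSE,
                        hidden = NULL, h, w) {
  ch <- if (!is.null(hidden)) hidden else floor(out * e)
  recs <- conv_rec(c1, 2 * ch, 1, h = h, w = w)
  for (i in seq_len(n)) {
    unit <- if (pruned) {
      dplyr::bind_rows(
        conv_rec(ch, ch, 3, g = ch, h = h, w = w),
        conv_rec(ch, ch, 1, h = h, w = w)
      )
    } else if (c3k) {
      expand_c3k(ch, ch, 2, 0.5, 3, h, w)
    } else {
      expand_bottleneck(ch, ch, 0.5, 3, 3, h, w)
    }
    recs <- dplyr::bind_rows(recs, unit)
  }
  recs <- dplyr::bind_rows(recs, conv_rec((2 + n) * ch, out, 1, h = h, w = w))
  list(recs = recs, c_out = out, h = h, w = w)
}

# Partial self-attention stage used by the published baseline backbones.
expand_c2psa <- function(c1, n = 1, e = 0.5, h, w) {
  cc <- floor(c1 * e)
  num_heads <- max(1, cc %/% 64)
  head_dim <- cc %/% num_heads
  key_dim <- floor(head_dim * 0.5)
  qkv_out <- cc + key_dim * num_heads * 2
  recs <- conv_rec(c1, 2 * cc, 1, h = h, w = w)
  for (i in seq_len(n)) {
    recs <- dplyr::bind_rows(
      recs,
      conv_rec(cc, qkv_out, 1, act = FALSE, h = h, w = w),   # qkv
      conv_rec(cc, cc, 1, act = FALSE, h = h, w = w),        # attention proj
      conv_rec(cc, cc, 3, g = cc, act = FALSE, h = h, w = w),# positional enc
      conv_rec(cc, 2 * cc, 1, h = h, w = w),                 # ffn expand
      conv_rec(2 * cc, cc, 1, act = FALSE, h = h, w = w)     # ffn project
    )
  }
  recs <- dplyr::bind_rows(recs, conv_rec(2 * cc, c1, 1, h = h, w = w))
  list(recs = recs, c_out = c1, h = h, w = w)
}

# Anchor-free decoupled detection head over three scales. The box branch
# regresses 4 x reg_max distribution bins; the class branch uses the
# lightweight depthwise form. The distribution projection (DFL) is a fixed
# 16-parameter convolution counted with the totals but never trained.
detect_reg_max <- 16L

expand_detect <- function(ch, nc, hs, ws) {
  c2h <- max(16, ch[1] %/% 4, detect_reg_max * 4)
  c3h <- max(ch[1], min(nc, 100))
  recs <- list()
  for (i in seq_along(ch)) {
    x <- ch[i]; h <- hs[i]; w <- ws[i]
    recs[[i]] <- dplyr::bind_rows(
      conv_rec(x, c2h, 3, h = h, w = w),
      conv_rec(c2h, c2h, 3, h = h, w = w),
      conv_rec(c2h, 4 * detect_reg_max, 1, bn = FALSE, bias = TRUE,
               act = FALSE, h = h, w = w),
      conv_rec(x, x, 3, g = x, h = h, w = w),
      conv_rec(x, c3h, 1, h = h, w = w),
      conv_rec(c3h, c3h, 3, g = c3h, h = h, w = w),
      conv_rec(c3h, c3h, 1, h = h, w = w),
      conv_rec(c3h, nc, 1, bn = FALSE, bias = TRUE, act = FALSE, h = h, w = w)
    )
  }
  list(recs = dplyr::bind_rows(recs), c_out = NA_integer_)
}

#' Analytic parameter count of a single architecture block
#'
#' Expands the block to its primitive convolutions and sums their parameter
#' counts under the requested convention. Under `"training"`, convolutions
#' are bias-free and every batch-norm layer contributes `2 * channels`
#' trainable parameters; under `"deployed"` the batch-norm is folded into the
#' convolution, which then carries a bias (this is the convention in which
#' total model sizes are reported).
#'
#' @param kind One of `"conv_bn"`, `"mirb"`, `"muib"`, `"sppf"`, `"c3k2"`,
#'   `"c2psa"`.
#' @param in_channels Input channel count.
#' @param out Output channel count.
#' @param kernel Kernel size (3 or 5; 1 for pointwise `conv_bn`).
#' @param stride Stride (1 or 2).
#' @param expansion Expansion ratio for `mirb`/`muib`.
#' @param convention `"training"` or `"deployed"`.
#' @param ... Further block fields (`n`, `e`, `c3k`, `pruned`, `hidden` for
#'   `c3k2`; `hidden` for `sppf`).
#' @return Integer parameter count.
#' @examples
#' block_params("conv_bn", in_channels = 3, out = 40, kernel = 3,
#'              convention = "training")  # 3*40*9 + 2*40 = 1160
#' @export
block_params <- function(kind, in_channels, out = NULL, kernel = 3, stride = 1,
                         expansion = NULL, convention = c("training", "deployed"),
                         ...) {
  convention <- match.arg(convention)
  stopifnot(in_channels >= 1)
  spec <- c(list(kind = kind, out = out, kernel = kernel, stride = stride,
                 expansion = expansion), list(...))
  if (!is.null(out) && out < 1) stop("spec error: out channels must be >= 1",
                                     call. = FALSE)
  ex <- expand_block(spec, in_channels, h = 64, w = 64)
  as.integer(round(rec_params(ex$recs, convention)))
}

expand_block <- function(spec, c_in, h, w) {
  kind <- spec$kind
  switch(kind,
    conv_bn = expand_conv_bn(c_in, spec$out, spec$kernel, spec$stride %||% 1, h, w),
    mirb = expand_mirb(c_in, spec$out, spec$kernel, spec$stride %||% 1,
                       spec$expansion %||% 2, h, w),
    muib = expand_muib(c_in, spec$out, spec$kernel, spec$stride %||% 1,
                       spec$expansion %||% 4, h, w),
    sppf = expand_sppf(c_in, spec$out, spec$hidden %||% (c_in %/% 2), h, w),
    c3k2 = expand_c3k2(c_in, spec$out, spec$n %||% 1, spec$e %||% 0.5,
                       isTRUE(spec$c3k), isTRUE(spec$pruned), spec$hidden, h, w),
    c2psa = expand_c2psa(c_in, spec$n %||% 1, spec$e %||% 0.5, h, w),
    upsample = list(recs = conv_rec(integer(), integer()), c_out = c_in,
                    h = h * (spec$scale %||% 2), w = w * (spec$scale %||% 2)),
    stop(sprintf("spec error: unsupported block kind '%s'", kind), call. = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
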
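# Numeric forward pass for built models. Images are arrays (C, H, W); all
# convolutions use 'same' padding via im2col + BLAS matrix multiplication,
# depthwise convolutions use shift-accumulate. Heavy by deep-learning
# standards but adequate for validating graph wiring, output shapes and the
# parameter accounting at moderate input sizes.

silu <- function(x) x * stats::plogis(x)

pad_chw <- function(x, p, value = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1], d[2] + 2 * p, d[3] + 2 * p))
  out[, p + seq_len(d[2]), p + seq_len(d[3])] <- x
  out
}

# dense convolution via im2col; W is (c2, c1*k^2)
conv_dense <- function(x, W, k, stride) {
  d <- dim(x); C <- d[1]
  p <- k %/% 2
  xp <- pad_chw(x, p)
  ho <- ceiling(d[2] / stride); wo <- ceiling(d[3] / stride)
  cols <- matrix(0, C * k * k, ho * wo)
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    blk <- (dj * k + di) * C
    sub <- xp[, di + seq(1, by = stride, length.out = ho),
              dj + seq(1, by = stride, length.out = wo), drop = FALSE]
    cols[blk + seq_len(C), ] <- sub
  }
  y <- W %*% cols
  array(y, c(nrow(W), ho, wo))
}

# depthwise convolution (groups == c1 == c2); W is (c, k^2)
conv_depthwise <- function(x, W, k, stride) {
  d <- dim(x); C <- d[1]
  p <- k %/% 2
  xp <- pad_chw(x, p)
  ho <- ceiling(d[2] / stride); wo <- ceiling(d[3] / stride)
  out <- array(0, c(C, ho, wo))
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    sub <- xp[, di + seq(1, by = stride, length.out = ho),
              dj + seq(1, by = stride, length.out = wo), drop = FALSE]
    out <- out + sub * W[, dj * k + di + 1]
  }
  out
}

maxpool_same <- function(x, k = 5) {
  d <- dim(x); p <- k %/% 2
  xp <- pad_chw(x, p, value = -Inf)  # padding must never win the max
  out <- array(-Inf, d)
  for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    out <- pmax(out, xp[, di + seq_len(d[2]), dj + seq_len(d[3]), drop = FALSE])
  }
  out
}

upsample2 <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), drop = FALSE]
}

concat_c <- function(xs) {
  hs <- vapply(xs, function(x) dim(x)[2], 0)
  ws <- vapply(xs, function(x) dim(x)[3], 0)
  stopifnot(length(unique(hs)) == 1, length(unique(ws)) == 1)
  cs <- vapply(xs, function(x) dim(x)[1], 0)
  out <- array(0, c(sum(cs), hs[1], ws[1]))
  at <- 0
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

# apply one convolution record with its weights
apply_conv <- function(x, rec, wts) {
  y <- if (rec$g == 1) {
    conv_dense(x, wts$W, rec$k, rec$stride)
  } else {
    stopifnot(rec$g == rec$c1, rec$c1 == rec$c2)
    conv_depthwise(x, wts$W, rec$k, rec$stride)
  }
  if (rec$bn) {
    y <- y * wts$gamma + wts$beta
  } else if (rec$bias) {
    y <- y + wts$bias
  }
  if (rec$act) y <- silu(y) else y
}

split_c <- function(x, at) {
  list(x[seq_len(at), , , drop = FALSE],
       x[at + seq_len(dim(x)[1] - at), , , drop = FALSE])
}

#' Run a numeric forward pass
#'
#' Maps an input image to the three raw detection feature maps at strides
#' 8, 16 and 32. Each map has `4 * 16 + num_classes` channels (box
#' distribution bins plus class logits). The input side must be a multiple
#' of 32; a grayscale matrix is replicated to three channels.
#'
#' @param model A [build_model()] result.
#' @param image Matrix `(H, W)`, array `(H, W, 3)` or array `(3, H, W)` with
#'   values on any numeric scale.
#' @return Named list `p3`, `p4`, `p5` of arrays `(channels, H/s, W/s)`.
#' @examples
#' m <- build_model(arch_plan("yolov11n_plus"))
#' maps <- model_forward(m, matrix(0, 64, 64))
#' vapply(maps, function(x) dim(x)[2], 0)
#' @export
model_forward <- function(model, image) {
  stopifnot(inherits(model, "rotoloc_model"))
  x <- as_chw(image)
  if (dim(x)[2] %% 32 != 0 || dim(x)[3] %% 32 != 0) {
    stop("input size must be a multiple of 32", call. = FALSE)
  }
  plan <- model$plan
  recs <- model$records
  cursor <- 0L
  take <- function() {
    cursor <<- cursor + 1L
    list(rec = recs[cursor, ], wts = model$weights[[cursor]])
  }
  outputs <- vector("list", length(plan$layers))
  result <- NULL
  for (i in seq_along(plan$layers)) {
    ly <- plan$layers[[i]]
    from <- unlist(ly$from %||% -1L)
    src <- ifelse(from < 0, i + from, from + 1)
    xin <- if (i == 1) x else outputs[[src[1]]]
    outputs[[i]] <- switch(ly$kind,
      conv_bn = { cv <- take(); apply_conv(xin, cv$rec, cv$wts) },
      mirb = forward_mirb(xin, ly, take),
      muib = forward_muib(xin, ly, take),
      sppf = forward_sppf(xin, take),
      c3k2 = forward_c3k2(xin, ly, take),
      c2psa = forward_c2psa(xin, ly, take),
      upsample = upsample2(xin),
      concat = concat_c(outputs[src]),
      detect = { result <- forward_detect(outputs[src], plan$num_classes, take); NULL },
      stop(sprintf("unsupported kind '%s'", ly$kind), call. = FALSE)
    )
  }
  result
}

as_chw <- function(image) {
  if (is.matrix(image)) {
    array(rep(image, 3), c(dim(image), 3)) |> aperm(c(3, 1, 2))
  } else if (length(dim(image)) == 3 && dim(image)[3] == 3) {
    aperm(image, c(3, 1, 2))
  } else if (length(dim(image)) == 3 && dim(image)[1] == 3) {
    image
  } else stop("image must be (H,W), (H,W,3) or (3,H,W)", call. = FALSE)
}

forward_mirb <- function(x, ly, take) {
  if ((ly$stride %||% 1) == 1) {
    a <- take(); b <- take(); cc <- take()
    y <- apply_conv(apply_conv(apply_conv(x, a$rec, a$wts), b$rec, b$wts),
                    cc$rec, cc$wts)
    if (dim(x)[1] == dim(y)[1]) y + x else y
  } else {
    a <- take(); b <- take()
    apply_conv(apply_conv(x, a$rec, a$wts), b$rec, b$wts)
  }
}

forward_muib <- function(x, ly, take) {
  a <- take(); b <- take(); cc <- take(); d <- take()
  y <- apply_conv(x, a$rec, a$wts)
  y <- apply_conv(y, b$rec, b$wts)
  y <- apply_conv(y, cc$rec, cc$wts)
  y <- apply_conv(y, d$rec, d$wts)
  if ((ly$stride %||% 1) == 1 && dim(x)[1] == dim(y)[1]) y + x else y
}

forward_sppf <- function(x, take) {
  cv1 <- take(); cv2 <- take()
  y0 <- apply_conv(x, cv1$rec, cv1$wts)
  y1 <- maxpool_same(y0); y2 <- maxpool_same(y1); y3 <- maxpool_same(y2)
  apply_conv(concat_c(list(y0, y1, y2, y3)), cv2$rec, cv2$wts)
}

forward_bottleneck <- function(x, take, shortcut = TRUE) {
  a <- take(); b <- take()
  y <- apply_conv(apply_conv(x, a$rec, a$wts), b$rec, b$wts)
  if (shortcut && dim(x)[1] == dim(y)[1]) y + x else y
}

forward_c3k <- function(x, take, n = 2) {
  cv1 <- take(); cv2 <- take(); cv3 <- take()
  a <- apply_conv(x, cv1$rec, cv1$wts)
  b <- apply_conv(x, cv2$rec, cv2$wts)
  for (i in seq_len(n)) a <- forward_bottleneck(a, take)
  apply_conv(concat_c(list(a, b)), cv3$rec, cv3$wts)
}

forward_c3k2 <- function(x, ly, take) {
  n <- ly$n %||% 1
  cv1 <- take()
  y <- apply_conv(x, cv1$rec, cv1$wts)
  ch <- dim(y)[1] %/% 2
  parts <- split_c(y, ch)
  for (i in seq_len(n)) {
    last <- parts[[length(parts)]]
    nxt <- if (isTRUE(ly$pruned)) {
      a <- take(); b <- take()
      z <- apply_conv(apply_conv(last, a$rec, a$wts), b$rec, b$wts)
      z + last
    } else if (isTRUE(ly$c3k)) {
      forward_c3k(last, take)
    } else {
      forward_bottleneck(last, take)
    }
    parts[[length(parts) + 1]] <- nxt
  }
  cv2 <- take()
  apply_conv(concat_c(parts), cv2$rec, cv2$wts)
}

forward_attention <- function(x, take) {
  qkv <- take(); proj_pe <- NULL
  proj <- take(); pe <- take()
  cc <- dim(x)[1]
  num_heads <- max(1, cc %/% 64)
  head_dim <- cc %/% num_heads
  key_dim <- floor(head_dim * 0.5)
  h <- dim(x)[2]; w <- dim(x)[3]; N <- h * w
  q_all <- apply_conv(x, qkv$rec, qkv$wts)
  qm <- matrix(q_all, dim(q_all)[1], N)
  per <- 2 * key_dim + head_dim
  outs <- vector("list", num_heads)
  vs <- vector("list", num_heads)
  for (hh in seq_len(num_heads)) {
    base <- (hh - 1) * per
    q <- qm[base + seq_len(key_dim), , drop = FALSE]
    k <- qm[base + key_dim + seq_len(key_dim), , drop = FALSE]
    v <- qm[base + 2 * key_dim + seq_len(head_dim), , drop = FALSE]
    att <- crossprod(q, k) / sqrt(key_dim)          # N x N
    att <- exp(att - apply(att, 1, max))
    att <- att / rowSums(att)
    outs[[hh]] <- v %*% t(att)                      # head_dim x N
    vs[[hh]] <- v
  }
  xo <- do.call(rbind, outs)
  vcat <- array(do.call(rbind, vs), c(cc, h, w))
  xo <- array(xo, c(cc, h, w)) + apply_conv(vcat, pe$rec, pe$wts)
  apply_conv(xo, proj$rec, proj$wts)
}

forward_c2psa <- function(x, ly, take) {
  n <- ly$n %||% 1
  cv1 <- take()
  y <- apply_conv(x, cv1$rec, cv1$wts)
  cc <- dim(y)[1] %/% 2
  ab <- split_c(y, cc)
  a <- ab[[1]]; b <- ab[[2]]
  for (i in seq_len(n)) {
    b <- b + forward_attention(b, take)
    f1 <- take(); f2 <- take()
    b <- b + apply_conv(apply_conv(b, f1$rec, f1$wts), f2$rec, f2$wts)
  }
  cv2 <- take()
  apply_conv(concat_c(list(a, b)), cv2$rec, cv2$wts)
}

forward_detect <- function(xs, nc, take) {
  out <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    x <- xs[[i]]
    b1 <- take(); b2 <- take(); b3 <- take()
    box <- apply_conv(apply_conv(apply_conv(x, b1$rec, b1$wts),
                                 b2$rec, b2$wts), b3$rec, b3$wts)
    c1 <- take(); c2 <- take(); c3 <- take(); c4 <- take(); c5 <- take()
    cls <- apply_conv(x, c1$rec, c1$wts)
    cls <- apply_conv(cls, c2$rec, c2$wts)
    cls <- apply_conv(cls, c3$rec, c3$wts)
    cls <- apply_conv(cls, c4$rec, c4$wts)
    cls <- apply_conv(cls, c5$rec, c5$wts)
    out[[i]] <- concat_c(list(box, cls))
  }
  names(out) <- c("p3", "p4", "p5")
  out
}
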
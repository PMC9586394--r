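#' Vector pooling block parameters
#'
#' Parameters of a VPB: one 1x1 convolution per directional path, the
#' directional kernel length `N` and the common stride. Both convolutions
#' must preserve the channel count.
#'
#' @param conv_vertical,conv_horizontal [conv1x1_params()] for the `1 x N`
#'   (vertical) and `N x 1` (horizontal) paths.
#' @param N directional kernel length (>= 2 in normal use; `N = 1` gives the
#'   degenerate identity-pool limit used in tests).
#' @param stride downsampling stride applied in both dimensions.
#' @return an object of class `vpb_params`.
#' @export
vpb_params <- function(conv_vertical, conv_horizontal, N, stride = N) {
  if (!identical(dim(conv_vertical$weights), dim(conv_horizontal$weights)))
    stop_config("both VPB path convolutions must share channel counts")
  structure(list(conv_vertical = conv_vertical,
                 conv_horizontal = conv_horizontal,
                 N = as.integer(N), stride = as.integer(stride)),
            class = "vpb_params")
}

#' AVG-MAX vector pooling block parameters
#'
#' Parameters of the four-path block: a 1x1 convolution per path (max and
#' average pooling, each in both orientations) plus the batch-normalization
#' layer applied to the four-path sum before the final ReLU.
#'
#' @param conv_max_v,conv_max_h,conv_avg_v,conv_avg_h [conv1x1_params()] for
#'   the four paths.
#' @param bn a [bn_params()] for the post-sum batch normalization.
#' @param N directional kernel length.
#' @param stride downsampling stride applied in both dimensions.
#' @return an object of class `avgmax_vpb_params`.
#' @export
avgmax_vpb_params <- function(conv_max_v, conv_max_h, conv_avg_v, conv_avg_h,
                              bn, N, stride = N) {
  dims <- lapply(list(conv_max_v, conv_max_h, conv_avg_v, conv_avg_h),
                 function(p) dim(p$weights))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop_config("all four path convolutions must share channel counts")
  structure(list(conv_max_v = conv_max_v, conv_max_h = conv_max_h,
                 conv_avg_v = conv_avg_v, conv_avg_h = conv_avg_h,
                 bn = bn, N = as.integer(N), stride = as.integer(stride)),
            class = "avgmax_vpb_params")
}

#' Initialize pooling-block parameters
#'
#' Draws 1x1 convolution weights from a zero-mean Gaussian with variance
#' `2 / channels` (the usual scaling for ReLU networks), zero biases, and —
#' for the AVG-MAX block — identity batch-normalization state. Deterministic
#' given `seed`.
#'
#' @param channels channel count of the feature maps the block will see.
#' @param N directional kernel length.
#' @param stride downsampling stride.
#' @param kind `"vpb"` or `"avgmax"`.
#' @param seed integer seed.
#' @return [vpb_params()] or [avgmax_vpb_params()].
#' @export
init_block_params <- function(channels, N, stride = N,
                              kind = c("vpb", "avgmax"), seed = 1L) {
  kind <- match.arg(kind)
  with_seed(seed, {
    draw <- function() {
      conv1x1_params(matrix(stats::rnorm(channels * channels,
                                         sd = sqrt(2 / channels)),
                            channels, channels))
    }
    if (kind == "vpb") {
      vpb_params(draw(), draw(), N = N, stride = stride)
    } else {
      avgmax_vpb_params(draw(), draw(), draw(), draw(),
                        bn = bn_params(channels), N = N, stride = stride)
    }
  })
}

#' Identity-convolution VPB parameters
#'
#' A [vpb_params()] whose 1x1 convolutions are the identity with zero bias,
#' so the block output exposes the pooling paths directly. Used by the
#' max-pool collision demonstration and the degenerate-limit checks.
#'
#' @param channels channel count.
#' @param N directional kernel length.
#' @param stride downsampling stride.
#' @return a [vpb_params()].
#' @export
identity_vpb_params <- function(channels, N, stride = N) {
  id <- conv1x1_params(diag(channels))
  vpb_params(id, id, N = N, stride = stride)
}

# path = relu(conv1x1(pool(x))); shared by both blocks
.block_path <- function(x4, mode, kh, kw, s, conv, want_cache) {
  pool <- pool2d_forward(x4, mode, kh, kw, s, s, "same_ceil", want_cache)
  z <- conv1x1(pool$out, conv)
  a <- relu(z)
  list(a = a,
       cache = if (want_cache) list(pool = pool$cache, pooled = pool$out,
                                    z = z) else NULL)
}

.block_path_backward <- function(pc, conv, grad) {
  grad <- grad * (pc$z > 0)
  cb <- conv1x1_backward(pc$pooled, conv, grad)
  gx <- pool2d_backward(pc$pool, cb$gx)
  list(gx = gx, gw = cb$gw, gb = cb$gb)
}

#' Vector pooling block forward pass
#'
#' Two parallel paths: the vertical path pools with a `1 x N` max kernel and
#' the horizontal path with `N x 1`, both with stride `(s, s)` and same-ceil
#' padding so their outputs share the shape `(ceil(H/s), ceil(W/s))`. Each
#' path applies a 1x1 convolution and ReLU; the paths are summed elementwise
#' and passed through a final ReLU.
#'
#' @param x feature map (matrix, `C x H x W`, or batch `C x H x W x N`).
#' @param p a [vpb_params()].
#' @param cache if `TRUE`, return `list(out, cache)` where `cache` feeds
#'   [vpb_backward()].
#' @return the output feature map, or `list(out, cache)` when `cache = TRUE`.
#' @examples
#' vpb_forward(matrix(1:4, 2, byrow = TRUE), identity_vpb_params(1, 2))
#' @export
vpb_forward <- function(x, p, cache = FALSE) {
  f <- fm4d(x)
  if (ncol(p$conv_vertical$weights) != dim(f$a)[1])
    stop_config("VPB expects ", ncol(p$conv_vertical$weights),
                " channels, got ", dim(f$a)[1])
  v <- .block_path(f$a, "max", 1L, p$N, p$stride, p$conv_vertical, cache)
  h <- .block_path(f$a, "max", p$N, 1L, p$stride, p$conv_horizontal, cache)
  s <- elementwise_sum(list(v$a, h$a))
  out <- relu(s)
  if (!cache) return(fm_restore(out, f$rank))
  list(out = fm_restore(out, f$rank),
       cache = list(v = v$cache, h = h$cache, s = s, p = p,
                    rank = f$rank, dims = dim(f$a)))
}

#' Vector pooling block backward pass
#'
#' Reverse-mode gradients of a scalar loss through [vpb_forward()]: ReLU
#' gate masks, summation fan-out, 1x1 convolution transpose rules and
#' max-pool routing to the first maximal cell in row-major window order.
#'
#' @param cache the cache returned by `vpb_forward(..., cache = TRUE)`.
#' @param grad_out gradient of the loss w.r.t. the block output (same shape).
#' @return list with `grad_input` (shape of the block input) and
#'   `grad_params` (list mirroring [vpb_params()]: `conv_vertical` and
#'   `conv_horizontal`, each with `gw`, `gb`).
#' @export
vpb_backward <- function(cache, grad_out) {
  if (is.null(cache$v) || is.null(cache$v$pool))
    stop_usage("vpb_backward needs the cache from vpb_forward(cache = TRUE)")
  g <- fm4d_grad(grad_out, dim(cache$s))
  g <- g * (cache$s > 0)
  bv <- .block_path_backward(cache$v, cache$p$conv_vertical, g)
  bh <- .block_path_backward(cache$h, cache$p$conv_horizontal, g)
  grad_input <- bv$gx + bh$gx
  list(grad_input = fm_restore(grad_input, cache$rank),
       grad_params = list(conv_vertical = list(gw = bv$gw, gb = bv$gb),
                          conv_horizontal = list(gw = bh$gw, gb = bh$gb)))
}

# coerce a gradient array to the 4D shape of the forward output
fm4d_grad <- function(g, d4) {
  if (is.null(dim(g))) stop_usage("grad_out must be a matrix or array")
  if (prod(dim(g)) != prod(d4))
    stop_usage("grad_out shape does not match the forward output")
  dim(g) <- d4
  g
}

#' AVG-MAX vector pooling block forward pass
#'
#' Four parallel paths — max-vertical `1 x N`, max-horizontal `N x 1`,
#' avg-vertical `1 x N`, avg-horizontal `N x 1` — each pooled with stride
#' `(s, s)` and same-ceil padding, then 1x1 convolution and ReLU. The four
#' path outputs are summed elementwise, batch-normalized, and passed through
#' a final ReLU.
#'
#' @param x batch of feature maps (`C x H x W x N` array; lower ranks are a
#'   batch of one).
#' @param p an [avgmax_vpb_params()].
#' @param mode `"train"` (batch statistics, running stats updated) or
#'   `"infer"` (running statistics).
#' @param cache if `TRUE`, also return the backward cache.
#' @return list with `out`, `params` (updated BN running statistics) and,
#'   when requested, `cache` for [avgmax_vpb_backward()].
#' @export
avgmax_vpb_forward <- function(x, p, mode = c("train", "infer"),
                               cache = FALSE) {
  mode <- match.arg(mode)
  f <- fm4d(x)
  if (ncol(p$conv_max_v$weights) != dim(f$a)[1])
    stop_config("AVG-MAX VPB expects ", ncol(p$conv_max_v$weights),
                " channels, got ", dim(f$a)[1])
  mv <- .block_path(f$a, "max", 1L, p$N, p$stride, p$conv_max_v, cache)
  mh <- .block_path(f$a, "max", p$N, 1L, p$stride, p$conv_max_h, cache)
  av <- .block_path(f$a, "avg", 1L, p$N, p$stride, p$conv_avg_v, cache)
  ah <- .block_path(f$a, "avg", p$N, 1L, p$stride, p$conv_avg_h, cache)
  s <- elementwise_sum(list(mv$a, mh$a, av$a, ah$a))
  bn <- bn_forward(s, p$bn, mode, want_cache = cache)
  out <- relu(bn$out)
  p$bn <- bn$params
  res <- list(out = fm_restore(out, f$rank), params = p)
  if (cache) {
    res$cache <- list(mv = mv$cache, mh = mh$cache, av = av$cache,
                      ah = ah$cache, bn = bn$cache, bn_out = bn$out,
                      p = p, rank = f$rank)
  }
  res
}

#' AVG-MAX vector pooling block backward pass
#'
#' Reverse-mode gradients through [avgmax_vpb_forward()], including the
#' train-mode batch-normalization gradient, average-pool uniform spreading
#' over non-padded cells and max-pool argmax routing.
#'
#' @param cache cache from `avgmax_vpb_forward(..., cache = TRUE)`.
#' @param grad_out gradient w.r.t. the block output.
#' @return list with `grad_input` and `grad_params` (per-path `gw`/`gb` plus
#'   `bn` with `ggamma`, `gbeta`).
#' @export
avgmax_vpb_backward <- function(cache, grad_out) {
  if (is.null(cache$bn))
    stop_usage("avgmax_vpb_backward needs the cache from avgmax_vpb_forward(cache = TRUE)")
  g <- fm4d_grad(grad_out, dim(cache$bn_out))
  g <- g * (cache$bn_out > 0)
  bnb <- bn_backward(cache$bn, g)
  gz <- bnb$gx
  p <- cache$p
  bmv <- .block_path_backward(cache$mv, p$conv_max_v, gz)
  bmh <- .block_path_backward(cache$mh, p$conv_max_h, gz)
  bav <- .block_path_backward(cache$av, p$conv_avg_v, gz)
  bah <- .block_path_backward(cache$ah, p$conv_avg_h, gz)
  grad_input <- bmv$gx + bmh$gx + bav$gx + bah$gx
  list(grad_input = fm_restore(grad_input, cache$rank),
       grad_params = list(
         conv_max_v = list(gw = bmv$gw, gb = bmv$gb),
         conv_max_h = list(gw = bmh$gw, gb = bmh$gb),
         conv_avg_v = list(gw = bav$gw, gb = bav$gb),
         conv_avg_h = list(gw = bah$gw, gb = bah$gb),
         bn = list(ggamma = bnb$ggamma, gbeta = bnb$gbeta)))
}
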
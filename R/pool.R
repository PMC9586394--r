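#' Pooling specification
#'
#' Describes one pooling operation: mode, kernel, stride and padding.
#' Directional kernels have `kh = 1` or `kw = 1`; square kernels are used by
#' the baseline architectures. `padding = "same_ceil"` makes the output
#' `ceil(dim / stride)` along each axis, padding with `-Inf` sentinels for max
#' pooling and excluding padded cells from the mean for average pooling;
#' `"none"` gives the usual `floor((dim - k) / stride) + 1` output.
#'
#' @param mode `"max"` or `"avg"`.
#' @param kernel integer pair `(kh, kw)`.
#' @param stride integer pair `(sh, sw)`; a scalar is recycled.
#' @param padding `"none"` or `"same_ceil"`.
#' @return an object of class `pool_spec`.
#' @examples
#' pool_spec("max", c(1, 2), c(2, 2))
#' @export
pool_spec <- function(mode = c("max", "avg"), kernel, stride = kernel,
                      padding = c("none", "same_ceil")) {
  mode <- match.arg(mode)
  padding <- match.arg(padding)
  kernel <- as.integer(rep(kernel, length.out = 2L))
  stride <- as.integer(rep(stride, length.out = 2L))
  if (any(kernel < 1L) || any(stride < 1L))
    stop_config("pool kernel and stride entries must be >= 1")
  structure(list(mode = mode, kernel = kernel, stride = stride,
                 padding = padding),
            class = "pool_spec")
}

pool_out_dim <- function(dim, k, s, padding) {
  if (padding == "same_ceil") {
    as.integer(ceiling(dim / s))
  } else {
    o <- floor((dim - k) / s) + 1
    if (o < 1) stop_config("pooling window larger than input (dim ", dim,
                           ", kernel ", k, ", padding none)")
    as.integer(o)
  }
}

# Core 2D pooling on a 4D batch array c(C, H, W, N). Returns list(out, cache);
# cache holds what the backward pass needs.
pool2d_forward <- function(x, mode, kh, kw, sh, sw, padding,
                           want_cache = FALSE) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  Ho <- pool_out_dim(H, kh, sh, padding)
  Wo <- pool_out_dim(W, kw, sw, padding)
  if (padding == "same_ceil") {
    ph <- max((Ho - 1L) * sh + kh - H, 0L)
    pw <- max((Wo - 1L) * sw + kw - W, 0L)
  } else {
    ph <- 0L; pw <- 0L
  }
  pt <- ph %/% 2L; pl <- pw %/% 2L
  Hp <- H + ph; Wp <- W + pw
  fill <- if (mode == "max") -Inf else 0
  if (ph > 0L || pw > 0L) {
    xp <- array(fill, c(C, Hp, Wp, N))
    xp[, pt + seq_len(H), pl + seq_len(W), ] <- x
  } else {
    xp <- x
  }
  rows <- function(dh) dh + 1L + (seq_len(Ho) - 1L) * sh
  cols <- function(dw) dw + 1L + (seq_len(Wo) - 1L) * sw
  if (mode == "max") {
    out <- array(-Inf, c(C, Ho, Wo, N))
    for (dh in 0:(kh - 1L)) for (dw in 0:(kw - 1L)) {
      out <- pmax(out, xp[, rows(dh), cols(dw), , drop = FALSE])
    }
    dim(out) <- c(C, Ho, Wo, N)
    if (any(!is.finite(out)))
      stop("internal error: pooling window entirely outside image")
    cnt <- NULL
  } else {
    out <- array(0, c(C, Ho, Wo, N))
    # count of non-padded cells per output position (same for all C, N)
    valid <- array(0, c(1L, Hp, Wp, 1L))
    valid[1L, pt + seq_len(H), pl + seq_len(W), 1L] <- 1
    cnt <- array(0, c(1L, Ho, Wo, 1L))
    for (dh in 0:(kh - 1L)) for (dw in 0:(kw - 1L)) {
      out <- out + xp[, rows(dh), cols(dw), , drop = FALSE]
      cnt <- cnt + valid[, rows(dh), cols(dw), , drop = FALSE]
    }
    if (any(cnt == 0))
      stop("internal error: pooling window entirely outside image")
    out <- pool2d_forward_div(out, cnt, C, Ho, Wo, N)
    dim(out) <- c(C, Ho, Wo, N)
  }
  cache <- NULL
  if (want_cache) {
    cache <- list(mode = mode, kh = kh, kw = kw, sh = sh, sw = sw,
                  padding = padding, dims = d, pt = pt, pl = pl,
                  Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
                  xp = if (mode == "max") xp else NULL,
                  out = if (mode == "max") out else NULL,
                  cnt = cnt)
  }
  list(out = out, cache = cache)
}

# divide each (ho, wo) cell of out by cnt[1, ho, wo, 1] across channels/batch
pool2d_forward_div <- function(out, cnt, C, Ho, Wo, N) {
  cc <- array(rep(cnt[1L, , , 1L], each = C), c(C, Ho, Wo))
  out / as.vector(cc)  # recycles over the batch dimension
}

pool2d_backward <- function(cache, grad_out) {
  C <- cache$dims[1]; H <- cache$dims[2]; W <- cache$dims[3]; N <- cache$dims[4]
  Ho <- cache$Ho; Wo <- cache$Wo
  dim(grad_out) <- c(C, Ho, Wo, N)
  gp <- array(0, c(C, cache$Hp, cache$Wp, N))
  rows <- function(dh) dh + 1L + (seq_len(Ho) - 1L) * cache$sh
  cols <- function(dw) dw + 1L + (seq_len(Wo) - 1L) * cache$sw
  if (cache$mode == "max") {
    # route to the first maximal cell in row-major window order
    routed <- array(FALSE, c(C, Ho, Wo, N))
    for (dh in 0:(cache$kh - 1L)) for (dw in 0:(cache$kw - 1L)) {
      sub <- cache$xp[, rows(dh), cols(dw), , drop = FALSE]
      dim(sub) <- c(C, Ho, Wo, N)
      hit <- (sub == cache$out) & !routed
      if (any(hit)) {
        g <- grad_out * hit
        gp[, rows(dh), cols(dw), ] <- array(gp[, rows(dh), cols(dw), , drop = FALSE], dim(g)) + g
        routed <- routed | hit
      }
    }
  } else {
    cc <- array(rep(cache$cnt[1L, , , 1L], each = C), c(C, Ho, Wo))
    g <- grad_out / as.vector(cc)
    for (dh in 0:(cache$kh - 1L)) for (dw in 0:(cache$kw - 1L)) {
      gp[, rows(dh), cols(dw), ] <- array(gp[, rows(dh), cols(dw), , drop = FALSE], dim(g)) + g
    }
  }
  gp[, cache$pt + seq_len(H), cache$pl + seq_len(W), , drop = FALSE]
}

#' Directional pooling
#'
#' Applies max or average pooling with a directional kernel (`1 x N` along
#' rows or `N x 1` along columns) to a feature map. Directional pooling with
#' stride in both dimensions is the downsampling primitive inside the vector
#' pooling blocks: a long kernel in one orientation collects extended
#' structure while the unit extent in the other keeps local detail.
#'
#' @param x feature map (matrix, `C x H x W` array, or `C x H x W x N` batch).
#' @param spec a [pool_spec()] whose kernel has `kh = 1` or `kw = 1`.
#' @return pooled feature map of the same rank as `x`.
#' @examples
#' pool_directional(matrix(1:4, 2, byrow = TRUE), pool_spec("max", c(1, 2), 2))
#' @export
pool_directional <- function(x, spec) {
  if (!inherits(spec, "pool_spec")) stop_config("spec must be a pool_spec")
  if (spec$kernel[1] != 1L && spec$kernel[2] != 1L)
    stop_config("directional pooling requires kernel height or width 1, got ",
                paste(spec$kernel, collapse = "x"))
  f <- fm4d(x)
  out <- pool2d_forward(f$a, spec$mode, spec$kernel[1], spec$kernel[2],
                        spec$stride[1], spec$stride[2], spec$padding)$out
  fm_restore(out, f$rank)
}

#' Square or directional pooling
#'
#' General pooling entry point used by the network executor; accepts any
#' [pool_spec()] including square kernels.
#'
#' @inheritParams pool_directional
#' @param spec a [pool_spec()].
#' @return pooled feature map of the same rank as `x`.
#' @export
pool_apply <- function(x, spec) {
  if (!inherits(spec, "pool_spec")) stop_config("spec must be a pool_spec")
  f <- fm4d(x)
  out <- pool2d_forward(f$a, spec$mode, spec$kernel[1], spec$kernel[2],
                        spec$stride[1], spec$stride[2], spec$padding)$out
  fm_restore(out, f$rank)
}
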
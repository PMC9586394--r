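#' 1x1 convolution parameters
#'
#' Channel-mixing weights and bias for a pointwise convolution. Inside the
#' pooling blocks the output channel count equals the input channel count, so
#' the block preserves channel dimensionality.
#'
#' @param weights `out_channels x in_channels` numeric matrix.
#' @param bias numeric vector of length `out_channels` (default zeros).
#' @return an object of class `conv1x1_params`.
#' @examples
#' conv1x1_params(diag(2))
#' @export
conv1x1_params <- function(weights, bias = numeric(nrow(weights))) {
  weights <- as.matrix(weights)
  if (length(bias) != nrow(weights))
    stop_config("bias length must equal the number of output channels")
  if (!all(is.finite(weights)) || !all(is.finite(bias)))
    stop_config("conv1x1 parameters must be finite")
  structure(list(weights = weights, bias = as.numeric(bias)),
            class = "conv1x1_params")
}

#' Pointwise (1x1) convolution
#'
#' Applies `out[c, i, j] = bias[c] + sum_d weights[c, d] * x[d, i, j]` at
#' every spatial position; spatial dimensions are unchanged.
#'
#' @param x feature map (matrix, `C x H x W`, or `C x H x W x N`).
#' @param p a [conv1x1_params()] with `in_channels` matching `x`.
#' @return feature map with `nrow(p$weights)` channels.
#' @examples
#' conv1x1(array(1:4, c(1, 2, 2)), conv1x1_params(matrix(2), bias = 1))
#' @export
conv1x1 <- function(x, p) {
  f <- fm4d(x)
  d <- dim(f$a)
  if (ncol(p$weights) != d[1])
    stop_config("conv1x1 expects ", ncol(p$weights), " input channels, got ",
                d[1])
  xm <- matrix(f$a, nrow = d[1])
  out <- p$weights %*% xm + p$bias
  dim(out) <- c(nrow(p$weights), d[2], d[3], d[4])
  fm_restore(out, f$rank)
}

# backward of conv1x1: returns grads wrt weights, bias and input (all 4D x)
conv1x1_backward <- function(x4, p, grad_out4) {
  d <- dim(x4)
  xm <- matrix(x4, nrow = d[1])
  gm <- matrix(grad_out4, nrow = nrow(p$weights))
  gw <- gm %*% t(xm)
  gb <- rowSums(gm)
  gx <- t(p$weights) %*% gm
  dim(gx) <- d
  list(gw = gw, gb = gb, gx = gx)
}

# --- general k x k convolution (zero "same" padding, configurable stride) ---
# Weights: array c(Cout, Cin, kh, kw); flattening order matches im2col rows.

conv2d_forward <- function(x, w, b, stride = 1L, want_cache = FALSE) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  dw <- dim(w)
  if (dw[2] != C) stop_config("conv2d channel mismatch: weights expect ",
                              dw[2], ", input has ", C)
  kh <- dw[3]; kw <- dw[4]; s <- as.integer(stride)
  Ho <- as.integer(ceiling(H / s)); Wo <- as.integer(ceiling(W / s))
  ph <- max((Ho - 1L) * s + kh - H, 0L)
  pw <- max((Wo - 1L) * s + kw - W, 0L)
  pt <- ph %/% 2L; pl <- pw %/% 2L
  Hp <- H + ph; Wp <- W + pw
  xp <- array(0, c(C, Hp, Wp, N))
  xp[, pt + seq_len(H), pl + seq_len(W), ] <- x
  L <- Ho * Wo * N
  P <- array(0, c(C, kh, kw, L))
  rows <- function(dh) dh + 1L + (seq_len(Ho) - 1L) * s
  cols <- function(dw_) dw_ + 1L + (seq_len(Wo) - 1L) * s
  for (j in 0:(kw - 1L)) for (i in 0:(kh - 1L)) {
    P[, i + 1L, j + 1L, ] <- xp[, rows(i), cols(j), ]
  }
  Pm <- matrix(P, nrow = C * kh * kw)
  Wm <- matrix(w, nrow = dw[1])
  out <- Wm %*% Pm + b
  dim(out) <- c(dw[1], Ho, Wo, N)
  cache <- NULL
  if (want_cache)
    cache <- list(Pm = Pm, dims = d, dw = dw, s = s, pt = pt, pl = pl,
                  Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  list(out = out, cache = cache)
}

conv2d_backward <- function(cache, w, grad_out) {
  dw <- cache$dw
  C <- cache$dims[1]; H <- cache$dims[2]; W <- cache$dims[3]; N <- cache$dims[4]
  kh <- dw[3]; kw <- dw[4]
  Ho <- cache$Ho; Wo <- cache$Wo
  gm <- matrix(grad_out, nrow = dw[1])
  gw <- gm %*% t(cache$Pm)
  dim(gw) <- dw
  gb <- rowSums(gm)
  Wm <- matrix(w, nrow = dw[1])
  gP <- t(Wm) %*% gm                       # (C*kh*kw) x L
  dim(gP) <- c(C, kh, kw, Ho, Wo, N)
  gxp <- array(0, c(C, cache$Hp, cache$Wp, N))
  rows <- function(dh) dh + 1L + (seq_len(Ho) - 1L) * cache$s
  cols <- function(dw_) dw_ + 1L + (seq_len(Wo) - 1L) * cache$s
  for (j in 0:(kw - 1L)) for (i in 0:(kh - 1L)) {
    g <- gP[, i + 1L, j + 1L, , , , drop = FALSE]
    dim(g) <- c(C, Ho, Wo, N)
    gxp[, rows(i), cols(j), ] <- array(gxp[, rows(i), cols(j), , drop = FALSE], dim(g)) + g
  }
  gx <- gxp[, cache$pt + seq_len(H), cache$pl + seq_len(W), , drop = FALSE]
  list(gw = gw, gb = gb, gx = gx)
}

# --- dense (fully connected) layer on flattened feature maps ---

dense_forward <- function(x, w, b, want_cache = FALSE) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[4])
  if (nrow(xm) != ncol(w))
    stop_config("dense layer expects ", ncol(w), " inputs, got ", nrow(xm))
  out <- w %*% xm + b
  dim(out) <- c(nrow(w), 1L, 1L, d[4])
  list(out = out,
       cache = if (want_cache) list(xm = xm, dims = d) else NULL)
}

dense_backward <- function(cache, w, grad_out) {
  gm <- matrix(grad_out, nrow = nrow(w))
  gw <- gm %*% t(cache$xm)
  gb <- rowSums(gm)
  gx <- t(w) %*% gm
  dim(gx) <- cache$dims
  list(gw = gw, gb = gb, gx = gx)
}
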
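# Independent oracles used across the test suite. These are deliberately
# naive loop implementations, coded separately from the package internals.

# exhaustive window-enumeration pooling oracle on a single C x H x W array
oracle_pool <- function(x, mode, kh, kw, sh, sw, padding = "same_ceil") {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]
  if (padding == "same_ceil") {
    Ho <- ceiling(H / sh); Wo <- ceiling(W / sw)
    ph <- max((Ho - 1) * sh + kh - H, 0)
    pw <- max((Wo - 1) * sw + kw - W, 0)
    pt <- ph %/% 2; pl <- pw %/% 2
  } else {
    Ho <- floor((H - kh) / sh) + 1; Wo <- floor((W - kw) / sw) + 1
    pt <- 0; pl <- 0
  }
  out <- array(NA_real_, c(C, Ho, Wo))
  for (c in seq_len(C)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    rs <- (i - 1) * sh + seq_len(kh) - pt
    cs <- (j - 1) * sw + seq_len(kw) - pl
    rs <- rs[rs >= 1 & rs <= H]; cs <- cs[cs >= 1 & cs <= W]
    v <- as.vector(x[c, rs, cs])
    out[c, i, j] <- if (mode == "max") max(v) else mean(v)
  }
  out
}

# per-pixel matrix-vector 1x1 convolution oracle
oracle_conv1x1 <- function(x, w, b) {
  d <- dim(x)
  out <- array(NA_real_, c(nrow(w), d[2], d[3]))
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    out[, i, j] <- w %*% x[, i, j] + b
  }
  out
}

# straight-line transcription of the two-path block:
# y_vertical  = relu(conv1x1(max_pool_1xN(x)))
# y_horizontal= relu(conv1x1(max_pool_Nx1(x)))
# y_output    = relu(y_vertical + y_horizontal)
oracle_vpb <- function(x, p) {
  r <- function(a) { a[a < 0] <- 0; a }
  yv <- r(oracle_conv1x1(oracle_pool(x, "max", 1, p$N, p$stride, p$stride),
                         p$conv_vertical$weights, p$conv_vertical$bias))
  yh <- r(oracle_conv1x1(oracle_pool(x, "max", p$N, 1, p$stride, p$stride),
                         p$conv_horizontal$weights, p$conv_horizontal$bias))
  r(yv + yh)
}

# straight-line transcription of the four-path block with batch
# normalization (inference statistics) inserted before the final relu:
# y = relu(BN(y_max_v + y_max_h + y_avg_v + y_avg_h))
oracle_avgmax_vpb_infer <- function(x, p) {
  r <- function(a) { a[a < 0] <- 0; a }
  path <- function(mode, kh, kw, conv)
    r(oracle_conv1x1(oracle_pool(x, mode, kh, kw, p$stride, p$stride),
                     conv$weights, conv$bias))
  s <- path("max", 1, p$N, p$conv_max_v) + path("max", p$N, 1, p$conv_max_h) +
    path("avg", 1, p$N, p$conv_avg_v) + path("avg", p$N, 1, p$conv_avg_h)
  bn <- p$bn
  for (c in seq_len(dim(s)[1])) {
    s[c, , ] <- bn$gamma[c] * (s[c, , ] - bn$running_mean[c]) /
      sqrt(bn$running_var[c] + bn$eps) + bn$beta[c]
  }
  r(s)
}

# central finite differences of a scalar function at selected indices of an
# array-valued argument
fd_grad <- function(f, x, idx = seq_along(x), h = 1e-6) {
  g <- numeric(length(idx))
  for (k in seq_along(idx)) {
    xp <- x; xp[idx[k]] <- xp[idx[k]] + h
    xm <- x; xm[idx[k]] <- xm[idx[k]] - h
    g[k] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

max_rel_err <- function(analytic, numeric, floor = 1e-8) {
  max(abs(analytic - numeric) / pmax(floor, abs(numeric)))
}

# in-memory synthetic dataset helper shared by the pipeline tests
make_synth_set <- function(seeds, labels, size = c(64L, 64L)) {
  H <- size[1]; W <- size[2]
  x <- array(0, c(H, W, length(seeds)))
  m <- array(0L, c(H, W, length(seeds)))
  for (i in seq_along(seeds)) {
    s <- generate_sample(seeds[i], labels[i], size)
    x[, , i] <- s$image
    m[, , i] <- s$mask
  }
  list(x = x, masks = m, labels = labels)
}
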
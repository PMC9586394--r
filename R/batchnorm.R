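#' Batch-normalization parameters
#'
#' Per-channel scale (`gamma`), shift (`beta`), running statistics and the
#' numerical constants of a batch-normalization layer.
#'
#' @param channels number of channels `C`.
#' @param gamma,beta numeric vectors of length `channels`.
#' @param running_mean,running_var running statistics (defaults 0 and 1).
#' @param eps small positive constant added to the variance.
#' @param momentum exponential moving-average weight in `(0, 1)` used to
#'   update running statistics in training mode.
#' @return an object of class `bn_params`.
#' @export
bn_params <- function(channels, gamma = rep(1, channels),
                      beta = rep(0, channels),
                      running_mean = rep(0, channels),
                      running_var = rep(1, channels),
                      eps = 1e-5, momentum = 0.1) {
  stopifnot(length(gamma) == channels, length(beta) == channels,
            length(running_mean) == channels, length(running_var) == channels)
  if (eps <= 0) stop_config("bn eps must be positive")
  if (momentum <= 0 || momentum >= 1) stop_config("bn momentum must be in (0,1)")
  if (any(running_var < 0)) stop_config("running_var must be nonnegative")
  structure(list(gamma = as.numeric(gamma), beta = as.numeric(beta),
                 running_mean = as.numeric(running_mean),
                 running_var = as.numeric(running_var),
                 eps = eps, momentum = momentum),
            class = "bn_params")
}

# core on 4D arrays; returns out, updated params, cache for backward
bn_forward <- function(x4, p, mode = c("train", "infer"), want_cache = FALSE) {
  mode <- match.arg(mode)
  d <- dim(x4)
  C <- d[1]
  m <- prod(d[-1])
  if (mode == "train" && m == 0) stop_config("batch_norm: empty batch")
  xm <- matrix(x4, nrow = C)
  if (mode == "train") {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc * xc)          # biased (1/m) variance
    p$running_mean <- (1 - p$momentum) * p$running_mean + p$momentum * mu
    p$running_var <- (1 - p$momentum) * p$running_var + p$momentum * va
  } else {
    mu <- p$running_mean
    va <- p$running_var
    xc <- xm - mu
  }
  istd <- 1 / sqrt(va + p$eps)
  xhat <- xc * istd
  out <- p$gamma * xhat + p$beta
  dim(out) <- d
  cache <- NULL
  if (want_cache)
    cache <- list(xhat = xhat, istd = istd, dims = d, mode = mode,
                  gamma = p$gamma)
  list(out = out, params = p, cache = cache)
}

bn_backward <- function(cache, grad_out) {
  d <- cache$dims
  C <- d[1]
  gm <- matrix(grad_out, nrow = C)
  ggamma <- rowSums(gm * cache$xhat)
  gbeta <- rowSums(gm)
  if (cache$mode == "train") {
    m <- prod(d[-1])
    gx <- (cache$gamma * cache$istd) *
      (gm - gbeta / m - cache$xhat * (ggamma / m))
  } else {
    gx <- (cache$gamma * cache$istd) * gm
  }
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

#' Batch normalization
#'
#' Normalizes each channel of a batch of feature maps. In training mode the
#' batch statistics over (batch, H, W) are used and the running statistics
#' are updated by an exponential moving average with the configured momentum;
#' in inference mode the stored running statistics are used.
#'
#' @param x batch of feature maps (`C x H x W x N` array; lower ranks are
#'   treated as a batch of one).
#' @param p a [bn_params()].
#' @param mode `"train"` or `"infer"`.
#' @return a list with `out` (same rank as `x`) and `params` (the updated
#'   [bn_params()]).
#' @export
batch_norm <- function(x, p, mode = c("train", "infer")) {
  f <- fm4d(x)
  r <- bn_forward(f$a, p, mode)
  list(out = fm_restore(r$out, f$rank), params = r$params)
}
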
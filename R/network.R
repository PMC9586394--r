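# Network executor: forward, backward and parameter initialization for
# arch_spec networks. Feature maps flow as 4D arrays c(C, H, W, N).

#' Initialize network parameters
#'
#' He-style initialization for every parametric layer of an architecture:
#' convolution weights are zero-mean Gaussian with variance `2 / fan_in`,
#' biases zero; pooling blocks use [init_block_params()]; batch-norm layers
#' start at identity. Deterministic given `seed` (each layer draws from a
#' seed derived from `seed` and its position).
#'
#' @param arch an [arch_spec()].
#' @param seed integer seed.
#' @return named list of per-layer parameter lists.
#' @export
init_network_params <- function(arch, seed = 1L) {
  sh <- arch_shapes(arch)
  params <- list()
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    lseed <- (seed * 131L + i) %% .Machine$integer.max
    inshape <- if (l$kind == "input") NULL else sh[[l$inputs[1]]]
    params[[l$name]] <- switch(l$kind,
      conv = with_seed(lseed, {
        k <- l$cfg$kernel
        fan <- inshape[1] * k * k
        list(w = array(stats::rnorm(l$cfg$out_channels * fan,
                                    sd = sqrt(2 / fan)),
                       c(l$cfg$out_channels, inshape[1], k, k)),
             b = numeric(l$cfg$out_channels))
      }),
      dense = with_seed(lseed, {
        fan <- prod(inshape)
        list(w = matrix(stats::rnorm(l$cfg$units * fan, sd = sqrt(2 / fan)),
                        l$cfg$units, fan),
             b = numeric(l$cfg$units))
      }),
      vpb = init_block_params(inshape[1], l$cfg$N, l$cfg$stride, "vpb",
                              seed = if (is.null(l$cfg$init_seed)) lseed
                                     else l$cfg$init_seed),
      avgmax_vpb = init_block_params(inshape[1], l$cfg$N, l$cfg$stride,
                                     "avgmax",
                                     seed = if (is.null(l$cfg$init_seed)) lseed
                                            else l$cfg$init_seed),
      bn = bn_params(inshape[1]),
      NULL)
  }
  params
}

softmax_channels <- function(x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1])
  xm <- xm - rep(apply(xm, 2, max), each = d[1])
  e <- exp(xm)
  p <- e / rep(colSums(e), each = d[1])
  dim(p) <- d
  p
}

#' Run a network forward
#'
#' Executes an architecture on a batch. In `"train"` mode batch-norm layers
#' (including those inside AVG-MAX blocks) use batch statistics and update
#' their running averages; with `want_cache = TRUE` every layer retains the
#' intermediates its backward pass needs.
#'
#' @param arch an [arch_spec()].
#' @param params parameters from [init_network_params()].
#' @param x input batch: `C x H x W x N` array (or a single map).
#' @param mode `"train"` or `"infer"`.
#' @param want_cache keep intermediates for [backward_network()].
#' @return list with `out` (the final layer's 4D output), `values` (per-layer
#'   outputs), `params` (possibly updated running statistics) and `caches`.
#' @export
forward_network <- function(arch, params, x, mode = c("infer", "train"),
                            want_cache = FALSE) {
  mode <- match.arg(mode)
  f <- fm4d(x)
  if (!identical(dim(f$a)[1:3], as.integer(arch$input_shape)))
    stop_config("input shape ", paste(dim(f$a)[1:3], collapse = "x"),
                " does not match architecture input ",
                paste(arch$input_shape, collapse = "x"))
  values <- list()
  caches <- list()
  for (l in arch$layers) {
    inx <- lapply(l$inputs, function(n) values[[n]])
    v <- switch(l$kind,
      input = f$a,
      conv = {
        st <- if (is.null(l$cfg$stride)) 1L else l$cfg$stride
        r <- conv2d_forward(inx[[1]], params[[l$name]]$w, params[[l$name]]$b,
                            st, want_cache)
        caches[[l$name]] <- r$cache
        r$out
      },
      relu = relu(inx[[1]]),
      pool = {
        sp <- l$cfg$spec
        r <- pool2d_forward(inx[[1]], sp$mode, sp$kernel[1], sp$kernel[2],
                            sp$stride[1], sp$stride[2], sp$padding,
                            want_cache)
        caches[[l$name]] <- r$cache
        r$out
      },
      vpb = {
        r <- vpb_forward(inx[[1]], params[[l$name]], cache = want_cache)
        if (want_cache) { caches[[l$name]] <- r$cache; r$out } else r
      },
      avgmax_vpb = {
        r <- avgmax_vpb_forward(inx[[1]], params[[l$name]], mode,
                                cache = want_cache)
        params[[l$name]] <- r$params
        if (want_cache) caches[[l$name]] <- r$cache
        r$out
      },
      bn = {
        r <- bn_forward(inx[[1]], params[[l$name]], mode, want_cache)
        params[[l$name]] <- r$params
        caches[[l$name]] <- r$cache
        r$out
      },
      upsample = {
        d <- dim(inx[[1]])
        inx[[1]][, rep(seq_len(d[2]), each = 2L),
                 rep(seq_len(d[3]), each = 2L), , drop = FALSE]
      },
      concat_skip = {
        a <- inx[[1]]; b <- inx[[2]]
        da <- dim(a); db <- dim(b)
        a <- a[, seq_len(db[2]), seq_len(db[3]), , drop = FALSE]
        out <- array(0, c(da[1] + db[1], db[2], db[3], db[4]))
        out[seq_len(da[1]), , , ] <- a
        out[da[1] + seq_len(db[1]), , , ] <- b
        caches[[l$name]] <- list(da = da, db = db)
        out
      },
      dense = {
        r <- dense_forward(inx[[1]], params[[l$name]]$w, params[[l$name]]$b,
                           want_cache)
        caches[[l$name]] <- r$cache
        r$out
      },
      softmax = softmax_channels(inx[[1]]))
    values[[l$name]] <- v
  }
  list(out = values[[arch$layers[[length(arch$layers)]]$name]],
       values = values, params = params, caches = caches)
}

# relu backward needs the forward output; fetch from values
#' Run a network backward under cross-entropy loss
#'
#' Computes gradients of the mean cross-entropy between the final softmax
#' output and one-hot targets with respect to every trainable parameter.
#'
#' @param arch an [arch_spec()].
#' @param params network parameters.
#' @param fw result of `forward_network(..., want_cache = TRUE)`.
#' @param target one-hot array shaped like the network output.
#' @return list with `loss`, `grads` (named per layer) and `grad_input`.
#' @export
backward_network <- function(arch, params, fw, target) {
  layers <- arch$layers
  last <- layers[[length(layers)]]
  if (last$kind != "softmax")
    stop_config("cross-entropy backward expects a final softmax layer")
  p <- fw$out
  m <- prod(dim(p)[-1])  # pixels (or 1) times batch
  loss <- -sum(log(pmax(p, 1e-12)) * target) / m
  if (!is.finite(loss)) stop_data("NaN/Inf loss: training diverged")
  gacc <- list()
  add_grad <- function(gacc, name, g) {
    gacc[[name]] <- if (is.null(gacc[[name]])) g else gacc[[name]] + g
    gacc
  }
  # fused softmax + CE seed gradient
  gacc[[last$inputs[1]]] <- (p - target) / m
  grads <- list()
  for (i in rev(seq_along(layers))[-1]) {
    l <- layers[[i]]
    g <- gacc[[l$name]]
    if (is.null(g)) next
    if (l$kind == "input") next
    v_in <- fw$values[[l$inputs[1]]]
    switch(l$kind,
      conv = {
        r <- conv2d_backward(fw$caches[[l$name]], params[[l$name]]$w, g)
        grads[[l$name]] <- list(w = r$gw, b = r$gb)
        gacc <- add_grad(gacc, l$inputs[1], r$gx)
      },
      relu = {
        gacc <- add_grad(gacc, l$inputs[1], g * (fw$values[[l$name]] > 0))
      },
      pool = {
        gacc <- add_grad(gacc, l$inputs[1],
                         pool2d_backward(fw$caches[[l$name]], g))
      },
      vpb = {
        r <- vpb_backward(fw$caches[[l$name]], g)
        grads[[l$name]] <- r$grad_params
        gacc <- add_grad(gacc, l$inputs[1], r$grad_input)
      },
      avgmax_vpb = {
        r <- avgmax_vpb_backward(fw$caches[[l$name]], g)
        grads[[l$name]] <- r$grad_params
        gacc <- add_grad(gacc, l$inputs[1], r$grad_input)
      },
      bn = {
        r <- bn_backward(fw$caches[[l$name]], g)
        grads[[l$name]] <- list(gamma = r$ggamma, beta = r$gbeta)
        gacc <- add_grad(gacc, l$inputs[1], r$gx)
      },
      upsample = {
        d <- dim(v_in)
        gi <- array(0, d)
        for (dh in 1:2) for (dw in 1:2) {
          sub <- g[, seq(dh, 2L * d[2], by = 2L), seq(dw, 2L * d[3], by = 2L),
                   , drop = FALSE]
          gi <- gi + array(sub, d)
        }
        gacc <- add_grad(gacc, l$inputs[1], gi)
      },
      concat_skip = {
        cc <- fw$caches[[l$name]]
        ga <- array(0, cc$da)
        ga[, seq_len(cc$db[2]), seq_len(cc$db[3]), ] <-
          g[seq_len(cc$da[1]), , , , drop = FALSE]
        gb <- g[cc$da[1] + seq_len(cc$db[1]), , , , drop = FALSE]
        dim(gb) <- cc$db
        gacc <- add_grad(gacc, l$inputs[1], ga)
        gacc <- add_grad(gacc, l$inputs[2], gb)
      },
      dense = {
        r <- dense_backward(fw$caches[[l$name]], params[[l$name]]$w, g)
        grads[[l$name]] <- list(w = r$gw, b = r$gb)
        gacc <- add_grad(gacc, l$inputs[1], r$gx)
      },
      softmax = {
        # softmax layers other than the final fused one: full Jacobian
        pv <- fw$values[[l$name]]
        d <- dim(pv)
        gm <- matrix(g, nrow = d[1]); pm <- matrix(pv, nrow = d[1])
        gi <- pm * (gm - rep(colSums(gm * pm), each = d[1]))
        dim(gi) <- d
        gacc <- add_grad(gacc, l$inputs[1], gi)
      },
      stop_config("no backward rule for layer kind ", l$kind))
  }
  list(loss = loss, grads = grads, grad_input = gacc[[layers[[1]]$name]])
}
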
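#' Layer specification
#'
#' One layer of a declarative architecture. Supported kinds: `input`,
#' `conv` (3x3 zero-padded, optional stride), `relu`, `pool` (any
#' [pool_spec()], with `trailing = TRUE` marking a final global average
#' pool), `vpb`, `avgmax_vpb`, `bn`, `upsample` (nearest-neighbour x2),
#' `concat_skip` (channel concatenation, cropping the first input to the
#' second's spatial size), `dense` and `softmax` (channelwise).
#'
#' @param name unique layer name.
#' @param kind layer kind (see above).
#' @param inputs names of the layers feeding this one (default: the previous
#'   layer in the list).
#' @param ... kind-specific configuration (`out_channels`, `kernel`,
#'   `stride`, `spec`, `N`, `units`, `trailing`, ...).
#' @return an object of class `layer_spec`.
#' @export
layer_spec <- function(name, kind, inputs = NULL, ...) {
  kinds <- c("input", "conv", "relu", "pool", "vpb", "avgmax_vpb", "bn",
             "upsample", "concat_skip", "dense", "softmax")
  if (!kind %in% kinds) stop_config("unknown layer kind: ", kind)
  structure(list(name = name, kind = kind, inputs = inputs, cfg = list(...)),
            class = "layer_spec")
}

#' Architecture specification
#'
#' An ordered, acyclic list of [layer_spec()]s. Layers appear in executable
#' order; a layer without explicit `inputs` consumes the previous layer.
#'
#' @param layers list of [layer_spec()]s, the first of kind `input`.
#' @param task `"segmentation"` or `"classification"`.
#' @param input_shape `c(C, H, W)` of the network input.
#' @return an object of class `arch_spec`.
#' @export
arch_spec <- function(layers, task = c("segmentation", "classification"),
                      input_shape) {
  task <- match.arg(task)
  nms <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_config("layer names must be unique")
  if (layers[[1]]$kind != "input") stop_config("first layer must be input")
  seen <- character(0)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (is.null(l$inputs) && i > 1L) layers[[i]]$inputs <- nms[i - 1L]
    if (i > 1L && !all(layers[[i]]$inputs %in% seen))
      stop_config("layer '", l$name, "' consumes a later or unknown layer")
    seen <- c(seen, l$name)
  }
  structure(list(layers = layers, task = task,
                 input_shape = as.integer(input_shape)),
            class = "arch_spec")
}

#' @export
print.arch_spec <- function(x, ...) {
  cat("arch_spec (", x$task, "), input ",
      paste(x$input_shape, collapse = "x"), "\n", sep = "")
  sh <- arch_shapes(x)
  for (l in x$layers) {
    cat(sprintf("  %-14s %-12s -> %s\n", l$name, l$kind,
                paste(sh[[l$name]], collapse = "x")))
  }
  invisible(x)
}

# shape propagation / dry-run check; returns named list of c(C,H,W)
arch_shapes <- function(arch) {
  sh <- list()
  for (l in arch$layers) {
    s <- switch(l$kind,
      input = arch$input_shape,
      conv = {
        i <- sh[[l$inputs[1]]]
        st <- if (is.null(l$cfg$stride)) 1L else l$cfg$stride
        c(l$cfg$out_channels, ceiling(i[2] / st), ceiling(i[3] / st))
      },
      relu = , bn = , softmax = sh[[l$inputs[1]]],
      pool = {
        i <- sh[[l$inputs[1]]]
        sp <- l$cfg$spec
        c(i[1],
          pool_out_dim(i[2], sp$kernel[1], sp$stride[1], sp$padding),
          pool_out_dim(i[3], sp$kernel[2], sp$stride[2], sp$padding))
      },
      vpb = , avgmax_vpb = {
        i <- sh[[l$inputs[1]]]
        c(i[1], ceiling(i[2] / l$cfg$stride), ceiling(i[3] / l$cfg$stride))
      },
      upsample = {
        i <- sh[[l$inputs[1]]]
        c(i[1], i[2] * 2L, i[3] * 2L)
      },
      concat_skip = {
        a <- sh[[l$inputs[1]]]; b <- sh[[l$inputs[2]]]
        if (a[2] < b[2] || a[3] < b[3])
          stop_config("surgery/shape error at layer '", l$name,
                      "': upsampled path ", paste(a, collapse = "x"),
                      " smaller than skip ", paste(b, collapse = "x"))
        c(a[1] + b[1], b[2], b[3])
      },
      dense = c(l$cfg$units, 1L, 1L),
      stop_config("unknown layer kind: ", l$kind))
    sh[[l$name]] <- as.integer(s)
  }
  sh
}

#' Dry-run shape check
#'
#' Propagates shapes through an architecture, raising a configuration error
#' on any inconsistency (e.g. a block whose output no longer matches a skip
#' connection after surgery).
#'
#' @param arch an [arch_spec()].
#' @return invisibly, the named list of layer output shapes `c(C, H, W)`.
#' @export
check_shapes <- function(arch) {
  invisible(arch_shapes(arch))
}

#' Build a mini U-Net
#'
#' Encoder-decoder segmentation network with `depth` 2x2-stride-2 max-pool
#' layers, two 3x3 convolutions per level, nearest-neighbour upsampling with
#' skip concatenations, and a final per-pixel 2-class softmax. `depth = 4`
#' matches the original U-Net pool count; the desk-scale default elsewhere
#' in the package is `depth = 2` with narrow channels.
#'
#' @param depth number of pooling stages (>= 1).
#' @param base_channels channels of the first encoder level; doubled per
#'   level.
#' @param input_size `c(H, W)` of the (single-channel) input image.
#' @param classes number of output classes.
#' @return an [arch_spec()] with task `"segmentation"`.
#' @export
build_unet <- function(depth = 4L, base_channels = 8L,
                       input_size = c(64L, 64L), classes = 2L) {
  if (depth < 1L) stop_config("depth must be >= 1")
  L <- list(layer_spec("in", "input"))
  conv_block <- function(name, ch, from) {
    list(layer_spec(paste0(name, "_c1"), "conv", inputs = from,
                    out_channels = ch, kernel = 3L),
         layer_spec(paste0(name, "_r1"), "relu"),
         layer_spec(paste0(name, "_c2"), "conv", out_channels = ch,
                    kernel = 3L),
         layer_spec(paste0(name, "_r2"), "relu"))
  }
  prev <- "in"
  skips <- character(depth)
  ch <- base_channels
  for (d in seq_len(depth)) {
    L <- c(L, conv_block(paste0("enc", d), ch, prev))
    skips[d] <- paste0("enc", d, "_r2")
    L <- c(L, list(layer_spec(paste0("pool", d), "pool",
                              spec = pool_spec("max", c(2L, 2L), c(2L, 2L),
                                               "same_ceil"))))
    prev <- paste0("pool", d)
    ch <- ch * 2L
  }
  L <- c(L, conv_block("bott", ch, prev))
  prev <- "bott_r2"
  for (d in rev(seq_len(depth))) {
    ch <- ch %/% 2L
    L <- c(L, list(
      layer_spec(paste0("up", d), "upsample", inputs = prev),
      layer_spec(paste0("cat", d), "concat_skip",
                 inputs = c(paste0("up", d), skips[d]))))
    L <- c(L, conv_block(paste0("dec", d), ch, paste0("cat", d)))
    prev <- paste0("dec", d, "_r2")
  }
  L <- c(L, list(
    layer_spec("logits", "conv", inputs = prev, out_channels = classes,
               kernel = 1L),
    layer_spec("probs", "softmax")))
  arch <- arch_spec(L, "segmentation", c(1L, input_size))
  check_shapes(arch)
  arch
}

#' Build a mini classification backbone
#'
#' Small convolutional classifiers whose pooling inventory matches the named
#' full-size backbone: `alexnet_like` has three 3x3 max pools;
#' `resnet18_like` one 3x3 max pool plus one trailing global average pool;
#' `googlenet_like` four 3x3 max pools plus one trailing average pool. The
#' convolutional trunk is deliberately miniaturized for CPU training.
#'
#' @param pool_layout `"alexnet_like"`, `"resnet18_like"` or
#'   `"googlenet_like"`.
#' @param input_size `c(H, W)` of the single-channel input.
#' @param classes number of output classes.
#' @return an [arch_spec()] with task `"classification"`.
#' @export
build_classifier <- function(pool_layout = c("alexnet_like", "resnet18_like",
                                             "googlenet_like"),
                             input_size = c(64L, 64L), classes = 2L) {
  pool_layout <- match.arg(pool_layout)
  mp3 <- function(name, inputs = NULL)
    layer_spec(name, "pool", inputs = inputs,
               spec = pool_spec("max", c(3L, 3L), c(2L, 2L), "same_ceil"))
  stage <- function(i, ch) list(
    layer_spec(paste0("c", i), "conv", out_channels = ch, kernel = 3L),
    layer_spec(paste0("r", i), "relu"),
    mp3(paste0("p", i)))
  L <- list(layer_spec("in", "input"))
  if (pool_layout == "alexnet_like") {
    L <- c(L, stage(1, 8L), stage(2, 16L), stage(3, 16L))
  } else if (pool_layout == "resnet18_like") {
    L <- c(L, stage(1, 8L),
           list(layer_spec("c2", "conv", out_channels = 16L, kernel = 3L,
                           stride = 2L),
                layer_spec("r2", "relu"),
                layer_spec("c3", "conv", out_channels = 16L, kernel = 3L,
                           stride = 2L),
                layer_spec("r3", "relu")))
  } else {
    L <- c(L, stage(1, 8L), stage(2, 12L), stage(3, 16L), stage(4, 16L))
  }
  if (pool_layout %in% c("resnet18_like", "googlenet_like")) {
    sh <- arch_shapes(arch_spec(L, "classification", c(1L, input_size)))
    last <- sh[[length(sh)]]
    L <- c(L, list(layer_spec("gap", "pool",
                              spec = pool_spec("avg", c(last[2], last[3]),
                                               c(1L, 1L), "none"),
                              trailing = TRUE)))
  }
  L <- c(L, list(layer_spec("fc", "dense", units = classes),
                 layer_spec("probs", "softmax")))
  arch <- arch_spec(L, "classification", c(1L, input_size))
  check_shapes(arch)
  arch
}

#' Replace pooling layers with directional blocks
#'
#' The pooling-substitution ("surgery") transform: every intermediate pool
#' layer with a `k x k` kernel and stride `s` becomes a VPB or AVG-MAX VPB
#' with `N = k` and stride `s`. Trailing global average pools (layers marked
#' `trailing = TRUE`) are replaced only when `replace_trailing_avg` is set.
#' The input spec is not modified; the returned spec passes the dry-run
#' shape check or an error names the offending layer. The number of
#' replacements is attached as attribute `"replacements"`.
#'
#' @param arch an [arch_spec()].
#' @param block `"vpb"` or `"avgmax_vpb"`.
#' @param replace_trailing_avg also replace trailing average pools.
#' @param seed seed recorded per replaced layer; parameter initialization
#'   (in [init_network_params()]) derives per-layer seeds from it.
#' @return a new [arch_spec()] with attribute `replacements`.
#' @export
replace_pooling <- function(arch, block = c("vpb", "avgmax_vpb"),
                            replace_trailing_avg = FALSE, seed = 1L) {
  block <- match.arg(block)
  check_shapes(arch)
  n <- 0L
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    if (l$kind != "pool") next
    trailing <- isTRUE(l$cfg$trailing)
    if (trailing && !replace_trailing_avg) next
    k <- max(l$cfg$spec$kernel)
    s <- l$cfg$spec$stride[1]
    if (trailing) {
      # a global pool reduces to 1x1: the block uses N = kernel, stride = kernel
      s <- k
    }
    arch$layers[[i]] <- layer_spec(l$name, block, inputs = l$inputs,
                                   N = k, stride = s,
                                   init_seed = seed + i)
    n <- n + 1L
  }
  check_shapes(arch)
  attr(arch, "replacements") <- n
  arch
}

#' Serialize an architecture to a YAML file
#'
#' @param arch an [arch_spec()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_arch <- function(arch, path) {
  to_plain <- function(l) {
    cfg <- l$cfg
    if (!is.null(cfg$spec)) cfg$spec <- unclass(cfg$spec)
    list(name = l$name, kind = l$kind, inputs = l$inputs, cfg = cfg)
  }
  yaml::write_yaml(list(task = arch$task,
                        input_shape = arch$input_shape,
                        layers = lapply(arch$layers, to_plain)), path)
  invisible(path)
}

#' Read an architecture from a YAML file
#'
#' @param path file written by [write_arch()].
#' @return an [arch_spec()].
#' @export
read_arch <- function(path) {
  y <- yaml::read_yaml(path)
  layers <- lapply(y$layers, function(l) {
    cfg <- l$cfg
    if (!is.null(cfg$spec))
      cfg$spec <- pool_spec(cfg$spec$mode, unlist(cfg$spec$kernel),
                            unlist(cfg$spec$stride), cfg$spec$padding)
    do.call(layer_spec, c(list(name = l$name, kind = l$kind,
                               inputs = unlist(l$inputs)), cfg))
  })
  arch_spec(layers, y$task, unlist(y$input_shape))
}
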
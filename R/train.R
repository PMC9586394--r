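#' Training configuration
#'
#' ADAM hyperparameters and schedule for the desk-scale training loop. The
#' segmentation defaults follow the thermogram study setup (initial learning
#' rate 1e-3 dropped by a factor of 0.30 every 10 epochs, batch size 8); the
#' classification setup uses initial rate 2e-3 and batch size 60 at full
#' scale. Desk-scale runs shrink `epochs` and `batch_size` via arguments.
#'
#' @param task `"segmentation"` or `"classification"` (sets defaults).
#' @param initial_lr initial learning rate.
#' @param lr_factor multiplicative drop applied every `lr_period` epochs.
#' @param lr_period epochs between drops.
#' @param batch_size mini-batch size.
#' @param epochs number of epochs.
#' @param beta1,beta2,eps ADAM moment decay rates and stabilizer.
#' @param seed seed controlling initialization and data order.
#' @return list of class `train_config`.
#' @export
train_config <- function(task = c("segmentation", "classification"),
                         initial_lr = NULL, lr_factor = 0.30, lr_period = 10L,
                         batch_size = NULL, epochs = 30L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1L) {
  task <- match.arg(task)
  if (is.null(initial_lr))
    initial_lr <- if (task == "segmentation") 1.0e-3 else 2.0e-3
  if (is.null(batch_size))
    batch_size <- if (task == "segmentation") 8L else 60L
  if (initial_lr <= 0) stop_config("learning rate must be positive")
  if (batch_size < 1L || epochs < 1L)
    stop_config("batch_size and epochs must be >= 1")
  structure(list(task = task, initial_lr = initial_lr, lr_factor = lr_factor,
                 lr_period = as.integer(lr_period),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed), loss = "cross_entropy"),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Piecewise-constant schedule: `initial_lr * lr_factor^floor((epoch - 1) /
#' lr_period)`, so e.g. initial 1e-3 with factor 0.30 every 10 epochs gives
#' 9e-5 at epoch 21.
#'
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch index.
#' @return the learning rate.
#' @export
schedule_lr <- function(cfg, epoch) {
  cfg$initial_lr * cfg$lr_factor^((epoch - 1L) %/% cfg$lr_period)
}

# recursive ADAM update over nested lists of numeric arrays; bn running
# stats and non-numeric entries are left untouched.
adam_step <- function(params, grads, state, lr, cfg, t) {
  walk <- function(p, g, s) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, s = s))
      if (is.null(s)) s <- list(m = p * 0, v = p * 0)
      s$m <- cfg$beta1 * s$m + (1 - cfg$beta1) * g
      s$v <- cfg$beta2 * s$v + (1 - cfg$beta2) * g * g
      mh <- s$m / (1 - cfg$beta1^t)
      vh <- s$v / (1 - cfg$beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + cfg$eps), s = s)
    } else if (is.list(p)) {
      if (is.null(s)) s <- vector("list", length(p))
      for (k in seq_along(p)) {
        nm <- names(p)[k]
        gk <- if (is.null(g)) NULL else g[[grad_name(nm)]]
        r <- walk(p[[k]], gk, if (k <= length(s)) s[[k]] else NULL)
        p[k] <- list(r$p)
        s[k] <- list(r$s)
      }
      list(p = p, s = s)
    } else list(p = p, s = s)
  }
  # map parameter field names to gradient field names
  grad_name <- function(nm) {
    switch(nm,
           weights = "gw", bias = "gb", w = "w", b = "b",
           gamma = "ggamma", beta = "gbeta",
           running_mean = ".none", running_var = ".none",
           eps = ".none", momentum = ".none", N = ".none", stride = ".none",
           nm)
  }
  out <- list(params = params, state = state)
  for (nm in names(params)) {
    if (is.null(params[[nm]]) || is.null(grads[[nm]])) next
    r <- walk(params[[nm]], grads[[nm]], state[[nm]])
    out$params[[nm]] <- r$p
    out$state[[nm]] <- r$s
  }
  out
}

one_hot_masks <- function(masks, classes = 2L) {
  # masks: H x W x N integer 0/1 -> target c(classes, H, W, N)
  d <- dim(masks)
  t <- array(0, c(classes, d[1], d[2], d[3]))
  for (k in seq_len(classes)) {
    t[k, , , ] <- as.numeric(masks == (k - 1L))
  }
  t
}

one_hot_labels <- function(labels, levels) {
  n <- length(labels)
  t <- array(0, c(length(levels), 1L, 1L, n))
  for (i in seq_len(n)) t[match(labels[i], levels), 1L, 1L, i] <- 1
  t
}

#' Train a network
#'
#' Mini-batch ADAM with the piecewise learning-rate schedule. Deterministic
#' given `cfg$seed`: initialization, data order and every other source of
#' randomness derive from it. Targets are per-pixel masks (segmentation,
#' `H x W x N` array of 0/1) or a label vector (classification).
#'
#' @param arch an [arch_spec()].
#' @param x input batch `C x H x W x N` (or `H x W x N` for single-channel).
#' @param y targets: `H x W x N` 0/1 masks or character/factor labels.
#' @param cfg a [train_config()].
#' @param val optional list `(x, y)` evaluated after each epoch (mean IoU for
#'   segmentation, accuracy for classification).
#' @param label_levels class labels in order (negative, positive); default
#'   `c("normal", "abnormal")`.
#' @param verbose print a line per epoch.
#' @return object of class `vpb_net`: `arch`, `params`, `config`, `log`
#'   (data frame with epoch, lr, train_loss, val_metric).
#' @export
train_network <- function(arch, x, y, cfg, val = NULL,
                          label_levels = c("normal", "abnormal"),
                          verbose = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  n <- dim(x)[4]
  seg <- arch$task == "segmentation"
  target_all <- if (seg) one_hot_masks(y) else
    one_hot_labels(as.character(y), label_levels)
  params <- init_network_params(arch, cfg$seed)
  state <- list()
  t <- 0L
  log <- data.frame(epoch = integer(), lr = numeric(),
                    train_loss = numeric(), val_metric = numeric())
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- schedule_lr(cfg, epoch)
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        xb <- x[, , , b, drop = FALSE]
        tb <- if (seg) target_all[, , , b, drop = FALSE] else
          target_all[, , , b, drop = FALSE]
        fw <- forward_network(arch, params, xb, mode = "train",
                              want_cache = TRUE)
        params <- fw$params
        bw <- backward_network(arch, params, fw, tb)
        t <- t + 1L
        up <- adam_step(params, bw$grads, state, lr, cfg, t)
        params <- up$params
        state <- up$state
        losses <- c(losses, bw$loss)
      }
      vm <- NA_real_
      if (!is.null(val)) {
        vm <- eval_metric(arch, params, val$x, val$y, label_levels)
      }
      log[nrow(log) + 1L, ] <- list(epoch, lr, mean(losses), vm)
      if (verbose)
        message(sprintf("epoch %2d lr %.2e loss %.4f val %.4f",
                        epoch, lr, mean(losses), vm))
    }
  })
  structure(list(arch = arch, params = params, config = cfg, log = log,
                 label_levels = label_levels),
            class = "vpb_net")
}

eval_metric <- function(arch, params, x, y, label_levels) {
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  fw <- forward_network(arch, params, x, mode = "infer")
  if (arch$task == "segmentation") {
    pred <- apply(fw$out, c(2, 3, 4), which.max) - 1L
    preds <- lapply(seq_len(dim(pred)[3]), function(i) pred[, , i])
    truths <- lapply(seq_len(dim(y)[3]), function(i) y[, , i])
    cm <- confusion_matrix(c("background", "breast"))
    for (i in seq_along(preds))
      cm <- accumulate_confusion(mask_labels(preds[[i]]),
                                 mask_labels(truths[[i]]), cm)
    as.numeric(mean_iou(cm))
  } else {
    pm <- matrix(fw$out, nrow = dim(fw$out)[1])
    pred <- label_levels[apply(pm, 2, which.max)]
    mean(pred == as.character(y))
  }
}

#' @export
print.vpb_net <- function(x, ...) {
  cat("vpb_net:", x$arch$task, "network,",
      length(x$arch$layers), "layers\n")
  nb <- sum(vapply(x$arch$layers, function(l)
    l$kind %in% c("vpb", "avgmax_vpb"), logical(1)))
  cat("  pooling blocks:", nb, "\n")
  if (nrow(x$log)) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("  trained %d epochs, final loss %.4f, val metric %s\n",
                last$epoch, last$train_loss,
                ifelse(is.na(last$val_metric), "-",
                       sprintf("%.4f", last$val_metric))))
  }
  invisible(x)
}

#' @export
summary.vpb_net <- function(object, ...) {
  print(object)
  print(object$arch)
  invisible(object)
}

#' @export
plot.vpb_net <- function(x, ...) {
  graphics::plot(x$log$epoch, x$log$train_loss, type = "b",
                 xlab = "epoch", ylab = "training loss", ...)
  if (any(!is.na(x$log$val_metric))) {
    graphics::par(new = TRUE)
    graphics::plot(x$log$epoch, x$log$val_metric, type = "l", col = 2,
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = 2)
  }
  invisible(x)
}

#' Predict from a trained network
#'
#' @param object a `vpb_net`.
#' @param x input images: `H x W` matrix, `H x W x N` or `C x H x W x N`
#'   array.
#' @param type `"prob"` for softmax outputs, `"class"` for argmax masks
#'   (segmentation, `H x W x N` 0/1) or labels (classification).
#' @param ... unused.
#' @return probabilities or class predictions.
#' @export
predict.vpb_net <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(1L, dim(x))
  fw <- forward_network(object$arch, object$params, x, mode = "infer")
  if (type == "prob") return(fw$out)
  if (object$arch$task == "segmentation") {
    pred <- apply(fw$out, c(2, 3, 4), which.max) - 1L
    pred
  } else {
    pm <- matrix(fw$out, nrow = dim(fw$out)[1])
    object$label_levels[apply(pm, 2, which.max)]
  }
}

#' Save / load trained network parameters
#'
#' Portable archive of the parameter arrays plus the architecture YAML; the
#' parameter file is an RDS of plain numeric arrays.
#'
#' @param model a `vpb_net`.
#' @param path file path for the parameter archive.
#' @return invisibly, `path`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(arch = model$arch, params = model$params,
               config = model$config, log = model$log,
               label_levels = model$label_levels), path)
  invisible(path)
}

#' @rdname save_model
#' @return for `load_model`, the restored `vpb_net`.
#' @export
load_model <- function(path) {
  structure(readRDS(path), class = "vpb_net")
}
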
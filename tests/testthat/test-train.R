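test_that("whole-network gradients match finite differences on a tiny net", {
  set.seed(55)
  arch <- build_unet(depth = 1, base_channels = 2, input_size = c(8, 8))
  params <- init_network_params(arch, 3)
  x <- array(runif(8 * 8 * 2) + seq_len(128) * 1e-4, c(1, 8, 8, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.5), c(8, 8, 2))
  target <- vpbpool:::one_hot_masks(y)
  lossf <- function(p) {
    fw <- forward_network(arch, p, x, mode = "train")
    m <- prod(dim(fw$out)[-1])
    -sum(log(pmax(fw$out, 1e-12)) * target) / m
  }
  fw <- forward_network(arch, params, x, mode = "train", want_cache = TRUE)
  bw <- backward_network(arch, fw$params, fw, target)
  h <- 1e-6
  for (lname in c("enc1_c1", "logits")) {
    w <- params[[lname]]$w
    idx <- sample(length(w), min(6, length(w)))
    num <- vapply(idx, function(i) {
      pp <- params; pp[[lname]]$w[i] <- pp[[lname]]$w[i] + h
      pm <- params; pm[[lname]]$w[i] <- pm[[lname]]$w[i] - h
      (lossf(pp) - lossf(pm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(bw$grads[[lname]]$w[idx] - num) /
                    pmax(1e-6, abs(num))), 1e-4)
  }
})

test_that("zero learning rate leaves parameters unchanged", {
  set.seed(8)
  arch <- build_unet(depth = 1, base_channels = 2, input_size = c(16, 16))
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.5), c(16, 16, 2))
  cfg <- train_config("segmentation", initial_lr = 1e-12, epochs = 1,
                      batch_size = 2, seed = 4)
  net <- train_network(arch, x, y, cfg)
  ref <- init_network_params(arch, cfg$seed)
  expect_equal(net$params$enc1_c1$w, ref$enc1_c1$w, tolerance = 1e-9)
})

test_that("training is deterministic given the seed", {
  set.seed(99)
  arch <- replace_pooling(build_unet(depth = 1, base_channels = 2,
                                     input_size = c(16, 16)), "vpb")
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  y <- array(0L, c(16, 16, 4)); y[4:12, 4:12, ] <- 1L
  cfg <- train_config("segmentation", epochs = 1, batch_size = 2, seed = 21)
  l1 <- train_network(arch, x, y, cfg)$log$train_loss
  l2 <- train_network(arch, x, y, cfg)$log$train_loss
  expect_identical(l1, l2)
})

test_that("training loss decreases on an easy separable problem", {
  set.seed(12)
  arch <- replace_pooling(build_unet(depth = 1, base_channels = 4,
                                     input_size = c(16, 16)), "avgmax_vpb")
  n <- 8
  x <- array(runif(16 * 16 * n) * 0.1, c(16, 16, n))
  y <- array(0L, c(16, 16, n))
  for (i in seq_len(n)) {
    y[5:12, 5:12, i] <- 1L
    x[, , i] <- x[, , i] + 0.6 * y[, , i]
  }
  cfg <- train_config("segmentation", epochs = 10, batch_size = 4, seed = 6)
  net <- train_network(arch, x, y, cfg)
  losses <- net$log$train_loss
  expect_lt(losses[length(losses)], losses[1])
  # strictly decreasing in at least 90% of epoch transitions
  expect_gte(mean(diff(losses) < 0), 0.9)
})

test_that("model save/load and predict round-trip", {
  set.seed(14)
  arch <- build_classifier("alexnet_like", input_size = c(32, 32))
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  labs <- c("normal", "abnormal", "normal", "abnormal")
  cfg <- train_config("classification", epochs = 1, batch_size = 2, seed = 2)
  net <- train_network(arch, x, labs, cfg)
  f <- tempfile(fileext = ".rds")
  save_model(net, f)
  net2 <- load_model(f)
  expect_equal(predict(net2, x), predict(net, x))
  expect_true(all(predict(net, x) %in% c("normal", "abnormal")))
  p <- predict(net, x, type = "prob")
  expect_equal(colSums(matrix(p, nrow = 2)), rep(1, 4), tolerance = 1e-9)
})
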
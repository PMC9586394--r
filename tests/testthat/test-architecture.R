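test_that("mini U-Net has the requested pool count and valid shapes", {
  a4 <- build_unet(depth = 4, base_channels = 4, input_size = c(64, 64))
  pools <- sum(vapply(a4$layers, function(l) l$kind == "pool", logical(1)))
  expect_equal(pools, 4)
  expect_silent(check_shapes(a4))
  a1 <- build_unet(depth = 1, base_channels = 2, input_size = c(8, 8))
  sh <- check_shapes(a1)
  expect_equal(sh[["pool1"]], c(2L, 4L, 4L))
  a2 <- build_unet(depth = 2, base_channels = 4, input_size = c(64, 64))
  sh2 <- check_shapes(a2)
  expect_equal(sh2[["probs"]], c(2L, 64L, 64L))
  expect_error(build_unet(depth = 0), class = "vpb_config_error")
})

test_that("classifier pooling inventories match the named backbones", {
  inventory <- function(arch) {
    kinds <- vapply(arch$layers, function(l) l$kind, character(1))
    pools <- arch$layers[kinds == "pool"]
    table(vapply(pools, function(l) l$cfg$spec$mode, character(1)))
  }
  al <- build_classifier("alexnet_like")
  expect_equal(unname(inventory(al)["max"]), 3L)
  expect_true(is.na(inventory(al)["avg"]))
  rn <- build_classifier("resnet18_like")
  expect_equal(unname(inventory(rn)["max"]), 1L)
  expect_equal(unname(inventory(rn)["avg"]), 1L)
  gn <- build_classifier("googlenet_like")
  expect_equal(unname(inventory(gn)["max"]), 4L)
  expect_equal(unname(inventory(gn)["avg"]), 1L)
  # final dense layer of width classes + softmax
  sh <- check_shapes(build_classifier("alexnet_like", classes = 2))
  expect_equal(sh[["fc"]], c(2L, 1L, 1L))
})

test_that("pooling surgery replaces intermediate pools and reports counts", {
  u <- build_unet(depth = 4, base_channels = 4, input_size = c(64, 64))
  uv <- replace_pooling(u, "vpb")
  expect_equal(attr(uv, "replacements"), 4L)
  kinds <- vapply(uv$layers, function(l) l$kind, character(1))
  expect_equal(sum(kinds == "vpb"), 4L)
  expect_equal(sum(kinds == "pool"), 0L)
  expect_silent(check_shapes(uv))
  # replaced blocks inherit N and stride from the replaced pool
  blk <- uv$layers[[which(kinds == "vpb")[1]]]
  expect_equal(blk$cfg$N, 2L)
  expect_equal(blk$cfg$stride, 2L)
  # original spec untouched
  expect_equal(sum(vapply(u$layers, function(l) l$kind == "pool",
                          logical(1))), 4L)
  # no pools -> no-op with count 0
  again <- replace_pooling(uv, "avgmax_vpb")
  expect_equal(attr(again, "replacements"), 0L)
  # trailing average pools kept unless asked for
  gn <- build_classifier("googlenet_like")
  gnv <- replace_pooling(gn, "vpb")
  expect_equal(attr(gnv, "replacements"), 4L)
  kinds_gn <- vapply(gnv$layers, function(l) l$kind, character(1))
  expect_equal(sum(kinds_gn == "pool"), 1L)
  gnv2 <- replace_pooling(gn, "vpb", replace_trailing_avg = TRUE)
  expect_equal(attr(gnv2, "replacements"), 5L)
})

test_that("surgery preserves output shapes across pooling variants", {
  u <- build_unet(depth = 2, base_channels = 4, input_size = c(48, 48))
  for (blk in c("vpb", "avgmax_vpb")) {
    r <- replace_pooling(u, blk)
    expect_equal(check_shapes(r)[["probs"]], check_shapes(u)[["probs"]])
  }
  # odd input size still reconciles thanks to same-ceil blocks
  uo <- build_unet(depth = 2, base_channels = 4, input_size = c(50, 50))
  expect_silent(check_shapes(replace_pooling(uo, "vpb")))
})

test_that("the three pooling variants produce identically shaped outputs", {
  set.seed(2)
  u <- build_unet(depth = 2, base_channels = 4, input_size = c(32, 32))
  x <- array(runif(32 * 32 * 2), c(1, 32, 32, 2))
  outs <- lapply(list(u, replace_pooling(u, "vpb"),
                      replace_pooling(u, "avgmax_vpb")), function(a) {
    forward_network(a, init_network_params(a, 3), x)$out
  })
  expect_identical(dim(outs[[1]]), dim(outs[[2]]))
  expect_identical(dim(outs[[1]]), dim(outs[[3]]))
  # per-pixel softmax sums to one
  expect_equal(apply(outs[[2]], c(2, 3, 4), sum),
               array(1, c(32, 32, 2)), tolerance = 1e-9)
})

test_that("learning-rate schedule follows the piecewise drop", {
  cfg <- train_config("segmentation", initial_lr = 1.0e-3,
                      lr_factor = 0.30, lr_period = 10)
  expect_equal(schedule_lr(cfg, 1), 1.0e-3)
  expect_equal(schedule_lr(cfg, 10), 1.0e-3)
  expect_equal(schedule_lr(cfg, 11), 3.0e-4)
  expect_equal(schedule_lr(cfg, 21), 9.0e-5)
})

test_that("architecture YAML round-trips", {
  u <- replace_pooling(build_unet(depth = 2, base_channels = 4,
                                  input_size = c(32, 32)), "vpb")
  f <- tempfile(fileext = ".yaml")
  write_arch(u, f)
  u2 <- read_arch(f)
  expect_equal(check_shapes(u2), check_shapes(u))
  expect_equal(vapply(u2$layers, function(l) l$kind, character(1)),
               vapply(u$layers, function(l) l$kind, character(1)))
})
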
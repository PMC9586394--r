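test_that("VPB forward matches the hand-composed 2x2 example", {
  x <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  p <- identity_vpb_params(1, N = 2, stride = 2)
  expect_equal(vpb_forward(x, p), matrix(5))
  # all-zero input with zero biases gives zero output
  expect_equal(vpb_forward(matrix(0, 4, 4), p), matrix(0, 2, 2))
})

test_that("AVG-MAX VPB forward matches the hand-composed 2x2 example", {
  x <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  id <- conv1x1_params(diag(1))
  p <- avgmax_vpb_params(id, id, id, id, bn = bn_params(1, eps = 1e-12),
                         N = 2, stride = 2)
  r <- avgmax_vpb_forward(x, p, mode = "infer")
  expect_equal(r$out, matrix(2 + 3 + 1.5 + 2.0), tolerance = 1e-9)
  z <- avgmax_vpb_forward(matrix(0, 4, 4), p, mode = "infer")
  expect_equal(z$out, matrix(0, 2, 2), tolerance = 1e-9)
})

test_that("blocks agree with straight-line transcription oracles", {
  set.seed(23)
  for (rep in 1:25) {
    C <- sample(1:4, 1)
    H <- sample(c(5, 8, 16, 32), 1)
    W <- sample(c(5, 8, 16, 32), 1)
    N <- sample(2:3, 1)
    s <- sample(2:3, 1)
    x <- array(rnorm(C * H * W), c(C, H, W))
    p <- init_block_params(C, N, s, "vpb", seed = rep)
    expect_equal(vpb_forward(x, p), oracle_vpb(x, p), tolerance = 1e-12)
    pa <- init_block_params(C, N, s, "avgmax", seed = rep + 100)
    pa$bn$running_mean <- rnorm(C)
    pa$bn$running_var <- abs(rnorm(C)) + 0.5
    pa$bn$gamma <- rnorm(C)
    pa$bn$beta <- rnorm(C)
    out <- avgmax_vpb_forward(x, pa, mode = "infer")$out
    expect_equal(out, oracle_avgmax_vpb_infer(x, pa), tolerance = 1e-12)
  }
})

test_that("degenerate N=1, s=1 identity-conv VPB doubles the relu", {
  set.seed(3)
  x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  p <- identity_vpb_params(2, N = 1, stride = 1)
  expect_equal(vpb_forward(x, p), 2 * relu(x), tolerance = 1e-12)
})

test_that("block backward passes match central finite differences", {
  set.seed(77)
  C <- 2; H <- 6; W <- 6
  # jitter off max-pool ties and relu kinks
  x <- array(runif(C * H * W), c(C, H, W)) +
    array(seq_len(C * H * W) * 1e-4, c(C, H, W))
  p <- init_block_params(C, N = 2, stride = 2, kind = "vpb", seed = 7)
  R <- array(rnorm(C * 9), c(C, 3, 3))
  fw <- vpb_forward(x, p, cache = TRUE)
  bk <- vpb_backward(fw$cache, R)
  idx <- sample(length(x), 30)
  num <- fd_grad(function(z) sum(vpb_forward(z, p) * R), x, idx)
  expect_lt(max_rel_err(bk$grad_input[idx], num), 1e-5)
  numw <- fd_grad(function(w) {
    p2 <- p; p2$conv_vertical$weights[] <- w
    sum(vpb_forward(x, p2) * R)
  }, p$conv_vertical$weights)
  expect_lt(max_rel_err(as.vector(bk$grad_params$conv_vertical$gw), numw),
            1e-5)

  # AVG-MAX block, train mode, batch of 2
  xb <- array(runif(C * H * W * 2), c(C, H, W, 2)) +
    array(seq_len(C * H * W * 2) * 2e-4, c(C, H, W, 2))
  pa <- init_block_params(C, N = 2, stride = 2, kind = "avgmax", seed = 9)
  Rb <- array(rnorm(C * 9 * 2), c(C, 3, 3, 2))
  fwa <- avgmax_vpb_forward(xb, pa, mode = "train", cache = TRUE)
  bka <- avgmax_vpb_backward(fwa$cache, Rb)
  idx <- sample(length(xb), 30)
  numa <- fd_grad(function(z)
    sum(avgmax_vpb_forward(z, pa, mode = "train")$out * Rb), xb, idx)
  expect_lt(max_rel_err(bka$grad_input[idx], numa), 1e-5)
  numg <- fd_grad(function(g) {
    p2 <- pa; p2$bn$gamma[] <- g
    sum(avgmax_vpb_forward(xb, p2, mode = "train")$out * Rb)
  }, pa$bn$gamma)
  expect_lt(max_rel_err(bka$grad_params$bn$ggamma, numg), 1e-5)
})

test_that("zero upstream gradient yields zero gradients everywhere", {
  set.seed(1)
  x <- array(runif(2 * 4 * 4), c(2, 4, 4))
  p <- init_block_params(2, 2, 2, "vpb", seed = 2)
  fw <- vpb_forward(x, p, cache = TRUE)
  bk <- vpb_backward(fw$cache, array(0, dim(fw$out)))
  expect_true(all(bk$grad_input == 0))
  expect_true(all(bk$grad_params$conv_vertical$gw == 0))
})

test_that("backward without a cache is a usage error", {
  expect_error(vpb_backward(list(), matrix(0, 1, 1)),
               class = "vpb_usage_error")
  expect_error(avgmax_vpb_backward(list(), matrix(0, 1, 1)),
               class = "vpb_usage_error")
})
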
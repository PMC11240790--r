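test_that("network configuration is validated", {
  expect_error(network_config(1, 1, depth = 3, filters = c(8, 16)), "per level")
  expect_error(network_config(1, 1, depth = 2, filters = c(16, 8)),
               "increasing")
  expect_error(network_config(0, 1, depth = 1, filters = 8), "channel")
  expect_error(network_config(1, 1, depth = 1, filters = 8, head = "softmax"),
               "softmax")
  cfg <- network_config(1, 1, depth = 4, filters = c(32, 64, 128, 256))
  expect_s3_class(cfg, "pd_network_config")
})

test_that("initialization is deterministic per seed and counted exactly", {
  cfg <- network_config(1, 1, depth = 2, filters = c(4, 8))
  a <- build_model(cfg, seed = 5); b <- build_model(cfg, seed = 5)
  expect_identical(a$params, b$params)
  c2 <- build_model(cfg, seed = 6)
  expect_false(identical(a$params, c2$params))

  # closed-form parameter count for this config (residual projections incl.)
  blk <- function(cin, cout, proj)
    27 * cin * cout + cout + 27 * cout * cout + cout + 4 * cout +
      if (proj) cin * cout + cout else 0
  expected <- blk(1, 4, TRUE) + blk(4, 8, TRUE) + blk(12, 4, TRUE) + (4 + 1)
  expect_equal(n_parameters(a), expected)
})

test_that("prediction honours shape, range and normalization contracts", {
  m <- build_model(network_config(1, 1, depth = 2, filters = c(4, 8)), seed = 1)
  x <- array(rnorm(16^3), dim = c(16, 16, 16, 1))
  p <- predict_proba(m, x)
  expect_equal(dim(p), c(16, 16, 16, 1))
  expect_true(all(p >= 0 & p <= 1))

  sm <- build_model(network_config(1, 3, depth = 2, filters = c(4, 8),
                                   head = "softmax"), seed = 2)
  ps <- predict_proba(sm, x)
  sums <- ps[, , , 1] + ps[, , , 2] + ps[, , , 3]
  expect_lt(max(abs(sums - 1)), 1e-5)

  # randomized configs/sizes: output spatial shape always equals input
  set.seed(3)
  for (i in 1:5) {
    depth <- sample(1:3, 1)
    f <- cumsum(sample(2:4, depth, replace = TRUE))
    mm <- build_model(network_config(1, 1, depth = depth, filters = f), seed = i)
    d <- 2^(depth - 1) * sample(2:4, 3, replace = TRUE)
    xx <- array(rnorm(prod(d)), dim = c(d, 1))
    expect_equal(dim(predict_proba(mm, xx))[1:3], d)
  }
})

test_that("divisibility and channel mismatches produce named errors", {
  m <- build_model(network_config(2, 1, depth = 3, filters = c(4, 8, 12)),
                   seed = 1)
  expect_error(predict_proba(m, array(0, dim = c(10, 12, 12, 2))),
               "divisible by 4")
  expect_error(predict_proba(m, array(0, dim = c(12, 12, 12, 1))),
               "channels")
})

test_that("backpropagation matches numeric differentiation", {
  set.seed(1)
  for (head in c("sigmoid", "softmax")) {
    out_ch <- if (head == "softmax") 3L else 1L
    cfg <- network_config(2, out_ch, depth = 2, filters = c(3, 5), head = head)
    m <- build_model(cfg, seed = 3)
    x <- array(rnorm(8 * 8 * 8 * 2), dim = c(8, 8, 8, 2))
    if (head == "sigmoid") {
      t <- array(rbinom(512, 1, 0.3), dim = c(8, 8, 8, 1))
    } else {
      cls <- sample(1:3, 512, replace = TRUE)
      t <- array(0, dim = c(8, 8, 8, 3))
      for (c in 1:3) t[, , , c] <- as.numeric(cls == c)
    }
    fw <- pdacascade:::unet_forward(m, x, keep_cache = TRUE)
    lg <- pdacascade:::nn_loss_grad(fw$logits, t, head)
    gr <- pdacascade:::unet_backward(m, fw, lg$dlogits)
    f <- function(mm) {
      fw <- pdacascade:::unet_forward(mm, x, keep_cache = FALSE)
      pdacascade:::nn_loss_grad(fw$logits, t, head)$loss
    }
    eps <- 1e-5
    for (spot in list(c("enc1", "w1"), c("enc2", "g2"), c("dec1", "wp"),
                      c("final", "w"))) {
      idx <- 2L
      mp <- m; mp$params[[spot[1]]][[spot[2]]][idx] <-
        mp$params[[spot[1]]][[spot[2]]][idx] + eps
      mn <- m; mn$params[[spot[1]]][[spot[2]]][idx] <-
        mn$params[[spot[1]]][[spot[2]]][idx] - eps
      num <- (f(mp) - f(mn)) / (2 * eps)
      ana <- gr[[spot[1]]][[spot[2]]][idx]
      expect_lt(abs(num - ana), 1e-6 + 1e-4 * (abs(num) + abs(ana)))
    }
  }
})

test_that("GEMM convolution agrees with the direct-loop reference kernels", {
  set.seed(4)
  x <- array(rnorm(10 * 9 * 8 * 3), dim = c(10, 9, 8, 3))
  w <- array(rnorm(27 * 3 * 4), dim = c(3, 3, 3, 3, 4))
  b <- rnorm(4)
  y_ref <- pdacascade:::conv3_fwd(x, w, b)
  y <- pdacascade:::nn_conv_fwd(x, w, b)
  expect_lt(max(abs(y - y_ref)), 1e-10)
  gy <- array(rnorm(length(y)), dim = dim(y))
  ref_in <- pdacascade:::conv3_bwd_input(gy, w)
  ref_w <- pdacascade:::conv3_bwd_weight(x, gy, 3L)
  got <- pdacascade:::nn_conv_bwd(x, w, gy)
  expect_lt(max(abs(got$gx - ref_in)), 1e-10)
  expect_lt(max(abs(got$gw - ref_w$gw)), 1e-9)
  expect_lt(max(abs(got$gb - ref_w$gb)), 1e-9)
})

test_that("constant and function models honour the prediction contract", {
  cm <- const_model(0.3, in_channels = 2, out_channels = 2)
  p <- predict_proba(cm, array(0, dim = c(4, 4, 4, 2)))
  expect_true(all(p == 0.3))
  expect_equal(dim(p), c(4, 4, 4, 2))
  expect_error(predict_proba(cm, array(0, dim = c(4, 4, 4, 1))), "mismatch")

  fm <- fn_model(function(x) x[, , , 1, drop = FALSE] * 0 + 0.9)
  expect_true(all(predict_proba(fm, array(0, dim = c(3, 3, 3, 1))) == 0.9))
  expect_error(predict_proba(oracle_model("tumor"), array(0, c(2, 2, 2, 1))),
               "cascade")
})
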
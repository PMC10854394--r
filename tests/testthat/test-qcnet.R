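test_that("the default architecture matches its specification by introspection", {
  net <- buildNetwork(networkConfig(), seed = 1)
  d <- networkSummary(net)
  expect_equal(d$block_filters, c(8L, 16L, 32L, 64L))
  expect_equal(d$conv_kernel, c(3L, 3L, 3L))
  expect_equal(d$pool_size, 2L)
  expect_equal(d$pool_stride, 2L)
  expect_true(d$batchnorm_per_block)
  expect_equal(d$dense_units, c(128L, 128L, 1L))
  expect_equal(d$dropout_rate, 0.5)
  # spatial trace with floor-halving per block: 128x128x70 -> 8x8x4
  expect_equal(d$pooled_dims,
               matrix(c(64L, 32L, 16L, 8L, 64L, 32L, 16L, 8L,
                        35L, 17L, 8L, 4L), ncol = 3L))
  expect_equal(d$flatten_units, 8 * 8 * 4 * 64)
})

test_that("too-small inputs fail with the offending axis named", {
  err <- expect_error(buildNetwork(networkConfig(input_shape = c(32, 32, 8))),
                      "axis 'z'")
  expect_match(conditionMessage(err), "block 4")
})

test_that("inference is total, bounded and deterministic", {
  dims <- c(16L, 16L, 16L)
  net <- buildNetwork(networkConfig(input_shape = dims), seed = 3)
  z <- array(0, dims)
  p0 <- predictVolume(net, z)
  expect_true(p0 >= 0 && p0 <= 1)
  set.seed(1)
  v <- array(runif(prod(dims)), dims)
  expect_identical(predictVolume(net, v), predictVolume(net, v))
  err <- expect_error(predictVolume(net, array(0, c(8, 8, 8))), "does not match")
  expect_match(conditionMessage(err), "16x16x16")
  expect_match(conditionMessage(err), "8x8x8")
})

test_that("builds are seed-deterministic", {
  cfg <- networkConfig(input_shape = c(16, 16, 16))
  w1 <- dwiQC:::.qcnet_weights(buildNetwork(cfg, seed = 42)@ptr)
  w2 <- dwiQC:::.qcnet_weights(buildNetwork(cfg, seed = 42)@ptr)
  expect_identical(w1, w2)
  w3 <- dwiQC:::.qcnet_weights(buildNetwork(cfg, seed = 43)@ptr)
  expect_false(identical(w1$dense1$W, w3$dense1$W))
})

test_that("save/load round-trips predictions bitwise", {
  dims <- c(16L, 16L, 16L)
  task <- toy_task(n = 8L, dims = dims, seed = 5)
  net <- buildNetwork(networkConfig(input_shape = dims), seed = 5)
  trainNetwork(net, task$x, task$y, trainConfig(epochs = 2, seed = 5))
  p_before <- predictVolume(net, task$x)
  td <- withr::local_tempdir()
  path <- file.path(td, "model.rds")
  saveModel(net, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- loadModel(path)
  expect_identical(predictVolume(back, task$x), p_before)

  expect_error(loadModel(file.path(td, "nope.rds")), "not found")
  saveRDS(list(junk = 1), file.path(td, "junk.rds"))
  expect_error(loadModel(file.path(td, "junk.rds")), "not a dwiQC model")
  # weights from a different architecture are rejected with the mismatch named
  obj <- readRDS(path)
  obj$config$block_filters <- c(8L, 16L, 32L, 16L)
  saveRDS(obj, file.path(td, "mismatch.rds"))
  expect_error(loadModel(file.path(td, "mismatch.rds")), "mismatch")
})

test_that("backpropagation matches numerical differentiation", {
  dims <- c(16L, 16L, 16L)
  cfg <- networkConfig(input_shape = dims, dropout_rate = 0)
  net <- buildNetwork(cfg, seed = 11)
  set.seed(4)
  n <- 4L
  x <- array(runif(prod(dims) * n), c(dims, n))
  y <- c(0L, 1L, 1L, 0L)
  lg <- dwiQC:::.qcnet_loss_grads(net@ptr, x, c(dims, n), y)
  w0 <- dwiQC:::.qcnet_weights(net@ptr)
  num_grad <- function(set, get, idx, eps = 3e-3) {
    p <- get(w0)
    for (s in c(1, -1)) {
      p2 <- p; p2[idx] <- p[idx] + s * eps
      dwiQC:::.qcnet_set_weights(net@ptr, set(w0, p2))
      l <- dwiQC:::.qcnet_loss_grads(net@ptr, x, c(dims, n), y)$loss
      if (s == 1) lp <- l else lm <- l
    }
    dwiQC:::.qcnet_set_weights(net@ptr, w0)
    (lp - lm) / (2 * eps)
  }
  # check the largest-magnitude gradients of each parameter group: small
  # entries drown in the float32 forward noise of the finite difference
  check <- function(analytic, set, get, npick = 2L) {
    for (i in order(abs(analytic), decreasing = TRUE)[seq_len(npick)]) {
      ng <- num_grad(set, get, i)
      expect_lt(abs(analytic[i] - ng) / max(abs(ng), abs(analytic[i]), 1e-4), 0.05)
    }
  }
  for (k in 1:4) for (par in c("W", "gamma", "beta")) {
    check(lg$blocks[[k]][[par]],
          function(w, p) { w$blocks[[k]][[par]] <- p; w },
          function(w) w$blocks[[k]][[par]])
  }
  for (dn in c("dense1", "dense2", "dense3")) {
    check(lg[[dn]]$W,
          function(w, p) { w[[dn]]$W <- p; w },
          function(w) w[[dn]]$W)
  }
})
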
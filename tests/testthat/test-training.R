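test_that("thresholding classifies with ties going to artifact", {
  expect_equal(classifyVolumes(0.7, 0.5), 1L)
  expect_equal(classifyVolumes(0.5, 0.5), 1L)   # tie -> artifact
  expect_equal(classifyVolumes(0.49, 0.3), 1L)  # lowered threshold raises sensitivity
  expect_equal(classifyVolumes(0.49, 0.5), 0L)
  expect_error(classifyVolumes(0.5, 0), "threshold")
})

test_that("confusion counts follow the 2x2 table with artifact positive", {
  c1 <- confusionCounts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unclass(c1), c(TP = 2L, TN = 1L, FP = 0L, FN = 0L))
  c2 <- confusionCounts(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(unclass(c2), c(TP = 0L, TN = 0L, FP = 2L, FN = 2L))
  expect_error(confusionCounts(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("a 612-volume test set with the reference error pattern books correctly", {
  truth <- c(rep(1L, 291L), rep(0L, 301L), rep(0L, 5L), rep(1L, 15L))
  pred <- c(rep(1L, 291L), rep(0L, 301L), rep(1L, 5L), rep(0L, 15L))
  cnt <- confusionCounts(truth, pred)
  expect_equal(unclass(cnt), c(TP = 291L, TN = 301L, FP = 5L, FN = 15L))
  expect_equal(sum(cnt), 612L)
})

test_that("metrics compute the four ratios with undefined flagged as NA", {
  m <- qcMetrics(c(TP = 291, TN = 301, FP = 5, FN = 15))
  expect_equal(round(m$accuracy, 1), 96.7)
  expect_equal(round(m$precision, 1), 98.3)
  expect_equal(round(m$tpr, 1), 95.1)
  expect_equal(round(m$tnr, 1), 98.4)
  m50 <- qcMetrics(c(TP = 1, TN = 1, FP = 1, FN = 1))
  expect_equal(unlist(m50[c("accuracy", "precision", "tpr", "tnr")]),
               c(accuracy = 50, precision = 50, tpr = 50, tnr = 50))
  m0 <- qcMetrics(c(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_equal(m0$accuracy, 100)
  expect_equal(m0$tnr, 100)
  expect_true(is.na(m0$precision))
  expect_true(is.na(m0$tpr))
})

test_that("accuracy decomposes into TPR/TNR on random confusion tables", {
  set.seed(21)
  for (i in 1:25) {
    cnt <- c(TP = sample(0:50, 1), TN = sample(0:50, 1),
             FP = sample(0:50, 1), FN = sample(0:50, 1))
    if (sum(cnt) == 0) next
    m <- qcMetrics(cnt)
    pos <- cnt["TP"] + cnt["FN"]
    neg <- cnt["TN"] + cnt["FP"]
    tpr <- if (pos > 0) m$tpr else 0
    tnr <- if (neg > 0) m$tnr else 0
    expect_equal(m$accuracy, unname((tpr * pos + tnr * neg) / sum(cnt)))
    # brute-force recount oracle
    truth <- rep(c(1, 0, 0, 1), cnt)  # TP, TN, FP, FN patterns
    pred <- rep(c(1, 0, 1, 0), cnt)
    expect_equal(unclass(confusionCounts(truth, pred)[names(cnt)]),
                 setNames(as.integer(cnt), names(cnt)))
  }
})

test_that("lowering the threshold never lowers TPR nor raises TNR", {
  set.seed(33)
  for (rep in 1:10) {
    p <- runif(60)
    y <- rbinom(60, 1, 0.4)
    ths <- sort(runif(8, 0.05, 0.95))
    ms <- lapply(ths, function(t)
      qcMetrics(confusionCounts(y, classifyVolumes(p, t)), t))
    tprs <- vapply(ms, function(m) ifelse(is.na(m$tpr), 100, m$tpr), 0)
    tnrs <- vapply(ms, function(m) ifelse(is.na(m$tnr), 0, m$tnr), 0)
    expect_true(all(diff(tprs) <= 1e-9))   # TPR non-increasing in threshold
    expect_true(all(diff(tnrs) >= -1e-9))  # TNR non-decreasing
  }
})

test_that("training validates inputs and is seed-reproducible", {
  dims <- c(16L, 16L, 16L)
  task <- toy_task(n = 16L, dims = dims, seed = 8)
  cfg <- networkConfig(input_shape = dims)
  expect_error(trainConfig(epochs = 0), "epochs")
  expect_error(
    trainNetwork(buildNetwork(cfg, 1), task$x, rep(1L, 16L), trainConfig(epochs = 1)),
    "single class")

  run <- function() {
    net <- buildNetwork(cfg, seed = 4)
    trainNetwork(net, task$x, task$y, trainConfig(epochs = 3, seed = 4))
    dwiQC:::.qcnet_weights(net@ptr)
  }
  expect_identical(run(), run())
})

test_that("training reduces the loss and fits an easy artifact task", {
  dims <- c(24L, 24L, 16L)
  task <- toy_task(n = 32L, dims = dims, seed = 1)
  net <- buildNetwork(networkConfig(input_shape = dims), seed = 2)
  fit <- trainNetwork(net, task$x, task$y, trainConfig(epochs = 6, seed = 3))
  expect_equal(nrow(fit$history), 6L)
  expect_lt(tail(fit$history$loss, 1), head(fit$history$loss, 1))
  expect_gt(tail(fit$history$train_accuracy, 1), 0.9)
})

test_that("cross-validation never leaks subjects and means match fold rows", {
  dims <- c(16L, 16L, 16L)
  nsub <- 8L
  per <- 6L
  task <- toy_task(n = nsub * per, dims = dims, seed = 13)
  subjects <- rep(sprintf("s%02d", 1:nsub), each = per)
  cv <- crossValidate(task$x, task$y, subjects, splitConfig(k = 4, seed = 2),
                      networkConfig(input_shape = dims),
                      trainConfig(epochs = 2, seed = 2))
  expect_length(cv$folds, 4L)
  for (i in 1:4) for (j in seq_len(4)[-i])
    expect_length(intersect(cv$folds[[i]], cv$folds[[j]]), 0L)
  expect_setequal(unlist(cv$folds), unique(subjects))
  rep_int <- cv$report[cv$report$dataset == "internal", ]
  folds <- rep_int[!(rep_int$fold %in% c("mean", "sd")), ]
  mu <- rep_int[rep_int$fold == "mean", ]
  expect_equal(mu$accuracy, mean(folds$accuracy))
  expect_equal(mu$tpr, mean(folds$tpr))
  expect_false(anyNA(cv$probabilities))
  expect_error(crossValidate(task$x, task$y, rep("s1", nsub * per),
                             splitConfig(k = 4), networkConfig(input_shape = dims)),
               "cannot split")
})

test_that("threshold tuning matches an exhaustive scan and flags borderline cases", {
  # perfectly separated: midpoint of the gap, balanced accuracy 100
  p <- c(0.1, 0.2, 0.3, 0.8, 0.85, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  tt <- tuneThreshold(p, y)
  expect_equal(tt$threshold, 0.55)
  expect_equal(tt$value, 100)

  # toy set: compare against a brute-force grid scan
  p2 <- c(0.15, 0.4, 0.45, 0.55, 0.6, 0.9)
  y2 <- c(0, 1, 0, 1, 0, 1)
  tt2 <- tuneThreshold(p2, y2)
  grid <- seq(0.01, 0.99, by = 0.001)
  bal <- vapply(grid, function(t) {
    m <- qcMetrics(confusionCounts(y2, classifyVolumes(p2, t)), t)
    mean(c(m$tpr, m$tnr))
  }, 0)
  expect_equal(tt2$value, max(bal))

  # borderline flag: exactly the volumes with |p - threshold| < eps
  p4 <- c(0.1, 0.48, 0.9)
  bl <- tuneThreshold(p4, c(0, 1, 1), eps = 0.2)
  expect_setequal(bl$borderline, which(abs(p4 - bl$threshold) < 0.2) - 1L)
  expect_true(1L %in% bl$borderline)  # 0-based index of the near-threshold volume

  # min-FN objective under an FP budget
  mf <- tuneThreshold(p2, y2, objective = "min_fn", fp_budget = 3)
  expect_equal(mf$value, 0)
  expect_error(tuneThreshold(c(0.2, 0.3), c(1, 1)), "both classes")
})
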
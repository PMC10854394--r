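noiseless_exam <- function(grid = c(20L, 20L, 12L), extra = 12L, seed = 1L) {
  sp <- phantomSpec(grid = grid, noise_sigma = 0)
  ph <- buildPhantom(sp)
  ser <- simulateSignal(ph, tiny_scheme(extra = extra), S0 = sp$S0,
                        noise_sigma = 0, seed = seed)
  list(spec = sp, phantom = ph, series = ser)
}

test_that("applyQC removes volumes, scheme entries and labels in lockstep", {
  ex <- noiseless_exam()
  ser <- ex$series
  artifactLabels(ser) <- rep(0L, nVolumes(ser))
  expect_identical(applyQC(ser, "manual"), ser)
  labs <- rep(0L, nVolumes(ser)); labs[c(2L, 5L, 9L)] <- 1L
  artifactLabels(ser) <- labs
  qc <- applyQC(ser, "manual")
  expect_equal(nVolumes(qc), nVolumes(ser) - 3L)
  expect_equal(length(bvalues(qc)), nVolumes(qc))
  expect_true(all(artifactLabels(qc) == 0L))
  expect_error(applyQC(ser, "model"), "requires a trained model")
  un <- ser; artifactLabels(un) <- NULL
  expect_error(applyQC(un, "manual"), "label")
  # removing a whole shell warns
  labs_b0 <- as.integer(bvalues(ser) == 0)
  artifactLabels(ser) <- labs_b0
  expect_warning(applyQC(ser, "manual"), "shell")
})

test_that("model QC at a threshold above every probability is the identity", {
  ex <- noiseless_exam(grid = c(16L, 16L, 16L), extra = 5L)
  net <- buildNetwork(networkConfig(input_shape = c(16L, 16L, 16L)), seed = 1)
  qc <- applyQC(ex$series, "model", model = net, threshold = 1 - 1e-9)
  expect_equal(nVolumes(qc), nVolumes(ex$series))
})

test_that("WLS recovers noiseless tensors to numerical precision", {
  ex <- noiseless_exam()
  fit <- fitDtiWls(ex$series, ex$phantom$brain_mask)
  # per-voxel tensor components against the generating field
  tens <- ex$phantom$tensors
  truth <- sapply(1:6, function(k) tens[, , , k][fit@voxels])
  est <- t(fit@beta[2:7, , drop = FALSE])
  expect_lt(max(abs(est - truth)) / max(abs(truth)), 1e-9)
  # ln S0 recovered too
  expect_lt(max(abs(exp(fit@beta[1L, ]) - ex$spec$S0)) / ex$spec$S0, 1e-9)
  # OLS and WLS agree exactly on noiseless data
  fit_ols <- fitDtiWls(ex$series, ex$phantom$brain_mask, method = "ols")
  expect_equal(fit@evals, fit_ols@evals, tolerance = 1e-9)
  # structure FA equals the closed-form oracle value
  maps <- deriveMaps(fit)
  fa <- extractRoi(maps$FA, ex$phantom$roi_masks$structure)
  expect_equal(unname(range(fa)), rep(0.8703883, 2L), tolerance = 1e-6)
})

test_that("tensor fitting validates its preconditions", {
  ex <- noiseless_exam(extra = 0L)  # 7 volumes: minimum
  expect_s4_class(fitDtiWls(ex$series, ex$phantom$brain_mask), "DTIFit")
  short <- applyQC({
    s <- ex$series; artifactLabels(s) <- c(0L, 1L, rep(0L, 5L)); s
  }, "manual")
  expect_error(fitDtiWls(short, ex$phantom$brain_mask), ">= 7")
  # no b0
  sch <- acquisitionScheme(rep(800, 7), dwiQC:::.sphere_dirs(7))
  ser2 <- volumeSeries(ex$series@volumes, sch)
  expect_error(fitDtiWls(ser2, ex$phantom$brain_mask), "b = 0")
  # collinear directions -> rank deficiency named
  g <- c(1, 0, 0)
  sch3 <- acquisitionScheme(c(0, rep(800, 6)), cbind(c(0, 0, 0), matrix(g, 3, 6)))
  ser3 <- volumeSeries(ex$series@volumes, sch3)
  expect_error(fitDtiWls(ser3, ex$phantom$brain_mask), "rank deficient")
})

test_that("WLS keeps the in-structure FA bias small under Rician noise", {
  sp <- phantomSpec(grid = c(40L, 40L, 24L))
  ph <- buildPhantom(sp)
  ser <- simulateSignal(ph, multiShellScheme("A"), S0 = sp$S0,
                        noise_sigma = sp$S0 / 30, seed = 11)
  fit <- fitDtiWls(ser, ph$roi_masks$structure)
  fa <- .subset(dwiQC::deriveMaps(fit)$FA, fit@voxels)
  expect_gt(length(fa), 1000L)
  expect_lt(abs(median(fa) - 0.8703883), 0.03)
})

test_that("scalar maps follow their defining formulas", {
  mkfit <- function(evals) new("DTIFit", beta = matrix(0, 7, nrow(evals)),
                               evals = evals, voxels = seq_len(nrow(evals)),
                               dims = c(nrow(evals), 1L, 1L), method = "wls")
  d <- 1.3e-3
  m_iso <- deriveMaps(mkfit(matrix(d, 1, 3)))
  expect_equal(m_iso$FA[1], 0)
  expect_equal(m_iso$MD[1], d)
  expect_equal(m_iso$AD[1], d)
  expect_equal(m_iso$RD[1], d)
  m_cc <- deriveMaps(mkfit(matrix(c(1.7e-3, 0.2e-3, 0.2e-3), 1)))
  expect_equal(m_cc$MD[1], 0.7e-3)
  expect_equal(m_cc$AD[1], 1.7e-3)
  expect_equal(m_cc$RD[1], 0.2e-3)
  expect_equal(m_cc$FA[1], 0.8703883, tolerance = 1e-7)
  # stick tensor: FA = 1; all-zero eigenvalues: FA defined as 0
  m_stick <- deriveMaps(mkfit(matrix(c(d, 0, 0), 1)))
  expect_equal(m_stick$FA[1], 1)
  expect_equal(deriveMaps(mkfit(matrix(0, 1, 3)))$FA[1], 0)
})

test_that("ROI extraction keeps nonzero in-mask voxels and flags empties", {
  map <- array(1, c(5, 5, 4))
  map[1:3] <- 0
  mask <- array(TRUE, c(5, 5, 4))
  v <- extractRoi(map, mask)
  expect_length(v, 100L - 3L)
  expect_true(all(v == 1))
  mask2 <- array(FALSE, c(5, 5, 4)); mask2[1:3] <- TRUE
  expect_warning(v2 <- extractRoi(map, mask2), "no nonzero")
  expect_length(v2, 0L)
  expect_true(attr(v2, "empty"))
  expect_error(extractRoi(map, array(TRUE, c(4, 4, 4))), "shape")
})

test_that("Lin's CCC matches its definition, with the documented properties", {
  expect_equal(linCCC(1:5, 1:5)$ccc, 1)
  expect_equal(linCCC(c(1, 2, 3), c(3, 2, 1))$ccc, -1)
  set.seed(14)
  for (i in 1:25) {
    x <- rnorm(50, sd = runif(1, 0.5, 3))
    y <- 0.5 * x + rnorm(50, mean = runif(1, -1, 1))
    cc <- linCCC(x, y)
    # independent direct-formula evaluation with divisor n
    n <- 50
    oracle <- 2 * (sum((x - mean(x)) * (y - mean(y))) / n) /
      (sum((x - mean(x))^2) / n + sum((y - mean(y))^2) / n + (mean(x) - mean(y))^2)
    expect_equal(cc$ccc, oracle, tolerance = 1e-12)
    expect_lte(abs(cc$ccc), abs(cc$pearson) + 1e-12)
    expect_equal(linCCC(y, x)$ccc, cc$ccc, tolerance = 1e-12)  # symmetry
  }
  expect_error(linCCC(1, 1), "at least 2")
  expect_error(linCCC(c(1, 1), c(2, 2)), "constant")
})

test_that("pipeline comparison agrees with the reference test statistics", {
  a <- c(1, 2, 3, 4)
  r0 <- comparePipelines(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$F, 1)
  expect_false(r0$sig_t || r0$sig_F)

  set.seed(15)
  a <- rnorm(200); b <- rnorm(200, mean = 1)
  r1 <- comparePipelines(a, b)
  expect_true(r1$sig_t)
  expect_false(r1$sig_F)
  # variance ratio 4, equal means
  c2 <- rnorm(200, sd = 2)
  r2 <- comparePipelines(c2, rnorm(200, sd = 1))
  expect_gt(r2$F, 2.5)
  expect_true(r2$sig_F)
  expect_error(comparePipelines(1, c(1, 2)), "n >= 2")
})

test_that("FA is invariant under joint rotation of gradients and tensor field", {
  ex <- noiseless_exam(grid = c(16L, 16L, 10L), extra = 10L)
  fit1 <- fitDtiWls(ex$series, ex$phantom$brain_mask)
  th <- 0.7; ax <- c(1, 1, 1) / sqrt(3)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  # signals S(g; D) = S(Rg; R D R'): refit the same data against rotated
  # gradients; the recovered tensors are rotated, eigenvalues unchanged
  sch_rot <- acquisitionScheme(bvalues(ex$series), R %*% bvectors(ex$series))
  ser_rot <- volumeSeries(ex$series@volumes, sch_rot)
  fit2 <- fitDtiWls(ser_rot, ex$phantom$brain_mask)
  expect_equal(dwiQC:::.fa_from_evals(fit2@evals),
               dwiQC:::.fa_from_evals(fit1@evals), tolerance = 1e-8)
})

test_that("deleting clean volumes from a noiseless series leaves FA unchanged", {
  ex <- noiseless_exam(grid = c(14L, 14L, 10L), extra = 20L)  # 27 volumes
  fit_full <- fitDtiWls(ex$series, ex$phantom$brain_mask)
  ser <- ex$series
  labs <- rep(0L, nVolumes(ser))
  drop <- dwiQC:::.with_seed(3, sample(which(bvalues(ser) > 0), 12L))
  labs[drop] <- 1L
  artifactLabels(ser) <- labs
  sub <- applyQC(ser, "manual")
  expect_equal(nVolumes(sub), 15L)
  fit_sub <- fitDtiWls(sub, ex$phantom$brain_mask)
  fa_full <- dwiQC:::.fa_from_evals(fit_full@evals)
  fa_sub <- dwiQC:::.fa_from_evals(fit_sub@evals)
  expect_lt(max(abs(fa_full - fa_sub)), 1e-6)
})

test_that("a zero-artifact study gives identical pipelines: CCC 1, null tests", {
  rec <- datasetRecipe(3L, scheme = tiny_scheme(extra = 13L), prevalence = 0,
                       phantom = phantomSpec(grid = c(16L, 16L, 16L),
                                             noise_sigma = 20), seed = 5)
  exams <- lapply(1:3, function(i) simulateExam(rec, i))
  net <- buildNetwork(networkConfig(input_shape = c(16L, 16L, 16L)), seed = 1)
  res <- qcImpactStudy(exams, net, threshold = 1 - 1e-9)
  expect_true(all(abs(res$ccc$ccc - 1) < 1e-12))
  expect_true(all(res$tests$t == 0))
  expect_true(all(res$tests$F == 1))
  expect_false(any(res$tests$sig_t | res$tests$sig_F))
})

test_that("a single-subject study emits tests but no CCC rows", {
  rec <- datasetRecipe(1L, scheme = tiny_scheme(extra = 13L), prevalence = 0,
                       phantom = phantomSpec(grid = c(16L, 16L, 16L),
                                             noise_sigma = 20), seed = 6)
  exams <- list(simulateExam(rec, 1))
  net <- buildNetwork(networkConfig(input_shape = c(16L, 16L, 16L)), seed = 1)
  res <- qcImpactStudy(exams, net, threshold = 1 - 1e-9)
  expect_null(res$ccc)
  expect_false(is.null(res$tests))
})
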
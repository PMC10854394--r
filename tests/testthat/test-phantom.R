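spec_small <- function(...) phantomSpec(grid = c(20L, 20L, 12L), noise_sigma = 0, ...)

test_that("an isotropic phantom has FA 0 everywhere in the mask", {
  sp <- spec_small(eigen_structure = rep(1e-3, 3L))
  ph <- buildPhantom(sp)
  # every in-mask tensor is d * I, whose eigenvalues are equal
  v <- which(ph$brain_mask)[c(1, 50, 200)]
  for (i in v) {
    D <- matrix(0, 3, 3)
    D[1, 1] <- ph$tensors[,,,1][i]; D[2, 2] <- ph$tensors[,,,2][i]
    D[3, 3] <- ph$tensors[,,,3][i]
    D[1, 2] <- D[2, 1] <- ph$tensors[,,,4][i]
    D[1, 3] <- D[3, 1] <- ph$tensors[,,,5][i]
    D[2, 3] <- D[3, 2] <- ph$tensors[,,,6][i]
    expect_equal(fa_oracle(eigen(D)$values), 0)
  }
})

test_that("the anisotropic structure matches the closed-form FA", {
  # frozen from the independent oracle: fa_oracle(c(1.7, 0.2, 0.2) * 1e-3)
  expect_equal(fa_oracle(c(1.7e-3, 0.2e-3, 0.2e-3)), 0.8703883, tolerance = 1e-7)
  ph <- buildPhantom(spec_small())
  i <- which(ph$roi_masks$structure)[1L]
  D <- matrix(c(ph$tensors[,,,1][i], ph$tensors[,,,4][i], ph$tensors[,,,5][i],
                ph$tensors[,,,4][i], ph$tensors[,,,2][i], ph$tensors[,,,6][i],
                ph$tensors[,,,5][i], ph$tensors[,,,6][i], ph$tensors[,,,3][i]), 3)
  expect_equal(fa_oracle(eigen(D)$values), 0.8703883, tolerance = 1e-6)
})

test_that("phantom construction is deterministic and validates geometry", {
  expect_identical(buildPhantom(spec_small()), buildPhantom(spec_small()))
  bad <- spec_small()
  bad$structure_extent <- bad$grid  # slab larger than the brain
  expect_error(buildPhantom(bad), "outside the brain mask")
})

test_that("noiseless signal follows S0 exp(-b g'Dg)", {
  sp <- spec_small()
  ph <- buildPhantom(sp)
  sch <- acquisitionScheme(c(0, 800, 800),
                           cbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)))
  ser <- simulateSignal(ph, sch, S0 = 500, noise_sigma = 0)
  inmask <- which(ph$brain_mask & !ph$roi_masks$structure)
  instr <- which(ph$roi_masks$structure)
  # b = 0: every in-mask voxel equals S0
  expect_equal(unique(ser@volumes[[1L]][inmask]), 500)
  # isotropic background, any direction: S0 exp(-b d)
  expect_equal(unique(round(ser@volumes[[2L]][inmask], 9)),
               round(500 * exp(-800 * 1e-3), 9))
  # structure, gradient along the principal axis, eigenvalue 1.7e-3:
  # S0 exp(-800 * 1.7e-3) = S0 exp(-1.36)
  expect_equal(unique(round(ser@volumes[[2L]][instr], 9)),
               round(500 * exp(-1.36), 9))
  expect_identical(artifactLabels(ser), rep(0L, 3L))
  # determinism and positivity
  ser2 <- simulateSignal(ph, sch, S0 = 500, noise_sigma = 0)
  expect_identical(ser@volumes, ser2@volumes)
  expect_true(all(ser@volumes[[2L]][ph$brain_mask] > 0))
})

test_that("Rician noise shows the expected high-SNR bias bound", {
  sp <- phantomSpec(grid = c(40L, 40L, 20L))
  ph <- buildPhantom(sp)
  sch <- acquisitionScheme(0, matrix(0, 3, 1))
  S0 <- 1000; sigma <- 100  # SNR 10
  noisy <- simulateSignal(ph, sch, S0 = S0, noise_sigma = sigma, seed = 3)
  inmask <- which(ph$brain_mask)
  expect_gt(length(inmask), 1e4)
  bias <- mean(noisy@volumes[[1L]][inmask]) - S0
  expect_gt(bias, 0)                 # Rician bias is positive
  expect_lt(bias, 2 * sigma^2 / S0)  # high-SNR Gaussian limit bound
})

test_that("slice dropout scales energy by a^2 and touches nothing else", {
  v <- array(runif(8 * 8 * 10, 1, 2), c(8, 8, 10))
  a <- 0.4
  out <- injectArtifact(v, artifactSpec("slice_dropout", slices = c(3L, 4L),
                                        attenuation = a))
  expect_equal(out$label, 1L)
  expect_equal(sum(out$volume[, , 4:5]^2), a^2 * sum(v[, , 4:5]^2))
  expect_identical(out$volume[, , -(4:5)], v[, , -(4:5)])
  expect_identical(v, v)  # input untouched
  # attenuation 0 zeroes the slices
  z <- injectArtifact(v, artifactSpec("slice_dropout", slices = c(0L, 9L),
                                      attenuation = 0))
  expect_true(all(z$volume[, , c(1L, 10L)] == 0))
  expect_error(injectArtifact(v, artifactSpec("slice_dropout", slices = 10L)),
               "out of range")
})

test_that("interleave halves every period-th slice; identity misalignment is exact", {
  v <- array(runif(6 * 6 * 8, 1, 2), c(6, 6, 8))
  out <- injectArtifact(v, artifactSpec("interleave", period = 2L, amplitude = 0.5))
  even <- seq(1L, 8L, by = 2L)  # 0-based slices 0, 2, 4, 6
  expect_equal(out$volume[, , even], v[, , even] * 0.5)
  expect_identical(out$volume[, , -even], v[, , -even])
  idn <- injectArtifact(v, artifactSpec("misalignment", rotation = c(0, 0, 0),
                                        translation = c(0, 0, 0)))
  expect_equal(idn$volume, v, tolerance = 1e-12)
  # a real misalignment changes the volume
  mv <- injectArtifact(v, artifactSpec("misalignment", rotation = c(5, 0, 0),
                                       translation = c(1, 0, 0)))
  expect_gt(max(abs(mv$volume - v)), 0.01)
})

test_that("generated datasets hit the requested prevalence and reproduce", {
  ph <- phantomSpec(grid = c(12L, 12L, 8L))
  sch <- tiny_scheme(extra = 3L)  # 10 volumes
  rec0 <- datasetRecipe(3L, scheme = sch, prevalence = 0, phantom = ph, seed = 2)
  expect_true(all(generateDataset(rec0)$manifest$label == 0L))
  rec1 <- datasetRecipe(3L, scheme = sch, prevalence = 1, phantom = ph, seed = 2)
  expect_true(all(generateDataset(rec1)$manifest$label == 1L))

  rec <- datasetRecipe(10L, scheme = multiShellScheme("A"), prevalence = 0.11,
                       phantom = phantomSpec(grid = c(8L, 8L, 8L)), seed = 7)
  d1 <- generateDataset(rec)
  n <- nrow(d1$manifest)
  se <- sqrt(0.11 * 0.89 / n)
  expect_lt(abs(d1$corrupted_fraction - 0.11), 3 * se)  # binomial oracle
  d2 <- generateDataset(rec)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(lapply(d1$series, seriesVolumes), lapply(d2$series, seriesVolumes))
})

test_that("the two standard schemes have the documented shell structure", {
  a <- multiShellScheme("A")
  expect_equal(nVolumes(a), 69L)
  expect_equal(as.vector(table(bvalues(a))), c(6L, 9L, 18L, 36L))
  b <- multiShellScheme("B")
  expect_equal(nVolumes(b), 105L)
  expect_equal(sort(unique(bvalues(b))), c(0, 300, 800, 1200, 2500))
})
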
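# Synthetic multi-shell diffusion phantom with parametric motion artifacts.
# Every downstream stage (curation, training, tensor fitting, QC-impact
# analysis) is testable against its known ground truth.

#' Describe a synthetic diffusion phantom
#'
#' The phantom is an ellipsoidal "brain" of isotropic tissue containing a
#' corpus-callosum-like anisotropic slab with known tensor eigenvalues, plus
#' an isotropic control region; both are returned as ROI masks so region
#' statistics can be computed without atlas registration.
#'
#' @param grid integer grid shape (nx, ny, nz) in voxels.
#' @param semi_axes ellipsoid semi-axes of the brain mask (voxels).
#' @param structure_center,structure_extent slab center and half-extents
#'   (voxels).
#' @param structure_dir unit principal diffusion direction of the slab.
#' @param eigen_structure,eigen_background tensor eigenvalues (mm^2/s),
#'   descending, for the anisotropic slab and the background tissue.
#' @param S0 baseline (b = 0) signal intensity, arbitrary units.
#' @param noise_sigma Rician noise level (same units as \code{S0}).
#' @param seed integer seed for the noise stream.
#' @return A \code{phantomSpec} list.
#' @export
phantomSpec <- function(grid = c(64L, 64L, 36L),
                        semi_axes = 0.45 * grid,
                        structure_center = grid / 2,
                        structure_extent = c(0.28, 0.13, 0.10) * grid,
                        structure_dir = c(1, 0, 0),
                        eigen_structure = c(1.7e-3, 0.2e-3, 0.2e-3),
                        eigen_background = rep(1.0e-3, 3L),
                        S0 = 1000, noise_sigma = S0 / 30, seed = 1L) {
  if (any(eigen_structure <= 0) || any(eigen_background <= 0))
    .stop2("tensor eigenvalues must be positive")
  if (noise_sigma < 0) .stop2("noise_sigma must be non-negative")
  structure_dir <- structure_dir / sqrt(sum(structure_dir^2))
  spec <- list(grid = as.integer(grid), semi_axes = semi_axes,
               structure_center = structure_center,
               structure_extent = structure_extent,
               structure_dir = structure_dir,
               eigen_structure = eigen_structure,
               eigen_background = eigen_background,
               S0 = S0, noise_sigma = noise_sigma, seed = as.integer(seed))
  class(spec) <- "phantomSpec"
  spec
}

# symmetric tensor with eigenvalues l (descending) and principal direction v:
# D = l2 I + (l1 - l2) v v' + (l3 - l2) u u'  with u a unit vector orthogonal
# to v (only relevant when l2 != l3)
.make_tensor <- function(l, v) {
  D <- diag(rep(l[2L], 3L)) + (l[1L] - l[2L]) * tcrossprod(v)
  if (abs(l[3L] - l[2L]) > 0) {
    ref <- if (abs(v[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * v) * v
    u <- u / sqrt(sum(u^2))
    D <- D + (l[3L] - l[2L]) * tcrossprod(u)
  }
  D
}

#' Build the phantom tensor field and masks
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return A list with \code{tensors} (nx x ny x nz x 6 array of
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz; zero outside the brain), \code{brain_mask},
#'   and \code{roi_masks} (logical arrays: \code{structure}, the anisotropic
#'   slab; \code{control}, an isotropic region). Deterministic given the spec.
#' @export
buildPhantom <- function(spec) {
  g <- spec$grid
  cx <- (g + 1) / 2
  ix <- slice.index(array(0, g), 1L)
  iy <- slice.index(array(0, g), 2L)
  iz <- slice.index(array(0, g), 3L)
  brain <- ((ix - cx[1L]) / spec$semi_axes[1L])^2 +
    ((iy - cx[2L]) / spec$semi_axes[2L])^2 +
    ((iz - cx[3L]) / spec$semi_axes[3L])^2 <= 1
  sc <- spec$structure_center
  se <- spec$structure_extent
  slab <- abs(ix - sc[1L]) <= se[1L] & abs(iy - sc[2L]) <= se[2L] &
    abs(iz - sc[3L]) <= se[3L]
  if (any(slab & !brain))
    .stop2("anisotropic structure extends outside the brain mask (%d voxels)",
           sum(slab & !brain))
  # control ROI: isotropic ball displaced along y, clear of the slab
  cc <- sc + c(0, se[2L] + 0.18 * g[2L], 0)
  r <- 0.10 * min(g)
  control <- ((ix - cc[1L])^2 + (iy - cc[2L])^2 + (iz - cc[3L])^2) <= r^2 & brain & !slab

  Dbg <- .make_tensor(spec$eigen_background, c(1, 0, 0))
  Dst <- .make_tensor(spec$eigen_structure, spec$structure_dir)
  comp <- function(D) c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  tensors <- array(0, c(g, 6L))
  for (k in 1:6) {
    plane <- array(0, g)
    plane[brain] <- comp(Dbg)[k]
    plane[slab] <- comp(Dst)[k]
    tensors[, , , k] <- plane
  }
  list(tensors = tensors, brain_mask = brain,
       roi_masks = list(structure = slab, control = control))
}

#' Simulate the diffusion-weighted signal of a phantom
#'
#' The noiseless signal follows the monoexponential tensor model
#' \eqn{S = S_0 \exp(-b\, g^T D g)} per voxel and volume. With
#' \code{noise_sigma > 0}, Rician noise is applied (magnitude of a complex
#' Gaussian perturbation), the appropriate model for magnitude MRI; a
#' Gaussian option is available for analytic tests.
#'
#' @param phantom output of \code{\link{buildPhantom}}.
#' @param scheme an \linkS4class{AcquisitionScheme}.
#' @param S0 baseline intensity (a.u.).
#' @param noise_sigma noise level; 0 gives the deterministic noiseless signal.
#' @param seed RNG seed for the noise.
#' @param noise_model "rician" (default) or "gaussian".
#' @param subject,session identifiers for the resulting series.
#' @return A \linkS4class{VolumeSeries} with labels initialised to all 0.
#' @export
simulateSignal <- function(phantom, scheme, S0 = 1000, noise_sigma = 0,
                           seed = 1L, noise_model = c("rician", "gaussian"),
                           subject = "sub01", session = "ses01") {
  noise_model <- match.arg(noise_model)
  if (S0 <= 0) .stop2("S0 must be positive")
  validObject(scheme)
  tens <- phantom$tensors
  g <- dim(tens)[1:3]
  n <- nVolumes(scheme)
  base <- S0 * phantom$brain_mask
  vols <- .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      b <- scheme@bvals[i]
      v <- scheme@bvecs[, i]
      q <- b * (v[1L]^2 * tens[, , , 1L] + v[2L]^2 * tens[, , , 2L] +
                  v[3L]^2 * tens[, , , 3L] + 2 * v[1L] * v[2L] * tens[, , , 4L] +
                  2 * v[1L] * v[3L] * tens[, , , 5L] + 2 * v[2L] * v[3L] * tens[, , , 6L])
      s <- base * exp(-q)
      if (noise_sigma > 0) {
        if (noise_model == "rician") {
          s <- sqrt((s + rnorm(length(s), 0, noise_sigma))^2 +
                      rnorm(length(s), 0, noise_sigma)^2)
        } else {
          s <- s + rnorm(length(s), 0, noise_sigma)
        }
        dim(s) <- g
      }
      s
    })
  })
  volumeSeries(vols, scheme, subject = subject, session = session,
               labels = rep(0L, n))
}

#' Describe a motion artifact
#'
#' Three slice-wise artifact families along the axial (third) axis, matching
#' the phenomenology of interleaved 2D-EPI motion corruption: whole-slice
#' signal dropout, alternating-slice ("venetian blind") interleave
#' modulation, and rigid misalignment.
#'
#' @param kind one of "slice_dropout", "interleave", "misalignment".
#' @param slices 0-based axial slice indices (slice_dropout).
#' @param attenuation multiplicative factor in [0, 1) for dropped slices.
#' @param period integer >= 2: every period-th axial slice is modulated
#'   (interleave).
#' @param amplitude multiplicative factor in (0, 1] for modulated slices.
#' @param rotation per-axis rotation in degrees (misalignment).
#' @param translation per-axis translation in voxels (misalignment).
#' @return An \code{artifactSpec} list.
#' @export
artifactSpec <- function(kind = c("slice_dropout", "interleave", "misalignment"),
                         slices = integer(0), attenuation = 0,
                         period = 2L, amplitude = 0.5,
                         rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  kind <- match.arg(kind)
  if (kind == "slice_dropout") {
    if (attenuation < 0 || attenuation >= 1)
      .stop2("attenuation must lie in [0, 1)")
  } else if (kind == "interleave") {
    if (period < 2L) .stop2("interleave period must be >= 2")
    if (amplitude <= 0 || amplitude > 1) .stop2("amplitude must lie in (0, 1]")
  }
  structure(list(kind = kind, slices = as.integer(slices),
                 attenuation = attenuation, period = as.integer(period),
                 amplitude = amplitude, rotation = rotation,
                 translation = translation),
            class = "artifactSpec")
}

.rigid_resample <- function(vol, rotation, translation) {
  d <- dim(vol)
  ctr <- (d + 1) / 2
  rad <- rotation * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(rad[1]), -sin(rad[1])), c(0, sin(rad[1]), cos(rad[1])))
  ry <- rbind(c(cos(rad[2]), 0, sin(rad[2])), c(0, 1, 0), c(-sin(rad[2]), 0, cos(rad[2])))
  rz <- rbind(c(cos(rad[3]), -sin(rad[3]), 0), c(sin(rad[3]), cos(rad[3]), 0), c(0, 0, 1))
  R <- rz %*% ry %*% rx
  ix <- as.vector(slice.index(vol, 1L)) - ctr[1L]
  iy <- as.vector(slice.index(vol, 2L)) - ctr[2L]
  iz <- as.vector(slice.index(vol, 3L)) - ctr[3L]
  # inverse mapping: source = R^T (target - center) + center - translation
  src <- t(R) %*% rbind(ix, iy, iz)
  sx <- src[1L, ] + ctr[1L] - translation[1L]
  sy <- src[2L, ] + ctr[2L] - translation[2L]
  sz <- src[3L, ] + ctr[3L] - translation[3L]
  x0 <- floor(sx); y0 <- floor(sy); z0 <- floor(sz)
  fx <- sx - x0; fy <- sy - y0; fz <- sz - z0
  out <- numeric(length(sx))
  at <- function(x, y, z) {
    ok <- x >= 1 & x <= d[1L] & y >= 1 & y <= d[2L] & z >= 1 & z <= d[3L]
    v <- numeric(length(x))
    idx <- ((z[ok] - 1) * d[2L] + (y[ok] - 1)) * d[1L] + x[ok]
    v[ok] <- vol[idx]
    v
  }
  out <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  array(out, d)
}

#' Inject a motion artifact into a volume
#'
#' \code{slice_dropout} multiplies the named axial slices by the attenuation
#' factor; \code{interleave} multiplies every period-th axial slice by the
#' amplitude factor; \code{misalignment} applies a rigid rotation +
#' translation with trilinear interpolation and zero fill. All other voxels
#' are untouched and the input volume is never mutated.
#'
#' @param volume a 3D array.
#' @param spec an \code{\link{artifactSpec}}.
#' @return A list with the corrupted \code{volume} and \code{label = 1L}.
#' @export
injectArtifact <- function(volume, spec) {
  d <- dim(volume)
  out <- volume
  if (spec$kind == "slice_dropout") {
    if (length(spec$slices) == 0L) .stop2("slice_dropout needs slice indices")
    if (any(spec$slices < 0L | spec$slices >= d[3L]))
      .stop2("slice index out of range [0, %d): %s", d[3L],
             paste(spec$slices[spec$slices < 0L | spec$slices >= d[3L]], collapse = ", "))
    out[, , spec$slices + 1L] <- out[, , spec$slices + 1L] * spec$attenuation
  } else if (spec$kind == "interleave") {
    sl <- seq.int(0L, d[3L] - 1L, by = spec$period)
    out[, , sl + 1L] <- out[, , sl + 1L] * spec$amplitude
  } else {
    out <- .rigid_resample(volume, spec$rotation, spec$translation)
  }
  list(volume = out, label = 1L)
}

# approximately uniform unit directions on the sphere (spherical Fibonacci)
.sphere_dirs <- function(m) {
  i <- seq_len(m) - 0.5
  z <- 1 - 2 * i / m
  phi <- (seq_len(m) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(cos(phi) * r, sin(phi) * r, z)
}

#' Multi-shell infant acquisition schemes
#'
#' Two standard layouts: "A" (69 volumes: 6 at b = 0, then 9/18/36 directions
#' at b = 350/800/1500 s/mm^2) and "B" (105 volumes: 6 at b = 0, then
#' 9/15/30/45 directions at b = 300/800/1200/2500 s/mm^2). Directions are a
#' deterministic spherical Fibonacci spread per shell.
#'
#' @param layout "A" or "B".
#' @return An \linkS4class{AcquisitionScheme}.
#' @export
multiShellScheme <- function(layout = c("A", "B")) {
  layout <- match.arg(layout)
  plan <- if (layout == "A") {
    list(b = c(0, 350, 800, 1500), n = c(6L, 9L, 18L, 36L))
  } else {
    list(b = c(0, 300, 800, 1200, 2500), n = c(6L, 9L, 15L, 30L, 45L))
  }
  bvals <- rep(plan$b, plan$n)
  bvecs <- do.call(cbind, lapply(seq_along(plan$b), function(i) {
    if (plan$b[i] == 0) matrix(0, 3L, plan$n[i]) else .sphere_dirs(plan$n[i])
  }))
  acquisitionScheme(bvals, bvecs)
}

#' Describe a synthetic dataset
#'
#' The recipe fixes the study conditions for a simulated cohort: number of
#' subjects, acquisition layout, per-volume artifact prevalence, the severity
#' distribution of injected artifacts, and between-subject anatomical /
#' intensity variation.
#'
#' @param n_subjects number of subjects (one exam each).
#' @param scheme an \linkS4class{AcquisitionScheme} shared by all exams.
#' @param prevalence probability in [0, 1] that a volume is corrupted.
#' @param severity list describing the artifact severity distribution; see
#'   Details.
#' @param phantom base \code{\link{phantomSpec}}; per-subject geometry,
#'   eigenvalues and intensity are jittered around it.
#' @param jitter list of relative jitter amplitudes (\code{axes},
#'   \code{eigen}, \code{s0}).
#' @param seed master seed; all per-subject randomness is derived from it.
#' @details The default severity distribution spans severe to subtle motion:
#'   a corrupted volume receives slice dropout (probability 0.5; 1 to nz/4
#'   slices, attenuation uniform on [0, 0.5]) or interleave modulation
#'   (period 2, amplitude uniform on [0.3, 0.8]).
#' @return A \code{datasetRecipe} list.
#' @export
datasetRecipe <- function(n_subjects, scheme = multiShellScheme("A"),
                          prevalence = 0.11,
                          severity = list(kind_probs = c(slice_dropout = 0.5,
                                                         interleave = 0.5),
                                          dropout_slice_frac = 0.25,
                                          attenuation_range = c(0, 0.5),
                                          interleave_period = 2L,
                                          amplitude_range = c(0.3, 0.8)),
                          phantom = phantomSpec(),
                          jitter = list(axes = 0.08, eigen = 0.12, s0 = 0.10),
                          seed = 1L) {
  if (n_subjects < 1L) .stop2("n_subjects must be >= 1")
  if (prevalence < 0 || prevalence > 1) .stop2("prevalence must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects), scheme = scheme,
                 prevalence = prevalence, severity = severity,
                 phantom = phantom, jitter = jitter, seed = as.integer(seed)),
            class = "datasetRecipe")
}

.sample_artifact <- function(severity, nz) {
  kinds <- names(severity$kind_probs)
  kind <- sample(kinds, 1L, prob = severity$kind_probs)
  if (kind == "slice_dropout") {
    nmax <- max(1L, floor(nz * severity$dropout_slice_frac))
    ns <- sample.int(nmax, 1L)
    start <- sample.int(nz - ns + 1L, 1L) - 1L
    artifactSpec("slice_dropout", slices = start + seq_len(ns) - 1L,
                 attenuation = runif(1L, severity$attenuation_range[1L],
                                     severity$attenuation_range[2L]))
  } else if (kind == "interleave") {
    artifactSpec("interleave", period = severity$interleave_period,
                 amplitude = runif(1L, severity$amplitude_range[1L],
                                   severity$amplitude_range[2L]))
  } else {
    artifactSpec("misalignment", rotation = runif(3L, -8, 8),
                 translation = runif(3L, -3, 3))
  }
}

#' Simulate a single labelled exam
#'
#' Deterministic given (recipe, index): the per-subject phantom jitter, noise
#' stream and artifact draws all derive from the recipe seed.
#'
#' @param recipe a \code{\link{datasetRecipe}}.
#' @param index subject index in 1..n_subjects.
#' @return A list: \code{series} (labelled \linkS4class{VolumeSeries}),
#'   \code{brain_mask}, \code{roi_masks}, and the jittered \code{phantom}
#'   spec used.
#' @export
simulateExam <- function(recipe, index) {
  subject <- sprintf("sub%03d", index)
  sseed <- .derive_seed(recipe$seed, paste0("subject-", index))
  base <- recipe$phantom
  .with_seed(sseed, {
    jit <- function(x, amp) x * (1 + runif(length(x), -amp, amp))
    spec <- base
    spec$semi_axes <- jit(base$semi_axes, recipe$jitter$axes)
    spec$structure_extent <- jit(base$structure_extent, recipe$jitter$axes / 2)
    spec$eigen_structure <- jit(base$eigen_structure, recipe$jitter$eigen)
    spec$eigen_background <- rep(jit(base$eigen_background[1L], recipe$jitter$eigen), 3L)
    spec$S0 <- jit(base$S0, recipe$jitter$s0)
    ph <- buildPhantom(spec)
    noise_seed <- sample.int(.Machine$integer.max, 1L)
    series <- simulateSignal(ph, recipe$scheme, S0 = spec$S0,
                             noise_sigma = spec$noise_sigma, seed = noise_seed,
                             subject = subject, session = "ses01")
    n <- nVolumes(series)
    nz <- dim(series@volumes[[1L]])[3L]
    labels <- rep(0L, n)
    corrupt <- runif(n) < recipe$prevalence
    for (i in which(corrupt)) {
      art <- .sample_artifact(recipe$severity, nz)
      series@volumes[[i]] <- injectArtifact(series@volumes[[i]], art)$volume
      labels[i] <- 1L
    }
    artifactLabels(series) <- labels
    list(series = series, brain_mask = ph$brain_mask, roi_masks = ph$roi_masks,
         phantom = spec)
  })
}

#' Generate a labelled synthetic dataset
#'
#' @param recipe a \code{\link{datasetRecipe}}.
#' @return A list with \code{series} (list of labelled
#'   \linkS4class{VolumeSeries}), \code{manifest} (ground-truth label
#'   manifest), and \code{corrupted_fraction}, the realised per-volume
#'   corruption rate. Bit-reproducible given the recipe.
#' @export
generateDataset <- function(recipe) {
  exams <- lapply(seq_len(recipe$n_subjects), function(i) simulateExam(recipe, i))
  series <- lapply(exams, `[[`, "series")
  manifest <- do.call(rbind, lapply(series, function(s)
    data.frame(subject_id = s@subject, session_id = s@session,
               volume_index = seq_len(nVolumes(s)) - 1L, label = s@labels)))
  list(series = series, manifest = manifest,
       corrupted_fraction = mean(manifest$label))
}
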
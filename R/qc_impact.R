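# Downstream QC impact: apply a QC policy, fit the diffusion tensor by
# weighted least squares, derive scalar maps, and compare pipelines with
# Lin's concordance correlation and per-subject t/F tests.

#' Apply a quality-control policy to an exam
#'
#' \code{none} returns the series unchanged; \code{manual} removes the
#' volumes labelled as artifact (the reference reader labels); \code{model}
#' removes the volumes the classifier calls artifact at the given threshold.
#' Scheme entries and labels are removed in lockstep with the volumes. If a
#' whole shell (all volumes of one b-value) is removed, a warning is issued.
#'
#' @param series a \linkS4class{VolumeSeries}.
#' @param mode one of "none", "manual", "model".
#' @param model a trained \linkS4class{QCNetwork} (mode = "model").
#' @param threshold decision threshold for model QC.
#' @return The retained subset as a \linkS4class{VolumeSeries}.
#' @export
applyQC <- function(series, mode = c("none", "manual", "model"), model = NULL,
                    threshold = 0.5) {
  mode <- match.arg(mode)
  if (mode == "none") return(series)
  if (mode == "manual") {
    if (length(series@labels) == 0L)
      .stop2("manual QC requires a labelled series")
    drop <- series@labels == 1L
  } else {
    if (is.null(model)) .stop2("model QC requires a trained model")
    p <- predictSeries(model, series)
    drop <- classifyVolumes(p, threshold) == 1L
  }
  keep <- which(!drop)
  shells <- unique(round(series@scheme@bvals))
  gone <- setdiff(shells, unique(round(series@scheme@bvals[keep])))
  if (length(gone))
    warning(sprintf("QC removed every volume of shell(s) b = %s",
                    paste(gone, collapse = ", ")), call. = FALSE)
  new("VolumeSeries", subject = series@subject, session = series@session,
      volumes = series@volumes[keep],
      scheme = acquisitionScheme(series@scheme@bvals[keep],
                                 series@scheme@bvecs[, keep, drop = FALSE]),
      labels = if (length(series@labels)) series@labels[keep] else integer(0),
      affine = series@affine)
}

.dti_design <- function(scheme) {
  b <- scheme@bvals
  g <- scheme@bvecs
  cbind(1, -b * g[1L, ]^2, -b * g[2L, ]^2, -b * g[3L, ]^2,
        -2 * b * g[1L, ] * g[2L, ], -2 * b * g[1L, ] * g[3L, ],
        -2 * b * g[2L, ] * g[3L, ])
}

#' Fit the diffusion tensor by weighted least squares
#'
#' Per in-mask voxel the log-linear tensor model
#' \eqn{\ln S = \ln S_0 - b\, g^T D g} is solved: first by ordinary least
#' squares, then (for \code{method = "wls"}) one reweighted pass with weights
#' equal to the squared predicted signals, the standard variance model for
#' log-transformed magnitude data. Non-positive signals (possible under heavy
#' noise) are clipped to \code{floor_frac} of the voxel's baseline before the
#' log.
#'
#' @param series a \linkS4class{VolumeSeries} with at least 7 volumes,
#'   at least one \code{b = 0} volume and 6 non-collinear directions.
#' @param mask logical 3D array selecting the voxels to fit.
#' @param method "wls" (default) or "ols".
#' @param floor_frac positive floor applied to the signal, as a fraction of
#'   the voxel's mean b = 0 intensity.
#' @return A \linkS4class{DTIFit}.
#' @export
fitDtiWls <- function(series, mask, method = c("wls", "ols"), floor_frac = 1e-6) {
  method <- match.arg(method)
  n <- nVolumes(series)
  if (n < 7L) .stop2("tensor fitting needs >= 7 volumes, got %d", n)
  if (!any(series@scheme@bvals == 0))
    .stop2("tensor fitting needs at least one b = 0 volume")
  X <- .dti_design(series@scheme)
  if (qr(X)$rank < 7L)
    .stop2("gradient scheme is rank deficient (rank %d < 7): directions are collinear",
           qr(X)$rank)
  d <- dim(series@volumes[[1L]])
  if (!identical(dim(mask), d)) .stop2("mask shape does not match the volumes")
  vox <- which(mask)
  if (!length(vox)) .stop2("empty mask")
  S <- vapply(series@volumes, function(v) v[vox], numeric(length(vox)))
  b0 <- series@scheme@bvals == 0
  s0 <- rowMeans(S[, b0, drop = FALSE])
  floorv <- pmax(floor_frac * pmax(s0, 0), .Machine$double.xmin)
  S <- pmax(S, floorv)  # recycles per voxel down the columns
  fit <- .dti_fit(X, t(log(S)), method == "wls")
  new("DTIFit", beta = fit$beta, evals = t(fit$evals), voxels = as.integer(vox),
      dims = as.integer(d), method = method)
}

.fa_from_evals <- function(ev) {
  md <- rowMeans(ev)
  num <- (ev[, 1L] - md)^2 + (ev[, 2L] - md)^2 + (ev[, 3L] - md)^2
  den <- ev[, 1L]^2 + ev[, 2L]^2 + ev[, 3L]^2
  fa <- sqrt(1.5) * sqrt(ifelse(den > 0, num / den, 0))
  fa[den == 0] <- 0
  fa
}

#' Derive scalar parameter maps from a tensor fit
#'
#' MD = (l1+l2+l3)/3, AD = l1, RD = (l2+l3)/2 and
#' FA = sqrt(3/2) sqrt(sum (li - MD)^2 / sum li^2), with FA defined as 0
#' where all eigenvalues vanish.
#'
#' @param fit a \linkS4class{DTIFit}.
#' @param provenance optional string recording which QC variant produced the
#'   maps, stored as an attribute on each map.
#' @return Named list of 3D arrays (\code{FA}, \code{MD}, \code{RD},
#'   \code{AD}), zero outside the fitted voxels.
#' @export
deriveMaps <- function(fit, provenance = NULL) {
  ev <- fit@evals
  vals <- list(FA = .fa_from_evals(ev), MD = rowMeans(ev),
               RD = (ev[, 2L] + ev[, 3L]) / 2, AD = ev[, 1L])
  lapply(vals, function(v) {
    m <- array(0, fit@dims)
    m[fit@voxels] <- v
    if (!is.null(provenance)) attr(m, "provenance") <- provenance
    m
  })
}

#' Extract nonzero in-mask voxel values
#'
#' @param map a 3D array (a parameter map).
#' @param roi_mask logical array of the same shape.
#' @return Numeric vector of the nonzero voxel values inside the mask, in
#'   voxel-index order. An empty result is flagged with a warning and the
#'   attribute \code{empty = TRUE}.
#' @export
extractRoi <- function(map, roi_mask) {
  if (!identical(dim(map)[1:3], dim(roi_mask)[1:3]))
    .stop2("ROI mask shape does not match the map")
  v <- map[which(roi_mask)]
  v <- v[v != 0]
  if (!length(v)) {
    warning("ROI extraction returned no nonzero voxels", call. = FALSE)
    attr(v, "empty") <- TRUE
  }
  v
}

#' Lin's concordance correlation coefficient
#'
#' CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2) with moment
#' estimators using divisor n. It penalises both correlation loss and
#' location/scale shift, which makes it a reproducibility index rather than
#' a mere correlation; |CCC| <= |Pearson r| always.
#'
#' @param x,y equal-length numeric vectors (n >= 2, not both constant).
#' @param labels optional character pair naming the two methods compared.
#' @return A list of class \code{"linCCC"}: \code{ccc}, \code{n},
#'   \code{pearson}, \code{labels}.
#' @export
linCCC <- function(x, y, labels = c("x", "y")) {
  if (length(x) != length(y)) .stop2("x and y must have equal length")
  n <- length(x)
  if (n < 2L) .stop2("CCC needs at least 2 pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 && sy2 == 0) .stop2("both inputs are constant; CCC is undefined")
  sxy <- mean((x - mx) * (y - my))
  r <- if (sx2 > 0 && sy2 > 0) sxy / sqrt(sx2 * sy2) else NA_real_
  structure(list(ccc = 2 * sxy / (sx2 + sy2 + (mx - my)^2), n = n,
                 pearson = r, labels = labels),
            class = "linCCC")
}

#' @export
print.linCCC <- function(x, ...) {
  cat(sprintf("Lin CCC(%s, %s) = %.4f  (n = %d, Pearson r = %.4f)\n",
              x$labels[1L], x$labels[2L], x$ccc, x$n, x$pearson))
  invisible(x)
}

#' Compare two pipelines on one subject's ROI values
#'
#' Welch's two-sample two-sided t-test on the means and a two-sided F-test on
#' the variance ratio, with significance flagged at the Bonferroni-corrected
#' level (0.05 / 3 metric families by default, i.e. p < 0.0167).
#'
#' @param a,b numeric vectors of ROI voxel values from the two pipelines
#'   (each n >= 2), treated as independent samples.
#' @param alpha significance level applied to the raw p-values.
#' @return One-row data.frame: \code{t}, \code{F}, \code{p_t}, \code{p_F},
#'   \code{sig_t}, \code{sig_F}.
#' @export
comparePipelines <- function(a, b, alpha = 0.05 / 3) {
  if (length(a) < 2L || length(b) < 2L)
    .stop2("both samples need n >= 2 (got %d and %d)", length(a), length(b))
  tt <- t.test(a, b)                 # Welch by default
  ft <- var.test(a, b)
  data.frame(t = unname(tt$statistic), F = unname(ft$statistic),
             p_t = tt$p.value, p_F = ft$p.value,
             sig_t = tt$p.value < alpha, sig_F = ft$p.value < alpha)
}

#' Three-way QC impact study
#'
#' Runs the full downstream analysis for each exam under the three QC
#' policies (none / manual / model): tensor fit on the retained volumes,
#' scalar maps, and per-ROI statistics. Reproducibility between pipelines is
#' summarised per (ROI, metric) by the CCC of per-subject ROI means between
#' the reference manual QC and each alternative; per-subject model-vs-none
#' differences are tested with t and F tests at the Bonferroni-corrected
#' threshold.
#'
#' On synthetic data the "manual" arm uses the simulator's ground-truth
#' labels as the stand-in for human annotation.
#'
#' @param exams list of exams as returned by \code{\link{simulateExam}}
#'   (each with \code{series}, \code{brain_mask}, \code{roi_masks}).
#' @param model a trained \linkS4class{QCNetwork}.
#' @param threshold decision threshold for model QC.
#' @param metrics which scalar maps to analyse.
#' @param alpha per-test significance level after Bonferroni correction.
#' @return A list of class \code{"qcImpact"}: \code{roi_means} (long
#'   data.frame subject x roi x metric x variant), \code{ccc} (per roi x
#'   metric, manual-vs-model and manual-vs-none), \code{tests} (per-subject
#'   model-vs-none t/F results).
#' @export
qcImpactStudy <- function(exams, model, threshold = 0.5,
                          metrics = c("FA", "MD", "RD", "AD"),
                          alpha = 0.05 / 3) {
  variants <- c("none", "manual", "model")
  means <- list()
  tests <- list()
  for (ex in exams) {
    ser <- ex$series
    roi_vals <- list()
    for (variant in variants) {
      qc <- applyQC(ser, variant, model = model, threshold = threshold)
      fit <- fitDtiWls(qc, ex$brain_mask)
      maps <- deriveMaps(fit, provenance = variant)
      for (roi in names(ex$roi_masks)) {
        for (metric in metrics) {
          v <- suppressWarnings(extractRoi(maps[[metric]], ex$roi_masks[[roi]]))
          roi_vals[[paste(variant, roi, metric, sep = ".")]] <- v
          means[[length(means) + 1L]] <- data.frame(
            subject = subjectID(ser), roi = roi, metric = metric,
            variant = variant, mean = mean(v), var = var(v), n = length(v))
        }
      }
    }
    for (roi in names(ex$roi_masks)) {
      for (metric in metrics) {
        a <- roi_vals[[paste("model", roi, metric, sep = ".")]]
        b <- roi_vals[[paste("none", roi, metric, sep = ".")]]
        if (length(a) >= 2L && length(b) >= 2L) {
          row <- comparePipelines(a, b, alpha)
          tests[[length(tests) + 1L]] <- cbind(
            data.frame(subject = subjectID(ser), roi = roi, metric = metric), row)
        }
      }
    }
  }
  roi_means <- do.call(rbind, means)
  ccc_rows <- list()
  if (length(exams) >= 2L) {
    for (roi in unique(roi_means$roi)) {
      for (metric in metrics) {
        pick <- function(variant) {
          sub <- roi_means[roi_means$roi == roi & roi_means$metric == metric &
                             roi_means$variant == variant, ]
          sub$mean[order(sub$subject)]
        }
        manual <- pick("manual")
        for (other in c("model", "none")) {
          cc <- linCCC(manual, pick(other), labels = c("manual", other))
          ccc_rows[[length(ccc_rows) + 1L]] <- data.frame(
            roi = roi, metric = metric, comparison = paste0("manual_vs_", other),
            ccc = cc$ccc, n = cc$n)
        }
      }
    }
  }
  structure(list(roi_means = roi_means,
                 ccc = if (length(ccc_rows)) do.call(rbind, ccc_rows) else NULL,
                 tests = if (length(tests)) do.call(rbind, tests) else NULL,
                 threshold = threshold, alpha = alpha),
            class = "qcImpact")
}
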
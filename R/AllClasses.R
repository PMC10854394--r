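#' @import methods
#' @importFrom stats rnorm runif sd var t.test var.test pt pf setNames
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib dwiQC, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Diffusion acquisition scheme
#'
#' One b-value (s/mm^2) and one gradient direction per volume, in the FSL
#' convention (directions are unit vectors; \code{b = 0} volumes may carry a
#' zero vector).
#'
#' @slot bvals numeric vector of b-values, one per volume.
#' @slot bvecs 3 x n matrix of gradient directions (columns).
#' @export
setClass("AcquisitionScheme",
         representation(bvals = "numeric", bvecs = "matrix"))

setValidity("AcquisitionScheme", function(object) {
  msgs <- character()
  if (!is.numeric(object@bvecs) || nrow(object@bvecs) != 3L)
    msgs <- c(msgs, "bvecs must be a 3 x n numeric matrix")
  else if (length(object@bvals) != ncol(object@bvecs))
    msgs <- c(msgs, sprintf("length(bvals) [%d] != ncol(bvecs) [%d]",
                            length(object@bvals), ncol(object@bvecs)))
  if (any(object@bvals < 0)) msgs <- c(msgs, "b-values must be non-negative")
  if (length(msgs) == 0L && length(object@bvals) > 0L) {
    norms <- sqrt(colSums(object@bvecs^2))
    bad <- which(object@bvals > 0 & abs(norms - 1) > 1e-3)
    if (length(bad) > 0L)
      msgs <- c(msgs, sprintf(
        "non-unit gradient direction(s) at volume index (0-based): %s",
        paste(bad - 1L, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an acquisition scheme
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs 3 x n matrix (or n x 3, transposed automatically) of gradient
#'   directions.
#' @return An \linkS4class{AcquisitionScheme}.
#' @examples
#' sch <- acquisitionScheme(c(0, 1000), cbind(c(0, 0, 0), c(1, 0, 0)))
#' nVolumes(sch)
#' @export
acquisitionScheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  new("AcquisitionScheme", bvals = as.numeric(bvals), bvecs = bvecs)
}

#' A labelled series of diffusion-weighted volumes
#'
#' The unit of curation and prediction: one exam, i.e. an ordered list of 3D
#' volumes with its acquisition scheme, a shared voxel-to-world affine, and
#' optional per-volume binary artifact labels (1 = artifact, 0 =
#' artifact-free; \code{integer(0)} when unlabelled).
#'
#' @slot subject subject identifier (opaque string).
#' @slot session session identifier (opaque string).
#' @slot volumes list of 3D numeric arrays, all of identical shape.
#' @slot scheme an \linkS4class{AcquisitionScheme} of matching length.
#' @slot labels integer vector of 0/1 labels, or \code{integer(0)}.
#' @slot affine 4 x 4 voxel-to-world transform (mm).
#' @export
setClass("VolumeSeries",
         representation(subject = "character", session = "character",
                        volumes = "list", scheme = "AcquisitionScheme",
                        labels = "integer", affine = "matrix"))

setValidity("VolumeSeries", function(object) {
  msgs <- character()
  n <- length(object@volumes)
  if (n != nVolumes(object@scheme))
    msgs <- c(msgs, sprintf("series has %d volumes but scheme has %d entries",
                            n, nVolumes(object@scheme)))
  if (n > 0L) {
    dims <- vapply(object@volumes, function(v) paste(dim(v), collapse = "x"), "")
    if (length(unique(dims)) > 1L)
      msgs <- c(msgs, "all volumes must share one shape")
    if (!all(vapply(object@volumes, function(v) length(dim(v)) == 3L, NA)))
      msgs <- c(msgs, "volumes must be 3D arrays")
  }
  nl <- length(object@labels)
  if (nl > 0L) {
    if (nl != n)
      msgs <- c(msgs, sprintf("%d labels for %d volumes", nl, n))
    if (!all(object@labels %in% c(0L, 1L)))
      msgs <- c(msgs, "labels must be 0 or 1")
  }
  if (!identical(dim(object@affine), c(4L, 4L)))
    msgs <- c(msgs, "affine must be 4 x 4")
  else if (abs(det(object@affine)) < .Machine$double.eps)
    msgs <- c(msgs, "affine must be invertible")
  if (length(msgs)) msgs else TRUE
})

#' Construct a volume series
#'
#' @param volumes list of 3D arrays (or a 4D array, split along its 4th axis).
#' @param scheme an \linkS4class{AcquisitionScheme}.
#' @param subject,session identifiers.
#' @param labels optional integer 0/1 vector, one per volume.
#' @param affine 4 x 4 voxel-to-world matrix; identity-scaled default.
#' @return A \linkS4class{VolumeSeries}.
#' @export
volumeSeries <- function(volumes, scheme, subject = "sub01", session = "ses01",
                         labels = NULL, affine = diag(4)) {
  if (is.array(volumes) && length(dim(volumes)) == 4L) {
    n <- dim(volumes)[4L]
    volumes <- lapply(seq_len(n), function(i) volumes[, , , i, drop = TRUE])
  }
  volumes <- lapply(volumes, function(v) {
    storage.mode(v) <- "double"
    v
  })
  new("VolumeSeries", subject = subject, session = session, volumes = volumes,
      scheme = scheme, labels = if (is.null(labels)) integer(0) else as.integer(labels),
      affine = affine)
}

#' A 3D convolutional artifact classifier
#'
#' Wraps the native network state (weights, optimizer state, batch-norm
#' statistics) behind an external pointer together with the architecture
#' configuration used to build it.
#'
#' @slot ptr external pointer to the native network.
#' @slot config the \code{\link{networkConfig}} list used at construction.
#' @export
setClass("QCNetwork", representation(ptr = "externalptr", config = "list"))

#' A per-voxel diffusion tensor fit
#'
#' @slot beta 7 x n matrix of log-linear parameters
#'   (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) for the fitted voxels.
#' @slot evals n x 3 matrix of tensor eigenvalues, sorted descending.
#' @slot voxels linear indices of the fitted (in-mask) voxels.
#' @slot dims spatial grid dimensions.
#' @slot method "wls" or "ols".
#' @export
setClass("DTIFit",
         representation(beta = "matrix", evals = "matrix", voxels = "integer",
                        dims = "integer", method = "character"))

# ---- generics ----

#' Number of volumes in a scheme or series
#' @param x an \linkS4class{AcquisitionScheme} or \linkS4class{VolumeSeries}.
#' @return integer count.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname nVolumes
#' @export
setMethod("nVolumes", "AcquisitionScheme", function(x) length(x@bvals))

#' @rdname nVolumes
#' @export
setMethod("nVolumes", "VolumeSeries", function(x) length(x@volumes))

#' Accessors for acquisition schemes and series
#' @param x the object.
#' @return \code{bvalues}: numeric vector; \code{bvectors}: 3 x n matrix.
#' @export
setGeneric("bvalues", function(x) standardGeneric("bvalues"))
#' @rdname bvalues
#' @export
setMethod("bvalues", "AcquisitionScheme", function(x) x@bvals)
#' @rdname bvalues
#' @export
setMethod("bvalues", "VolumeSeries", function(x) x@scheme@bvals)

#' @rdname bvalues
#' @export
setGeneric("bvectors", function(x) standardGeneric("bvectors"))
#' @rdname bvalues
#' @export
setMethod("bvectors", "AcquisitionScheme", function(x) x@bvecs)
#' @rdname bvalues
#' @export
setMethod("bvectors", "VolumeSeries", function(x) x@scheme@bvecs)

#' Series accessors
#' @param x a \linkS4class{VolumeSeries}.
#' @param value replacement labels (0/1 integer vector or NULL).
#' @return \code{seriesVolumes}: list of 3D arrays; \code{acquisition}: the
#'   scheme; \code{artifactLabels}: integer labels (length 0 if unlabelled);
#'   \code{subjectID}/\code{sessionID}: character.
#' @export
setGeneric("seriesVolumes", function(x) standardGeneric("seriesVolumes"))
#' @rdname seriesVolumes
#' @export
setMethod("seriesVolumes", "VolumeSeries", function(x) x@volumes)

#' @rdname seriesVolumes
#' @export
setGeneric("acquisition", function(x) standardGeneric("acquisition"))
#' @rdname seriesVolumes
#' @export
setMethod("acquisition", "VolumeSeries", function(x) x@scheme)

#' @rdname seriesVolumes
#' @export
setGeneric("artifactLabels", function(x) standardGeneric("artifactLabels"))
#' @rdname seriesVolumes
#' @export
setMethod("artifactLabels", "VolumeSeries", function(x) x@labels)

#' @rdname seriesVolumes
#' @export
setGeneric("artifactLabels<-", function(x, value) standardGeneric("artifactLabels<-"))
#' @rdname seriesVolumes
#' @export
setMethod("artifactLabels<-", "VolumeSeries", function(x, value) {
  x@labels <- if (is.null(value)) integer(0) else as.integer(value)
  validObject(x)
  x
})

#' @rdname seriesVolumes
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))
#' @rdname seriesVolumes
#' @export
setMethod("subjectID", "VolumeSeries", function(x) x@subject)

#' @rdname seriesVolumes
#' @export
setGeneric("sessionID", function(x) standardGeneric("sessionID"))
#' @rdname seriesVolumes
#' @export
setMethod("sessionID", "VolumeSeries", function(x) x@session)

setMethod("show", "AcquisitionScheme", function(object) {
  shells <- table(round(object@bvals))
  cat("AcquisitionScheme:", length(object@bvals), "volumes\n")
  cat("  shells (b-value [n]):",
      paste(sprintf("%s [%d]", names(shells), shells), collapse = ", "), "\n")
})

setMethod("show", "VolumeSeries", function(object) {
  d <- if (length(object@volumes)) dim(object@volumes[[1L]]) else c(NA, NA, NA)
  cat(sprintf("VolumeSeries %s/%s: %d volumes of %s\n", object@subject,
              object@session, length(object@volumes), paste(d, collapse = " x ")))
  if (length(object@labels))
    cat(sprintf("  labels: %d artifact / %d clean\n", sum(object@labels == 1L),
                sum(object@labels == 0L)))
  else cat("  labels: none\n")
})

setMethod("show", "QCNetwork", function(object) {
  d <- .qcnet_describe(object@ptr)
  cat("QCNetwork (3D CNN artifact classifier)\n")
  cat("  input:", paste(d$input_shape, collapse = " x "), "\n")
  cat("  conv blocks:", paste(d$block_filters, collapse = ", "),
      "filters (3x3x3 kernel, pool 2/stride 2, batch norm)\n")
  cat("  dense head:", paste(d$dense_units, collapse = " -> "),
      sprintf("(dropout %.0f%%)\n", 100 * d$dropout_rate))
  cat("  parameters:", format(d$n_parameters, big.mark = ","), "\n")
})

setMethod("show", "DTIFit", function(object) {
  cat(sprintf("DTIFit (%s): %d voxels on a %s grid\n", object@method,
              length(object@voxels), paste(object@dims, collapse = " x ")))
})
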
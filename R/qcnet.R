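# The volume-level 3D convolutional artifact classifier.

#' Network architecture configuration
#'
#' Four feature-extraction blocks, each a 3D convolution (3 x 3 x 3 kernel,
#' same padding, ReLU) followed by 3D max pooling (size 2, stride 2) and
#' batch normalisation, with filter counts doubling per block; the flattened
#' features pass through dense(128) + 50\% dropout, dense(128), and a single
#' sigmoid output unit.
#'
#' @param input_shape input grid (nx, ny, nz); each axis must survive one
#'   halving per block.
#' @param block_filters filter counts per block.
#' @param dense_units width of the two fully connected layers.
#' @param dropout_rate dropout after the first dense layer, in [0, 1).
#' @return A \code{networkConfig} list. Convolution kernel (3 x 3 x 3) and
#'   pooling (2, stride 2) are fixed.
#' @export
networkConfig <- function(input_shape = c(128L, 128L, 70L),
                          block_filters = c(8L, 16L, 32L, 64L),
                          dense_units = 128L, dropout_rate = 0.5) {
  if (length(block_filters) < 1L || any(block_filters < 1L))
    .stop2("block_filters must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    .stop2("dropout_rate must lie in [0, 1)")
  structure(list(input_shape = as.integer(input_shape),
                 block_filters = as.integer(block_filters),
                 conv_kernel = c(3L, 3L, 3L), pool_size = 2L, pool_stride = 2L,
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate),
            class = "networkConfig")
}

#' Build an (untrained) artifact classifier
#'
#' Weights are initialised from a seeded fan-in-scaled Gaussian scheme, so
#' two builds with the same configuration and seed are identical.
#'
#' @param config a \code{\link{networkConfig}}.
#' @param seed initialisation seed.
#' @return A \linkS4class{QCNetwork}.
#' @examples
#' net <- buildNetwork(networkConfig(input_shape = c(32, 32, 16)), seed = 1)
#' networkSummary(net)$pooled_dims
#' @export
buildNetwork <- function(config = networkConfig(), seed = 1L) {
  ptr <- .qcnet_create(config$input_shape, config$block_filters,
                       config$dense_units, config$dropout_rate, as.integer(seed))
  new("QCNetwork", ptr = ptr, config = c(config, list(seed = as.integer(seed))))
}

#' Introspect a built network
#'
#' @param model a \linkS4class{QCNetwork}.
#' @return A list describing the realised architecture: filter counts,
#'   kernel/pool sizes, the per-block spatial dimensions before and after
#'   pooling, flattened feature count, dense widths, dropout rate and total
#'   parameter count.
#' @export
networkSummary <- function(model) .qcnet_describe(model@ptr)

.check_volume_shape <- function(model, d) {
  want <- model@config$input_shape
  if (!identical(as.integer(d[1:3]), want))
    .stop2("volume shape %s does not match the model input %s",
           paste(d[1:3], collapse = "x"), paste(want, collapse = "x"))
}

#' Predict the artifact probability of volumes
#'
#' Inference is deterministic: dropout is disabled and normalisation layers
#' use their stored running statistics. Volumes must already be conformed
#' and normalised to the model's input shape.
#'
#' @param model a trained (or untrained) \linkS4class{QCNetwork}.
#' @param volumes a 3D array, 4D array (volumes stacked along the 4th axis),
#'   or list of 3D arrays.
#' @return Numeric vector of probabilities in [0, 1], one per volume.
#' @export
predictVolume <- function(model, volumes) {
  x <- .as_volume_array(volumes)
  .check_volume_shape(model, dim(x))
  as.numeric(.qcnet_predict(model@ptr, x, dim(x)))
}

#' Predict artifact probabilities for a whole series
#'
#' Convenience wrapper: conforms and normalises every volume of the series to
#' the model input and returns per-volume probabilities.
#'
#' @param model a \linkS4class{QCNetwork}.
#' @param series a \linkS4class{VolumeSeries}.
#' @return Numeric vector of probabilities, one per volume.
#' @export
predictSeries <- function(model, series) {
  cfg <- conformConfig(model@config$input_shape)
  vols <- lapply(series@volumes, function(v) normalizeVolume(conformVolume(v, cfg)))
  predictVolume(model, vols)
}

#' Save or load a classifier
#'
#' The model is stored as a single RDS file holding the weights, batch-norm
#' statistics and configuration, with a human-readable JSON sidecar recording
#' the architecture and training provenance. A load rebuilds the native
#' state; predictions after a save/load round trip are bitwise identical.
#'
#' @param model a \linkS4class{QCNetwork}.
#' @param path file path (the sidecar adds ".json").
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: a
#'   \linkS4class{QCNetwork}.
#' @export
saveModel <- function(model, path) {
  obj <- list(format = "dwiQC-model-1", config = model@config,
              weights = .qcnet_weights(model@ptr))
  saveRDS(obj, path)
  sidecar <- list(format = obj$format,
                  input_shape = model@config$input_shape,
                  block_filters = model@config$block_filters,
                  dense_units = model@config$dense_units,
                  dropout_rate = model@config$dropout_rate,
                  seed = model@config$seed,
                  n_parameters = networkSummary(model)$n_parameters,
                  saved = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) .stop2("model file not found: %s", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    .stop2("cannot read model file %s: %s", path, conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "dwiQC-model-1"))
    .stop2("file %s is not a dwiQC model", path)
  cfg <- obj$config
  model <- buildNetwork(networkConfig(cfg$input_shape, cfg$block_filters,
                                      cfg$dense_units, cfg$dropout_rate),
                        seed = cfg$seed)
  .qcnet_set_weights(model@ptr, obj$weights)
  model
}
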
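# High-level synthetic workflow helpers.

#' Build a curated, conformed training set from a dataset recipe
#'
#' Simulates the cohort one exam at a time, applies per-subject balanced
#' curation, and conforms + normalises the selected volumes, so the full
#' (much larger) raw dataset never has to be held in memory at once.
#'
#' @param recipe a \code{\link{datasetRecipe}}.
#' @param target_shape grid the curated volumes are conformed to (defaults
#'   to the recipe's phantom grid).
#' @param curation_seed seed for the balanced sampling of clean volumes.
#' @return A list: \code{x} (4D array of curated volumes), \code{labels},
#'   \code{subjects}, and \code{realized_prevalence} of the raw dataset.
#' @export
synthCuratedSet <- function(recipe, target_shape = recipe$phantom$grid,
                            curation_seed = recipe$seed) {
  cfg <- conformConfig(target_shape)
  chunks <- vector("list", recipe$n_subjects)
  labels <- list()
  subjects <- list()
  ncorr_raw <- 0L
  ntot_raw <- 0L
  for (i in seq_len(recipe$n_subjects)) {
    ex <- simulateExam(recipe, i)
    ser <- ex$series
    ncorr_raw <- ncorr_raw + sum(ser@labels)
    ntot_raw <- ntot_raw + nVolumes(ser)
    cur <- curateBalanced(list(ser), seed = curation_seed)
    if (!nrow(cur)) next
    vols <- lapply(cur$volume_index + 1L, function(j)
      normalizeVolume(conformVolume(ser@volumes[[j]], cfg)))
    chunks[[i]] <- .as_volume_array(vols)
    labels[[i]] <- cur$label
    subjects[[i]] <- cur$subject_id
  }
  keep <- !vapply(chunks, is.null, NA)
  if (!any(keep)) .stop2("curation selected no volumes")
  x <- array(0, c(as.integer(target_shape), sum(lengths(labels))))
  at <- 0L
  for (i in which(keep)) {
    n <- dim(chunks[[i]])[4L]
    x[, , , at + seq_len(n)] <- chunks[[i]]
    chunks[i] <- list(NULL)  # release, keeping list positions stable
    at <- at + n
  }
  list(x = x, labels = unlist(labels), subjects = unlist(subjects),
       realized_prevalence = ncorr_raw / ntot_raw)
}
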
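# Data preparation: conformation to a fixed grid, per-volume [0, 1] intensity
# normalisation, class-balanced curation, subject-level k-fold splitting.

#' Conformation configuration
#' @param target_shape target grid (nx, ny, nz); all dimensions >= 1.
#' @return A \code{conformConfig} list.
#' @export
conformConfig <- function(target_shape = c(128L, 128L, 70L)) {
  if (any(target_shape < 1L)) .stop2("target dimensions must be >= 1")
  structure(list(target_shape = as.integer(target_shape)), class = "conformConfig")
}

#' Subject-level split configuration
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return A \code{splitConfig} list.
#' @export
splitConfig <- function(k = 4L, seed = 1L) {
  if (k < 2L) .stop2("k must be >= 2")
  structure(list(k = as.integer(k), seed = as.integer(seed)), class = "splitConfig")
}

#' Conform a volume to a fixed grid
#'
#' Each axis is handled independently: smaller axes are centred with zero
#' padding, larger axes receive a centred crop. Odd pad/crop remainders go to
#' the high-index side, making the operation bit-reproducible; it is the
#' identity when the shape already matches.
#'
#' @param volume a 3D array.
#' @param config a \code{\link{conformConfig}}; the default target is
#'   128 x 128 x 70.
#' @return A 3D array of exactly the target shape.
#' @export
conformVolume <- function(volume, config = conformConfig()) {
  d <- dim(volume)
  tg <- config$target_shape
  if (identical(as.integer(d), tg)) return(volume)
  out <- array(0, tg)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    if (d[a] >= tg[a]) {            # centred crop, extra removed high side
      lo <- (d[a] - tg[a]) %/% 2L
      src[[a]] <- seq.int(lo + 1L, lo + tg[a])
      dst[[a]] <- seq_len(tg[a])
    } else {                        # centred zero pad, extra pad high side
      lo <- (tg[a] - d[a]) %/% 2L
      src[[a]] <- seq_len(d[a])
      dst[[a]] <- seq.int(lo + 1L, lo + d[a])
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- volume[src[[1L]], src[[2L]], src[[3L]]]
  out
}

#' Min-max normalise a volume to [0, 1]
#'
#' Linear map taking the volume minimum to 0 and maximum to 1. A constant
#' volume (max == min) maps to all zeros, marking a physically meaningless
#' volume as featureless rather than dividing by zero.
#'
#' @param volume a 3D array.
#' @return The normalised array.
#' @export
normalizeVolume <- function(volume) {
  lo <- min(volume)
  hi <- max(volume)
  if (hi == lo) return(array(0, dim(volume)))
  (volume - lo) / (hi - lo)
}

.curate_one_subject <- function(labels_by_series, seed) {
  # labels_by_series: named list (series key -> integer labels)
  tab <- do.call(rbind, lapply(names(labels_by_series), function(key) {
    lab <- labels_by_series[[key]]
    data.frame(key = key, volume_index = seq_along(lab) - 1L, label = lab)
  }))
  ncorr <- sum(tab$label == 1L)
  ntot <- nrow(tab)
  if (ncorr == 0L) return(tab[0L, ])
  if (ncorr > ntot / 2) return(tab)        # ">half" rule: keep everything
  clean <- which(tab$label == 0L)
  keep_clean <- .with_seed(seed, sample(clean, ncorr))
  tab[sort(c(which(tab$label == 1L), keep_clean)), ]
}

#' Class-balanced curation of labelled exams
#'
#' Per subject (pooling that subject's sessions): all corrupted volumes are
#' kept together with an equal number of artifact-free volumes sampled
#' uniformly without replacement; if more than half of a subject's volumes
#' are corrupted, all of them are kept; subjects without corrupted volumes
#' contribute nothing. Deterministic given the seed, independent of list
#' order.
#'
#' @param series_list list of labelled \linkS4class{VolumeSeries}.
#' @param seed sampling seed.
#' @return A \code{data.frame} (the curated set) with columns
#'   \code{subject_id}, \code{session_id}, \code{volume_index} (0-based),
#'   \code{label}, and the seed as attribute \code{"seed"}.
#' @export
curateBalanced <- function(series_list, seed = 1L) {
  if (!length(series_list)) .stop2("empty series list")
  unlabelled <- vapply(series_list, function(s) length(s@labels) == 0L, NA)
  if (any(unlabelled))
    .stop2("series without labels cannot be curated (series %s)",
           paste(which(unlabelled), collapse = ", "))
  subjects <- vapply(series_list, subjectID, "")
  out <- lapply(sort(unique(subjects)), function(sub) {
    idx <- which(subjects == sub)
    labs <- lapply(idx, function(i) series_list[[i]]@labels)
    names(labs) <- vapply(idx, function(i)
      paste(series_list[[i]]@subject, series_list[[i]]@session, sep = "\r"), "")
    sel <- .curate_one_subject(labs, .derive_seed(seed, sub))
    if (!nrow(sel)) return(NULL)
    parts <- strsplit(sel$key, "\r", fixed = TRUE)
    data.frame(subject_id = vapply(parts, `[[`, "", 1L),
               session_id = vapply(parts, `[[`, "", 2L),
               volume_index = sel$volume_index, label = sel$label)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(subject_id = character(), session_id = character(),
                      volume_index = integer(), label = integer())
  rownames(res) <- NULL
  attr(res, "seed") <- seed
  res
}

#' Subject-level k-fold split
#'
#' Subjects are shuffled by the seed and partitioned into k disjoint sets
#' whose sizes differ by at most one. All sessions and volumes of a subject
#' travel with the subject, preventing information leakage between training
#' and test folds.
#'
#' @param subject_ids character vector (duplicates collapse to one subject).
#' @param config a \code{\link{splitConfig}}.
#' @return A list of k disjoint character vectors covering all subjects.
#' @export
splitSubjectKfold <- function(subject_ids, config = splitConfig()) {
  subjects <- sort(unique(as.character(subject_ids)))
  k <- config$k
  if (k > length(subjects))
    .stop2("cannot split %d subject(s) into %d folds", length(subjects), k)
  shuffled <- .with_seed(config$seed, sample(subjects))
  sizes <- rep(length(subjects) %/% k, k)
  extra <- length(subjects) %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) shuffled[starts[i]:ends[i]])
}
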
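# Reading and writing exams: 4D NIfTI + FSL bval/bvec text + CSV manifests.

#' Read a diffusion exam from disk
#'
#' Assembles a \linkS4class{VolumeSeries} from a 4D NIfTI image, FSL-dialect
#' \code{bval}/\code{bvec} whitespace text files and, optionally, a CSV label
#' manifest. The 4th image axis must match the scheme length; volume order is
#' preserved; voxel data are converted to double precision on load.
#'
#' @param image_path path to a 4D NIfTI (.nii or .nii.gz).
#' @param bval_path path to the b-value file (one whitespace-separated row).
#' @param bvec_path path to the gradient file (3 rows x n columns).
#' @param manifest_path optional CSV manifest with per-volume labels.
#' @param subject,session identifiers; when a manifest is given they default
#'   to its (unique) subject/session.
#' @return A \linkS4class{VolumeSeries}, labelled when a manifest was given.
#' @export
readVolumeSeries <- function(image_path, bval_path, bvec_path,
                             manifest_path = NULL, subject = NULL, session = NULL) {
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) arr <- array(arr, c(dim(arr), 1L))
  if (length(dim(arr)) != 4L)
    .stop2("image '%s' is %d-dimensional; a 4D diffusion series is required",
           image_path, length(dim(arr)))
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3L, byrow = TRUE)
  if (dim(arr)[4L] != length(bvals))
    .stop2("volume count mismatch: image has %d frames but scheme has %d b-values",
           dim(arr)[4L], length(bvals))
  scheme <- acquisitionScheme(bvals, bvecs)
  labels <- NULL
  if (!is.null(manifest_path)) {
    man <- readManifest(manifest_path)
    if (is.null(subject)) subject <- unique(man$subject_id)[1L]
    if (is.null(session)) session <- unique(man$session_id)[1L]
    man <- man[man$subject_id == subject & man$session_id == session, ]
    if (nrow(man) != dim(arr)[4L])
      .stop2("manifest has %d rows for %s/%s but the image has %d volumes",
             nrow(man), subject, session, dim(arr)[4L])
    labels <- man$label[order(man$volume_index)]
  }
  if (is.null(subject)) subject <- "sub01"
  if (is.null(session)) session <- "ses01"
  affine <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  volumeSeries(arr, scheme, subject = subject, session = session,
               labels = labels, affine = affine)
}

#' Write a diffusion exam to disk
#'
#' Emits a 4D NIfTI plus FSL \code{bval}/\code{bvec} files (and a manifest CSV
#' when the series is labelled and \code{manifest_path} is given) such that
#' \code{\link{readVolumeSeries}} round-trips the voxel data bit-exactly and
#' the gradients to within 1e-6.
#'
#' @param series a valid, non-empty \linkS4class{VolumeSeries}.
#' @param image_path,bval_path,bvec_path output paths.
#' @param manifest_path optional manifest CSV output path.
#' @return Invisibly, the named vector of paths written.
#' @export
writeVolumeSeries <- function(series, image_path, bval_path, bvec_path,
                              manifest_path = NULL) {
  validObject(series)
  n <- nVolumes(series)
  if (n == 0L) .stop2("refusing to write an empty series (no volumes)")
  arr <- .as_volume_array(series@volumes)
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(series@affine, code = 2L))
  RNifti::writeNifti(img, image_path)
  writeLines(paste(format(series@scheme@bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(series@scheme@bvecs, 1L, function(r)
    paste(sprintf("%.10f", r), collapse = " ")), bvec_path)
  paths <- c(image = image_path, bval = bval_path, bvec = bvec_path)
  if (!is.null(manifest_path)) {
    if (length(series@labels) == 0L)
      .stop2("series has no labels; cannot write a manifest")
    man <- data.frame(subject_id = series@subject, session_id = series@session,
                      volume_index = seq_len(n) - 1L, label = series@labels)
    writeManifest(man, manifest_path)
    paths <- c(paths, manifest = manifest_path)
  }
  invisible(paths)
}

.validate_manifest <- function(man) {
  need <- c("subject_id", "session_id", "volume_index", "label")
  missing <- setdiff(need, names(man))
  if (length(missing))
    .stop2("manifest is missing column(s): %s", paste(missing, collapse = ", "))
  key <- paste(man$subject_id, man$session_id, man$volume_index, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    .stop2("duplicate (subject_id, session_id, volume_index) triple(s): %s",
           paste(unique(sub("\r", "/", sub("\r", "/", key[dup]))), collapse = "; "))
  if (!all(man$label %in% c(0L, 1L)))
    .stop2("labels outside {0, 1} at row(s): %s",
           paste(which(!(man$label %in% c(0L, 1L))), collapse = ", "))
  if ("probability" %in% names(man) &&
      any(!is.na(man$probability) & (man$probability < 0 | man$probability > 1)))
    .stop2("probabilities must lie in [0, 1]")
  invisible(man)
}

#' Read or write a per-volume label manifest
#'
#' A manifest is a CSV with header columns \code{subject_id}, \code{session_id},
#' \code{volume_index} (0-based), \code{label} (0/1) and optionally
#' \code{probability}. Key triples must be unique. An absent probability
#' column is preserved as absent, not as zeros.
#'
#' @param path CSV path.
#' @return \code{readManifest}: a validated data.frame.
#' @export
readManifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  man$volume_index <- as.integer(man$volume_index)
  man$label <- as.integer(man$label)
  .validate_manifest(man)
  man
}

#' @rdname readManifest
#' @param manifest a manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  .validate_manifest(manifest)
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
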
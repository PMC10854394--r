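# Training, cross-validation, confusion metrics and threshold calibration.

#' Training configuration
#'
#' Binary cross-entropy minimised with Adam over a fixed number of epochs;
#' the learning rate decays by a constant factor per epoch and training
#' batches are reshuffled each epoch under the run seed.
#'
#' @param batch_size volumes per gradient step.
#' @param epochs training epochs.
#' @param initial_lr initial Adam learning rate.
#' @param lr_decay per-epoch multiplicative learning-rate decay.
#' @param seed seed controlling shuffling and dropout masks.
#' @return A \code{trainConfig} list.
#' @export
trainConfig <- function(batch_size = 8L, epochs = 30L, initial_lr = 1e-3,
                        lr_decay = 0.9, seed = 1L) {
  if (batch_size < 1L) .stop2("batch_size must be >= 1")
  if (epochs < 1L) .stop2("epochs must be >= 1")
  if (initial_lr <= 0) .stop2("initial_lr must be positive")
  structure(list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 initial_lr = initial_lr, lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Train a classifier
#'
#' Updates the model weights in place by minimising binary cross-entropy
#' with Adam. Volumes must be conformed and normalised to the model input
#' shape. Fully reproducible given the seed (data order, dropout masks).
#'
#' @param model a \linkS4class{QCNetwork}; modified in place.
#' @param volumes 4D array or list of conformed, normalised 3D volumes.
#' @param labels binary labels (1 = artifact), one per volume.
#' @param config a \code{\link{trainConfig}}.
#' @return Invisibly, a list with the \code{model} and \code{history}
#'   (per-epoch mean loss and training accuracy).
#' @export
trainNetwork <- function(model, volumes, labels, config = trainConfig()) {
  x <- .as_volume_array(volumes)
  .check_volume_shape(model, dim(x))
  labels <- as.integer(labels)
  if (length(labels) != dim(x)[4L])
    .stop2("%d labels for %d volumes", length(labels), dim(x)[4L])
  if (!all(labels %in% c(0L, 1L))) .stop2("labels must be 0 or 1")
  if (length(unique(labels)) < 2L)
    .stop2("training set contains a single class; the loss is degenerate")
  hist <- .qcnet_train(model@ptr, x, dim(x), labels, config$epochs,
                       config$batch_size, config$initial_lr, config$lr_decay,
                       config$seed)
  invisible(list(model = model, history = as.data.frame(hist)))
}

#' Threshold a probability into a binary label
#'
#' A volume is called an artifact when its probability reaches the decision
#' threshold; ties classify as artifact, the conservative direction for
#' quality control. Lowering the threshold increases artifact sensitivity.
#'
#' @param probability numeric vector in [0, 1].
#' @param threshold decision threshold in (0, 1).
#' @return Integer labels (1 = artifact).
#' @export
classifyVolumes <- function(probability, threshold = 0.5) {
  if (any(probability < 0 | probability > 1)) .stop2("probabilities must lie in [0, 1]")
  if (threshold <= 0 || threshold >= 1) .stop2("threshold must lie in (0, 1)")
  as.integer(probability >= threshold)
}

#' Confusion counts
#'
#' Standard 2 x 2 table with artifact as the positive class.
#'
#' @param truth,predicted equal-length binary (0/1) vectors.
#' @return Named integer vector (TP, TN, FP, FN) of class
#'   \code{"confusionCounts"}.
#' @export
confusionCounts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    .stop2("length mismatch: %d true vs %d predicted labels",
           length(truth), length(predicted))
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (!all(c(truth, predicted) %in% c(0L, 1L))) .stop2("labels must be 0 or 1")
  structure(c(TP = sum(truth == 1L & predicted == 1L),
              TN = sum(truth == 0L & predicted == 0L),
              FP = sum(truth == 0L & predicted == 1L),
              FN = sum(truth == 1L & predicted == 0L)),
            class = "confusionCounts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy (TP+TN)/total, precision TP/(TP+FP), true positive rate (recall)
#' TP/(TP+FN) and true negative rate TN/(TN+FP), as percentages. A metric
#' whose denominator is zero is reported as \code{NA} (undefined), never as
#' zero. Full-precision values are kept; printing rounds to one decimal.
#'
#' @param counts a \code{\link{confusionCounts}} vector (or any named vector
#'   with TP, TN, FP, FN).
#' @param threshold the decision threshold the predictions used (recorded).
#' @return A list of class \code{"qcMetrics"} with fields \code{accuracy},
#'   \code{precision}, \code{tpr}, \code{tnr} (percent), \code{counts} and
#'   \code{threshold}.
#' @export
qcMetrics <- function(counts, threshold = 0.5) {
  cnt <- as.numeric(counts[c("TP", "TN", "FP", "FN")])
  if (any(is.na(cnt)) || any(cnt < 0)) .stop2("counts must be non-negative TP/TN/FP/FN")
  total <- sum(cnt)
  if (total < 1) .stop2("at least one observation is required")
  rat <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(accuracy = rat(cnt[1L] + cnt[2L], total),
                 precision = rat(cnt[1L], cnt[1L] + cnt[3L]),
                 tpr = rat(cnt[1L], cnt[1L] + cnt[4L]),
                 tnr = rat(cnt[2L], cnt[2L] + cnt[3L]),
                 counts = setNames(as.integer(cnt), c("TP", "TN", "FP", "FN")),
                 threshold = threshold),
            class = "qcMetrics")
}

#' @export
print.qcMetrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undef" else sprintf("%.1f", v)
  cat(sprintf("accuracy %s%%  precision %s%%  TPR %s%%  TNR %s%%  (threshold %.3g)\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$tpr), fmt(x$tnr), x$threshold))
  cat(sprintf("counts: TP %d  TN %d  FP %d  FN %d\n", x$counts["TP"],
              x$counts["TN"], x$counts["FP"], x$counts["FN"]))
  invisible(x)
}

.metrics_row <- function(fold, dataset, m) {
  data.frame(fold = fold, dataset = dataset, accuracy = m$accuracy,
             precision = m$precision, tpr = m$tpr, tnr = m$tnr,
             TP = m$counts["TP"], TN = m$counts["TN"], FP = m$counts["FP"],
             FN = m$counts["FN"], row.names = NULL)
}

#' Subject-level k-fold cross-validation
#'
#' For each fold a fresh network is trained on the volumes of all subjects
#' outside the fold and evaluated on the held-out fold (and, optionally, on
#' an external test set). Folds are split by subject, never by volume, so no
#' subject contributes to both training and test of the same fold.
#'
#' @param volumes 4D array of conformed, normalised volumes.
#' @param labels binary labels, one per volume.
#' @param subjects subject id per volume.
#' @param split_config a \code{\link{splitConfig}}.
#' @param net_config a \code{\link{networkConfig}} matching the volume shape.
#' @param train_config a \code{\link{trainConfig}}.
#' @param external optional list(volumes =, labels =) evaluated by every
#'   fold's model.
#' @param threshold decision threshold for the reported metrics.
#' @return A list of class \code{"cvReport"}: \code{report} (per-fold metric
#'   rows plus mean and sd rows, in percent), \code{folds} (subject sets),
#'   \code{histories}, and per-volume held-out \code{probabilities}.
#' @export
crossValidate <- function(volumes, labels, subjects, split_config = splitConfig(),
                          net_config, train_config = trainConfig(),
                          external = NULL, threshold = 0.5) {
  x <- .as_volume_array(volumes)
  n <- dim(x)[4L]
  labels <- as.integer(labels)
  subjects <- as.character(subjects)
  stopifnot(length(labels) == n, length(subjects) == n)
  folds <- splitSubjectKfold(subjects, split_config)
  k <- length(folds)
  rows <- list()
  histories <- list()
  probs <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test_subj <- folds[[f]]
    train_idx <- which(!(subjects %in% test_subj))
    test_idx <- which(subjects %in% test_subj)
    if (length(intersect(subjects[train_idx], subjects[test_idx])) > 0L)
      .stop2("internal error: subject leakage between folds")
    model <- buildNetwork(net_config, seed = .derive_seed(train_config$seed,
                                                          paste0("fold", f)))
    fit <- trainNetwork(model, x[, , , train_idx, drop = FALSE],
                        labels[train_idx], train_config)
    histories[[f]] <- fit$history
    p <- predictVolume(model, x[, , , test_idx, drop = FALSE])
    probs[test_idx] <- p
    m <- qcMetrics(confusionCounts(labels[test_idx], classifyVolumes(p, threshold)),
                   threshold)
    rows[[length(rows) + 1L]] <- .metrics_row(as.character(f), "internal", m)
    if (!is.null(external)) {
      pe <- predictVolume(model, external$volumes)
      me <- qcMetrics(confusionCounts(external$labels,
                                      classifyVolumes(pe, threshold)), threshold)
      rows[[length(rows) + 1L]] <- .metrics_row(as.character(f), "external", me)
    }
  }
  report <- do.call(rbind, rows)
  for (ds in unique(report$dataset)) {
    sub <- report[report$dataset == ds, ]
    mu <- sub[1L, ]; mu$fold <- "mean"
    sdv <- sub[1L, ]; sdv$fold <- "sd"
    for (col in c("accuracy", "precision", "tpr", "tnr", "TP", "TN", "FP", "FN")) {
      mu[[col]] <- mean(sub[[col]])
      sdv[[col]] <- sd(sub[[col]])
    }
    report <- rbind(report, mu, sdv)
  }
  structure(list(report = report, folds = folds, histories = histories,
                 probabilities = probs, threshold = threshold),
            class = "cvReport")
}

#' Calibrate the decision threshold
#'
#' Scans all candidate thresholds (midpoints between sorted distinct
#' probabilities, plus 0.5) on a labelled calibration set and returns the
#' optimum under the requested objective, together with the "borderline"
#' volumes whose probability lies within \code{eps} of the chosen threshold
#' and therefore merit human review.
#'
#' @param probabilities model outputs in [0, 1].
#' @param labels binary reference labels; both classes must be present.
#' @param objective "balanced_accuracy" (maximise (TPR+TNR)/2) or "min_fn"
#'   (minimise false negatives subject to FP <= \code{fp_budget}).
#' @param fp_budget false-positive budget for \code{"min_fn"}.
#' @param eps borderline half-width around the returned threshold.
#' @return A list: \code{threshold}, \code{objective}, \code{value} (the
#'   achieved objective), and \code{borderline} (0-based volume indices).
#' @export
tuneThreshold <- function(probabilities, labels,
                          objective = c("balanced_accuracy", "min_fn"),
                          fp_budget = Inf, eps = 0.05) {
  objective <- match.arg(objective)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    .stop2("calibration set must contain both classes")
  sp <- sort(unique(probabilities))
  cand <- sort(unique(c(0.5, if (length(sp) > 1L) (head(sp, -1L) + tail(sp, -1L)) / 2)))
  cand <- cand[cand > 0 & cand < 1]
  eval_t <- function(t) {
    cnt <- confusionCounts(labels, classifyVolumes(probabilities, t))
    m <- qcMetrics(cnt, t)
    if (objective == "balanced_accuracy") {
      mean(c(m$tpr, m$tnr))
    } else {
      if (cnt["FP"] > fp_budget) -Inf else -as.numeric(cnt["FN"])
    }
  }
  vals <- vapply(cand, eval_t, 0)
  best <- max(vals)
  ties <- which(vals == best)
  # tie-break: the most stable threshold, i.e. the one farthest from any
  # observed probability (a separating gap's midpoint wins in the gap)
  margin <- vapply(cand[ties], function(t) min(abs(probabilities - t)), 0)
  thr <- cand[ties[which.max(margin)]]
  list(threshold = thr, objective = objective,
       value = if (objective == "min_fn") -best else best,
       borderline = which(abs(probabilities - thr) < eps) - 1L)
}
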
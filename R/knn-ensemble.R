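## Outcome prediction: k-NN models trained on the balanced undersampled
## subsets, combined by max-voting; rank-based ROC AUC and the confusion
## metrics with LF as the positive class.

#' Fit the balanced-subset k-NN ensemble
#'
#' One k-NN model per balanced subset; each model z-scores the selected
#' features with that subset's mean/sd (constant features get scale 1)
#' and stores the standardized training points and labels.
#'
#' @param table training \linkS4class{FeatureTable}.
#' @param feature_ids selected feature ids.
#' @param subsets list of row-index vectors (see
#'   \code{\link{makeBalancedSubsets}}).
#' @param k neighbour count (default 5; must not exceed the subset size).
#' @return A \linkS4class{KnnEnsemble}.
#' @export
fitKnnEnsemble <- function(table, feature_ids, subsets, k = 5) {
  stopifnot(all(feature_ids %in% colnames(table@values)))
  y <- .binLabels(table@lesionData$outcome)
  mat <- table@values[, feature_ids, drop = FALSE]
  models <- lapply(subsets, function(idx) {
    if (k > length(idx)) stop("k larger than subset size")
    x <- mat[idx, , drop = FALSE]
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl <= 0 | !is.finite(scl)] <- 1
    list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"),
         y = y[idx], center = ctr, scale = scl)
  })
  new("KnnEnsemble", models = models, k = as.integer(k),
      featureIds = feature_ids)
}

#' Predict LC/LF by ensemble max-voting
#'
#' Each model standardizes the query features with its own statistics and
#' votes with the majority label of its k nearest (Euclidean) training
#' points, distance ties broken by training-point index; the ensemble
#' vote fraction is the fraction of models voting LF and the final label
#' is LF iff that fraction exceeds 0.5 (odd model and neighbour counts
#' make every vote decisive).
#'
#' @param ensemble a \linkS4class{KnnEnsemble}.
#' @param newdata a \linkS4class{FeatureTable} or numeric matrix holding
#'   all ensemble features.
#' @return data.frame with \code{vote_fraction} and \code{label}.
#' @export
predictEnsemble <- function(ensemble, newdata) {
  mat <- if (is(newdata, "FeatureTable")) newdata@values else newdata
  missing <- setdiff(ensemble@featureIds, colnames(mat))
  if (length(missing))
    stop("missing features: ", paste(missing, collapse = ", "))
  mat <- mat[, ensemble@featureIds, drop = FALSE]
  votes <- matrix(0, nrow(mat), length(ensemble@models))
  for (m in seq_along(ensemble@models)) {
    mod <- ensemble@models[[m]]
    std <- sweep(sweep(mat, 2, mod$center), 2, mod$scale, "/")
    vf <- cpp_knn_vote(mod$x, as.integer(mod$y), std, ensemble@k)
    votes[, m] <- as.numeric(vf > 0.5) # each model's majority label
  }
  vote_fraction <- rowMeans(votes)
  data.frame(lesion_id = rownames(mat) %||% seq_len(nrow(mat)),
             vote_fraction = vote_fraction,
             label = ifelse(vote_fraction > 0.5, "LF", "LC"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank-based ROC AUC
#'
#' Mann-Whitney AUC (midrank ties) of a continuous score for LF.
#'
#' @param scores numeric scores (e.g. ensemble vote fractions).
#' @param labels LC/LF labels (or 0/1 with 1 = LF).
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, labels) {
  y <- .binLabels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  cpp_auc(as.numeric(scores), as.integer(y))
}

#' Confusion metrics with LF as the positive class
#'
#' Sensitivity is the fraction of LF lesions predicted LF; specificity the
#' fraction of LC lesions predicted LC. Percentages are stored at full
#' precision.
#'
#' @param predicted predicted labels (LC/LF).
#' @param truth true labels (LC/LF).
#' @param scores optional continuous scores for the AUC.
#' @return A list of class \code{MetricsReport}: sensitivity, specificity,
#'   accuracy (percent), auc (or NA), confusion counts.
#' @export
classificationMetrics <- function(predicted, truth, scores = NULL) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  tp <- sum(predicted == "LF" & truth == "LF")
  tn <- sum(predicted == "LC" & truth == "LC")
  fp <- sum(predicted == "LF" & truth == "LC")
  fn <- sum(predicted == "LC" & truth == "LF")
  auc <- if (!is.null(scores) && length(unique(truth)) == 2)
    rocAUC(scores, truth) else NA_real_
  structure(list(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    auc = auc,
    confusion = c(TP = tp, TN = tn, FP = fp, FN = fn)),
    class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%  AUC %s\n",
              x$sensitivity, x$specificity, x$accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Serialize / restore a KnnEnsemble as JSON
#'
#' @param ensemble a \linkS4class{KnnEnsemble}.
#' @param path output JSON path.
#' @return \code{writeKnnEnsemble} returns the path invisibly;
#'   \code{readKnnEnsemble} the restored ensemble.
#' @export
writeKnnEnsemble <- function(ensemble, path) {
  obj <- list(format = "BrainMetRadiomics-knn-ensemble-v1",
              k = ensemble@k, feature_ids = ensemble@featureIds,
              models = lapply(ensemble@models, function(m)
                list(x = unname(m$x), y = m$y, center = unname(m$center),
                     scale = unname(m$scale))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeKnnEnsemble
#' @export
readKnnEnsemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "BrainMetRadiomics-knn-ensemble-v1"))
    stop("unrecognized ensemble file")
  fids <- obj$feature_ids
  models <- lapply(seq_len(nrow(obj$models)), function(i) {
    x <- obj$models$x[[i]]
    colnames(x) <- fids
    list(x = x, y = as.integer(obj$models$y[[i]]),
         center = setNames(obj$models$center[[i]], fids),
         scale = setNames(obj$models$scale[[i]], fids))
  })
  new("KnnEnsemble", models = models, k = as.integer(obj$k),
      featureIds = fids)
}
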
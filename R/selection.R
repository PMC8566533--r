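## Multi-phase feature reduction/selection: Pearson R^2 redundancy pruning
## (connected components of the thresholded correlation graph, keeping the
## feature with the best univariate AUC), greedy mRMR ranking (difference
## criterion, mutual information on 4-quantile-discretized features), and
## sequential forward selection scored by patient-level stratified 5-fold
## CV AUC averaged over class-balanced undersampled replicates.

#' Feature selection configuration
#'
#' @param r2_threshold Pearson R-squared above which two features are
#'   treated as redundant (default 0.8).
#' @param mrmr_pool number of top-ranked features kept after mRMR
#'   (default 100).
#' @param n_subsets number of balanced undersampled replicates; odd so
#'   max-voting is decisive (default 501).
#' @param cv_folds patient-level stratified folds (default 5).
#' @param max_features cap on the sequential forward selection (default 10).
#' @param min_improvement minimum mean-AUC gain to accept another feature
#'   (default 1e-4).
#' @param seed integer seed for subset and fold draws.
#' @return A validated list of class \code{SelectionConfig}.
#' @export
selectionConfig <- function(r2_threshold = 0.8, mrmr_pool = 100,
                            n_subsets = 501, cv_folds = 5,
                            max_features = 10, min_improvement = 1e-4,
                            seed = 1L) {
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stop("r2_threshold must be in (0, 1)")
  if (n_subsets %% 2 == 0) stop("n_subsets must be odd")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(r2_threshold = r2_threshold, mrmr_pool = mrmr_pool,
                 n_subsets = n_subsets, cv_folds = cv_folds,
                 max_features = max_features,
                 min_improvement = min_improvement,
                 seed = as.integer(seed)),
            class = "SelectionConfig")
}

#' Direction-corrected univariate rank AUC
#'
#' Threshold-free (Mann-Whitney, midrank ties) AUC of a raw feature as a
#' score for LF, corrected for direction: \code{max(AUC, 1 - AUC)}, so the
#' result is in [0.5, 1].
#'
#' @param x numeric feature values.
#' @param labels \code{"LC"}/\code{"LF"} labels (or 0/1 with 1 = LF).
#' @return AUC in [0.5, 1].
#' @export
univariateAUC <- function(x, labels) {
  y <- .binLabels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  a <- cpp_auc(as.numeric(x), as.integer(y))
  max(a, 1 - a)
}

.binLabels <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "LF")
  else as.integer(labels != 0)
}

#' Correlation-based redundancy reduction
#'
#' Builds a graph on features with edges where pairwise Pearson
#' R-squared exceeds the threshold; every connected component is a set of
#' highly correlated features, from which the feature with the highest
#' direction-corrected univariate AUC on the training labels is retained
#' (ties broken by lexicographically smallest id). Constant features have
#' undefined correlation and form singleton components.
#'
#' @param table a \linkS4class{FeatureTable} (training lesions).
#' @param config a \code{SelectionConfig}.
#' @return A list: \code{table} (reduced \linkS4class{FeatureTable}) and
#'   \code{audit} (per-component members and representatives).
#' @export
correlationReduce <- function(table, config = selectionConfig()) {
  mat <- table@values
  p <- ncol(mat)
  if (p < 2)
    return(list(table = table,
                audit = list(components = list(colnames(mat)),
                             representatives = colnames(mat))))
  sds <- apply(mat, 2, stats::sd)
  ok <- which(sds > 0)
  r2 <- matrix(0, p, p)
  if (length(ok) >= 2) {
    cc <- suppressWarnings(stats::cor(mat[, ok, drop = FALSE]))
    cc[!is.finite(cc)] <- 0
    r2[ok, ok] <- cc^2
  }
  diag(r2) <- 0
  adj <- r2 > config$r2_threshold

  ## connected components by repeated BFS
  comp <- integer(p)
  ncomp <- 0L
  for (s in seq_len(p)) {
    if (comp[s] > 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- ncomp
      queue <- c(queue, nb)
    }
  }

  y <- .binLabels(table@lesionData$outcome)
  aucs <- vapply(seq_len(p), function(j) {
    if (sds[j] == 0) return(0.5)
    a <- cpp_auc(mat[, j], y)
    max(a, 1 - a)
  }, numeric(1))

  ids <- colnames(mat)
  comps <- split(seq_len(p), comp)
  reps <- vapply(comps, function(members) {
    best <- max(aucs[members])
    cand <- members[aucs[members] >= best - 1e-15]
    cand[order(ids[cand])][1]
  }, integer(1))
  reps <- sort(reps)
  list(table = table[, reps],
       audit = list(
         components = lapply(comps, function(m) ids[m]),
         representatives = ids[reps],
         univariate_auc = setNames(aucs, ids)))
}

## mutual information (nats) of two small positive-integer vectors
.mi <- function(a, b) {
  na <- max(a)
  nb <- max(b)
  tab <- matrix(tabulate((a - 1L) * nb + b, na * nb), na, nb, byrow = TRUE)
  n <- length(a)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  e <- outer(pa, pb)
  sel <- p > 0
  sum(p[sel] * log(p[sel] / e[sel]))
}

## 4-bin equal-frequency discretization (continuous features); already
## discrete-ish vectors (few unique values) are left as they are
.discretize4 <- function(x, bins = 4) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 7))
  as.integer(cut(x, qs, include.lowest = TRUE))
}

#' Greedy mRMR feature ranking (difference criterion)
#'
#' Ranks features by minimal-redundancy-maximal-relevance with the MID
#' (mutual information difference) criterion: the first feature maximizes
#' I(f; y); each subsequent feature maximizes I(f; y) minus the mean
#' mutual information with the already-ranked features. Mutual information
#' is estimated after discretizing each continuous feature into 4
#' equal-frequency bins. Ties break by lexicographic feature id.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param pool how many top-ranked ids to return (default 100).
#' @return Character vector of feature ids, best first.
#' @export
mrmrRank <- function(table, pool = 100) {
  if (pool <= 0) stop("pool must be positive")
  mat <- table@values
  y <- .binLabels(table@lesionData$outcome)
  if (length(unique(y)) < 2) stop("both classes must be present")
  p <- ncol(mat)
  ids <- colnames(mat)
  disc <- lapply(seq_len(p), function(j) as.integer(.discretize4(mat[, j])))
  rel <- vapply(disc, function(d) .mi(d, y + 1L), numeric(1))

  pool <- min(pool, p)
  selected <- integer(0)
  remaining <- seq_len(p)
  redSum <- numeric(p)
  while (length(selected) < pool) {
    if (length(selected) == 0) {
      score <- rel[remaining]
    } else {
      score <- rel[remaining] - redSum[remaining] / length(selected)
    }
    best <- max(score)
    cand <- remaining[score >= best - 1e-12]
    pick <- cand[order(ids[cand])][1]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      redSum[remaining] <- redSum[remaining] +
        vapply(remaining, function(j) .mi(disc[[j]], disc[[pick]]),
               numeric(1))
  }
  ids[selected]
}

#' Build class-balanced undersampled subsets
#'
#' Each subset contains every minority-class lesion plus a
#' without-replacement draw of equal size from the majority class; subsets
#' differ by the seeded RNG and are deterministic given the seed. If the
#' LF class outnumbers LC the roles are swapped with a warning.
#'
#' @param table a \linkS4class{FeatureTable} (training lesions).
#' @param config a \code{SelectionConfig} (uses \code{n_subsets},
#'   \code{seed}).
#' @return List of integer row-index vectors into \code{table}.
#' @export
makeBalancedSubsets <- function(table, config = selectionConfig()) {
  y <- .binLabels(table@lesionData$outcome)
  lf <- which(y == 1)
  lc <- which(y == 0)
  if (length(lf) == 0 || length(lc) == 0)
    stop("both classes must be non-empty")
  minority <- lf
  majority <- lc
  if (length(lf) > length(lc)) {
    warning("LF outnumbers LC; undersampling the LF class instead")
    minority <- lc
    majority <- lf
  }
  .withSeed(deriveSeed(config$seed, "subsets"), {
    lapply(seq_len(config$n_subsets), function(s) {
      draw <- sample(majority, length(minority), replace = FALSE)
      sample(c(minority, draw)) # combined and shuffled
    })
  })
}

## patient-level stratified fold assignment within one subset: all lesions
## of a patient share a fold; patients are stratified by their any-LF
## outcome within the subset and dealt round-robin after a seeded shuffle
.patientFolds <- function(patient_id, y, nfold, seed) {
  .withSeed(seed, {
    pat <- unique(patient_id)
    plf <- vapply(pat, function(p) as.integer(any(y[patient_id == p] == 1)),
                  integer(1))
    fold_of <- setNames(integer(length(pat)), pat)
    for (cls in unique(plf)) {
      ps <- sample(pat[plf == cls])
      fold_of[ps] <- rep_len(seq_len(nfold), length(ps))
    }
    as.integer(fold_of[patient_id])
  })
}

#' Cross-validated score of a feature set over balanced subsets
#'
#' For each balanced subset, splits patients into stratified folds (all
#' lesions of a patient in one fold, stratified by the patient's any-LF
#' outcome), fits the k-NN on the training folds with per-fold
#' standardization, scores validation lesions by neighbour vote fraction
#' and averages the per-fold AUCs; the result is the mean over subsets.
#' Folds whose training or validation part is single-class are skipped; a
#' subset with no usable fold is dropped (all dropped is an error).
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param feature_ids character vector of feature columns to use.
#' @param subsets list of row-index vectors from
#'   \code{\link{makeBalancedSubsets}}.
#' @param config a \code{SelectionConfig}.
#' @param k neighbour count for the scoring k-NN (default 5).
#' @param folds optional precomputed per-subset fold assignments (as
#'   produced internally from the config seed); computed when NULL.
#' @return Mean cross-validated AUC.
#' @export
cvFeatureSetScore <- function(table, feature_ids, subsets,
                              config = selectionConfig(), k = 5,
                              folds = NULL) {
  stopifnot(length(feature_ids) > 0)
  mat <- table@values[, feature_ids, drop = FALSE]
  y <- .binLabels(table@lesionData$outcome)
  if (is.null(folds)) folds <- .subsetFolds(table, subsets, config)
  val <- cpp_cv_auc_mean(mat, y, lapply(subsets, function(i) i - 1L),
                         folds, as.integer(k), as.integer(config$cv_folds))
  if (is.na(val)) stop("no usable folds in any subset")
  val
}

## fold assignments for every subset, derived from the config seed
.subsetFolds <- function(table, subsets, config) {
  y <- .binLabels(table@lesionData$outcome)
  pid <- table@lesionData$patient_id
  lapply(seq_along(subsets), function(s)
    .patientFolds(pid[subsets[[s]]], y[subsets[[s]]], config$cv_folds,
                  deriveSeed(config$seed, "folds", s)))
}

#' Sequential forward feature selection
#'
#' Greedily adds the candidate feature maximizing the cross-validated
#' balanced-subset AUC (\code{\link{cvFeatureSetScore}}). A candidate is
#' accepted only if its mean improvement over the current set exceeds
#' \code{min_improvement} \emph{and} one standard error of the paired
#' per-subset improvement (the same balanced subsets score both feature
#' sets, so the improvement is a paired comparison across subsets); this
#' keeps chance fluctuations of the scorer from padding the biomarker with
#' uninformative features. Selection stops at the first rejected candidate
#' or at \code{max_features}. Candidate ties break lexicographically.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param candidates candidate feature ids (e.g. the mRMR pool).
#' @param config a \code{SelectionConfig}.
#' @param k neighbour count for the scoring k-NN.
#' @param subsets optional precomputed balanced subsets.
#' @return A list of class \code{SelectionResult}: \code{selected}
#'   (ordered ids), \code{scores} (per-step mean AUC), \code{audit}.
#' @export
sequentialForwardSelect <- function(table, candidates,
                                    config = selectionConfig(), k = 5,
                                    subsets = NULL) {
  stopifnot(length(candidates) > 0)
  if (is.null(subsets)) subsets <- makeBalancedSubsets(table, config)
  folds <- .subsetFolds(table, subsets, config)
  subs0 <- lapply(subsets, function(i) i - 1L)
  y <- .binLabels(table@lesionData$outcome)
  perSubset <- function(fids) {
    cpp_cv_auc_persubset(table@values[, fids, drop = FALSE], y, subs0,
                         folds, as.integer(k), as.integer(config$cv_folds))
  }
  selected <- character(0)
  scores <- numeric(0)
  currentPer <- NULL
  steps <- list()
  while (length(selected) < config$max_features && length(candidates)) {
    stepPer <- lapply(candidates, function(f) perSubset(c(selected, f)))
    stepScores <- vapply(stepPer, mean, numeric(1), na.rm = TRUE)
    if (all(is.na(stepScores))) stop("no usable folds in any subset")
    best <- max(stepScores)
    ibest <- which(stepScores >= best - 1e-12)
    ipick <- ibest[order(candidates[ibest])][1]
    pick <- candidates[ipick]
    accept <- TRUE
    if (length(selected)) {
      d <- stepPer[[ipick]] - currentPer
      d <- d[!is.na(d)]
      se <- if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else 0
      improvement <- mean(d)
      accept <- improvement >= config$min_improvement && improvement >= se
    } else {
      improvement <- best
    }
    steps[[length(steps) + 1]] <- list(candidates = candidates,
                                       scores = stepScores, picked = pick,
                                       best = best,
                                       improvement = improvement,
                                       accepted = accept)
    if (!accept) break
    selected <- c(selected, pick)
    scores <- c(scores, best)
    currentPer <- stepPer[[ipick]]
    candidates <- setdiff(candidates, pick)
  }
  structure(list(selected = selected, scores = scores,
                 audit = list(steps = steps)),
            class = "SelectionResult")
}

#' Run the full reduction/selection pipeline
#'
#' Correlation-based reduction, mRMR ranking to the top pool, then
#' sequential forward selection.
#'
#' @param table training \linkS4class{FeatureTable}.
#' @param config a \code{SelectionConfig}.
#' @param k scoring k-NN neighbour count.
#' @return A \code{SelectionResult} with the reduction/ranking audit
#'   attached.
#' @export
selectFeatures <- function(table, config = selectionConfig(), k = 5) {
  red <- correlationReduce(table, config)
  ranked <- mrmrRank(red$table, pool = config$mrmr_pool)
  res <- sequentialForwardSelect(red$table, ranked, config, k)
  res$audit$reduction <- red$audit
  res$audit$mrmr <- ranked
  res
}
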
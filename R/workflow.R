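## Orchestration: pipeline configuration, patient-level stratified
## train/test split, clinical-feature encoding, and the end-to-end run
## (preprocess -> extract -> select -> fit -> predict -> metrics ->
## survival) with artifact writing and hashing.

#' Pipeline configuration
#'
#' Defaults match the method's stated constants: 0.5 mm isotropic
#' resampling, 5 mm margins, gray-level bin width 25, k = 5 neighbours,
#' 501 balanced subsets.
#'
#' @param target_spacing isotropic voxel size (mm).
#' @param margin_distance margin expansion (mm).
#' @param bin_width gray-level quantization bin width.
#' @param intensity_scale post-normalization intensity scale.
#' @param selection a \code{SelectionConfig}.
#' @param k_neighbors k-NN neighbour count.
#' @param feature_set_mode one of \code{"radiomic"}, \code{"clinical"},
#'   \code{"clinical_plus_radiomic"} (radiomic features added
#'   incrementally to the clinical set), \code{"radiomic_plus_clinical"}
#'   (clinical features added incrementally to the radiomic set).
#' @param train_fraction fraction of patients assigned to training.
#' @param seed root seed; all stage streams derive from it.
#' @return A list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(target_spacing = 0.5, margin_distance = 5,
                           bin_width = 25, intensity_scale = 100,
                           selection = selectionConfig(),
                           k_neighbors = 5,
                           feature_set_mode = c("radiomic", "clinical",
                                                "clinical_plus_radiomic",
                                                "radiomic_plus_clinical"),
                           train_fraction = 100 / 120, seed = 1L) {
  feature_set_mode <- match.arg(feature_set_mode)
  stopifnot(target_spacing > 0, margin_distance > 0, bin_width > 0,
            train_fraction > 0, train_fraction < 1)
  selection$seed <- as.integer(deriveSeed(seed, "selection"))
  structure(list(target_spacing = target_spacing,
                 margin_distance = margin_distance, bin_width = bin_width,
                 intensity_scale = intensity_scale, selection = selection,
                 k_neighbors = k_neighbors,
                 feature_set_mode = feature_set_mode,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Patient-level stratified train/test split
#'
#' Splits at patient level so no patient appears in both sets. Strata are
#' the patient-level outcome (any lesion LF) crossed with the
#' lesion-count bucket (1 / 2 / >= 3); the training count per stratum is
#' allocated by largest remainder so the overall split matches
#' \code{train_fraction} exactly after rounding. A single-patient stratum
#' goes to training with a warning.
#'
#' @param manifest data.frame with one row per lesion (\code{patient_id},
#'   \code{outcome}).
#' @param train_fraction fraction of patients for training.
#' @param seed integer seed.
#' @return A list with \code{train} and \code{test} manifests.
#' @export
splitTrainTest <- function(manifest, train_fraction, seed = 1L) {
  pid <- as.character(manifest$patient_id)
  pat <- unique(pid)
  anyLF <- vapply(pat, function(p)
    any(manifest$outcome[pid == p] == "LF"), logical(1))
  nles <- vapply(pat, function(p) sum(pid == p), numeric(1))
  bucket <- pmin(nles, 3)
  stratum <- paste(as.integer(anyLF), bucket, sep = ":")

  nTrainTotal <- round(train_fraction * length(pat))
  strata <- split(seq_along(pat), stratum)
  base <- vapply(strata, function(s) floor(train_fraction * length(s)),
                 numeric(1))
  frac <- vapply(strata, function(s) train_fraction * length(s), numeric(1)) -
    base
  rem <- nTrainTotal - sum(base)
  if (rem > 0) {
    up <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[up] <- base[up] + 1
  }
  trainPat <- character(0)
  .withSeed(deriveSeed(seed, "split"), {
    for (s in seq_along(strata)) {
      members <- pat[strata[[s]]]
      if (length(members) == 1 && base[s] < 1) {
        warning("stratum with a single patient assigned to training")
        base[s] <- 1
      }
      take <- min(base[s], length(members))
      trainPat <- c(trainPat, sample(members)[seq_len(take)])
    }
  })
  list(train = manifest[pid %in% trainPat, , drop = FALSE],
       test = manifest[!pid %in% trainPat, , drop = FALSE])
}

#' Encode a clinical record as numeric features
#'
#' Binary fields map to 0/1; location to 1 for supratentorium; histology
#' to a one-hot over the study categories (lung, breast, melanoma,
#' colorectal, RCC, other; unknown values map to "other" with a warning);
#' total dose, number of brain metastases and maximum diameter stay
#' numeric. Ids are prefixed \code{"clin|"}.
#'
#' @param record named list with histology, total_dose, n_brain_mets,
#'   location, max_diameter, prev_wbrt, prev_srs_srt, targeted_systemic.
#' @return Named numeric vector of 13 values.
#' @export
encodeClinical <- function(record) {
  need <- c("histology", "total_dose", "n_brain_mets", "location",
            "max_diameter", "prev_wbrt", "prev_srs_srt",
            "targeted_systemic")
  if (!all(need %in% names(record)))
    stop("incomplete clinical record: missing ",
         paste(setdiff(need, names(record)), collapse = ", "))
  hist <- as.character(record$histology)
  if (!hist %in% .HISTOLOGIES) {
    warning(sprintf("unknown histology '%s' mapped to 'other'", hist))
    hist <- "other"
  }
  onehot <- setNames(as.numeric(.HISTOLOGIES == hist),
                     paste0("clin|histology|", .HISTOLOGIES))
  c(setNames(as.numeric(record$total_dose), "clin|TD"),
    setNames(as.numeric(record$n_brain_mets), "clin|NBM"),
    setNames(as.numeric(record$max_diameter), "clin|MaxDiam"),
    setNames(as.numeric(record$location == "supratentorium"),
             "clin|location"),
    setNames(as.numeric(as.logical(record$prev_wbrt)), "clin|prev_wbrt"),
    setNames(as.numeric(as.logical(record$prev_srs_srt)),
             "clin|prev_srs_srt"),
    setNames(as.numeric(as.logical(record$targeted_systemic)),
             "clin|targeted_systemic"),
    onehot)
}

## clinical FeatureTable from a manifest
.clinicalTable <- function(manifest) {
  rows <- lapply(seq_len(nrow(manifest)), function(i)
    encodeClinical(as.list(manifest[i, ])))
  mat <- do.call(rbind, rows)
  FeatureTable(mat, manifest[c("patient_id", "lesion_id", "outcome")])
}

#' Run the full outcome-prediction pipeline
#'
#' Executes preprocess, feature extraction, (clinical encoding per
#' \code{feature_set_mode}), feature reduction/ranking/selection on the
#' training patients, ensemble fitting, test-set prediction, metric
#' computation and the patient-level survival comparison. Deterministic
#' given (cohort, config).
#'
#' @param cohort result of \code{\link{generateCohort}} /
#'   \code{\link{readCohort}}: a list with \code{lesions} and
#'   \code{manifest}.
#' @param config a \code{PipelineConfig}.
#' @param outDir optional directory for artifacts (feature table CSV,
#'   selection audit JSON, model JSON, predictions CSV, metrics JSON,
#'   survival JSON); artifact MD5 hashes are always returned.
#' @return A list with \code{features}, \code{split}, \code{selection},
#'   \code{ensemble}, \code{predictions}, \code{metrics},
#'   \code{survival}, \code{incremental} (for the combined modes) and
#'   \code{artifactHashes}.
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), outDir = NULL) {
  stopifnot(length(cohort$lesions) > 0)
  mode <- config$feature_set_mode

  radiomic <- NULL
  if (mode != "clinical") {
    radiomic <- extractCohortFeatures(
      cohort$lesions, targetSpacing = config$target_spacing,
      marginDistance = config$margin_distance,
      intensityScale = config$intensity_scale,
      binWidth = config$bin_width)
  }
  clinical <- .clinicalTable(cohort$manifest)

  features <- switch(mode,
    radiomic = radiomic,
    clinical = clinical,
    ## combined modes carry both namespaces in one table
    FeatureTable(cbind(radiomic@values, clinical@values),
                 radiomic@lesionData))

  split <- splitTrainTest(cohort$manifest, config$train_fraction,
                          seed = config$seed)
  trainIdx <- which(features@lesionData$lesion_id %in% split$train$lesion_id)
  testIdx <- which(features@lesionData$lesion_id %in% split$test$lesion_id)
  if (length(intersect(split$train$patient_id, split$test$patient_id)))
    stop("patient leakage between train and test")
  trainTab <- features[trainIdx, ]
  testTab <- features[testIdx, ]

  selcfg <- config$selection

  ## selection operates within one namespace; combined modes select within
  ## each namespace then combine incrementally
  selectWithin <- function(tab, prefixKeep = NULL) {
    t2 <- if (is.null(prefixKeep)) tab else
      tab[, grep(prefixKeep, colnames(tab@values))]
    selectFeatures(t2, selcfg, k = config$k_neighbors)
  }

  subsets <- makeBalancedSubsets(trainTab, selcfg)
  evalSet <- function(fids) {
    ens <- fitKnnEnsemble(trainTab, fids, subsets, k = config$k_neighbors)
    pred <- predictEnsemble(ens, testTab)
    met <- classificationMetrics(pred$label, testTab@lesionData$outcome,
                                 scores = pred$vote_fraction)
    list(ensemble = ens, predictions = pred, metrics = met)
  }

  incremental <- NULL
  if (mode %in% c("radiomic", "clinical")) {
    selection <- selectWithin(trainTab)
    fids <- selection$selected
  } else {
    baseMode <- if (mode == "clinical_plus_radiomic") "^clin\\|" else
      "^(T1|FLAIR)\\|"
    addMode <- if (mode == "clinical_plus_radiomic") "^(T1|FLAIR)\\|" else
      "^clin\\|"
    selBase <- selectWithin(trainTab, baseMode)
    selAdd <- selectWithin(trainTab, addMode)
    selection <- selBase
    incremental <- list()
    fids <- selBase$selected
    for (step in seq_along(selAdd$selected)) {
      fidsStep <- c(selBase$selected, selAdd$selected[seq_len(step)])
      ev <- evalSet(fidsStep)
      incremental[[step]] <- list(added = selAdd$selected[seq_len(step)],
                                  metrics = ev$metrics)
    }
    selection$added <- selAdd$selected
    fids <- c(selBase$selected, selAdd$selected)
  }

  final <- evalSet(fids)

  ## survival on the independent test set, predicted vs labelled cohorts
  testManifest <- split$test
  predMap <- setNames(final$predictions$label, testTab@lesionData$lesion_id)
  survData <- data.frame(
    patient_id = testManifest$patient_id,
    outcome = testManifest$outcome,
    predicted = unname(predMap[testManifest$lesion_id]),
    survival_time = testManifest$survival_time,
    survival_event = testManifest$survival_event,
    stringsAsFactors = FALSE)
  surv <- survivalComparison(survData)

  hashes <- NULL
  dir <- outDir %||% tempfile("bmr_run_")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFeatureTable(features, file.path(dir, "features.csv"))
  jsonlite::write_json(
    list(selected = selection$selected, scores = selection$scores),
    file.path(dir, "selection.json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(final$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(sensitivity = final$metrics$sensitivity,
         specificity = final$metrics$specificity,
         accuracy = final$metrics$accuracy, auc = final$metrics$auc,
         confusion = as.list(final$metrics$confusion)),
    file.path(dir, "metrics.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(predicted_p = surv$predicted$logrank$p_value %||% NA,
         label_p = surv$label$logrank$p_value %||% NA,
         predicted_median_lc = surv$predicted$km_lc$median %||% NA,
         predicted_median_lf = surv$predicted$km_lf$median %||% NA),
    file.path(dir, "survival.json"), digits = NA, auto_unbox = TRUE)
  writeKnnEnsemble(final$ensemble, file.path(dir, "model.json"))
  arts <- c("features.csv", "selection.json", "predictions.csv",
            "metrics.json", "survival.json", "model.json")
  hashes <- tools::md5sum(file.path(dir, arts))
  names(hashes) <- arts
  if (is.null(outDir)) unlink(dir, recursive = TRUE)

  list(features = features, split = split, selection = selection,
       ensemble = final$ensemble, predictions = final$predictions,
       metrics = final$metrics, survival = surv,
       incremental = incremental, artifactHashes = hashes)
}
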
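#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib BrainMetRadiomics, .registration = TRUE
NULL

#' VolumetricImage: a 3D scalar grid with physical metadata
#'
#' A minimal container for a single 3D MRI volume. Voxel centres sit at
#' \code{origin + (index - 1) * spacing} (1-based indices, millimetres).
#'
#' @slot values numeric 3D array of voxel intensities.
#' @slot spacing numeric length-3, mm per axis (strictly positive).
#' @slot origin numeric length-3, mm position of the first voxel centre.
#' @slot modality character, one of \code{"CE-T1w"}, \code{"T2-FLAIR"}.
#'
#' @aliases VolumetricImage-class
#' @exportClass VolumetricImage
setClass("VolumetricImage",
  representation(
    values   = "array",
    spacing  = "numeric",
    origin   = "numeric",
    modality = "character"
  ),
  prototype(
    spacing  = c(1, 1, 1),
    origin   = c(0, 0, 0),
    modality = "CE-T1w"
  )
)

setValidity("VolumetricImage", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite everywhere")
  if (!object@modality %in% c("CE-T1w", "T2-FLAIR"))
    msg <- c(msg, "modality must be 'CE-T1w' or 'T2-FLAIR'")
  if (length(msg)) msg else TRUE
})

#' Construct a VolumetricImage
#'
#' @param values numeric 3D array.
#' @param spacing mm per axis (length 3).
#' @param origin mm triple for the first voxel centre.
#' @param modality \code{"CE-T1w"} or \code{"T2-FLAIR"}.
#' @return A \linkS4class{VolumetricImage}.
#' @export
VolumetricImage <- function(values, spacing = c(1, 1, 1),
                            origin = c(0, 0, 0), modality = "CE-T1w") {
  new("VolumetricImage", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality)
}

.MASK_KINDS <- c("tumour", "edema", "tumour-margin", "lesion-margin", "brain")

#' RegionMask: a binary grid aligned with an image grid
#'
#' @slot values logical 3D array (TRUE inside the region).
#' @slot spacing numeric length-3 (mm).
#' @slot origin numeric length-3 (mm).
#' @slot kind character; one of tumour, edema, tumour-margin,
#'   lesion-margin, brain.
#'
#' @aliases RegionMask-class
#' @exportClass RegionMask
setClass("RegionMask",
  representation(
    values  = "array",
    spacing = "numeric",
    origin  = "numeric",
    kind    = "character"
  ),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), kind = "tumour")
)

setValidity("RegionMask", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (!is.logical(object@values))
    msg <- c(msg, "values must be logical (strictly binary)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive numbers")
  if (!object@kind %in% .MASK_KINDS)
    msg <- c(msg, paste("kind must be one of:", paste(.MASK_KINDS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a RegionMask
#'
#' @param values logical (or 0/1 numeric) 3D array.
#' @param spacing mm per axis.
#' @param origin mm triple.
#' @param kind region kind; see \linkS4class{RegionMask}.
#' @return A \linkS4class{RegionMask}.
#' @export
RegionMask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       kind = "tumour") {
  if (!is.logical(values)) {
    v <- values != 0
    dim(v) <- dim(values)
    values <- v
  }
  new("RegionMask", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), kind = kind)
}

#' QuantizedROI: fixed-bin-width gray levels on mask voxels
#'
#' Integer gray levels defined on the voxels of a region of interest, with
#' level 0 outside the mask. Bin edges sit at integer multiples of
#' \code{binWidth} (edges equally spaced from zero) and the minimum in-mask
#' intensity maps to level 1.
#'
#' @slot levels integer 3D array; 0 outside the mask, in \code{[1, nLevels]}
#'   inside.
#' @slot nLevels integer, the maximum gray level Ng.
#' @slot binWidth numeric bin width in intensity units.
#' @slot spacing numeric length-3 (mm).
#'
#' @aliases QuantizedROI-class
#' @exportClass QuantizedROI
setClass("QuantizedROI",
  representation(
    levels   = "array",
    nLevels  = "integer",
    binWidth = "numeric",
    spacing  = "numeric"
  )
)

setValidity("QuantizedROI", function(object) {
  msg <- character()
  if (!is.integer(object@levels) || length(dim(object@levels)) != 3L)
    msg <- c(msg, "levels must be an integer 3D array")
  inmask <- object@levels[object@levels > 0L]
  if (length(inmask) == 0L)
    msg <- c(msg, "mask must be non-empty")
  else if (max(inmask) != object@nLevels || min(inmask) < 1L)
    msg <- c(msg, "in-mask levels must span [1, nLevels]")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  if (length(msg)) msg else TRUE
})

#' LesionSample: one lesion's images, masks, outcome and survival
#'
#' Bundles the per-lesion inputs of the pipeline: a CE-T1w and a T2-FLAIR
#' volume, each with its own tumour / edema / brain masks rasterized on
#' that volume's grid, the treatment outcome label, clinical covariates and
#' the patient-level survival record.
#'
#' @slot patientId character patient identifier.
#' @slot lesionId character lesion identifier (unique within the cohort).
#' @slot images named list with elements \code{T1} and \code{FLAIR}, each a
#'   \linkS4class{VolumetricImage}.
#' @slot masks named list with elements \code{T1} and \code{FLAIR}; each a
#'   named list of \linkS4class{RegionMask} with at least
#'   \code{tumour}, \code{edema}, \code{brain}.
#' @slot outcome character, \code{"LC"} or \code{"LF"}.
#' @slot clinical named list of clinical covariates.
#' @slot survivalTime numeric, patient survival in months.
#' @slot survivalEvent logical, TRUE if death observed.
#'
#' @aliases LesionSample-class
#' @exportClass LesionSample
setClass("LesionSample",
  representation(
    patientId     = "character",
    lesionId      = "character",
    images        = "list",
    masks         = "list",
    outcome       = "character",
    clinical      = "list",
    survivalTime  = "numeric",
    survivalEvent = "logical"
  )
)

setValidity("LesionSample", function(object) {
  msg <- character()
  if (!object@outcome %in% c("LC", "LF"))
    msg <- c(msg, "outcome must be 'LC' or 'LF'")
  if (!all(c("T1", "FLAIR") %in% names(object@images)))
    msg <- c(msg, "images must contain 'T1' and 'FLAIR'")
  for (mod in intersect(c("T1", "FLAIR"), names(object@images))) {
    img <- object@images[[mod]]
    mk <- object@masks[[mod]]
    if (is.null(mk) || !all(c("tumour", "edema", "brain") %in% names(mk))) {
      msg <- c(msg, sprintf("masks$%s must contain tumour, edema, brain", mod))
      next
    }
    for (nm in names(mk)) {
      m <- mk[[nm]]
      if (!identical(dim(m@values), dim(img@values)))
        msg <- c(msg, sprintf("mask '%s' grid does not match %s image", nm, mod))
    }
    tum <- mk$tumour@values; bra <- mk$brain@values
    if (!any(tum)) msg <- c(msg, sprintf("%s tumour mask is empty", mod))
    if (any(tum & !bra)) msg <- c(msg, sprintf("%s tumour extends outside brain", mod))
    if (any(mk$edema@values & !bra))
      msg <- c(msg, sprintf("%s edema extends outside brain", mod))
  }
  if (length(msg)) msg else TRUE
})

#' FeatureTable: lesions-by-features matrix with lesion metadata
#'
#' @slot values numeric matrix, one row per lesion, columns named by
#'   feature id (\code{"<image>|<region>|<family>|<name>"} for radiomic
#'   features, \code{"clin|<name>"} for clinical ones).
#' @slot lesionData data.frame with columns \code{patient_id},
#'   \code{lesion_id}, \code{outcome}, aligned with rows of \code{values}.
#'
#' @aliases FeatureTable-class
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(values = "matrix", lesionData = "data.frame")
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (nrow(object@values) != nrow(object@lesionData))
    msg <- c(msg, "values and lesionData must have the same number of rows")
  need <- c("patient_id", "lesion_id", "outcome")
  if (!all(need %in% names(object@lesionData)))
    msg <- c(msg, "lesionData needs patient_id, lesion_id, outcome columns")
  else if (!all(object@lesionData$outcome %in% c("LC", "LF")))
    msg <- c(msg, "outcome labels must be 'LC' or 'LF'")
  if (is.null(colnames(object@values)) && ncol(object@values) > 0)
    msg <- c(msg, "feature columns must be named")
  if (anyDuplicated(colnames(object@values)))
    msg <- c(msg, "feature ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric lesions-by-features matrix with column names.
#' @param lesionData data.frame with patient_id, lesion_id, outcome.
#' @return A \linkS4class{FeatureTable}.
#' @export
FeatureTable <- function(values, lesionData) {
  lesionData$patient_id <- as.character(lesionData$patient_id)
  lesionData$lesion_id <- as.character(lesionData$lesion_id)
  lesionData$outcome <- as.character(lesionData$outcome)
  rownames(values) <- lesionData$lesion_id
  new("FeatureTable", values = values, lesionData = lesionData)
}

#' KnnEnsemble: k-NN models trained on balanced undersampled subsets
#'
#' Each model keeps its own training points (z-scored with that subset's
#' per-feature mean/sd) and labels; prediction is by max-voting across
#' models, each model voting with the majority label of its k nearest
#' training points.
#'
#' @slot models list; each element has \code{x} (standardized training
#'   matrix), \code{y} (integer labels, 1 = LF), \code{center}, \code{scale}.
#' @slot k integer neighbour count (odd).
#' @slot featureIds character, the feature ids the ensemble consumes.
#'
#' @aliases KnnEnsemble-class
#' @exportClass KnnEnsemble
setClass("KnnEnsemble",
  representation(models = "list", k = "integer", featureIds = "character")
)

setValidity("KnnEnsemble", function(object) {
  msg <- character()
  if (length(object@models) < 1L) msg <- c(msg, "ensemble has no models")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----

setMethod("show", "VolumetricImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("VolumetricImage [%s] %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              object@modality, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "RegionMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("RegionMask [%s] %d x %d x %d, %d voxels in mask\n",
              object@kind, d[1], d[2], d[3], sum(object@values)))
})

setMethod("show", "QuantizedROI", function(object) {
  cat(sprintf("QuantizedROI: %d voxels, Ng = %d, bin width %.4g\n",
              sum(object@levels > 0L), object@nLevels, object@binWidth))
})

setMethod("show", "LesionSample", function(object) {
  cat(sprintf("LesionSample %s (patient %s), outcome %s\n",
              object@lesionId, object@patientId, object@outcome))
  cat(sprintf("  T1 grid %s; FLAIR grid %s\n",
              paste(dim(object@images$T1@values), collapse = "x"),
              paste(dim(object@images$FLAIR@values), collapse = "x")))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d lesions x %d features (%d patients; %d LF / %d LC)\n",
              nrow(object@values), ncol(object@values),
              length(unique(object@lesionData$patient_id)),
              sum(object@lesionData$outcome == "LF"),
              sum(object@lesionData$outcome == "LC")))
})

setMethod("show", "KnnEnsemble", function(object) {
  cat(sprintf("KnnEnsemble: %d models, k = %d, %d features\n",
              length(object@models), object@k, length(object@featureIds)))
})

## ---- accessors ----

#' Accessors for pipeline containers
#'
#' \code{imageValues}/\code{maskValues} return the raw 3D arrays;
#' \code{imageSpacing} the mm spacing triple; \code{featureMatrix} and
#' \code{lesionInfo} the two components of a \linkS4class{FeatureTable};
#' \code{featureIds} the feature column names; \code{outcomeLabels} the
#' per-lesion LC/LF labels.
#'
#' @param x a package object.
#' @return The component named by each accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
imageValues <- function(x) x@values

#' @rdname accessors
#' @export
imageSpacing <- function(x) x@spacing

#' @rdname accessors
#' @export
maskValues <- function(x) x@values

#' @rdname accessors
#' @export
featureMatrix <- function(x) x@values

#' @rdname accessors
#' @export
lesionInfo <- function(x) x@lesionData

#' @rdname accessors
#' @export
featureIds <- function(x) {
  if (is(x, "KnnEnsemble")) x@featureIds else colnames(x@values)
}

#' @rdname accessors
#' @export
outcomeLabels <- function(x) x@lesionData$outcome

#' Subset a FeatureTable
#'
#' @param x a \linkS4class{FeatureTable}.
#' @param i lesion (row) index.
#' @param j feature (column) index or ids.
#' @param ... ignored.
#' @param drop ignored; the result is always a FeatureTable.
#' @return A \linkS4class{FeatureTable}.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  FeatureTable(x@values[i, j, drop = FALSE], x@lesionData[i, , drop = FALSE])
})
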
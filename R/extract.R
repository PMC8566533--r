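## Per-lesion preprocessing and assembly of the full radiomic panel.
## Default configuration: 4 regions (tumour, edema, tumour-margin,
## lesion-margin) x 2 images x (18 first-order + 24 GLCM + 14 GLDM +
## 16 GLSZM + 5 NGTDM) texture/intensity features, plus 14 morphology
## features per region computed once (tumour and tumour-margin from the
## CE-T1w-grid masks; edema and lesion-margin from the T2-FLAIR-grid
## masks): 4 x 2 x 77 + 4 x 14 = 672 features per lesion.

.REGIONS <- c("tumour", "edema", "tumour-margin", "lesion-margin")

#' Preprocess one lesion sample
#'
#' Resamples both modalities (and their masks) to an isotropic grid,
#' normalizes intensities to zero mean / unit variance within the brain
#' (then rescales by \code{intensityScale}), and builds the tumour-margin
#' and lesion-margin masks (expansion shell clipped to the brain).
#'
#' @param lesion a \linkS4class{LesionSample}.
#' @param targetSpacing isotropic voxel size in mm (default 0.5).
#' @param marginDistance margin expansion distance in mm (default 5).
#' @param intensityScale post-normalization intensity scale (default 100).
#' @return A preprocessed \linkS4class{LesionSample} whose masks include
#'   \code{tumour-margin} and \code{lesion-margin}.
#' @export
preprocessLesion <- function(lesion, targetSpacing = 0.5,
                             marginDistance = 5, intensityScale = 100) {
  stopifnot(is(lesion, "LesionSample"))
  images <- list()
  masks <- list()
  for (mod in c("T1", "FLAIR")) {
    res <- resampleToIsotropic(lesion@images[[mod]], lesion@masks[[mod]],
                               target = targetSpacing)
    img <- normalizeWithinBrain(res$image, res$masks$brain,
                                scale = intensityScale)
    mk <- res$masks
    lesionMask <- RegionMask(mk$tumour@values | mk$edema@values,
                             spacing = mk$tumour@spacing,
                             origin = mk$tumour@origin, kind = "edema")
    mk[["tumour-margin"]] <- buildMarginMask(mk$tumour, mk$brain,
                                             distance = marginDistance,
                                             kind = "tumour-margin")
    mk[["lesion-margin"]] <- buildMarginMask(lesionMask, mk$brain,
                                             distance = marginDistance,
                                             kind = "lesion-margin")
    images[[mod]] <- img
    masks[[mod]] <- mk
  }
  initialize(lesion, images = images, masks = masks)
}

#' Extract the radiomic feature vector of one preprocessed lesion
#'
#' Computes first-order and GLCM/GLDM/GLSZM/NGTDM texture features for
#' each of the four regions on each of the two images, and the 14
#' morphology features once per region. Feature ids follow
#' \code{"<image>|<region>|<family>|<name>"}. An empty region yields NA
#' values for its features together with a warning naming the lesion; the
#' lesion is reported, not dropped.
#'
#' @param lesion a preprocessed \linkS4class{LesionSample} (isotropic,
#'   normalized, margins present).
#' @param binWidth gray-level quantization bin width (default 25).
#' @return Named numeric vector (672 features under the default
#'   configuration).
#' @export
extractLesionFeatures <- function(lesion, binWidth = 25) {
  stopifnot(is(lesion, "LesionSample"))
  out <- numeric(0)

  intensityBlock <- function(img, msk, prefix) {
    if (!any(msk@values)) {
      warning(sprintf("lesion %s: empty region for '%s'; features set to NA",
                      lesion@lesionId, prefix))
      nms <- c(paste0(prefix, "|firstorder|", .FIRSTORDER_NAMES),
               unlist(lapply(.TEXTURE_FAMILIES, function(f)
                 paste0(prefix, "|", f, "|", .textureFeatureNames(f)))))
      return(setNames(rep(NA_real_, length(nms)), nms))
    }
    fo <- firstOrderFeatures(img, msk, binWidth = binWidth)
    names(fo) <- paste0(prefix, "|firstorder|", names(fo))
    q <- quantizeROI(img, msk, binWidth = binWidth)
    tex <- unlist(lapply(.TEXTURE_FAMILIES, function(f) {
      v <- textureFeatures(textureMatrix(q, f))
      names(v) <- paste0(prefix, "|", f, "|", names(v))
      v
    }))
    c(fo, tex)
  }

  for (mod in c("T1", "FLAIR")) {
    img <- lesion@images[[mod]]
    for (reg in .REGIONS) {
      msk <- lesion@masks[[mod]][[reg]]
      if (is.null(msk))
        stop(sprintf("lesion %s: missing region '%s' on %s grid (preprocess first)",
                     lesion@lesionId, reg, mod))
      out <- c(out, intensityBlock(img, msk, paste0(mod, "|", reg)))
    }
  }

  ## morphology: tumour-family regions from the T1 grid, edema-family
  ## regions from the FLAIR grid
  shapeSrc <- c("tumour" = "T1", "tumour-margin" = "T1",
                "edema" = "FLAIR", "lesion-margin" = "FLAIR")
  for (reg in .REGIONS) {
    mod <- shapeSrc[[reg]]
    msk <- lesion@masks[[mod]][[reg]]
    if (!any(msk@values)) {
      warning(sprintf("lesion %s: empty region for shape '%s'; features set to NA",
                      lesion@lesionId, reg))
      sh <- setNames(rep(NA_real_, length(.SHAPE_NAMES)), .SHAPE_NAMES)
    } else {
      sh <- shapeFeatures(msk)
    }
    names(sh) <- paste0(mod, "|", reg, "|shape|", names(sh))
    out <- c(out, sh)
  }
  out
}

.textureFeatureNames <- function(family) {
  ## stable name lists, used when a region is empty
  counts <- if (family == "NGTDM") matrix(c(1, 0), 1, 2) else matrix(1, 1, 1)
  dummy <- new("TextureMatrix", family = family, counts = counts,
               nLevels = 1L, normalizer = 1)
  names(textureFeatures(dummy))
}

#' Extract a FeatureTable for a whole cohort
#'
#' Preprocesses and extracts every lesion, returning a
#' \linkS4class{FeatureTable} with one row per lesion.
#'
#' @param cohort list of \linkS4class{LesionSample}.
#' @param targetSpacing,marginDistance,intensityScale,binWidth see
#'   \code{\link{preprocessLesion}} and \code{\link{extractLesionFeatures}}.
#' @param preprocessed set TRUE if the lesions are already preprocessed.
#' @return A \linkS4class{FeatureTable}.
#' @export
extractCohortFeatures <- function(cohort, targetSpacing = 0.5,
                                  marginDistance = 5, intensityScale = 100,
                                  binWidth = 25, preprocessed = FALSE) {
  stopifnot(length(cohort) > 0)
  rows <- lapply(cohort, function(ls) {
    if (!preprocessed)
      ls <- preprocessLesion(ls, targetSpacing = targetSpacing,
                             marginDistance = marginDistance,
                             intensityScale = intensityScale)
    extractLesionFeatures(ls, binWidth = binWidth)
  })
  ids <- names(rows[[1]])
  mat <- do.call(rbind, lapply(rows, function(r) r[ids]))
  colnames(mat) <- ids
  info <- data.frame(
    patient_id = vapply(cohort, function(x) x@patientId, character(1)),
    lesion_id = vapply(cohort, function(x) x@lesionId, character(1)),
    outcome = vapply(cohort, function(x) x@outcome, character(1)),
    stringsAsFactors = FALSE)
  FeatureTable(mat, info)
}

#' Write / read a FeatureTable as CSV with a provenance header
#'
#' The CSV carries comment lines (\code{#}) recording the feature count
#' and a hash of the feature-id header, so identical configurations give
#' byte-identical headers.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param path output CSV path.
#' @return \code{writeFeatureTable} returns \code{path} invisibly;
#'   \code{readFeatureTable} returns a \linkS4class{FeatureTable}.
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(is(table, "FeatureTable"))
  df <- cbind(table@lesionData[c("patient_id", "lesion_id", "outcome")],
              as.data.frame(table@values, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  idhash <- .stableHash(paste(colnames(table@values), collapse = ","))
  writeLines(sprintf("# n_features: %d", ncol(table@values)), con)
  writeLines(sprintf("# header_hash: %s", idhash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @param path CSV path written by \code{writeFeatureTable}.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  meta <- df[c("patient_id", "lesion_id", "outcome")]
  vals <- as.matrix(df[setdiff(names(df), names(meta))])
  FeatureTable(vals, meta)
}

## deterministic 31-bit polynomial content hash, hex-encoded
.stableHash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
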
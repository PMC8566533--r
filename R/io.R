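## Cohort persistence: per-lesion NIfTI volumes and masks plus a
## manifest.csv tying them to outcomes, survival and clinical fields.
## Grid origins are carried in the manifest (one row per lesion) so the
## full grid metadata round-trips.

#' Write a cohort to NIfTI volumes and a manifest
#'
#' Writes \code{<lesion>_T1.nii.gz}, \code{<lesion>_FLAIR.nii.gz} and the
#' mask volumes \code{<lesion>_<grid>_<region>.nii.gz} for each lesion,
#' plus \code{manifest.csv} with patient id, lesion id, outcome, survival,
#' the eight clinical fields, file paths and grid origins.
#'
#' @param cohort result of \code{\link{generateCohort}} (or a compatible
#'   list with \code{lesions} and \code{manifest}).
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  exdf <- list()
  for (i in seq_along(cohort$lesions)) {
    ls <- cohort$lesions[[i]]
    paths <- list()
    for (mod in c("T1", "FLAIR")) {
      img <- ls@images[[mod]]
      base <- sprintf("%s_%s", ls@lesionId, mod)
      p <- file.path(dir, paste0(base, ".nii.gz"))
      .writeNifti(img@values, img@spacing, p)
      paths[[paste0("path_", tolower(mod))]] <- basename(p)
      for (reg in names(ls@masks[[mod]])) {
        mp <- file.path(dir, sprintf("%s_%s.nii.gz", base, reg))
        .writeNifti(ls@masks[[mod]][[reg]]@values * 1L,
                    ls@masks[[mod]][[reg]]@spacing, mp)
      }
      o <- img@origin
      paths[[paste0("origin_", tolower(mod))]] <-
        paste(format(o, digits = 12), collapse = ";")
    }
    exdf[[i]] <- as.data.frame(paths, stringsAsFactors = FALSE)
  }
  if (length(exdf))
    manifest <- cbind(manifest, do.call(rbind, exdf))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

.writeNifti <- function(values, spacing, path) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
}

#' Read a cohort manifest (and optionally its volumes)
#'
#' @param path path to \code{manifest.csv} (or its directory).
#' @param withImages if TRUE, read the NIfTI volumes and return full
#'   \linkS4class{LesionSample} objects; otherwise return the manifest
#'   data.frame only.
#' @return A list with \code{manifest} and (if requested) \code{lesions}.
#' @export
readCohort <- function(path, withImages = TRUE) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(manifest$outcome %in% c("LC", "LF")))
    stop("manifest outcomes must be 'LC' or 'LF'")
  if (!withImages) return(list(manifest = manifest))
  dir <- dirname(path)
  lesions <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    images <- list()
    masks <- list()
    for (mod in c("T1", "FLAIR")) {
      base <- file.path(dir, sprintf("%s_%s", row$lesion_id, mod))
      ip <- paste0(base, ".nii.gz")
      if (!file.exists(ip)) stop("missing image file: ", ip)
      nim <- RNifti::readNifti(ip)
      spacing <- RNifti::pixdim(nim)
      origin <- as.numeric(strsplit(
        row[[paste0("origin_", tolower(mod))]], ";")[[1]])
      modality <- if (mod == "T1") "CE-T1w" else "T2-FLAIR"
      images[[mod]] <- VolumetricImage(array(as.numeric(nim), dim(nim)),
                                       spacing, origin, modality)
      mk <- list()
      for (reg in c("tumour", "edema", "brain")) {
        mpth <- paste0(base, "_", reg, ".nii.gz")
        if (!file.exists(mpth)) stop("missing mask file: ", mpth)
        mm <- RNifti::readNifti(mpth)
        mk[[reg]] <- RegionMask(array(as.numeric(mm), dim(mm)) != 0,
                                spacing, origin, kind = reg)
      }
      masks[[mod]] <- mk
    }
    new("LesionSample", patientId = as.character(row$patient_id),
        lesionId = as.character(row$lesion_id),
        images = images, masks = masks, outcome = row$outcome,
        clinical = as.list(row[c("histology", "total_dose", "n_brain_mets",
                                 "location", "max_diameter", "prev_wbrt",
                                 "prev_srs_srt", "targeted_systemic")]),
        survivalTime = row$survival_time,
        survivalEvent = as.logical(row$survival_event))
  })
  list(manifest = manifest, lesions = lesions)
}
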
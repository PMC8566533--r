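## Pre-processing: isotropic resampling, within-brain intensity
## normalization, morphological margin masks and fixed-bin-width gray-level
## quantization. Voxel centres are at origin + (index - 1) * spacing.

#' Resample an image (and its masks) to an isotropic grid
#'
#' The output grid is anchored at the input origin and has
#' \code{ceil(n_in * spacing_in / target)} voxels per axis, so no tissue is
#' cropped. The image is interpolated trilinearly; masks follow by
#' nearest-neighbour so they stay strictly binary.
#'
#' @param image a \linkS4class{VolumetricImage}.
#' @param masks a named list of \linkS4class{RegionMask} on the same grid
#'   (may be empty).
#' @param target isotropic voxel size in mm (default 0.5).
#' @return A list with elements \code{image} and \code{masks}.
#' @export
resampleToIsotropic <- function(image, masks = list(), target = 0.5) {
  stopifnot(is(image, "VolumetricImage"), target > 0)
  dIn <- dim(image@values)
  if (any(dIn == 0)) stop("empty image")
  sIn <- image@spacing
  dOut <- as.integer(ceiling(dIn * sIn / target))

  ## fractional 0-based input coordinates of each output voxel centre
  ux <- (seq_len(dOut[1]) - 1) * target / sIn[1]
  uy <- (seq_len(dOut[2]) - 1) * target / sIn[2]
  uz <- (seq_len(dOut[3]) - 1) * target / sIn[3]

  outImg <- .trilinear(image@values, ux, uy, uz)
  img <- VolumetricImage(outImg, spacing = rep(target, 3),
                         origin = image@origin, modality = image@modality)

  ix <- pmin(pmax(round(ux) + 1, 1), dIn[1])
  iy <- pmin(pmax(round(uy) + 1, 1), dIn[2])
  iz <- pmin(pmax(round(uz) + 1, 1), dIn[3])
  outMasks <- lapply(masks, function(m) {
    stopifnot(identical(dim(m@values), dIn))
    RegionMask(m@values[ix, iy, iz, drop = FALSE],
               spacing = rep(target, 3), origin = m@origin, kind = m@kind)
  })
  list(image = img, masks = outMasks)
}

## Trilinear interpolation of a 3D array at the grid outer(ux, uy, uz) of
## 0-based fractional input coordinates, with clamping at the borders.
## Works slab-by-slab along z to bound memory.
.trilinear <- function(a, ux, uy, uz) {
  d <- dim(a)
  x0 <- pmin(pmax(floor(ux), 0), d[1] - 1)
  y0 <- pmin(pmax(floor(uy), 0), d[2] - 1)
  x1 <- pmin(x0 + 1, d[1] - 1)
  y1 <- pmin(y0 + 1, d[2] - 1)
  fx <- pmin(pmax(ux - x0, 0), 1)
  fy <- pmin(pmax(uy - y0, 0), 1)
  out <- array(0, dim = c(length(ux), length(uy), length(uz)))
  ## 2D bilinear weights are shared across slabs
  WX0 <- matrix(1 - fx, length(ux), length(uy))
  WY0 <- matrix(1 - fy, length(ux), length(uy), byrow = TRUE)
  WX1 <- 1 - WX0
  WY1 <- 1 - WY0
  i00 <- cbind(rep(x0 + 1, length(uy)), rep(y0 + 1, each = length(ux)))
  i10 <- cbind(rep(x1 + 1, length(uy)), rep(y0 + 1, each = length(ux)))
  i01 <- cbind(rep(x0 + 1, length(uy)), rep(y1 + 1, each = length(ux)))
  i11 <- cbind(rep(x1 + 1, length(uy)), rep(y1 + 1, each = length(ux)))
  for (kz in seq_along(uz)) {
    z0 <- min(max(floor(uz[kz]), 0), d[3] - 1)
    z1 <- min(z0 + 1, d[3] - 1)
    fz <- min(max(uz[kz] - z0, 0), 1)
    s0 <- a[, , z0 + 1]
    s1 <- a[, , z1 + 1]
    bil <- function(s) {
      v00 <- matrix(s[i00], length(ux), length(uy))
      v10 <- matrix(s[i10], length(ux), length(uy))
      v01 <- matrix(s[i01], length(ux), length(uy))
      v11 <- matrix(s[i11], length(ux), length(uy))
      v00 * WX0 * WY0 + v10 * WX1 * WY0 + v01 * WX0 * WY1 + v11 * WX1 * WY1
    }
    out[, , kz] <- (1 - fz) * bil(s0) + fz * bil(s1)
  }
  out
}

#' Normalize image intensities within the brain
#'
#' Centres and scales the whole image by the mean and population standard
#' deviation of the in-brain voxels, so the brain-masked intensities have
#' zero mean and unit variance; the result is then multiplied by
#' \code{scale}. The default scale of 100 pairs unit-variance
#' normalization with the fixed gray-level bin width of 25 so that typical
#' regions of interest span a non-degenerate number of gray levels.
#'
#' @param image a \linkS4class{VolumetricImage}.
#' @param brain a \linkS4class{RegionMask} of kind \code{"brain"}.
#' @param scale intensity scale factor applied after normalization.
#' @return A \linkS4class{VolumetricImage}.
#' @export
normalizeWithinBrain <- function(image, brain, scale = 100) {
  stopifnot(is(image, "VolumetricImage"), is(brain, "RegionMask"))
  v <- image@values[brain@values]
  if (length(v) < 2) stop("brain mask must contain at least 2 voxels")
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2)) # population sd
  if (sdv == 0) stop("zero intensity variance within brain: degenerate image")
  out <- (image@values - mu) / sdv * scale
  VolumetricImage(out, spacing = image@spacing, origin = image@origin,
                  modality = image@modality)
}

#' Build a margin mask around a region
#'
#' The margin is the shell of voxels outside \code{region} whose centre
#' lies within \code{distance} mm (Euclidean) of the region, clipped to the
#' brain. From a tumour mask the result has kind \code{"tumour-margin"};
#' from the tumour-plus-edema lesion it has kind \code{"lesion-margin"}.
#'
#' @param region a \linkS4class{RegionMask} (tumour, or tumour union edema).
#' @param brain the brain \linkS4class{RegionMask} on the same grid.
#' @param distance expansion distance in mm (default 5).
#' @param kind output kind; defaults to \code{"tumour-margin"} when
#'   \code{region@kind == "tumour"}, else \code{"lesion-margin"}.
#' @return A \linkS4class{RegionMask}; may be empty if \code{distance} is
#'   smaller than the voxel pitch.
#' @export
buildMarginMask <- function(region, brain, distance = 5, kind = NULL) {
  stopifnot(is(region, "RegionMask"), is(brain, "RegionMask"), distance > 0)
  sp <- region@spacing
  if (max(sp) - min(sp) > 1e-9)
    stop("margin masks require an isotropic grid; resample first")
  if (!identical(dim(region@values), dim(brain@values)))
    stop("region and brain grids differ")
  if (is.null(kind))
    kind <- if (region@kind == "tumour") "tumour-margin" else "lesion-margin"
  d2 <- cpp_edt_sq(as.logical(region@values), dim(region@values), sp)
  sel <- d2 <= distance^2 + 1e-9
  dim(sel) <- dim(region@values)
  out <- sel & !region@values & brain@values
  RegionMask(out, spacing = sp, origin = region@origin, kind = kind)
}

#' Quantize region-of-interest intensities with a fixed bin width
#'
#' Bin edges are anchored at integer multiples of \code{binWidth} (equally
#' spaced from zero); the level of a voxel with intensity x is
#' \code{floor(x / binWidth) - floor(min / binWidth) + 1} where min is the
#' minimum in-mask intensity, so level 1 is the bin holding the ROI
#' minimum and Ng the bin holding its maximum.
#'
#' @param image a \linkS4class{VolumetricImage}.
#' @param mask a non-empty \linkS4class{RegionMask} on the image grid.
#' @param binWidth bin width in intensity units (default 25).
#' @return A \linkS4class{QuantizedROI}.
#' @export
quantizeROI <- function(image, mask, binWidth = 25) {
  stopifnot(is(image, "VolumetricImage"), is(mask, "RegionMask"),
            binWidth > 0)
  sel <- mask@values
  if (!any(sel)) stop("empty mask")
  lev <- array(0L, dim = dim(image@values))
  x <- image@values[sel]
  base <- floor(min(x) / binWidth)
  lev[sel] <- as.integer(floor(x / binWidth) - base + 1)
  new("QuantizedROI", levels = lev, nLevels = max(lev),
      binWidth = as.numeric(binWidth), spacing = image@spacing)
}
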
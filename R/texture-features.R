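## Texture matrices (GLCM / GLDM / GLSZM / NGTDM) and their feature sets,
## following the community-standard (IBSI-consistent) definitions:
## GLCM at distance 1 over the 13 unique 3D directions, merged by symmetric
## accumulation before normalization; GLDM with dependence threshold
## alpha = 0 over the 26-neighbourhood; GLSZM zones as maximal 26-connected
## constant-level sets; NGTDM over the 26-neighbourhood.

.TEXTURE_FAMILIES <- c("GLCM", "GLDM", "GLSZM", "NGTDM")

#' TextureMatrix: counts underlying one texture family
#'
#' @slot family one of GLCM, GLDM, GLSZM, NGTDM.
#' @slot counts numeric matrix of counts: Ng x Ng (GLCM), Ng x 27 columns
#'   for dependence 0..26 (GLDM), Ng x Smax (GLSZM), or Ng x 2 with
#'   columns (n_i, s_i) (NGTDM).
#' @slot nLevels number of gray levels Ng.
#' @slot normalizer total count Nz (pairs / voxels / zones / valid voxels).
#'
#' @aliases TextureMatrix-class
#' @exportClass TextureMatrix
setClass("TextureMatrix",
  representation(family = "character", counts = "matrix",
                 nLevels = "integer", normalizer = "numeric"))

setValidity("TextureMatrix", function(object) {
  msg <- character()
  if (!object@family %in% .TEXTURE_FAMILIES)
    msg <- c(msg, "unknown texture family")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TextureMatrix", function(object) {
  cat(sprintf("TextureMatrix [%s]: Ng = %d, Nz = %g\n",
              object@family, object@nLevels, object@normalizer))
})

#' Compute a texture matrix from a quantized ROI
#'
#' @param qroi a \linkS4class{QuantizedROI}.
#' @param family \code{"GLCM"}, \code{"GLDM"}, \code{"GLSZM"} or
#'   \code{"NGTDM"}.
#' @param alpha GLDM dependence threshold on the absolute level difference
#'   (default 0, i.e. equal levels only).
#' @return A \linkS4class{TextureMatrix}.
#' @export
textureMatrix <- function(qroi, family = c("GLCM", "GLDM", "GLSZM", "NGTDM"),
                          alpha = 0L) {
  stopifnot(is(qroi, "QuantizedROI"))
  family <- match.arg(family)
  ng <- qroi@nLevels
  if (ng < 1L) stop("Ng must be >= 1")
  lev <- qroi@levels
  counts <- switch(family,
    GLCM  = cpp_glcm(as.integer(lev), dim(lev), ng),
    GLDM  = cpp_gldm(as.integer(lev), dim(lev), ng, as.integer(alpha)),
    GLSZM = cpp_glszm(as.integer(lev), dim(lev), ng),
    NGTDM = cpp_ngtdm(as.integer(lev), dim(lev), ng))
  nz <- switch(family,
    GLCM = sum(counts),
    GLDM = sum(counts),
    GLSZM = sum(counts),
    NGTDM = sum(counts[, 1]))
  new("TextureMatrix", family = family, counts = counts,
      nLevels = as.integer(ng), normalizer = nz)
}

#' Texture features of one texture matrix
#'
#' Returns the standard feature set of the matrix family: 24 GLCM, 14
#' GLDM, 16 GLSZM or 5 NGTDM features. Gray-level weights use the level
#' index i in [1, Ng]; the GLDM dependence weight is d + 1 (the dependent
#' neighbour count including the centre voxel) so small-dependence
#' emphases are defined at d = 0.
#'
#' @param tm a \linkS4class{TextureMatrix}.
#' @return Named numeric vector.
#' @export
textureFeatures <- function(tm) {
  stopifnot(is(tm, "TextureMatrix"))
  if (tm@normalizer <= 0) stop("zero normalizer")
  switch(tm@family,
    GLCM  = .glcmFeatures(tm),
    GLDM  = .gldmFeatures(tm),
    GLSZM = .glszmFeatures(tm),
    NGTDM = .ngtdmFeatures(tm))
}

.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.glcmFeatures <- function(tm) {
  ng <- tm@nLevels
  p <- tm@counts / tm@normalizer
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p) # equals px by symmetry
  mux <- sum(px * seq_len(ng))
  muy <- sum(py * seq_len(ng))
  sdx <- sqrt(sum(px * (seq_len(ng) - mux)^2))
  sdy <- sqrt(sum(py * (seq_len(ng) - muy)^2))

  ## diagonal (difference) and cross-diagonal (sum) distributions
  k_d <- 0:(ng - 1)
  pd <- vapply(k_d, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_s <- 2:(2 * ng)
  ps <- vapply(k_s, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(k_d * pd)

  hxy <- .entropy2(p)
  pxpy <- outer(px, py)
  hxy1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- .entropy2(pxpy)
  hx <- .entropy2(px)
  hy <- .entropy2(py)
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))

  corr <- if (sdx > 0 && sdy > 0)
    (sum(p * i * j) - mux * muy) / (sdx * sdy) else 1

  mcc <- 1
  if (ng > 1 && all(px > 0)) {
    q <- matrix(0, ng, ng)
    for (a in seq_len(ng))
      q[a, ] <- colSums(t(p) * p[a, ] / (px[a] * py))
    lam <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(min(lam[2], 1), 0))
  } else if (ng > 1) {
    ## drop empty gray levels before forming Q
    keep <- px > 0
    if (sum(keep) > 1) {
      pk <- p[keep, keep, drop = FALSE]
      pk <- pk / sum(pk)
      pxk <- rowSums(pk)
      q <- matrix(0, nrow(pk), nrow(pk))
      for (a in seq_len(nrow(pk)))
        q[a, ] <- colSums(t(pk) * pk[a, ] / (pxk[a] * pxk))
      lam <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
      mcc <- sqrt(max(min(lam[2], 1), 0))
    }
  }

  offd <- abs(i - j) > 0
  c(Autocorrelation = sum(p * i * j),
    JointAverage = mux,
    ClusterProminence = sum(p * (i + j - mux - muy)^4),
    ClusterShade = sum(p * (i + j - mux - muy)^3),
    ClusterTendency = sum(p * (i + j - mux - muy)^2),
    Contrast = sum(p * (i - j)^2),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = .entropy2(pd),
    DifferenceVariance = sum(pd * (k_d - da)^2),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[offd] / (i - j)[offd]^2),
    MaximumProbability = max(p),
    SumAverage = sum(k_s * ps),
    SumEntropy = .entropy2(ps),
    SumSquares = sum(p * (i - mux)^2),
    MCC = mcc)
}

.gldmFeatures <- function(tm) {
  ng <- tm@nLevels
  nz <- tm@normalizer
  P <- tm@counts
  nd <- ncol(P)
  p <- P / nz
  i <- matrix(seq_len(ng), ng, nd)
  j <- matrix(seq_len(nd), ng, nd, byrow = TRUE) # dependence d + 1
  mui <- sum(p * i)
  muj <- sum(p * j)
  c(SmallDependenceEmphasis = sum(p / j^2),
    LargeDependenceEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mui)^2),
    DependenceVariance = sum(p * (j - muj)^2),
    DependenceEntropy = .entropy2(p),
    LowGrayLevelEmphasis = sum(p / i^2),
    HighGrayLevelEmphasis = sum(p * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * j^2))
}

.glszmFeatures <- function(tm) {
  ng <- tm@nLevels
  nz <- tm@normalizer
  P <- tm@counts
  ns <- ncol(P)
  p <- P / nz
  i <- matrix(seq_len(ng), ng, ns)
  j <- matrix(seq_len(ns), ng, ns, byrow = TRUE) # zone size
  np <- sum(P * j)                               # voxels covered by zones
  mui <- sum(p * i)
  muj <- sum(p * j)
  c(SmallAreaEmphasis = sum(p / j^2),
    LargeAreaEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nz^2,
    SizeZoneNonUniformity = sum(colSums(P)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(p * (i - mui)^2),
    ZoneVariance = sum(p * (j - muj)^2),
    ZoneEntropy = .entropy2(p),
    LowGrayLevelZoneEmphasis = sum(p / i^2),
    HighGrayLevelZoneEmphasis = sum(p * i^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallAreaHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeAreaLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = sum(p * i^2 * j^2))
}

.ngtdmFeatures <- function(tm) {
  ng <- tm@nLevels
  n_i <- tm@counts[, 1]
  s_i <- tm@counts[, 2]
  nvp <- tm@normalizer
  p_i <- n_i / nvp
  lv <- seq_len(ng)
  act <- p_i > 0
  ngp <- sum(act)

  coarse <- sum(p_i * s_i)
  coarseness <- if (coarse > 0) 1 / coarse else 1e6

  contrast <- 0
  if (ngp > 1) {
    dd <- outer(lv[act], lv[act], "-")^2
    pp <- outer(p_i[act], p_i[act])
    contrast <- sum(pp * dd) / (ngp * (ngp - 1)) * sum(s_i) / nvp
  }

  busy_den <- 0
  complexity <- 0
  strength_num <- 0
  if (ngp >= 1) {
    ia <- lv[act]; pa <- p_i[act]; sa <- s_i[act]
    ipa <- ia * pa
    busy_den <- sum(abs(outer(ipa, ipa, "-"))) # all ordered pairs
    dif <- abs(outer(ia, ia, "-"))
    sumterm <- outer(pa * sa, pa * sa, "+")
    psum <- outer(pa, pa, "+")
    complexity <- sum(dif * sumterm / psum) / nvp
    strength_num <- sum(outer(pa, pa, "+") * outer(ia, ia, "-")^2)
  }
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0

  c(Coarseness = coarseness,
    Contrast = contrast,
    Busyness = busyness,
    Complexity = complexity,
    Strength = strength)
}
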
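## Shared fixtures and independent brute-force oracles used across the
## suite. The oracles deliberately re-derive each quantity by direct
## enumeration, independently of the package's compiled implementations.

## the 26 neighbour offsets in 3D
nb26 <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off[rowSums(off == 0) < 3, , drop = FALSE]
}

## brute-force GLCM: every ordered voxel pair at Chebyshev distance 1
bfGLCM <- function(lev, ng) {
  d <- dim(lev)
  off <- nb26()
  P <- matrix(0, ng, ng)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (a < 1) next
    for (o in seq_len(nrow(off))) {
      ii <- i + off[o, 1]; jj <- j + off[o, 2]; kk <- k + off[o, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      b <- lev[ii, jj, kk]
      if (b >= 1) P[a, b] <- P[a, b] + 1
    }
  }
  P
}

## brute-force GLDM: dependence = similar 26-neighbours, alpha threshold
bfGLDM <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  off <- nb26()
  P <- matrix(0, ng, 27)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (a < 1) next
    dep <- 0
    for (o in seq_len(nrow(off))) {
      ii <- i + off[o, 1]; jj <- j + off[o, 2]; kk <- k + off[o, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      b <- lev[ii, jj, kk]
      if (b >= 1 && abs(a - b) <= alpha) dep <- dep + 1
    }
    P[a, dep + 1] <- P[a, dep + 1] + 1
  }
  P
}

## brute-force GLSZM: flood-fill 26-connected equal-level zones
bfGLSZM <- function(lev, ng) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  off <- nb26()
  zones <- list()
  for (s in which(lev > 0)) {
    if (seen[s]) next
    g <- lev[s]
    stack <- list(arrayInd(s, d))
    seen[s] <- TRUE
    size <- 0
    while (length(stack)) {
      c0 <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (o in seq_len(nrow(off))) {
        cc <- c0 + off[o, ]
        if (any(cc < 1) || any(cc > d)) next
        li <- cc[1] + d[1] * ((cc[2] - 1) + d[2] * (cc[3] - 1))
        if (!seen[li] && lev[li] == g) {
          seen[li] <- TRUE
          stack[[length(stack) + 1]] <- cc
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  zz <- do.call(rbind, zones)
  P <- matrix(0, ng, max(zz[, 2]))
  for (r in seq_len(nrow(zz))) P[zz[r, 1], zz[r, 2]] <- P[zz[r, 1], zz[r, 2]] + 1
  P
}

## brute-force NGTDM: per level, count and summed neighbourhood deviation
bfNGTDM <- function(lev, ng) {
  d <- dim(lev)
  off <- nb26()
  P <- matrix(0, ng, 2)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (a < 1) next
    vals <- integer(0)
    for (o in seq_len(nrow(off))) {
      ii <- i + off[o, 1]; jj <- j + off[o, 2]; kk <- k + off[o, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      b <- lev[ii, jj, kk]
      if (b >= 1) vals <- c(vals, b)
    }
    if (!length(vals)) next
    P[a, 1] <- P[a, 1] + 1
    P[a, 2] <- P[a, 2] + abs(a - mean(vals))
  }
  P
}

## exhaustive Mann-Whitney AUC (pair counting, ties at 1/2)
bfAUC <- function(x, y) {
  pos <- x[y == 1]
  neg <- x[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

## wrap an integer level array as a QuantizedROI
asQROI <- function(lev, spacing = c(1, 1, 1), binWidth = 25) {
  new("QuantizedROI", levels = array(as.integer(lev), dim(lev)),
      nLevels = as.integer(max(lev)), binWidth = binWidth,
      spacing = spacing)
}

## digitized solid ellipsoid mask (voxel centres inside)
ellipsoidMask <- function(semi, spacing = c(1, 1, 1), pad = 2) {
  nd <- ceiling(semi / spacing) + pad
  ax <- lapply(1:3, function(d) (-nd[d]:nd[d]) * spacing[d])
  arr <- array(FALSE, sapply(ax, length))
  for (k in seq_along(ax[[3]])) {
    z2 <- (ax[[3]][k] / semi[3])^2
    sl <- outer(ax[[1]], ax[[2]], function(x, y)
      (x / semi[1])^2 + (y / semi[2])^2 + z2) <= 1
    arr[, , k] <- sl
  }
  RegionMask(arr, spacing = spacing)
}

## constant-value image on a given grid
constImage <- function(dims, value = 0, spacing = c(1, 1, 1)) {
  VolumetricImage(array(value, dims), spacing = spacing)
}

## small preprocessed synthetic lesion shared by extraction tests
smallLesion <- function(seed = 11, target = 1.0) {
  p <- syntheticParams(n_patients = 1, lesion_count_mixture = c(1, 0, 0),
                       diameter_range_cm = c(1.0, 1.4), seed = seed)
  co <- generateCohort(p)
  preprocessLesion(co$lesions[[1]], targetSpacing = target)
}
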
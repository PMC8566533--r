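## Synthetic MRI cohort generator. Each lesion is an ellipsoidal tumour
## plus an edema shell placed inside a fixed ellipsoidal brain phantom
## (~120 x 150 x 100 mm, no skull); region interiors are filled with
## stationary correlated random fields (Gaussian white noise smoothed with
## an isotropic Gaussian kernel, rescaled to a class-dependent mean and
## sd), rendered on the native anisotropic grids of the two modalities.
## Class effects are planted through the texture fields (correlation
## length and mean shift) and through the tumour axis-ratio distribution.
## Per-lesion volumes are rendered on a subvolume around the lesion (the
## brain mask is the phantom clipped to that subvolume); whole-head
## rendering adds nothing the downstream feature analysis uses.

.HISTOLOGIES <- c("lung", "breast", "melanoma", "colorectal", "RCC", "other")
.HISTOLOGY_P <- c(86, 41, 15, 9, 9, 11) / 171
.DOSE_LEVELS <- c(22.5, 25, 27.5, 30, 32.5, 35)
.DOSE_P <- c(1, 29, 8, 104, 13, 16) / 171

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the target study population: 120 patients of whom
#' about 68 percent carry a single treated lesion (the mixture is
#' calibrated so 120 patients yield about 171 treated lesions and 100
#' about 141), a lesion-level
#' local-failure prevalence of 0.37 (63/171), CE-T1w voxels of
#' 0.5 x 0.5 x 1.5 mm and T2-FLAIR voxels of 0.5 x 0.5 x 5 mm, and
#' exponential survival with medians 26.2 (LC) / 13.5 (LF) months.
#'
#' @param n_patients number of patients.
#' @param lesion_count_mixture probabilities of 1 / 2 / >=3 treated
#'   lesions per patient (sums to 1).
#' @param lf_prevalence probability that a lesion has an LF outcome.
#' @param texture_effect list with elements \code{tumour} and \code{edema},
#'   each a list of per-class (\code{LC}, \code{LF}) lists with
#'   \code{corr_mm} (correlation length, mm), \code{mean} and \code{sd}
#'   (raw intensity); the per-class sd is what separates the classes in
#'   gray-level texture, since texture quantization is anchored at the
#'   region minimum and is therefore insensitive to pure mean shifts.
#' @param elongation_effect per-class ranges of the tumour second-to-first
#'   axis ratio.
#' @param noise_sd additive white-noise standard deviation.
#' @param spacing_t1,spacing_flair mm triples for the two native grids.
#' @param survival_median_lc,survival_median_lf months.
#' @param censor_rate probability a patient's survival time is censored.
#' @param diameter_range_cm range of tumour maximum diameters (cm).
#' @param wbrt_lf_logodds log-odds bump linking previous WBRT to LF, so
#'   clinical-model code paths carry signal; centred so the marginal LF
#'   prevalence is preserved.
#' @param brain_semiaxes_mm semi-axes of the ellipsoidal brain phantom.
#' @param seed integer root seed.
#' @return A validated list of class \code{SyntheticParams}.
#' @export
syntheticParams <- function(
    n_patients = 120,
    lesion_count_mixture = c(0.68, 0.25, 0.07),
    lf_prevalence = 63 / 171,
    texture_effect = list(
      tumour = list(LC = list(corr_mm = 1.5, mean = 180, sd = 25),
                    LF = list(corr_mm = 3.0, mean = 230, sd = 45)),
      edema = list(LC = list(corr_mm = 2.0, mean = 140, sd = 25),
                   LF = list(corr_mm = 3.5, mean = 165, sd = 40))),
    elongation_effect = list(LC = c(0.65, 0.95), LF = c(0.45, 0.80)),
    noise_sd = 10,
    spacing_t1 = c(0.5, 0.5, 1.5),
    spacing_flair = c(0.5, 0.5, 5.0),
    survival_median_lc = 26.2,
    survival_median_lf = 13.5,
    censor_rate = 0.2,
    diameter_range_cm = c(0.8, 3.0),
    wbrt_lf_logodds = 0.8,
    brain_semiaxes_mm = c(60, 75, 50),
    seed = 1L) {
  p <- list(n_patients = n_patients,
            lesion_count_mixture = lesion_count_mixture,
            lf_prevalence = lf_prevalence, texture_effect = texture_effect,
            elongation_effect = elongation_effect, noise_sd = noise_sd,
            spacing_t1 = spacing_t1, spacing_flair = spacing_flair,
            survival_median_lc = survival_median_lc,
            survival_median_lf = survival_median_lf,
            censor_rate = censor_rate,
            diameter_range_cm = diameter_range_cm,
            wbrt_lf_logodds = wbrt_lf_logodds,
            brain_semiaxes_mm = brain_semiaxes_mm,
            seed = as.integer(seed))
  .validateSyntheticParams(p)
  class(p) <- "SyntheticParams"
  p
}

.validateSyntheticParams <- function(p) {
  if (p$n_patients < 0) stop("n_patients must be non-negative")
  m <- p$lesion_count_mixture
  if (length(m) != 3 || any(m < 0) || any(m > 1) || abs(sum(m) - 1) > 1e-8)
    stop("lesion_count_mixture must be 3 probabilities summing to 1")
  if (p$lf_prevalence < 0 || p$lf_prevalence > 1)
    stop("lf_prevalence must be in [0, 1]")
  if (any(p$spacing_t1 <= 0) || any(p$spacing_flair <= 0))
    stop("spacing triples must be strictly positive")
  if (p$survival_median_lc <= 0 || p$survival_median_lf <= 0)
    stop("survival medians must be strictly positive")
  if (p$censor_rate < 0 || p$censor_rate > 1)
    stop("censor_rate must be in [0, 1]")
  invisible(TRUE)
}

#' Draw a synthetic survival record
#'
#' Event times are exponential with the class median
#' (\code{rate = log(2) / median}); censoring is independent, uniform on
#' \code{[0, U]} with U solved so that the overall censoring probability
#' equals \code{censor_rate}. The recorded time is the minimum of the
#' event and censoring times.
#'
#' @param outcome \code{"LC"} or \code{"LF"} (the patient-level label).
#' @param params a \code{SyntheticParams} list.
#' @return A list with \code{time} (months) and \code{event} (logical).
#' @export
synthSurvival <- function(outcome, params) {
  stopifnot(outcome %in% c("LC", "LF"))
  med <- if (outcome == "LC") params$survival_median_lc else
    params$survival_median_lf
  rate <- log(2) / med
  t_event <- stats::rexp(1, rate)
  if (params$censor_rate <= 0)
    return(list(time = t_event, event = TRUE))
  U <- .censorHorizon(rate, params$censor_rate)
  t_cens <- stats::runif(1, 0, U)
  list(time = min(t_event, t_cens), event = t_event <= t_cens)
}

## solve (1 - exp(-rate * U)) / (rate * U) = censor_rate for U
.censorHorizon <- function(rate, censor_rate) {
  g <- function(U) (1 - exp(-rate * U)) / (rate * U) - censor_rate
  stats::uniroot(g, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Generate a synthetic cohort of lesion samples
#'
#' Draws per-patient lesion counts from the configured mixture, per-lesion
#' outcomes with the configured LF prevalence (optionally tilted by
#' previous WBRT), clinical covariates from the study's marginal
#' frequencies, patient-level survival, and renders per-lesion CE-T1w /
#' T2-FLAIR volumes with tumour / edema / brain masks on their native
#' anisotropic grids. Deterministic given \code{params$seed}; each lesion
#' is generated from a seed forked by (patient, lesion) index, so
#' per-lesion regeneration is stable.
#'
#' @param params a \code{SyntheticParams} list (see
#'   \code{\link{syntheticParams}}).
#' @return A list with \code{lesions} (list of
#'   \linkS4class{LesionSample}) and \code{manifest} (data.frame with
#'   patient id, lesion id, outcome, survival and clinical fields).
#' @export
generateCohort <- function(params) {
  .validateSyntheticParams(params)
  if (params$n_patients == 0)
    return(list(lesions = list(), manifest = .emptyManifest()))

  plan <- .withSeed(deriveSeed(params$seed, "cohort"), {
    .cohortPlan(params)
  })

  lesions <- vector("list", nrow(plan))
  for (r in seq_len(nrow(plan))) {
    row <- plan[r, ]
    lseed <- deriveSeed(params$seed, "lesion",
                        row$patient_index * 1000L + row$lesion_index)
    lesions[[r]] <- .withSeed(lseed, {
      .renderLesion(row, params)
    })
  }
  list(lesions = lesions, manifest = plan[, .MANIFEST_COLS])
}

.MANIFEST_COLS <- c("patient_id", "lesion_id", "outcome", "survival_time",
                    "survival_event", "histology", "total_dose",
                    "n_brain_mets", "location", "max_diameter", "prev_wbrt",
                    "prev_srs_srt", "targeted_systemic")

.emptyManifest <- function() {
  df <- as.data.frame(setNames(rep(list(character(0)), length(.MANIFEST_COLS)),
                               .MANIFEST_COLS))
  df
}

## all cohort-level draws (counts, outcomes, clinical, survival); one row
## per lesion
.cohortPlan <- function(params) {
  rows <- list()
  wbrt_marg <- 61 / 171
  for (p in seq_len(params$n_patients)) {
    bucket <- sample.int(3, 1, prob = params$lesion_count_mixture)
    nles <- if (bucket < 3) bucket else sample(3:4, 1, prob = c(0.7, 0.3))
    pid <- sprintf("P%03d", p)
    prow <- list()
    for (l in seq_len(nles)) {
      wbrt <- stats::runif(1) < wbrt_marg
      p_lf <- stats::plogis(stats::qlogis(params$lf_prevalence) +
                            params$wbrt_lf_logodds * (wbrt - wbrt_marg))
      outcome <- if (stats::runif(1) < p_lf) "LF" else "LC"
      elo <- params$elongation_effect[[outcome]]
      diam <- stats::runif(1, params$diameter_range_cm[1],
                           params$diameter_range_cm[2])
      prow[[l]] <- data.frame(
        patient_index = p, lesion_index = l,
        patient_id = pid, lesion_id = sprintf("%s_L%d", pid, l),
        outcome = outcome,
        histology = sample(.HISTOLOGIES, 1, prob = .HISTOLOGY_P),
        total_dose = sample(.DOSE_LEVELS, 1, prob = .DOSE_P),
        n_brain_mets = max(nles, sample.int(3, 1, prob = c(42, 41, 37) / 120)),
        location = sample(c("supratentorium", "infratentorium"), 1,
                          prob = c(128, 43) / 171),
        max_diameter = diam,
        prev_wbrt = wbrt,
        prev_srs_srt = stats::runif(1) < 1 / 171,
        targeted_systemic = stats::runif(1) < 54 / 171,
        axis_ratio2 = stats::runif(1, elo[1], elo[2]),
        stringsAsFactors = FALSE)
    }
    prow <- do.call(rbind, prow)
    ## patient-level survival: the max-risk lesion governs the class
    pclass <- if (any(prow$outcome == "LF")) "LF" else "LC"
    sv <- synthSurvival(pclass, params)
    prow$survival_time <- sv$time
    prow$survival_event <- sv$event
    rows[[p]] <- prow
  }
  do.call(rbind, rows)
}

## render one lesion's images and masks on both native grids
.renderLesion <- function(row, params) {
  a1 <- row$max_diameter * 10 / 2             # semi-major axis, mm
  r2 <- row$axis_ratio2
  r3 <- r2 * stats::runif(1, 0.8, 1.0)
  semi <- c(a1, a1 * r2, a1 * r3)
  edema_th <- stats::runif(1, 3, 8)           # edema shell thickness, mm
  rot <- .randomRotation()
  brain <- params$brain_semiaxes_mm
  halo <- max(semi) + edema_th + 9            # margin + padding
  ## lesion centre placed so lesion + margin stays inside the phantom
  room <- pmax(brain - halo, 1)
  centre <- stats::runif(3, -1, 1) * room * 0.8

  tex <- params$texture_effect
  cls <- row$outcome
  mkimg <- function(spacing, modality) {
    half <- rep(halo, 3)
    dims <- as.integer(ceiling(2 * half / spacing)) + 1L
    origin <- centre - (dims - 1) / 2 * spacing
    ax <- lapply(1:3, function(d) origin[d] + (seq_len(dims[d]) - 1) * spacing[d])
    ## world coordinates of every voxel centre
    X <- array(ax[[1]], dims)
    Y <- array(rep(ax[[2]], each = dims[1]), dims)
    Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
    ## lesion-frame coordinates
    dx <- X - centre[1]; dy <- Y - centre[2]; dz <- Z - centre[3]
    u <- rot[1, 1] * dx + rot[1, 2] * dy + rot[1, 3] * dz
    v <- rot[2, 1] * dx + rot[2, 2] * dy + rot[2, 3] * dz
    w <- rot[3, 1] * dx + rot[3, 2] * dy + rot[3, 3] * dz
    tum <- (u / semi[1])^2 + (v / semi[2])^2 + (w / semi[3])^2 <= 1
    es <- semi + edema_th
    les <- (u / es[1])^2 + (v / es[2])^2 + (w / es[3])^2 <= 1
    bra <- (X / brain[1])^2 + (Y / brain[2])^2 + (Z / brain[3])^2 <= 1
    tum <- tum & bra
    ede <- les & !tum & bra
    if (!any(tum)) { # tiny lesion on a coarse grid: keep the centre voxel
      ci <- pmin(pmax(round((centre - origin) / spacing) + 1, 1), dims)
      tum[ci[1], ci[2], ci[3]] <- TRUE
      bra[ci[1], ci[2], ci[3]] <- TRUE
    }

    bg <- .correlatedField(dims, spacing, corr_mm = 4, mean = 100, sd = 15)
    bg <- bg + 0.15 * (X + Y) # slow background drift
    img <- bg
    tfield <- .correlatedField(dims, spacing,
                               corr_mm = tex$tumour[[cls]]$corr_mm,
                               mean = tex$tumour[[cls]]$mean,
                               sd = tex$tumour[[cls]]$sd)
    efield <- .correlatedField(dims, spacing,
                               corr_mm = tex$edema[[cls]]$corr_mm,
                               mean = tex$edema[[cls]]$mean,
                               sd = tex$edema[[cls]]$sd)
    img[tum] <- tfield[tum]
    img[ede] <- efield[ede]
    img <- img + stats::rnorm(length(img), 0, params$noise_sd)
    img[!bra] <- 0
    list(image = VolumetricImage(img, spacing = spacing, origin = origin,
                                 modality = modality),
         masks = list(
           tumour = RegionMask(tum, spacing, origin, kind = "tumour"),
           edema = RegionMask(ede, spacing, origin, kind = "edema"),
           brain = RegionMask(bra, spacing, origin, kind = "brain")))
  }

  t1 <- mkimg(params$spacing_t1, "CE-T1w")
  fl <- mkimg(params$spacing_flair, "T2-FLAIR")
  new("LesionSample",
      patientId = row$patient_id, lesionId = row$lesion_id,
      images = list(T1 = t1$image, FLAIR = fl$image),
      masks = list(T1 = t1$masks, FLAIR = fl$masks),
      outcome = row$outcome,
      clinical = as.list(row[c("histology", "total_dose", "n_brain_mets",
                               "location", "max_diameter", "prev_wbrt",
                               "prev_srs_srt", "targeted_systemic")]),
      survivalTime = row$survival_time,
      survivalEvent = row$survival_event)
}

## stationary correlated field: white noise smoothed by a separable
## Gaussian kernel (sd = corr_mm per axis, in voxels), then standardized
## and rescaled to the target mean/sd
.correlatedField <- function(dims, spacing, corr_mm, mean, sd) {
  f <- array(stats::rnorm(prod(dims)), dims)
  for (d in 1:3) {
    sdv <- corr_mm / spacing[d]
    if (sdv < 0.2) next
    K <- .gaussConvMatrix(dims[d], sdv)
    f <- .applyAlongAxis(f, K, d)
  }
  mu <- mean(f)
  s <- stats::sd(as.vector(f))
  if (s == 0) s <- 1
  (f - mu) / s * sd + mean
}

.gaussConvMatrix <- function(n, sdv) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(a, b) exp(-((a - b)^2) / (2 * sdv^2)))
  K / rowSums(K)
}

.applyAlongAxis <- function(f, K, axis) {
  d <- dim(f)
  perm <- c(axis, setdiff(1:3, axis))
  g <- aperm(f, perm)
  m <- matrix(g, nrow = d[axis])
  m <- K %*% m
  g <- array(m, dim = d[perm])
  aperm(g, order(perm))
}

## uniform random rotation from the QR decomposition of a Gaussian matrix
.randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Synthetic feature table with planted discriminative features
#'
#' Generates a lesions-by-features table directly (no images): planted
#' features differ between classes by \code{separation} standardized
#' units; noise features are independent standard normals; optional
#' redundant features are affine copies of planted ones plus small noise
#' (to exercise correlation-based reduction). Lesion counts per patient
#' and outcomes follow the same mixture/prevalence rules as the image
#' generator.
#'
#' @param n_patients number of patients.
#' @param n_planted number of planted discriminative features.
#' @param n_noise number of noise features.
#' @param n_redundant number of redundant (correlated) copies of planted
#'   features.
#' @param separation standardized class separation of planted features.
#' @param lesion_count_mixture,lf_prevalence as in
#'   \code{\link{syntheticParams}}.
#' @param seed integer seed.
#' @return A \linkS4class{FeatureTable}.
#' @export
syntheticFeatureTable <- function(n_patients, n_planted = 2, n_noise = 60,
                                  n_redundant = 0, separation = 1.5,
                                  lesion_count_mixture = c(0.68, 0.25, 0.07),
                                  lf_prevalence = 63 / 171, seed = 1L) {
  .withSeed(deriveSeed(seed, "feature_table"), {
    rows <- list()
    for (p in seq_len(n_patients)) {
      bucket <- sample.int(3, 1, prob = lesion_count_mixture)
      nles <- if (bucket < 3) bucket else sample(3:4, 1, prob = c(0.7, 0.3))
      for (l in seq_len(nles)) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = sprintf("P%03d", p),
          lesion_id = sprintf("P%03d_L%d", p, l),
          outcome = if (stats::runif(1) < lf_prevalence) "LF" else "LC",
          stringsAsFactors = FALSE)
      }
    }
    info <- do.call(rbind, rows)
    n <- nrow(info)
    y <- as.numeric(info$outcome == "LF")
    planted <- matrix(stats::rnorm(n * n_planted), n, n_planted) +
      separation * y
    noise <- matrix(stats::rnorm(n * n_noise), n, n_noise)
    mat <- cbind(planted, noise)
    colnames(mat) <- c(sprintf("planted|f%d", seq_len(n_planted)),
                       sprintf("noise|f%03d", seq_len(n_noise)))
    if (n_redundant > 0) {
      src <- rep_len(seq_len(n_planted), n_redundant)
      red <- sapply(seq_len(n_redundant), function(i)
        2 * planted[, src[i]] + 1 + stats::rnorm(n, 0, 0.05))
      red <- matrix(red, n, n_redundant)
      colnames(red) <- sprintf("redundant|f%d", seq_len(n_redundant))
      mat <- cbind(mat, red)
    }
    FeatureTable(mat, info)
  })
}
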
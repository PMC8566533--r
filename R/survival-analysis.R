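## Patient-level survival comparison: cohort assignment by the any-LF
## rule, Kaplan-Meier product-limit curves and the two-sample log-rank
## test. Estimation is delegated to the survival package; this module
## fixes the cohort semantics and the reporting format.

#' Assign patients to LC/LF cohorts
#'
#' A patient with at least one LF lesion belongs to the LF cohort;
#' otherwise LC. Works on true labels or on predictions.
#'
#' @param patient_id character vector, one entry per lesion.
#' @param outcome per-lesion labels (\code{"LC"}/\code{"LF"}).
#' @return Named character vector, cohort per patient.
#' @export
assignPatientCohorts <- function(patient_id, outcome) {
  if (length(patient_id) == 0) stop("no lesions given")
  stopifnot(length(patient_id) == length(outcome))
  vapply(split(as.character(outcome), as.character(patient_id)),
         function(o) if (any(o == "LF")) "LF" else "LC", character(1))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator. The median is the smallest time with
#' S(t) <= 0.5 and is NA when the curve never reaches 0.5 (reported
#' explicitly, never extrapolated).
#'
#' @param time months (> 0).
#' @param event logical/0-1, TRUE if the event (death) was observed.
#' @return A list of class \code{KMCurve}: \code{time}, \code{surv},
#'   \code{n_risk}, \code{n_event}, \code{median}.
#' @export
kmCurve <- function(time, event) {
  if (length(time) == 0) stop("no records")
  if (any(time <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  med <- unname(summary(fit)$table["median"])
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 median = if (is.na(med)) NA_real_ else med),
            class = "KMCurve")
}

#' @export
print.KMCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, median %s months\n",
              length(x$time),
              ifelse(is.na(x$median), "not reached", sprintf("%.1f", x$median))))
  invisible(x)
}

#' Two-sample log-rank test
#'
#' Standard log-rank statistic (hypergeometric expectation/variance at
#' each distinct event time, ties handled together), chi-square with 1
#' degree of freedom.
#'
#' @param time months.
#' @param event logical/0-1 event indicators.
#' @param group two-level group labels (e.g. cohorts).
#' @return A list of class \code{LogRankResult}: \code{chi_square},
#'   \code{p_value}.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (sum(event) == 0) stop("no events in either group")
  sd <- survival::survdiff(
    survival::Surv(time, as.integer(event)) ~ group)
  chi <- unname(sd$chisq)
  structure(list(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE)),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("log-rank chi-square %.3f, p = %.4g\n", x$chi_square,
              x$p_value))
  invisible(x)
}

#' Patient-level survival comparison of predicted and labelled cohorts
#'
#' Assigns each patient to LC/LF by the any-LF rule twice -- once from
#' the model's predicted lesion outcomes and once from the ground-truth
#' labels -- and runs the Kaplan-Meier / log-rank comparison for both
#' assignments.
#'
#' @param lesionData data.frame with per-lesion \code{patient_id},
#'   \code{outcome} (true label), \code{predicted} (predicted label),
#'   \code{survival_time}, \code{survival_event} (patient-level values,
#'   repeated per lesion).
#' @return A list with elements \code{predicted} and \code{label}, each
#'   containing per-cohort \code{KMCurve}s and a \code{LogRankResult}.
#' @export
survivalComparison <- function(lesionData) {
  need <- c("patient_id", "outcome", "predicted", "survival_time",
            "survival_event")
  stopifnot(all(need %in% names(lesionData)))
  pat <- lesionData[!duplicated(lesionData$patient_id), ]
  one <- function(outcomes) {
    coh <- assignPatientCohorts(lesionData$patient_id, outcomes)
    coh <- coh[pat$patient_id]
    res <- list(cohorts = coh)
    for (g in c("LC", "LF")) {
      sel <- coh == g
      res[[paste0("km_", tolower(g))]] <- if (any(sel))
        kmCurve(pat$survival_time[sel], pat$survival_event[sel]) else NULL
    }
    if (length(unique(coh)) == 2)
      res$logrank <- logrankTest(pat$survival_time, pat$survival_event, coh)
    res
  }
  list(predicted = one(lesionData$predicted),
       label = one(lesionData$outcome))
}

#' Plot Kaplan-Meier curves for the LC/LF cohorts
#'
#' Step-function survival curves (base graphics) for the two cohorts,
#' with medians marked when reached.
#'
#' @param kmLC,kmLF \code{KMCurve} objects for the LC and LF cohorts.
#' @param main plot title.
#' @return Invisibly, NULL; draws on the active device.
#' @export
plotKMCurves <- function(kmLC, kmLF, main = "Overall survival by cohort") {
  xmax <- max(kmLC$time, kmLF$time)
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "Months", ylab = "Survival probability",
                 main = main)
  for (g in list(list(km = kmLC, col = "#2166AC"),
                 list(km = kmLF, col = "#B2182B"))) {
    km <- g$km
    graphics::lines(stats::stepfun(km$time, c(1, km$surv)), do.points = FALSE,
                    col = g$col, lwd = 2)
    if (!is.na(km$median))
      graphics::abline(v = km$median, col = g$col, lty = 3)
  }
  graphics::legend("topright", legend = c("LC cohort", "LF cohort"),
                   col = c("#2166AC", "#B2182B"), lwd = 2, bty = "n")
  invisible(NULL)
}
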
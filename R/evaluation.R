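#' Confusion counts at a cutoff
#'
#' A case is predicted present iff its continuous suitability is greater than
#' or equal to the cutoff (ties count as positive; this convention is shared
#' with [binarize()]).
#'
#' @param predictions Numeric vector in `[0, 1]`.
#' @param labels 0/1 vector of the same length (1 = presence).
#' @param cutoff Threshold in `[0, 1]`.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_at <- function(predictions, labels, cutoff) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have the same length")
  stopifnot(length(predictions) >= 1L, all(labels %in% c(0, 1)))
  pos <- predictions >= cutoff
  structure(list(TP = sum(pos & labels == 1),
                 FP = sum(pos & labels == 0),
                 TN = sum(!pos & labels == 0),
                 FN = sum(!pos & labels == 1)),
            class = "confusion_counts")
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1`, where sensitivity is the proportion
#' of correctly predicted presences `TP/(TP+FN)` and specificity the
#' proportion of correctly predicted absences `TN/(TN+FP)`.  Ranges over
#' `[-1, 1]`; 0 is chance performance.  Unlike kappa, TSS is insensitive to
#' prevalence.
#'
#' @param conf A [confusion_at()] result.
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(conf) {
  stopifnot(inherits(conf, "confusion_counts"))
  pos <- conf$TP + conf$FN
  neg <- conf$TN + conf$FP
  if (pos < 1 || neg < 1) stop("both classes must be present")
  conf$TP / pos + conf$TN / neg - 1
}

sensitivity_of <- function(conf) conf$TP / (conf$TP + conf$FN)
specificity_of <- function(conf) conf$TN / (conf$TN + conf$FP)

#' ROC area under the curve
#'
#' The probability that a randomly chosen presence is ranked above a randomly
#' chosen absence, with ties counted one half (Mann-Whitney formulation,
#' computed from midranks).
#'
#' @inheritParams confusion_at
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have the same length")
  stopifnot(all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 < 1 || n0 < 1) stop("both classes must be present")
  r <- rank(predictions)           # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimal binary cutoff by maximum sensitivity + specificity
#'
#' Scans candidate cutoffs — the midpoints between adjacent distinct sorted
#' prediction values, plus 0 and 1 — and returns the one maximizing TSS
#' (equivalently sensitivity + specificity).  Ties are broken toward the
#' smallest cutoff.  Because candidates are data-adaptive, the optimum is
#' exact, not grid-resolution limited.
#'
#' @inheritParams confusion_at
#' @return An object of class `threshold_result`: `cutoff`, `tss`,
#'   `sensitivity`, `specificity` (with `tss = sensitivity + specificity - 1`
#'   exactly).
#' @export
optimal_cutoff <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels must have the same length")
  stopifnot(all(labels %in% c(0, 1)))
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1)
    stop("both classes must be present")
  u <- sort(unique(predictions))
  cand <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  best <- NULL
  for (ct in cand) {
    conf <- confusion_at(predictions, labels, ct)
    t <- tss(conf)
    if (is.null(best) || t > best$tss + 1e-12) {
      best <- list(cutoff = ct, tss = t,
                   sensitivity = sensitivity_of(conf),
                   specificity = specificity_of(conf))
    }
  }
  structure(best, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> cutoff %.4f: TSS %.3f (sens %.3f, spec %.3f)\n",
    x$cutoff, x$tss, x$sensitivity, x$specificity))
  invisible(x)
}

# full held-out score set used by the modeling and ensemble layers
score_predictions <- function(predictions, labels) {
  thr <- optimal_cutoff(predictions, labels)
  list(TSS = thr$tss, ROC = roc_auc(predictions, labels),
       sensitivity = thr$sensitivity, specificity = thr$specificity,
       cutoff = thr$cutoff)
}
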
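# Confusion-matrix metrics and Bayesian pre-/post-test probability of
# pneumonitis.  The positive class is pneumonitis throughout the package.

#' Positive class label
#'
#' Single source of truth: pneumonitis is coded 1 and is the positive class
#' for sensitivity/specificity and post-test probabilities.
#' @return integer 1.
#' @export
positiveClass <- function() 1L

#' Build a confusion matrix from labels and predictions
#'
#' @param truth,predicted 0/1 vectors (pneumonitis = 1 = positive).
#' @return named numeric (TP, FP, TN, FN).
#' @export
confusionFromPredictions <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  pos <- positiveClass()
  c(TP = sum(truth == pos & predicted == pos),
    FP = sum(truth != pos & predicted == pos),
    TN = sum(truth != pos & predicted != pos),
    FN = sum(truth == pos & predicted != pos))
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' Accuracy = (TP+TN)/n; sensitivity = TP/(TP+FN), the true-positive rate of
#' pneumonitis; specificity = TN/(TN+FP), its true-negative rate.  A zero
#' denominator yields 0 with a warning.
#'
#' @param cm named numeric with TP, FP, TN, FN (all >= 0, not all zero).
#' @return named numeric (accuracy, sensitivity, specificity).
#' @export
confusionMetrics <- function(cm) {
  cm <- cm[c("TP", "FP", "TN", "FN")]
  if (any(is.na(cm)) || any(cm < 0)) stop("confusion counts must be >= 0")
  n <- sum(cm)
  if (n == 0) stop("all-zero confusion matrix")
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning 0", what))
      return(0)
    }
    num / den
  }
  out <- c(unname((cm["TP"] + cm["TN"]) / n),
           unname(rate(cm["TP"], cm["TP"] + cm["FN"], "sensitivity")),
           unname(rate(cm["TN"], cm["TN"] + cm["FP"], "specificity")))
  names(out) <- c("accuracy", "sensitivity", "specificity")
  out
}

#' Pre-test probability (prevalence) of pneumonitis
#'
#' @param labels nonempty 0/1 label vector.
#' @return fraction of labels equal to 1.
#' @export
preTestProbability <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  mean(labels == positiveClass())
}

#' Post-test probability of pneumonitis given a positive model call
#'
#' Bayes' theorem:
#' `sens * prev / (sens * prev + (1 - spec) * (1 - prev))` — the probability
#' that a patient the model calls positive truly has pneumonitis.  Monotone
#' increasing in sensitivity and specificity; equals the prevalence exactly
#' when the positive likelihood ratio `sens / (1 - spec)` is 1.
#'
#' @param prevalence,sensitivity,specificity probabilities in \[0,1\].
#' @return posterior probability in \[0,1\].
#' @export
postTestPositive <- function(prevalence, sensitivity, specificity) {
  vals <- c(prevalence, sensitivity, specificity)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("all inputs must be probabilities in [0, 1]")
  den <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  if (den == 0)
    stop("the model never calls positive (sens * prev and (1-spec) * (1-prev) are both 0)")
  sensitivity * prevalence / den
}

#' Diagnostic probability report
#'
#' Combines confusion-matrix metrics with the Bayesian pre-/post-test
#' probabilities; percentages are rounded to the nearest percent for
#' display, raw probabilities retained.
#'
#' @param cm confusion matrix (named TP/FP/TN/FN).
#' @param labels cohort 0/1 labels (for the prevalence); defaults to the
#'   label composition implied by `cm`.
#' @return list of class `diagReport`: `confusion`, `metrics`, `preTest`,
#'   `postTestPositive`, and rounded `percent` versions.
#' @export
bayesReport <- function(cm, labels = NULL) {
  m <- confusionMetrics(cm)
  prev <- if (is.null(labels))
    (cm["TP"] + cm["FN"]) / sum(cm[c("TP", "FP", "TN", "FN")])
  else preTestProbability(labels)
  prev <- unname(prev)
  post <- postTestPositive(prev, m["sensitivity"], m["specificity"])
  structure(list(confusion = cm, metrics = m, preTest = prev,
                 postTestPositive = unname(post),
                 percent = round(100 * c(accuracy = unname(m["accuracy"]),
                                         sensitivity = unname(m["sensitivity"]),
                                         specificity = unname(m["specificity"]),
                                         preTest = prev,
                                         postTest = unname(post)))),
            class = "diagReport")
}

#' @export
print.diagReport <- function(x, ...) {
  p <- x$percent
  cat("Diagnostic report (positive class: pneumonitis)\n")
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  cat(sprintf("  accuracy %d%%  sensitivity %d%%  specificity %d%%\n",
              p["accuracy"], p["sensitivity"], p["specificity"]))
  cat(sprintf("  pre-test probability  %d%%\n", p["preTest"]))
  cat(sprintf("  post-test probability %d%% (if the model calls pneumonitis)\n",
              p["postTest"]))
  invisible(x)
}
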
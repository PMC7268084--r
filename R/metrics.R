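#' Balanced accuracy, sensitivity, specificity
#'
#' Patients are the positive class: sensitivity is the patient recall,
#' specificity the control recall, and balanced accuracy their mean. All
#' three are reported as percentages.
#'
#' @param truth,pred label vectors with values `"patient"` / `"control"`;
#'   `truth` must contain both classes.
#' @return Named numeric: `bac`, `sen`, `spec` (percent).
#' @export
balanced_metrics <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("balanced_metrics: length mismatch")
  is_pat <- truth == "patient"
  if (!any(is_pat) || all(is_pat))
    stop("balanced_metrics: both classes must be present in truth")
  sen <- mean(pred[is_pat] == "patient") * 100
  spec <- mean(pred[!is_pat] == "control") * 100
  c(bac = (sen + spec) / 2, sen = sen, spec = spec)
}

#' Soft-voting fusion of per-measure probabilities
#'
#' Each measure's patient probability is weighted by its positive integer
#' coefficient; the fused patient score is the coefficient-weighted mean
#' and the predicted label is the class with the highest fused score, with
#' the patient class winning exact ties.
#'
#' @param probs list (or matrix columns) of per-measure patient
#'   probabilities, aligned on subjects.
#' @param coeffs positive numeric coefficients, one per measure.
#' @return List: `score` (fused patient score), `label`.
#' @export
soft_vote <- function(probs, coeffs) {
  P <- if (is.list(probs)) do.call(cbind, probs) else as.matrix(probs)
  if (length(coeffs) != ncol(P))
    stop("soft_vote: ", length(coeffs), " coefficients for ", ncol(P),
         " measures")
  if (any(coeffs <= 0)) stop("soft_vote: coefficients must be positive")
  score <- as.vector(P %*% coeffs) / sum(coeffs)
  list(score = score,
       label = ifelse(score >= 0.5, "patient", "control"))
}
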
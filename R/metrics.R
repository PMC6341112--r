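case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  l <- as.character(labels)
  if (!all(l %in% c("case", "control")))
    stop("labels must be 'case'/'control' (or logical)")
  l == "case"
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a randomly chosen case
#' outscores a randomly chosen control, with ties counted one half
#' (midrank formula).
#'
#' @param scores numeric scores, higher = more case-like
#' @param labels `"case"`/`"control"` vector (or logical, `TRUE` = case)
#' @return AUC in `[0, 1]`
#' @export
roc_auc <- function(scores, labels) {
  is_case <- case_logical(labels)
  stopifnot(length(scores) == length(is_case))
  if (anyNA(scores) || anyNA(is_case)) stop("scores/labels contain NA")
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity, specificity and their mean at a fixed cutoff
#'
#' Classifies as case when the score exceeds `cutoff`. The mean of
#' sensitivity and specificity (balanced accuracy) is diagnostic of
#' cross-site score-distribution shifts even when the AUC is high.
#'
#' @param scores numeric case scores
#' @param labels `"case"`/`"control"` vector (or logical)
#' @param cutoff classification cutoff in `(0, 1)` for vote-fraction scores
#'   (any finite value for decision-value scores)
#' @return list with `sensitivity`, `specificity`, `mean`
#' @export
mean_sens_spec <- function(scores, labels, cutoff = 0.5) {
  is_case <- case_logical(labels)
  if (!any(is_case) || !any(!is_case))
    stop("both classes must be present; one rate is undefined otherwise")
  sens <- mean(scores[is_case] > cutoff)
  spec <- mean(scores[!is_case] <= cutoff)
  list(sensitivity = sens, specificity = spec, mean = (sens + spec) / 2)
}
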
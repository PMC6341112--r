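#' Train a cost-tuned linear support vector machine
#'
#' Linear maximum-margin classifier with the cost parameter chosen from a
#' log-spaced grid (default `10^-5 ... 10^5`, 11 candidates) by stratified
#' 10-fold cross-validation on the training data only; ties are broken
#' toward the smaller (more regularized) cost. Decision values oriented so
#' that larger means more case-like are exposed as scores; the
#' classification rule is case iff the decision value is positive.
#'
#' @param x numeric matrix or feature table of predictors
#' @param labels `"case"`/`"control"` vector
#' @param cost_grid candidate cost values (at least 2, all positive)
#' @param n_folds cross-validation folds (default 10)
#' @param seed integer seed for fold assignment
#' @return object of class `ms_svm` with the fitted model, chosen cost and
#'   the cross-validation accuracy per candidate
#' @export
train_linear_svm <- function(x, labels, cost_grid = 10^seq(-5, 5),
                             n_folds = 10, seed = 1) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  is_case <- case_logical(labels)
  y <- factor(ifelse(is_case, "case", "control"), levels = c("case", "control"))
  if (nlevels(droplevels(y)) < 2) stop("two classes required")
  if (length(cost_grid) < 2 || any(cost_grid <= 0) ||
      length(unique(cost_grid)) < 2)
    stop("degenerate cost grid")
  cost_grid <- sort(cost_grid)

  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  cv_acc <- sapply(cost_grid, function(cost) {
    correct <- 0L
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      if (nlevels(droplevels(y[tr])) < 2 || !any(!tr)) next
      m <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cost)
      correct <- correct + sum(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }
    correct / length(y)
  })
  best <- cost_grid[which.max(cv_acc)]
  fit <- e1071::svm(x, y, kernel = "linear", cost = best)
  structure(list(fit = fit, cost = best, cost_grid = cost_grid,
                 cv_accuracy = setNames(cv_acc, cost_grid),
                 feature_names = colnames(x)),
            class = "ms_svm")
}

#' Decision-value scores from a linear SVM
#'
#' @param model an `ms_svm`
#' @param features feature table or numeric matrix
#' @return numeric decision values, oriented so larger = more case-like
#' @export
svm_predict <- function(model, features) {
  stopifnot(inherits(model, "ms_svm"))
  x <- if (is.data.frame(features)) feature_matrix(features) else features
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  p <- predict(model$fit, x, decision.values = TRUE)
  dv <- attr(p, "decision.values")
  # e1071 orients decision values toward the first class named in the
  # colname "A/B": positive means class A
  ori <- strsplit(colnames(dv)[1], "/")[[1]][1]
  s <- dv[, 1]
  if (ori != "case") s <- -s
  setNames(s, rownames(x))
}
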
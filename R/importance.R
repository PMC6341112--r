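#' Backward feature elimination under the min-error-plus-1-SD rule
#'
#' Starting from the full predictor set, iteratively refits the
#' site-stratified forest and drops the least important fraction of
#' features (by mean decrease in Gini), recording the out-of-bag error of
#' every solution. The selected set is the smallest one whose out-of-bag
#' error does not exceed the minimum observed error plus one standard
#' deviation of that minimum (binomial standard error of the error
#' estimate) -- a near-optimal but sparser solution, generally favourable
#' for generalizability.
#'
#' @param x feature table or numeric matrix
#' @param labels `"case"`/`"control"` vector
#' @param sites site id per subject
#' @param drop_frac fraction of features removed per round, in `(0, 1)`
#' @param n_trees trees per refit
#' @param seed integer seed
#' @return list with `selected` (feature ids), `m` (its size), and `path`
#'   (data.frame of set size, out-of-bag error, and feature sets)
#' @export
backward_feature_elimination <- function(x, labels, sites, drop_frac = 0.2,
                                         n_trees = 2000, seed = 1) {
  if (drop_frac <= 0 || drop_frac >= 1)
    stop("drop_frac must lie strictly between 0 and 1")
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (ncol(x) < 2) stop("at least 2 features required")
  n <- nrow(x)
  current <- colnames(x)
  sizes <- integer(0); errors <- numeric(0); sets <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    fit <- train_site_stratified_forest(x[, current, drop = FALSE], labels,
                                        sites, n_trees = n_trees,
                                        seed = seed + round)
    ok <- !is.na(fit$oob_scores)
    pred_case <- fit$oob_scores[ok] > 0.5
    err <- mean(pred_case != case_logical(labels)[ok])
    sizes <- c(sizes, length(current)); errors <- c(errors, err)
    sets <- c(sets, list(current))
    if (length(current) <= 2) break
    n_drop <- max(1L, floor(drop_frac * length(current)))
    keep_n <- max(2L, length(current) - n_drop)
    ord <- order(fit$importance[current], decreasing = TRUE)
    current <- current[ord][seq_len(keep_n)]
  }
  err_min <- min(errors)
  se <- sqrt(err_min * (1 - err_min) / n)
  ok_sets <- which(errors <= err_min + se)
  pick <- ok_sets[which.min(sizes[ok_sets])]
  list(selected = sort(sets[[pick]]), m = sizes[pick],
       path = data.frame(n_features = sizes, oob_error = errors),
       sets = sets)
}

rank_sum_statistic <- function(importance, top_set) {
  stopifnot(all(top_set %in% names(importance)))
  r <- rank(importance, ties.method = "average")
  m <- length(top_set)
  sum(r[top_set]) - m * (m + 1) / 2  # Mann-Whitney U, larger = top set larger
}

#' Permutation test of cross-task feature-importance overlap
#'
#' Tests whether the top features of one classification task (e.g. the
#' schizophrenia-like contrast) are also disproportionately important in a
#' second case-control task. The observed statistic is the Wilcoxon
#' rank-sum statistic comparing the second task's importances of the top
#' set against the remaining features. The null distribution is built by
#' permuting the second task's diagnostic labels, retraining its forest and
#' recomputing the statistic; the empirical p-value is the frequency of
#' null statistics at least as high as the observed one (a zero count is
#' reported as 0 and should be read as below `1/B`). The top set is held
#' fixed across permutations.
#'
#' @param top_set character vector of top feature ids from the reference
#'   task (a strict, nonempty subset of the second task's features)
#' @param x feature table or matrix of the second task
#' @param labels,sites second task's labels and sites
#' @param B number of label permutations (default 5000)
#' @param n_trees trees for the observed forest
#' @param perm_n_trees trees per permutation forest (reduced for
#'   tractability; set equal to `n_trees` for a strict run)
#' @param seed integer seed
#' @return list of class `permutation_result`: `observed_statistic`,
#'   `null_draws`, `empirical_p`, `B`, `m`
#' @export
importance_overlap_test <- function(top_set, x, labels, sites, B = 5000,
                                    n_trees = 5000, perm_n_trees = 500,
                                    seed = 1) {
  if (B < 1) stop("B must be at least 1")
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (!length(top_set) || !all(top_set %in% colnames(x)))
    stop("top_set must be a nonempty subset of the task's features")
  if (length(top_set) >= ncol(x))
    stop("top_set must be a strict subset of the task's features")
  fit <- train_site_stratified_forest(x, labels, sites, n_trees = n_trees,
                                      seed = seed)
  obs <- rank_sum_statistic(fit$importance, top_set)
  null_draws <- vapply(seq_len(B), function(b) {
    set.seed(seed + 5000L + b)
    yp <- sample(as.character(labels))
    f <- train_site_stratified_forest(x, yp, sites,
                                      n_trees = perm_n_trees,
                                      seed = seed + 6000L + b)
    rank_sum_statistic(f$importance, top_set)
  }, numeric(1))
  structure(list(observed_statistic = obs, null_draws = null_draws,
                 empirical_p = mean(null_draws >= obs), B = B,
                 m = length(top_set)),
            class = "permutation_result")
}

#' Cross-cohort similarity of importance profiles
#'
#' Median Pearson correlation over all pairs of per-cohort feature
#' importance profiles, quantifying how consistently features are selected
#' as important across cohorts.
#'
#' @param profiles list of at least two named numeric importance vectors
#'   over identical feature sets
#' @return median pairwise Pearson correlation
#' @export
cross_cohort_importance_similarity <- function(profiles) {
  if (length(profiles) < 2) stop("at least 2 profiles required")
  nm <- names(profiles[[1]])
  for (p in profiles)
    if (!identical(sort(names(p)), sort(nm)))
      stop("profiles cover different feature sets")
  pairs <- utils::combn(length(profiles), 2)
  median(apply(pairs, 2, function(ij)
    cor(profiles[[ij[1]]][nm], profiles[[ij[2]]][nm])))
}

#' Importance profile of a trained forest
#'
#' @param model an `ms_forest`
#' @param source optional task descriptor stored with the profile
#' @return data.frame (feature_id, importance, rank) sorted by importance
#'   descending, ties broken by feature id
#' @export
importance_profile <- function(model, source = NULL) {
  stopifnot(inherits(model, "ms_forest"))
  imp <- model$importance
  ord <- order(-imp, names(imp))
  out <- data.frame(feature_id = names(imp)[ord],
                    importance = unname(imp[ord]),
                    rank = seq_along(imp), stringsAsFactors = FALSE)
  attr(out, "source") <- source
  out
}
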
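#' Train a site-stratified random forest
#'
#' Grows a classification forest in which every tree's bag contains exactly
#' `s` subjects drawn without replacement from each training site, so no
#' site dominates any tree. Trees are grown unpruned to purity with the Gini
#' split criterion and `mtry = floor(sqrt(p))` by default; no parameter
#' tuning is performed. Out-of-bag case scores (fraction of a subject's
#' out-of-bag trees voting case) and mean-decrease-in-Gini importance are
#' recorded.
#'
#' The literal per-site draw size "sample size of the smallest cohort"
#' leaves every smallest-site subject in-bag for every tree, so their
#' out-of-bag scores would be undefined. The default mode therefore draws
#' `s = ceiling(0.632 * n_min)` per site, preserving the stratification
#' while keeping out-of-bag evaluation defined for all subjects;
#' `s_mode = "strict"` reproduces the literal rule and excludes always
#' in-bag subjects from out-of-bag metrics.
#'
#' @param x numeric matrix or feature table of predictors
#' @param labels `"case"`/`"control"` vector
#' @param sites site/cohort id per subject
#' @param n_trees number of trees (default 5000)
#' @param mtry predictors tried per split (default `floor(sqrt(p))`)
#' @param s per-site per-tree draw size; default depends on `s_mode`
#' @param s_mode `"fraction"` (default, `ceiling(0.632 * n_min)`) or
#'   `"strict"` (`n_min`, the literal smallest-cohort rule)
#' @param seed integer seed
#' @return object of class `ms_forest` with the fitted `randomForest`, the
#'   per-subject out-of-bag scores (`NA` where undefined), Gini importance,
#'   and the bag parameters
#' @export
train_site_stratified_forest <- function(x, labels, sites, n_trees = 5000,
                                         mtry = NULL, s = NULL,
                                         s_mode = c("fraction", "strict"),
                                         seed = 1) {
  s_mode <- match.arg(s_mode)
  if (is.data.frame(x)) x <- feature_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  is_case <- case_logical(labels)
  y <- factor(ifelse(is_case, "case", "control"), levels = c("case", "control"))
  site <- factor(sites)
  stopifnot(nrow(x) == length(y), length(site) == length(y))
  n_per_site <- table(site)
  if (any(n_per_site < 2)) stop("every site needs at least 2 subjects")
  n_min <- min(n_per_site)
  if (is.null(s))
    s <- if (s_mode == "strict") n_min else ceiling(0.632 * n_min)
  small <- names(n_per_site)[n_per_site < s]
  if (length(small))
    stop(sprintf("site(s) smaller than the per-tree draw size s=%d: %s",
                 s, paste(small, collapse = ", ")))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))

  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = mtry,
    strata = site, sampsize = rep(s, nlevels(site)), replace = FALSE,
    keep.inbag = TRUE, keep.forest = TRUE)

  oob <- rf$votes[, "case"]
  n_oob <- rf$oob.times
  oob[n_oob == 0] <- NA_real_
  imp <- rf$importance[, "MeanDecreaseGini"]
  structure(list(rf = rf, n_trees = n_trees, mtry = mtry, s = s,
                 s_mode = s_mode, sites = site, labels = y,
                 feature_names = colnames(x),
                 oob_scores = unname(oob), oob_times = unname(n_oob),
                 importance = imp, seed = seed),
            class = "ms_forest")
}

#' Per-subject case scores from a trained forest
#'
#' The score is the fraction of all trees voting case; the conventional
#' classification rule is case iff score exceeds 0.5. Feature columns must
#' match the training columns in name and order.
#'
#' @param model an `ms_forest`
#' @param features feature table or numeric matrix
#' @return numeric vector of case scores (named by subject where available)
#' @export
forest_predict <- function(model, features) {
  stopifnot(inherits(model, "ms_forest"))
  x <- if (is.data.frame(features)) feature_matrix(features) else features
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  v <- predict(model$rf, x, type = "vote", norm.votes = TRUE)
  setNames(v[, "case"], rownames(x))
}

#' Per-tree per-site bag sizes of a stratified forest
#'
#' Returns the number of in-bag subjects per site for each tree, for
#' checking the stratified-bag invariant (every entry equals `s`).
#'
#' @param model an `ms_forest`
#' @param trees tree indices to inspect (default all)
#' @return sites x trees integer matrix of bag counts
#' @export
forest_bag_counts <- function(model, trees = NULL) {
  stopifnot(inherits(model, "ms_forest"))
  ib <- model$rf$inbag
  if (is.null(trees)) trees <- seq_len(ncol(ib))
  sapply(trees, function(t) tapply(ib[, t], model$sites, sum))
}
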
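regional_columns <- function(atlas, family = c("combined", "densitylike",
                                               "surfacelike")) {
  family <- match.arg(family)
  keep <- !atlas$is_global & atlas$measure != "icv" & !atlas$is_median_placeholder
  if (family != "combined") keep <- keep & atlas$family %in% family
  atlas$feature_id[keep]
}

# Normalize one leave-site-out fold (or an external-validation split):
# within-dataset models and the between-dataset adjustment are fit on the
# matched training subjects only and applied to training and test rows
# alike. Optionally assembles the global feature set and residualizes the
# regional features of the active family against it (fit on training
# subjects only), and/or centers the test cohort's feature means at zero.
prep_fold <- function(features, phenotypes, atlas, train_cohorts,
                      test_cohorts, matches, family = "combined",
                      feature_set = "regional", residualize_globals = FALSE,
                      global_perm = NULL, center_test = FALSE,
                      test_subjects = NULL) {
  audit <- list()
  ph <- declare_test_cohorts(phenotypes, test_cohorts)
  train_ids <- matched_subjects(matches[train_cohorts])
  if (is.null(test_subjects)) {
    test_ids <- unlist(lapply(test_cohorts, function(h)
      if (h %in% names(matches)) matched_subjects(matches[h])
      else ph$subject_id[ph$cohort_id == h]), use.names = FALSE)
  } else test_ids <- test_subjects

  fold_ids <- c(train_ids, test_ids)
  rows <- match(fold_ids, features$subject_id)
  fx <- features[rows, , drop = FALSE]
  px <- ph[match(fold_ids, ph$subject_id), , drop = FALSE]
  attr(px, "test_cohorts") <- test_cohorts
  is_train <- px$subject_id %in% train_ids

  m1 <- fit_within_dataset_models(fx[is_train, , drop = FALSE],
                                  px[is_train, , drop = FALSE],
                                  train_cohorts, atlas)
  audit <- c(audit, list(audit_entry("within_dataset_normalization",
                                     test_cohorts, train_cohorts, train_ids)))
  adj <- apply_normalization(m1, fx, px)
  adj <- fit_apply_between_dataset_adjustment(adj, px, train_cohorts,
                                              fit_subjects = train_ids)
  audit <- c(audit, list(audit_entry("between_dataset_adjustment",
                                     test_cohorts, train_cohorts, train_ids)))

  globals <- NULL
  if (feature_set == "globals" || residualize_globals) {
    if (family == "combined" && feature_set != "globals")
      stop("global residualization is defined per feature family, not for the combined set")
    globals <- assemble_global_features(adj, atlas,
                                        family = if (family == "combined")
                                          "surfacelike" else family)
    if (!is.null(global_perm)) {
      gm <- feature_matrix(globals)
      perm <- if (identical(global_perm, "identity")) seq_len(nrow(gm))
              else { set.seed(global_perm); sample(nrow(gm)) }
      gm <- gm[perm, , drop = FALSE]
      globals <- as_feature_table(gm, globals$subject_id)
    }
  }

  if (feature_set == "globals") {
    tab <- globals
  } else {
    cols <- c(regional_columns(atlas, family), "icv")
    tab <- adj[, c("subject_id", intersect(cols, names(adj))), drop = FALSE]
    if (residualize_globals) {
      tab <- residualize_against_globals(tab, globals, train_ids = train_ids,
                                         exclude = "icv")
      audit <- c(audit, list(audit_entry("global_residualization",
                                         test_cohorts, train_cohorts,
                                         train_ids)))
    }
  }
  if (center_test)
    for (h in test_cohorts) tab <- center_test_features(tab, px, h)

  list(table = tab, phenotypes = px, is_train = is_train,
       train_ids = train_ids, test_ids = test_ids, audit = audit)
}

make_matches <- function(phenotypes, cohorts, seed, skip_matching = character(0)) {
  matches <- lapply(seq_along(cohorts), function(i)
    propensity_match(phenotypes, cohorts[i], seed = seed + i,
                     skip_matching = cohorts[i] %in% skip_matching))
  names(matches) <- cohorts
  matches
}

fit_fold_classifier <- function(tab, px, is_train, classifier, n_trees,
                                s_mode, cost_grid, seed) {
  xtr <- tab[is_train, , drop = FALSE]
  ytr <- px$diagnosis[is_train]
  str <- px$cohort_id[is_train]
  if (classifier == "forest") {
    model <- train_site_stratified_forest(xtr, ytr, str, n_trees = n_trees,
                                          s_mode = s_mode, seed = seed)
    list(model = model,
         score = function(newtab) forest_predict(model, newtab),
         cutoff_default = 0.5)
  } else {
    model <- train_linear_svm(xtr, ytr, cost_grid = cost_grid, seed = seed)
    list(model = model,
         score = function(newtab) svm_predict(model, newtab),
         cutoff_default = 0)
  }
}

#' Leave-site-out cross-validation of a multi-site classifier
#'
#' Iteratively holds out each training cohort: propensity matching and both
#' covariate-normalization steps are (re)fit on the remaining cohorts only,
#' a site-stratified random forest (or cost-tuned linear SVM) is trained on
#' the matched training data, and the held-out cohort is scored. Reports
#' per-site AUC, sensitivity/specificity at the fixed cutoff and their mean,
#' plus the median and range of AUC across sites. Every fitting stage is
#' recorded in an audit log checkable with [verify_no_leakage()].
#'
#' @param features raw feature table
#' @param phenotypes phenotype table
#' @param atlas feature atlas
#' @param cohorts training cohorts to rotate over (default: all cohorts with
#'   role `"training"`; at least 3 required)
#' @param classifier `"forest"` or `"svm"`
#' @param family feature family used for classification: `"combined"`
#'   (default), `"densitylike"` or `"surfacelike"`
#' @param feature_set `"regional"` (family features plus ICV) or
#'   `"globals"` (the assembled 22-member global set)
#' @param residualize_globals if `TRUE`, regional features are residualized
#'   against the covariate-adjusted global set (models fit on training
#'   sites only)
#' @param global_perm `NULL`, `"identity"`, or an integer seed to
#'   row-permute the assembled global features before residualization
#'   (permutation control)
#' @param center_test if `TRUE`, set the held-out cohort's per-feature means
#'   to zero before scoring
#' @param n_trees,s_mode forest parameters (see
#'   [train_site_stratified_forest()])
#' @param cost_grid SVM cost grid (see [train_linear_svm()])
#' @param cutoff score cutoff for sensitivity/specificity (default 0.5 for
#'   vote fractions, 0 for SVM decision values)
#' @param skip_matching cohort ids passed through unmatched
#' @param matches optional precomputed list of `matched_cohort` objects
#' @param seed integer seed
#' @return list with `per_site` (data.frame), `median_auc`, `auc_range`,
#'   `scores`, `audit`, and the call parameters
#' @export
run_leave_site_out <- function(features, phenotypes, atlas, cohorts = NULL,
                               classifier = c("forest", "svm"),
                               family = "combined",
                               feature_set = c("regional", "globals"),
                               residualize_globals = FALSE,
                               global_perm = NULL, center_test = FALSE,
                               n_trees = 5000, s_mode = "fraction",
                               cost_grid = 10^seq(-5, 5), cutoff = NULL,
                               skip_matching = character(0), matches = NULL,
                               seed = 1) {
  classifier <- match.arg(classifier)
  feature_set <- match.arg(feature_set)
  cohorts <- cohorts %||% unique(phenotypes$cohort_id[phenotypes$role == "training"])
  if (length(cohorts) < 3)
    stop("leave-site-out requires at least 3 cohorts")
  if (is.null(matches))
    matches <- make_matches(phenotypes, cohorts, seed, skip_matching)

  audit <- list(); per_site <- list(); score_tab <- list()
  for (h in cohorts) {
    train_cohorts <- setdiff(cohorts, h)
    test_labels <- phenotypes$diagnosis[phenotypes$subject_id %in%
                                          matched_subjects(matches[h])]
    if (length(unique(test_labels)) < 2) {
      warning("held-out cohort ", h, " lacks a class; skipped")
      next
    }
    fold <- prep_fold(features, phenotypes, atlas, train_cohorts, h, matches,
                      family = family, feature_set = feature_set,
                      residualize_globals = residualize_globals,
                      global_perm = global_perm, center_test = center_test)
    clf <- fit_fold_classifier(fold$table, fold$phenotypes, fold$is_train,
                               classifier, n_trees, s_mode, cost_grid,
                               seed + match(h, cohorts))
    audit <- c(audit, fold$audit,
               list(audit_entry("classifier_training", h, train_cohorts,
                                fold$train_ids)))
    test_rows <- !fold$is_train
    sc <- clf$score(fold$table[test_rows, , drop = FALSE])
    lab <- fold$phenotypes$diagnosis[test_rows]
    cut <- cutoff %||% clf$cutoff_default
    ss <- mean_sens_spec(sc, lab, cut)
    per_site[[h]] <- data.frame(
      site = h, n_test = length(sc), auc = roc_auc(sc, lab),
      sensitivity = ss$sensitivity, specificity = ss$specificity,
      mean_sens_spec = ss$mean, stringsAsFactors = FALSE)
    score_tab[[h]] <- data.frame(
      subject_id = fold$phenotypes$subject_id[test_rows], site = h,
      score = unname(sc), diagnosis = lab, stringsAsFactors = FALSE)
  }
  per_site <- do.call(rbind, per_site); rownames(per_site) <- NULL
  list(per_site = per_site,
       median_auc = median(per_site$auc),
       auc_range = range(per_site$auc),
       median_mean_sens_spec = median(per_site$mean_sens_spec),
       scores = do.call(rbind, score_tab),
       audit = audit,
       params = list(classifier = classifier, family = family,
                     feature_set = feature_set,
                     residualize_globals = residualize_globals,
                     center_test = center_test, n_trees = n_trees,
                     seed = seed))
}

#' Within-site out-of-bag classification with permutation significance
#'
#' Trains a forest on a single cohort's matched data (after within-dataset
#' covariate normalization) and reports the AUC of the out-of-bag scores.
#' Significance is assessed by retraining under `n_label_perms` random
#' permutations of the diagnostic labels; the empirical p-value is the
#' fraction of permutation AUCs at least as high as the observed one.
#'
#' @param features raw feature table
#' @param phenotypes phenotype table
#' @param atlas feature atlas
#' @param cohort_id cohort to analyse
#' @param n_label_perms number of label permutations (at least 1)
#' @param family feature family (default `"combined"`)
#' @param n_trees trees for the observed forest
#' @param perm_n_trees trees for each permutation forest (reduced for
#'   tractability)
#' @param skip_matching pass the cohort through unmatched
#' @param seed integer seed
#' @return list with `auc`, `p_value`, `null_aucs`, `model`
#' @export
run_within_site <- function(features, phenotypes, atlas, cohort_id,
                            n_label_perms = 1000, family = "combined",
                            n_trees = 5000, perm_n_trees = 500,
                            skip_matching = FALSE, seed = 1) {
  if (n_label_perms < 1) stop("n_label_perms must be at least 1")
  m <- propensity_match(phenotypes, cohort_id, seed = seed,
                        skip_matching = skip_matching)
  ids <- matched_subjects(m)
  rows <- match(ids, features$subject_id)
  fx <- features[rows, , drop = FALSE]
  px <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  if (length(unique(px$diagnosis)) < 2) stop("cohort lacks a class")

  m1 <- fit_within_dataset_models(fx, px, cohort_id, atlas)
  adj <- apply_normalization(m1, fx, px)
  cols <- c(regional_columns(atlas, family), "icv")
  tab <- adj[, c("subject_id", intersect(cols, names(adj))), drop = FALSE]

  fit <- train_site_stratified_forest(tab, px$diagnosis, px$cohort_id,
                                      n_trees = n_trees, seed = seed)
  ok <- !is.na(fit$oob_scores)
  obs <- roc_auc(fit$oob_scores[ok], px$diagnosis[ok])
  x <- feature_matrix(tab)
  null_aucs <- vapply(seq_len(n_label_perms), function(b) {
    set.seed(seed + 1000L + b)
    yp <- sample(px$diagnosis)
    f <- train_site_stratified_forest(x, yp, px$cohort_id,
                                      n_trees = perm_n_trees,
                                      seed = seed + 2000L + b)
    ok <- !is.na(f$oob_scores)
    roc_auc(f$oob_scores[ok], yp[ok])
  }, numeric(1))
  list(auc = obs, p_value = mean(null_aucs >= obs), null_aucs = null_aucs,
       model = fit, cohort_id = cohort_id)
}

#' Specificity of a trained classifier in independent cohorts
#'
#' Trains the case-control classifier on all training cohorts (matching and
#' both normalization steps fit there only), applies the frozen pipeline to
#' the target cohorts, and reports per cohort and diagnosis group the
#' fraction of subjects classified as non-case (score at or below the
#' cutoff) -- the specificity for control groups and, for patient groups
#' with another disorder, the complement of the cross-disorder
#' misclassification rate.
#'
#' @param features raw feature table
#' @param phenotypes phenotype table
#' @param atlas feature atlas
#' @param train_cohorts cohorts to train on
#' @param target_cohorts independent cohorts to score (must not overlap the
#'   training cohorts or subjects)
#' @param classifier,family,n_trees,s_mode,cost_grid,cutoff,skip_matching,seed
#'   as in [run_leave_site_out()]
#' @return list with `per_group` (cohort x diagnosis-group specificity),
#'   `scores`, `model`, `audit`
#' @export
run_external_specificity <- function(features, phenotypes, atlas,
                                     train_cohorts, target_cohorts,
                                     classifier = c("forest", "svm"),
                                     family = "combined", n_trees = 5000,
                                     s_mode = "fraction",
                                     cost_grid = 10^seq(-5, 5),
                                     cutoff = NULL,
                                     skip_matching = character(0), seed = 1) {
  classifier <- match.arg(classifier)
  if (length(intersect(train_cohorts, target_cohorts)))
    stop("target cohorts overlap the training cohorts")
  matches <- make_matches(phenotypes, train_cohorts, seed, skip_matching)
  target_ids <- phenotypes$subject_id[phenotypes$cohort_id %in% target_cohorts]
  if (length(intersect(matched_subjects(matches), target_ids)))
    stop("target cohorts share subjects with the training data")

  fold <- prep_fold(features, phenotypes, atlas, train_cohorts,
                    target_cohorts, matches, family = family,
                    test_subjects = target_ids)
  clf <- fit_fold_classifier(fold$table, fold$phenotypes, fold$is_train,
                             classifier, n_trees, s_mode, cost_grid, seed)
  cut <- cutoff %||% clf$cutoff_default
  test_rows <- !fold$is_train
  sc <- clf$score(fold$table[test_rows, , drop = FALSE])
  px <- fold$phenotypes[test_rows, , drop = FALSE]
  grp <- interaction(px$cohort_id, px$disorder, drop = TRUE, sep = ":")
  per_group <- do.call(rbind, lapply(levels(grp), function(g) {
    i <- grp == g
    data.frame(cohort_id = px$cohort_id[i][1], group = px$disorder[i][1],
               n = sum(i), specificity = mean(sc[i] <= cut),
               stringsAsFactors = FALSE)
  }))
  list(per_group = per_group,
       scores = data.frame(subject_id = px$subject_id,
                           cohort_id = px$cohort_id, group = px$disorder,
                           score = unname(sc), stringsAsFactors = FALSE),
       model = clf$model,
       audit = c(fold$audit,
                 list(audit_entry("classifier_training", target_cohorts,
                                  train_cohorts, fold$train_ids))))
}
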
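#' Assemble the global structural feature set
#'
#' Collects the atlas-designated global summary features and adds two
#' per-subject medians: the median across all ventricle features
#' (`ventricle_median`) and the median across all regional features of the
#' active family (`family_median`), for a total of 22 members under the
#' default atlas. The input table is expected to be covariate-adjusted
#' (the medians are computed after adjustment, consistent with the
#' downstream use of "covariate-adjusted global features").
#'
#' @param features covariate-adjusted feature table containing the
#'   designated global columns and the regional family columns
#' @param atlas feature atlas
#' @param family regional family supplying the family median
#'   (`"densitylike"` or `"surfacelike"`); the assembled sets for the two
#'   modes differ only in this member
#' @return feature table of global features with a `roles` attribute
#' @export
assemble_global_features <- function(features, atlas,
                                     family = c("densitylike", "surfacelike")) {
  family <- match.arg(family)
  designated <- atlas$feature_id[atlas$is_global & !atlas$is_median_placeholder]
  if (length(designated) == 0) stop("atlas flags no designated global features")
  miss <- setdiff(designated, names(features))
  if (length(miss))
    stop("designated global feature(s) missing from table: ",
         paste(miss, collapse = ", "))
  vent <- atlas$feature_id[atlas$is_global & atlas$is_ventricle %in% TRUE]
  if (length(vent) == 0) stop("atlas flags no ventricle features")

  Y <- feature_matrix(features)
  reg <- intersect(regional_columns(atlas, family), colnames(Y))
  if (length(reg) == 0) stop("no regional features of family ", family)
  out <- cbind(Y[, designated, drop = FALSE],
               ventricle_median = apply(Y[, vent, drop = FALSE], 1, median),
               family_median = apply(Y[, reg, drop = FALSE], 1, median))
  expected <- sum(atlas$is_global)
  if (ncol(out) != expected)
    stop(sprintf("assembled %d global features, atlas declares %d",
                 ncol(out), expected))
  tab <- as_feature_table(out, features$subject_id)
  attr(tab, "roles") <- c(setNames(rep("designated", length(designated)),
                                   designated),
                          ventricle_median = "ventricle_member",
                          family_median = "family_median")
  tab
}

#' Residualize regional features against the global feature set
#'
#' Replaces each feature by its residual from an additive ordinary
#' least-squares model on all global features simultaneously (no
#' interactions). In leave-site-out use the models are fit on training
#' subjects only (`train_ids`) and applied to training and test rows alike,
#' preserving the leakage discipline of the rest of the pipeline. Collinear
#' global columns are dropped with a warning.
#'
#' @param features feature table to residualize
#' @param globals global feature table over the same subjects
#' @param train_ids subject ids to fit on (default: all)
#' @param exclude feature columns to pass through untouched (e.g. `"icv"`)
#' @return residualized feature table
#' @export
residualize_against_globals <- function(features, globals, train_ids = NULL,
                                        exclude = character(0)) {
  if (!setequal(features$subject_id, globals$subject_id))
    stop("feature and global tables cover different subjects")
  globals <- globals[match(features$subject_id, globals$subject_id), ,
                     drop = FALSE]
  G <- cbind(intercept = 1, feature_matrix(globals))
  fit_rows <- if (is.null(train_ids)) rep(TRUE, nrow(G))
              else features$subject_id %in% train_ids
  qrG <- qr(G[fit_rows, , drop = FALSE])
  if (qrG$rank < ncol(G)) {
    dropped <- colnames(G)[qrG$pivot[(qrG$rank + 1):ncol(G)]]
    warning("collinear global column(s) dropped: ",
            paste(dropped, collapse = ", "))
    G <- G[, qrG$pivot[seq_len(qrG$rank)], drop = FALSE]
    qrG <- qr(G[fit_rows, , drop = FALSE])
  }
  target <- setdiff(names(features), c("subject_id", exclude))
  Y <- feature_matrix(features)
  b <- qr.coef(qrG, Y[fit_rows, target, drop = FALSE])
  out <- Y
  out[, target] <- Y[, target, drop = FALSE] - G %*% b
  as_feature_table(out, features$subject_id)
}

#' Permuted-global-covariate control for the decomposition analysis
#'
#' Repeats the residualize-then-classify leave-site-out pipeline with
#' row-order-permuted global features. Because permuted globals carry no
#' subject-specific information, accuracy should not drop substantially;
#' a drop under true (unpermuted) residualization therefore isolates the
#' contribution of the global signal rather than of residualizing against
#' many covariates per se.
#'
#' @param features,phenotypes,atlas as in [run_leave_site_out()]
#' @param B number of repetitions (at least 1)
#' @param seed integer seed; repetition b permutes with seed `seed + b`
#' @param ... further arguments passed to [run_leave_site_out()]
#'   (`family`, `n_trees`, ...)
#' @return numeric vector of B median leave-site-out AUCs
#' @export
permuted_global_control <- function(features, phenotypes, atlas, B = 100,
                                    seed = 1, ...) {
  if (B < 1) stop("B must be at least 1")
  vapply(seq_len(B), function(b) {
    run_leave_site_out(features, phenotypes, atlas,
                       residualize_globals = TRUE,
                       global_perm = seed + 7000L + b, seed = seed, ...)$median_auc
  }, numeric(1))
}

#' Permuted-diagnosis null band for leave-site-out accuracy
#'
#' Re-runs the full pipeline (matching, normalization, classification) with
#' diagnostic labels permuted within each cohort, returning the
#' distribution of median leave-site-out AUCs under the null. With small
#' cohorts the band's mean can sit above 0.5 because matching and training
#' adapt to chance associations.
#'
#' @param features,phenotypes,atlas as in [run_leave_site_out()]
#' @param B number of repetitions (at least 1)
#' @param seed integer seed
#' @param ... further arguments passed to [run_leave_site_out()]
#' @return numeric vector of B median leave-site-out AUCs
#' @export
permuted_diagnosis_control <- function(features, phenotypes, atlas, B = 100,
                                       seed = 1, ...) {
  if (B < 1) stop("B must be at least 1")
  vapply(seq_len(B), function(b) {
    set.seed(seed + 9000L + b)
    ph <- phenotypes
    for (coh in unique(ph$cohort_id)) {
      i <- which(ph$cohort_id == coh)
      ph$diagnosis[i] <- sample(ph$diagnosis[i])
    }
    run_leave_site_out(features, ph, atlas, seed = seed + b, ...)$median_auc
  }, numeric(1))
}

#' Classification from global features alone
#'
#' Evaluates the 22-member covariate-adjusted global set as the only
#' classifier input, both under leave-site-out cross-validation and as
#' whole-dataset out-of-bag accuracy after site-factor correction. A gap
#' between the two quantifies how strongly site-to-site variability affects
#' the global signal.
#'
#' @param features,phenotypes,atlas as in [run_leave_site_out()]
#' @param family regional family supplying the family median
#' @param cohorts training cohorts (default: role `"training"`)
#' @param n_trees forest size
#' @param skip_matching cohort ids passed through unmatched
#' @param seed integer seed
#' @return list with `loso` (full leave-site-out result), `oob_auc`
#'   (whole-dataset out-of-bag AUC) and `median_loso_auc`
#' @export
globals_only_classification <- function(features, phenotypes, atlas,
                                        family = "densitylike",
                                        cohorts = NULL, n_trees = 5000,
                                        skip_matching = character(0),
                                        seed = 1) {
  cohorts <- cohorts %||% unique(phenotypes$cohort_id[phenotypes$role == "training"])
  loso <- run_leave_site_out(features, phenotypes, atlas, cohorts = cohorts,
                             family = family, feature_set = "globals",
                             n_trees = n_trees,
                             skip_matching = skip_matching, seed = seed)
  # whole-dataset analysis: two-step adjustment, then site-factor correction
  matches <- make_matches(phenotypes, cohorts, seed, skip_matching)
  ids <- matched_subjects(matches)
  fx <- features[match(ids, features$subject_id), , drop = FALSE]
  px <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  m1 <- fit_within_dataset_models(fx, px, cohorts, atlas)
  adj <- apply_normalization(m1, fx, px)
  adj <- fit_apply_between_dataset_adjustment(adj, px, cohorts)
  adj <- residualize_site_factor(adj, px)
  glb <- assemble_global_features(adj, atlas, family = family)
  fit <- train_site_stratified_forest(glb, px$diagnosis, px$cohort_id,
                                      n_trees = n_trees, seed = seed)
  ok <- !is.na(fit$oob_scores)
  list(loso = loso, median_loso_auc = loso$median_auc,
       oob_auc = roc_auc(fit$oob_scores[ok], px$diagnosis[ok]))
}

#' Out-of-bag variance in individual features explained by globals
#'
#' Random-forest regression of each feature on the global feature set; the
#' explained variance is `1 - MSE_oob / Var(feature)`, floored at zero for
#' reporting. Inputs are expected on the site-factor-corrected data path
#' used for the univariate analyses.
#'
#' @param features feature table of response features
#' @param globals global feature table over the same subjects
#' @param n_trees trees per regression forest (default 500)
#' @param seed integer seed
#' @return named numeric vector of per-feature explained variance
#' @export
oob_explained_variance <- function(features, globals, n_trees = 500,
                                   seed = 1) {
  if (!setequal(features$subject_id, globals$subject_id))
    stop("feature and global tables cover different subjects")
  globals <- globals[match(features$subject_id, globals$subject_id), ,
                     drop = FALSE]
  G <- feature_matrix(globals)
  Y <- feature_matrix(features)
  vapply(colnames(Y), function(f) {
    y <- Y[, f]
    v <- var(y)
    if (v == 0) {
      warning("zero-variance feature: ", f)
      return(NA_real_)
    }
    set.seed(seed)
    rf <- randomForest::randomForest(x = G, y = y, ntree = n_trees)
    max(0, 1 - mean((rf$predicted - y)^2) / mean((y - mean(y))^2))
  }, numeric(1))
}

#' Correlation between explained variance and structure size
#'
#' Spearman correlation (rank-based, to prevent undue influence of larger
#' structures) between per-feature variance explained by the global set and
#' the feature's mean size in the atlas.
#'
#' @param r2 named vector of per-feature explained variance
#' @param atlas feature atlas supplying `mean_size`
#' @return list with `rho` and `p_value`
#' @export
explained_variance_size_correlation <- function(r2, atlas) {
  r2 <- r2[!is.na(r2)]
  if (length(r2) < 3) stop("at least 3 features required")
  if (sd(r2) == 0) stop("explained-variance vector is constant; correlation undefined")
  sz <- atlas$mean_size[match(names(r2), atlas$feature_id)]
  if (anyNA(sz)) stop("features missing from atlas")
  ct <- suppressWarnings(cor.test(r2, sz, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Association of top-feature principal components with global measures
#'
#' Residualizes the features against diagnosis, standardizes them, extracts
#' the first principal component of each top-feature set (density-like and
#' surface-like), and reports: variance explained by each PC1, the PC1-PC1
#' correlation, correlations of each PC1 with every global feature, and
#' confound checks of each PC1 against ICV, age, age^2, sex, scanner
#' vendor, field strength and site.
#'
#' @param features covariate-adjusted feature table (site-factor-corrected
#'   data path)
#' @param globals global feature table over the same subjects
#' @param phenotypes phenotype table aligned with `features`
#' @param top_density,top_surface character vectors of top feature ids per
#'   family (nonempty)
#' @return list with `var_explained`, `pc_correlation` (estimate and
#'   p-value), `global_correlations` (data.frame), `confounds` (data.frame
#'   of per-covariate association p-values per PC), and the PC score
#'   vectors
#' @export
top_feature_pc_global_association <- function(features, globals, phenotypes,
                                              top_density, top_surface) {
  if (!length(top_density) || !length(top_surface))
    stop("both top sets must be nonempty")
  phenotypes <- check_alignment(features, phenotypes)
  globals <- globals[match(features$subject_id, globals$subject_id), ,
                     drop = FALSE]
  Y <- feature_matrix(features)
  dx <- as.numeric(phenotypes$diagnosis == "case")
  Yr <- apply(Y, 2, function(y) lm.fit(cbind(1, dx), y)$residuals)
  Ys <- scale(Yr)

  pc1 <- function(set) {
    if (length(set) == 1) {
      warning("top set of size 1; PC1 is the standardized feature itself")
      return(list(scores = Ys[, set], var_explained = 1))
    }
    pr <- prcomp(Ys[, set, drop = FALSE], center = FALSE, scale. = FALSE)
    s <- pr$x[, 1]
    if (cor(s, rowMeans(Ys[, set, drop = FALSE])) < 0) s <- -s
    list(scores = s, var_explained = pr$sdev[1]^2 / sum(pr$sdev^2))
  }
  pd <- pc1(intersect(top_density, colnames(Ys)))
  ps <- pc1(intersect(top_surface, colnames(Ys)))
  ct <- cor.test(pd$scores, ps$scores)

  G <- feature_matrix(globals)
  gc <- do.call(rbind, lapply(colnames(G), function(g) {
    cd <- cor.test(pd$scores, G[, g]); cs <- cor.test(ps$scores, G[, g])
    data.frame(global = g, r_density = unname(cd$estimate),
               p_density = cd$p.value, r_surface = unname(cs$estimate),
               p_surface = cs$p.value, stringsAsFactors = FALSE)
  }))

  confound_p <- function(scores) {
    covs <- list(icv = phenotypes$icv, age = phenotypes$age,
                 age2 = (phenotypes$age - mean(phenotypes$age))^2,
                 sex = factor(phenotypes$sex),
                 vendor = factor(phenotypes$scanner_vendor),
                 field = factor(phenotypes$field_strength),
                 site = factor(phenotypes$cohort_id))
    vapply(covs, function(v) {
      if (is.factor(v)) {
        if (nlevels(droplevels(v)) < 2) return(NA_real_)
        anova(lm(scores ~ v))[1, "Pr(>F)"]
      } else cor.test(scores, v)$p.value
    }, numeric(1))
  }
  confounds <- data.frame(covariate = c("icv", "age", "age2", "sex",
                                        "vendor", "field", "site"),
                          p_density = confound_p(pd$scores),
                          p_surface = confound_p(ps$scores),
                          row.names = NULL, stringsAsFactors = FALSE)

  list(var_explained = c(density = pd$var_explained,
                         surface = ps$var_explained),
       pc_correlation = list(estimate = unname(ct$estimate),
                             p_value = ct$p.value),
       global_correlations = gc, confounds = confounds,
       pc_scores = data.frame(subject_id = features$subject_id,
                              pc_density = pd$scores, pc_surface = ps$scores))
}
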
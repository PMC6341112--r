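# Design matrix for the within-dataset step: intercept, centered age,
# centered age squared, sex (M = 1), ICV. Age is centered at the pooled
# training mean before squaring to decorrelate the linear and quadratic
# terms; this changes conditioning only, not the residuals.
step1_design <- function(ph, age_center, icv_center) {
  miss <- !complete.cases(ph[, c("age", "sex", "icv")])
  if (any(miss))
    stop("missing covariate value for subject(s): ",
         paste(ph$subject_id[miss], collapse = ", "))
  a <- ph$age - age_center
  cbind(intercept = 1, age = a, age2 = a^2,
        sex = as.numeric(ph$sex == "M"), icv = ph$icv - icv_center)
}

model_features <- function(features, atlas) {
  fn <- setdiff(names(features), "subject_id")
  unknown <- setdiff(fn, atlas$feature_id)
  if (length(unknown))
    stop("feature column(s) absent from atlas: ", paste(unknown, collapse = ", "))
  meta <- atlas[match(fn, atlas$feature_id), ]
  fn[meta$measure != "icv"]
}

#' Fit within-dataset normalization models
#'
#' Step one of the two-step covariate normalization. For every feature, one
#' linear model per training cohort regresses the feature on age, age^2,
#' sex, and ICV (the ICV term is omitted for thickness-measure features);
#' the per-cohort coefficients are then averaged arithmetically into a
#' single final model per feature. Only subjects from `train_cohorts` enter
#' any design matrix; if the phenotype table declares test cohorts (see
#' [declare_test_cohorts()]), an overlap raises an error.
#'
#' @param features feature table (matched training subjects)
#' @param phenotypes phenotype table aligned with `features`
#' @param train_cohorts cohorts to fit on
#' @param atlas feature atlas (identifies thickness features and the ICV
#'   column)
#' @return object of class `norm_model`: coefficient matrix (features x
#'   terms, ICV coefficient `NA` for thickness features), covariate centers,
#'   fit provenance
#' @export
fit_within_dataset_models <- function(features, phenotypes, train_cohorts,
                                      atlas) {
  assert_no_test_subjects(phenotypes, train_cohorts, "within-dataset normalization")
  phenotypes <- check_alignment(features, phenotypes)
  keep <- phenotypes$cohort_id %in% train_cohorts
  if (!any(keep)) stop("no subjects in the requested training cohorts")
  ph <- phenotypes[keep, ]; Y <- feature_matrix(features)[keep, , drop = FALSE]

  fn <- model_features(features, atlas)
  thick <- atlas$feature_id[atlas$measure == "thickness"]
  age_center <- mean(ph$age); icv_center <- mean(ph$icv)

  terms <- c("intercept", "age", "age2", "sex", "icv")
  acc <- array(NA_real_, dim = c(length(fn), length(terms), length(train_cohorts)),
               dimnames = list(fn, terms, train_cohorts))
  for (coh in train_cohorts) {
    rows <- ph$cohort_id == coh
    X <- step1_design(ph[rows, ], age_center, icv_center)
    keep_col <- apply(X[, -1, drop = FALSE], 2, function(v) sd(v) > 0)
    if (!all(keep_col))
      warning(sprintf("cohort %s: constant covariate(s) %s dropped from its model",
                      coh, paste(names(keep_col)[!keep_col], collapse = ", ")))
    Xc <- X[, c(TRUE, keep_col), drop = FALSE]
    b <- qr.coef(qr(Xc), Y[rows, fn, drop = FALSE])
    acc[, colnames(Xc), coh] <- t(b)
    # thickness features: refit without the ICV term
    th <- intersect(fn, thick)
    if (length(th) && "icv" %in% colnames(Xc)) {
      Xt <- Xc[, setdiff(colnames(Xc), "icv"), drop = FALSE]
      bt <- qr.coef(qr(Xt), Y[rows, th, drop = FALSE])
      acc[th, , coh] <- NA
      acc[th, colnames(Xt), coh] <- t(bt)
    }
  }
  coefs <- apply(acc, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  # a term dropped in only some cohorts is still part of the model: treat
  # the missing cohort coefficient as absent from the average, but a term
  # absent everywhere stays NA (thickness/ICV by construction)
  coefs[is.na(coefs[, "intercept"]), "intercept"] <- 0
  structure(list(coef = coefs, age_center = age_center,
                 icv_center = icv_center, fit_cohorts = train_cohorts,
                 step = "within_dataset"),
            class = "norm_model")
}

#' Apply a within-dataset normalization model
#'
#' Replaces each feature by its residual (observed minus model prediction)
#' and afterwards appends ICV as an additional feature column, mirroring the
#' training-time treatment of test data: the model is fit on training
#' cohorts only and applied unchanged everywhere.
#'
#' @param model a `norm_model` from [fit_within_dataset_models()]
#' @param features feature table (any subjects)
#' @param phenotypes phenotype table aligned with `features`
#' @return residualized feature table with an `icv` column appended
#' @export
apply_normalization <- function(model, features, phenotypes) {
  stopifnot(inherits(model, "norm_model"))
  phenotypes <- check_alignment(features, phenotypes)
  fn <- rownames(model$coef)
  present <- setdiff(names(features), c("subject_id", "icv"))
  if (!all(present %in% fn))
    stop("model does not cover feature(s): ",
         paste(setdiff(present, fn), collapse = ", "))
  X <- step1_design(phenotypes, model$age_center, model$icv_center)
  B <- model$coef[present, , drop = FALSE]
  B[is.na(B)] <- 0
  Y <- feature_matrix(features)[, present, drop = FALSE]
  R <- Y - X %*% t(B)
  out <- as_feature_table(R, features$subject_id)
  out$icv <- phenotypes$icv
  out
}

#' Fit and apply the between-dataset adjustment
#'
#' Step two of the normalization: linear models on scanner vendor and field
#' strength (reference-coded dummies), fit on training cohorts only and
#' applied to residualize training and test data alike. A vendor or
#' field-strength level present only in test data is predicted with the
#' reference-level effect, with a warning.
#'
#' @param features within-dataset residualized feature table (training and
#'   test subjects)
#' @param phenotypes phenotype table aligned with `features`
#' @param train_cohorts cohorts whose subjects may enter the fit
#' @param fit_subjects optional subject ids restricting the fit further
#'   (e.g. matched subjects only)
#' @return feature table of residuals, same shape as the input
#' @export
fit_apply_between_dataset_adjustment <- function(features, phenotypes,
                                                 train_cohorts,
                                                 fit_subjects = NULL) {
  assert_no_test_subjects(phenotypes, train_cohorts, "between-dataset adjustment")
  phenotypes <- check_alignment(features, phenotypes)
  train <- phenotypes$cohort_id %in% train_cohorts
  if (!is.null(fit_subjects)) train <- train & phenotypes$subject_id %in% fit_subjects
  if (!any(train)) stop("no training subjects for between-dataset adjustment")

  v_lev <- unique(phenotypes$scanner_vendor[train])
  f_lev <- unique(phenotypes$field_strength[train])
  unseen <- !(phenotypes$scanner_vendor %in% v_lev) |
            !(phenotypes$field_strength %in% f_lev)
  if (any(unseen))
    warning(sprintf("%d subject(s) carry vendor/field levels absent from training; using reference-level prediction",
                    sum(unseen)))
  dummies <- function(x, lev) {
    if (length(lev) < 2) return(NULL)
    m <- sapply(lev[-1], function(l) as.numeric(x == l))
    if (is.null(dim(m))) m <- matrix(m, ncol = length(lev) - 1)
    m
  }
  X <- cbind(intercept = rep(1, nrow(phenotypes)),
             dummies(phenotypes$scanner_vendor, v_lev),
             dummies(phenotypes$field_strength, f_lev))
  Y <- feature_matrix(features)
  b <- qr.coef(qr(X[train, , drop = FALSE]), Y[train, , drop = FALSE])
  b[is.na(b)] <- 0
  as_feature_table(Y - X %*% b, features$subject_id)
}

#' Set per-feature means of a test cohort to zero
#'
#' Centers every feature within the given test cohort at zero, leaving all
#' other subjects untouched. For training data this is already (near)
#' fulfilled by the residualization; applying it to the test cohort removes
#' residual cross-site mean shifts at the cost of requiring test-site data
#' in aggregate. Idempotent and exact.
#'
#' @param features feature table
#' @param phenotypes phenotype table aligned with `features`
#' @param test_cohort cohort id to center
#' @return feature table with the test cohort centered
#' @export
center_test_features <- function(features, phenotypes, test_cohort) {
  phenotypes <- check_alignment(features, phenotypes)
  rows <- phenotypes$cohort_id == test_cohort
  if (!any(rows)) stop("unknown test cohort: ", test_cohort)
  Y <- feature_matrix(features)
  Y[rows, ] <- sweep(Y[rows, , drop = FALSE], 2,
                     colMeans(Y[rows, , drop = FALSE]))
  as_feature_table(Y, features$subject_id)
}

#' Residualize features against site and vendor factors
#'
#' Whole-dataset correction used for univariate analyses and out-of-bag
#' evaluation on the pooled data (not in leave-site-out mode): every feature
#' is residualized against recruitment-site and scanner-vendor factors
#' jointly via linear models fit on all supplied data. Factor levels aliased
#' with site (e.g. vendor when each site has exactly one vendor) are dropped
#' automatically.
#'
#' @param features feature table
#' @param phenotypes phenotype table aligned with `features`
#' @return residualized feature table
#' @export
residualize_site_factor <- function(features, phenotypes) {
  phenotypes <- check_alignment(features, phenotypes)
  site <- factor(phenotypes$cohort_id)
  vendor <- factor(phenotypes$scanner_vendor)
  if (nlevels(site) == 1 && nlevels(vendor) == 1) {
    Y <- feature_matrix(features)
    return(as_feature_table(sweep(Y, 2, colMeans(Y)), features$subject_id))
  }
  X <- model.matrix(~ site + vendor)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    if (any(grepl("^vendor", dropped)))
      warning("vendor factor aliased with site; redundant column(s) dropped: ",
              paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  Y <- feature_matrix(features)
  as_feature_table(Y - X %*% qr.coef(qrX, Y), features$subject_id)
}
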
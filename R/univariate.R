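#' Per-feature case-control t-tests
#'
#' Two-sample Student's t-test (pooled variance by default; Welch available
#' behind a flag) per feature. Inputs are expected on the residualized,
#' site-factor-corrected data path so results are comparable with the
#' machine-learning feature importances.
#'
#' @param features feature table
#' @param labels `"case"`/`"control"` vector
#' @param var_equal pooled-variance (classical) t-test if `TRUE` (default);
#'   Welch otherwise
#' @return data.frame (feature_id, t, p, mean_case, mean_control)
#' @export
feature_ttests <- function(features, labels, var_equal = TRUE) {
  is_case <- case_logical(labels)
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    stop("both classes need at least 2 subjects")
  Y <- feature_matrix(features)
  res <- lapply(colnames(Y), function(f) {
    a <- Y[is_case, f]; b <- Y[!is_case, f]
    if (var(a) == 0 && var(b) == 0) {
      warning("zero pooled variance for feature ", f, "; p undefined")
      return(data.frame(feature_id = f, t = NA_real_, p = NA_real_,
                        mean_case = mean(a), mean_control = mean(b),
                        stringsAsFactors = FALSE))
    }
    tt <- t.test(a, b, var.equal = var_equal)
    data.frame(feature_id = f, t = unname(tt$statistic), p = tt$p.value,
               mean_case = mean(a), mean_control = mean(b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Benjamini-Hochberg adjustment within feature families
#'
#' Step-up false-discovery-rate adjustment applied independently within
#' each feature family (the multiple-testing burden is controlled per
#' family, not jointly).
#'
#' @param pvalues numeric p-values in `[0, 1]` (`NA` allowed, passed
#'   through)
#' @param family_labels family label per p-value (single family if omitted)
#' @return numeric q-values, same order as the input
#' @export
bh_adjust <- function(pvalues, family_labels = NULL) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (is.null(family_labels)) family_labels <- rep("all", length(pvalues))
  stopifnot(length(family_labels) == length(pvalues))
  q <- rep(NA_real_, length(pvalues))
  for (fam in unique(family_labels)) {
    i <- which(family_labels == fam)
    q[i] <- p.adjust(pvalues[i], method = "BH")
  }
  q
}

#' Univariate case-control analysis with per-family FDR control
#'
#' Runs [feature_ttests()] and [bh_adjust()] over the regional features,
#' labelling each result with its family and analysis stage.
#'
#' @param features feature table (residualized data path)
#' @param labels `"case"`/`"control"` vector
#' @param atlas feature atlas supplying the family labels
#' @param stage analysis stage label, `"pre_global"` or `"post_global"`
#' @param var_equal see [feature_ttests()]
#' @return data.frame (feature_id, family, stage, t, p, q)
#' @export
univariate_analysis <- function(features, labels, atlas,
                                stage = c("pre_global", "post_global"),
                                var_equal = TRUE) {
  stage <- match.arg(stage)
  res <- feature_ttests(features, labels, var_equal = var_equal)
  fam <- atlas$family[match(res$feature_id, atlas$feature_id)]
  res$family <- ifelse(is.na(fam), "other", fam)
  res$stage <- stage
  res$q <- bh_adjust(res$p, res$family)
  res[, c("feature_id", "family", "stage", "t", "p", "q",
          "mean_case", "mean_control")]
}
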
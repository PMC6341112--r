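`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats coef cor cor.test lm lm.fit median model.matrix p.adjust
#'   pnorm prcomp predict qr qr.coef quantile rbinom rnorm runif sd setNames
#'   t.test var glm binomial as.formula anova complete.cases
#' @importFrom utils head read.delim write.table
NULL

# feature-table helpers ------------------------------------------------------

feature_matrix <- function(features) {
  stopifnot(is.data.frame(features), "subject_id" %in% names(features))
  m <- as.matrix(features[, setdiff(names(features), "subject_id"), drop = FALSE])
  rownames(m) <- features$subject_id
  storage.mode(m) <- "double"
  m
}

as_feature_table <- function(m, subject_id = rownames(m)) {
  data.frame(subject_id = subject_id, as.data.frame(m, check.names = FALSE),
             check.names = FALSE, row.names = NULL)
}

check_alignment <- function(features, phenotypes) {
  if (!identical(features$subject_id, phenotypes$subject_id)) {
    if (!setequal(features$subject_id, phenotypes$subject_id))
      stop("feature and phenotype tables cover different subjects")
    phenotypes <- phenotypes[match(features$subject_id, phenotypes$subject_id), ]
  }
  phenotypes
}

# Declare cohorts as held-out test data. Downstream fitting functions refuse
# to include any subject from a declared test cohort in a design matrix.
#' Declare held-out test cohorts on a phenotype table
#'
#' Marks one or more cohorts as test data. Any model-fitting step in the
#' package that receives a phenotype table carrying this declaration will
#' raise an error if asked to fit on subjects from a declared cohort,
#' providing an assertable leakage guard for leave-site-out analyses.
#'
#' @param phenotypes phenotype table
#' @param cohorts character vector of cohort ids to hold out
#' @return the phenotype table with a `test_cohorts` attribute set
#' @export
declare_test_cohorts <- function(phenotypes, cohorts) {
  stopifnot(all(cohorts %in% phenotypes$cohort_id))
  attr(phenotypes, "test_cohorts") <- cohorts
  phenotypes
}

assert_no_test_subjects <- function(phenotypes, fit_cohorts, stage) {
  held <- attr(phenotypes, "test_cohorts")
  if (is.null(held)) return(invisible(TRUE))
  bad <- intersect(fit_cohorts, held)
  if (length(bad))
    stop(sprintf("leakage in %s: declared test cohort(s) %s present in fitting set",
                 stage, paste(bad, collapse = ", ")))
  invisible(TRUE)
}

audit_entry <- function(stage, held_out, cohorts, subject_ids) {
  list(stage = stage, held_out = held_out, cohorts = cohorts,
       subjects = subject_ids, n = length(subject_ids))
}

#' Verify a leave-site-out audit log is leakage-free
#'
#' Checks every recorded fitting stage of a leave-site-out run: no subject
#' belonging to the held-out cohort of a fold may appear among the subjects
#' used for matching, normalization, tuning or classifier training in that
#' fold.
#'
#' @param result object returned by [run_leave_site_out()]
#' @param phenotypes the phenotype table the run was based on
#' @return `TRUE` invisibly; stops with a message naming the offending stage
#'   if a leak is found
#' @export
verify_no_leakage <- function(result, phenotypes) {
  stopifnot(!is.null(result$audit))
  for (e in result$audit) {
    held_subj <- phenotypes$subject_id[phenotypes$cohort_id %in% e$held_out]
    bad <- intersect(e$subjects, held_subj)
    if (length(bad))
      stop(sprintf("leakage detected at stage '%s' (held-out %s): %d held-out subject(s) used",
                   e$stage, e$held_out, length(bad)))
  }
  invisible(TRUE)
}
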
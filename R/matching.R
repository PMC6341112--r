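#' Propensity-score match cases to controls within one cohort
#'
#' Fits a logistic propensity model of case status on age and sex within the
#' given cohort and pairs each case with the nearest unused control on the
#' logit of the propensity score (greedy nearest neighbour without
#' replacement, cases processed in seeded random order). Controls left
#' unmatched are reported so they can be retained for validation. Cohorts
#' flagged `skip_matching` pass through unmatched, keeping all subjects in
#' the analysis set (used when a cohort has fewer controls than cases and no
#' case-control covariate imbalance).
#'
#' If the propensity model separates the classes perfectly, a warning is
#' issued and matching falls back to a standardized Euclidean distance on
#' (age, sex).
#'
#' @param phenotypes phenotype table
#' @param cohort_id cohort to match within
#' @param seed integer seed for the case processing order
#' @param skip_matching if `TRUE`, no pairs are formed and all subjects are
#'   retained
#' @return list of class `matched_cohort` with elements `cohort_id`,
#'   `pairs` (data.frame of case/control subject ids), `unmatched_controls`,
#'   `unmatched_cases`, `skipped`
#' @export
propensity_match <- function(phenotypes, cohort_id, seed = 1,
                             skip_matching = FALSE) {
  ph <- phenotypes[phenotypes$cohort_id == cohort_id, , drop = FALSE]
  if (nrow(ph) == 0) stop("unknown cohort: ", cohort_id)
  if (skip_matching) {
    out <- list(cohort_id = cohort_id,
                pairs = data.frame(case = character(0), control = character(0)),
                unmatched_controls = ph$subject_id[ph$diagnosis == "control"],
                unmatched_cases = ph$subject_id[ph$diagnosis == "case"],
                skipped = TRUE)
    class(out) <- "matched_cohort"
    return(out)
  }
  cases <- ph[ph$diagnosis == "case", , drop = FALSE]
  ctrls <- ph[ph$diagnosis == "control", , drop = FALSE]
  if (nrow(ctrls) == 0) stop("no controls available in cohort ", cohort_id)
  if (nrow(cases) == 0) stop("no cases available in cohort ", cohort_id)

  y <- as.numeric(ph$diagnosis == "case")
  fit <- suppressWarnings(glm(y ~ age + sex, data = ph, family = binomial()))
  lp <- fit$linear.predictors
  separated <- !fit$converged || any(abs(lp) > 15)
  if (separated) {
    warning("degenerate propensity model (near-perfect separation) in cohort ",
            cohort_id, "; falling back to covariate-distance matching")
    a <- (ph$age - mean(ph$age)) / max(sd(ph$age), 1e-8)
    s <- as.numeric(ph$sex == "M")
    s <- (s - mean(s)) / max(sd(s), 1e-8)
    coord <- cbind(a, s)
  } else {
    coord <- cbind(lp)
  }
  rownames(coord) <- ph$subject_id

  set.seed(seed)
  case_order <- sample(cases$subject_id)
  avail <- ctrls$subject_id
  pairs <- matrix(character(0), 0, 2)
  for (cs in case_order) {
    if (!length(avail)) break
    dist <- sqrt(rowSums((coord[avail, , drop = FALSE] -
                          rep(coord[cs, ], each = length(avail)))^2))
    pick <- avail[which.min(dist)]
    pairs <- rbind(pairs, c(cs, pick))
    avail <- setdiff(avail, pick)
  }
  matched_cases <- pairs[, 1]
  out <- list(cohort_id = cohort_id,
              pairs = data.frame(case = pairs[, 1], control = pairs[, 2],
                                 stringsAsFactors = FALSE),
              unmatched_controls = avail,
              unmatched_cases = setdiff(cases$subject_id, matched_cases),
              skipped = FALSE)
  class(out) <- "matched_cohort"
  out
}

#' Subject ids retained in the matched analysis set
#'
#' @param match a `matched_cohort` object (or list of them)
#' @return character vector of subject ids: paired cases and controls, plus
#'   all subjects of cohorts where matching was skipped
#' @export
matched_subjects <- function(match) {
  if (inherits(match, "matched_cohort")) match <- list(match)
  unlist(lapply(match, function(m) {
    if (isTRUE(m$skipped))
      c(m$unmatched_cases, m$unmatched_controls)
    else
      c(m$pairs$case, m$pairs$control)
  }), use.names = FALSE)
}

#' Standardized mean difference of a covariate between cases and controls
#'
#' Balance diagnostic: difference of group means divided by the pooled SD.
#'
#' @param values numeric covariate
#' @param diagnosis vector of `"case"`/`"control"`
#' @return signed SMD
#' @export
standardized_mean_difference <- function(values, diagnosis) {
  a <- values[diagnosis == "case"]; b <- values[diagnosis == "control"]
  sp <- sqrt((var(a) * (length(a) - 1) + var(b) * (length(b) - 1)) /
             (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}
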
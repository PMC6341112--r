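# symmetric square root of a K x K equicorrelation matrix
equicor_sqrt <- function(K, rho) {
  if (K == 1) return(matrix(1, 1, 1))
  S <- matrix(rho, K, K); diag(S) <- 1
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

cohort_plan <- function(config) {
  n_train <- config$n_cohorts
  vd <- config$validation_disorders
  ids <- c(sprintf("train_%02d", seq_len(n_train)),
           if (length(vd)) sprintf("valid_%02d", seq_along(vd)))
  disorders <- c(rep("SZ-like", n_train), vd)
  roles <- c(rep("training", n_train), rep("validation", length(vd)))
  n_coh <- length(ids)
  data.frame(cohort_id = ids, disorder = disorders, role = roles,
             scanner_vendor = c("vendorA", "vendorB", "vendorC")[(seq_len(n_coh) - 1L) %% 3L + 1L],
             field_strength = c("3T", "1.5T")[(seq_len(n_coh) - 1L) %% 2L + 1L],
             stringsAsFactors = FALSE)
}

#' Simulate multi-site case-control morphometry cohorts
#'
#' Generates a feature table, phenotype table and ground-truth record under
#' the package's generative model. Each feature value is the sum of a
#' baseline (the atlas mean size), linear age/age^2/sex/ICV effects, a fixed
#' per-(site, feature) offset, scanner-vendor and field-strength offsets,
#' loadings on correlated latent global factors, a case-control effect
#' (split between a global-factor route and a direct route on informative
#' regional features by `global_mediation`), and Gaussian noise.
#'
#' The diagnosis effect enters the factor model on the independent latent
#' innovations: each of the `K = n_global_factors` innovations is shifted by
#' `global_mediation * effect_d` in cases, so the factor-space separation is
#' `global_mediation * effect_d * sqrt(K)` and every factor-loaded feature
#' shows a positive marginal case-control difference. BD-like validation
#' cases share `bd_share` of the factor shift; ADHD-like cases instead carry
#' a direct effect on a disjoint informative feature set.
#'
#' @param config a [sim_config()] object
#' @param atlas atlas from [build_feature_atlas()] (built from the same
#'   config)
#' @return list with elements `features` (subjects x features data.frame,
#'   first column `subject_id`), `phenotypes`, and `truth` (informative
#'   feature ids, loadings, injected effect sizes and offsets)
#' @export
simulate_cohorts <- function(config, atlas) {
  validate_sim_config(config)
  if (config$global_mediation > 0 && config$n_global_factors == 0)
    stop("global mediation requested but n_global_factors is 0")
  set.seed(bitwXor(as.integer(config$seed), 762538467L))

  sim_atlas <- atlas[!atlas$is_median_placeholder, , drop = FALSE]
  p <- nrow(sim_atlas)
  fid <- sim_atlas$feature_id
  is_icv <- sim_atlas$measure == "icv"
  regional <- !sim_atlas$is_global & !is_icv
  K <- max(config$n_global_factors, 1L)

  # covariate coefficients (per feature; ICV term absent for thickness)
  betas <- cbind(age  = rnorm(p, -0.02, 0.01),
                 age2 = rnorm(p, -5e-4, 5e-4),
                 sex  = rnorm(p, 0, 0.2),
                 icv  = rnorm(p, 0.004, 0.002))
  betas[sim_atlas$measure == "thickness", "icv"] <- 0
  betas[is_icv, ] <- 0
  rownames(betas) <- fid

  # factor loadings: positive, scaled with mean size within (family, measure)
  loadings <- matrix(0, p, K, dimnames = list(fid, NULL))
  if (config$n_global_factors > 0) {
    grp <- paste(sim_atlas$family, sim_atlas$measure)
    lsize <- log(sim_atlas$mean_size)
    sf <- stats::ave(lsize, grp, FUN = function(x)
      if (length(x) > 1 && sd(x) > 0) exp(0.5 * (x - mean(x)) / sd(x)) else rep(1, length(x)))
    l <- ifelse(sim_atlas$is_global, config$global_loading_scale,
                config$loading_scale * sf)
    l[is_icv] <- 0
    a <- matrix(runif(p * K, 0.2, 1), p, K)
    loadings <- l * a / sqrt(rowSums(a^2))
  }
  S <- equicor_sqrt(K, config$factor_cor)

  # informative regional sets (direct effects), disjoint
  reg_ids <- fid[regional]
  n_inf <- min(config$n_regional_informative, length(reg_ids))
  informative_sz <- sort(sample(reg_ids, n_inf))
  informative_adhd <- sort(sample(setdiff(reg_ids, informative_sz),
                                  min(n_inf, length(reg_ids) - n_inf)))

  plan <- cohort_plan(config)
  site_offsets <- matrix(rnorm(nrow(plan) * p, 0, config$site_shift_sd),
                         nrow(plan), p, dimnames = list(plan$cohort_id, fid))
  vendors <- unique(plan$scanner_vendor)
  fields <- unique(plan$field_strength)
  vendor_offsets <- matrix(rnorm(length(vendors) * p, 0, config$vendor_offset_sd),
                           length(vendors), p, dimnames = list(vendors, fid))
  field_offsets <- matrix(rnorm(length(fields) * p, 0, config$field_offset_sd),
                          length(fields), p, dimnames = list(fields, fid))
  site_offsets[, is_icv] <- 0
  vendor_offsets[, is_icv] <- 0
  field_offsets[, is_icv] <- 0

  w <- config$global_mediation
  d <- config$effect_d

  pheno_list <- list(); feat_list <- list()
  for (ci in seq_len(nrow(plan))) {
    coh <- plan[ci, ]
    n_cases <- if (coh$disorder == "control") 0L else config$n_cases
    n_ctrl <- config$n_controls
    n <- n_cases + n_ctrl
    diagnosis <- rep(c("case", "control"), c(n_cases, n_ctrl))
    adolescent <- coh$disorder == "ADHD-like-adolescent"
    age <- if (adolescent) runif(n, 12, 18) else runif(n, 18, 65)
    sex <- ifelse(runif(n) < 0.5, "M", "F")
    icv <- 1400 + 150 * (sex == "M") + rnorm(n, 0, 110)

    z <- matrix(rnorm(n * K), n, K)
    is_case <- diagnosis == "case"
    if (config$n_global_factors > 0) {
      shift <- switch(sub("-adolescent$", "", coh$disorder),
                      "SZ-like" = w * d,
                      "BD-like" = config$bd_share * d,
                      0)
      z[is_case, ] <- z[is_case, , drop = FALSE] + shift
    }
    g <- z %*% S

    X <- matrix(rep(sim_atlas$mean_size, each = n), n, p)
    X <- X + outer(age - 40, betas[, "age"]) +
      outer((age - 40)^2, betas[, "age2"]) +
      outer(as.numeric(sex == "M"), betas[, "sex"]) +
      outer(icv - 1475, betas[, "icv"])
    X <- X + rep(site_offsets[coh$cohort_id, ], each = n)
    X <- X + rep(vendor_offsets[coh$scanner_vendor, ], each = n)
    X <- X + rep(field_offsets[coh$field_strength, ], each = n)
    if (config$n_global_factors > 0) X <- X + g %*% t(loadings)
    # direct (non-mediated) case effects
    if (any(is_case)) {
      if (coh$disorder == "SZ-like" && (1 - w) > 0 && length(informative_sz))
        X[is_case, match(informative_sz, fid)] <-
          X[is_case, match(informative_sz, fid), drop = FALSE] +
          (1 - w) * d * config$noise_sd
      if (grepl("^ADHD-like", coh$disorder) && length(informative_adhd))
        X[is_case, match(informative_adhd, fid)] <-
          X[is_case, match(informative_adhd, fid), drop = FALSE] +
          config$adhd_effect_d * config$noise_sd
    }
    X <- X + matrix(rnorm(n * p, 0, config$noise_sd), n, p)
    X[, is_icv] <- icv

    sid <- sprintf("%s_s%04d", coh$cohort_id, seq_len(n))
    pheno_list[[ci]] <- data.frame(
      subject_id = sid, diagnosis = diagnosis,
      disorder = ifelse(is_case, coh$disorder, "control"),
      cohort_id = coh$cohort_id, role = coh$role, age = age, sex = sex,
      icv = icv, scanner_vendor = coh$scanner_vendor,
      field_strength = coh$field_strength, stringsAsFactors = FALSE)
    colnames(X) <- fid
    feat_list[[ci]] <- data.frame(subject_id = sid, X,
                                  check.names = FALSE, row.names = NULL)
  }

  phenotypes <- do.call(rbind, pheno_list)
  features <- do.call(rbind, feat_list)
  rownames(phenotypes) <- rownames(features) <- NULL

  # analytic marginal case-control effect for the global route (SZ-like)
  factor_shift_per <- w * d * sqrt(1 + (K - 1) * config$factor_cor)
  Sigma <- S %*% S
  fac_var <- rowSums((loadings %*% Sigma) * loadings)
  marg_shift <- factor_shift_per * rowSums(loadings)
  marg_shift[fid %in% informative_sz] <-
    marg_shift[fid %in% informative_sz] + (1 - w) * d * config$noise_sd
  marg_sd <- sqrt(fac_var + config$noise_sd^2)
  marg_sd[is_icv] <- NA
  truth <- list(informative_sz = informative_sz,
                informative_adhd = informative_adhd,
                loadings = loadings, factor_sqrt = S,
                betas = betas, site_offsets = site_offsets,
                vendor_offsets = vendor_offsets, field_offsets = field_offsets,
                marginal_shift = setNames(marg_shift, fid),
                marginal_d = setNames(marg_shift / marg_sd, fid),
                config = config)

  list(features = features, phenotypes = phenotypes, truth = truth)
}
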
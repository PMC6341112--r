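#' Simulation configuration for synthetic multi-site cohorts
#'
#' Builds the configuration object consumed by [build_feature_atlas()] and
#' [simulate_cohorts()]. The defaults encode the study conditions the
#' package's analyses assume: four matched case-control training cohorts,
#' two regional feature families (122 density-like and 152 surface-like
#' features plus total intracranial volume), per-site mean shifts,
#' scanner-vendor and field-strength offsets, and a set of correlated
#' latent global factors that can mediate all, part, or none of the
#' case-control effect.
#'
#' @param n_cohorts number of matched case-control training cohorts
#' @param n_cases,n_controls cases and controls per training cohort (extra
#'   controls are left unmatched and can be retained for validation)
#' @param validation_disorders character vector defining the validation
#'   cohorts; entries from `"control"`, `"BD-like"` (cases sharing the
#'   global-factor alteration), `"ADHD-like"` (cases with an orthogonal
#'   regional signal), `"ADHD-like-adolescent"` (same, ages 12-18)
#' @param n_densitylike,n_surfacelike regional feature counts per family
#' @param n_global size of the global summary feature set, counting the two
#'   per-subject median placeholders (0 disables globals; default 22)
#' @param effect_d total case-control effect size (Cohen's d scale)
#' @param global_mediation fraction of `effect_d` routed through the latent
#'   global factors (in `[0, 1]`); the remainder acts directly on
#'   `n_regional_informative` regional features
#' @param n_regional_informative number of regional features carrying the
#'   direct (non-mediated) case-control effect
#' @param n_global_factors number of latent global factors
#' @param factor_cor equicorrelation of the observed global factors
#' @param loading_scale overall magnitude of regional-feature loadings onto
#'   the global factors (loadings scale with feature mean size)
#' @param global_loading_scale loading magnitude of the designated global
#'   summary features (large: they are near-noiseless factor readouts)
#' @param site_shift_sd SD of per-(site, feature) mean offsets
#' @param vendor_offset_sd,field_offset_sd SD of per-(vendor, feature) and
#'   per-(field-strength, feature) offsets
#' @param noise_sd residual (measurement) noise SD, the unit of the
#'   simulated feature scale
#' @param bd_share fraction of the global-factor shift shared by BD-like
#'   cases
#' @param adhd_effect_d direct effect size on the ADHD-like informative set
#' @param seed integer seed; fully determines the simulated tables
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_cohorts = 4,
                       n_cases = 90,
                       n_controls = 110,
                       validation_disorders = c("control", "BD-like",
                                                "ADHD-like", "ADHD-like-adolescent"),
                       n_densitylike = 122,
                       n_surfacelike = 152,
                       n_global = 22,
                       effect_d = 0.8,
                       global_mediation = 1,
                       n_regional_informative = 10,
                       n_global_factors = 6,
                       factor_cor = 0.3,
                       loading_scale = 1,
                       global_loading_scale = 6,
                       site_shift_sd = 0.4,
                       vendor_offset_sd = 0.3,
                       field_offset_sd = 0.3,
                       noise_sd = 1,
                       bd_share = 0.8,
                       adhd_effect_d = 0.5,
                       seed = 1) {
  cfg <- list(n_cohorts = n_cohorts, n_cases = n_cases, n_controls = n_controls,
              validation_disorders = validation_disorders,
              n_densitylike = n_densitylike, n_surfacelike = n_surfacelike,
              n_global = n_global, effect_d = effect_d,
              global_mediation = global_mediation,
              n_regional_informative = n_regional_informative,
              n_global_factors = n_global_factors, factor_cor = factor_cor,
              loading_scale = loading_scale,
              global_loading_scale = global_loading_scale,
              site_shift_sd = site_shift_sd,
              vendor_offset_sd = vendor_offset_sd,
              field_offset_sd = field_offset_sd, noise_sd = noise_sd,
              bd_share = bd_share, adhd_effect_d = adhd_effect_d, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cohorts >= 1, cfg$n_cases >= 1, cfg$n_controls >= 1)
  if (cfg$n_densitylike < 1 || cfg$n_surfacelike < 1)
    stop("each feature family must contain at least one feature")
  if (!(cfg$n_global == 0 || (cfg$n_global >= 8 && cfg$n_global <= 22)))
    stop("n_global must be 0 or between 8 and 22")
  if (cfg$global_mediation < 0 || cfg$global_mediation > 1)
    stop("global_mediation must lie in [0, 1]")
  if (cfg$global_mediation > 0 && cfg$n_global_factors == 0)
    stop("global mediation requested but n_global_factors is 0")
  stopifnot(cfg$site_shift_sd >= 0, cfg$vendor_offset_sd >= 0,
            cfg$field_offset_sd >= 0, cfg$noise_sd >= 0)
  invisible(cfg)
}

# Candidate designated global summary features, ordered so that truncating
# the list still leaves ventricle members available. The two bilateral
# aggregates are redundant with their unilateral pairs and are dropped
# during assembly (redundancy rule).
global_candidates <- function() {
  d <- data.frame(
    feature_id = c("total_gm", "total_wm", "total_csf",
                   "hemisphere_gm_lh", "hemisphere_gm_rh",
                   "lateral_ventricle_lh", "lateral_ventricle_rh",
                   "third_ventricle", "fourth_ventricle",
                   "subcortical_gm", "brainstem", "supratentorial",
                   "mean_thickness_lh", "mean_thickness_rh",
                   "total_surface_area_lh", "total_surface_area_rh",
                   "cerebellum_lh", "cerebellum_rh",
                   "inferior_lateral_ventricle_lh", "inferior_lateral_ventricle_rh",
                   # bilateral duplicates of unilateral members above
                   "hemisphere_gm_bilateral", "mean_thickness_bilateral"),
    measure = c("volume", "volume", "volume", "volume", "volume",
                "volume", "volume", "volume", "volume", "volume", "volume",
                "volume", "thickness", "thickness", "area", "area",
                "volume", "volume", "volume", "volume", "volume", "thickness"),
    laterality = c("none", "none", "none", "left", "right", "left", "right",
                   "none", "none", "none", "none", "none", "left", "right",
                   "left", "right", "left", "right", "left", "right",
                   "bilateral", "bilateral"),
    is_ventricle = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                     TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                     FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  d
}

drop_redundant_bilateral <- function(atlas) {
  bil <- atlas$laterality == "bilateral"
  if (!any(bil)) return(atlas)
  stem <- sub("_(lh|rh|bilateral)$", "", atlas$feature_id)
  keep <- rep(TRUE, nrow(atlas))
  for (i in which(bil)) {
    pair <- atlas$feature_id[stem == stem[i] & atlas$laterality %in% c("left", "right")]
    if (length(pair) >= 2) keep[i] <- FALSE
  }
  atlas[keep, , drop = FALSE]
}

#' Build a synthetic feature atlas
#'
#' Constructs the per-feature metadata table for the simulator: two regional
#' feature families (density-like grey-matter measures and surface-like
#' thickness/area/volume measures), one total-intracranial-volume feature, a
#' set of designated global summary features (total grey matter, hemisphere
#' aggregates, ventricles, ...) flagged `is_global`, and two placeholder
#' rows for the per-subject ventricle median and family median that are
#' materialized by [assemble_global_features()]. Bilateral global aggregates
#' are removed when both unilateral counterparts exist.
#'
#' @param config a [sim_config()] object
#' @return data.frame with columns `feature_id`, `family`, `measure`,
#'   `laterality`, `is_global`, `is_ventricle`, `is_median_placeholder`,
#'   `mean_size`
#' @export
build_feature_atlas <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  dens_lat <- rep(c("left", "right"), length.out = config$n_densitylike)
  dens <- data.frame(
    feature_id = sprintf("dens_region_%03d_%s", seq_len(config$n_densitylike),
                         ifelse(dens_lat == "left", "lh", "rh")),
    family = "densitylike", measure = "density", laterality = dens_lat,
    is_global = FALSE, is_ventricle = FALSE, is_median_placeholder = FALSE,
    stringsAsFactors = FALSE)

  surf_measure <- rep(c("thickness", "area", "volume"),
                      length.out = config$n_surfacelike)
  surf_lat <- rep(c("left", "left", "left", "right", "right", "right"),
                  length.out = config$n_surfacelike)
  surf <- data.frame(
    feature_id = sprintf("surf_region_%03d_%s_%s",
                         seq_len(config$n_surfacelike), surf_measure,
                         ifelse(surf_lat == "left", "lh", "rh")),
    family = "surfacelike", measure = surf_measure, laterality = surf_lat,
    is_global = FALSE, is_ventricle = FALSE, is_median_placeholder = FALSE,
    stringsAsFactors = FALSE)

  icv <- data.frame(feature_id = "icv", family = NA_character_,
                    measure = "icv", laterality = "none", is_global = FALSE,
                    is_ventricle = FALSE, is_median_placeholder = FALSE,
                    stringsAsFactors = FALSE)

  atlas <- rbind(dens, surf, icv)

  if (config$n_global > 0) {
    n_designated <- config$n_global - 2L
    glob <- global_candidates()
    glob <- drop_redundant_bilateral(cbind(glob,
      family = "surfacelike", is_global = TRUE, is_median_placeholder = FALSE,
      stringsAsFactors = FALSE))
    if (n_designated > nrow(glob))
      stop("n_global exceeds the available designated global candidates")
    glob <- glob[seq_len(n_designated),
                 c("feature_id", "family", "measure", "laterality",
                   "is_global", "is_ventricle", "is_median_placeholder")]
    if (!any(glob$is_ventricle))
      stop("global set must include at least one ventricle feature")
    med <- data.frame(
      feature_id = c("ventricle_median", "family_median"),
      family = NA_character_, measure = "volume", laterality = "none",
      is_global = TRUE, is_ventricle = FALSE, is_median_placeholder = TRUE,
      stringsAsFactors = FALSE)
    atlas <- rbind(atlas, glob, med)
  }

  # population mean scale per feature, lognormal around a measure-typical size
  meanlog <- c(density = log(1), thickness = log(2.5), area = log(2000),
               volume = log(4000), icv = log(1500))
  atlas$mean_size <- exp(rnorm(nrow(atlas), meanlog[atlas$measure], 0.6))
  atlas$mean_size[atlas$measure == "icv"] <- 1500
  atlas$mean_size[atlas$is_global & !atlas$is_median_placeholder] <-
    exp(rnorm(sum(atlas$is_global & !atlas$is_median_placeholder), log(1e5), 0.5))
  atlas$mean_size[atlas$is_median_placeholder] <- NA_real_

  stopifnot(!anyDuplicated(atlas$feature_id),
            sum(atlas$measure == "icv") == 1L)
  rownames(atlas) <- NULL
  atlas
}
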
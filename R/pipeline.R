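config_hash <- function(obj) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(obj, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full experiment graph on a simulated multi-site dataset
#'
#' Orchestrates the analysis flow as one seeded, reproducible command:
#' simulate (or load) the cohorts, propensity-match, apply the two-step
#' normalization, run leave-site-out and within-site classification,
#' external-specificity testing in the validation cohorts, and the
#' univariate analysis before and after global-signal residualization.
#' Emits TSV/JSON artifacts plus a run manifest with the config hash and
#' per-file digests; identical configs produce identical digests.
#'
#' @param config a [sim_config()]; alternatively supply `tables` to skip
#'   simulation
#' @param out_dir output directory (created if needed)
#' @param tables optional list (features, phenotypes, atlas) replacing the
#'   simulation stage
#' @param n_trees forest size for all classifiers in this run
#' @param within_site_perms label permutations per within-site test
#' @param classifier `"forest"` or `"svm"`
#' @param decomposition if `TRUE`, adds the global-signal decomposition
#'   (original / residualized / globals-only leave-site-out AUC)
#' @param seed master seed; all stage seeds derive from it
#' @return the run manifest (invisibly returns the full report as an
#'   attribute)
#' @export
run_experiment <- function(config = sim_config(), out_dir,
                           tables = NULL, n_trees = 500,
                           within_site_perms = 100,
                           classifier = "forest",
                           decomposition = FALSE, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% config$seed
  if (is.null(tables)) {
    atlas <- build_feature_atlas(config)
    sim <- simulate_cohorts(config, atlas)
    tables <- list(features = sim$features, phenotypes = sim$phenotypes,
                   atlas = atlas)
    yaml::write_yaml(unclass(config),
                     file.path(out_dir, "sim_config.yaml"))
  }
  features <- tables$features; phenotypes <- tables$phenotypes
  atlas <- tables$atlas
  write_tsv_table(features, file.path(out_dir, "features.tsv"))
  write_tsv_table(phenotypes, file.path(out_dir, "phenotypes.tsv"))
  write_tsv_table(atlas, file.path(out_dir, "atlas.tsv"))

  train <- unique(phenotypes$cohort_id[phenotypes$role == "training"])
  valid <- setdiff(unique(phenotypes$cohort_id), train)
  report <- list()

  loso <- run_leave_site_out(features, phenotypes, atlas, cohorts = train,
                             classifier = classifier, n_trees = n_trees,
                             seed = seed)
  verify_no_leakage(loso, phenotypes)
  report$leave_site_out <- list(per_site = loso$per_site,
                                median_auc = loso$median_auc,
                                auc_range = loso$auc_range)
  write_tsv_table(loso$scores, file.path(out_dir, "loso_scores.tsv"))

  report$within_site <- lapply(setNames(train, train), function(coh) {
    ws <- run_within_site(features, phenotypes, atlas, coh,
                          n_label_perms = within_site_perms,
                          n_trees = n_trees,
                          perm_n_trees = max(100, n_trees %/% 2),
                          seed = seed)
    list(auc = ws$auc, p_value = ws$p_value)
  })

  if (length(valid)) {
    ext <- run_external_specificity(features, phenotypes, atlas, train,
                                    valid, classifier = classifier,
                                    n_trees = n_trees, seed = seed)
    report$external_specificity <- ext$per_group
    write_tsv_table(ext$scores, file.path(out_dir, "external_scores.tsv"))
  }

  # univariate stages on the site-factor-corrected whole-dataset path
  matches <- make_matches(phenotypes, train, seed)
  ids <- matched_subjects(matches)
  fx <- features[match(ids, features$subject_id), , drop = FALSE]
  px <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  m1 <- fit_within_dataset_models(fx, px, train, atlas)
  adj <- apply_normalization(m1, fx, px)
  adj <- fit_apply_between_dataset_adjustment(adj, px, train)
  adj <- residualize_site_factor(adj, px)
  write_normalization_model(m1, file.path(out_dir, "normalization_model.yaml"))

  uni <- univariate_analysis(adj[, c("subject_id", regional_columns(atlas))],
                             px$diagnosis, atlas, stage = "pre_global")
  if (sum(atlas$is_global) > 0) {
    glb <- assemble_global_features(adj, atlas, family = "surfacelike")
    res <- residualize_against_globals(
      adj[, c("subject_id", regional_columns(atlas))], glb)
    uni <- rbind(uni, univariate_analysis(res, px$diagnosis, atlas,
                                          stage = "post_global"))
  }
  write_tsv_table(uni, file.path(out_dir, "univariate.tsv"))
  report$univariate <- list(
    n_significant_pre = sum(uni$q[uni$stage == "pre_global"] < 0.05,
                            na.rm = TRUE),
    n_significant_post = sum(uni$q[uni$stage == "post_global"] < 0.05,
                             na.rm = TRUE))

  if (decomposition && sum(atlas$is_global) > 0) {
    fam <- "densitylike"
    orig <- run_leave_site_out(features, phenotypes, atlas, cohorts = train,
                               family = fam, n_trees = n_trees, seed = seed)
    resid <- run_leave_site_out(features, phenotypes, atlas, cohorts = train,
                                family = fam, residualize_globals = TRUE,
                                n_trees = n_trees, seed = seed)
    glob <- globals_only_classification(features, phenotypes, atlas,
                                        family = fam, cohorts = train,
                                        n_trees = n_trees, seed = seed)
    report$decomposition <- list(auc_original = orig$median_auc,
                                 auc_residualized = resid$median_auc,
                                 auc_globals_only = glob$median_loso_auc,
                                 oob_auc_globals = glob$oob_auc)
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(config_hash = config_hash(config), seed = seed,
                   package_version = as.character(utils::packageVersion("morphosite")),
                   digests = as.list(setNames(unname(tools::md5sum(files)),
                                              basename(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(manifest, report = report)
}
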
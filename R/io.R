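# TSV table I/O with schema validation --------------------------------------

#' Write feature, phenotype or atlas tables as TSV
#'
#' @param table data.frame to write
#' @param path output path
#' @return the path, invisibly
#' @export
write_tsv_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from TSV
#'
#' @param path TSV path with a header row and a `subject_id` key column
#' @return feature table data.frame
#' @export
read_feature_table <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(d)) stop("feature table lacks subject_id column")
  if (anyDuplicated(d$subject_id))
    stop("duplicate subject ids in feature table: ",
         paste(unique(d$subject_id[duplicated(d$subject_id)]), collapse = ", "))
  non_num <- names(d)[-1][!vapply(d[-1], is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric feature column(s): ", paste(non_num, collapse = ", "))
  d
}

#' Read a phenotype table from TSV
#'
#' @param path TSV path
#' @return phenotype table data.frame
#' @export
read_phenotype_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "diagnosis", "cohort_id", "age", "sex", "icv",
                "scanner_vendor", "field_strength")
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$subject_id))
    stop("duplicate subject ids in phenotype table")
  for (col in c("age", "sex", "icv", "diagnosis")) {
    bad <- is.na(d[[col]])
    if (any(bad))
      stop(sprintf("missing %s for subject(s): %s", col,
                   paste(d$subject_id[bad], collapse = ", ")))
  }
  d
}

#' Read a feature atlas from TSV
#'
#' @param path TSV path
#' @return atlas data.frame
#' @export
read_atlas <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("feature_id", "family", "measure", "laterality", "is_global",
                "is_ventricle", "is_median_placeholder", "mean_size")
  miss <- setdiff(required, names(d))
  if (length(miss)) stop("atlas lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$feature_id)) stop("duplicate feature ids in atlas")
  d
}

#' Load and jointly validate the three input tables
#'
#' Reads the feature, phenotype and atlas TSVs, checks that the two subject
#' tables cover the same subjects and that the atlas covers every feature
#' column, and returns the aligned triple.
#'
#' @param feature_path,phenotype_path,atlas_path TSV paths
#' @return list with `features`, `phenotypes`, `atlas`
#' @export
load_tables <- function(feature_path, phenotype_path, atlas_path) {
  features <- read_feature_table(feature_path)
  phenotypes <- read_phenotype_table(phenotype_path)
  atlas <- read_atlas(atlas_path)
  if (!setequal(features$subject_id, phenotypes$subject_id))
    stop("feature and phenotype tables cover different subjects")
  phenotypes <- phenotypes[match(features$subject_id, phenotypes$subject_id), ]
  rownames(phenotypes) <- NULL
  unknown <- setdiff(names(features)[-1], atlas$feature_id)
  if (length(unknown))
    stop("feature column(s) absent from atlas: ", paste(unknown, collapse = ", "))
  list(features = features, phenotypes = phenotypes, atlas = atlas)
}

# normalization model serialization ------------------------------------------

#' Serialize a normalization model to YAML
#'
#' Writes the per-feature coefficient map with its fit provenance so a
#' train-time model can be shipped and applied at new sites.
#'
#' @param model a `norm_model`
#' @param path output YAML path
#' @return the path, invisibly
#' @export
write_normalization_model <- function(model, path) {
  stopifnot(inherits(model, "norm_model"))
  coefs <- apply(model$coef, 1, function(r) as.list(r[!is.na(r)]),
                 simplify = FALSE)
  yaml::write_yaml(list(step = model$step,
                        fit_cohorts = as.list(model$fit_cohorts),
                        age_center = model$age_center,
                        icv_center = model$icv_center,
                        coefficients = coefs), path, precision = 15)
  invisible(path)
}

#' Read a normalization model from YAML
#'
#' @param path YAML path written by [write_normalization_model()]
#' @return a `norm_model`
#' @export
read_normalization_model <- function(path) {
  y <- yaml::read_yaml(path)
  terms <- c("intercept", "age", "age2", "sex", "icv")
  fn <- names(y$coefficients)
  coefs <- matrix(NA_real_, length(fn), length(terms),
                  dimnames = list(fn, terms))
  for (f in fn) {
    v <- unlist(y$coefficients[[f]])
    coefs[f, names(v)] <- v
  }
  structure(list(coef = coefs, age_center = y$age_center,
                 icv_center = y$icv_center,
                 fit_cohorts = unlist(y$fit_cohorts), step = y$step),
            class = "norm_model")
}
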
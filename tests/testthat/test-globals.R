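adjusted_sim <- function(seed = 7, ...) {
  s <- small_sim(seed = seed, ...)
  train <- unique(s$phenotypes$cohort_id[s$phenotypes$role == "training"])
  m1 <- fit_within_dataset_models(s$features, s$phenotypes, train, s$atlas)
  adj <- apply_normalization(m1, s$features, s$phenotypes)
  adj <- suppressWarnings(
    fit_apply_between_dataset_adjustment(adj, s$phenotypes, train))
  c(s, list(adj = adj, train = train))
}

test_that("the assembled global set has 22 members differing only in the family median", {
  s <- adjusted_sim(seed = 3)
  gd <- assemble_global_features(s$adj, s$atlas, family = "densitylike")
  gs <- assemble_global_features(s$adj, s$atlas, family = "surfacelike")
  expect_equal(ncol(gd) - 1, 22)
  expect_setequal(names(gd), names(gs))
  shared <- setdiff(names(gd), c("subject_id", "family_median"))
  expect_equal(gd[, shared], gs[, shared])
  expect_false(isTRUE(all.equal(gd$family_median, gs$family_median)))
  roles <- attr(gd, "roles")
  expect_equal(sum(roles == "designated"), 20)
})

test_that("median members reduce correctly in degenerate cases", {
  s <- adjusted_sim(seed = 5, n_densitylike = 4, n_surfacelike = 4)
  # all regional density values equal per subject: family median equals them
  adj <- s$adj
  dens <- grep("^dens_", names(adj), value = TRUE)
  for (f in dens) adj[[f]] <- adj[[dens[1]]]
  g <- assemble_global_features(adj, s$atlas, family = "densitylike")
  expect_equal(g$family_median, adj[[dens[1]]])
  # a single ventricle feature: the ventricle median equals it
  cfg8 <- sim_config(n_cases = 10, n_controls = 10, n_global = 8, seed = 2)
  atlas8 <- build_feature_atlas(cfg8)
  vent <- atlas8$feature_id[atlas8$is_global & atlas8$is_ventricle]
  expect_length(vent, 1)
  sim8 <- simulate_cohorts(cfg8, atlas8)
  g8 <- assemble_global_features(sim8$features, atlas8, "densitylike")
  expect_equal(g8$ventricle_median, sim8$features[[vent]])
  # missing designated columns are rejected
  expect_error(assemble_global_features(adj[, 1:4], s$atlas, "densitylike"),
               "missing from table")
})

test_that("residualization against globals removes exactly the spanned part", {
  s <- adjusted_sim(seed = 9, n_densitylike = 6, n_surfacelike = 6)
  g <- assemble_global_features(s$adj, s$atlas, family = "densitylike")
  G <- as.matrix(g[, -1])
  n <- nrow(G)
  # feature inside the span of the globals
  span <- as.numeric(G %*% runif(ncol(G), -1, 1))
  # feature orthogonalized against the globals by construction
  set.seed(1)
  raw <- rnorm(n)
  ortho <- raw - cbind(1, G) %*% qr.coef(qr(cbind(1, G)), raw)
  ft <- data.frame(subject_id = g$subject_id, in_span = span,
                   ortho = as.numeric(ortho))
  out <- residualize_against_globals(ft, g)
  expect_lt(max(abs(out$in_span)), 1e-8)
  expect_equal(out$ortho, ft$ortho, tolerance = 1e-8)
  # residuals orthogonal to every global feature
  expect_lt(max(abs(cor(G, out$in_span + out$ortho))), 1e-6)
  # collinear global columns are dropped with a warning
  g2 <- g; g2$dup <- g2$total_gm
  expect_warning(residualize_against_globals(ft, g2), "collinear")
})

test_that("train-only global residualization leaves test means unconstrained", {
  s <- adjusted_sim(seed = 11, n_densitylike = 6, n_surfacelike = 6)
  g <- assemble_global_features(s$adj, s$atlas, family = "densitylike")
  train_ids <- s$phenotypes$subject_id[s$phenotypes$cohort_id %in%
                                         paste0("train_0", 1:3)]
  dens <- grep("^dens_", names(s$adj), value = TRUE)
  ft <- s$adj[, c("subject_id", dens)]
  out <- residualize_against_globals(ft, g, train_ids = train_ids)
  G <- as.matrix(g[g$subject_id %in% train_ids, -1])
  R <- as.matrix(out[out$subject_id %in% train_ids, -1])
  expect_lt(max(abs(cor(G, R))), 1e-10)
  test_rows <- !out$subject_id %in% train_ids
  expect_gt(max(abs(colMeans(as.matrix(out[test_rows, -1])))), 1e-4)
})

test_that("identity-permuted global control equals the true residualization", {
  s <- small_sim(seed = 13, n_densitylike = 6, n_surfacelike = 6,
                 n_cases = 25, n_controls = 25)
  r_true <- suppressWarnings(
    run_leave_site_out(s$features, s$phenotypes, s$atlas,
                       family = "densitylike", residualize_globals = TRUE,
                       n_trees = 100, seed = 2))
  r_id <- suppressWarnings(
    run_leave_site_out(s$features, s$phenotypes, s$atlas,
                       family = "densitylike", residualize_globals = TRUE,
                       global_perm = "identity", n_trees = 100, seed = 2))
  expect_equal(r_true$per_site$auc, r_id$per_site$auc)
})

test_that("out-of-bag explained variance tracks constructed targets", {
  s <- adjusted_sim(seed = 15, n_densitylike = 6, n_surfacelike = 6,
                    n_cases = 60, n_controls = 60)
  g <- assemble_global_features(s$adj, s$atlas, family = "densitylike")
  set.seed(4)
  base <- as.numeric(scale(g$total_gm))
  n <- length(base)
  ft <- data.frame(subject_id = g$subject_id,
                   noise = rnorm(n),
                   strong = base + rnorm(n, 0, sqrt(1 / 9)))  # R^2 = 0.9
  r2 <- oob_explained_variance(ft, g, n_trees = 300, seed = 5)
  expect_lt(r2["noise"], 0.05)
  expect_gt(r2["strong"], 0.75)
  ft$flat <- 1
  expect_warning(r2f <- oob_explained_variance(ft, g, n_trees = 50, seed = 1),
                 "zero-variance")
  expect_true(is.na(r2f["flat"]))
})

test_that("explained variance correlates with structure size when loadings scale with size", {
  s <- small_sim(seed = 17, n_cases = 80, n_controls = 80,
                 n_densitylike = 40, n_surfacelike = 10,
                 validation_disorders = character(0),
                 loading_scale = 1.5, site_shift_sd = 0)
  train <- paste0("train_0", 1:4)
  m1 <- fit_within_dataset_models(s$features, s$phenotypes, train, s$atlas)
  adj <- apply_normalization(m1, s$features, s$phenotypes)
  g <- assemble_global_features(adj, s$atlas, family = "densitylike")
  dens <- grep("^dens_", names(adj), value = TRUE)
  r2 <- oob_explained_variance(adj[, c("subject_id", dens)], g,
                               n_trees = 150, seed = 6)
  out <- explained_variance_size_correlation(r2, s$atlas)
  expect_gt(out$rho, 0.2)
  expect_error(explained_variance_size_correlation(r2[1:2], s$atlas),
               "at least 3")
  expect_error(explained_variance_size_correlation(
    setNames(rep(0.5, 5), names(r2)[1:5]), s$atlas), "constant")
})

test_that("top-set principal components recover the shared global structure", {
  s <- adjusted_sim(seed = 19, n_densitylike = 20, n_surfacelike = 20,
                    n_cases = 60, n_controls = 60)
  adj <- residualize_site_factor(s$adj, s$phenotypes) |> suppressWarnings()
  g <- assemble_global_features(adj, s$atlas, family = "densitylike")
  td <- grep("^dens_", names(adj), value = TRUE)[1:10]
  ts <- grep("^surf_", names(adj), value = TRUE)[1:10]
  pc <- top_feature_pc_global_association(adj[, c("subject_id", td, ts)], g,
                                          s$phenotypes, td, ts)
  # both families load on the same factors, so the PCs correlate strongly
  expect_gt(pc$pc_correlation$estimate, 0.3)
  expect_equal(nrow(pc$global_correlations), 22)
  # PC1 variance explained equals the leading eigenvalue share
  expect_true(all(pc$var_explained > 1 / 10 & pc$var_explained <= 1))
  expect_equal(nrow(pc$confounds), 7)
  # degenerate one-feature set is flagged
  expect_warning(
    top_feature_pc_global_association(adj[, c("subject_id", td, ts)], g,
                                      s$phenotypes, td[1], ts),
    "size 1")
  expect_error(
    top_feature_pc_global_association(adj[, c("subject_id", td)], g,
                                      s$phenotypes, character(0), ts),
    "nonempty")
})
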
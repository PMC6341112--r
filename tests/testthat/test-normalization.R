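# minimal atlas for hand-built normalization fixtures
tiny_atlas <- function() {
  data.frame(
    feature_id = c("vol_a", "thick_b", "icv"),
    family = c("densitylike", "surfacelike", NA),
    measure = c("volume", "thickness", "icv"),
    laterality = "none", is_global = FALSE, is_ventricle = FALSE,
    is_median_placeholder = FALSE, mean_size = c(100, 2.5, 1500),
    stringsAsFactors = FALSE)
}

tiny_pheno <- function(n, cohort, seed, vendor = "vendorA", field = "3T") {
  set.seed(seed)
  data.frame(subject_id = sprintf("%s_%03d", cohort, seq_len(n)),
             diagnosis = rep(c("case", "control"), length.out = n),
             disorder = "SZ-like", cohort_id = cohort, role = "training",
             age = runif(n, 18, 65), sex = sample(c("M", "F"), n, TRUE),
             icv = rnorm(n, 1475, 100), scanner_vendor = vendor,
             field_strength = field, stringsAsFactors = FALSE)
}

test_that("noiseless linear covariate effects are recovered and removed exactly", {
  ph <- tiny_pheno(50, "c1", seed = 1)
  ft <- data.frame(subject_id = ph$subject_id,
                   vol_a = 2 * ph$age, thick_b = 3 + 0.5 * (ph$sex == "M"),
                   icv = ph$icv)
  m <- fit_within_dataset_models(ft, ph, "c1", tiny_atlas())
  expect_equal(unname(m$coef["vol_a", "age"]), 2, tolerance = 1e-10)
  expect_equal(unname(m$coef["thick_b", "sex"]), 0.5, tolerance = 1e-10)
  # thickness features carry no ICV coefficient at all
  expect_true(is.na(m$coef["thick_b", "icv"]))
  expect_false(is.na(m$coef["vol_a", "icv"]))
  out <- apply_normalization(m, ft, ph)
  expect_equal(max(abs(out$vol_a)), 0, tolerance = 1e-9)
  expect_equal(max(abs(out$thick_b)), 0, tolerance = 1e-9)
  # ICV appended as a feature column
  expect_equal(out$icv, ph$icv)
})

test_that("coefficients are averaged arithmetically across cohorts", {
  # three cohorts with exact slopes 1, 2, 3 and identical design
  ph <- do.call(rbind, lapply(1:3, function(i) tiny_pheno(30, paste0("c", i),
                                                          seed = i)))
  slope <- rep(1:3, each = 30)
  ft <- data.frame(subject_id = ph$subject_id, vol_a = slope * ph$age,
                   thick_b = 1, icv = ph$icv)
  m <- suppressWarnings(
    fit_within_dataset_models(ft, ph, paste0("c", 1:3), tiny_atlas()))
  expect_equal(unname(m$coef["vol_a", "age"]), 2, tolerance = 1e-8)

  # averaging two identical cohorts is idempotent
  ph2 <- rbind(tiny_pheno(30, "a", seed = 9), tiny_pheno(30, "b", seed = 9))
  ph2$subject_id <- sprintf("s%03d", seq_len(60))
  noise <- rnorm(30)
  ft2 <- data.frame(subject_id = ph2$subject_id,
                    vol_a = 5 + 0.3 * ph2$age + rep(noise, 2),
                    thick_b = 2 + rep(noise, 2), icv = ph2$icv)
  ma <- fit_within_dataset_models(ft2[1:30, ], ph2[1:30, ], "a", tiny_atlas())
  mab <- fit_within_dataset_models(ft2, ph2, c("a", "b"), tiny_atlas())
  expect_equal(mab$coef[, "age"], ma$coef[, "age"], tolerance = 1e-8)
})

test_that("training residuals are orthogonal to all modeled covariates", {
  s <- small_sim(seed = 13)
  train <- paste0("train_0", 1:4)
  keep <- s$phenotypes$cohort_id %in% train
  ph <- s$phenotypes[keep, ]; ft <- s$features[keep, ]
  m <- fit_within_dataset_models(ft, ph, train, s$atlas)
  out <- apply_normalization(m, ft, ph)
  # single-cohort fit: per-feature residual mean is 0 within that cohort
  m1 <- fit_within_dataset_models(ft[ph$cohort_id == "train_01", ],
                                  ph[ph$cohort_id == "train_01", ],
                                  "train_01", s$atlas)
  out1 <- apply_normalization(m1, ft[ph$cohort_id == "train_01", ],
                              ph[ph$cohort_id == "train_01", ])
  r1 <- as.matrix(out1[, setdiff(names(out1), c("subject_id", "icv"))])
  expect_lt(max(abs(colMeans(r1))), 1e-9)
  covs <- cbind(ph$age[ph$cohort_id == "train_01"],
                (ph$age - m1$age_center)[ph$cohort_id == "train_01"]^2,
                as.numeric(ph$sex == "M")[ph$cohort_id == "train_01"])
  expect_lt(max(abs(cor(covs, r1))), 1e-10)
})

test_that("identity model appends ICV and leaves features untouched", {
  ph <- tiny_pheno(20, "c1", seed = 2)
  ft <- data.frame(subject_id = ph$subject_id, vol_a = rnorm(20),
                   thick_b = rnorm(20), icv = ph$icv)
  m <- fit_within_dataset_models(ft, ph, "c1", tiny_atlas())
  m$coef[] <- 0
  out <- apply_normalization(m, ft, ph)
  expect_equal(out$vol_a, ft$vol_a)
  expect_equal(out$icv, ph$icv)
})

test_that("a model fit on some cohorts leaves shifted held-out means nonzero", {
  ph <- rbind(tiny_pheno(40, "a", seed = 3), tiny_pheno(40, "b", seed = 4),
              tiny_pheno(40, "c", seed = 5))
  shift <- ifelse(ph$cohort_id == "c", 5, 0)
  ft <- data.frame(subject_id = ph$subject_id,
                   vol_a = 10 + 0.1 * ph$age + shift + rnorm(120, 0, 0.5),
                   thick_b = rnorm(120), icv = ph$icv)
  m <- fit_within_dataset_models(ft[ph$cohort_id != "c", ],
                                 ph[ph$cohort_id != "c", ], c("a", "b"),
                                 tiny_atlas())
  out <- apply_normalization(m, ft, ph)
  expect_gt(abs(mean(out$vol_a[ph$cohort_id == "c"])), 3)
  expect_lt(abs(mean(out$vol_a[ph$cohort_id != "c"])), 0.5)
})

test_that("missing covariates and single-sex cohorts are handled explicitly", {
  ph <- tiny_pheno(20, "c1", seed = 6)
  ft <- data.frame(subject_id = ph$subject_id, vol_a = rnorm(20),
                   thick_b = rnorm(20), icv = ph$icv)
  ph_bad <- ph; ph_bad$age[3] <- NA
  expect_error(fit_within_dataset_models(ft, ph_bad, "c1", tiny_atlas()),
               ph$subject_id[3])
  ph_m <- ph; ph_m$sex <- "M"
  expect_warning(fit_within_dataset_models(ft, ph_m, "c1", tiny_atlas()),
                 "constant covariate")
})

test_that("between-dataset adjustment removes vendor offsets fit on training only", {
  ph <- rbind(tiny_pheno(40, "a", seed = 7, vendor = "vendorA"),
              tiny_pheno(40, "b", seed = 8, vendor = "vendorB"))
  ft <- data.frame(subject_id = ph$subject_id,
                   vol_a = rnorm(80) + 5 * (ph$scanner_vendor == "vendorB"),
                   icv = ph$icv)
  out <- fit_apply_between_dataset_adjustment(ft, ph, c("a", "b"))
  ma <- mean(out$vol_a[ph$cohort_id == "a"])
  mb <- mean(out$vol_a[ph$cohort_id == "b"])
  expect_lt(abs(ma - mb), 1e-9)

  # single vendor and field strength: only the intercept is removed
  ph1 <- tiny_pheno(30, "a", seed = 9)
  ft1 <- data.frame(subject_id = ph1$subject_id, vol_a = rnorm(30) + 2)
  out1 <- fit_apply_between_dataset_adjustment(ft1, ph1, "a")
  expect_equal(out1$vol_a, ft1$vol_a - mean(ft1$vol_a), tolerance = 1e-10)

  # vendor level present only in test data: reference prediction plus warning
  ph2 <- rbind(tiny_pheno(30, "a", seed = 10, vendor = "vendorA"),
               tiny_pheno(30, "z", seed = 11, vendor = "vendorZ"))
  ft2 <- data.frame(subject_id = ph2$subject_id, vol_a = rnorm(60))
  expect_warning(fit_apply_between_dataset_adjustment(ft2, ph2, "a"),
                 "reference-level")
})

test_that("center_test_features is exact, idempotent and training-preserving", {
  s <- small_sim(seed = 17, n_densitylike = 5, n_surfacelike = 5)
  ft <- s$features; ph <- s$phenotypes
  out <- center_test_features(ft, ph, "train_02")
  rows <- ph$cohort_id == "train_02"
  m <- as.matrix(out[rows, -1])
  expect_lt(max(abs(colMeans(m))), 1e-9)
  # constant feature becomes all zeros
  ft2 <- ft; ft2$dens_region_001_lh <- 7
  out2 <- center_test_features(ft2, ph, "train_02")
  expect_equal(unique(out2$dens_region_001_lh[rows]), 0)
  # idempotent; other cohorts untouched
  expect_equal(center_test_features(out, ph, "train_02"), out)
  expect_equal(out[!rows, ], ft[!rows, ])
})

test_that("site-factor residualization equalizes per-site means", {
  ph <- rbind(tiny_pheno(40, "a", seed = 12, vendor = "vendorA"),
              tiny_pheno(40, "b", seed = 13, vendor = "vendorB"))
  ft <- data.frame(subject_id = ph$subject_id,
                   vol_a = rnorm(80) + 4 * (ph$cohort_id == "b"))
  out <- suppressWarnings(residualize_site_factor(ft, ph))
  expect_lt(abs(mean(out$vol_a[ph$cohort_id == "a"])), 1e-9)
  expect_lt(abs(mean(out$vol_a[ph$cohort_id == "b"])), 1e-9)
  # vendor aliased with site is flagged
  expect_warning(residualize_site_factor(ft, ph), "aliased")
  # single site reduces to mean-centering
  one <- residualize_site_factor(ft[1:40, ], ph[1:40, ])
  expect_equal(one$vol_a, ft$vol_a[1:40] - mean(ft$vol_a[1:40]))
})

test_that("fitting on a declared test cohort raises a leakage error", {
  s <- small_sim(seed = 19, n_densitylike = 4, n_surfacelike = 4)
  ph <- declare_test_cohorts(s$phenotypes, "train_03")
  expect_error(
    fit_within_dataset_models(s$features, ph, paste0("train_0", 1:3), s$atlas),
    "leakage")
  expect_error(
    fit_apply_between_dataset_adjustment(s$features, ph, "train_03"),
    "leakage")
})
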
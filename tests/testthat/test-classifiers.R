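sep_data <- function(n = 60, p = 5, gap = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- rep(c("case", "control"), length.out = n)
  x[y == "case", 1] <- x[y == "case", 1] + gap
  list(x = x, y = y, sites = rep(c("A", "B"), each = n / 2))
}

test_that("roc_auc matches the brute-force pairwise oracle, ties included", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    labels <- sample(c("case", "control"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), auc_oracle(scores, labels))
  }
})

test_that("roc_auc handles the canonical edge cases", {
  expect_equal(roc_auc(c(0.9, 0.1), c("case", "control")), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("case", "control"), 5)), 0.5)
  expect_error(roc_auc(1:3, rep("case", 3)), "both classes")
  # label flip maps AUC to its complement
  set.seed(1)
  sc <- rnorm(40); lb <- sample(c("case", "control"), 40, TRUE)
  flipped <- ifelse(lb == "case", "control", "case")
  expect_equal(roc_auc(sc, lb) + roc_auc(sc, flipped), 1)
})

test_that("roc_auc agrees with the pROC reference implementation", {
  set.seed(14)
  for (i in 1:5) {
    sc <- round(rnorm(50), 1)
    lb <- sample(c("case", "control"), 50, TRUE)
    if (length(unique(lb)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(response = lb, predictor = sc,
                                          levels = c("control", "case"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(sc, lb), ref)
  }
})

test_that("mean_sens_spec reports rates at the cutoff, including degenerate shifts", {
  r <- mean_sens_spec(c(0.9, 0.8, 0.1, 0.2), c("case", "case", "control", "control"))
  expect_equal(unlist(r), c(sensitivity = 1, specificity = 1, mean = 1))
  # all scores above the cutoff: sens 1, spec 0 -- the cross-site shift pattern
  r2 <- mean_sens_spec(rep(0.6, 6), rep(c("case", "control"), 3), cutoff = 0.5)
  expect_equal(unlist(r2), c(sensitivity = 1, specificity = 0, mean = 0.5))
  expect_error(mean_sens_spec(1:3, rep("case", 3)), "both classes")
})

test_that("forest defaults, bag stratification and reproducibility hold", {
  d <- sep_data(n = 40, p = 9, gap = 0, seed = 2)
  m <- train_site_stratified_forest(d$x, d$y, d$sites, n_trees = 100, seed = 5)
  expect_equal(m$mtry, 3)  # floor(sqrt(9))
  expect_equal(m$s, ceiling(0.632 * 20))
  bags <- forest_bag_counts(m)
  expect_true(all(bags == m$s))
  m2 <- train_site_stratified_forest(d$x, d$y, d$sites, n_trees = 100, seed = 5)
  expect_identical(m$oob_scores, m2$oob_scores)
  expect_identical(m$importance, m2$importance)
  # strict mode uses the literal smallest-site rule
  d2 <- sep_data(n = 60, p = 4, seed = 3)
  sites2 <- rep(c("A", "B"), c(40, 20))
  ms <- train_site_stratified_forest(d2$x, d2$y, sites2, n_trees = 50,
                                     s_mode = "strict", seed = 1)
  expect_equal(ms$s, 20)
  expect_true(all(is.na(ms$oob_scores[sites2 == "B"])))
  expect_error(train_site_stratified_forest(d2$x, d2$y, sites2, s = 30),
               "smaller than the per-tree draw size")
})

test_that("a separating feature yields perfect OOB AUC and memorized predictions", {
  d <- sep_data(n = 60, p = 5, gap = 6, seed = 4)
  m <- train_site_stratified_forest(d$x, d$y, d$sites, n_trees = 200, seed = 2)
  ok <- !is.na(m$oob_scores)
  expect_equal(roc_auc(m$oob_scores[ok], d$y[ok]), 1)
  # duplicate of a training case scores as a case
  expect_gt(forest_predict(m, d$x[1, , drop = FALSE]), 0.5)
  # constant test input gives identical scores
  const <- matrix(0, 3, 5, dimnames = list(NULL, colnames(d$x)))
  expect_length(unique(forest_predict(m, const)), 1)
  expect_error(forest_predict(m, d$x[, 1:3]), "missing feature")
})

test_that("in-bag votes are optimistic relative to out-of-bag scores", {
  set.seed(6)
  d <- sep_data(n = 80, p = 20, gap = 1, seed = 6)
  m <- train_site_stratified_forest(d$x, d$y, d$sites, n_trees = 300, seed = 7)
  full_vote <- forest_predict(m, d$x)
  ok <- !is.na(m$oob_scores)
  auc_full <- roc_auc(full_vote[ok], d$y[ok])
  auc_oob <- roc_auc(m$oob_scores[ok], d$y[ok])
  expect_gt(auc_full, auc_oob)
})

test_that("the linear SVM tunes cost on training data and separates toy data", {
  expect_length(10^seq(-5, 5), 11)  # default grid size
  d <- sep_data(n = 40, p = 4, gap = 6, seed = 8)
  m <- train_linear_svm(d$x, d$y, cost_grid = 10^seq(-2, 2), n_folds = 5,
                        seed = 1)
  expect_true(m$cost %in% 10^seq(-2, 2))
  sc <- svm_predict(m, d$x)
  expect_equal(mean((sc > 0) == (d$y == "case")), 1)
  expect_equal(roc_auc(sc, d$y), 1)
  expect_error(train_linear_svm(d$x, d$y, cost_grid = 5), "degenerate")
  expect_error(train_linear_svm(d$x, rep("case", 40), cost_grid = c(1, 10)),
               "two classes")
})

test_that("label-permuted data yields chance-level SVM cross-validation accuracy", {
  set.seed(9)
  accs <- replicate(10, {
    x <- matrix(rnorm(60 * 5), 60, 5)
    y <- sample(rep(c("case", "control"), 30))
    m <- train_linear_svm(x, y, cost_grid = c(0.01, 1), n_folds = 5, seed = 1)
    max(m$cv_accuracy)
  })
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})

test_that("leave-site-out requires at least three cohorts and skips one-class sites", {
  s <- small_sim(seed = 23, n_densitylike = 4, n_surfacelike = 4)
  expect_error(run_leave_site_out(s$features, s$phenotypes, s$atlas,
                                  cohorts = c("train_01", "train_02")),
               "at least 3")
})
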
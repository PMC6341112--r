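# Independent oracles, kept deliberately naive.

# AUC by brute force over all case-control pairs, ties counted one half.
auc_oracle <- function(scores, labels) {
  cs <- scores[labels == "case"]; ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}

# Benjamini-Hochberg step-up by direct definition:
# q_(k) = min_{j >= k} p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (k in seq_len(m)) {
    cand <- vapply(k:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[ord[k]] <- min(1, min(cand))
  }
  q
}

# small simulated dataset used across tests
small_sim <- function(seed = 7, n_cases = 40, n_controls = 40,
                      n_densitylike = 20, n_surfacelike = 30, ...) {
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    n_densitylike = n_densitylike,
                    n_surfacelike = n_surfacelike, seed = seed, ...)
  atlas <- build_feature_atlas(cfg)
  sim <- simulate_cohorts(cfg, atlas)
  list(cfg = cfg, atlas = atlas, features = sim$features,
       phenotypes = sim$phenotypes, truth = sim$truth)
}

# phenotype table with a controllable case-control age confound
confounded_cohort <- function(n_cases = 200, n_controls = 400,
                              age_shift = 10, seed = 1) {
  set.seed(seed)
  n <- n_cases + n_controls
  diagnosis <- rep(c("case", "control"), c(n_cases, n_controls))
  # cases U(20, 50); controls U(20, 50 + 2 * age_shift), i.e. `age_shift`
  # years older on average while still covering the case age range
  age <- ifelse(diagnosis == "case", runif(n, 20, 50),
                runif(n, 20, 50 + 2 * age_shift))
  data.frame(subject_id = sprintf("s%04d", seq_len(n)), diagnosis = diagnosis,
             disorder = ifelse(diagnosis == "case", "SZ-like", "control"),
             cohort_id = "c1", role = "training", age = age,
             sex = sample(c("M", "F"), n, replace = TRUE),
             icv = rnorm(n, 1475, 110), scanner_vendor = "vendorA",
             field_strength = "3T", stringsAsFactors = FALSE)
}
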
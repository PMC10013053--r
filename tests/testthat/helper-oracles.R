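# Independent brute-force oracles and small fixtures used across the suite.

# Plain pairwise Pearson correlation between rows of x, computed entry by
# entry from the definition (sample SD), independent of cor()'s vectorized
# path and of the package's constructors.
oracle_pearson_rows <- function(x) {
  p <- nrow(x)
  out <- diag(1, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    a <- x[i, ]; b <- x[j, ]
    out[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  out
}

# Weighted Pearson from the definition: weighted means, variances and
# covariance with element weights w (sum 1).
oracle_weighted_pearson <- function(a, b, w) {
  ma <- sum(w * a); mb <- sum(w * b)
  cab <- sum(w * (a - ma) * (b - mb))
  cab / sqrt(sum(w * (a - ma)^2) * sum(w * (b - mb)^2))
}

oracle_weighted_pearson_rows <- function(x, w) {
  p <- nrow(x)
  out <- diag(1, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j) out[i, j] <- oracle_weighted_pearson(x[i, ], x[j, ], w)
  }
  out
}

# AUC by enumerating every patient-control pair; ties count one half.
oracle_auc_pairs <- function(scores, labels) {
  a <- scores[labels == 1]; b <- scores[labels == 0]
  tot <- 0
  for (x in a) for (y in b)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(b))
}

# Rank-sum statistic from the pairwise definition (equals wilcox.test's W).
oracle_ranksum_W <- function(a, b) {
  tot <- 0
  for (x in a) for (y in b) tot <- tot + (x > y) + 0.5 * (x == y)
  tot
}

# Random region x feature table with plausible scales.
random_feature_table <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(p * 9), p, 9,
              dimnames = list(paste0("r", seq_len(p)), msn_features))
  m
}

# Standard six-covariate table.
random_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(age = rnorm(n, 44, 13), sex = rbinom(n, 1, 0.5),
             bmi = rnorm(n, 23, 3), education = rbinom(n, 1, 0.5),
             alcohol = sample(0:2, n, TRUE), exercise = sample(0:2, n, TRUE))
}

# Small synthetic cohort used by the model tests.
small_cohort <- function(seed = 1, p = 24, n_per_group = 17, t = 30, ...) {
  generate_cohort(cohort_spec(n_regions = p, n_timepoints = t,
                              n_per_group = n_per_group,
                              effect_regions = 1:4, ...), seed = seed)
}
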
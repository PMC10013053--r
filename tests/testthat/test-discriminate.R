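make_mms <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p, 0.3, 0.1), n, p,
         dimnames = list(NULL, paste0("region", seq_len(p))))
}

test_that("univariable region test adjusts for covariates and calibrates", {
  n <- 40; p <- 6
  cv <- random_covariates(n, seed = 1)
  labels <- rep(c(1L, 0L), each = n / 2)

  # identical profiles in both groups (and shared covariates) give t = 0
  half <- make_mms(n / 2, p, seed = 2)
  mms <- rbind(half, half)
  cv2 <- rbind(cv[1:(n / 2), ], cv[1:(n / 2), ])
  res <- univariable_region_test(mms, labels, cv2)
  expect_equal(res$t, rep(0, p), tolerance = 1e-10)
  expect_equal(res$p, rep(1, p), tolerance = 1e-10)

  # null labels: p-values are well spread over (0, 1)
  pvals <- unlist(lapply(1:25, function(seed) {
    m <- make_mms(n, p, seed = seed + 10)
    univariable_region_test(m, labels, cv)$p
  }))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # a planted shift on one region gives it the largest |t|
  hits <- 0L
  for (seed in 1:10) {
    m <- make_mms(n, p, seed = seed + 50)
    m[labels == 1, 3] <- m[labels == 1, 3] + 0.15
    tt <- univariable_region_test(m, labels, cv)$t
    if (which.max(abs(tt)) == 3) hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  # rank-deficient designs are refused with the collinear column named
  cv_bad <- cv; cv_bad$bmi <- cv_bad$age
  expect_error(univariable_region_test(make_mms(n, p), labels, cv_bad),
               "collinear")
})

test_that("replication rule requires significance and matching sign", {
  mk <- function(p, t) {
    r <- data.frame(region = seq_along(p), t = t, p = p, sign = sign(t))
    class(r) <- c("univariable_result", "data.frame")
    r
  }
  d <- mk(c(0.025, 0.02, 0.20, 0.01), c(2.25, 2.4, 1.2, -2.8))
  v <- mk(c(0.047, 0.30, 0.01, 0.04), c(2.01, 2.2, 2.9, 2.5))
  # region 1: significant both halves, same sign -> included
  # region 2: significant in discovery only -> excluded
  # region 3: significant in validation only -> excluded
  # region 4: significant both halves, opposite signs -> excluded
  expect_equal(replicated_regions(d, v, 0.05), 1L)
  expect_error(replicated_regions(d, v, 1.5), "alpha")
})

test_that("per-region logistic betas behave under symmetry and separation", {
  n <- 60; p <- 5
  cv <- random_covariates(n, seed = 3)
  labels <- rep(c(1L, 0L), each = n / 2)
  mms <- make_mms(n, p, seed = 4)

  fit <- fit_region_logistics(mms, labels, cv)
  flipped <- fit_region_logistics(mms, 1L - labels, cv)
  expect_equal(fit$beta, -flipped$beta, tolerance = 1e-6)

  # a perfectly separating region triggers the ridge fallback and still
  # carries the largest standardized coefficient
  mms2 <- mms
  mms2[, 2] <- ifelse(labels == 1, 1, 0) + rnorm(n, sd = 1e-3)
  expect_warning(fit2 <- fit_region_logistics(mms2, labels, cv),
                 "ridge-stabilized")
  expect_true(2L %in% fit2$stabilized)
  std <- abs(fit2$beta) * apply(mms2, 2, sd)
  expect_equal(which.max(std), 2L, ignore_attr = TRUE)

  # null data: coefficients hover near zero
  expect_lt(max(abs(fit$beta) * apply(mms, 2, sd)), 3)
})

test_that("mMS linear predictor is a bare dot product", {
  beta <- c(0.5, -1, 2)
  expect_equal(score_mms(beta, c(1, 2, 3)), 0.5 - 2 + 6)
  expect_equal(score_mms(rep(0, 3), c(1, 2, 3)), 0)
  expect_equal(score_mms(c(0, 1, 0), c(4, 5, 6)), 5)
  set.seed(6)
  b <- rnorm(8); m <- rnorm(8)
  expect_identical(score_mms(b, m), sum(b * m))
  expect_error(score_mms(b, m[-1]), "mismatch")
})

test_that("network classifier scores identically in component and edge space", {
  coh <- small_cohort(seed = 9)
  em <- cohort_edge_matrix(coh, "MS")
  fit <- fit_network_classifier(em, coh$labels, coh$covariates)

  # algebraic identity: R_pca beta_pca == (r - mean) beta_upper
  edge_scores <- predict(fit, em)
  expect_equal(edge_scores, fit$train_scores, tolerance = 1e-8)
  expect_equal(rank(edge_scores), rank(fit$train_scores))

  # beta_upper is the back-projection of the component coefficients
  expect_equal(fit$beta_upper,
               as.vector(fit$pca_basis %*% fit$beta_pca), tolerance = 1e-12)

  # translation invariance: adding a constant to every edge leaves AUC alone
  shifted <- em; shifted$values <- em$values + 0.37
  expect_equal(auc(predict(fit, shifted), coh$labels),
               auc(edge_scores, coh$labels))

  expect_error(fit_network_classifier(em$values[1:5, ], coh$labels[1:5],
                                      coh$covariates[1:5, ]), "at least 10")
})

test_that("activation pattern matches the materialized covariance transform", {
  # closed form at E = 2 with identity covariance and beta = (2, 0):
  # var(score) = 4, A = Sigma beta / 4 = (0.5, 0)
  set.seed(10)
  n <- 30
  x <- matrix(rnorm(n * 2), n, 2)
  xc <- scale(x, scale = FALSE)
  whiten <- backsolve(chol(crossprod(xc) / (n - 1)), diag(2))
  xw <- xc %*% whiten                       # sample covariance exactly I
  beta <- c(2, 0)
  scores <- xw %*% beta
  a <- activation_pattern(xw, beta, scores)
  expect_equal(a, c(0.5, 0), tolerance = 1e-10)

  # factored form equals an explicitly materialized covariance at E <= 50
  e <- 40
  r <- matrix(rnorm(25 * e), 25, e)
  beta2 <- rnorm(e)
  sc <- sweep(r, 2, colMeans(r)) %*% beta2
  a_fact <- activation_pattern(r, beta2, as.vector(sc))
  a_full <- as.vector(cov(r) %*% beta2) / var(as.vector(sc))
  expect_equal(a_fact, a_full, tolerance = 1e-10)

  expect_error(activation_pattern(r, rep(0, e), rep(0, 25)), "variance")
})

test_that("top-fraction edge extraction ranks by |weight| with ceil count", {
  w <- numeric(47278); w[5] <- -3
  top <- top_fraction_edges(w, 0.001)
  expect_equal(nrow(top), 48L)            # ceil(0.001 * 47278)
  expect_equal(top$edge[1], 5L)
  expect_equal(top$weight[1], -3)

  w2 <- c(0.1, -0.9, 0.5, 0.2, -0.2, 0.7)  # P = 4
  all_edges <- top_fraction_edges(w2, 1)
  expect_equal(all_edges$edge, c(2L, 6L, 3L, 4L, 5L, 1L))  # ties by index
  expect_equal(all_edges$i[1], 1L)         # edge 2 is pair (1, 3)
  expect_equal(all_edges$j[1], 3L)
  expect_error(top_fraction_edges(numeric(0), 0.5), "empty")
  expect_error(top_fraction_edges(w2, 0), "fraction")
})
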
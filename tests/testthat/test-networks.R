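test_that("feature z-scoring standardizes columns with sample SD", {
  x <- matrix(c(1, 0, 0), 3, 9, dimnames = list(NULL, msn_features))
  z <- zscore_features(x)
  expect_equal(z[, 1], c(1.1547005, -0.5773503, -0.5773503),
               tolerance = 1e-6, ignore_attr = TRUE)
  # idempotence: z-scoring a standardized table changes nothing
  expect_equal(zscore_features(z), z, tolerance = 1e-12, ignore_attr = TRUE)
  # degenerate: constant feature column is an error naming the feature
  bad <- random_feature_table(5, seed = 1)
  bad[, "CT"] <- 2.5
  expect_error(zscore_features(bad), "CT")
})

test_that("morphometric similarity matches the pairwise Pearson oracle", {
  # 3 regions, identity pattern: every off-diagonal correlation is -0.5
  x <- diag(3)[, c(1, 2, 3, 1, 2, 3, 1, 2, 3)]
  colnames(x) <- msn_features
  ms <- morphometric_similarity(x)
  expect_equal(ms$values[upper.tri(ms$values)], rep(-0.5, 3),
               tolerance = 1e-12)
  expect_equal(ms$mean_profile, rep(-0.5, 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical feature rows correlate at exactly 1
  y <- random_feature_table(4, seed = 2)
  y[2, ] <- y[1, ]
  expect_equal(morphometric_similarity(y)$values[1, 2], 1, tolerance = 1e-12)

  # random tables match the brute-force oracle on the z-scored features
  for (seed in 1:5) {
    tab <- random_feature_table(10, seed = seed)
    ms <- morphometric_similarity(tab)
    oracle <- oracle_pearson_rows(zscore_features(tab))
    expect_equal(ms$values, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("functional connectivity is affine-invariant Pearson correlation", {
  set.seed(3)
  ts <- matrix(rnorm(5 * 50), 5, 50)
  ts[2, ] <- 2 * ts[1, ] + 3
  ts[3, ] <- -ts[1, ]
  fc <- functional_connectivity(ts)
  expect_equal(fc$values[1, 2], 1, tolerance = 1e-12)
  expect_equal(fc$values[1, 3], -1, tolerance = 1e-12)
  expect_equal(fc$values, oracle_pearson_rows(ts), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(functional_connectivity(matrix(1, 3, 10)), "constant")
})

test_that("ensemble similarity interpolates between MS and FC", {
  set.seed(4)
  tab <- random_feature_table(6)
  ts <- matrix(rnorm(6 * 20), 6, 20)
  expect_equal(ensemble_similarity(tab, ts, 1)$values,
               morphometric_similarity(tab)$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ensemble_similarity(tab, ts, 0)$values,
               functional_connectivity(ts)$values, tolerance = 1e-12,
               ignore_attr = TRUE)

  # mid-weight matches the direct weighted-Pearson oracle on the
  # concatenated z-scored vectors
  w_ms <- 0.5
  zf <- zscore_features(tab)
  zt <- t(scale(t(ts)))
  x <- cbind(zf, zt)
  w <- c(rep(w_ms, 9), rep(1 - w_ms, 20)); w <- w / sum(w)
  expect_equal(ensemble_similarity(tab, ts, w_ms)$values,
               oracle_weighted_pearson_rows(x, w),
               tolerance = 1e-12, ignore_attr = TRUE)

  # continuity in w_ms: small weight changes move entries by little
  m1 <- ensemble_similarity(tab, ts, 0.5)$values
  m2 <- ensemble_similarity(tab, ts, 0.5 + 1e-4)$values
  expect_lt(max(abs(m1 - m2)), 1e-2)
  expect_error(ensemble_similarity(tab, ts, 1.2), "w_ms")
})

test_that("constructed matrices satisfy the similarity invariants", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- sample(4:12, 1)
    ms <- morphometric_similarity(random_feature_table(p))
    fc <- functional_connectivity(matrix(rnorm(p * 15), p, 15))
    en <- ensemble_similarity(random_feature_table(p),
                              matrix(rnorm(p * 15), p, 15), runif(1))
    for (m in list(ms, fc, en)) {
      v <- m$values
      expect_equal(v, t(v), tolerance = 1e-12)
      expect_equal(diag(v), rep(1, p), ignore_attr = TRUE)
      expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12))
      expect_equal(m$mean_profile, (rowSums(v) - 1) / (p - 1),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("edge vectorization uses fixed row-major upper-triangle order", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- 12; m[1, 3] <- 13; m[1, 4] <- 14
  m[2, 3] <- 23; m[2, 4] <- 24; m[3, 4] <- 34
  m <- m + t(m); diag(m) <- 1
  expect_equal(vectorize_upper(m), c(12, 13, 14, 23, 24, 34))
  idx <- edge_index(4)
  expect_equal(idx$i, c(1, 1, 1, 2, 2, 3))
  expect_equal(idx$j, c(2, 3, 4, 3, 4, 4))

  # round-trip restores the off-diagonal exactly
  set.seed(5)
  s <- morphometric_similarity(random_feature_table(7))$values
  expect_equal(unvectorize_upper(vectorize_upper(s), 7), s,
               tolerance = 0, ignore_attr = TRUE)

  a <- m; a[1, 2] <- a[1, 2] + 1e-6
  expect_error(vectorize_upper(a), "asymmetric")
})

test_that("stacking subjects preserves order and dimensions", {
  mats <- lapply(1:3, function(s)
    morphometric_similarity(random_feature_table(6, seed = s)))
  em <- stack_subjects(mats, c("a", "b", "c"))
  expect_equal(dim(em$values), c(3L, 15L))
  expect_equal(em$values[2, ], vectorize_upper(mats[[2]]), ignore_attr = TRUE)
  expect_equal(em$subject_ids, c("a", "b", "c"))

  one <- stack_subjects(mats[1])
  expect_equal(as.vector(one$values), vectorize_upper(mats[[1]]))

  bad <- c(mats, list(morphometric_similarity(random_feature_table(5))))
  expect_error(stack_subjects(bad), "mismatch")
})
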
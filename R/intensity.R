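#' Fit the PCA-LASSO pain-intensity predictor
#'
#' Regresses 0-100 pain intensity on the principal components of the
#' patients' edge matrix with an L1 penalty. The edge matrix R is
#' column-centered and reduced to K = min(N - 1, E) component scores; the
#' design is the K scores plus the six covariates (all penalized by
#' default); a Gaussian-family lasso path is fit on a geometric grid of 100
#' penalties spanning four decades down from lambda_max (the smallest
#' penalty that zeroes every penalized coefficient); the penalty is chosen
#' by leave-one-out cross-validation minimizing mean squared-error deviance;
#' the model is refit at the chosen penalty on all patients; component
#' coefficients are back-projected to edge space and transformed to an
#' activation pattern `A = Sigma_R beta_upper / var(prediction)`.
#'
#' @param R An `edge_matrix` of patients (or bare patients x edges matrix).
#' @param intensity Pain-intensity scores in \[0, 100\].
#' @param covariates Data frame with the six covariate columns.
#' @param n_lambda Grid size (default 100).
#' @param lambda_min_ratio Grid floor as a fraction of lambda_max (1e-4).
#' @param penalize_covariates If `FALSE`, covariates are exempt from the L1
#'   penalty (default `TRUE`: all regressors penalized alike).
#' @param k Components retained (default min(N - 1, E)).
#' @return A `pca_lasso` with the penalty path, CV deviances, chosen
#'   penalty, `beta_pca`, `beta_upper`, `activation`, `intercept`,
#'   `covariate_coefficients` and the training fit.
#' @export
fit_pca_lasso <- function(R, intensity, covariates, n_lambda = 100L,
                          lambda_min_ratio = 1e-4,
                          penalize_covariates = TRUE, k = NULL) {
  values <- if (inherits(R, "edge_matrix")) R$values else as.matrix(R)
  n <- nrow(values)
  if (n < 10L) stop("need at least 10 patients")
  intensity <- as.numeric(intensity)
  if (length(intensity) != n) stop("intensity length does not match subjects")
  if (anyNA(intensity) || any(intensity < 0 | intensity > 100))
    stop("intensity must be within [0, 100] with no missing values")
  if (stats::sd(intensity) == 0) stop("constant intensity; nothing to fit")
  cv <- check_covariates(covariates, n)
  pc <- thin_pca(values, k)
  x <- cbind(pc$scores, cv)
  colnames(x) <- c(paste0("PC", seq_len(pc$k)), covariate_names)
  pf <- rep(1, ncol(x))
  if (!penalize_covariates) pf[pc$k + 1:6] <- 0

  # lambda_max in glmnet's parameterization: smallest penalty zeroing all
  # penalized coefficients of the standardize = FALSE Gaussian problem
  # grid: lambda_max (the smallest penalty zeroing every penalized
  # coefficient of the standardized problem) down lambda_min_ratio decades
  # over n_lambda values; built explicitly so the solver fits the whole grid
  sx <- sqrt(colMeans(sweep(x, 2L, colMeans(x))^2))     # population SD
  yr <- if (any(pf == 0)) {
    stats::lm.fit(cbind(1, x[, pf == 0, drop = FALSE]), intensity)$residuals
  } else intensity - mean(intensity)
  x_std <- sweep(sweep(x, 2L, colMeans(x)), 2L, sx, "/")
  grad <- abs(crossprod(x_std, yr)) / n
  lambda_max <- max(grad[pf > 0]) * sum(pf) / length(pf)
  lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = n_lambda))

  fit_path <- function(rows) {
    glmnet::glmnet(x[rows, , drop = FALSE], intensity[rows],
                   family = "gaussian", alpha = 1, lambda = lambda,
                   standardize = TRUE, penalty.factor = pf,
                   thresh = 1e-12, maxit = 1e6)
  }

  # leave-one-out: squared-error deviance accumulated per lambda
  dev <- matrix(NA_real_, n, n_lambda)
  for (i in seq_len(n)) {
    f <- fit_path(setdiff(seq_len(n), i))
    pred <- stats::predict(f, x[i, , drop = FALSE], s = lambda)
    dev[i, ] <- (intensity[i] - as.vector(pred))^2
  }
  cv_deviance <- colMeans(dev)
  lambda_chosen <- lambda[which.min(cv_deviance)]

  full <- fit_path(seq_len(n))
  b <- as.vector(stats::coef(full, s = lambda_chosen))
  intercept <- b[1L]
  beta_pca <- b[1L + seq_len(pc$k)]
  covariate_coefficients <- stats::setNames(b[(1L + pc$k) + 1:6],
                                            covariate_names)
  if (all(beta_pca == 0) && all(covariate_coefficients == 0))
    warning("empty active set at the chosen penalty; intercept-only predictor")
  beta_upper <- as.vector(pc$basis %*% beta_pca)
  xc <- sweep(values, 2L, pc$center)
  train_pred <- intercept + as.vector(pc$scores %*% beta_pca) +
    as.vector(cv %*% covariate_coefficients)
  act <- if (stats::var(train_pred) > 0)
    activation_from_centered(xc, beta_upper, train_pred) else
      rep(NA_real_, length(beta_upper))
  structure(list(
    edge_mean = pc$center, pca_basis = pc$basis,
    lambda = lambda, cv_deviance = cv_deviance, lambda_chosen = lambda_chosen,
    beta_pca = beta_pca, beta_upper = beta_upper, activation = act,
    intercept = intercept, covariate_coefficients = covariate_coefficients,
    train_prediction = train_pred, k = pc$k,
    edge_index = if (inherits(R, "edge_matrix")) R$edge_index else NULL,
    p = if (inherits(R, "edge_matrix")) R$p else NULL,
    glmnet_fit = full), class = "pca_lasso")
}

#' @export
print.pca_lasso <- function(x, ...) {
  cat(sprintf(
    "<pca_lasso> %d components, lambda = %.4g (%d nonzero component coefs)\n",
    x$k, x$lambda_chosen, sum(x$beta_pca != 0)))
  invisible(x)
}

#' @export
coef.pca_lasso <- function(object, ...) object$beta_upper

#' Predict pain intensity from a fitted PCA-LASSO model
#'
#' Full prediction is `intercept + (r - edge_mean) . beta_upper + covariate
#' terms`; with `score_only = TRUE` the bare uncentered dot product
#' `r . beta_upper` is returned — the raw linear predictor whose correlation
#' with observed intensity is the headline validation statistic.
#'
#' @param object A `pca_lasso`.
#' @param newdata A `similarity_matrix`, `edge_matrix`, edge vector or
#'   subjects x edges matrix.
#' @param covariates Covariate rows for the new subjects (ignored when
#'   `score_only = TRUE`; required otherwise).
#' @param score_only Return the bare dot product (default `FALSE`).
#' @param ... Unused.
#' @return Numeric prediction(s).
#' @export
predict.pca_lasso <- function(object, newdata, covariates = NULL,
                              score_only = FALSE, ...) {
  v <- as_edge_rows(newdata, length(object$beta_upper))
  if (score_only) return(as.vector(v %*% object$beta_upper))
  if (is.null(covariates))
    stop("covariates required for full predictions (or use score_only = TRUE)")
  cv <- check_covariates(covariates, nrow(v))
  as.vector(object$intercept + sweep(v, 2L, object$edge_mean) %*%
              object$beta_upper + cv %*% object$covariate_coefficients)
}

#' Agreement between predicted and observed intensity
#'
#' Pearson r with its two-sided p-value, R-squared = r^2, and RMSE. Because
#' the bare dot-product score lives on an arbitrary scale, the default RMSE
#' is computed after a univariate linear recalibration of the predictions
#' onto the observed scale; `raw_rmse = TRUE` skips the recalibration.
#'
#' @param predicted,observed Numeric vectors of equal length (n >= 3).
#' @param raw_rmse Compute RMSE without recalibration (default `FALSE`).
#' @return List with `r`, `p`, `r_squared`, `rmse`, `n`.
#' @export
evaluate_prediction <- function(predicted, observed, raw_rmse = FALSE) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    stop("zero variance in predicted or observed values")
  ct <- stats::cor.test(predicted, observed)
  rmse <- if (raw_rmse) {
    sqrt(mean((observed - predicted)^2))
  } else {
    cal <- stats::lm(observed ~ predicted)
    sqrt(mean(stats::residuals(cal)^2))
  }
  list(r = unname(ct$estimate), p = ct$p.value,
       r_squared = unname(ct$estimate)^2, rmse = rmse,
       n = length(predicted))
}
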
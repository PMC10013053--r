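covariate_names <- c("age", "sex", "bmi", "education", "alcohol", "exercise")

check_covariates <- function(covariates, n) {
  covariates <- as.data.frame(covariates)
  missing <- setdiff(covariate_names, names(covariates))
  if (length(missing))
    stop("covariate table lacks column(s): ", paste(missing, collapse = ", "))
  covariates <- covariates[covariate_names]
  if (nrow(covariates) != n)
    stop("covariate rows (", nrow(covariates), ") do not match subjects (", n, ")")
  if (anyNA(covariates)) stop("covariate table contains missing values")
  as.matrix(covariates)
}

check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) stop("label length does not match subjects")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  labels
}

#' Covariate-adjusted univariable test of regional mean similarity
#'
#' For each region j, fits a least-squares regression of the region's mean
#' similarity (mMS or mFC) on pain state plus the six covariates (age, sex,
#' BMI, education, alcohol, exercise) and an intercept, and returns the
#' t-statistic and two-sided p-value of the pain-state coefficient.
#'
#' @param mms Subjects x regions matrix of mean-similarity profiles.
#' @param labels Binary pain-state vector (1 = patient).
#' @param covariates Data frame with the six covariate columns.
#' @return A `univariable_result` data frame with columns `region`, `t`, `p`,
#'   `sign`, plus attribute `df`.
#' @export
univariable_region_test <- function(mms, labels, covariates) {
  mms <- as.matrix(mms)
  n <- nrow(mms)
  labels <- check_labels(labels, n)
  cv <- check_covariates(covariates, n)
  x <- cbind(`(Intercept)` = 1, state = labels, cv)
  if (n <= ncol(x)) stop("need more subjects than regressors")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop_cols <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  coefs <- qr.coef(qx, mms)                      # p x P
  res <- mms - x %*% coefs
  df <- n - ncol(x)
  sigma2 <- colSums(res^2) / df
  pos <- match(2L, qx$pivot)                     # state column through the pivot
  xtx_inv_state <- chol2inv(qr.R(qx))[pos, pos]
  se <- sqrt(sigma2 * xtx_inv_state)
  tval <- coefs["state", ] / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  out <- data.frame(region = colnames(mms) %||% seq_len(ncol(mms)),
                    t = tval, p = pval, sign = sign(tval),
                    row.names = NULL)
  attr(out, "df") <- df
  class(out) <- c("univariable_result", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regions significant and replicated across halves
#'
#' Returns the regions whose pain-state coefficient has p < alpha in both the
#' discovery and the validation half with matching sign — the replication
#' rule for calling a univariable regional biomarker.
#'
#' @param discovery,validation `univariable_result` objects of equal length.
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @return Integer vector of replicated region indices.
#' @export
replicated_regions <- function(discovery, validation, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (nrow(discovery) != nrow(validation))
    stop("result lengths differ between halves")
  which(discovery$p < alpha & validation$p < alpha &
          discovery$sign == validation$sign & discovery$sign != 0)
}

# Ridge-stabilized logistic regression by IRLS. Penalty eps/2 * ||beta||^2 on
# all coefficients except the intercept. Deterministic; returns coefficients.
ridge_logistic <- function(x, y, eps = 1e-4, max_iter = 200L, tol = 1e-10) {
  d <- diag(ncol(x)) * eps
  d[1L, 1L] <- 0                                   # intercept unpenalized
  beta <- numeric(ncol(x))
  beta[1L] <- stats::qlogis(mean(y) * 0.98 + 0.01)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta_new <- solve(xtw %*% x + d, xtw %*% z)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.vector(beta)
}

#' Per-region logistic coefficients of mean similarity
#'
#' Independently for each region j, fits a logistic regression of pain state
#' on the region's mean similarity plus the six covariates and stores the
#' mean-similarity coefficient beta_j. Regions where the unpenalized fit
#' fails to converge or separates are refit with a ridge-stabilized logistic
#' (penalty 1e-4) and reported in the fit.
#'
#' @param mms Subjects x regions matrix of mean-similarity profiles.
#' @param labels Binary pain-state vector (1 = patient).
#' @param covariates Data frame with the six covariate columns.
#' @param ridge_eps Ridge penalty used for stabilized refits.
#' @return An `mms_model`: list with `beta` (length P), `stabilized` (region
#'   indices refit with ridge), `region_ids`.
#' @export
fit_region_logistics <- function(mms, labels, covariates, ridge_eps = 1e-4) {
  mms <- as.matrix(mms)
  n <- nrow(mms)
  labels <- check_labels(labels, n)
  cv <- check_covariates(covariates, n)
  if (n <= 8L) stop("need more than 8 subjects")
  p <- ncol(mms)
  beta <- numeric(p)
  stabilized <- integer(0)
  for (j in seq_len(p)) {
    xj <- cbind(1, mms[, j], cv)
    fit_ok <- TRUE
    fit <- withCallingHandlers(
      stats::glm.fit(xj, labels, family = stats::binomial()),
      warning = function(w) {
        fit_ok <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (fit_ok && fit$converged &&
        all(fit$fitted.values > 1e-8 & fit$fitted.values < 1 - 1e-8)) {
      beta[j] <- fit$coefficients[2L]
    } else {
      beta[j] <- ridge_logistic(xj, labels, eps = ridge_eps)[2L]
      stabilized <- c(stabilized, j)
    }
  }
  if (length(stabilized))
    warning("ridge-stabilized logistic used for ", length(stabilized),
            " region(s): ", paste(utils::head(stabilized, 10L), collapse = ", "),
            if (length(stabilized) > 10L) ", ..." else "")
  structure(list(beta = beta, stabilized = stabilized,
                 region_ids = colnames(mms) %||% paste0("region", seq_len(p))),
            class = "mms_model")
}

#' @export
print.mms_model <- function(x, ...) {
  cat(sprintf("<mms_model> %d per-region logistic coefficients", length(x$beta)))
  if (length(x$stabilized))
    cat(sprintf(" (%d ridge-stabilized)", length(x$stabilized)))
  cat("\n")
  invisible(x)
}

#' @export
coef.mms_model <- function(object, ...) {
  stats::setNames(object$beta, object$region_ids)
}

#' Linear predictor of the per-region model
#'
#' The dot product of the fitted per-region coefficient vector with a
#' subject's mean-similarity profile; covariate terms and intercepts are
#' excluded from the score.
#'
#' @param model An `mms_model` (or bare numeric beta vector).
#' @param mms_subject Length-P mean-similarity profile, or a subjects x P
#'   matrix for several subjects at once.
#' @return Numeric score(s).
#' @export
score_mms <- function(model, mms_subject) {
  beta <- if (inherits(model, "mms_model")) model$beta else as.numeric(model)
  if (is.matrix(mms_subject)) {
    if (ncol(mms_subject) != length(beta)) stop("length mismatch")
    return(as.vector(mms_subject %*% beta))
  }
  if (length(mms_subject) != length(beta)) stop("length mismatch")
  sum(beta * mms_subject)
}

#' @export
predict.mms_model <- function(object, newdata, ...) {
  score_mms(object, newdata)
}

# Thin PCA of a wide matrix (N << E): eigen-decomposition of the N x N Gram
# matrix; returns centered scores (N x K), basis (E x K) with orthonormal
# columns, and the column means. K = min(N - 1, E) by default: centering
# removes one rank, so the N-th component is degenerate and dropped.
thin_pca <- function(x, k = NULL) {
  n <- nrow(x); e <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  kmax <- min(n - 1L, e)
  if (is.null(k)) k <- kmax
  k <- min(k, kmax)
  if (n <= e) {
    gram <- tcrossprod(xc)
    eg <- eigen(gram, symmetric = TRUE)
    pos <- which(eg$values > max(eg$values) * 1e-12)
    k <- min(k, length(pos))
    d <- sqrt(eg$values[seq_len(k)])
    u <- eg$vectors[, seq_len(k), drop = FALSE]
    basis <- crossprod(xc, u) %*% diag(1 / d, k)
    scores <- u %*% diag(d, k)
  } else {
    sv <- svd(xc, nu = k, nv = k)
    basis <- sv$v
    scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  }
  list(scores = scores, basis = basis, center = mu, k = k)
}

#' Fit the PCA-logistic network classifier
#'
#' The network-level discrimination model: the subjects x edges matrix R is
#' column-centered and reduced by PCA to K = min(N - 1, E) components; a
#' single ridge-stabilized logistic regression of pain state on all K
#' component scores plus the six covariates is fit; the component
#' coefficients are back-projected to edge space
#' (`beta_upper = basis %*% beta_pca`); and the decoding weights are
#' transformed to a forward-model activation pattern
#' `A = Sigma_R beta_upper / var(s)` with s the training linear predictor,
#' computed in factored form so the E x E covariance is never materialized.
#'
#' @param R An `edge_matrix` (or bare subjects x edges matrix).
#' @param labels Binary pain-state vector (1 = patient).
#' @param covariates Data frame with the six covariate columns.
#' @param ridge_eps Ridge penalty stabilizing the K ~ N logistic fit.
#' @param k Number of components retained (default min(N - 1, E)).
#' @return A `network_classifier` with elements `edge_mean`, `pca_basis`,
#'   `beta_pca`, `beta_upper`, `activation`, `covariate_coefficients`,
#'   `train_scores`, `edge_index`, `p`, `k`.
#' @export
fit_network_classifier <- function(R, labels, covariates, ridge_eps = 1e-4,
                                   k = NULL) {
  values <- if (inherits(R, "edge_matrix")) R$values else as.matrix(R)
  n <- nrow(values)
  if (n < 10L) stop("need at least 10 subjects")
  labels <- check_labels(labels, n)
  cv <- check_covariates(covariates, n)
  pc <- thin_pca(values, k)
  x <- cbind(1, pc$scores, cv)
  beta_all <- ridge_logistic(x, labels, eps = ridge_eps)
  if (!all(is.finite(beta_all))) stop("non-finite logistic fit; check inputs")
  beta_pca <- beta_all[1L + seq_len(pc$k)]
  beta_upper <- as.vector(pc$basis %*% beta_pca)
  train_scores <- as.vector(pc$scores %*% beta_pca)
  xc <- sweep(values, 2L, pc$center)
  act <- activation_from_centered(xc, beta_upper, train_scores)
  structure(list(
    edge_mean = pc$center, pca_basis = pc$basis, beta_pca = beta_pca,
    beta_upper = beta_upper, activation = act,
    intercept = beta_all[1L],
    covariate_coefficients = stats::setNames(beta_all[(1L + pc$k) + 1:6],
                                             covariate_names),
    train_scores = train_scores,
    edge_index = if (inherits(R, "edge_matrix")) R$edge_index else NULL,
    p = if (inherits(R, "edge_matrix")) R$p else NULL,
    k = pc$k, ridge_eps = ridge_eps), class = "network_classifier")
}

activation_from_centered <- function(xc, beta_upper, scores) {
  vs <- as.numeric(stats::var(as.vector(scores)))
  if (!is.finite(vs) || vs <= 0)
    stop("zero variance of the linear predictor; activation undefined")
  sigma_beta <- crossprod(xc, xc %*% beta_upper) / (nrow(xc) - 1L)
  as.vector(sigma_beta) / vs
}

#' Activation pattern of a backward model
#'
#' Transforms decoding weights into a forward-model activation pattern:
#' `A = Sigma_R beta / var(scores)`, with `Sigma_R` the covariance of the
#' edge matrix columns. Computed via the factored form
#' `t(Xc) (Xc beta) / (N - 1)` so the E x E covariance is never built.
#'
#' @param R An `edge_matrix` or subjects x edges matrix.
#' @param beta_upper Length-E decoding weight vector.
#' @param scores Per-subject linear predictor used for the variance.
#' @return Length-E activation vector.
#' @export
activation_pattern <- function(R, beta_upper, scores) {
  values <- if (inherits(R, "edge_matrix")) R$values else as.matrix(R)
  if (ncol(values) != length(beta_upper)) stop("dimension mismatch")
  xc <- sweep(values, 2L, colMeans(values))
  activation_from_centered(xc, beta_upper, scores)
}

#' @export
print.network_classifier <- function(x, ...) {
  cat(sprintf("<network_classifier> %d components over %d edges (ridge %.1e)\n",
              x$k, length(x$beta_upper), x$ridge_eps))
  invisible(x)
}

#' @export
coef.network_classifier <- function(object, ...) object$beta_upper

#' Score subjects with a fitted network classifier
#'
#' The linear predictor `(r_i - edge_mean) . beta_upper` for each subject;
#' covariate contributions are excluded. Accepts a `similarity_matrix`, an
#' `edge_matrix`, a bare edge vector or a subjects x edges matrix.
#'
#' @param object A `network_classifier`.
#' @param newdata Subject network(s) as above.
#' @param ... Unused.
#' @return Numeric score(s).
#' @export
predict.network_classifier <- function(object, newdata, ...) {
  v <- as_edge_rows(newdata, length(object$beta_upper))
  as.vector(sweep(v, 2L, object$edge_mean) %*% object$beta_upper)
}

as_edge_rows <- function(newdata, e) {
  v <- if (inherits(newdata, "similarity_matrix")) {
    matrix(vectorize_upper(newdata), nrow = 1L)
  } else if (inherits(newdata, "edge_matrix")) {
    newdata$values
  } else if (is.matrix(newdata)) {
    if (nrow(newdata) == ncol(newdata) && ncol(newdata) != e &&
        isTRUE(all.equal(newdata, t(newdata))))
      matrix(vectorize_upper(newdata), nrow = 1L)
    else newdata
  } else matrix(as.numeric(newdata), nrow = 1L)
  if (ncol(v) != e) stop("edge dimension mismatch: got ", ncol(v),
                         ", model has ", e)
  v
}

#' Top fraction of edges by absolute weight
#'
#' Ranks edges by |weight| descending and returns the top
#' `ceiling(fraction * E)` (48 edges for the conventional top 0.1% of the
#' 47,278 edges of a 308-region network). Ties are broken by edge-index
#' order.
#'
#' @param weights Length-E edge weight vector (e.g. `beta_upper` or an
#'   activation pattern).
#' @param fraction Fraction in (0, 1] of edges to keep (default 0.001).
#' @param index Optional [edge_index()] data frame labelling the edges.
#' @return Data frame with `rank`, `edge`, `i`, `j`, `weight`.
#' @export
top_fraction_edges <- function(weights, fraction = 0.001, index = NULL) {
  if (!length(weights)) stop("empty weight vector")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n_top <- ceiling(fraction * length(weights))
  ord <- order(-abs(weights), seq_along(weights))[seq_len(n_top)]
  if (is.null(index)) {
    p <- (1 + sqrt(1 + 8 * length(weights))) / 2
    index <- if (p == round(p)) edge_index(as.integer(p)) else
      data.frame(i = NA_integer_, j = NA_integer_)[rep(1L, length(weights)), ]
  }
  data.frame(rank = seq_len(n_top), edge = ord,
             i = index$i[ord], j = index$j[ord],
             weight = weights[ord], row.names = NULL)
}
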
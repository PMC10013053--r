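#' Canonical morphometric feature names
#'
#' The nine region-level features a morphometric similarity network is built
#' from: surface area (SA), gray-matter volume (GM), cortical thickness (CT),
#' mean curvature (MC), intrinsic curvature (IC), folding index (FI), curved
#' index (CI), fractional anisotropy (FA) and mean diffusivity (MD). Feature
#' order is fixed; every feature table in the package uses these column names
#' in this order.
#'
#' @format Character vector of length 9.
#' @export
msn_features <- c("SA", "GM", "CT", "MC", "IC", "FI", "CI", "FA", "MD")

#' Z-score feature columns within a subject
#'
#' Standardizes each feature column across the regions of a single subject's
#' region-by-feature table: column mean 0, sample (n-1) standard deviation 1.
#' This within-subject standardization is what makes a single-subject
#' morphometric similarity matrix well defined.
#'
#' @param table Numeric matrix, regions x features (typically P x 9 with
#'   columns named as in [msn_features]).
#' @return Matrix of the same shape with standardized columns.
#' @export
zscore_features <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 3L) stop("need at least 3 regions to z-score features")
  if (anyNA(table)) stop("feature table contains missing values")
  sds <- apply(table, 2L, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    nm <- colnames(table)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-variance feature(s): ", paste(nm, collapse = ", "))
  }
  scale(table, center = TRUE, scale = sds)[, , drop = FALSE]
}

new_similarity_matrix <- function(values, modality, region_ids = NULL) {
  p <- nrow(values)
  if (is.null(region_ids)) {
    region_ids <- rownames(values)
    if (is.null(region_ids)) region_ids <- paste0("region", seq_len(p))
  }
  dimnames(values) <- list(region_ids, region_ids)
  structure(
    list(modality = modality, values = values, region_ids = region_ids,
         mean_profile = (rowSums(values) - 1) / (p - 1)),
    class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> modality=%s, %d regions\n",
              x$modality, nrow(x$values)))
  cat(sprintf("  mean profile: %.4f .. %.4f (mean %.4f)\n",
              min(x$mean_profile), max(x$mean_profile), mean(x$mean_profile)))
  invisible(x)
}

check_region_variance <- function(mat, what) {
  v <- apply(mat, 1L, stats::sd)
  bad <- which(v == 0 | !is.finite(v))
  if (length(bad)) {
    nm <- rownames(mat)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("constant ", what, " for region(s): ", paste(nm, collapse = ", "))
  }
}

#' Morphometric similarity matrix of one subject
#'
#' Z-scores the nine feature columns across regions, then computes the Pearson
#' correlation between every pair of regions' nine-element feature profiles.
#' The diagonal is set to exactly 1 and the mean similarity profile (mMS: the
#' mean of each row excluding the diagonal) is attached.
#'
#' @param table Regions x features numeric matrix (P >= 3).
#' @return A `similarity_matrix` with `modality = "MS"`.
#' @export
morphometric_similarity <- function(table) {
  z <- zscore_features(table)
  check_region_variance(z, "feature profile")
  m <- stats::cor(t(z))
  diag(m) <- 1
  new_similarity_matrix(m, "MS", rownames(table))
}

#' Functional connectivity matrix of one subject
#'
#' Pearson correlation between every pair of regions' time series; the
#' diagonal is 1 and the mean connectivity profile (mFC) is attached.
#'
#' @param ts Regions x timepoints numeric matrix (T >= 3).
#' @return A `similarity_matrix` with `modality = "FC"`.
#' @export
functional_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3L) stop("need at least 3 timepoints")
  check_region_variance(ts, "time series")
  m <- stats::cor(t(ts))
  diag(m) <- 1
  new_similarity_matrix(m, "FC", rownames(ts))
}

#' Ensemble (weighted-correlation) similarity matrix
#'
#' Fuses the morphometric and functional channels of one subject into a single
#' network. Each region's nine features (z-scored per feature across regions)
#' and its time series (z-scored within the region) are concatenated into one
#' vector; the matrix entry for a region pair is the weighted Pearson
#' correlation between the two concatenated vectors, with per-element weights
#' `w_ms` on the 9 feature elements and `1 - w_ms` on the T time elements
#' (weights normalized to sum to 1). `w_ms = 1` reproduces
#' [morphometric_similarity()]; `w_ms = 0` reproduces
#' [functional_connectivity()].
#'
#' @param table Regions x features matrix.
#' @param ts Regions x timepoints matrix with the same region order.
#' @param w_ms Morphometric weight in \[0, 1\].
#' @return A `similarity_matrix` with modality `"ensemble"` and attribute-free
#'   `w_ms` stored in the object.
#' @export
ensemble_similarity <- function(table, ts, w_ms) {
  if (!is.numeric(w_ms) || length(w_ms) != 1L || is.na(w_ms) ||
      w_ms < 0 || w_ms > 1)
    stop("w_ms must be a single number in [0, 1]")
  table <- as.matrix(table); ts <- as.matrix(ts)
  if (nrow(table) != nrow(ts)) stop("region counts differ between table and ts")
  zf <- zscore_features(table)                     # per feature, across regions
  check_region_variance(ts, "time series")
  zt <- t(scale(t(ts)))                            # per region, across time
  x <- cbind(zf, zt)                               # P x (9 + T)
  w <- c(rep(w_ms, ncol(zf)), rep(1 - w_ms, ncol(zt)))
  if (sum(w) <= 0) stop("all-zero weight vector")
  w <- w / sum(w)
  m <- weighted_pearson_matrix(x, w)
  diag(m) <- 1
  out <- new_similarity_matrix(m, "ensemble", rownames(table))
  out$w_ms <- w_ms
  out
}

# Weighted Pearson correlation between rows of x with element weights w
# (weights sum to 1): weighted means/variances/covariances.
weighted_pearson_matrix <- function(x, w) {
  mu <- as.vector(x %*% w)
  xc <- x - mu
  xw <- xc * rep(sqrt(w), each = nrow(xc))
  cv <- tcrossprod(xw)                 # weighted covariance matrix
  s <- sqrt(diag(cv))
  if (any(s == 0 | !is.finite(s)))
    stop("zero weighted variance for region(s): ",
         paste(which(s == 0 | !is.finite(s)), collapse = ", "))
  cv / tcrossprod(s)
}

#' Edge index of a P-region network
#'
#' The fixed edge ordering used everywhere in the package: the strict upper
#' triangle traversed row-major, i.e. (1,2), (1,3), ..., (1,P), (2,3), ...
#' Identical across subjects and between fit and predict.
#'
#' @param p Number of regions.
#' @return Data frame with integer columns `i`, `j` (i < j), P(P-1)/2 rows.
#' @export
edge_index <- function(p) {
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p), use.names = FALSE)
  data.frame(i = i, j = as.integer(j))
}

#' Vectorize the strict upper triangle of a similarity matrix
#'
#' Returns the off-diagonal upper triangle in the row-major order of
#' [edge_index()]; length P(P-1)/2 (47,278 at P = 308).
#'
#' @param m A `similarity_matrix` or a symmetric numeric matrix.
#' @param tol Absolute asymmetry tolerance (default 1e-10).
#' @return Numeric vector of edge values.
#' @export
vectorize_upper <- function(m, tol = 1e-10) {
  v <- if (inherits(m, "similarity_matrix")) m$values else as.matrix(m)
  if (nrow(v) != ncol(v)) stop("matrix is not square")
  if (max(abs(v - t(v))) > tol) stop("matrix is asymmetric beyond tolerance")
  vt <- t(v)
  vt[lower.tri(vt)]          # column-major lower triangle of t(v) = row-major upper
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper()]; the diagonal is set to 1.
#'
#' @param edges Edge vector of length P(P-1)/2.
#' @param p Number of regions.
#' @return P x P symmetric matrix.
#' @export
unvectorize_upper <- function(edges, p) {
  if (length(edges) != p * (p - 1L) / 2L)
    stop("edge vector length does not match p")
  m <- matrix(0, p, p)
  mt <- t(m)
  mt[lower.tri(mt)] <- edges
  m <- t(mt)
  m <- m + t(m)
  diag(m) <- 1
  m
}

#' Stack subjects' networks into an edge matrix
#'
#' Vectorizes each subject's similarity matrix and row-binds them into the
#' N x P(P-1)/2 matrix R used by the multivariate models (136 x 47,278 at the
#' reference design of 136 subjects and 308 regions).
#'
#' @param matrices List of `similarity_matrix` objects sharing P and region
#'   order.
#' @param subject_ids Optional subject labels (defaults to names or s1..sN).
#' @return An `edge_matrix`: list with `values` (N x E), `subject_ids`,
#'   `edge_index`, `p`.
#' @export
stack_subjects <- function(matrices, subject_ids = NULL) {
  if (!length(matrices)) stop("empty list of matrices")
  ps <- vapply(matrices, function(m)
    nrow(if (inherits(m, "similarity_matrix")) m$values else m), integer(1))
  if (length(unique(ps)) != 1L)
    stop("matrices have mismatched region counts: ",
         paste(unique(ps), collapse = ", "))
  p <- ps[[1L]]
  if (is.null(subject_ids)) {
    subject_ids <- names(matrices)
    if (is.null(subject_ids)) subject_ids <- paste0("s", seq_along(matrices))
  }
  values <- do.call(rbind, lapply(matrices, vectorize_upper))
  rownames(values) <- subject_ids
  structure(list(values = values, subject_ids = subject_ids,
                 edge_index = edge_index(p), p = p),
            class = "edge_matrix")
}

#' @export
print.edge_matrix <- function(x, ...) {
  cat(sprintf("<edge_matrix> %d subjects x %d edges (P = %d)\n",
              nrow(x$values), ncol(x$values), x$p))
  invisible(x)
}
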
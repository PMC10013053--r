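#' Area under the ROC curve
#'
#' Rank-sum AUC: the fraction of patient-control pairs in which the patient
#' scores higher, ties counted one half — identical to Mann-Whitney
#' U / (n1 * n0).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = patient, scored high).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Step-function ROC of a score vector: false-positive rate vs. true-positive
#' rate at every threshold, from (0, 0) to (1, 1).
#'
#' @inheritParams auc
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes must be present")
  ord <- order(-scores)
  lab <- labels[ord]
  tpr <- cumsum(lab == 1L) / sum(lab == 1L)
  fpr <- cumsum(lab == 0L) / sum(lab == 0L)
  keep <- !duplicated(scores[ord], fromLast = TRUE)  # one point per threshold
  data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' Two-group test on model scores
#'
#' Compares patient vs. control score distributions with a Student
#' two-sample t-test (equal variance, df = n1 + n0 - 2), a Wilcoxon
#' rank-sum test (normal approximation), or an automatic choice: a
#' Shapiro-Wilk test at 0.05 on the pooled within-group residuals selects
#' the t-test when normality is not rejected, the rank-sum test otherwise.
#'
#' @inheritParams auc
#' @param method `"auto"`, `"t"` or `"wilcoxon"`.
#' @return List with `statistic`, `p`, `method`, `df` (t only).
#' @export
group_score_test <- function(scores, labels, method = c("auto", "t", "wilcoxon")) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  a <- scores[labels == 1L]; b <- scores[labels == 0L]
  if (length(a) < 3L || length(b) < 3L)
    stop("need at least 3 subjects per class")
  if (method == "auto") {
    res <- c(a - mean(a), b - mean(b))
    method <- if (stats::shapiro.test(res)$p.value >= 0.05) "t" else "wilcoxon"
  }
  if (method == "t") {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         method = "t", df = unname(tt$parameter))
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    list(statistic = unname(wt$statistic), p = wt$p.value,
         method = "wilcoxon", df = NA_real_)
  }
}

#' Shared variance between two group-mean networks
#'
#' Squared Pearson correlation between the vectorized upper triangles of two
#' group-mean similarity matrices, as a percentage — the overlap statistic
#' used to ask how much of the morphometric and functional networks' edge
#' variation is common.
#'
#' @param m1,m2 `similarity_matrix` objects or symmetric matrices with the
#'   same regions.
#' @return Shared variance in percent (0-100).
#' @export
network_variance_overlap <- function(m1, m2) {
  e1 <- vectorize_upper(m1); e2 <- vectorize_upper(m2)
  if (length(e1) != length(e2)) stop("matrices have different sizes")
  if (stats::sd(e1) == 0 || stats::sd(e2) == 0)
    stop("zero edge variance")
  100 * stats::cor(e1, e2)^2
}

#' Mean similarity matrix over subjects
#'
#' @param cohort An `msn_cohort`.
#' @param modality `"MS"` or `"FC"`.
#' @param subset Optional subject index (e.g. `cohort$labels == 0`).
#' @return A `similarity_matrix` averaging the selected subjects' networks.
#' @export
cohort_mean_network <- function(cohort, modality = c("MS", "FC"),
                                subset = NULL) {
  modality <- match.arg(modality)
  idx <- if (is.null(subset)) seq_along(cohort$subject_ids)
  else if (is.logical(subset)) which(rep_len(subset, length(cohort$subject_ids)))
  else as.integer(subset)
  mats <- lapply(idx, function(s) switch(modality,
    MS = morphometric_similarity(cohort$features[[s]])$values,
    FC = functional_connectivity(cohort$timeseries[[s]])$values))
  new_similarity_matrix(Reduce(`+`, mats) / length(mats), modality,
                        cohort$region_ids)
}

#' Run the discovery/validation discrimination experiment
#'
#' Fits the three discrimination models on the discovery half and scores the
#' validation half: the univariable model (validation scored by the
#' discovery half's largest-|t| region, oriented by its sign), the
#' per-region logistic (mMS multivariable) model, and the PCA-logistic
#' network model. With `modality = "FC"` the same models run on mFC profiles
#' and FCN edge matrices; with `"ensemble"`, on the weighted fusion.
#'
#' @param discovery,validation `msn_cohort` halves.
#' @param modality `"MS"`, `"FC"` or `"ensemble"`.
#' @param w_ms Ensemble weight (only used for `modality = "ensemble"`).
#' @param models Character subset of `c("univar", "profile", "network")`.
#' @param alpha Replication significance level for the univariable model.
#' @return An `evaluation_report`: per-model validation AUC, group tests on
#'   validation scores, the fitted models, and the replicated regions.
#' @export
run_discrimination <- function(discovery, validation,
                               modality = c("MS", "FC", "ensemble"),
                               w_ms = 0.5,
                               models = c("univar", "profile", "network"),
                               alpha = 0.05) {
  modality <- match.arg(modality)
  profile_mod <- if (modality == "FC") "FC" else "MS"
  out <- list(modality = modality, w_ms = if (modality == "ensemble") w_ms
              else NA_real_, auc = c(), tests = list(), models = list())

  if (any(c("univar", "profile") %in% models)) {
    mms_d <- cohort_mean_profiles(discovery, profile_mod)
    mms_v <- cohort_mean_profiles(validation, profile_mod)
  }
  if ("univar" %in% models) {
    ut_d <- univariable_region_test(mms_d, discovery$labels,
                                    discovery$covariates)
    ut_v <- univariable_region_test(mms_v, validation$labels,
                                    validation$covariates)
    best <- which.max(abs(ut_d$t))
    sc <- mms_v[, best] * ut_d$sign[best]
    out$auc["univar"] <- auc(sc, validation$labels)
    out$tests$univar <- group_score_test(sc, validation$labels)
    out$models$univar <- list(discovery = ut_d, validation = ut_v,
                              best_region = best,
                              replicated = replicated_regions(ut_d, ut_v, alpha))
  }
  if ("profile" %in% models) {
    pm <- fit_region_logistics(mms_d, discovery$labels, discovery$covariates)
    sc <- score_mms(pm, mms_v)
    out$auc["profile"] <- auc(sc, validation$labels)
    out$tests$profile <- group_score_test(sc, validation$labels)
    out$models$profile <- pm
  }
  if ("network" %in% models) {
    r_d <- cohort_edge_matrix(discovery, modality, w_ms)
    r_v <- cohort_edge_matrix(validation, modality, w_ms)
    nc <- fit_network_classifier(r_d, discovery$labels, discovery$covariates)
    sc <- predict(nc, r_v)
    out$auc["network"] <- auc(sc, validation$labels)
    out$tests$network <- group_score_test(sc, validation$labels)
    out$models$network <- nc
  }
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> modality=%s\n", x$modality))
  for (m in names(x$auc))
    cat(sprintf("  %-8s validation AUC = %.3f (%s p = %.3g)\n",
                m, x$auc[m], x$tests[[m]]$method, x$tests[[m]]$p))
  invisible(x)
}

#' Re-run an experiment with discovery and validation switched
#'
#' Refits every requested model with the roles of the two halves exchanged
#' — the sampling-variability check of the discovery/validation design.
#'
#' @inheritParams run_discrimination
#' @param ... Passed to [run_discrimination()].
#' @return An `evaluation_report` for the switched orientation.
#' @export
switch_halves <- function(discovery, validation, ...) {
  run_discrimination(validation, discovery, ...)
}

#' Sweep the ensemble weight
#'
#' For each weight in `w_grid`, builds the ensemble networks, fits the
#' network classifier (discovery) and evaluates its validation AUC, and —
#' when patient intensity is available — fits the PCA-LASSO predictor on
#' discovery patients and reports the validation correlation between the
#' dot-product score and observed intensity, with its two-sided p-value
#' against the null r = 0.
#'
#' @param discovery,validation `msn_cohort` halves.
#' @param w_grid Weights in \[0, 1\] (default 0, 0.1, ..., 1).
#' @param predict_intensity Also run the intensity predictor per weight.
#' @return Data frame with columns `w_ms`, `auc`, `r`, `p_r`.
#' @export
weight_sweep <- function(discovery, validation,
                         w_grid = seq(0, 1, by = 0.1),
                         predict_intensity = TRUE) {
  if (!length(w_grid)) stop("empty weight grid")
  if (any(w_grid < 0 | w_grid > 1)) stop("weights must lie in [0, 1]")
  rows <- lapply(w_grid, function(w) {
    r_d <- cohort_edge_matrix(discovery, "ensemble", w)
    r_v <- cohort_edge_matrix(validation, "ensemble", w)
    nc <- fit_network_classifier(r_d, discovery$labels, discovery$covariates)
    a <- auc(predict(nc, r_v), validation$labels)
    r_val <- p_val <- NA_real_
    if (predict_intensity) {
      pd <- which(discovery$labels == 1L)
      pv <- which(validation$labels == 1L)
      lp <- fit_pca_lasso(r_d$values[pd, , drop = FALSE],
                          discovery$intensity[pd],
                          discovery$covariates[pd, , drop = FALSE])
      sc <- predict(lp, r_v$values[pv, , drop = FALSE], score_only = TRUE)
      if (stats::sd(sc) > 0) {
        ev <- evaluate_prediction(sc, validation$intensity[pv])
        r_val <- ev$r; p_val <- ev$p
      }
    }
    data.frame(w_ms = w, auc = a, r = r_val, p_r = p_val)
  })
  do.call(rbind, rows)
}
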
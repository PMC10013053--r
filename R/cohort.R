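#' Specification of a synthetic case-control cohort
#'
#' Describes the study design emulated by [generate_cohort()]: two matched
#' arms (patients with chronic pain vs. healthy controls), nine morphometric
#' features per region, region-averaged BOLD-like series, six covariates,
#' a planted group effect on selected regions and a planted pain-intensity
#' signal carried by selected network edges.
#'
#' Defaults reproduce the reference design: 308 regions, 226 retained fMRI
#' volumes, 68 subjects per arm per half (so the full cohort holds 136
#' patients and 136 controls and splits into 68+68 discovery and validation
#' halves), a standardized shift of 1.5 on 10 regions, a 5-edge pain signal
#' and intensity noise SD of 5 on the 0-100 scale.
#'
#' @param n_regions Number of cortical regions P (default 308).
#' @param n_timepoints Number of BOLD samples T (default 226).
#' @param n_per_group Subjects per arm per half (default 68); the generated
#'   cohort holds `2 * n_per_group` patients and as many controls.
#' @param effect_regions Integer region indices carrying the group effect.
#' @param effect_size Standardized mean shift d applied (with an alternating
#'   sign pattern across the nine features) to patients' feature cells on
#'   `effect_regions`, in units of each feature's across-region SD.
#' @param pain_edge_set Integer matrix or data frame with columns i, j (i < j)
#'   of region pairs whose MSN edges drive pain intensity; `NULL` picks
#'   5 default pairs among the first regions.
#' @param pain_coefficients Per-edge weights gamma_e (recycled).
#' @param pain_noise_sd SD of the additive intensity noise (0-100 scale).
#' @param covariate_confounding Single strength in \[0, 1\] controlling how
#'   strongly covariate distributions differ between arms (0 = none).
#' @param n_communities Latent communities shared by features and time series.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_regions = 308L, n_timepoints = 226L,
                        n_per_group = 68L,
                        effect_regions = 1:10,
                        effect_size = 1.5,
                        pain_edge_set = NULL,
                        pain_coefficients = 40,
                        pain_noise_sd = 5,
                        covariate_confounding = 0,
                        n_communities = 4L) {
  if (is.null(pain_edge_set)) {
    # default: edges among the first community's regions (1, 1+q, 1+2q, ...),
    # the community whose coupling the severity factor modulates
    comm1 <- seq(1L, n_regions, by = n_communities)
    if (length(comm1) >= 5L) {
      c1 <- comm1[1:5]
      pain_edge_set <- cbind(i = c(c1[1], c1[1], c1[2], c1[2], c1[3]),
                             j = c(c1[2], c1[3], c1[3], c1[4], c1[5]))
    } else {
      pain_edge_set <- cbind(i = 1L, j = 2L)
    }
  }
  pain_edge_set <- as.matrix(pain_edge_set)
  spec <- structure(list(
    n_regions = as.integer(n_regions),
    n_features = 9L,
    n_timepoints = as.integer(n_timepoints),
    n_per_group = as.integer(n_per_group),
    effect_regions = as.integer(effect_regions),
    effect_size = effect_size,
    pain_edge_set = pain_edge_set,
    pain_coefficients = rep_len(pain_coefficients, nrow(pain_edge_set)),
    pain_noise_sd = pain_noise_sd,
    covariate_confounding = covariate_confounding,
    n_communities = as.integer(n_communities)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_regions < 3L) stop("invalid cohort spec: n_regions must be >= 3")
    if (n_per_group < 2L) stop("invalid cohort spec: n_per_group must be >= 2")
    if (effect_size < 0) stop("invalid cohort spec: effect_size must be >= 0")
    if (pain_noise_sd < 0) stop("invalid cohort spec: pain_noise_sd must be >= 0")
    if (length(effect_regions) &&
        (max(effect_regions) > n_regions || min(effect_regions) < 1L))
      stop("invalid cohort spec: effect_regions out of range 1..n_regions")
    if (nrow(pain_edge_set)) {
      if (max(pain_edge_set) > n_regions || min(pain_edge_set) < 1L)
        stop("invalid cohort spec: pain_edge_set indices out of range")
      if (any(pain_edge_set[, 1L] >= pain_edge_set[, 2L]))
        stop("invalid cohort spec: pain_edge_set must have i < j")
    }
    if (covariate_confounding < 0 || covariate_confounding > 1)
      stop("invalid cohort spec: covariate_confounding must be in [0, 1]")
  })
  invisible(spec)
}

# Evaluate expr with the RNG fixed to `seed`, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Per-feature baseline scales: plausible magnitudes for SA (mm^2), GM (mm^3),
# CT (mm), curvatures, folding/curved indices, FA, MD. Only relative
# variation matters downstream (features are z-scored per subject).
feature_baselines <- function() {
  list(mean = c(SA = 400, GM = 1200, CT = 2.5, MC = 0.12, IC = 0.15,
                FI = 15, CI = 4, FA = 0.35, MD = 0.85),
       sd = c(SA = 90, GM = 260, CT = 0.25, MC = 0.03, IC = 0.05,
              FI = 4, CI = 1, FA = 0.04, MD = 0.08))
}

#' Generate a synthetic case-control cohort
#'
#' Draws per-subject region x feature tables from a community-structured
#' latent-factor model, region x time BOLD-like series sharing the same
#' community assignment, six covariates, binary pain-state labels and 0-100
#' pain-intensity scores. Patients receive an additive shift of
#' `effect_size * feature SD` (alternating sign across the nine features) on
#' the feature cells of `effect_regions`, and patient intensity is computed
#' from the subject's own MSN edges:
#' `clamp(alpha + sum_e gamma_e * msn_e + eps, 0, 100)` with
#' `eps ~ N(0, pain_noise_sd)` and `alpha` chosen so intensity is centred
#' near 50. Identical seeds give bit-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed governing all randomness.
#' @return An `msn_cohort`: list with `features` (list of P x 9 matrices),
#'   `timeseries` (list of P x T matrices), `covariates` (data frame),
#'   `labels` (0/1, 1 = patient), `intensity` (0-100; NA for controls),
#'   `subject_ids`, `region_ids`, and `truth` (the planted effects).
#' @export
generate_cohort <- function(spec, seed = 1L) {
  validate_cohort_spec(spec)
  with_seed(seed, {
    p <- spec$n_regions; q <- spec$n_communities
    n_pat <- 2L * spec$n_per_group; n_con <- 2L * spec$n_per_group
    n <- n_pat + n_con
    labels <- c(rep(1L, n_pat), rep(0L, n_con))
    subject_ids <- sprintf("%s%03d", ifelse(labels == 1L, "pat", "con"),
                           c(seq_len(n_pat), seq_len(n_con)))
    region_ids <- sprintf("region%03d", seq_len(p))
    community <- rep_len(seq_len(q), p)

    base <- feature_baselines()
    # community loading matrix: regions load mostly on their own community
    load_f <- matrix(0.25, p, q)
    load_f[cbind(seq_len(p), community)] <- 1
    sign_pattern <- rep_len(c(1, -1), spec$n_features)

    # latent severity: a per-subject factor modulating how strongly the
    # first community's regions load on their shared factor; this puts a
    # coherent, leading-variance direction into edge space that the default
    # pain edges read out (mimicking network-level coupling differences)
    severity <- stats::rnorm(n)
    comm1 <- which(community == 1L)

    features <- vector("list", n)
    for (s in seq_len(n)) {
      fac <- matrix(stats::rnorm(q * spec$n_features), q, spec$n_features)
      load_s <- load_f
      load_s[comm1, 1L] <- 1 + 0.4 * severity[s]
      z <- load_s %*% fac + matrix(stats::rnorm(p * spec$n_features, sd = 0.8),
                                   p, spec$n_features)
      x <- sweep(sweep(z, 2L, base$sd, "*"), 2L, base$mean, "+")
      if (labels[s] == 1L && spec$effect_size > 0 && length(spec$effect_regions))
        x[spec$effect_regions, ] <- x[spec$effect_regions, ] +
          rep(spec$effect_size * base$sd * sign_pattern,
              each = length(spec$effect_regions))
      dimnames(x) <- list(region_ids, msn_features)
      features[[s]] <- x
    }

    # the functional channel shares only part of the morphometric community
    # structure (odd regions keep their community, even regions are
    # reassigned), so the two mean networks overlap only partially
    community_ts <- ifelse(seq_len(p) %% 2L == 1L, community,
                           rev(community))
    load_t <- matrix(0.2, p, q)
    load_t[cbind(seq_len(p), community_ts)] <- 0.9
    timeseries <- vector("list", n)
    for (s in seq_len(n)) {
      g <- matrix(stats::rnorm(q * spec$n_timepoints), q, spec$n_timepoints)
      ts <- load_t %*% g + matrix(stats::rnorm(p * spec$n_timepoints, sd = 0.9),
                                  p, spec$n_timepoints)
      rownames(ts) <- region_ids
      timeseries[[s]] <- ts
    }

    cc <- spec$covariate_confounding
    covariates <- data.frame(
      age = pmin(85, pmax(18, stats::rnorm(n, 44 + 2 * cc * labels, 13))),
      sex = stats::rbinom(n, 1L, 0.6),
      bmi = stats::rnorm(n, 23 + 1.5 * cc * labels, 3),
      education = stats::rbinom(n, 1L, 0.5 - 0.2 * cc * labels),
      alcohol = sample(0:2, n, replace = TRUE),
      exercise = sample(0:2, n, replace = TRUE),
      row.names = subject_ids)

    intensity <- rep(NA_real_, n)
    if (n_pat > 0L) {
      es <- spec$pain_edge_set
      msn_edges <- vapply(which(labels == 1L), function(s) {
        m <- morphometric_similarity(features[[s]])$values
        m[cbind(es[, 1L], es[, 2L])]
      }, numeric(nrow(es)))
      msn_edges <- matrix(msn_edges, nrow = n_pat, byrow = TRUE)
      signal <- as.vector(msn_edges %*% spec$pain_coefficients)
      alpha <- 50 - mean(signal)
      eps <- stats::rnorm(n_pat, 0, spec$pain_noise_sd)
      intensity[labels == 1L] <- pmin(100, pmax(0, alpha + signal + eps))
    }

    structure(list(
      features = stats::setNames(features, subject_ids),
      timeseries = stats::setNames(timeseries, subject_ids),
      covariates = covariates,
      labels = labels,
      intensity = intensity,
      subject_ids = subject_ids,
      region_ids = region_ids,
      truth = list(effect_regions = spec$effect_regions,
                   effect_size = spec$effect_size,
                   pain_edge_set = spec$pain_edge_set,
                   pain_coefficients = spec$pain_coefficients),
      spec = spec, seed = seed), class = "msn_cohort")
  })
}

#' @export
print.msn_cohort <- function(x, ...) {
  cat(sprintf("<msn_cohort> %d subjects (%d patients, %d controls), %d regions\n",
              length(x$subject_ids), sum(x$labels == 1L), sum(x$labels == 0L),
              length(x$region_ids)))
  invisible(x)
}

subset_cohort <- function(cohort, idx) {
  structure(list(
    features = cohort$features[idx],
    timeseries = cohort$timeseries[idx],
    covariates = cohort$covariates[idx, , drop = FALSE],
    labels = cohort$labels[idx],
    intensity = cohort$intensity[idx],
    subject_ids = cohort$subject_ids[idx],
    region_ids = cohort$region_ids,
    truth = cohort$truth, spec = cohort$spec, seed = cohort$seed),
    class = "msn_cohort")
}

#' Split a cohort into discovery and validation halves
#'
#' Patients and controls are each split evenly at random into two disjoint
#' halves, mirroring the even allocation of a case-control sample into an
#' exploratory (discovery) and a validation group. Reproducible by seed.
#'
#' @param cohort An `msn_cohort`.
#' @param seed Integer seed for the random allocation.
#' @return List with `discovery` and `validation` cohort views.
#' @export
allocate_split <- function(cohort, seed = 1L) {
  pat <- which(cohort$labels == 1L)
  con <- which(cohort$labels == 0L)
  if (length(pat) %% 2L || length(con) %% 2L)
    stop("odd group size: drop one subject explicitly before splitting ",
         "(patients = ", length(pat), ", controls = ", length(con), ")")
  with_seed(seed, {
    pat_d <- sort(sample(pat, length(pat) / 2L))
    con_d <- sort(sample(con, length(con) / 2L))
    disc <- sort(c(pat_d, con_d))
    vali <- setdiff(seq_along(cohort$labels), disc)
    list(discovery = subset_cohort(cohort, disc),
         validation = subset_cohort(cohort, vali))
  })
}

#' Build the edge matrix of a cohort
#'
#' Constructs one network per subject (MSN from the feature tables, FCN from
#' the time series, or the weighted ensemble of both) and stacks the
#' vectorized upper triangles into the subjects x edges matrix R.
#'
#' @param cohort An `msn_cohort`.
#' @param modality `"MS"`, `"FC"` or `"ensemble"`.
#' @param w_ms Morphometric weight, used when `modality = "ensemble"`.
#' @return An `edge_matrix`.
#' @export
cohort_edge_matrix <- function(cohort, modality = c("MS", "FC", "ensemble"),
                               w_ms = 0.5) {
  modality <- match.arg(modality)
  mats <- switch(modality,
    MS = lapply(cohort$features, morphometric_similarity),
    FC = lapply(cohort$timeseries, functional_connectivity),
    ensemble = Map(function(f, t) ensemble_similarity(f, t, w_ms),
                   cohort$features, cohort$timeseries))
  stack_subjects(mats, cohort$subject_ids)
}

#' Mean-similarity profile matrix of a cohort
#'
#' @param cohort An `msn_cohort`.
#' @param modality `"MS"` or `"FC"`.
#' @return Subjects x regions matrix of mMS (or mFC) profiles.
#' @export
cohort_mean_profiles <- function(cohort, modality = c("MS", "FC")) {
  modality <- match.arg(modality)
  mats <- switch(modality,
    MS = lapply(cohort$features, morphometric_similarity),
    FC = lapply(cohort$timeseries, functional_connectivity))
  out <- do.call(rbind, lapply(mats, function(m) m$mean_profile))
  dimnames(out) <- list(cohort$subject_ids, cohort$region_ids)
  out
}
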
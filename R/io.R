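#' Read a region-by-feature table
#'
#' Tab-delimited text with a `region` column and exactly the nine canonical
#' feature columns ([msn_features]), one row per region. Region order is
#' preserved as given.
#'
#' @param path File path.
#' @return Numeric P x 9 matrix with region rownames.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"region" %in% names(df)) stop("feature table lacks a 'region' column")
  missing <- setdiff(msn_features, names(df))
  if (length(missing))
    stop("feature table lacks feature column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c("region", msn_features))
  if (length(extra))
    stop("feature table has unexpected column(s): ",
         paste(extra, collapse = ", "))
  if (anyDuplicated(df$region))
    stop("duplicate region id(s): ",
         paste(unique(df$region[duplicated(df$region)]), collapse = ", "))
  m <- as.matrix(df[msn_features])
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)
    stop("non-numeric or missing cell at row ", bad[1, 1],
         ", column ", msn_features[bad[1, 2]])
  }
  rownames(m) <- df$region
  m
}

#' Write a region-by-feature table
#'
#' @param table Numeric P x 9 matrix with region rownames.
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(region = rownames(table) %||% paste0("region", seq_len(nrow(table))),
                   full_precision(table), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 17 significant digits: enough to round-trip a double through text exactly
full_precision <- function(m) {
  out <- matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a region-by-time series table
#'
#' Tab-delimited text with a `region` column followed by one column per
#' timepoint; T is inferred from the columns.
#'
#' @param path File path.
#' @return Numeric P x T matrix with region rownames.
#' @export
read_timeseries_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty time-series table: ", path)
  if (!"region" %in% names(df)) stop("time-series table lacks a 'region' column")
  m <- as.matrix(df[setdiff(names(df), "region")])
  if (!ncol(m)) stop("time-series table has no timepoint columns")
  if (!is.numeric(m) || anyNA(m)) stop("non-numeric or missing cells in ", path)
  rownames(m) <- df$region
  m
}

#' Write a region-by-time series table
#'
#' @param ts Numeric P x T matrix with region rownames.
#' @param path Output path.
#' @export
write_timeseries_table <- function(ts, path) {
  df <- data.frame(region = rownames(ts) %||% paste0("region", seq_len(nrow(ts))),
                   full_precision(ts), check.names = FALSE)
  names(df)[-1L] <- paste0("t", seq_len(ncol(ts)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to a directory of delimited tables
#'
#' One feature table and one time-series table per subject, a single subject
#' table (covariates, label, intensity) and a JSON-style sidecar recording
#' the planted truth and the generating seed.
#'
#' @param cohort An `msn_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "features"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE)
  for (s in cohort$subject_ids) {
    write_feature_table(cohort$features[[s]],
                        file.path(dir, "features", paste0(s, ".tsv")))
    write_timeseries_table(cohort$timeseries[[s]],
                           file.path(dir, "timeseries", paste0(s, ".tsv")))
  }
  subj <- data.frame(subject = cohort$subject_ids, cohort$covariates,
                     label = cohort$labels, intensity = cohort$intensity)
  utils::write.table(subj, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  sidecar <- paste0(
    '{"seed": ', cohort$seed,
    ', "effect_regions": [', paste(truth$effect_regions, collapse = ","),
    '], "effect_size": ', truth$effect_size,
    ', "pain_edges": [',
    paste(sprintf('[%d,%d]', truth$pain_edge_set[, 1], truth$pain_edge_set[, 2]),
          collapse = ","),
    '], "pain_coefficients": [',
    paste(truth$pain_coefficients, collapse = ","), ']}')
  writeLines(sidecar, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return An `msn_cohort` (without the generating spec; `truth` is not
#'   re-parsed beyond the sidecar text).
#' @export
read_cohort <- function(dir) {
  subj <- utils::read.delim(file.path(dir, "subjects.tsv"),
                            stringsAsFactors = FALSE)
  ids <- subj$subject
  features <- lapply(ids, function(s)
    read_feature_table(file.path(dir, "features", paste0(s, ".tsv"))))
  timeseries <- lapply(ids, function(s)
    read_timeseries_table(file.path(dir, "timeseries", paste0(s, ".tsv"))))
  structure(list(
    features = stats::setNames(features, ids),
    timeseries = stats::setNames(timeseries, ids),
    covariates = subj[covariate_names],
    labels = subj$label,
    intensity = subj$intensity,
    subject_ids = ids,
    region_ids = rownames(features[[1L]]),
    truth = NULL, spec = NULL, seed = NA_integer_), class = "msn_cohort")
}

#' Write a similarity matrix as delimited text
#'
#' @param m A `similarity_matrix`.
#' @param path Output path (tab-delimited, region labels as header).
#' @export
write_similarity_matrix <- function(m, path) {
  utils::write.table(m$values, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
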
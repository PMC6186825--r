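# Functional-connectivity feature extraction from ROI time series.

#' Construct a per-subject ROI time-series object
#'
#' Holds one subject's representative regional signals: a matrix with one row
#' per timepoint and one column per brain region (e.g., the region-mean BOLD
#' signal after preprocessing and parcellation, which happen upstream of this
#' package).
#'
#' @param signals Numeric matrix, T timepoints x R regions, T >= 3, R >= 2,
#'   no missing values.
#' @param subject_id Subject identifier (single string).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(signals, subject_id = "subject") {
  if (!is.matrix(signals) || !is.numeric(signals))
    ewr_stop("`signals` must be a numeric matrix (timepoints x regions)")
  if (nrow(signals) < 3L)
    ewr_stop("need at least 3 timepoints to compute correlations")
  if (ncol(signals) < 2L)
    ewr_stop("need at least 2 regions")
  if (anyNA(signals) || any(!is.finite(signals)))
    ewr_stop("`signals` contains missing or non-finite values")
  if (!is.character(subject_id) || length(subject_id) != 1L)
    ewr_stop("`subject_id` must be a single string")
  structure(
    list(subject_id = subject_id, signals = signals,
         region_count = ncol(signals)),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("roi_timeseries '%s': %d timepoints x %d regions\n",
              x$subject_id, nrow(x$signals), x$region_count))
  invisible(x)
}

constant_columns <- function(signals) {
  which(apply(signals, 2L, function(col) max(col) - min(col) == 0))
}

#' Compute the functional-connectivity feature vector of one subject
#'
#' Entry `k` is the Pearson correlation between the two regional signals given
#' by `index_to_pair(k, map)`; features are ordered row-major over the upper
#' triangle of the region correlation matrix. Raw Pearson r is used (no
#' Fisher z-transform), so every feature lies in `[-1, 1]`.
#'
#' A constant regional signal has undefined correlations. By default this is
#' an error naming the offending region(s); with `on_constant = "zero"` the
#' affected features are set to 0 and a warning is emitted.
#'
#' @param ts A [roi_timeseries()].
#' @param map A [pair_index_map()] with matching region count; built
#'   automatically when `NULL`.
#' @param on_constant Either `"error"` (default) or `"zero"`.
#' @return Numeric vector of length `R*(R-1)/2`.
#' @export
compute_fc_vector <- function(ts, map = NULL, on_constant = c("error", "zero")) {
  stopifnot(inherits(ts, "roi_timeseries"))
  on_constant <- match.arg(on_constant)
  if (is.null(map)) map <- pair_index_map(ts$region_count)
  if (map$region_count != ts$region_count)
    ewr_stop(sprintf("map is for %d regions but subject '%s' has %d",
                     map$region_count, ts$subject_id, ts$region_count))
  const <- constant_columns(ts$signals)
  if (length(const) > 0L) {
    if (on_constant == "error")
      ewr_stop(sprintf(
        "constant signal for region(s) %s of subject '%s'; correlation undefined",
        paste(const, collapse = ", "), ts$subject_id), class = "degenerate_signal")
    warning(sprintf("subject '%s': constant region(s) %s; affected features set to 0",
                    ts$subject_id, paste(const, collapse = ", ")))
  }
  C <- suppressWarnings(stats::cor(ts$signals))
  # row-major upper triangle of C == column-major lower triangle of t(C)
  tC <- t(C)
  fc <- tC[lower.tri(tC)]
  fc[!is.finite(fc)] <- 0
  fc <- pmin(1, pmax(-1, fc))
  fc
}

#' Build a labeled functional-connectivity dataset
#'
#' Converts a list of subjects' ROI time series into the N x d feature matrix
#' consumed by the ensemble, where d = R*(R-1)/2. Row order follows the input
#' order of `series`.
#'
#' @param series List of [roi_timeseries()] objects sharing one region count.
#' @param labels Named vector mapping every subject id to `+1` or `-1`.
#' @param on_constant Passed to [compute_fc_vector()].
#' @return An object of class `fc_dataset`: list with `features` (N x d
#'   matrix), `labels` (integer +1/-1), `subject_ids`, and `pair_map`.
#' @export
build_dataset <- function(series, labels, on_constant = c("error", "zero")) {
  on_constant <- match.arg(on_constant)
  if (length(series) == 0L) ewr_stop("`series` is empty")
  if (!all(vapply(series, inherits, logical(1), "roi_timeseries")))
    ewr_stop("`series` must be a list of roi_timeseries objects")
  Rs <- vapply(series, function(s) s$region_count, integer(1))
  if (length(unique(Rs)) != 1L)
    ewr_stop(sprintf("inconsistent region counts across subjects: %s",
                     paste(unique(Rs), collapse = ", ")))
  ids <- vapply(series, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids))
    ewr_stop(sprintf("duplicate subject ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab) > 0L)
    ewr_stop(sprintf("no label for subject(s): %s",
                     paste(missing_lab, collapse = ", ")))
  lab <- as.integer(labels[ids])
  if (!all(lab %in% c(-1L, 1L)))
    ewr_stop("labels must take values +1 and -1")
  if (length(unique(lab)) < 2L)
    ewr_stop("both classes (+1 and -1) must be present")
  map <- pair_index_map(Rs[1])
  feats <- t(vapply(series, compute_fc_vector, numeric(map$n_features),
                    map = map, on_constant = on_constant))
  rownames(feats) <- ids
  structure(
    list(features = feats, labels = lab, subject_ids = ids, pair_map = map),
    class = "fc_dataset"
  )
}

#' @export
print.fc_dataset <- function(x, ...) {
  cat(sprintf("fc_dataset: %d subjects x %d FC features (%d regions); classes +1: %d, -1: %d\n",
              nrow(x$features), ncol(x$features), x$pair_map$region_count,
              sum(x$labels == 1L), sum(x$labels == -1L)))
  invisible(x)
}
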
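# Reading the external text formats and persisting fitted objects.
#
# Per-subject time series are delimited text (T rows x R columns); the label
# table is a two-column CSV; region names are one per line. Fitted ensembles
# are stored as self-describing JSON and must round-trip to identical
# predictions.

ENSEMBLE_FORMAT_VERSION <- "1"

#' Read one subject's ROI time-series matrix
#'
#' Delimiter is auto-detected from the extension: `.csv` is comma-separated,
#' `.tsv` tab-separated, anything else whitespace-separated. No header row
#' by default.
#'
#' @param path File path.
#' @param header Whether the file has a header row.
#' @param subject_id Subject id; defaults to the file name without extension.
#' @return A [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path, header = FALSE, subject_id = NULL) {
  if (!file.exists(path)) ewr_stop(sprintf("time-series file not found: %s", path))
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  sep <- switch(tolower(sub(".*\\.", "", path)), csv = ",", tsv = "\t", "")
  df <- utils::read.table(path, header = header, sep = sep)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) ewr_stop(sprintf("non-numeric values in %s", path))
  dimnames(mat) <- NULL
  roi_timeseries(mat, subject_id)
}

#' Read a subject label table
#'
#' CSV with columns `subject_id` and `label`; labels are the two class names
#' and are mapped internally to +1/-1. The mapping is returned so every
#' downstream report can state which class is positive.
#'
#' @param path File path.
#' @param positive Class name mapped to +1; defaults to the
#'   lexicographically first class, with a message.
#' @return List with `labels` (named +1/-1 vector), `positive_name`,
#'   `negative_name`.
#' @export
read_label_table <- function(path, positive = NULL) {
  if (!file.exists(path)) ewr_stop(sprintf("label file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "label") %in% names(df)))
    ewr_stop("label table needs columns `subject_id` and `label`")
  if (anyDuplicated(df$subject_id))
    ewr_stop("duplicate subject ids in label table")
  classes <- sort(unique(as.character(df$label)))
  if (length(classes) != 2L)
    ewr_stop(sprintf("expected exactly 2 classes, found %d (%s)",
                     length(classes), paste(classes, collapse = ", ")))
  if (is.null(positive)) {
    positive <- classes[1]
    message(sprintf("positive class not specified; using '%s' (vs '%s')",
                    classes[1], classes[2]))
  }
  if (!positive %in% classes)
    ewr_stop(sprintf("positive class '%s' not among labels (%s)",
                     positive, paste(classes, collapse = ", ")))
  labels <- ifelse(df$label == positive, 1L, -1L)
  names(labels) <- df$subject_id
  list(labels = labels, positive_name = positive,
       negative_name = setdiff(classes, positive))
}

serialize_member <- function(mb) {
  list(features = mb$features, train = mb$train, validation = mb$validation,
       weight = mb$weight, sigma = mb$sigma, cost = mb$cost,
       gamma = mb$gamma, rho = mb$rho, coefs = mb$coefs,
       positive_decision_label = mb$positive_decision_label,
       sv_nrow = nrow(mb$sv), sv_ncol = ncol(mb$sv),
       sv = as.numeric(mb$sv))
}

deserialize_member <- function(x) {
  for (field in c("features", "weight", "gamma", "rho", "coefs",
                  "positive_decision_label", "sv_nrow", "sv_ncol", "sv"))
    if (is.null(x[[field]]))
      ewr_stop(sprintf("corrupted ensemble file: member missing field '%s'", field),
               class = "parse")
  mb <- list(
    features = as.integer(x$features),
    train = as.integer(x$train), validation = as.integer(x$validation),
    weight = as.numeric(x$weight), sigma = as.numeric(x$sigma),
    cost = as.numeric(x$cost), gamma = as.numeric(x$gamma),
    rho = as.numeric(x$rho), coefs = as.numeric(x$coefs),
    positive_decision_label = as.integer(x$positive_decision_label),
    sv = matrix(as.numeric(x$sv), x$sv_nrow, x$sv_ncol)
  )
  class(mb) <- "base_classifier"
  mb
}

#' Write a fitted ensemble to a self-describing JSON file
#'
#' Stores the format version, ensemble-level settings, the optimal feature
#' set when given, and every member's feature subset, split indices, weight
#' and decision-function state at full numeric precision, so that
#' [read_ensemble_json()] reproduces predictions exactly.
#'
#' @param ensemble An `svm_ensemble`.
#' @param path Output path.
#' @param optimal_feature_set Optional feature set to embed (for region
#'   ranking downstream).
#' @param config Optional [run_config()] echoed into the file.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(ensemble, path, optimal_feature_set = NULL,
                                config = NULL) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  obj <- list(
    format = "ewrsvmc_ensemble", version = ENSEMBLE_FORMAT_VERSION,
    n_features_total = ensemble$n_features_total,
    feature_pool = ensemble$feature_pool,
    m = ensemble$m, sigma = ensemble$sigma, cost = ensemble$cost,
    seed = ensemble$seed, evolution_index = ensemble$evolution_index,
    optimal_feature_set = optimal_feature_set,
    config = if (!is.null(config)) unclass(config),
    members = lapply(ensemble$members, serialize_member)
  )
  # 17 significant digits round-trip IEEE doubles exactly, so reloaded
  # ensembles reproduce decision values (and hence predictions) bit-for-bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a fitted ensemble from JSON
#'
#' @param path Path written by [write_ensemble_json()].
#' @return List with `ensemble` (an `svm_ensemble`), `optimal_feature_set`
#'   (or NULL) and `config` (or NULL).
#' @export
read_ensemble_json <- function(path) {
  if (!file.exists(path)) ewr_stop(sprintf("ensemble file not found: %s", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE,
                                      simplifyMatrix = FALSE),
                  error = function(e)
                    ewr_stop(sprintf("cannot parse ensemble file: %s",
                                     conditionMessage(e)), class = "parse"))
  if (!identical(obj$format, "ewrsvmc_ensemble"))
    ewr_stop("not an ewrsvmc ensemble file (field 'format')", class = "parse")
  if (!identical(as.character(obj$version), ENSEMBLE_FORMAT_VERSION))
    ewr_stop(sprintf("unsupported ensemble format version '%s' (expected %s)",
                     obj$version, ENSEMBLE_FORMAT_VERSION), class = "parse")
  ensemble <- structure(
    list(members = lapply(obj$members, deserialize_member),
         feature_pool = as.integer(obj$feature_pool),
         n_features_total = as.integer(obj$n_features_total),
         m = as.integer(obj$m), sigma = as.numeric(obj$sigma),
         cost = as.numeric(obj$cost), seed = as.integer(obj$seed),
         evolution_index = as.integer(obj$evolution_index)),
    class = "svm_ensemble"
  )
  list(ensemble = ensemble,
       optimal_feature_set = if (!is.null(obj$optimal_feature_set))
         as.integer(obj$optimal_feature_set),
       config = obj$config)
}

#' Export an evolution history as CSV
#'
#' One row per generation: generation, pool size before and after, weak
#' member count, removed-feature count, test accuracy.
#'
#' @param history An `evolution_history`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  stopifnot(inherits(history, "evolution_history"))
  utils::write.csv(history$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an evolution history as JSON
#'
#' Includes the full removed-feature index lists per generation, the optimal
#' generation and feature set, the resolved configuration and the master
#' seed (audit trail).
#'
#' @inheritParams write_history_csv
#' @export
write_history_json <- function(history, path) {
  stopifnot(inherits(history, "evolution_history"))
  obj <- list(
    format = "ewrsvmc_history", version = ENSEMBLE_FORMAT_VERSION,
    records = history$records,
    removed_features = history$removed,
    optimal_generation = history$optimal_generation,
    optimal_accuracy = history$optimal_accuracy,
    optimal_feature_set = history$optimal_feature_set,
    trainval = history$trainval, test = history$test,
    stopped_reason = history$stopped_reason,
    config = unclass(history$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a metric report as JSON
#'
#' @param report A [metric_report()].
#' @param path Output path.
#' @param config Optional resolved [run_config()] echoed into the file.
#' @export
write_metric_report_json <- function(report, path, config = NULL) {
  stopifnot(inherits(report, "metric_report"))
  obj <- list(
    positive_class = report$positive_name,
    accuracy = report$accuracy, sensitivity = report$sensitivity,
    specificity = report$specificity,
    undefined = as.list(report$undefined),
    counts = list(tp = report$counts$tp, fp = report$counts$fp,
                  fn = report$counts$fn, tn = report$counts$tn),
    config = if (!is.null(config)) unclass(config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a region-frequency table as CSV
#'
#' @param freq_table A [region_frequencies()] table.
#' @param path Output path.
#' @export
write_region_table_csv <- function(freq_table, path) {
  stopifnot(inherits(freq_table, "region_frequency_table"))
  utils::write.csv(as.data.frame(freq_table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a generated synthetic study to disk
#'
#' Emits exactly the formats the fitting pipeline reads: one CSV per subject
#' (T rows x R columns, no header), `labels.csv` (subject_id,label),
#' `regions.txt` (one generic region name per line) and `truth.json` with
#' the planted pairs, regions and feature indices.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @param class_names Length-2 character vector naming classes +1 and -1.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, class_names = c("case", "control")) {
  stopifnot(inherits(study, "generated_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ts in study$series) {
    utils::write.table(ts$signals,
                       file.path(dir, paste0(ts$subject_id, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  lab <- data.frame(
    subject_id = names(study$labels),
    label = ifelse(study$labels == 1L, class_names[1], class_names[2])
  )
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  writeLines(sprintf("region_%02d", seq_len(study$spec$regions)),
             file.path(dir, "regions.txt"))
  jsonlite::write_json(
    list(planted_pairs = study$truth$pairs,
         planted_regions = study$truth$regions,
         planted_feature_indices = study$truth$feature_indices,
         seed = study$spec$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a study directory written by [write_study()] (or hand-prepared)
#'
#' @param dir Directory containing per-subject delimited matrices,
#'   `labels.csv` and `regions.txt`.
#' @param positive Class name mapped to +1 (see [read_label_table()]).
#' @param header Whether subject files carry a header row.
#' @return List with `dataset` (an `fc_dataset`), `region_names`,
#'   `positive_name`, `negative_name`.
#' @export
read_study <- function(dir, positive = NULL, header = FALSE) {
  lab <- read_label_table(file.path(dir, "labels.csv"), positive)
  region_names <- read_region_names(file.path(dir, "regions.txt"))
  series <- lapply(names(lab$labels), function(id) {
    candidates <- file.path(dir, paste0(id, c(".csv", ".tsv", ".txt")))
    hit <- candidates[file.exists(candidates)]
    if (length(hit) == 0L)
      ewr_stop(sprintf("no time-series file for subject '%s' in %s", id, dir))
    read_roi_timeseries(hit[1], header = header, subject_id = id)
  })
  dataset <- build_dataset(series, lab$labels)
  if (dataset$pair_map$region_count != length(region_names))
    ewr_stop(sprintf("region count mismatch: %d signal columns vs %d region names",
                     dataset$pair_map$region_count, length(region_names)))
  list(dataset = dataset, region_names = region_names,
       positive_name = lab$positive_name, negative_name = lab$negative_name)
}
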
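# Ranking discriminative brain regions by how often they appear as an
# endpoint of the selected functional-connectivity features.

#' Read a region-name table
#'
#' Plain text, one region name per line; line order defines the region
#' ordinal order (the column order of the time-series matrices).
#'
#' @param path File path.
#' @return Character vector of unique region names.
#' @export
read_region_names <- function(path) {
  if (!file.exists(path)) ewr_stop(sprintf("region-name file not found: %s", path))
  names <- trimws(readLines(path, warn = FALSE))
  names <- names[nzchar(names)]
  if (length(names) < 2L) ewr_stop("region-name file must list at least 2 regions")
  dup <- unique(names[duplicated(names)])
  if (length(dup) > 0L)
    ewr_stop(sprintf("duplicate region names: %s", paste(dup, collapse = ", ")))
  names
}

#' The 90 AAL cerebrum region names
#'
#' Short names of the 90-region automated anatomical labeling parcellation
#' (45 per hemisphere, `.L`/`.R` suffixes), in standard ordinal order.
#'
#' @return Character vector of length 90.
#' @export
aal90_regions <- function() {
  read_region_names(system.file("extdata", "aal90_regions.txt",
                                package = "ewrsvmc", mustWork = TRUE))
}

#' Per-region occurrence frequencies of a feature set
#'
#' Each functional-connectivity feature connects two regions; every feature
#' in `features` increments both endpoint regions by 1, so the frequencies
#' sum to twice the feature-set size. The table covers all regions (zeros
#' included) and is sorted by descending frequency with ties broken by
#' region ordinal.
#'
#' @param features Integer vector of feature indices (e.g., the optimal
#'   feature set).
#' @param map A [pair_index_map()].
#' @param region_names Character vector of length `map$region_count`.
#' @return A `region_frequency_table`: data frame with columns `region`,
#'   `ordinal`, `frequency`.
#' @export
region_frequencies <- function(features, map, region_names) {
  stopifnot(inherits(map, "pair_index_map"))
  R <- map$region_count
  if (length(region_names) != R)
    ewr_stop(sprintf("expected %d region names, got %d", R, length(region_names)))
  counts <- integer(R)
  if (length(features) > 0L) {
    pairs <- index_to_pair(features, map)  # validates the indices
    t1 <- tabulate(pairs[, "i"], nbins = R)
    t2 <- tabulate(pairs[, "j"], nbins = R)
    counts <- t1 + t2
  }
  out <- data.frame(region = region_names, ordinal = seq_len(R),
                    frequency = counts, stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_frequency_table", "data.frame")
  out
}

#' Filter a region-frequency table to regions exceeding a threshold
#'
#' @param freq_table A [region_frequencies()] table.
#' @param threshold Keep regions with frequency strictly greater than this
#'   (default 10, the conventional reporting cut for AAL-90 rankings).
#' @return The filtered table, order preserved.
#' @export
top_regions <- function(freq_table, threshold = 10L) {
  stopifnot(inherits(freq_table, "region_frequency_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    ewr_stop("`threshold` must be a single non-negative number")
  out <- freq_table[freq_table$frequency > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.region_frequency_table <- function(x, n = 10L, ...) {
  cat(sprintf("region_frequency_table: %d regions, total frequency %d\n",
              nrow(x), sum(x$frequency)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("  ... %d more regions\n", nrow(x) - n))
  invisible(x)
}
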
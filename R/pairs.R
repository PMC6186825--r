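# Feature indexing: bijection between unordered region pairs and FC features.
#
# Feature k corresponds to one unordered pair of regions (i, j), i < j, under
# a fixed row-major upper-triangle ordering:
#   (1,2), (1,3), ..., (1,R), (2,3), ..., (R-1,R)
# Region ordinals and feature indices are 1-based throughout the package.

#' Number of functional-connectivity features for a given region count
#'
#' One Pearson-correlation feature exists per unordered pair of regions, so a
#' parcellation with `R` regions yields `R*(R-1)/2` features (4005 for the
#' 90-region AAL atlas).
#'
#' @param region_count Number of brain regions `R` (positive integer).
#' @return `R*(R-1)/2` as an integer.
#' @export
#' @examples
#' n_features(90) # 4005
n_features <- function(region_count) {
  if (!is_count(region_count) || region_count < 1)
    ewr_stop("`region_count` must be a single integer >= 1")
  as.integer(region_count * (region_count - 1) / 2)
}

#' Construct the pair-to-feature index map
#'
#' @param region_count Number of regions `R` (>= 2).
#' @return An object of class `pair_index_map` with elements `region_count`
#'   and `n_features`.
#' @export
pair_index_map <- function(region_count) {
  if (!is_count(region_count) || region_count < 2)
    ewr_stop("`region_count` must be a single integer >= 2")
  structure(
    list(region_count = as.integer(region_count),
         n_features = n_features(region_count)),
    class = "pair_index_map"
  )
}

#' @export
print.pair_index_map <- function(x, ...) {
  cat(sprintf("pair_index_map: %d regions, %d region-pair features\n",
              x$region_count, x$n_features))
  invisible(x)
}

#' Map a region pair to its feature index
#'
#' @param i,j Region ordinals with `1 <= i < j <= R` (vectorised, recycled).
#' @param map A [pair_index_map()].
#' @return Integer feature indices in `[1, R*(R-1)/2]`.
#' @export
#' @examples
#' m <- pair_index_map(90)
#' pair_to_index(1, 2, m)   # 1
#' pair_to_index(89, 90, m) # 4005
pair_to_index <- function(i, j, map) {
  stopifnot(inherits(map, "pair_index_map"))
  R <- map$region_count
  if (length(i) == 0L || length(j) == 0L)
    ewr_stop("`i` and `j` must be non-empty")
  bad <- !is.finite(i) | !is.finite(j) | i != floor(i) | j != floor(j) |
    i < 1 | j < 1 | i >= j | j > R
  if (any(bad))
    ewr_stop(sprintf("invalid region pair(s): need 1 <= i < j <= %d", R))
  as.integer((i - 1) * R - i * (i + 1) / 2 + j)
}

#' Map a feature index back to its region pair
#'
#' @param k Feature indices in `[1, R*(R-1)/2]` (vectorised).
#' @param map A [pair_index_map()].
#' @return An integer matrix with columns `i` and `j` (one row per index).
#' @export
#' @examples
#' m <- pair_index_map(90)
#' index_to_pair(1, m)    # (1, 2)
#' index_to_pair(4005, m) # (89, 90)
index_to_pair <- function(k, map) {
  stopifnot(inherits(map, "pair_index_map"))
  R <- map$region_count
  if (length(k) == 0L) ewr_stop("`k` must be non-empty")
  if (any(!is.finite(k) | k != floor(k) | k < 1 | k > map$n_features))
    ewr_stop(sprintf("feature index out of range [1, %d]", map$n_features))
  # cum[i] = number of pairs whose first region ordinal is <= i
  cum <- cumsum(R - seq_len(R - 1L))
  i <- findInterval(k - 1L, c(0, cum), rightmost.closed = FALSE)
  offset <- c(0L, cum)[i]
  j <- as.integer(i + (k - offset))
  cbind(i = as.integer(i), j = j)
}
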
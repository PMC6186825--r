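# Run configuration with the method's canonical defaults.

#' Configuration for an evolutionary weighted random SVM cluster run
#'
#' Defaults follow the method's canonical settings for whole-cerebrum
#' AAL-90 functional-connectivity data: 500 base classifiers, 62 features per
#' member (about the square root of the 4005-feature space), RBF bandwidth
#' sigma = 3 with kernel `exp(-||u-v||^2 / (2*sigma^2))`, a large finite
#' penalty standing in for an unbounded C, removal threshold q = 7, 50
#' evolutions, a 3:1 outer and 2:1 inner split, stratified by class. The
#' removal threshold scales with `n_members * m / d` (the expected number of
#' times a feature is drawn), so smaller studies warrant a smaller q; see the
#' package vignette.
#'
#' @param n_members Number of base classifiers per generation.
#' @param m Feature-subset size per base classifier.
#' @param sigma RBF kernel bandwidth.
#' @param cost SVM penalty C (large finite value approximating a hard margin).
#' @param q Feature-removal threshold on the total weak-classifier weight.
#' @param n_evolutions Number of pruning steps (generations run is at most
#'   `n_evolutions + 1`).
#' @param outer_test_frac,inner_validation_frac,stratified See [split_spec()].
#' @param positive Label of the positive class (+1 or -1).
#' @param positive_name Human-readable positive-class name for reports.
#' @param optimal_set How the optimal feature set is defined: `"pool"` (the
#'   surviving pool of the optimal generation, default) or `"drawn"` (union
#'   of features actually drawn by that generation's members).
#' @param tie_break How ties in maximum test accuracy are resolved when
#'   selecting the optimal generation: `"sparsest"` (default; among tied
#'   generations prefer the smallest feature pool, i.e. the most parsimonious
#'   model, earliest among equal pool sizes) or `"earliest"`. On small test
#'   sets accuracy is coarsely quantised and ties at the maximum are common;
#'   the earliest rule then tends to select the unpruned generation 0, which
#'   makes the downstream region ranking uninformative.
#' @param seed Master seed; all randomness derives from it.
#' @param verbose Emit one-line per-generation progress messages.
#' @return Object of class `ewrsvmc_config`.
#' @export
run_config <- function(n_members = 500L, m = 62L, sigma = 3, cost = 1e6,
                       q = 7, n_evolutions = 50L,
                       outer_test_frac = 1 / 4, inner_validation_frac = 1 / 3,
                       stratified = TRUE, positive = 1L,
                       positive_name = as.character(positive),
                       optimal_set = c("pool", "drawn"),
                       tie_break = c("sparsest", "earliest"),
                       seed = 1L, verbose = FALSE) {
  optimal_set <- match.arg(optimal_set)
  tie_break <- match.arg(tie_break)
  if (!is_count(n_members) || n_members < 1) ewr_stop("`n_members` must be a positive integer")
  if (!is_count(m) || m < 1) ewr_stop("`m` must be a positive integer")
  if (!is.numeric(sigma) || sigma <= 0) ewr_stop("`sigma` must be positive")
  if (!is.numeric(cost) || cost <= 0) ewr_stop("`cost` must be positive")
  if (!is.numeric(q) || q < 0) ewr_stop("`q` must be non-negative")
  if (!is_count(n_evolutions) || n_evolutions < 0)
    ewr_stop("`n_evolutions` must be a non-negative integer")
  if (!positive %in% c(-1L, 1L)) ewr_stop("`positive` must be +1 or -1")
  if (!is_count(seed)) ewr_stop("`seed` must be a single integer")
  split_spec(outer_test_frac, inner_validation_frac, stratified) # validates
  structure(
    list(n_members = as.integer(n_members), m = as.integer(m),
         sigma = sigma, cost = cost, q = q,
         n_evolutions = as.integer(n_evolutions),
         outer_test_frac = outer_test_frac,
         inner_validation_frac = inner_validation_frac,
         stratified = isTRUE(stratified),
         positive = as.integer(positive), positive_name = positive_name,
         optimal_set = optimal_set, tie_break = tie_break,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "ewrsvmc_config"
  )
}

#' @export
print.ewrsvmc_config <- function(x, ...) {
  cat("ewrsvmc_config:\n")
  cat(sprintf("  n_members = %d, m = %d, sigma = %g, cost = %g\n",
              x$n_members, x$m, x$sigma, x$cost))
  cat(sprintf("  q = %g, n_evolutions = %d, optimal_set = %s, tie_break = %s\n",
              x$q, x$n_evolutions, x$optimal_set, x$tie_break))
  cat(sprintf("  outer test frac = %.3f, inner validation frac = %.3f, stratified = %s\n",
              x$outer_test_frac, x$inner_validation_frac, x$stratified))
  cat(sprintf("  positive class = %+d (%s), seed = %d\n",
              x$positive, x$positive_name, x$seed))
  invisible(x)
}
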
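# Evolutionary feature elimination: each generation builds a fresh weighted
# random SVM cluster from the active feature pool, identifies weak members
# (validation accuracy strictly below 0.5), accumulates each feature's total
# weight over the weak members, and removes features whose total strictly
# exceeds the threshold q. Removed features never re-enter.

#' Partition ensemble members into weak and strong
#'
#' Weak members are those whose validation-accuracy weight is strictly below
#' 0.5; a member at exactly 0.5 is strong.
#'
#' @param ensemble An `svm_ensemble`.
#' @return List with integer member-index vectors `weak` and `strong`.
#' @export
identify_weak <- function(ensemble) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  w <- ensemble_weights(ensemble)
  list(weak = which(w < 0.5), strong = which(w >= 0.5))
}

#' Total feature weight over the weak classifiers
#'
#' For each feature j, `Tw_j` is the sum over weak members l of `w_{l,j}`,
#' where `w_{l,j}` equals the member's weight `W_l` when feature j belongs to
#' that member's feature subset and 0 otherwise. Features used by no weak
#' member have total weight 0.
#'
#' @param ensemble An `svm_ensemble`.
#' @param weak Integer indices of the weak members (e.g.,
#'   `identify_weak(ensemble)$weak`).
#' @return Numeric vector of length `d` (the total feature space), entry j
#'   holding `Tw_j`.
#' @export
feature_total_weights <- function(ensemble, weak) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  tw <- numeric(ensemble$n_features_total)
  for (l in weak) {
    mb <- ensemble$members[[l]]
    tw[mb$features] <- tw[mb$features] + mb$weight
  }
  tw
}

#' Prune features whose total weak weight exceeds the threshold
#'
#' Removes from the pool every feature with `Tw_j > q` (strict inequality: a
#' feature at exactly q survives). These features carried the most weight in
#' poorly performing members and are taken to contribute little to the
#' ensemble.
#'
#' @param pool Integer vector of active feature indices.
#' @param tw Numeric vector of total weights indexed by feature (length d).
#' @param q Non-negative removal threshold (default 7).
#' @return List with `pool` (surviving indices, sorted) and `removed`.
#' @export
prune_pool <- function(pool, tw, q = 7) {
  if (!is.numeric(q) || length(q) != 1L || q < 0)
    ewr_stop("`q` must be a single non-negative number")
  removed <- pool[tw[pool] > q]
  list(pool = sort(setdiff(pool, removed)), removed = sort(removed))
}

# Sanity check on each pruning step: since every weak weight is < 0.5 (and
# <= the max weak weight), Tw_j > q forces feature j to occur in strictly
# more than q / max(weak weight) weak members.
check_prune_consistency <- function(ensemble, weak, removed, q) {
  if (length(removed) == 0L || length(weak) == 0L) return(invisible(TRUE))
  wmax <- max(ensemble_weights(ensemble)[weak])
  occ <- integer(ensemble$n_features_total)
  for (l in weak) {
    f <- ensemble$members[[l]]$features
    occ[f] <- occ[f] + 1L
  }
  if (any(occ[removed] <= q / wmax))
    ewr_stop("internal inconsistency: pruned feature occurs in too few weak members",
             class = "internal")
  invisible(TRUE)
}

#' Run the full evolutionary feature-elimination loop
#'
#' Generation 0 builds an ensemble from the complete feature pool; each
#' subsequent generation rebuilds a full `n`-member ensemble from the pruned
#' pool with a fresh seed derived from the master seed, evaluates its test
#' accuracy, and prunes again. The loop runs for `n_evolutions` pruning
#' steps (so up to `n_evolutions + 1` ensembles) and stops early — with the
#' reason recorded — if the surviving pool drops below `m` or empties.
#'
#' The per-generation selection criterion is accuracy on the held-out test
#' set, mirroring how the optimal number of evolutions is chosen in this
#' method family; selecting on the test set is optimistically biased, which
#' is documented in the package vignette.
#'
#' @param dataset An `fc_dataset`.
#' @param config A [run_config()].
#' @return Object of class `evolution_history`: per-generation records
#'   (pool sizes, weak count, removed features, test accuracy), the split
#'   indices, and the optimal generation with its feature set and ensemble.
#' @export
run_evolution <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "fc_dataset"), inherits(config, "ewrsvmc_config"))
  d <- ncol(dataset$features)
  if (config$m > d)
    ewr_stop(sprintf("invalid config: m = %d exceeds feature count d = %d",
                     config$m, d), class = "invalid_config")
  spec <- split_spec(config$outer_test_frac, config$inner_validation_frac,
                     config$stratified)
  outer <- split_outer(dataset, spec, derive_seed(config$seed, "outer"))
  test_X <- dataset$features[outer$test, , drop = FALSE]
  test_y <- dataset$labels[outer$test]

  pool <- seq_len(d)
  records <- list()
  removed_sets <- list()
  best <- list(accuracy = -Inf, pool_size = Inf, generation = NA_integer_,
               feature_set = NULL, ensemble = NULL)
  stopped_reason <- NULL

  for (g in 0:config$n_evolutions) {
    if (length(pool) < config$m) {
      stopped_reason <- sprintf(
        "stopped before generation %d: pool size %d < m = %d",
        g, length(pool), config$m)
      message(stopped_reason)
      break
    }
    ens <- build_ensemble(
      dataset, outer$trainval, pool,
      n = config$n_members, m = config$m,
      sigma = config$sigma, cost = config$cost, spec = spec,
      seed = derive_seed(config$seed, "generation", g),
      evolution_index = g
    )
    acc <- accuracy(confusion(test_y, predict_batch(ens, test_X),
                              config$positive))
    wk <- identify_weak(ens)

    removed <- integer(0)
    size_before <- length(pool)
    if (g < config$n_evolutions) {
      tw <- feature_total_weights(ens, wk$weak)
      pruned <- prune_pool(pool, tw, config$q)
      check_prune_consistency(ens, wk$weak, pruned$removed, config$q)
      removed <- pruned$removed
      pool <- pruned$pool
    }
    records[[length(records) + 1L]] <- data.frame(
      generation = g, pool_size_before = size_before,
      weak_count = length(wk$weak), removed_count = length(removed),
      pool_size_after = size_before - length(removed),
      test_accuracy = acc
    )
    removed_sets[[length(removed_sets) + 1L]] <- removed

    take <- acc > best$accuracy ||
      (acc == best$accuracy && config$tie_break == "sparsest" &&
         size_before < best$pool_size)
    if (take) {
      feature_set <- if (config$optimal_set == "pool") {
        ens$feature_pool
      } else {
        sort(unique(unlist(lapply(ens$members, function(mb) mb$features))))
      }
      best <- list(accuracy = acc, pool_size = size_before, generation = g,
                   feature_set = feature_set, ensemble = ens)
    }
    if (config$verbose)
      message(sprintf(
        "generation %d: pool %d, weak %d/%d, removed %d, test accuracy %.4f",
        g, size_before, length(wk$weak), config$n_members, length(removed), acc))
    if (length(pool) == 0L) {
      stopped_reason <- sprintf("stopped after generation %d: pool emptied", g)
      message(stopped_reason)
      break
    }
  }
  if (length(records) == 0L)
    ewr_stop("no generation could be run (pool smaller than m at start)",
             class = "invalid_config")
  structure(
    list(records = do.call(rbind, records), removed = removed_sets,
         optimal_generation = best$generation,
         optimal_accuracy = best$accuracy,
         optimal_feature_set = best$feature_set,
         optimal_ensemble = best$ensemble,
         trainval = outer$trainval, test = outer$test,
         stopped_reason = stopped_reason, config = config),
    class = "evolution_history"
  )
}

#' @export
print.evolution_history <- function(x, ...) {
  r <- x$records
  cat(sprintf("evolution_history: %d generation(s), d = %d\n",
              nrow(r), x$optimal_ensemble$n_features_total))
  cat(sprintf("  optimal generation %d: test accuracy %.4f, %d features\n",
              x$optimal_generation, x$optimal_accuracy,
              length(x$optimal_feature_set)))
  if (!is.null(x$stopped_reason)) cat("  ", x$stopped_reason, "\n", sep = "")
  invisible(x)
}

#' Select the optimal generation from an evolution history
#'
#' The optimal generation attains the maximum test accuracy. Ties are
#' resolved per the run configuration's `tie_break`: `"sparsest"` prefers
#' the tied generation with the smallest feature pool (most parsimonious
#' model; earliest among equal sizes), `"earliest"` simply the earliest tied
#' generation. Recomputed from the records (and consistent with the
#' ensemble tracked during the run).
#'
#' @param history An `evolution_history`.
#' @return List with `generation`, `accuracy`, `feature_set`, `ensemble`.
#' @export
select_optimal <- function(history) {
  stopifnot(inherits(history, "evolution_history"))
  r <- history$records
  if (is.null(r) || nrow(r) == 0L)
    ewr_stop("empty evolution history", class = "invalid_state")
  tied <- r[r$test_accuracy == max(r$test_accuracy), , drop = FALSE]
  g <- if (history$config$tie_break == "sparsest") {
    tied$generation[order(tied$pool_size_before, tied$generation)][1]
  } else {
    min(tied$generation)
  }
  if (g != history$optimal_generation)
    ewr_stop("history inconsistent with records", class = "internal")
  list(generation = g, accuracy = history$optimal_accuracy,
       feature_set = history$optimal_feature_set,
       ensemble = history$optimal_ensemble)
}
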
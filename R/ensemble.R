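# Weighted random SVM cluster: an ensemble of RBF-SVM base classifiers, each
# trained on a random subject partition and a random feature subset, weighted
# by its own validation accuracy, and combined by weighted vote.

#' Data-splitting specification
#'
#' The dataset is first divided into a "training and validation" part and a
#' held-out test part (3:1 by default, i.e. a test fraction of 1/4); each
#' base classifier then redraws its own 2:1 training/validation partition of
#' the first part (validation fraction 1/3). Splits are stratified by class
#' by default so both classes reach every part at small N; part sizes are
#' rounded to the nearest integer with both parts forced non-empty.
#'
#' @param outer_test_frac Fraction of subjects held out as the test set.
#' @param inner_validation_frac Fraction of the training-and-validation part
#'   used as a base classifier's validation subset.
#' @param stratified Stratify all splits by class label.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(outer_test_frac = 1 / 4, inner_validation_frac = 1 / 3,
                       stratified = TRUE) {
  if (!is.numeric(outer_test_frac) || outer_test_frac <= 0 || outer_test_frac >= 1)
    ewr_stop("`outer_test_frac` must be in (0, 1)")
  if (!is.numeric(inner_validation_frac) ||
      inner_validation_frac <= 0 || inner_validation_frac >= 1)
    ewr_stop("`inner_validation_frac` must be in (0, 1)")
  structure(list(outer_test_frac = outer_test_frac,
                 inner_validation_frac = inner_validation_frac,
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Partition `idx` into (rest, drawn) with the drawn part holding `frac`,
# rounded to nearest, both parts non-empty (per class when stratified).
split_two <- function(idx, labels, frac, stratified, seed) {
  set.seed(seed)
  draw_from <- function(sub) {
    n <- length(sub)
    if (n < 2L)
      ewr_stop("split infeasible: a stratum has fewer than 2 subjects",
               class = "split_infeasible")
    k <- max(1L, min(n - 1L, as.integer(round(n * frac))))
    sort(sample(sub, k))
  }
  if (stratified) {
    drawn <- sort(unlist(lapply(split(idx, labels[idx]), draw_from),
                         use.names = FALSE))
  } else {
    drawn <- draw_from(idx)
  }
  rest <- setdiff(idx, drawn)
  for (part in list(rest, drawn)) {
    if (length(unique(labels[part])) < 2L)
      ewr_stop("split infeasible: a part lacks one class",
               class = "split_infeasible")
  }
  list(rest = rest, drawn = drawn)
}

#' Outer split into training-and-validation and test sets
#'
#' @param dataset An [build_dataset()] `fc_dataset`.
#' @param spec A [split_spec()].
#' @param seed Integer seed for this split.
#' @return List with integer index vectors `trainval` and `test` (disjoint,
#'   exhaustive).
#' @export
split_outer <- function(dataset, spec = split_spec(), seed = 1L) {
  stopifnot(inherits(dataset, "fc_dataset"), inherits(spec, "split_spec"))
  parts <- split_two(seq_along(dataset$labels), dataset$labels,
                     spec$outer_test_frac, spec$stratified, seed)
  list(trainval = parts$rest, test = parts$drawn)
}

#' Draw one base classifier's samples and feature subset
#'
#' Each base classifier receives a fresh random training/validation partition
#' of the training-and-validation subjects (without replacement) and `m`
#' features sampled uniformly without replacement from the active pool.
#'
#' @param trainval Integer indices of the training-and-validation subjects.
#' @param labels Full label vector (used for stratification).
#' @param pool Integer vector of currently active feature indices.
#' @param m Feature-subset size, `m <= length(pool)`.
#' @param spec A [split_spec()] (inner ratio and stratification).
#' @param seed Integer seed for this draw.
#' @return List with `train`, `validation` (disjoint subject indices) and
#'   `features` (m distinct indices from `pool`).
#' @export
draw_classifier_data <- function(trainval, labels, pool, m,
                                 spec = split_spec(), seed = 1L) {
  if (m > length(pool))
    ewr_stop(sprintf("feature pool exhausted: m = %d > pool size %d",
                     m, length(pool)), class = "pool_exhausted")
  if (m < 1L) ewr_stop("`m` must be >= 1")
  parts <- split_two(trainval, labels, spec$inner_validation_frac,
                     spec$stratified, seed)
  set.seed(derive_seed(seed, "features"))
  features <- sort(sample(pool, m))
  list(train = parts$rest, validation = parts$drawn, features = features)
}

# Extract the fitted decision function from an e1071 binary SVM so that
# prediction and persistence do not depend on the fitted object itself:
# f(x) = sum_i coefs_i * exp(-gamma ||sv_i - x||^2) - rho, and f(x) > 0
# predicts levels[labels[1]] (e1071's sign convention).
extract_decision <- function(fit) {
  pos_level <- fit$levels[fit$labels[1]]
  list(sv = unname(as.matrix(fit$SV)),
       coefs = as.numeric(fit$coefs),
       rho = as.numeric(fit$rho),
       gamma = as.numeric(fit$gamma),
       positive_decision_label = as.integer(pos_level))
}

# Decision values for rows of Xs (already restricted to the member's feature
# subset) against stored support vectors.
decision_values <- function(member, Xs) {
  sv <- member$sv
  d2 <- outer(rowSums(Xs^2), rowSums(sv^2), "+") - 2 * Xs %*% t(sv)
  d2[d2 < 0] <- 0
  K <- exp(-member$gamma * d2)
  drop(K %*% member$coefs) - member$rho
}

member_predict <- function(member, X) {
  Xs <- X[, member$features, drop = FALSE]
  f <- decision_values(member, Xs)
  unname(ifelse(f > 0, member$positive_decision_label,
                -member$positive_decision_label))
}

#' Train one weighted base classifier
#'
#' Fits a hard-margin-style RBF SVM (kernel `exp(-||u-v||^2 / (2*sigma^2))`,
#' large finite penalty standing in for an unbounded one) on the given
#' training subjects restricted to the given feature subset, then scores it
#' on its validation subjects. The validation accuracy becomes the member's
#' voting weight `W = correct / total`.
#'
#' @param dataset An `fc_dataset`.
#' @param train,validation Disjoint subject-index vectors; training part must
#'   contain both classes.
#' @param features Feature-index subset (no duplicates).
#' @param sigma RBF kernel bandwidth (default 3).
#' @param cost Penalty parameter C (default 1e6).
#' @return An object of class `base_classifier` carrying the feature subset,
#'   split, decision-function state and weight.
#' @export
train_base_classifier <- function(dataset, train, validation, features,
                                  sigma = 3, cost = 1e6) {
  stopifnot(inherits(dataset, "fc_dataset"))
  if (anyDuplicated(features)) ewr_stop("duplicate feature indices")
  if (length(intersect(train, validation)) > 0L)
    ewr_stop("train and validation subjects overlap")
  y <- dataset$labels[train]
  if (length(unique(y)) < 2L)
    ewr_stop("training part contains a single class",
             class = "degenerate_training")
  fit <- e1071::svm(
    x = dataset$features[train, features, drop = FALSE],
    y = factor(y, levels = c(-1L, 1L)),
    scale = FALSE, kernel = "radial",
    gamma = 1 / (2 * sigma^2), cost = cost
  )
  member <- c(
    extract_decision(fit),
    list(features = as.integer(features),
         train = as.integer(train), validation = as.integer(validation),
         sigma = sigma, cost = cost)
  )
  class(member) <- "base_classifier"
  pred <- member_predict(member, dataset$features[validation, , drop = FALSE])
  member$weight <- mean(pred == dataset$labels[validation])
  member
}

#' @export
print.base_classifier <- function(x, ...) {
  cat(sprintf("base_classifier: %d features, %d train / %d validation, W = %.4f\n",
              length(x$features), length(x$train), length(x$validation),
              x$weight))
  invisible(x)
}

#' Build a weighted random SVM cluster
#'
#' Repeats the draw-and-train step `n` times: each member gets a fresh random
#' inner split and a fresh random `m`-feature subset from `pool`, and a
#' weight equal to its validation accuracy. Fully reproducible given `seed`;
#' member `l` uses the derived seed `derive_seed(seed, "member", l)`.
#'
#' Members whose random training part happens to contain a single class (only
#' possible with non-stratified splits) are redrawn with a retry cap of 25.
#'
#' @inheritParams draw_classifier_data
#' @param dataset An `fc_dataset`.
#' @param n Number of base classifiers (default 500).
#' @param sigma,cost Kernel bandwidth and penalty, see
#'   [train_base_classifier()].
#' @param seed Integer seed.
#' @param evolution_index Generation tag recorded on the ensemble.
#' @return Object of class `svm_ensemble`.
#' @export
build_ensemble <- function(dataset, trainval, pool, n = 500L, m = 62L,
                           sigma = 3, cost = 1e6, spec = split_spec(),
                           seed = 1L, evolution_index = 0L) {
  stopifnot(inherits(dataset, "fc_dataset"))
  if (!is_count(n) || n < 1L) ewr_stop("`n` must be a positive integer")
  members <- vector("list", n)
  for (l in seq_len(n)) {
    member <- NULL
    for (try in 1:25) {
      draw <- draw_classifier_data(trainval, dataset$labels, pool, m, spec,
                                   seed = derive_seed(seed, "member", l, try))
      member <- tryCatch(
        train_base_classifier(dataset, draw$train, draw$validation,
                              draw$features, sigma, cost),
        ewrsvmc_degenerate_training = function(e) NULL
      )
      if (!is.null(member)) break
    }
    if (is.null(member))
      ewr_stop(sprintf("member %d: retry cap exhausted drawing a two-class training part", l),
               class = "degenerate_training")
    members[[l]] <- member
  }
  structure(
    list(members = members, feature_pool = as.integer(sort(pool)),
         n_features_total = ncol(dataset$features),
         m = as.integer(m), sigma = sigma, cost = cost,
         seed = as.integer(seed), evolution_index = as.integer(evolution_index)),
    class = "svm_ensemble"
  )
}

#' @export
print.svm_ensemble <- function(x, ...) {
  w <- ensemble_weights(x)
  cat(sprintf(
    "svm_ensemble (evolution %d): %d members, m = %d of pool %d (d = %d)\n",
    x$evolution_index, length(x$members), x$m, length(x$feature_pool),
    x$n_features_total))
  cat(sprintf("  weights: mean %.3f, range [%.3f, %.3f]; weak (< 0.5): %d\n",
              mean(w), min(w), max(w), sum(w < 0.5)))
  invisible(x)
}

#' Member weights of an ensemble
#'
#' @param ensemble An `svm_ensemble`.
#' @return Numeric vector of validation-accuracy weights, one per member.
#' @export
ensemble_weights <- function(ensemble) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  vapply(ensemble$members, function(mb) mb$weight, numeric(1))
}

# members x samples matrix of each member's +1/-1 vote
member_vote_matrix <- function(ensemble, X) {
  votes <- vapply(ensemble$members, function(mb) member_predict(mb, X),
                  integer(nrow(X)))
  matrix(votes, nrow = length(ensemble$members), byrow = TRUE)
}

# votes: members x samples matrix of +1/-1; weights: per-member.
# Weighted vote with the documented tie rule: ties in total weight go to the
# label voted by the single highest-weight member; if the top-weight members
# disagree, +1.
vote_matrix <- function(votes, weights) {
  pos <- colSums(weights * (votes == 1L))
  neg <- colSums(weights * (votes == -1L))
  out <- ifelse(pos > neg, 1L, -1L)
  tied <- which(pos == neg)
  if (length(tied) > 0L) {
    top <- which(weights == max(weights))
    for (s in tied) {
      tv <- unique(votes[top, s])
      out[s] <- if (length(tv) == 1L) tv else 1L
    }
  }
  as.integer(out)
}

#' Predict labels for a feature matrix by weighted vote
#'
#' Each member votes with its weight; the per-label weight sums are compared
#' and the label with the larger sum wins. Exact ties are broken by the
#' single highest-weight member's vote, and by `+1` if the top-weight members
#' disagree. Weak members (weight < 0.5) still vote.
#'
#' @param ensemble An `svm_ensemble`.
#' @param X Numeric matrix, one row per sample, `d` columns in the same
#'   feature indexing the ensemble was trained with.
#' @return Integer vector of predicted labels (+1/-1), one per row.
#' @export
predict_batch <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != ensemble$n_features_total)
    ewr_stop(sprintf("feature dimension mismatch: got %d, ensemble expects %d",
                     ncol(X), ensemble$n_features_total))
  if (nrow(X) == 0L) return(integer(0))
  votes <- member_vote_matrix(ensemble, X)
  vote_matrix(votes, ensemble_weights(ensemble))
}

#' Predict the label of a single sample
#'
#' @param ensemble An `svm_ensemble`.
#' @param x Numeric feature vector of length `d`.
#' @return `+1L` or `-1L`.
#' @export
predict_sample <- function(ensemble, x) {
  predict_batch(ensemble, matrix(x, nrow = 1L))[1L]
}

#' Per-label summed vote weights
#'
#' @param ensemble An `svm_ensemble`.
#' @param X Feature matrix (rows = samples).
#' @return Matrix with columns `vote_pos` and `vote_neg`: the total member
#'   weight behind each label, per sample.
#' @export
vote_weights <- function(ensemble, X) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) == 0L)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("vote_pos", "vote_neg"))))
  votes <- member_vote_matrix(ensemble, X)
  w <- ensemble_weights(ensemble)
  cbind(vote_pos = colSums(w * (votes == 1L)),
        vote_neg = colSums(w * (votes == -1L)))
}
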
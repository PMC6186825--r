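# Synthetic connectome generator: per-class multivariate-Gaussian ROI time
# series whose between-class difference is confined to a planted set of
# region-pair correlations, so that the discriminative features and their
# endpoint regions are known ground truth.

#' Plant region pairs on a small region subset
#'
#' Draws `n_regions` regions at random and then `n_pairs` distinct pairs
#' among them, concentrating the class signal on a compact region set so
#' that region-recovery can be scored.
#'
#' @param R Total region count.
#' @param n_regions Size of the planted region subset.
#' @param n_pairs Number of planted pairs (at most `choose(n_regions, 2)`).
#' @param seed Integer seed.
#' @return List with `pairs` (matrix, columns `i` < `j`) and `regions`
#'   (sorted ordinals of the planted region subset).
#' @export
plant_pairs <- function(R, n_regions = 6L, n_pairs = 8L, seed = 1L) {
  if (n_regions > R) ewr_stop("`n_regions` exceeds R")
  if (n_pairs > choose(n_regions, 2))
    ewr_stop(sprintf("`n_pairs` exceeds the %d pairs available on %d regions",
                     choose(n_regions, 2), n_regions))
  set.seed(seed)
  regions <- sort(sample(R, n_regions))
  all_pairs <- t(utils::combn(regions, 2L))
  pick <- sort(sample(nrow(all_pairs), n_pairs))
  pairs <- all_pairs[pick, , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  # only regions actually touched by a planted pair count as planted
  list(pairs = pairs, regions = sort(unique(as.integer(pairs))))
}

#' Specification of a synthetic connectome study
#'
#' Subjects of the reference class (-1) have exchangeable regional signals
#' with a common baseline correlation `baseline_r`; subjects of class +1
#' additionally carry `effect` on the planted region pairs. Signals are
#' stationary zero-mean Gaussian (temporal structure is irrelevant to
#' Pearson-correlation features). The default 130 timepoints reflect a
#' typical resting-state acquisition of 140 volumes with the first 10
#' discarded.
#'
#' @param n_per_class Length-2 vector: subjects in class +1 and class -1.
#' @param regions Region count R.
#' @param timepoints Timepoints T per subject (default 130).
#' @param planted_pairs Matrix with columns `i < j`, or `NULL` to draw 8
#'   pairs on 6 regions via [plant_pairs()] from the seed.
#' @param baseline_r Baseline inter-regional correlation (default 0.1).
#' @param effect Additive correlation on planted pairs in class +1 (default
#'   0.4); `abs(baseline_r + effect)` must be < 1.
#' @param noise_scale Signal standard-deviation multiplier (default 1;
#'   correlations are scale-invariant).
#' @param seed Master seed for the study.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(30L, 30L), regions = 20L,
                           timepoints = 130L, planted_pairs = NULL,
                           baseline_r = 0.1, effect = 0.4,
                           noise_scale = 1, seed = 1L) {
  if (length(n_per_class) != 2L || !all(vapply(n_per_class, is_count, logical(1))) ||
      any(n_per_class < 1))
    ewr_stop("`n_per_class` must be two positive integers")
  if (!is_count(regions) || regions < 2) ewr_stop("`regions` must be an integer >= 2")
  if (!is_count(timepoints) || timepoints < 3)
    ewr_stop("`timepoints` must be an integer >= 3")
  if (abs(baseline_r) >= 1) ewr_stop("invalid spec: |baseline_r| must be < 1")
  if (abs(baseline_r + effect) >= 1)
    ewr_stop("invalid spec: |baseline_r + effect| must be < 1")
  if (!is.numeric(noise_scale) || noise_scale <= 0)
    ewr_stop("`noise_scale` must be positive")
  if (is.null(planted_pairs)) {
    planted_pairs <- plant_pairs(regions, seed = derive_seed(seed, "plant"))$pairs
  }
  planted_pairs <- as.matrix(planted_pairs)
  if (ncol(planted_pairs) != 2L) ewr_stop("`planted_pairs` needs two columns")
  i <- planted_pairs[, 1]; j <- planted_pairs[, 2]
  if (any(i >= j) || any(i < 1) || any(j > regions) ||
      any(i != floor(i)) || any(j != floor(j)))
    ewr_stop("planted pairs must satisfy 1 <= i < j <= regions")
  if (anyDuplicated(paste(i, j)))
    ewr_stop("planted pairs must be distinct")
  colnames(planted_pairs) <- c("i", "j")
  structure(
    list(n_per_class = as.integer(n_per_class), regions = as.integer(regions),
         timepoints = as.integer(timepoints),
         planted_pairs = planted_pairs,
         planted_regions = sort(unique(as.integer(planted_pairs))),
         baseline_r = baseline_r, effect = effect,
         noise_scale = noise_scale, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: %d + %d subjects, R = %d, T = %d\n",
              x$n_per_class[1], x$n_per_class[2], x$regions, x$timepoints))
  cat(sprintf("  %d planted pairs on %d regions; baseline r = %g, effect = %g\n",
              nrow(x$planted_pairs), length(x$planted_regions),
              x$baseline_r, x$effect))
  invisible(x)
}

#' Class correlation matrix of a synthetic spec
#'
#' All off-diagonal entries equal `baseline_r`; in class +1 the planted
#' pairs carry `baseline_r + effect`. If the implied matrix is not positive
#' definite it is projected to the nearest valid correlation matrix
#' (eigenvalue floor 1e-6, then diagonal re-normalisation), with a message.
#'
#' @param spec A [synthetic_spec()].
#' @param class `+1` or `-1`.
#' @return R x R correlation matrix.
#' @export
class_covariance <- function(spec, class = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!class %in% c(-1L, 1L)) ewr_stop("`class` must be +1 or -1")
  R <- spec$regions
  S <- matrix(spec$baseline_r, R, R)
  diag(S) <- 1
  if (class == 1L) {
    for (r in seq_len(nrow(spec$planted_pairs))) {
      i <- spec$planted_pairs[r, 1]; j <- spec$planted_pairs[r, 2]
      S[i, j] <- S[j, i] <- spec$baseline_r + spec$effect
    }
  }
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 0) {
    message(sprintf(
      "class %+d correlation matrix not positive definite (min eigenvalue %.3g); projecting",
      class, min(ev$values)))
    vals <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    S <- stats::cov2cor(S)
  }
  S
}

#' Generate a synthetic labeled study
#'
#' Each subject's T x R signal matrix is drawn independently from a
#' zero-mean Gaussian with the subject's class correlation matrix (scaled by
#' `noise_scale`). Fully reproducible from the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `generated_study`: `series` (list of
#'   [roi_timeseries()]), `labels` (named +1/-1 vector) and `truth` (planted
#'   pairs, planted regions and their feature indices).
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  map <- pair_index_map(spec$regions)
  chol_pos <- chol(class_covariance(spec, 1L)) * spec$noise_scale
  chol_neg <- chol(class_covariance(spec, -1L)) * spec$noise_scale
  n_total <- sum(spec$n_per_class)
  labels <- rep(c(1L, -1L), spec$n_per_class)
  ids <- sprintf("sub%03d", seq_len(n_total))
  names(labels) <- ids
  set.seed(derive_seed(spec$seed, "signals"))
  series <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    Z <- matrix(stats::rnorm(spec$timepoints * spec$regions),
                spec$timepoints, spec$regions)
    X <- Z %*% (if (labels[s] == 1L) chol_pos else chol_neg)
    series[[s]] <- roi_timeseries(X, ids[s])
  }
  truth <- list(
    pairs = spec$planted_pairs,
    regions = spec$planted_regions,
    feature_indices = pair_to_index(spec$planted_pairs[, 1],
                                    spec$planted_pairs[, 2], map)
  )
  structure(list(series = series, labels = labels, truth = truth, spec = spec),
            class = "generated_study")
}

#' @export
print.generated_study <- function(x, ...) {
  cat(sprintf("generated_study: %d subjects (%d positive), R = %d, T = %d; %d planted pairs\n",
              length(x$series), sum(x$labels == 1L), x$spec$regions,
              x$spec$timepoints, nrow(x$truth$pairs)))
  invisible(x)
}

#' Score recovery of the planted regions
#'
#' Fraction of planted regions found among the top-k of the region-frequency
#' ranking, with k equal to the number of planted regions.
#'
#' @param freq_table A [region_frequencies()] table.
#' @param truth_regions Integer ordinals of the planted regions (non-empty).
#' @return Fraction in `[0, 1]`.
#' @export
recovery_score <- function(freq_table, truth_regions) {
  stopifnot(inherits(freq_table, "region_frequency_table"))
  if (length(truth_regions) == 0L) ewr_stop("`truth_regions` is empty")
  k <- length(truth_regions)
  top <- freq_table$ordinal[seq_len(min(k, nrow(freq_table)))]
  length(intersect(top, truth_regions)) / k
}
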
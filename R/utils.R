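# internal helpers shared across modules

ewr_stop <- function(msg, class = "invalid_argument") {
  cond <- structure(
    class = c(paste0("ewrsvmc_", class), "ewrsvmc_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}

#' Derive a reproducible child seed from a master seed
#'
#' All randomness in the package flows from a single master seed through
#' named substreams: splits, per-member draws, per-generation ensembles and
#' simulation each receive a seed derived deterministically from the master
#' seed and a stream label. This avoids hidden coupling between consumers of
#' the global RNG while keeping every run fully replayable.
#'
#' @param seed Master seed (integer).
#' @param ... Stream labels (strings or integers) folded into the child seed.
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(42, "outer")
#' derive_seed(42, "member", 17)
derive_seed <- function(seed, ...) {
  if (!is_count(seed)) ewr_stop("`seed` must be a single integer")
  parts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  # modular folding over a prime below 2^31; products stay exact in doubles
  p <- 2147483629
  s <- abs(as.numeric(seed)) %% p
  for (part in parts) {
    for (b in utf8ToInt(part)) s <- (s * 69069 + b + 1) %% p
  }
  as.integer(s)
}
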
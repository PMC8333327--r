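# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  With seed = NULL the global stream is used as is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' A fixed splitting rule so that every stochastic stage of the pipeline gets
#' its own reproducible stream from one master seed.  Kept below 2^31 so the
#' result is always a valid R integer seed.
#'
#' @param seed Master seed (integer).
#' @param stage Stage index (integer >= 0).
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(stage)) %%
               2147483647)
}

# argmin with randomized tie-breaking (ties within tol)
tie_argmin <- function(x, tol = 1e-12) {
  m <- min(x)
  idx <- which(x <= m + tol)
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}

tie_argmax <- function(x, tol = 1e-12) {
  m <- max(x)
  idx <- which(x >= m - tol)
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}

# shared checker
stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) abort(paste0("non-finite values in ", what),
                                class = "zoopcurves_input_error")
}
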
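# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a root seed and a label
#'
#' Simulation cells (group x reference x contributor count x POI state) each
#' get their own RNG stream derived from one root seed, so results do not
#' depend on the order in which cells are run, and so the diagonal cells of
#' the mis-specified-reference study reproduce the correct-reference cells
#' exactly. The derivation is a 31-ary polynomial hash of the label bytes,
#' folded into the root seed, reduced modulo a prime below 2^31.
#'
#' @param root integer root seed.
#' @param label character scalar identifying the sub-stream.
#' @return a positive integer seed, strictly below 2^31.
#' @export
derive_seed <- function(root, label) {
  stopifnot(is.numeric(root), length(root) == 1L, length(label) == 1L)
  m <- 2147483629 # largest prime below 2^31 - 18
  h <- as.numeric(root) %% m
  for (b in utf8ToInt(as.character(label))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)` (vectorised over `k`, `n` as a
#'   two-column matrix when inputs have length > 1).
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(all(k >= 0), all(n > 0), all(k <= n))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  lo <- ifelse(k == 0, 0, pmax(0, centre - half))
  hi <- ifelse(k == n, 1, pmin(1, centre + half))
  if (length(lo) == 1L) c(lower = lo, upper = hi) else cbind(lower = lo, upper = hi)
}
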
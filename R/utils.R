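#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

stop_if <- function(cond, msg, ...) {
  if (isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Derive a child RNG seed from a master seed
#'
#' Deterministic, collision-poor derivation of per-stage / per-stream seeds
#' from a single master seed, kept within the 32-bit integer range.
#'
#' @param seed master seed (single integer).
#' @param stream stream index (non-negative integer), vectorised.
#' @return integer vector of derived seeds.
#' @export
derive_seed <- function(seed, stream) {
  stop_if(!is.numeric(seed) || length(seed) != 1, "seed must be a single number")
  # splitmix-style mix, reduced mod a large prime below 2^31
  x <- (as.double(seed) %% 2147483647) + 1
  s <- (x * 48271 + as.double(stream) * 362437 + 11) %% 2147483587
  as.integer(s %% 2147483587) + 1L
}

# Univariate slice sampler (stepping out, Neal 2003). logf returns the log
# target density (up to a constant) at a scalar.
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero-density point", call. = FALSE)
  logy <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(max_steps * stats::runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > logy) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}
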
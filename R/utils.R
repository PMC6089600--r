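# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that generators are pure
#' functions of their arguments and do not perturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG stream untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed derived from a dataset seed; kept below 2^31.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483629)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Linear (truncated) convolution of two equal-length vectors via FFT,
# returning the first length(g) lags: out[k] = sum_l w[l] g[k-l+1].
conv_trunc <- function(w, g) {
  n <- length(g)
  stopifnot(length(w) == n)
  np <- stats::nextn(2L * n, 2L)
  wp <- c(w, rep(0, np - n))
  gp <- c(g, rep(0, np - n))
  out <- Re(stats::fft(stats::fft(wp) * stats::fft(gp), inverse = TRUE)) / np
  out[seq_len(n)]
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
}
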
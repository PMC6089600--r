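# Bayesian inference on decay histograms: posterior ~ prod_i P_i^{y_i} under
# a uniform prior, evaluated on a parameter grid when at most three
# parameters are free and by Metropolis-within-Gibbs sampling otherwise.
# Posteriors from groups of kinetochores are multiplied and marginalized to
# estimate the group FRET fraction.

default_grids <- list(
  tau_D    = seq(2, 5, length.out = 151),
  tau_FRET = seq(0.05, 2.5, length.out = 99),
  f_FRET   = seq(0, 1, length.out = 201),
  noise_A  = seq(0.8, 1, length.out = 21))

param_order <- c("tau_D", "tau_FRET", "f_FRET", "noise_A")

#' Posterior inference for decay-model parameters
#'
#' Parameters left `NA` in `fixed` are inferred; the rest are held fixed.
#' With up to three free parameters the posterior is evaluated on a dense
#' grid; with more, a Metropolis-within-Gibbs sampler is used (uniform prior
#' over the parameter bounds in both cases).
#'
#' @param hist a [decay_histogram()] with at least one photon.
#' @param fixed a [decay_model()] with `NA` entries marking free parameters.
#' @param grid_spec named list of grid vectors overriding the defaults.
#' @param sampler_spec list with `n_draws` (default 5000), `burn` (1000) and
#'   `seed` (1) for the MCMC path.
#' @param method "auto" (grid when <= 3 free parameters), "grid" or "mcmc".
#' @return a `posterior_grid` (axes + normalized log-density array) or a
#'   `posterior_samples` object (draws matrix + convergence diagnostic).
#'   Both support [posterior_mean()], [posterior_sd()], [posterior_ci()] and
#'   [posterior_marginal()].
#' @export
infer_posterior <- function(hist, fixed, grid_spec = NULL,
                            sampler_spec = NULL,
                            method = c("auto", "grid", "mcmc")) {
  method <- match.arg(method)
  if (sum(hist$counts) == 0L) stop("histogram has no photons")
  free <- intersect(param_order, model_free_params(fixed))
  if (length(free) == 0L) stop("no free parameters to infer")
  if (method == "auto") method <- if (length(free) <= 3L) "grid" else "mcmc"
  if (method == "grid") infer_posterior_grid(hist, fixed, free, grid_spec)
  else infer_posterior_mcmc(hist, fixed, free, sampler_spec)
}

infer_posterior_grid <- function(hist, fixed, free, grid_spec) {
  axes <- lapply(free, function(p) grid_spec[[p]] %||% default_grids[[p]])
  names(axes) <- free
  spec <- hist_spec(hist)
  counts <- hist$counts
  lt_free <- intersect(free, c("tau_D", "tau_FRET"))
  mix_free <- intersect(free, c("f_FRET", "noise_A"))
  lt_grid <- if (length(lt_free)) expand.grid(axes[lt_free]) else
    data.frame(row.names = 1)
  f_grid <- if ("f_FRET" %in% mix_free) axes$f_FRET else fixed$f_FRET
  A_grid <- if ("noise_A" %in% mix_free) axes$noise_A else fixed$noise_A
  nf <- length(f_grid); nA <- length(A_grid)
  ll <- array(NA_real_, dim = c(nrow(lt_grid), nf, nA))
  for (i in seq_len(nrow(lt_grid))) {
    m <- fixed
    for (p in lt_free) m[[p]] <- lt_grid[i, p]
    if (m$kind == "double" && m$tau_FRET >= m$tau_D) {
      ll[i, , ] <- -Inf
      next
    }
    basis <- decay_basis(m, spec)
    for (a in seq_len(nA)) {
      for (k in seq_len(nf)) {
        fv <- if (m$kind == "double") f_grid[k] else NA_real_
        p <- decay_probs_from_basis(basis, fv, A_grid[a])
        ll[i, k, a] <- decay_loglik(counts, p)
      }
    }
  }
  # `ll` is laid out as [lifetime combinations, f, A] with expand.grid
  # varying the first lifetime axis fastest, so its linear layout already
  # matches the canonical axis order; dropping the unit-length dimensions of
  # fixed f/A leaves the free-parameter array.
  ll_vec <- as.vector(ll)
  dim(ll_vec) <- vapply(axes, length, integer(1))
  log_density <- ll_vec - logsumexp(as.vector(ll_vec))
  structure(list(axes = axes, log_density = log_density, method = "grid",
                 fixed = fixed),
            class = "posterior_grid")
}

infer_posterior_mcmc <- function(hist, fixed, free, sampler_spec) {
  spec0 <- sampler_spec %||% list()
  n_draws <- spec0$n_draws %||% 5000L
  burn <- spec0$burn %||% 1000L
  seed <- spec0$seed %||% 1L
  fn <- make_loglik_fn(hist, fixed, free)
  lo <- vapply(param_bounds[free], `[`, numeric(1), 1L)
  hi <- vapply(param_bounds[free], `[`, numeric(1), 2L)
  with_seed(seed, {
    cur <- start_values(hist, fixed, free)
    cur <- pmin(pmax(cur, lo), hi)
    ll_cur <- fn(cur)
    step <- (hi - lo) / 30
    draws <- matrix(NA_real_, n_draws, length(free),
                    dimnames = list(NULL, free))
    acc <- rep(0L, length(free))
    for (it in seq_len(burn + n_draws)) {
      for (j in seq_along(free)) {
        prop <- cur
        prop[j] <- cur[j] + stats::rnorm(1, 0, step[j])
        if (prop[j] < lo[j] || prop[j] > hi[j]) next
        ll_prop <- fn(prop)
        if (log(stats::runif(1)) < ll_prop - ll_cur) {
          cur <- prop; ll_cur <- ll_prop; acc[j] <- acc[j] + 1L
        }
      }
      if (it <= burn && it %% 100L == 0L) {
        rate <- acc / 100
        step <- step * ifelse(rate < 0.15, 0.6, ifelse(rate > 0.5, 1.6, 1))
        acc[] <- 0L
      }
      if (it > burn) draws[it - burn, ] <- cur
    }
    # split-chain diagnostic: compare first and second halves
    h1 <- draws[seq_len(n_draws %/% 2), , drop = FALSE]
    h2 <- draws[(n_draws %/% 2 + 1):n_draws, , drop = FALSE]
    w <- (apply(h1, 2, stats::var) + apply(h2, 2, stats::var)) / 2
    b <- (colMeans(h1) - colMeans(h2))^2 / 2
    rhat <- sqrt((w + b) / pmax(w, 1e-12))
    mixed <- all(rhat < 1.1)
    if (!mixed) warning("MCMC split-chain diagnostic indicates poor mixing")
    structure(list(draws = draws, method = "mcmc", fixed = fixed,
                   rhat = rhat, mixed = mixed),
              class = "posterior_samples")
  })
}

#' Marginal posterior of one parameter
#'
#' @param post a posterior object from [infer_posterior()].
#' @param param parameter name (default `"f_FRET"`).
#' @return data.frame with `value` and `prob` (grid) or a numeric vector of
#'   draws (samples).
#' @export
posterior_marginal <- function(post, param = "f_FRET") {
  UseMethod("posterior_marginal")
}

#' @export
posterior_marginal.posterior_grid <- function(post, param = "f_FRET") {
  if (!param %in% names(post$axes)) stop("parameter was not free: ", param)
  d <- exp(post$log_density - max(post$log_density))
  if (is.null(dim(d))) dim(d) <- length(d)
  k <- match(param, names(post$axes))
  p <- apply(d, k, sum)
  data.frame(value = post$axes[[param]], prob = p / sum(p))
}

#' @export
posterior_marginal.posterior_samples <- function(post, param = "f_FRET") {
  if (!param %in% colnames(post$draws)) stop("parameter was not free: ", param)
  post$draws[, param]
}

#' Posterior mean of a parameter
#' @inheritParams posterior_marginal
#' @export
posterior_mean <- function(post, param = "f_FRET") {
  m <- posterior_marginal(post, param)
  if (is.data.frame(m)) sum(m$value * m$prob) else mean(m)
}

#' Posterior standard deviation of a parameter
#' @inheritParams posterior_marginal
#' @export
posterior_sd <- function(post, param = "f_FRET") {
  m <- posterior_marginal(post, param)
  if (is.data.frame(m)) {
    mu <- sum(m$value * m$prob)
    sqrt(max(sum(m$value^2 * m$prob) - mu^2, 0))
  } else stats::sd(m)
}

#' Equal-tailed posterior credible interval
#' @inheritParams posterior_marginal
#' @param level credibility level (default 0.95).
#' @export
posterior_ci <- function(post, param = "f_FRET", level = 0.95) {
  a <- (1 - level) / 2
  m <- posterior_marginal(post, param)
  if (is.data.frame(m)) {
    cdf <- cumsum(m$prob)
    c(lower = m$value[which(cdf >= a)[1]],
      upper = m$value[which(cdf >= 1 - a)[1]])
  } else {
    q <- stats::quantile(m, c(a, 1 - a), names = FALSE)
    c(lower = q[1], upper = q[2])
  }
}

#' Combine FRET-fraction posteriors across kinetochores
#'
#' Multiplies the marginal posterior densities of the FRET fraction over a
#' shared grid, renormalizes, and reports the mean and SD of the product
#' posterior (the group SEM). Posteriors whose pairwise overlap (Bhattacharyya
#' coefficient) is near zero trigger a conflict warning.
#'
#' @param posteriors non-empty list of `posterior_grid` objects sharing the
#'   same `f_FRET` axis.
#' @param param parameter to combine over (default `"f_FRET"`).
#' @return an object of class `fret_estimate`: `mean_f_FRET`, `sem`,
#'   `n_kinetochores`, and the combined marginal.
#' @export
combine_posteriors <- function(posteriors, param = "f_FRET") {
  if (length(posteriors) == 0L) stop("empty posterior list")
  margs <- lapply(posteriors, posterior_marginal, param = param)
  ax <- margs[[1]]$value
  for (m in margs) if (length(m$value) != length(ax) ||
                       max(abs(m$value - ax)) > 1e-12)
    stop("posterior grids are incompatible")
  logp <- Reduce(`+`, lapply(margs, function(m) log(pmax(m$prob, 1e-300))))
  logp <- logp - logsumexp(logp)
  prob <- exp(logp)
  mu <- sum(ax * prob)
  sdv <- sqrt(max(sum(ax^2 * prob) - mu^2, 0))
  if (length(margs) > 1L) {
    idx <- utils::combn(min(length(margs), 40L), 2L)
    bc_min <- min(apply(idx, 2, function(ij)
      sum(sqrt(margs[[ij[1]]]$prob * margs[[ij[2]]]$prob))))
    if (bc_min < 0.05)
      warning("conflicting posteriors combined (near-zero overlap)")
  }
  structure(list(mean_f_FRET = mu, sem = sdv,
                 n_kinetochores = length(posteriors),
                 marginal = data.frame(value = ax, prob = prob)),
            class = "fret_estimate")
}

#' @export
print.fret_estimate <- function(x, ...) {
  cat(sprintf("FRET fraction %.4f +/- %.4f (SEM), %d kinetochores\n",
              x$mean_f_FRET, x$sem, x$n_kinetochores))
  invisible(x)
}

#' Convert FRET fraction to NDC80 binding fraction
#'
#' Not every bound donor contributes to the short-lifetime FRET state because
#' only a fraction of tubulin is labeled; the geometric calibration gives a
#' linear relation `f_FRET = slope * f_bound` with slope 0.42. This inverts
#' it, clipping to \[0, 1\] with a warning when the input exceeds the slope.
#'
#' @param f_FRET FRET fraction(s) in \[0, 1\].
#' @param slope calibration slope (default 0.42).
#' @return binding fraction(s) in \[0, 1\].
#' @export
fret_to_binding <- function(f_FRET, slope = 0.42) {
  if (!is.numeric(slope) || slope <= 0) stop("slope must be positive")
  if (any(f_FRET < 0 | f_FRET > 1)) stop("f_FRET must lie in [0, 1]")
  out <- f_FRET / slope
  if (any(out > 1)) {
    warning("binding fraction clipped to 1 (f_FRET exceeds calibration slope)")
    out <- pmin(out, 1)
  }
  out
}
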
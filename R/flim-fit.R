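# Maximum-likelihood fitting of decay histograms and BIC model selection.
#
# The likelihood is multinomial over coarse bins: L = prod_i P_i^{y_i} with
# P_i the normalized per-bin probabilities of the model (the total-count
# factor is a constant and is dropped).

# The short-lifetime search range is capped at 2.5 ns: FRET states closer to
# the donor lifetime are not resolvable as a separate component and letting
# tau_FRET approach tau_D makes the two-exponential fit degenerate.
param_bounds <- list(tau_D = c(0.05, 10), tau_FRET = c(0.02, 2.5),
                     f_FRET = c(0, 1), noise_A = c(0.5, 1))

decay_loglik <- function(counts, probs) {
  idx <- counts > 0L
  sum(counts[idx] * log(pmax(probs[idx], 1e-300)))
}

# Build a closure evaluating the log-likelihood for a free-parameter vector.
make_loglik_fn <- function(hist, model, free) {
  spec <- hist_spec(hist)
  counts <- hist$counts
  lifetime_free <- any(free %in% c("tau_D", "tau_FRET"))
  basis <- if (!lifetime_free) decay_basis(model, spec) else NULL
  function(par) {
    m <- model
    m[free] <- as.list(par)
    if (m$kind == "double" && m$tau_FRET >= m$tau_D)
      return(-1e9 * (1 + m$tau_FRET - m$tau_D))  # smooth penalty, L-BFGS-B safe
    b <- if (is.null(basis)) decay_basis(m, spec) else basis
    p <- decay_probs_from_basis(b, m$f_FRET, m$noise_A)
    decay_loglik(counts, p)
  }
}

start_values <- function(hist, model, free) {
  spec <- hist_spec(hist)
  coarse_w <- spec$bin_width * spec$adc_ratio
  t <- (seq_len(spec$n_bins) - 0.5) * coarse_w
  tot <- sum(hist$counts)
  irf_mean <- sum(spec$irf$weights * (seq_along(spec$irf$weights) - 0.5)) *
    spec$bin_width
  tau_hat <- max(min(sum(hist$counts * t) / tot - irf_mean, 8), 0.2)
  st <- c(tau_D = if (model$kind == "single") tau_hat else 3.75,
          tau_FRET = 0.9, f_FRET = 0.3, noise_A = 0.97)
  st[free]
}

finite_diff_hessian <- function(fn, par, h = NULL) {
  k <- length(par)
  if (is.null(h)) h <- pmax(abs(par) * 1e-4, 1e-6)
  H <- matrix(NA_real_, k, k)
  f0 <- fn(par)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (fn(par + ei) - 2 * f0 + fn(par - ei)) / h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (fn(par + ei + ej) - fn(par + ei - ej) -
           fn(par - ei + ej) + fn(par - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Maximum-likelihood fit of a decay model
#'
#' Maximizes the multinomial log-likelihood over the parameters left `NA` in
#' `fixed`; the others are held at their given values. The IRF shift
#' `bshift`, when requested via `profile_bshift`, is profiled over an integer
#' grid and fixed at its best value.
#'
#' @param hist a [decay_histogram()].
#' @param kind "single" or "double"; defaults to the kind of `fixed`.
#' @param fixed a [decay_model()] whose `NA` entries are free parameters.
#' @param profile_bshift integer vector of candidate IRF shifts (fine bins),
#'   or NULL to keep `fixed$bshift`.
#' @return a list of class `flim_fit` with elements `model` (the fitted
#'   [decay_model()]), `loglik`, `se` (named vector for free parameters),
#'   `vcov`, `converged`, and `n_photons`.
#' @export
fit_mle <- function(hist, kind = NULL, fixed = NULL, profile_bshift = NULL) {
  if (sum(hist$counts) == 0L) stop("histogram has no photons")
  if (is.null(fixed)) fixed <- decay_model(kind %||% "single")
  if (!is.null(kind) && kind != fixed$kind)
    fixed <- do.call(decay_model, utils::modifyList(unclass(fixed)[
      c("tau_D", "tau_FRET", "f_FRET", "noise_A", "bshift")],
      list(kind = kind)))
  free <- model_free_params(fixed)
  shifts <- profile_bshift %||% fixed$bshift
  best <- NULL
  for (b in shifts) {
    model <- fixed
    model$bshift <- as.integer(b)
    if (length(free) == 0L) {
      fn <- make_loglik_fn(hist, model, free)
      cand <- list(par = numeric(0), value = fn(numeric(0)), convergence = 0L)
    } else {
      fn <- make_loglik_fn(hist, model, free)
      lo <- vapply(param_bounds[free], `[`, numeric(1), 1L)
      hi <- vapply(param_bounds[free], `[`, numeric(1), 2L)
      cand <- stats::optim(start_values(hist, model, free), fn,
                           method = "L-BFGS-B", lower = lo, upper = hi,
                           control = list(fnscale = -1, maxit = 400))
    }
    if (is.null(best) || cand$value > best$value) {
      best <- cand
      best$model <- model
    }
  }
  model <- best$model
  model[free] <- as.list(best$par)
  se <- vcov <- NULL
  if (length(free) > 0L) {
    fn <- make_loglik_fn(hist, best$model, free)
    H <- finite_diff_hessian(fn, best$par)
    vcov <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(vcov)) {
      se <- sqrt(pmax(diag(vcov), 0))
      names(se) <- free
      dimnames(vcov) <- list(free, free)
    }
  }
  converged <- (best$convergence %||% 0L) == 0L
  if (!converged) warning("MLE optimizer did not report convergence")
  structure(list(model = model, loglik = best$value, se = se, vcov = vcov,
                 converged = converged, n_photons = sum(hist$counts),
                 free = free),
            class = "flim_fit")
}

#' @export
print.flim_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("%s-exponential MLE (logL = %.2f, %d photons)\n",
              m$kind, x$loglik, x$n_photons))
  vals <- c(tau_D = m$tau_D, tau_FRET = m$tau_FRET, f_FRET = m$f_FRET,
            noise_A = m$noise_A)
  vals <- vals[!is.na(vals)]
  for (p in names(vals)) {
    if (!is.null(x$se) && p %in% names(x$se))
      cat(sprintf("  %-8s %.4f (SE %.4f)\n", p, vals[[p]], x$se[[p]]))
    else cat(sprintf("  %-8s %.4f (fixed)\n", p, vals[[p]]))
  }
  invisible(x)
}

#' BIC comparison of single- vs two-exponential decay models
#'
#' Both models are fitted by maximum likelihood and scored with
#' `BIC = k log(n) - 2 logL` where `n` is the total photon count and `k` the
#' number of free parameters. The returned difference
#' `delta_bic = BIC(single) - BIC(double)` is positive when the
#' two-exponential model is preferred; an exact tie reports the
#' single-exponential model (parsimony).
#'
#' @param hist a [decay_histogram()].
#' @param fixed_single,fixed_double optional [decay_model()] templates with
#'   `NA` for free parameters; defaults free all lifetimes, fractions and
#'   amplitude.
#' @return list with `delta_bic`, `preferred`, and the two fits.
#' @export
select_model_bic <- function(hist, fixed_single = NULL, fixed_double = NULL) {
  f1 <- fit_mle(hist, fixed = fixed_single %||% decay_model("single"))
  f2 <- fit_mle(hist, fixed = fixed_double %||% decay_model("double"))
  n <- sum(hist$counts)
  bic <- function(f) length(f$free) * log(n) - 2 * f$loglik
  delta <- bic(f1) - bic(f2)
  list(delta_bic = delta,
       preferred = if (delta > 0) "double" else "single",
       fit_single = f1, fit_double = f2)
}
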
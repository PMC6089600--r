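# TCSPC decay model: instrument response, exponential decay laws, and the
# discretized per-bin photon probabilities used by both simulation and
# inference.
#
# Time is discretized on a fine grid of width `bin_width` ns (the grid on
# which the IRF is measured); the detector histogram lives on coarse bins of
# `adc_ratio` fine bins each, and per-coarse-bin probabilities are obtained
# by Riemann summation of the convolved model over the fine bins.

#' Instrument response function on the fine time grid
#'
#' @param weights nonnegative numeric vector over fine bins; normalized to
#'   unit sum.
#' @param bin_width fine bin width in ns.
#' @return an object of class `flim_irf`.
#' @export
flim_irf <- function(weights, bin_width) {
  stop_if_not_scalar_pos(bin_width, "bin_width")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("IRF weights must be finite and nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("IRF weights must have positive sum")
  structure(list(weights = weights / s, bin_width = bin_width),
            class = "flim_irf")
}

#' Generate a Gaussian instrument response function
#'
#' The measured IRF of a TCSPC system (e.g. second-harmonic generation from a
#' crystal) is approximated by a Gaussian profile on the fine time grid.
#' A `fwhm` at or below the bin width degenerates to a single-bin delta.
#'
#' @param center peak position in ns.
#' @param fwhm full width at half maximum in ns.
#' @param bin_width fine bin width in ns.
#' @param n_fine_bins number of fine bins.
#' @return a [flim_irf()] object with unit-sum weights.
#' @export
gen_irf <- function(center, fwhm, bin_width, n_fine_bins) {
  stop_if_not_scalar_pos(fwhm, "fwhm")
  stop_if_not_scalar_pos(bin_width, "bin_width")
  t <- (seq_len(n_fine_bins) - 0.5) * bin_width
  if (fwhm <= bin_width) {
    w <- numeric(n_fine_bins)
    w[which.min(abs(t - center))] <- 1
  } else {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    w <- exp(-0.5 * ((t - center) / sigma)^2)
  }
  flim_irf(w, bin_width)
}

#' Exponential decay model for a donor population
#'
#' Either a single-exponential decay (no FRET) or a two-exponential mixture in
#' which `f_FRET` is the relative amplitude of the short-lifetime (FRET-state)
#' component. `noise_A` in (0, 1] is the amplitude of the decay component; the
#' remaining 1 - noise_A is background spread uniformly over the measurement
#' window. `bshift` is an integer shift (in fine bins) of the measured IRF
#' relative to the theoretical time origin. Parameters left `NA` are treated
#' as free by the fitting and inference routines.
#'
#' @param kind "single" or "double".
#' @param tau_D donor (long, non-FRET) lifetime in ns.
#' @param tau_FRET short (FRET-state) lifetime in ns; "double" only.
#' @param f_FRET FRET fraction in \[0, 1\]; "double" only.
#' @param noise_A decay amplitude in (0, 1].
#' @param bshift integer IRF shift in fine bins.
#' @return an object of class `decay_model`.
#' @export
decay_model <- function(kind = c("single", "double"), tau_D = NA_real_,
                        tau_FRET = NA_real_, f_FRET = NA_real_,
                        noise_A = 1, bshift = 0L) {
  kind <- match.arg(kind)
  chk <- function(x, lo, hi, name) {
    if (!is.na(x) && (!is.finite(x) || x < lo || x > hi))
      stop(sprintf("'%s' out of range [%g, %g]", name, lo, hi), call. = FALSE)
  }
  chk(tau_D, 1e-6, Inf, "tau_D")
  if (kind == "double") {
    chk(tau_FRET, 1e-6, Inf, "tau_FRET")
    chk(f_FRET, 0, 1, "f_FRET")
    if (!is.na(tau_D) && !is.na(tau_FRET) && tau_FRET >= tau_D)
      stop("tau_FRET must be smaller than tau_D")
  }
  chk(noise_A, 1e-9, 1, "noise_A")
  if (!is.na(noise_A) && noise_A <= 0) stop("noise_A must be in (0, 1]")
  structure(list(kind = kind, tau_D = tau_D, tau_FRET = tau_FRET,
                 f_FRET = f_FRET, noise_A = noise_A,
                 bshift = as.integer(bshift)),
            class = "decay_model")
}

model_free_params <- function(model) {
  cand <- if (model$kind == "single") c("tau_D", "noise_A") else
    c("tau_D", "tau_FRET", "f_FRET", "noise_A")
  cand[vapply(cand, function(p) is.na(model[[p]]), logical(1))]
}

#' Simulation configuration for synthetic TCSPC decays
#'
#' Defaults correspond to an 80-MHz excitation repetition rate (12.5 ns
#' window) split into 250 coarse detector bins of 16 fine bins each
#' (ADC ratio 16), and a few hundred photons per kinetochore-timepoint.
#'
#' @param seed integer seed.
#' @param photons_per_decay expected total photon count.
#' @param irf_center,irf_fwhm Gaussian IRF peak and width, ns.
#' @param bin_width fine bin width in ns.
#' @param adc_ratio integer number of fine bins per coarse bin.
#' @param n_bins number of coarse bins.
#' @param condition experimental condition preset for movie/K-K generators.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, photons_per_decay = 300,
                       irf_center = 1.0, irf_fwhm = 0.3,
                       bin_width = 12.5 / (250 * 16), adc_ratio = 16L,
                       n_bins = 250L,
                       condition = c("untreated", "taxol", "stlc",
                                     "hec1_9A", "haspin_5itu")) {
  condition <- match.arg(condition)
  if (photons_per_decay < 0) stop("photons_per_decay must be >= 0")
  if (adc_ratio < 1) stop("adc_ratio must be >= 1")
  stop_if_not_scalar_pos(bin_width, "bin_width")
  cfg <- structure(list(seed = as.integer(seed),
                        photons_per_decay = photons_per_decay,
                        irf_center = irf_center, irf_fwhm = irf_fwhm,
                        bin_width = bin_width,
                        adc_ratio = as.integer(adc_ratio),
                        n_bins = as.integer(n_bins), condition = condition),
                   class = "sim_config")
  window <- n_bins * adc_ratio * bin_width
  if (window < 3 * 3.75)
    warning("measurement window shorter than 3 donor lifetimes")
  cfg
}

#' Photon-decay histogram
#'
#' @param counts nonnegative integer photon counts per coarse bin.
#' @param bin_width fine bin width in ns (the coarse width is
#'   `adc_ratio * bin_width`).
#' @param adc_ratio integer number of fine bins per coarse bin.
#' @param irf attached [flim_irf()]; its grid must match.
#' @param truth optional list of generating parameters (ground truth).
#' @return an object of class `decay_histogram`.
#' @export
decay_histogram <- function(counts, bin_width, adc_ratio, irf, truth = NULL) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  adc_ratio <- as.integer(adc_ratio)
  n_fine <- length(counts) * adc_ratio
  if (!inherits(irf, "flim_irf")) stop("'irf' must be a flim_irf")
  if (abs(irf$bin_width - bin_width) > 1e-12)
    stop("IRF bin width does not match histogram fine bin width")
  if (length(irf$weights) != n_fine)
    stop("IRF length does not match histogram fine grid")
  structure(list(counts = as.integer(round(counts)),
                 n_bins = length(counts), bin_width = bin_width,
                 adc_ratio = adc_ratio, irf = irf, truth = truth),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf(
    "TCSPC decay histogram: %d coarse bins x %.4g ns (ADC ratio %d), %d photons\n",
    x$n_bins, x$bin_width * x$adc_ratio, x$adc_ratio, sum(x$counts)))
  invisible(x)
}

# Shape (fine/coarse grid + IRF) of a histogram, without counts.
hist_spec <- function(h) {
  list(n_bins = h$n_bins, bin_width = h$bin_width,
       adc_ratio = h$adc_ratio, irf = h$irf)
}

hist_spec_from_config <- function(config) {
  irf <- gen_irf(config$irf_center, config$irf_fwhm, config$bin_width,
                 config$n_bins * config$adc_ratio)
  list(n_bins = config$n_bins, bin_width = config$bin_width,
       adc_ratio = config$adc_ratio, irf = irf)
}

shift_weights <- function(w, bshift) {
  n <- length(w)
  if (bshift == 0L) return(w)
  out <- numeric(n)
  if (bshift > 0L) out[(bshift + 1L):n] <- w[1L:(n - bshift)]
  else out[1L:(n + bshift)] <- w[(1L - bshift):n]
  out
}

# Convolve an arbitrary fine-grid decay curve with the (shifted) IRF and
# Riemann-sum into coarse bins. Returns the unnormalized coarse curve.
convolve_decay <- function(curve_fine, spec, bshift = 0L) {
  w <- shift_weights(spec$irf$weights, bshift)
  conv <- pmax(conv_trunc(w, curve_fine), 0)
  colSums(matrix(conv, nrow = spec$adc_ratio))
}

# Per-component normalized coarse probability basis for a lifetime set.
# P(f, A) is assembled from these by decay_probs_from_basis().
decay_basis <- function(model, spec) {
  n_fine <- spec$n_bins * spec$adc_ratio
  t <- (seq_len(n_fine) - 0.5) * spec$bin_width
  comp <- function(tau) {
    cc <- convolve_decay(exp(-t / tau), spec, model$bshift)
    list(p = cc, s = sum(cc))
  }
  out <- list(unif = rep(1 / spec$n_bins, spec$n_bins))
  out$D <- comp(model$tau_D)
  if (model$kind == "double") out$F <- comp(model$tau_FRET)
  out
}

decay_probs_from_basis <- function(basis, f_FRET, noise_A) {
  if (is.null(basis$F)) {
    decay <- basis$D$p / basis$D$s
  } else {
    num <- (1 - f_FRET) * basis$D$p + f_FRET * basis$F$p
    decay <- num / ((1 - f_FRET) * basis$D$s + f_FRET * basis$F$s)
  }
  noise_A * decay + (1 - noise_A) * basis$unif
}

#' Per-coarse-bin photon probabilities of a decay model
#'
#' Convolves the exponential decay law with the shifted IRF on the fine grid,
#' Riemann-sums over the `adc_ratio` fine bins of each coarse bin, and
#' normalizes so that probabilities sum to one over the measurement window.
#' The uniform background component contributes `(1 - noise_A)` of the total
#' mass, spread evenly over the window.
#'
#' @param model a fully specified [decay_model()] (no `NA` parameters).
#' @param spec a [decay_histogram()] (its counts are ignored) or the shape
#'   component of one.
#' @return numeric vector of per-coarse-bin probabilities summing to 1.
#' @export
decay_model_eval <- function(model, spec) {
  if (inherits(spec, "decay_histogram")) spec <- hist_spec(spec)
  if (length(model_free_params(model)) > 0)
    stop("decay_model_eval requires a fully specified model")
  decay_probs_from_basis(decay_basis(model, spec), model$f_FRET, model$noise_A)
}

#' Expected (noise-free) coarse decay curve of a model
#'
#' The per-bin Poisson mean for a total expected photon count, i.e.
#' `photons * decay_model_eval(model, spec)`.
#'
#' @inheritParams decay_model_eval
#' @param photons expected total photon count.
#' @return numeric vector of per-coarse-bin expected counts.
#' @export
decay_model_curve <- function(model, spec, photons) {
  photons * decay_model_eval(model, spec)
}
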
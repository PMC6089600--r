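# Coarse-grained geometric Monte Carlo of donor-acceptor distances for an
# NDC80 complex on (or translated away from) a FlAsH-labeled microtubule,
# and the calibration that converts FRET fraction to binding fraction.
#
# The microtubule is modeled as a cylindrical B-lattice of tubulin monomers;
# acceptor (TC-FlAsH) anchors sit at the beta-tubulin C-termini on the
# surface, jittered by a Gaussian tether. The donor (mTurquoise2) sits at a
# fixed offset outward from the CH-domain binding anchor.

#' Cylindrical-lattice geometry of the NDC80/microtubule system
#'
#' @param mt_radius microtubule surface radius, nm.
#' @param axial_rise axial rise per tubulin monomer, nm (dimer = 2x).
#' @param n_protofilaments number of protofilaments.
#' @param tc_tether_sd Gaussian spread (SD, nm) of the TC site about its
#'   beta-tubulin C-terminus anchor.
#' @param donor_offset radial offset of the mTurquoise2 chromophore from the
#'   Hec1 CH-domain anchor, nm.
#' @param n_acceptor_sites number of nearest acceptor sites retained.
#' @export
lattice_geometry <- function(mt_radius = 12.5, axial_rise = 4,
                             n_protofilaments = 13, tc_tether_sd = 1.5,
                             donor_offset = 2.5, n_acceptor_sites = 12L) {
  for (nm in c("mt_radius", "axial_rise", "tc_tether_sd", "donor_offset"))
    stop_if_not_scalar_pos(get(nm), nm)
  if (n_acceptor_sites < 1) stop("n_acceptor_sites must be >= 1")
  structure(list(mt_radius = mt_radius, axial_rise = axial_rise,
                 n_protofilaments = as.integer(n_protofilaments),
                 tc_tether_sd = tc_tether_sd, donor_offset = donor_offset,
                 n_acceptor_sites = as.integer(n_acceptor_sites)),
            class = "lattice_geometry")
}

# Beta-tubulin C-terminus anchors (x, y, z) near the binding site, plus the
# donor position for a given stand-off. The binding anchor sits on
# protofilament 0; inter- vs intra-dimer interfaces differ by one monomer
# rise along z.
lattice_anchors <- function(geom, interface = c("inter", "intra")) {
  interface <- match.arg(interface)
  z_b <- if (interface == "inter") 0 else geom$axial_rise
  n_pf <- geom$n_protofilaments
  dimer <- 2 * geom$axial_rise
  stagger <- 3 * geom$axial_rise / n_pf  # 3-start helical rise per pf
  grid <- expand.grid(j = 0:(n_pf - 1), m = -6:6)
  theta <- 2 * pi * grid$j / n_pf
  z <- grid$m * dimer + grid$j * stagger
  anchors <- cbind(x = geom$mt_radius * cos(theta),
                   y = geom$mt_radius * sin(theta),
                   z = z)
  surf <- c(geom$mt_radius, 0, z_b)  # donor's projection on the surface
  d2 <- colSums((t(anchors) - surf)^2)
  list(anchors = anchors[order(d2)[seq_len(geom$n_acceptor_sites)], ,
                         drop = FALSE],
       z_b = z_b)
}

#' Sample donor-acceptor distance vectors
#'
#' For each sample the binding interface (inter- vs intra-dimer) is chosen
#' 50/50, the donor is placed at
#' `radius = mt_radius + stand_off + donor_offset` above the binding anchor,
#' and the nearest acceptor anchors are jittered by the Gaussian tether
#' spread; Euclidean distances are returned in nm.
#'
#' @param geom a [lattice_geometry()].
#' @param stand_off distance of the CH domain from the microtubule surface,
#'   nm (0 = bound).
#' @param n_samples number of configuration samples.
#' @param seed integer seed.
#' @return an object of class `distance_ensemble`: matrix `samples`
#'   (n_samples x n_acceptor_sites, nm) plus `stand_off`.
#' @export
sample_distances <- function(geom, stand_off = 0, n_samples = 1000L,
                             seed = 1L) {
  if (stand_off < 0) stop("stand_off must be >= 0")
  if (geom$mt_radius <= 0) stop("degenerate geometry: zero radius")
  pre <- list(inter = lattice_anchors(geom, "inter"),
              intra = lattice_anchors(geom, "intra"))
  k <- geom$n_acceptor_sites
  with_seed(seed, {
    interface <- sample(c("inter", "intra"), n_samples, replace = TRUE)
    samples <- matrix(NA_real_, n_samples, k)
    for (i in seq_len(n_samples)) {
      la <- pre[[interface[i]]]
      donor <- c(geom$mt_radius + stand_off + geom$donor_offset, 0, la$z_b)
      acc <- la$anchors + matrix(stats::rnorm(3 * k, 0, geom$tc_tether_sd),
                                 k, 3)
      samples[i, ] <- sqrt(rowSums((acc - matrix(donor, k, 3,
                                                 byrow = TRUE))^2))
    }
    structure(list(samples = samples, stand_off = stand_off, geom = geom,
                   seed = seed),
              class = "distance_ensemble")
  })
}

#' Donor lifetime in the presence of multiple labeled acceptors
#'
#' `tau = tau_D / (1 + sum_labeled (R0 / r_i)^6)`: each labeled acceptor adds
#' an energy-transfer channel with the Forster rate law.
#'
#' @param r acceptor distances, nm (> 0).
#' @param labels logical vector; TRUE where the site carries a FlAsH label.
#' @param R0 Forster radius, nm.
#' @param tau_D unquenched donor lifetime, ns.
#' @return mixed lifetime in ns.
#' @export
mixed_lifetime <- function(r, labels, R0 = 5.90, tau_D = 3.75) {
  if (length(r) != length(labels)) stop("r and labels lengths differ")
  if (any(r <= 0)) stop("distances must be positive")
  labels <- as.logical(labels)
  tau_D / (1 + sum((R0 / r[labels])^6))
}

# Lifetimes for every ensemble row with fresh Bernoulli labels per site.
ensemble_lifetimes <- function(ensemble, f_label, R0, tau_D) {
  s <- ensemble$samples
  lab <- matrix(stats::runif(length(s)) < f_label, nrow(s), ncol(s))
  rate <- rowSums((R0 / s)^6 * lab)
  tau_D / (1 + rate)
}

# Expected fine-grid decay curve (amplitude-weighted, unit amplitude) of a
# population with lifetimes `taus`, evaluated in chunks to bound memory.
mean_exp_curve <- function(t, taus, chunk = 400L) {
  acc <- numeric(length(t))
  n <- length(taus)
  for (i in seq(1L, n, by = chunk)) {
    idx <- i:min(i + chunk - 1L, n)
    acc <- acc + rowSums(exp(outer(t, -1 / taus[idx])))
  }
  acc / n
}

#' Simulate a calibration decay for a partly bound donor population
#'
#' A fraction `f_b` of donors is bound and quenched according to the distance
#' ensemble (with per-site Bernoulli(`f_label`) labeling); the rest decay
#' with the unquenched lifetime. The expected curve is IRF-convolved and
#' Poisson photon counts are drawn, as in [gen_decay()].
#'
#' @param ensemble a [sample_distances()] result.
#' @param f_b bound fraction in \[0, 1\].
#' @param f_label acceptor labeling fraction in \[0, 1\].
#' @param R0 Forster radius, nm.
#' @param tau_D donor lifetime, ns.
#' @param photons expected total photon count (default 10000).
#' @param config a [sim_config()] defining the time grid and IRF.
#' @param seed integer seed.
#' @param expected_only if TRUE, return the noise-free expected coarse curve
#'   instead of a Poisson draw (oracle mode).
#' @return a [decay_histogram()] (or numeric vector in oracle mode).
#' @export
simulate_calibration_decay <- function(ensemble, f_b, f_label, R0 = 5.90,
                                       tau_D = 3.75, photons = 10000,
                                       config = sim_config(), seed = 1L,
                                       expected_only = FALSE) {
  if (f_b < 0 || f_b > 1 || f_label < 0 || f_label > 1)
    stop("f_b and f_label must lie in [0, 1]")
  if (nrow(ensemble$samples) == 0L) stop("empty ensemble")
  spec <- hist_spec_from_config(config)
  n_fine <- spec$n_bins * spec$adc_ratio
  t <- (seq_len(n_fine) - 0.5) * spec$bin_width
  with_seed(seed, {
    curve <- (1 - f_b) * exp(-t / tau_D)
    if (f_b > 0) {
      taus <- ensemble_lifetimes(ensemble, f_label, R0, tau_D)
      curve <- curve + f_b * mean_exp_curve(t, taus)
    }
    coarse <- convolve_decay(curve, spec, 0L)
    lambda <- photons * coarse / sum(coarse)
    if (expected_only) return(lambda)
    counts <- stats::rpois(length(lambda), lambda)
    decay_histogram(counts, spec$bin_width, spec$adc_ratio, spec$irf,
                    truth = list(f_b = f_b, f_label = f_label, R0 = R0,
                                 tau_D = tau_D, photons = photons,
                                 stand_off = ensemble$stand_off, seed = seed))
  })
}

#' Calibrate the FRET-fraction vs binding-fraction slope
#'
#' For each bound fraction on the grid, simulates calibration decays and
#' fits the two-exponential model (donor lifetime fixed, short lifetime
#' free); the fitted FRET fractions are regressed through the origin against
#' the true bound fractions. The slope is the conversion factor between FRET
#' fraction and binding fraction.
#'
#' @param geom a [lattice_geometry()].
#' @param f_b_grid bound fractions covering \[0, 1\].
#' @param f_label acceptor labeling fraction (default 0.261).
#' @param R0 Forster radius, nm (default 5.90).
#' @param tau_D donor lifetime, ns.
#' @param photons photons per simulated decay (default 10000).
#' @param reps replicate decays per grid point (default 30).
#' @param n_ensemble configuration samples in the distance ensemble.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return an object of class `calibration_result`: `slope`, bootstrap
#'   `ci95`, and the per-decay table `per_fb`.
#' @export
calibrate_slope <- function(geom = lattice_geometry(),
                            f_b_grid = seq(0, 1, by = 0.2),
                            f_label = 0.261, R0 = 5.90, tau_D = 3.75,
                            photons = 10000, reps = 30L,
                            n_ensemble = 2000L, config = sim_config(),
                            seed = 1L) {
  if (min(f_b_grid) > 0 || max(f_b_grid) < 1)
    warning("f_b_grid does not cover [0, 1]")
  ensemble <- sample_distances(geom, stand_off = 0, n_samples = n_ensemble,
                               seed = sub_seed(seed, 1L))
  fixed <- decay_model("double", tau_D = tau_D)
  rows <- list(); fails <- 0L
  k <- 0L
  for (rep in seq_len(reps)) {
    for (fb in f_b_grid) {
      k <- k + 1L
      h <- simulate_calibration_decay(ensemble, fb, f_label, R0, tau_D,
                                      photons, config,
                                      seed = sub_seed(seed, 100L + k))
      fit <- tryCatch(fit_mle(h, fixed = fixed), error = function(e) NULL)
      if (is.null(fit) || !fit$converged) {
        fails <- fails + 1L
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(rep = rep, f_b = fb, f_FRET = fit$model$f_FRET,
                   tau_FRET = fit$model$tau_FRET)
    }
  }
  if (fails > 0.1 * reps * length(f_b_grid))
    warning(sprintf("%d calibration fits failed", fails))
  per_fb <- do.call(rbind, rows)
  slope_of <- function(d) sum(d$f_b * d$f_FRET) / sum(d$f_b^2)
  slope <- slope_of(per_fb)
  boot <- with_seed(sub_seed(seed, 2L), {
    reps_ids <- unique(per_fb$rep)
    vapply(seq_len(200L), function(b) {
      pick <- sample(reps_ids, length(reps_ids), replace = TRUE)
      slope_of(do.call(rbind, lapply(pick, function(r)
        per_fb[per_fb$rep == r, ])))
    }, numeric(1))
  })
  structure(list(slope = slope,
                 ci95 = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
                 per_fb = per_fb, n_failed = fails),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("FRET-to-binding calibration slope %.3f (95%% CI %.3f-%.3f)\n",
              x$slope, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' FRET detectability as a function of NDC80-microtubule distance
#'
#' Simulates decays for donors held at each stand-off distance and reports
#' the mean BIC difference between single- and two-exponential fits
#' (positive = FRET detectable).
#'
#' @param geom a [lattice_geometry()].
#' @param stand_offs increasing stand-off distances, nm.
#' @param f_label,R0,tau_D as in [calibrate_slope()].
#' @param photons photons per decay (default 5000).
#' @param reps replicate decays per stand-off (default 30).
#' @param n_ensemble ensemble size per stand-off.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.frame `(stand_off, mean_delta_bic)`.
#' @export
detectability_vs_distance <- function(geom = lattice_geometry(),
                                      stand_offs = seq(0, 15, by = 5),
                                      f_label = 0.261, R0 = 5.90,
                                      tau_D = 3.75, photons = 5000,
                                      reps = 30L, n_ensemble = 1000L,
                                      config = sim_config(), seed = 1L) {
  if (is.unsorted(stand_offs)) stop("stand_offs must be sorted")
  out <- lapply(seq_along(stand_offs), function(i) {
    so <- stand_offs[i]
    ens <- sample_distances(geom, stand_off = so, n_samples = n_ensemble,
                            seed = sub_seed(seed, 10L + i))
    dbic <- vapply(seq_len(reps), function(r) {
      h <- simulate_calibration_decay(ens, 1, f_label, R0, tau_D, photons,
                                      config,
                                      seed = sub_seed(seed, 1000L * i + r))
      select_model_bic(h)$delta_bic
    }, numeric(1))
    data.frame(stand_off = so, mean_delta_bic = mean(dbic))
  })
  do.call(rbind, out)
}

#' Fit the Forster radius from a decay with a known distance distribution
#'
#' Models the decay as a non-FRET exponential plus a FRET population whose
#' lifetime distribution follows `tau(r; R0) = tau_D / (1 + (R0/r)^6)` over
#' the supplied distance distribution, and maximizes the multinomial
#' likelihood over the FRET-population fraction and R0. The 95% CI for R0 is
#' obtained by profile likelihood.
#'
#' @param hist a [decay_histogram()].
#' @param p_r data.frame with columns `r` (nm, > 0) and `p` (weights).
#' @param tau_D known donor lifetime, ns.
#' @param R0_range search interval for R0, nm.
#' @return an object of class `forster_fit`: `R0`, `A_D`, `A_FRET` (relative
#'   amplitudes), `ci95`.
#' @export
fit_forster_radius <- function(hist, p_r, tau_D = 3.75,
                               R0_range = c(3, 9)) {
  if (any(p_r$r <= 0)) stop("distance support must be positive")
  p_w <- p_r$p / sum(p_r$p)
  spec <- hist_spec(hist)
  n_fine <- spec$n_bins * spec$adc_ratio
  t <- (seq_len(n_fine) - 0.5) * spec$bin_width
  counts <- hist$counts
  probs_for <- function(phi, R0) {
    taus <- tau_D / (1 + (R0 / p_r$r)^6)
    fret_curve <- as.vector(exp(outer(t, -1 / taus)) %*% p_w)
    curve <- (1 - phi) * exp(-t / tau_D) + phi * fret_curve
    coarse <- convolve_decay(curve, spec, 0L)
    coarse / sum(coarse)
  }
  nll <- function(par) {
    phi <- stats::plogis(par[1]); R0 <- par[2]
    -decay_loglik(counts, probs_for(phi, R0))
  }
  opt <- stats::optim(c(0, mean(R0_range)), nll, method = "L-BFGS-B",
                      lower = c(-8, R0_range[1]), upper = c(8, R0_range[2]))
  phi_hat <- stats::plogis(opt$par[1])
  if (phi_hat < 0.02)
    stop("FRET amplitude near zero: R0 unidentifiable")
  # profile likelihood CI for R0
  prof <- function(R0) stats::optimize(function(lp)
    decay_loglik(counts, probs_for(stats::plogis(lp), R0)),
    c(-8, 8), maximum = TRUE)$objective
  ll_hat <- -opt$value
  grid <- seq(R0_range[1], R0_range[2], length.out = 61)
  pl <- vapply(grid, prof, numeric(1))
  keep <- grid[pl >= ll_hat - stats::qchisq(0.95, 1) / 2]
  structure(list(R0 = opt$par[2], A_D = 1 - phi_hat, A_FRET = phi_hat,
                 ci95 = range(keep), loglik = ll_hat),
            class = "forster_fit")
}
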
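# Geometric Monte Carlo of donor-acceptor distances and the FRET-fraction
# calibration.

test_that("distance ensembles respect geometry bounds and sample counts", {
  geom <- lattice_geometry()
  ens <- sample_distances(geom, stand_off = 50, n_samples = 40, seed = 1)
  expect_equal(nrow(ens$samples), 40L)
  expect_equal(ncol(ens$samples), geom$n_acceptor_sites)
  expect_gt(min(ens$samples), 10)
  expect_error(sample_distances(geom, stand_off = -1), "stand_off")
})

test_that("mean nearest-acceptor distance grows with stand-off", {
  geom <- lattice_geometry()
  nearest <- vapply(c(0, 4, 8, 12), function(so) {
    ens <- sample_distances(geom, stand_off = so, n_samples = 300, seed = 2)
    mean(apply(ens$samples, 1, min))
  }, numeric(1))
  expect_true(all(diff(nearest) > 0))
})

test_that("mixed lifetime follows the multi-acceptor quenching law", {
  expect_equal(mixed_lifetime(5.90, TRUE, R0 = 5.90, tau_D = 3.75), 1.875)
  expect_equal(mixed_lifetime(c(4, 7), c(FALSE, FALSE)), 3.75)
  expect_equal(mixed_lifetime(c(5.90, 5.90), c(TRUE, TRUE)), 1.25)
  expect_error(mixed_lifetime(c(-1, 2), c(TRUE, TRUE)), "positive")
  expect_error(mixed_lifetime(c(1, 2), TRUE), "lengths")
})

test_that("quenching never lengthens the lifetime and FRET efficiency decays with distance", {
  set.seed(3)
  for (i in 1:20) {
    r <- runif(12, 2, 15)
    lab <- runif(12) < 0.3
    tau <- mixed_lifetime(r, lab)
    expect_lte(tau, 3.75)
    if (!any(lab)) expect_equal(tau, 3.75)
  }
  r_grid <- seq(3, 12, by = 0.5)
  eff <- vapply(r_grid, function(r)
    1 - mixed_lifetime(r, TRUE) / 3.75, numeric(1))
  expect_true(all(diff(eff) < 0))
})

test_that("expected calibration decay matches a brute-force oracle", {
  # 3-sample, 2-site hand ensemble: lifetimes computed by hand for fixed
  # labels, expected decay summed directly
  geom <- lattice_geometry(n_acceptor_sites = 2L)
  ens <- structure(list(samples = rbind(c(4, 6), c(5, 9), c(7, 8)),
                        stand_off = 0, geom = geom, seed = 1),
                   class = "distance_ensemble")
  cfg <- sim_config(irf_fwhm = 1e-9, irf_center = 0)
  lam <- simulate_calibration_decay(ens, f_b = 1, f_label = 1, R0 = 5.9,
                                    tau_D = 3.75, photons = 1000,
                                    config = cfg, seed = 1,
                                    expected_only = TRUE)
  taus <- apply(ens$samples, 1, function(r)
    3.75 / (1 + sum((5.9 / r)^6)))
  spec <- ktflim:::hist_spec_from_config(cfg)
  n_fine <- spec$n_bins * spec$adc_ratio
  t <- (seq_len(n_fine) - 0.5) * spec$bin_width
  curve <- rowMeans(sapply(taus, function(tt) exp(-t / tt)))
  oracle <- ktflim:::convolve_decay(curve, spec, 0L)
  oracle <- 1000 * oracle / sum(oracle)
  expect_equal(lam, oracle, tolerance = 1e-9)
})

test_that("unbound or unlabeled populations look single-exponential", {
  geom <- lattice_geometry()
  ens <- sample_distances(geom, 0, n_samples = 500, seed = 4)
  dbic <- vapply(1:6, function(i) {
    h <- simulate_calibration_decay(ens, f_b = 0, f_label = 0.261,
                                    photons = 5000, seed = 40 + i)
    select_model_bic(h)$delta_bic
  }, numeric(1))
  expect_gte(mean(dbic < 0), 0.8)
  h0 <- simulate_calibration_decay(ens, f_b = 1, f_label = 0, photons = 5000,
                                   seed = 7)
  expect_lt(select_model_bic(h0)$delta_bic, 0)
})

test_that("a fully bound, fully labeled population is quenched", {
  ens <- sample_distances(lattice_geometry(), 0, n_samples = 500, seed = 5)
  h <- simulate_calibration_decay(ens, f_b = 1, f_label = 1, photons = 2e4,
                                  seed = 8)
  fit <- fit_mle(h, fixed = decay_model("single", noise_A = 1))
  expect_lt(fit$model$tau_D, 3.75)
})

test_that("calibration slope is zero without labeling and rises with it", {
  geom <- lattice_geometry()
  s0 <- calibrate_slope(geom, f_label = 0, reps = 2L, n_ensemble = 400L,
                        seed = 6)
  # the amplitude sits on its f = 0 boundary, so the MLE is biased slightly
  # positive; the slope must still be far below any labeled condition
  expect_lt(abs(s0$slope), 0.1)
  slopes <- vapply(c(0.1, 0.26, 0.5), function(fl)
    calibrate_slope(geom, f_label = fl, reps = 3L, n_ensemble = 600L,
                    seed = 7)$slope, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("FRET detectability vanishes beyond the quenching range", {
  tab <- detectability_vs_distance(stand_offs = c(0, 15), reps = 6L,
                                   n_ensemble = 400L, seed = 9)
  expect_gt(tab$mean_delta_bic[1], 0)
  expect_lt(tab$mean_delta_bic[2], 0)
})

test_that("Forster radius is recovered from a broad distance distribution", {
  p_r <- data.frame(r = seq(4, 9, by = 0.25))
  p_r$p <- stats::dnorm(p_r$r, 6.5, 1)
  cfg <- sim_config(seed = 5, photons_per_decay = 1e6)
  spec <- ktflim:::hist_spec_from_config(cfg)
  t <- (seq_len(spec$n_bins * spec$adc_ratio) - 0.5) * spec$bin_width
  taus <- 3.75 / (1 + (5.90 / p_r$r)^6)
  curve <- 0.5 * exp(-t / 3.75) +
    0.5 * as.vector(exp(outer(t, -1 / taus)) %*% (p_r$p / sum(p_r$p)))
  coarse <- ktflim:::convolve_decay(curve, spec, 0L)
  lam <- 1e6 * coarse / sum(coarse)
  h <- decay_histogram(ktflim:::with_seed(17, stats::rpois(length(lam), lam)),
                       spec$bin_width, spec$adc_ratio, spec$irf)
  fit <- fit_forster_radius(h, p_r, tau_D = 3.75)
  expect_lt(abs(fit$R0 - 5.90), 0.15)
  expect_true(fit$ci95[1] <= fit$R0 && fit$R0 <= fit$ci95[2])
})

test_that("a FRET-free decay makes the Forster radius unidentifiable", {
  cfg <- sim_config(seed = 6, photons_per_decay = 1e5)
  h <- gen_decay(decay_model("single", tau_D = 3.75, noise_A = 1),
                 config = cfg)
  p_r <- data.frame(r = seq(4, 9, by = 0.5))
  p_r$p <- rep(1, nrow(p_r))
  expect_error(fit_forster_radius(h, p_r), "unidentifiable")
})
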
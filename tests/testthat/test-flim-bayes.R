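# Bayesian posterior inference, posterior combination, and the
# FRET-to-binding conversion.

test_that("grid posterior recovers the FRET fraction within 3 posterior SD", {
  cfg <- sim_config(seed = 8, photons_per_decay = 5000)
  m <- decay_model("double", tau_D = 3.75, tau_FRET = 0.75, f_FRET = 0.13,
                   noise_A = 1)
  h <- gen_decay(m, config = cfg)
  post <- infer_posterior(h, decay_model("double", tau_D = 3.75,
                                         tau_FRET = 0.75,
                                         noise_A = NA_real_))
  expect_lt(abs(posterior_mean(post) - 0.13), 3 * posterior_sd(post))
})

test_that("a one-point grid concentrates all posterior mass there", {
  cfg <- sim_config(seed = 9, photons_per_decay = 2000)
  m <- decay_model("double", tau_D = 3.75, tau_FRET = 0.75, f_FRET = 0.3,
                   noise_A = 1)
  h <- gen_decay(m, config = cfg)
  post <- infer_posterior(h, decay_model("double", tau_D = 3.75,
                                         tau_FRET = 0.75, noise_A = 1),
                          grid_spec = list(f_FRET = 0.5))
  marg <- posterior_marginal(post)
  expect_equal(marg$prob, 1)
  expect_equal(marg$value, 0.5)
  expect_error(infer_posterior(gen_decay(m, config = sim_config(
    photons_per_decay = 0)), decay_model("double", tau_D = 3.75,
                                         tau_FRET = 0.75)), "no photons")
})

test_that("posterior mode agrees with the MLE maximizer within a grid step", {
  cfg <- sim_config(seed = 10, photons_per_decay = 5000)
  m <- decay_model("double", tau_D = 3.75, tau_FRET = 0.75, f_FRET = 0.25,
                   noise_A = 1)
  h <- gen_decay(m, config = cfg)
  fixed <- decay_model("double", tau_D = 3.75, tau_FRET = 0.75, noise_A = 1)
  post <- infer_posterior(h, fixed)
  marg <- posterior_marginal(post)
  mode_f <- marg$value[which.max(marg$prob)]
  fit <- fit_mle(h, fixed = fixed)
  expect_lt(abs(mode_f - fit$model$f_FRET), diff(marg$value[1:2]) + 1e-9)
})

test_that("grid and MCMC posteriors agree on a two-parameter problem", {
  cfg <- sim_config(seed = 12, photons_per_decay = 5000)
  m <- decay_model("double", tau_D = 3.75, tau_FRET = 0.75, f_FRET = 0.2,
                   noise_A = 0.97)
  h <- gen_decay(m, config = cfg)
  fixed <- decay_model("double", tau_D = 3.75, tau_FRET = 0.75,
                       noise_A = NA_real_)
  pg <- infer_posterior(h, fixed)
  pm <- infer_posterior(h, fixed, method = "mcmc",
                        sampler_spec = list(seed = 4))
  se <- sqrt(posterior_sd(pg)^2 + posterior_sd(pm)^2)
  expect_lt(abs(posterior_mean(pg) - posterior_mean(pm)), 3 * se)
  expect_true(pm$mixed)
})

test_that("95% credible intervals are calibrated over replicates", {
  reps <- 150
  fixed <- decay_model("double", tau_D = 3.75, tau_FRET = 0.75, noise_A = 1)
  covered <- vapply(seq_len(reps), function(i) {
    cfg <- sim_config(seed = 5000 + i, photons_per_decay = 2000)
    h <- gen_decay(decay_model("double", tau_D = 3.75, tau_FRET = 0.75,
                               f_FRET = 0.13, noise_A = 1), config = cfg)
    ci <- posterior_ci(infer_posterior(h, fixed))
    ci[1] <= 0.13 && 0.13 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 1.00)
})

test_that("combining a single posterior is the identity", {
  cfg <- sim_config(seed = 13, photons_per_decay = 3000)
  h <- gen_decay(decay_model("double", tau_D = 3.75, tau_FRET = 0.75,
                             f_FRET = 0.3, noise_A = 1), config = cfg)
  post <- infer_posterior(h, decay_model("double", tau_D = 3.75,
                                         tau_FRET = 0.75, noise_A = 1))
  est <- combine_posteriors(list(post))
  expect_equal(est$mean_f_FRET, posterior_mean(post))
  expect_equal(est$sem, posterior_sd(post))
  expect_error(combine_posteriors(list()), "empty")
})

test_that("combining n identical posteriors shrinks the SD like 1/sqrt(n)", {
  cfg <- sim_config(seed = 14, photons_per_decay = 3000)
  h <- gen_decay(decay_model("double", tau_D = 3.75, tau_FRET = 0.75,
                             f_FRET = 0.3, noise_A = 1), config = cfg)
  post <- infer_posterior(h, decay_model("double", tau_D = 3.75,
                                         tau_FRET = 0.75, noise_A = 1))
  sd1 <- posterior_sd(post)
  for (n in c(4, 9)) {
    est <- combine_posteriors(rep(list(post), n))
    expect_equal(est$sem, sd1 / sqrt(n), tolerance = 0.1)
  }
})

test_that("conflicting posteriors average with a warning", {
  ax <- seq(0, 1, length.out = 201)
  mk <- function(center) {
    lp <- -(ax - center)^2 / (2 * 0.03^2)
    structure(list(axes = list(f_FRET = ax),
                   log_density = lp - ktflim:::logsumexp(lp),
                   method = "grid"), class = "posterior_grid")
  }
  expect_warning(est <- combine_posteriors(list(mk(0), mk(1))),
                 "conflict")
  expect_equal(est$mean_f_FRET, 0.5, tolerance = 0.01)
})

test_that("incompatible grids are rejected", {
  ax1 <- seq(0, 1, length.out = 201); ax2 <- seq(0, 1, length.out = 101)
  mk <- function(ax) structure(list(
    axes = list(f_FRET = ax),
    log_density = rep(-log(length(ax)), length(ax)), method = "grid"),
    class = "posterior_grid")
  expect_error(combine_posteriors(list(mk(ax1), mk(ax2))), "incompatible")
})

test_that("FRET-to-binding conversion matches the calibration arithmetic", {
  expect_equal(signif(fret_to_binding(0.13) * 100, 2), 31)
  expect_equal(signif(fret_to_binding(0.18) * 100, 2), 43)
  expect_equal(fret_to_binding(0), 0)
  # inverse composition is the identity on [0, 1]
  fb <- seq(0, 1, by = 0.1)
  expect_equal(fret_to_binding(0.42 * fb), fb)
  expect_warning(out <- fret_to_binding(0.9), "clipped")
  expect_equal(out, 1)
  expect_error(fret_to_binding(-0.1), "f_FRET")
  expect_error(fret_to_binding(0.1, slope = 0), "slope")
})
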
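# The three-step Aurora B activation / NDC80 phosphorylation / binding
# model: closed forms, ODE cross-checks, fits, and calibration maps.

ref_aurora <- aurora_activation_params(K = 3.5, A_star = 4.6)
ref_pb <- phos_binding_params(Kphos = 19, K0 = 1.43, K0_prime = 18)
ref_params <- tension_model_params(ref_aurora, ref_pb)

test_that("active Aurora B follows the piecewise activation steady state", {
  expect_equal(active_aurora(10, ref_aurora), 6.5)
  expect_equal(active_aurora(2, ref_aurora), 1.1)
  expect_equal(active_aurora(4.6, ref_aurora), 4.6 - 3.5)
  expect_error(aurora_activation_params(K = 5, A_star = 4), "A_star")
  expect_error(active_aurora(-1, ref_aurora), "A_total")
})

test_that("phosphorylated fraction saturates with active Aurora B", {
  expect_equal(phos_fraction(19, 19), 0.5)
  expect_equal(phos_fraction(1e9, 19), 1, tolerance = 1e-7)
  expect_equal(phos_fraction(1.1, 19), 0.0547, tolerance = 1e-3)
  expect_error(phos_fraction(0, 19), "A_active")
})

test_that("binding fraction decreases linearly in the binding constant", {
  expect_equal(binding_fraction(0, ref_pb), 0.4115, tolerance = 1e-4)
  expect_equal(binding_fraction(1 / 9, ref_pb), 0.2257, tolerance = 1e-3)
  flat <- phos_binding_params(Kphos = 19, K0 = 1.43, K0_prime = 0)
  expect_equal(binding_fraction(0.1, flat), binding_fraction(0.9, flat))
})

test_that("the composed concentration-binding curve matches its reference operating points", {
  expect_equal(binding_from_concentration(10, ref_params), 0.1425,
               tolerance = 1e-3)
  expect_equal(binding_from_concentration(c(0, 2, 4.5), ref_params),
               rep(0.2928, 3), tolerance = 1e-3)
  lo <- binding_from_concentration(4.6 - 1e-9, ref_params)
  hi <- binding_from_concentration(4.6 + 1e-9, ref_params)
  expect_lt(abs(lo - hi), 1e-10)
})

test_that("the curve is constant below threshold and decreasing above", {
  A <- seq(0, 20, by = 0.01)
  fb <- binding_from_concentration(A, ref_params)
  below <- fb[A < 4.6]
  expect_lt(diff(range(below)), 1e-12)
  above <- fb[A >= 4.6]
  expect_true(all(diff(above) < 0))
  expect_true(all(abs(diff(fb)) < 0.01))  # no jumps anywhere
})

test_that("closed forms agree with the ODE oracle over a parameter lattice", {
  for (Khd in c(1, 2, 3)) for (Kphos in c(5, 19, 40))
    for (A_total in c(1, 4, 6, 9, 12)) {
      Khi <- 1.2; Ahi <- 2.2
      Ahd <- max(A_total - Ahi, 0)
      o <- ode_steady_state_oracle(
        list(k_a = c(1, 1), k_d = c(Khd, Khi), kp = 1, kdp = Kphos,
             kon = 1, koff0 = 1.43, koff_prime = 18),
        totals = c(Ahd, Ahi))
      aur <- aurora_activation_params(K = Khd + Khi, A_star = Khd + Ahi)
      pb <- phos_binding_params(Kphos = Kphos, K0 = 1.43, K0_prime = 18)
      expect_equal(o$A_active, active_aurora(A_total, aur), tolerance = 1e-6)
      expect_equal(o$f_bound,
                   binding_from_concentration(A_total,
                                              tension_model_params(aur, pb)),
                   tolerance = 1e-6)
    }
})

test_that("a pool below its activation constant decays to zero activity", {
  o <- ode_steady_state_oracle(
    list(k_a = c(1, 1), k_d = c(5, 1), kp = 1, kdp = 19, kon = 1,
         koff0 = 1.43, koff_prime = 18), totals = c(3, 4))
  # pool 1 (total 3 < K 5) dies out; pool 2 reaches total - K = 3
  expect_equal(o$A_active, 3, tolerance = 1e-6)
})

test_that("phosphorylation-binding fit round-trips and flags degeneracy", {
  d <- data.frame(f_phos = seq(0, 0.12, length.out = 20))
  d$f_bound <- binding_fraction(d$f_phos, ref_pb)
  fit <- fit_phos_binding(d)
  expect_equal(fit$K0, 1.43, tolerance = 1e-6)
  expect_equal(fit$K0_prime, 18, tolerance = 1e-5)
  dn <- d
  dn$f_bound <- dn$f_bound + ktflim:::with_seed(3,
    stats::rnorm(20, 0, 0.01))
  dn$sem <- 0.01
  fitn <- fit_phos_binding(dn)
  expect_lt(abs(fitn$K0 - 1.43), 3 * fitn$se[["K0"]])
  expect_lt(abs(fitn$K0_prime - 18), 3 * fitn$se[["K0_prime"]])
  expect_error(fit_phos_binding(data.frame(f_phos = rep(0.05, 5),
                                           f_bound = 0.3)),
               "unidentifiable")
})

test_that("concentration-binding fit recovers the threshold", {
  tb <- gen_tension_table(ref_params, list(intercept = 14, slope = -8),
                          n = 11, noise_sd = 0, dkk_range = c(0.25, 1.625),
                          seed = 5)
  fit0 <- fit_conc_binding(data.frame(A_um = tb$A_um, f_bound = tb$f_bound),
                           fixed = ref_pb)
  expect_equal(fit0$K, 3.5, tolerance = 1e-3)
  expect_equal(fit0$A_star, 4.6, tolerance = 1e-3)
  expect_equal(fit0$Kphos, 19, tolerance = 1e-2)
  tbn <- gen_tension_table(ref_params, list(intercept = 14, slope = -8),
                           n = 11, noise_sd = 0.005,
                           dkk_range = c(0.25, 1.625), seed = 6)
  fitn <- fit_conc_binding(data.frame(A_um = tbn$A_um,
                                      f_bound = tbn$f_bound),
                           fixed = ref_pb)
  expect_lt(abs(fitn$A_star - 4.6), 3 * fitn$se[["A_star"]])
})

test_that("plateau-only concentration data are flagged", {
  A <- seq(0.5, 4, length.out = 8)
  d <- data.frame(A_um = A,
                  f_bound = binding_from_concentration(A, ref_params))
  expect_warning(fit <- fit_conc_binding(d, fixed = ref_pb),
                 "plateau|one branch")
  expect_true(!is.null(fit$flag))
})

test_that("threshold confidence intervals are calibrated over replicates", {
  covered <- vapply(seq_len(100), function(i) {
    tb <- gen_tension_table(ref_params, list(intercept = 14, slope = -8),
                            n = 11, noise_sd = 0.005,
                            dkk_range = c(0.25, 1.625), seed = 7000 + i)
    fit <- tryCatch(suppressWarnings(
      fit_conc_binding(data.frame(A_um = tb$A_um, f_bound = tb$f_bound),
                       fixed = ref_pb)), error = function(e) NULL)
    if (is.null(fit) || is.null(fit$se)) return(NA)
    abs(fit$A_star - 4.6) <= 1.96 * fit$se[["A_star"]]
  }, logical(1))
  expect_gte(mean(covered, na.rm = TRUE), 0.90)
})

test_that("the sensor map hits its anchors and preserves midpoints", {
  expect_equal(sensor_to_phos(0.540), 1 / 9)
  expect_equal(sensor_to_phos(0.368), 0)
  expect_equal(sensor_to_phos(0.454), 1 / 18)
  x <- c(0.40, 0.52)
  expect_equal(sensor_to_phos(mean(x)), mean(sensor_to_phos(x)))
  expect_warning(out <- sensor_to_phos(0.30), "clipped")
  expect_equal(out, 0)
  expect_error(sensor_calibration(f_sensor_WT = 0.3, f_sensor_ZM = 0.4),
               "degenerate")
})

test_that("INCENP intensities convert linearly to concentrations", {
  cal <- intensity_calibration(peak_conc = 10, I_mid_bar = 500, I_bg = 100)
  expect_equal(incenp_to_concentration(500, cal)$conc_um, 10)
  expect_equal(incenp_to_concentration(100, cal)$conc_um, 0)
  c1 <- incenp_to_concentration(300, cal)$conc_um
  c2 <- incenp_to_concentration(500, cal)$conc_um
  expect_equal(c2 - 0, 2 * c1)
  expect_warning(incenp_to_concentration(50, cal), "clipped")
  expect_error(intensity_calibration(10, 100, 200), "I_mid_bar")
})

test_that("binding predictions vs K-K distance follow the piecewise model", {
  flat <- predict_binding_vs_kk(list(intercept = 3, slope = 0),
                                seq(0.8, 1.6, by = 0.1), ref_params)
  expect_equal(length(unique(round(flat$f_bound, 12))), 1L)
  expect_equal(unique(flat$f_bound), 0.2928, tolerance = 1e-3)
  dec <- predict_binding_vs_kk(list(intercept = 14, slope = -8),
                               seq(0.6, 1.6, by = 0.05), ref_params)
  expect_true(all(diff(dec$f_bound) >= 0))
  plateau <- dec$f_bound[dec$A_um < 4.6]
  expect_lt(diff(range(plateau)), 1e-12)
})

test_that("exponential time-course fits recover their parameters", {
  up <- gen_timecourse("rising", 0.088, 3.26, 0.089, seq(-5, 20, by = 0.5), 0)
  fit <- fit_exp_timecourse(up, "rising")
  expect_equal(fit$A, 0.088, tolerance = 1e-6)
  expect_equal(fit$tau, 3.26, tolerance = 1e-5)
  expect_equal(fit$c, 0.089, tolerance = 1e-6)
  # baseline before the switch equals c
  expect_equal(exp_timecourse_model("rising", -3, fit$A, fit$tau, fit$c),
               fit$c)
  dn <- gen_timecourse("decaying", 0.17, 1.95, 0.37,
                       seq(-5, 15, length.out = 40), 0.01, seed = 8)
  fitd <- fit_exp_timecourse(dn, "decaying")
  expect_lt(abs(fitd$tau - 1.95), 3 * fitd$se[["tau"]])
})
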
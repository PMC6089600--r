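# The three-step biophysical model linking Aurora B concentration at NDC80
# to NDC80-kMT binding:
#   (1) Aurora B autoactivation in trans balanced by phosphatases gives a
#       piecewise-linear active concentration with threshold A*;
#   (2) steady-state NDC80 phosphorylation is a saturating function of the
#       active concentration with equilibrium constant Kphos;
#   (3) NDC80-kMT binding follows a binding constant that is linear in the
#       phosphorylated fraction, K(f_phos) = K0 + K0' f_phos.
# Closed forms, weighted least-squares fits, the sensor and intensity
# calibration maps, exponential time-course fits, and an ODE oracle used to
# cross-check the closed forms.

#' Parameters of the Aurora B activation step
#'
#' `K` is the combined activation equilibrium constant of the two Aurora B
#' pools (haspin-dependent + haspin-independent) and `A_star` the threshold
#' concentration above which total active Aurora B grows with concentration.
#'
#' @param K equilibrium constant, muM.
#' @param A_star threshold concentration, muM; must satisfy `A_star >= K`.
#' @export
aurora_activation_params <- function(K = 3.5, A_star = 4.6) {
  if (A_star < K) stop("A_star must be >= K")
  structure(list(K = K, A_star = A_star), class = "aurora_activation_params")
}

#' Parameters of the phosphorylation and binding steps
#'
#' @param Kphos equilibrium constant of NDC80 phosphorylation, muM.
#' @param K0 baseline binding constant (dimensionless).
#' @param K0_prime slope of the binding constant in the phosphorylated
#'   fraction (dimensionless).
#' @export
phos_binding_params <- function(Kphos = 19, K0 = 1.43, K0_prime = 18) {
  if (Kphos <= 0 || K0 <= 0 || K0_prime < 0)
    stop("Kphos and K0 must be positive, K0_prime nonnegative")
  structure(list(Kphos = Kphos, K0 = K0, K0_prime = K0_prime),
            class = "phos_binding_params")
}

#' Full tension-model parameter set
#'
#' @param aurora an [aurora_activation_params()].
#' @param phos_binding a [phos_binding_params()].
#' @export
tension_model_params <- function(aurora = aurora_activation_params(),
                                 phos_binding = phos_binding_params()) {
  structure(list(aurora = aurora, phos_binding = phos_binding),
            class = "tension_model_params")
}

#' Total active Aurora B concentration
#'
#' Steady state of in-trans autoactivation balanced by dephosphorylation,
#' summed over the two pools: `A* - K` below the threshold `A*` and
#' `A_total - K` above it (continuous at the threshold).
#'
#' @param A_total total Aurora B concentration at NDC80, muM.
#' @param p an [aurora_activation_params()].
#' @return active concentration, muM.
#' @export
active_aurora <- function(A_total, p = aurora_activation_params()) {
  if (any(A_total < 0)) stop("A_total must be >= 0")
  ifelse(A_total < p$A_star, p$A_star - p$K, A_total - p$K)
}

#' Steady-state phosphorylated fraction of NDC80 sites
#'
#' `f_phos = (1 + Kphos / A_active)^-1`, increasing in the active Aurora B
#' concentration.
#'
#' @param A_active active Aurora B concentration, muM (> 0).
#' @param Kphos phosphorylation equilibrium constant, muM.
#' @export
phos_fraction <- function(A_active, Kphos = 19) {
  if (any(A_active <= 0)) stop("A_active must be > 0")
  1 / (1 + Kphos / A_active)
}

#' NDC80 binding fraction from phosphorylated fraction
#'
#' `f_bound = (1 + K0 + K0' f_phos)^-1`, decreasing in the phosphorylated
#' fraction.
#'
#' @param f_phos phosphorylated fraction in \[0, 1\].
#' @param p a [phos_binding_params()].
#' @export
binding_fraction <- function(f_phos, p = phos_binding_params()) {
  if (any(f_phos < 0 | f_phos > 1)) stop("f_phos must lie in [0, 1]")
  1 / (1 + p$K0 + p$K0_prime * f_phos)
}

#' NDC80 binding fraction from total Aurora B concentration
#'
#' Composition of [active_aurora()], [phos_fraction()] and
#' [binding_fraction()]: constant below the activation threshold and strictly
#' decreasing above it.
#'
#' @param A_total total Aurora B concentration, muM.
#' @param params a [tension_model_params()] (or both pieces separately via
#'   `aurora` / `phos_binding`).
#' @param aurora,phos_binding optional overrides of the two parameter blocks.
#' @export
binding_from_concentration <- function(A_total,
                                       params = tension_model_params(),
                                       aurora = NULL, phos_binding = NULL) {
  aur <- aurora %||% params$aurora
  pb <- phos_binding %||% params$phos_binding
  binding_fraction(phos_fraction(active_aurora(A_total, aur), pb$Kphos), pb)
}

#' Fit the phosphorylation-binding relation
#'
#' Weighted nonlinear least squares of
#' `f_bound = (1 + K0 + K0' f_phos)^-1`, with weights 1/sem^2 when provided.
#'
#' @param data data.frame with columns `f_phos`, `f_bound`, and optionally
#'   `sem`.
#' @return list with `K0`, `K0_prime`, their `se` and `ci95`, and the
#'   underlying fit.
#' @export
fit_phos_binding <- function(data) {
  if (nrow(data) < 3) stop("need at least 3 points")
  if (stats::sd(data$f_phos) == 0)
    stop("all f_phos identical: K0_prime unidentifiable")
  w <- if ("sem" %in% names(data)) 1 / data$sem^2 else rep(1, nrow(data))
  # start from the linearization 1/f_bound - 1 = K0 + K0' f_phos
  lin <- stats::lm(I(1 / f_bound - 1) ~ f_phos, data = data)
  st <- list(K0 = max(stats::coef(lin)[1], 0.01),
             K0p = max(stats::coef(lin)[2], 0))
  fit <- minpack.lm::nlsLM(f_bound ~ 1 / (1 + K0 + K0p * f_phos),
                           data = data, start = st, weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  list(K0 = cf[["K0"]], K0_prime = cf[["K0p"]],
       se = c(K0 = se[["K0"]], K0_prime = se[["K0p"]]),
       ci95 = rbind(K0 = cf[["K0"]] + c(-1.96, 1.96) * se[["K0"]],
                    K0_prime = cf[["K0p"]] + c(-1.96, 1.96) * se[["K0p"]]),
       fit = fit)
}

#' Fit the concentration-binding relation
#'
#' Weighted least squares of the piecewise model over `(K, Kphos, A_star)`
#' with `K0`, `K0'` held fixed. The constraint `A_star >= K` is enforced by
#' the reparameterization `A_star = K + exp(eta)`.
#'
#' @param data data.frame with columns `A_um`, `f_bound`, optionally `sem`.
#' @param fixed a [phos_binding_params()] supplying `K0` and `K0_prime`.
#' @param start optional named start list (K, Kphos, A_star).
#' @return list with `K`, `Kphos`, `A_star`, `se`, `ci95`, flags, and the
#'   underlying fit.
#' @export
fit_conc_binding <- function(data, fixed = phos_binding_params(),
                             start = list(K = 3, Kphos = 15, A_star = 5)) {
  if (!all(c("A_um", "f_bound") %in% names(data)))
    stop("data must have columns A_um and f_bound")
  w <- if ("sem" %in% names(data)) 1 / data$sem^2 else rep(1, nrow(data))
  K0 <- fixed$K0; K0p <- fixed$K0_prime
  model_fn <- function(A, K, Kphos, eta) {
    A_star <- K + exp(eta)
    act <- pmax(ifelse(A < A_star, A_star - K, A - K), 1e-9)
    1 / (1 + K0 + K0p / (1 + Kphos / act))
  }
  st <- list(K = start$K, Kphos = start$Kphos,
             eta = log(max(start$A_star - start$K, 0.1)))
  fit <- tryCatch(
    minpack.lm::nlsLM(f_bound ~ model_fn(A_um, K, Kphos, eta),
                      data = data, start = st, weights = w,
                      lower = c(K = 1e-3, Kphos = 1e-3, eta = -10),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # a flat (plateau-only) response makes the gradient singular
    slope_p <- tryCatch(
      suppressWarnings(summary(
        stats::lm(f_bound ~ A_um, data = data)))$coefficients[2, 4],
      error = function(e) NA_real_)
    flag <- if (is.na(slope_p) || slope_p > 0.05) "plateau_only" else
      "unidentifiable"
    warning("concentration-binding fit failed (", flag, ")")
    return(list(K = NA_real_, Kphos = NA_real_, A_star = NA_real_,
                se = NULL, ci95 = NULL, flag = flag,
                message = conditionMessage(fit), fit = NULL))
  }
  cf <- stats::coef(fit)
  A_star <- cf[["K"]] + exp(cf[["eta"]])
  # delta method for SE of A_star = K + exp(eta)
  V <- tryCatch(suppressWarnings(stats::vcov(fit)), error = function(e) NULL)
  se <- NULL
  if (!is.null(V)) {
    g <- c(K = 1, Kphos = 0, eta = exp(cf[["eta"]]))
    se <- c(K = sqrt(V["K", "K"]), Kphos = sqrt(V["Kphos", "Kphos"]),
            A_star = sqrt(drop(t(g) %*% V %*% g)))
  }
  flag <- NULL
  if (max(data$A_um) <= A_star) flag <- "plateau_only"
  if (min(data$A_um) >= A_star) flag <- "no_plateau"
  if (!is.null(flag))
    warning("concentration data lie on one branch of the model (", flag, ")")
  list(K = cf[["K"]], Kphos = cf[["Kphos"]], A_star = A_star, se = se,
       ci95 = if (!is.null(se)) rbind(
         K = cf[["K"]] + c(-1.96, 1.96) * se[["K"]],
         Kphos = cf[["Kphos"]] + c(-1.96, 1.96) * se[["Kphos"]],
         A_star = A_star + c(-1.96, 1.96) * se[["A_star"]]),
       flag = flag, fit = fit)
}

#' Calibration anchors of the Aurora B activity sensor
#'
#' Non-FRET fraction of the cytoplasmic Aurora B FRET sensor before
#' inhibition (`f_sensor_WT`) and after full inhibition (`f_sensor_ZM`),
#' mapped linearly to phosphorylated NDC80 fractions 1/9 and 0.
#'
#' @param f_sensor_WT,f_sensor_ZM sensor non-FRET fractions at the anchors.
#' @param f_phos_WT,f_phos_ZM phosphorylated fractions at the anchors.
#' @export
sensor_calibration <- function(f_sensor_WT = 0.540, f_sensor_ZM = 0.368,
                               f_phos_WT = 1 / 9, f_phos_ZM = 0) {
  if (f_sensor_WT <= f_sensor_ZM)
    stop("degenerate calibration: f_sensor_WT must exceed f_sensor_ZM")
  structure(list(f_sensor_WT = f_sensor_WT, f_sensor_ZM = f_sensor_ZM,
                 f_phos_WT = f_phos_WT, f_phos_ZM = f_phos_ZM),
            class = "sensor_calibration")
}

#' Convert sensor non-FRET fraction to phosphorylated fraction
#'
#' Exact two-anchor linear map; extrapolated values below zero are clipped
#' with a warning.
#'
#' @param f_sensor sensor non-FRET fraction(s).
#' @param cal a [sensor_calibration()].
#' @export
sensor_to_phos <- function(f_sensor, cal = sensor_calibration()) {
  out <- (f_sensor - cal$f_sensor_ZM) /
    (cal$f_sensor_WT - cal$f_sensor_ZM) *
    (cal$f_phos_WT - cal$f_phos_ZM) + cal$f_phos_ZM
  if (any(out < 0)) {
    warning("phosphorylated fraction clipped at 0")
    out <- pmax(out, 0)
  }
  out
}

#' INCENP intensity calibration
#'
#' @param peak_conc Aurora B concentration at the inner-centromere peak, muM.
#' @param I_mid_bar mean midpoint INCENP intensity (a.u.).
#' @param I_bg cytoplasmic background intensity (a.u.).
#' @export
intensity_calibration <- function(peak_conc = 10, I_mid_bar, I_bg) {
  if (I_mid_bar <= I_bg) stop("I_mid_bar must exceed I_bg")
  structure(list(peak_conc = peak_conc, I_mid_bar = I_mid_bar, I_bg = I_bg),
            class = "intensity_calibration")
}

#' Convert INCENP intensity at NDC80 to Aurora B concentration
#'
#' Normalizes by the background-subtracted midpoint intensity, whose mean
#' corresponds to the peak Aurora B concentration (10 muM).
#'
#' @param I_ndc80 INCENP intensity(ies) at NDC80 (a.u.).
#' @param cal an [intensity_calibration()].
#' @return data.frame with `norm` (dimensionless) and `conc_um` (muM).
#' @export
incenp_to_concentration <- function(I_ndc80, cal) {
  norm <- (I_ndc80 - cal$I_bg) / (cal$I_mid_bar - cal$I_bg)
  if (any(norm < 0)) {
    warning("negative normalized intensity clipped at 0")
    norm <- pmax(norm, 0)
  }
  data.frame(norm = norm, conc_um = norm * cal$peak_conc)
}

#' Predict binding fraction as a function of K-K distance
#'
#' Feeds the linear Aurora-B-concentration vs K-K-distance relation through
#' the three-step model.
#'
#' @param intensity_line list with `intercept` and `slope` of `[A]` (muM) vs
#'   K-K distance (um).
#' @param dkk_grid K-K distances, um.
#' @param params a [tension_model_params()].
#' @return data.frame `(dkk_um, A_um, f_bound)`.
#' @export
predict_binding_vs_kk <- function(intensity_line, dkk_grid,
                                  params = tension_model_params()) {
  A <- pmax(intensity_line$intercept + intensity_line$slope * dkk_grid, 1e-6)
  data.frame(dkk_um = dkk_grid, A_um = A,
             f_bound = binding_from_concentration(A, params))
}

exp_timecourse_model <- function(kind, t, A, tau, c) {
  I <- as.numeric(t >= 0)
  if (kind == "rising") A * (1 - exp(-I * t / tau)) + c
  else A * exp(-I * t / tau) + c
}

#' Fit an exponential drug-response time course
#'
#' Rising model `y = A (1 - exp(-I(t>=0) t/tau)) + c` or decaying model
#' `y = A exp(-I(t>=0) t/tau) + c`, fitted by (weighted) nonlinear least
#' squares with the on-switch indicator handled exactly.
#'
#' @param tc data.frame with columns `t_min`, `y`, optionally `sem`.
#' @param kind "rising" or "decaying".
#' @return list with `A`, `tau`, `c`, `se`, `ci95`, `flag`, and the fit.
#' @export
fit_exp_timecourse <- function(tc, kind = c("rising", "decaying")) {
  kind <- match.arg(kind)
  if (!any(tc$t_min < 0) || !any(tc$t_min > 0))
    warning("time course should include samples before and after t = 0")
  w <- if ("sem" %in% names(tc)) 1 / tc$sem^2 else rep(1, nrow(tc))
  rng <- range(tc$y)
  st <- if (kind == "rising")
    list(A = diff(rng), tau = 2, c = rng[1])
  else list(A = diff(rng), tau = 2, c = rng[1])
  fit <- minpack.lm::nlsLM(
    y ~ exp_timecourse_model(kind, t_min, A, tau, c), data = tc,
    start = st, weights = w,
    lower = c(A = 0, tau = 1e-3, c = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  flag <- if (cf[["tau"]] <= 2e-3) "tau_at_bound" else NULL
  if (!is.null(flag)) warning("fitted tau at its lower bound")
  list(A = cf[["A"]], tau = cf[["tau"]], c = cf[["c"]],
       se = c(A = se[["A"]], tau = se[["tau"]], c = se[["c"]]),
       ci95 = rbind(A = cf[["A"]] + c(-1.96, 1.96) * se[["A"]],
                    tau = cf[["tau"]] + c(-1.96, 1.96) * se[["tau"]],
                    c = cf[["c"]] + c(-1.96, 1.96) * se[["c"]]),
       flag = flag, fit = fit)
}

#' ODE oracle for the three-step steady state
#'
#' Integrates the activation, phosphorylation and binding kinetics forward
#' until relative change falls below `tol`, returning the steady state. Used
#' to cross-check the closed-form expressions.
#'
#' @param rates list with per-pool activation rates `k_a`, `k_d` (each
#'   length-2: haspin-dependent, haspin-independent), `kp`, `kdp`, `kon`,
#'   `koff0`, `koff_prime` (so that koff/kon = K0 + K0' f_phos).
#' @param totals length-2 vector of pool concentrations (muM).
#' @param t_end maximum integration time.
#' @param tol relative steady-state tolerance.
#' @return list `(A_active, f_phos, f_bound)` at steady state.
#' @export
ode_steady_state_oracle <- function(rates, totals, t_end = 1e5, tol = 1e-9) {
  stopifnot(all(unlist(rates) > 0), length(totals) == 2)
  deriv <- function(t, y, p) {
    a1 <- y[1]; a2 <- y[2]; fp <- y[3]; fb <- y[4]
    act <- a1 + a2
    list(c(
      p$k_a[1] * a1 * (totals[1] - p$k_d[1] / p$k_a[1] - a1),
      p$k_a[2] * a2 * (totals[2] - p$k_d[2] / p$k_a[2] - a2),
      p$kp * act * (1 - fp) - p$kdp * fp,
      p$kon * (1 - fb) - p$kon * (p$koff0 + p$koff_prime * fp) * fb))
  }
  y0 <- c(pmax(totals * 0.5, 1e-6), 0.5, 0.5)
  horizon <- 50
  yT <- y0
  converged <- FALSE
  # integrate over successively doubled horizons until the state stalls
  while (horizon <= t_end) {
    sol <- deSolve::ode(y = y0, times = c(0, horizon), func = deriv,
                        parms = rates, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12, maxsteps = 50000)
    yT <- sol[nrow(sol), -1]
    if (all(abs(yT - y0) <= tol * pmax(abs(yT), 1e-12))) {
      converged <- TRUE
      break
    }
    y0 <- pmax(yT, 0)
    horizon <- horizon * 2
  }
  if (!converged) stop("ODE oracle did not reach steady state")
  list(A_active = unname(yT[1] + yT[2]), f_phos = unname(yT[3]),
       f_bound = unname(yT[4]))
}
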
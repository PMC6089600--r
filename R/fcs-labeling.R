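# Fluorescence correlation spectroscopy models and the labeling-fraction
# arithmetic: a reference fit on a dye of known concentration and diffusion
# calibrates the focal volume; a brightness fit on the labeled peptide gives
# photons per molecule; image arithmetic converts photon rates to polymer
# concentration and finally to the fraction of labeled beta-tubulin.

MOLECULES_PER_UM3_PER_UM <- 602.214076  # 1 uM in molecules per um^3

#' FCS autocorrelation curve
#'
#' @param lags positive increasing lag times, seconds.
#' @param G autocorrelation values.
#' @param count_rate,background_rate detector rates, s^-1.
#' @export
fcs_curve <- function(lags, G, count_rate = NA_real_, background_rate = 0) {
  if (any(lags <= 0) || any(diff(lags) <= 0))
    stop("lags must be positive and increasing")
  structure(list(lags = lags, G = G, count_rate = count_rate,
                 background_rate = background_rate),
            class = "fcs_curve")
}

# Axial beam waist from the effective volume and radial waist:
# w_z = (2 / pi^(3/2)) V_eff / w_xy^2. Isolated here so an alternate
# volume convention is a one-line change.
wz_from_veff <- function(V_eff_um3, w_xy_um) {
  (2 / pi^1.5) * V_eff_um3 / w_xy_um^2
}

# Background noise correction factor from signal and background rates.
chi2_correction <- function(count_rate, background_rate) {
  if (is.na(count_rate) || background_rate <= 0) return(1)
  s <- count_rate - background_rate
  (s / (s + background_rate))^2
}

#' Two-photon diffusion FCS model with known concentration
#'
#' `G(tau) = 1/(V_eff chi2 C) (1 + 8 D tau / w_xy^2)^-1
#'  (1 + 8 D tau / w_z^2)^-1/2 + G_inf` with
#' `w_z = (2/pi^(3/2)) V_eff / w_xy^2`.
#'
#' @param tau lag times, s.
#' @param V_eff_um3 effective focal volume, um^3.
#' @param w_xy_um radial beam waist, um.
#' @param G_inf long-lag offset.
#' @param C_molar fluorophore concentration, molar.
#' @param D_um2s diffusion coefficient, um^2/s.
#' @param chi2 background correction factor.
#' @export
fcs_reference_model <- function(tau, V_eff_um3, w_xy_um, G_inf, C_molar,
                                D_um2s, chi2 = 1) {
  C_um3 <- C_molar * 1e6 * MOLECULES_PER_UM3_PER_UM
  wz <- wz_from_veff(V_eff_um3, w_xy_um)
  1 / (V_eff_um3 * chi2 * C_um3) /
    (1 + 8 * D_um2s * tau / w_xy_um^2) /
    sqrt(1 + 8 * D_um2s * tau / wz^2) + G_inf
}

#' Two-photon FCS model parameterized by molecule number
#'
#' `G(tau) = 1/(N chi2) (1 + tau/tau_d)^-1
#'  (1 + (w_xy^2/w_z^2)(tau/tau_d))^-1/2 + G_inf`.
#'
#' @param tau lag times, s.
#' @param N mean number of molecules in the focal volume.
#' @param tau_diff_s diffusion time, s.
#' @param w_ratio2 squared waist ratio `w_xy^2 / w_z^2`.
#' @param G_inf long-lag offset.
#' @param chi2 background correction factor.
#' @export
fcs_brightness_model <- function(tau, N, tau_diff_s, w_ratio2, G_inf,
                                 chi2 = 1) {
  1 / (N * chi2) / (1 + tau / tau_diff_s) /
    sqrt(1 + w_ratio2 * (tau / tau_diff_s)) + G_inf
}

#' Fit the reference FCS curve of a calibration dye
#'
#' Least squares over `(V_eff, w_xy, G_inf)` with the concentration and
#' diffusion coefficient known; the axial waist is eliminated through the
#' effective-volume relation.
#'
#' @param curve an [fcs_curve()].
#' @param known_C concentration, molar.
#' @param known_D diffusion coefficient, um^2/s.
#' @return object of class `fcs_reference_fit` with `V_eff_um3`, `w_xy_nm`,
#'   `w_z_nm`, `G_inf`, `chi2`, `se`.
#' @export
fit_reference_fcs <- function(curve, known_C, known_D) {
  stopifnot(known_C > 0, known_D > 0)
  chi2 <- chi2_correction(curve$count_rate, curve$background_rate)
  df <- data.frame(tau = curve$lags, G = curve$G)
  amp0 <- max(curve$G[1] - curve$G[length(curve$G)], 1e-4)
  V0 <- 1 / (amp0 * chi2 * known_C * 1e6 * MOLECULES_PER_UM3_PER_UM)
  fit <- minpack.lm::nlsLM(
    G ~ fcs_reference_model(tau, V, wxy, Ginf, known_C, known_D, chi2),
    data = df,
    start = list(V = V0, wxy = 0.3, Ginf = min(curve$G)),
    lower = c(V = 1e-4, wxy = 1e-3, Ginf = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  cf <- stats::coef(fit)
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  structure(list(V_eff_um3 = cf[["V"]], w_xy_nm = cf[["wxy"]] * 1e3,
                 w_z_nm = wz_from_veff(cf[["V"]], cf[["wxy"]]) * 1e3,
                 G_inf = cf[["Ginf"]], chi2 = chi2,
                 se = c(V_eff_um3 = se[["V"]], w_xy_nm = se[["wxy"]] * 1e3,
                        G_inf = se[["Ginf"]]),
                 fit = fit),
            class = "fcs_reference_fit")
}

#' Fit molecule number and molecular brightness from an FCS curve
#'
#' With the focal geometry fixed from the reference fit, fits `(N, tau_d,
#' G_inf)` and converts the background-corrected count rate to brightness
#' `(count_rate - background_rate) / N`.
#'
#' @param curve an [fcs_curve()] with `count_rate` set.
#' @param geometry an `fcs_reference_fit`.
#' @return object of class `fcs_brightness_fit` with `N`, `brightness_s1`,
#'   `tau_diff_s`, `G_inf`.
#' @export
fit_brightness_fcs <- function(curve, geometry) {
  signal <- curve$count_rate - curve$background_rate
  if (!is.na(signal) && signal <= 0) {
    warning("zero molecular brightness (background equals count rate)")
    return(structure(list(N = NA_real_, brightness_s1 = 0,
                          tau_diff_s = NA_real_, G_inf = NA_real_,
                          fit = NULL),
                     class = "fcs_brightness_fit"))
  }
  chi2 <- chi2_correction(curve$count_rate, curve$background_rate)
  w_ratio2 <- (geometry$w_xy_nm / geometry$w_z_nm)^2
  amp0 <- curve$G[1] - curve$G[length(curve$G)]
  if (amp0 <= 0) stop("nonpositive correlation amplitude")
  df <- data.frame(tau = curve$lags, G = curve$G)
  fit <- minpack.lm::nlsLM(
    G ~ fcs_brightness_model(tau, N, taud, w_ratio2, Ginf, chi2),
    data = df,
    start = list(N = 1 / (amp0 * chi2), taud = 1e-3, Ginf = min(curve$G)),
    lower = c(N = 1e-6, taud = 1e-9, Ginf = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  cf <- stats::coef(fit)
  brightness <- signal / cf[["N"]]
  structure(list(N = cf[["N"]], brightness_s1 = max(brightness, 0),
                 tau_diff_s = cf[["taud"]], G_inf = cf[["Ginf"]],
                 fit = fit),
            class = "fcs_brightness_fit")
}

#' Convert a photon rate to a molar concentration
#'
#' `conc = rate / (brightness x V_eff)` in molecules per um^3, converted to
#' muM (1 muM = 602.214 molecules/um^3).
#'
#' @param rate photon rate, s^-1.
#' @param brightness molecular brightness, s^-1 per molecule.
#' @param V_eff_um3 effective focal volume, um^3.
#' @return concentration in muM.
#' @export
concentration_from_rate <- function(rate, brightness, V_eff_um3) {
  if (rate < 0) stop("rate must be >= 0")
  stop_if_not_scalar_pos(brightness, "brightness")
  stop_if_not_scalar_pos(V_eff_um3, "V_eff_um3")
  rate / (brightness * V_eff_um3) / MOLECULES_PER_UM3_PER_UM
}

#' Segment a cell and estimate the polymer-bound photon rate
#'
#' The mean in-cell photon rate contains both diffusing and polymerized
#' tubulin; the mode of the in-cell rate histogram estimates the diffuse
#' (cytoplasmic) level, so their difference is the polymer contribution.
#' The mask defaults to Otsu thresholding, morphological closing, and the
#' largest connected component (requires EBImage).
#'
#' @param image numeric matrix of photon rates (ms^-1 per pixel).
#' @param mask optional logical matrix; TRUE inside the cell.
#' @param bin_width histogram bin width for the mode; default
#'   Freedman-Diaconis.
#' @return list with `total_mean`, `cytoplasm_mode`, `polymer_rate`.
#' @export
estimate_polymer_rate <- function(image, mask = NULL, bin_width = NULL) {
  if (is.null(mask)) mask <- segment_cell(image)
  if (!any(mask)) stop("empty cell mask")
  v <- image[mask]
  if (is.null(bin_width)) {
    iqr <- stats::IQR(v)
    bin_width <- if (iqr > 0) 2 * iqr / length(v)^(1 / 3) else
      max(diff(range(v)) / 30, 1e-9)
  }
  if (diff(range(v)) < .Machine$double.eps) {
    mode_v <- v[1]
  } else {
    breaks <- seq(min(v) - bin_width / 2, max(v) + bin_width, by = bin_width)
    hh <- hist(v, breaks = breaks, plot = FALSE)
    mode_v <- hh$mids[which.max(hh$counts)]
  }
  list(total_mean = mean(v), cytoplasm_mode = mode_v,
       polymer_rate = mean(v) - mode_v)
}

#' Otsu-threshold cell segmentation
#'
#' @param image numeric matrix.
#' @return logical matrix (largest connected component above the Otsu
#'   threshold, after morphological closing).
#' @export
segment_cell <- function(image) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("segment_cell requires the EBImage package")
  img <- (image - min(image)) / max(diff(range(image)), .Machine$double.eps)
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  bw <- EBImage::closing(img > thr, EBImage::makeBrush(5, "disc"))
  lab <- EBImage::bwlabel(bw)
  tab <- table(lab[lab > 0])
  if (length(tab) == 0L) return(matrix(FALSE, nrow(image), ncol(image)))
  as.matrix(lab) == as.integer(names(which.max(tab)))
}

#' Labeling-fraction arithmetic
#'
#' Scales the polymerized labeled-tubulin concentration by the polymerized
#' percentage to the total labeled concentration, and divides by the total
#' tubulin concentration.
#'
#' @param conc_polymer_labeled concentration of polymerized labeled tubulin,
#'   muM.
#' @param polymer_fraction percentage of tubulin that is polymerized,
#'   in (0, 100].
#' @param total_tubulin total tubulin-dimer concentration, muM.
#' @return list with `conc_total_labeled` (muM) and `fraction` (%).
#' @export
labeling_fraction <- function(conc_polymer_labeled, polymer_fraction,
                              total_tubulin) {
  if (polymer_fraction <= 0 || polymer_fraction > 100)
    stop("polymer_fraction must lie in (0, 100]")
  stop_if_not_scalar_pos(total_tubulin, "total_tubulin")
  total <- conc_polymer_labeled * 100 / polymer_fraction
  frac <- total / total_tubulin * 100
  if (frac > 100)
    warning("labeled concentration exceeds total tubulin (fraction > 100%)")
  list(conc_total_labeled = total, fraction = frac)
}
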
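# Synthetic-data generators. Every generator is a pure function of its
# parameters and seed, and attaches the generating parameters ("ground
# truth") to its output so downstream estimators can be validated without
# external data.

#' Condition presets for sister-kinetochore (K-K) distance distributions
#'
#' Normal(mean, SD) parameters in micrometers for the K-K distance under each
#' experimental condition: untreated bipolar spindles, taxol-treated
#' (microtubule-stabilized, reduced tension), STLC-treated (monopolar),
#' 9A-Hec1 (phospho-null mutant, increased tension), and haspin-inhibited
#' cells (5-ITu; K-K distribution matching untreated).
#'
#' @format named list of `c(mean, sd)` pairs.
#' @export
kk_condition_presets <- list(
  untreated   = c(mean = 1.19, sd = 0.19),
  taxol       = c(mean = 0.90, sd = 0.10),
  stlc        = c(mean = 0.87, sd = 0.10),
  hec1_9A     = c(mean = 1.36, sd = 0.21),
  haspin_5itu = c(mean = 1.19, sd = 0.19))

#' Generate a synthetic photon-decay histogram
#'
#' Draws per-coarse-bin counts from independent Poisson distributions whose
#' means follow the IRF-convolved decay model, with expected total count
#' `config$photons_per_decay`.
#'
#' @param model a fully specified [decay_model()].
#' @param irf a [flim_irf()]; defaults to the Gaussian IRF implied by
#'   `config`.
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a [decay_histogram()] whose `truth` field carries the generating
#'   model parameters and photon count.
#' @export
gen_decay <- function(model, irf = NULL, config = sim_config(), seed = NULL) {
  seed <- seed %||% config$seed
  spec <- if (is.null(irf)) hist_spec_from_config(config) else
    list(n_bins = config$n_bins, bin_width = config$bin_width,
         adc_ratio = config$adc_ratio, irf = irf)
  lambda <- decay_model_curve(model, spec, config$photons_per_decay)
  counts <- with_seed(seed, stats::rpois(length(lambda), lambda))
  decay_histogram(counts, spec$bin_width, spec$adc_ratio, spec$irf,
                  truth = list(model = model,
                               photons = config$photons_per_decay,
                               seed = seed))
}

#' Generate a synthetic metaphase movie with oscillating sister pairs
#'
#' Sister-pair kinematics: the pair center oscillates sinusoidally along the
#' pair axis while the K-K distance breathes in anti-phase about a mean drawn
#' from the condition preset; sister positions are center +/- (K-K)/2 along
#' the axis. Spots are rendered as 2D Gaussians with Poisson shot noise and
#' Gaussian read noise. Positions use 0-based pixel coordinates with pixel
#' centers at integers; the physical scale is `pixel_size_um` per pixel.
#'
#' @param n_pairs number of sister pairs.
#' @param n_frames number of frames.
#' @param condition condition preset name (see [kk_condition_presets]).
#' @param config a [sim_config()]; only its seed is used by default.
#' @param dt_s frame interval in seconds (default 13).
#' @param pixel_size_um pixel size in micrometers (default 0.107).
#' @param img_size image side in pixels (default 128; enlarged automatically
#'   for large `n_pairs`).
#' @param osc_amp_um,osc_period_s pair-center oscillation amplitude and
#'   period.
#' @param breath_amp_um,breath_period_s K-K breathing amplitude and period.
#' @param drift_um_per_frame length-2 global drift per frame in micrometers.
#' @param psf_sigma_px Gaussian spot width in pixels.
#' @param spot_photons,bg_photons,read_noise_sd camera model.
#' @param render if FALSE, skip image rendering and return truth only.
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with `frames` (h x w x n_frames array, or NULL), `truth`
#'   (per-frame sister positions and K-K distances), `pairs` (per-pair
#'   parameters) and the geometry/camera settings used.
#' @export
gen_movie <- function(n_pairs, n_frames, condition = "untreated",
                      config = sim_config(), dt_s = 13,
                      pixel_size_um = 0.107, img_size = 128L,
                      osc_amp_um = 0.5, osc_period_s = 150,
                      breath_amp_um = 0.15, breath_period_s = 75,
                      drift_um_per_frame = c(0, 0), psf_sigma_px = 1.3,
                      spot_photons = 500, bg_photons = 10,
                      read_noise_sd = 2, render = TRUE, seed = NULL) {
  stopifnot(n_pairs >= 1, n_frames >= 1)
  seed <- seed %||% config$seed
  preset <- kk_condition_presets[[condition]]
  if (is.null(preset)) stop("unknown condition: ", condition)
  with_seed(seed, {
    margin <- osc_amp_um + 1.5
    if (render) {
      # space pairs so they stay resolvable at the default density
      need <- ceiling((sqrt(n_pairs) * 3.5 + 2 * margin) / pixel_size_um)
      img_size <- max(img_size, need)
    }
    fov_um <- img_size * pixel_size_um
    kk0 <- pmax(stats::rnorm(n_pairs, preset["mean"], preset["sd"]), 0.3)
    # rejection-sample pair centers with a minimum mutual separation so
    # spots from different pairs stay resolvable
    min_sep <- 2.4
    cx <- cy <- numeric(n_pairs)
    for (i in seq_len(n_pairs)) {
      for (try in 1:200) {
        px <- stats::runif(1, margin, fov_um - margin)
        py <- stats::runif(1, margin, fov_um - margin)
        if (i == 1 || all((px - cx[seq_len(i - 1)])^2 +
                            (py - cy[seq_len(i - 1)])^2 > min_sep^2)) break
      }
      cx[i] <- px; cy[i] <- py
    }
    pars <- data.frame(
      pair = seq_len(n_pairs),
      cx = cx,
      cy = cy,
      angle = stats::rnorm(n_pairs, 0, 0.2),
      kk0 = kk0,
      phase_c = stats::runif(n_pairs, 0, 2 * pi),
      phase_b = stats::runif(n_pairs, 0, 2 * pi))
    t_s <- (seq_len(n_frames) - 1) * dt_s
    truth <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
      p <- pars[i, ]
      ux <- cos(p$angle); uy <- sin(p$angle)
      disp <- osc_amp_um * sin(2 * pi * t_s / osc_period_s + p$phase_c)
      kk <- pmax(p$kk0 + breath_amp_um *
                   sin(2 * pi * t_s / breath_period_s + p$phase_b), 0.3)
      cx <- p$cx + disp * ux + drift_um_per_frame[1] * (seq_len(n_frames) - 1)
      cy <- p$cy + disp * uy + drift_um_per_frame[2] * (seq_len(n_frames) - 1)
      data.frame(pair = p$pair, frame = rep(seq_len(n_frames), 2),
                 sister = rep(c("a", "b"), each = n_frames),
                 x_um = c(cx - kk / 2 * ux, cx + kk / 2 * ux),
                 y_um = c(cy - kk / 2 * uy, cy + kk / 2 * uy),
                 kk_um = rep(kk, 2))
    }))
    frames <- NULL
    if (render) {
      frames <- array(0, dim = c(img_size, img_size, n_frames))
      xs <- 0:(img_size - 1)
      for (fr in seq_len(n_frames)) {
        img <- matrix(bg_photons, img_size, img_size)
        sub <- truth[truth$frame == fr, ]
        for (r in seq_len(nrow(sub))) {
          x0 <- sub$x_um[r] / pixel_size_um
          y0 <- sub$y_um[r] / pixel_size_um
          gx <- exp(-0.5 * ((xs - x0) / psf_sigma_px)^2)
          gy <- exp(-0.5 * ((xs - y0) / psf_sigma_px)^2)
          img <- img + spot_photons / (2 * pi * psf_sigma_px^2) *
            outer(gy, gx)
        }
        img <- stats::rpois(length(img), img) +
          stats::rnorm(length(img), 0, read_noise_sd)
        frames[, , fr] <- matrix(pmax(img, 0), img_size, img_size)
      }
    }
    list(frames = frames, truth = truth, pairs = pars,
         condition = condition, pixel_size_um = pixel_size_um,
         dt_s = dt_s, img_size = img_size, seed = seed)
  })
}

#' Write a generated movie to a multi-page TIFF plus truth CSV
#'
#' @param movie result of [gen_movie()] with `render = TRUE`.
#' @param tiff_path,truth_path output paths.
#' @export
write_movie <- function(movie, tiff_path, truth_path = NULL) {
  if (is.null(movie$frames)) stop("movie has no rendered frames")
  imgs <- lapply(seq_len(dim(movie$frames)[3]), function(i) {
    m <- movie$frames[, , i]
    m / max(m)
  })
  tiff::writeTIFF(imgs, tiff_path, bits.per.sample = 16L)
  if (!is.null(truth_path))
    utils::write.csv(movie$truth, truth_path, row.names = FALSE)
  invisible(tiff_path)
}

#' Generate a synthetic (K-K distance, Aurora B, binding fraction) table
#'
#' Draws the tension-model observables: Aurora B concentration at NDC80 is a
#' linear function of K-K distance, and the binding fraction follows the
#' three-step activation/phosphorylation/binding model plus Gaussian noise.
#'
#' @param params a [tension_model_params()].
#' @param intensity_map list with `intercept` and `slope` (muM and muM/um) of
#'   the linear Aurora-B-concentration vs K-K-distance relation.
#' @param n number of rows.
#' @param noise_sd Gaussian noise SD added to the binding fraction.
#' @param dkk_range K-K distance range in micrometers.
#' @param seed integer seed.
#' @return data.frame `(dkk_um, A_um, f_bound)` with attribute `truth`.
#' @export
gen_tension_table <- function(params, intensity_map, n, noise_sd = 0,
                              dkk_range = c(0.7, 1.6), seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  dkk <- seq(dkk_range[1], dkk_range[2], length.out = n)
  A <- pmax(intensity_map$intercept + intensity_map$slope * dkk, 1e-6)
  fb <- binding_from_concentration(A, params)
  out <- with_seed(seed, data.frame(
    dkk_um = dkk, A_um = A,
    f_bound = fb + stats::rnorm(n, 0, noise_sd)))
  attr(out, "truth") <- list(params = params, intensity_map = intensity_map,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Generate a synthetic FCS autocorrelation curve
#'
#' @param model_kind "reference" (known concentration and diffusion, free
#'   geometry) or "brightness" (known geometry, free molecule number).
#' @param truth named list of generating parameters: for "reference",
#'   `V_eff_um3`, `w_xy_um`, `G_inf`, `C_molar`, `D_um2s` (and optionally
#'   `chi2`); for "brightness", `N`, `tau_diff_s`, `w_ratio2` (wxy^2/wz^2),
#'   `G_inf` (and optionally `chi2`).
#' @param lags positive increasing lag times in seconds.
#' @param noise_sd Gaussian noise SD added to G.
#' @param seed integer seed.
#' @return an [fcs_curve()] with attribute `truth`.
#' @export
gen_fcs_curve <- function(model_kind = c("reference", "brightness"), truth,
                          lags, noise_sd = 0, seed = 1L) {
  model_kind <- match.arg(model_kind)
  if (any(lags <= 0) || any(diff(lags) <= 0))
    stop("lags must be positive and increasing")
  g <- if (model_kind == "reference") {
    fcs_reference_model(lags, truth$V_eff_um3, truth$w_xy_um, truth$G_inf,
                        truth$C_molar, truth$D_um2s, truth$chi2 %||% 1)
  } else {
    fcs_brightness_model(lags, truth$N, truth$tau_diff_s, truth$w_ratio2,
                         truth$G_inf, truth$chi2 %||% 1)
  }
  g <- with_seed(seed, g + stats::rnorm(length(g), 0, noise_sd))
  curve <- fcs_curve(lags, g, count_rate = truth$count_rate %||% NA_real_,
                     background_rate = truth$background_rate %||% 0)
  attr(curve, "truth") <- c(truth, list(model_kind = model_kind, seed = seed))
  curve
}

#' Generate a synthetic exponential drug-response time course
#'
#' Rising: `y = A (1 - exp(-I(t>=0) t / tau)) + c` (e.g. NDC80 FRET fraction
#' after Aurora B inhibition). Decaying: `y = A exp(-I(t>=0) t / tau) + c`
#' (e.g. Aurora B sensor). The indicator switches the response on at t = 0.
#'
#' @param kind "rising" or "decaying".
#' @param A,tau,c model parameters (tau in minutes, > 0).
#' @param t_range time points in minutes (should include t < 0 baselines).
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @return data.frame `(t_min, y)` with attribute `truth`.
#' @export
gen_timecourse <- function(kind = c("rising", "decaying"), A, tau, c,
                           t_range, noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  stop_if_not_scalar_pos(tau, "tau")
  y <- exp_timecourse_model(kind, t_range, A, tau, c)
  out <- with_seed(seed, data.frame(
    t_min = t_range, y = y + stats::rnorm(length(y), 0, noise_sd)))
  attr(out, "truth") <- list(kind = kind, A = A, tau = tau, c = c,
                             noise_sd = noise_sd, seed = seed)
  out
}
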
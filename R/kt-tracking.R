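# Kinetochore spot detection, frame-to-frame linking, drift correction,
# sister pairing, velocity estimation, classification, and grouped
# statistics.
#
# Coordinate convention: 0-based pixel coordinates with pixel centers at
# integers, so the pixel in image row i, column j (1-based R indexing) is
# centered at (x, y) = (j - 1, i - 1). Physical scale is set by the pixel
# size in micrometers.

#' Detect spots by local maxima and intensity-weighted centroids
#'
#' Finds local maxima above `threshold` and refines each to sub-pixel
#' accuracy by the intensity-weighted centroid (above the local minimum) in a
#' square window.
#'
#' @param image numeric matrix (one frame).
#' @param threshold intensity threshold for candidate maxima (a.u.).
#' @param window odd window side in pixels for the centroid (default 7).
#' @return data.frame with `x`, `y` (sub-pixel, 0-based) and `intensity`.
#' @export
detect_spots <- function(image, threshold, window = 7L) {
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  half <- window %/% 2L
  is_max <- image >= threshold
  # strict local maximum over the 8-neighborhood
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- matrix(-Inf, h, w)
    ri <- max(1, 1 + di):min(h, h + di)
    rj <- max(1, 1 + dj):min(w, w + dj)
    shifted[ri, rj] <- image[ri - di, rj - dj]
    is_max <- is_max & (image > shifted | (image == shifted & (di < 0 | (di == 0 & dj < 0))))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0)))
  out <- lapply(seq_len(nrow(idx)), function(k) {
    i0 <- idx[k, 1]; j0 <- idx[k, 2]
    ri <- max(1, i0 - half):min(h, i0 + half)
    rj <- max(1, j0 - half):min(w, j0 + half)
    patch <- image[ri, rj, drop = FALSE]
    wgt <- pmax(patch - min(patch), 0)
    s <- sum(wgt)
    if (s == 0) {
      cx <- j0 - 1; cy <- i0 - 1
    } else {
      cy <- sum(rowSums(wgt) * (ri - 1)) / s
      cx <- sum(colSums(wgt) * (rj - 1)) / s
    }
    data.frame(x = cx, y = cy, intensity = sum(patch))
  })
  do.call(rbind, out)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbor assignment between consecutive frames with a
#' displacement gate; unmatched detections seed new tracks, and tracks
#' missing for a single frame are bridged.
#'
#' @param detections list of data.frames (one per frame) as returned by
#'   [detect_spots()].
#' @param max_disp maximum frame-to-frame displacement (same units as the
#'   coordinates).
#' @return data.frame with `track`, `frame`, `x`, `y`, `intensity`.
#' @export
link_tracks <- function(detections, max_disp) {
  if (length(detections) < 2L) stop("need at least 2 frames")
  next_id <- 0L
  active <- data.frame(track = integer(0), x = numeric(0), y = numeric(0),
                       last_frame = integer(0))
  rows <- list()
  for (fr in seq_along(detections)) {
    det <- detections[[fr]]
    assigned_det <- rep(FALSE, nrow(det))
    assigned_trk <- rep(FALSE, nrow(active))
    if (nrow(det) > 0 && nrow(active) > 0) {
      # allow a single-frame gap when re-acquiring a track
      eligible <- active$last_frame >= fr - 2L
      D <- outer(active$x, det$x, `-`)^2 + outer(active$y, det$y, `-`)^2
      D[!eligible, ] <- Inf
      repeat {
        m <- which.min(D)
        if (!length(m) || !is.finite(D[m]) || D[m] > max_disp^2) break
        ti <- (m - 1) %% nrow(D) + 1
        dj <- (m - 1) %/% nrow(D) + 1
        assigned_trk[ti] <- TRUE; assigned_det[dj] <- TRUE
        rows[[length(rows) + 1L]] <-
          data.frame(track = active$track[ti], frame = fr,
                     x = det$x[dj], y = det$y[dj],
                     intensity = det$intensity[dj])
        active$x[ti] <- det$x[dj]; active$y[ti] <- det$y[dj]
        active$last_frame[ti] <- fr
        D[ti, ] <- Inf; D[, dj] <- Inf
      }
    }
    if (any(!assigned_det)) {
      for (dj in which(!assigned_det)) {
        next_id <- next_id + 1L
        rows[[length(rows) + 1L]] <-
          data.frame(track = next_id, frame = fr, x = det$x[dj],
                     y = det$y[dj], intensity = det$intensity[dj])
        active <- rbind(active,
                        data.frame(track = next_id, x = det$x[dj],
                                   y = det$y[dj], last_frame = fr))
      }
    }
    active <- active[active$last_frame >= fr - 1L, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  out[order(out$track, out$frame), ]
}

#' Estimate global stage drift by frame-to-frame cross-correlation
#'
#' Maximizes the (FFT) cross-correlation between consecutive frames with
#' sub-pixel quadratic peak interpolation, and accumulates offsets relative
#' to the first frame. A normalized correlation peak below `min_corr` yields
#' a zero offset with a warning.
#'
#' @param frames 3D array (h x w x n_frames).
#' @param min_corr minimum normalized correlation (default 0.3).
#' @return data.frame with `frame`, `dx`, `dy` (cumulative offsets, px).
#' @export
correct_drift <- function(frames, min_corr = 0.3) {
  nf <- dim(frames)[3]
  if (is.na(nf) || nf < 2L) stop("need at least 2 frames")
  offs <- matrix(0, nf, 2)
  for (fr in 2:nf) {
    a <- frames[, , fr - 1]; b <- frames[, , fr]
    a <- a - mean(a); b <- b - mean(b)
    cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b),
                        inverse = TRUE)) / length(a)
    norm <- sqrt(sum(a^2) * sum(b^2))
    peak <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) / norm < min_corr) {
      warning(sprintf("low correlation between frames %d and %d; zero offset",
                      fr - 1, fr))
      offs[fr, ] <- offs[fr - 1, ]
      next
    }
    sub <- function(ix, n) {
      # quadratic interpolation around the peak along one axis (circular)
      i0 <- ix
      im <- (i0 - 2) %% n + 1; ip <- i0 %% n + 1
      y1 <- cc_axis[im]; y2 <- cc_axis[i0]; y3 <- cc_axis[ip]
      denom <- y1 - 2 * y2 + y3
      if (denom == 0) 0 else 0.5 * (y1 - y3) / denom
    }
    cc_axis <- cc[, peak[2]]
    di <- (peak[1] - 1) + sub(peak[1], nrow(cc))
    cc_axis <- cc[peak[1], ]
    dj <- (peak[2] - 1) + sub(peak[2], ncol(cc))
    if (di > nrow(cc) / 2) di <- di - nrow(cc)
    if (dj > ncol(cc) / 2) dj <- dj - ncol(cc)
    offs[fr, ] <- offs[fr - 1, ] + c(dj, di)  # (dx, dy) in (col, row) order
  }
  data.frame(frame = seq_len(nf), dx = offs[, 1], dy = offs[, 2])
}

#' Five-point central-difference velocity
#'
#' `v(t) = (-x(t+2) + 8 x(t+1) - 8 x(t-1) + x(t-2)) / (12 dt)`, exact for
#' polynomials up to degree four. Positions without a full two-frame margin
#' are reported as `NA`.
#'
#' @param x positions at consecutive equally spaced frames.
#' @param dt frame interval.
#' @return numeric vector of velocities, same length as `x`.
#' @export
five_point_velocity <- function(x, dt) {
  n <- length(x)
  if (n < 5L) stop("need at least 5 consecutive positions")
  v <- rep(NA_real_, n)
  i <- 3:(n - 2)
  v[i] <- (-x[i + 2] + 8 * x[i + 1] - 8 * x[i - 1] + x[i - 2]) / (12 * dt)
  v
}

track_displacements <- function(tr, frames) {
  # per-frame displacement vectors on the given frame set (NA where absent)
  m <- match(frames, tr$frame)
  dx <- diff(tr$x[m]); dy <- diff(tr$y[m])
  cbind(dx, dy)
}

#' Pair sister kinetochores
#'
#' Candidate pairs must share at least `min_covisible` frames, have mean
#' separation within `dist_range`, and frame-to-frame velocity correlation at
#' least `min_vel_corr` (sisters move coherently with the pair center).
#' Conflicts are resolved greedily by best correlation; each track joins at
#' most one pair.
#'
#' @param tracks data.frame from [link_tracks()] with coordinates in um.
#' @param dist_range allowed mean separation interval, um.
#' @param min_vel_corr minimum velocity correlation in \[-1, 1\].
#' @param min_covisible minimum number of shared frames.
#' @param max_dist_sd maximum SD of the separation, um; sister separation is
#'   tension-constrained and fluctuates far less than the distance between
#'   unrelated kinetochores.
#' @return list with `pairs` (track_a, track_b, vel_corr, mean_dist),
#'   `kk` (per-frame pair table: pair, frame, kk_um, positions), and
#'   `unpaired` track ids.
#' @export
pair_sisters <- function(tracks, dist_range = c(0.5, 2.5),
                         min_vel_corr = 0.5, min_covisible = 5L,
                         max_dist_sd = 0.35) {
  ids <- unique(tracks$track)
  by_id <- split(tracks, tracks$track)
  cand <- list()
  if (length(ids) >= 2) {
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (b <= a) next
      ta <- by_id[[as.character(ids[a])]]
      tb <- by_id[[as.character(ids[b])]]
      co <- intersect(ta$frame, tb$frame)
      if (length(co) < min_covisible) next
      ma <- match(co, ta$frame); mb <- match(co, tb$frame)
      d <- sqrt((ta$x[ma] - tb$x[mb])^2 + (ta$y[ma] - tb$y[mb])^2)
      if (mean(d) < dist_range[1] || mean(d) > dist_range[2]) next
      if (stats::sd(d) > max_dist_sd) next
      va <- track_displacements(ta, co)
      vb <- track_displacements(tb, co)
      ok <- stats::complete.cases(va) & stats::complete.cases(vb)
      if (sum(ok) < 3) next
      vc <- suppressWarnings(stats::cor(as.vector(va[ok, ]),
                                        as.vector(vb[ok, ])))
      if (is.na(vc) || vc < min_vel_corr) next
      cand[[length(cand) + 1L]] <-
        data.frame(track_a = ids[a], track_b = ids[b], vel_corr = vc,
                   mean_dist = mean(d))
    }
  }
  if (length(cand) == 0L)
    return(list(pairs = data.frame(track_a = integer(0),
                                   track_b = integer(0),
                                   vel_corr = numeric(0),
                                   mean_dist = numeric(0)),
                kk = NULL, unpaired = ids))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$vel_corr), ]
  used <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$track_a[i] %in% used || cand$track_b[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, cand$track_a[i], cand$track_b[i])
  }
  pairs <- cand[keep, , drop = FALSE]
  pairs$pair <- seq_len(nrow(pairs))
  kk <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ta <- by_id[[as.character(pairs$track_a[i])]]
    tb <- by_id[[as.character(pairs$track_b[i])]]
    co <- sort(intersect(ta$frame, tb$frame))
    ma <- match(co, ta$frame); mb <- match(co, tb$frame)
    data.frame(pair = pairs$pair[i], frame = co,
               xa = ta$x[ma], ya = ta$y[ma], xb = tb$x[mb], yb = tb$y[mb],
               kk_um = sqrt((ta$x[ma] - tb$x[mb])^2 +
                              (ta$y[ma] - tb$y[mb])^2))
  }))
  list(pairs = pairs, kk = kk, unpaired = setdiff(ids, used))
}

#' Classify sister-pair frames
#'
#' Adds per-frame labels to a pair table from [pair_sisters()]:
#' leading/trailing (which sister is in front of the pair-center motion along
#' the pair axis), centered/mid/off_centered (distance from the metaphase
#' plate, thresholds 1 and 2.5 um), and poleward/anti_poleward (which sister
#' is nearer the spindle pole, for monopolar spindles).
#'
#' @param kk per-frame pair table (one pair) from [pair_sisters()].
#' @param dt_s frame interval in seconds.
#' @param poles optional 2x2 matrix of spindle-pole positions (rows), um;
#'   the metaphase plate is the perpendicular bisector plane.
#' @param pole optional length-2 pole position for monopolar spindles, um.
#' @return the input with columns `leading` ("a"/"b"/NA), `plate_a`,
#'   `plate_b` (centered/mid/off_centered), `poleward` ("a"/"b").
#' @export
classify_pair <- function(kk, dt_s = 13, poles = NULL, pole = NULL) {
  stopifnot(length(unique(kk$pair)) == 1L)
  n <- nrow(kk)
  cx <- (kk$xa + kk$xb) / 2; cy <- (kk$ya + kk$yb) / 2
  ux <- kk$xb - kk$xa; uy <- kk$yb - kk$ya
  nrm <- sqrt(ux^2 + uy^2); ux <- ux / nrm; uy <- uy / nrm
  if (n >= 5) {
    vx <- five_point_velocity(cx, dt_s)
    vy <- five_point_velocity(cy, dt_s)
    proj <- vx * ux + vy * uy
    kk$leading <- ifelse(is.na(proj), NA,
                         ifelse(proj > 0, "b", ifelse(proj < 0, "a", NA)))
  } else kk$leading <- NA_character_
  if (!is.null(poles)) {
    mid <- colMeans(poles)
    axis <- poles[2, ] - poles[1, ]
    axis <- axis / sqrt(sum(axis^2))
    plate_dist <- function(x, y)
      abs((x - mid[1]) * axis[1] + (y - mid[2]) * axis[2])
    lab <- function(d) ifelse(d < 1, "centered",
                              ifelse(d > 2.5, "off_centered", "mid"))
    kk$plate_a <- lab(plate_dist(kk$xa, kk$ya))
    kk$plate_b <- lab(plate_dist(kk$xb, kk$yb))
  }
  if (!is.null(pole)) {
    da <- sqrt((kk$xa - pole[1])^2 + (kk$ya - pole[2])^2)
    db <- sqrt((kk$xb - pole[1])^2 + (kk$yb - pole[2])^2)
    kk$poleward <- ifelse(da <= db, "a", "b")
  }
  kk
}

#' Group observations by quantile bins of a variable
#'
#' Equal-count quantile bins with per-group mean, SEM and interquartile
#' range of the grouping variable; optionally combines per-row FLIM
#' posteriors within each group via [combine_posteriors()].
#'
#' @param data data.frame of observations.
#' @param variable column name to group on.
#' @param n_groups number of quantile bins.
#' @param value optional column to summarize alongside the grouping variable.
#' @param posteriors optional list of `posterior_grid`s aligned with rows.
#' @return data.frame of per-group summaries (and combined FRET estimates
#'   when posteriors are given).
#' @export
group_stats <- function(data, variable, n_groups, value = NULL,
                        posteriors = NULL) {
  n <- nrow(data)
  if (n_groups < 1) stop("n_groups must be >= 1")
  if (n < n_groups) stop("fewer observations than groups")
  v <- data[[variable]]
  rk <- rank(v, ties.method = "first")
  bin <- ceiling(rk * n_groups / n)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    row <- data.frame(group = b, n = sum(sel),
                      mean = mean(v[sel]),
                      sem = stats::sd(v[sel]) / sqrt(sum(sel)),
                      iqr_lo = stats::quantile(v[sel], 0.25, names = FALSE),
                      iqr_hi = stats::quantile(v[sel], 0.75, names = FALSE))
    if (!is.null(value)) {
      row$value_mean <- mean(data[[value]][sel])
      row$value_sem <- stats::sd(data[[value]][sel]) / sqrt(sum(sel))
    }
    if (!is.null(posteriors)) {
      est <- combine_posteriors(posteriors[sel])
      row$f_FRET <- est$mean_f_FRET
      row$f_FRET_sem <- est$sem
    }
    row
  }))
  out
}
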
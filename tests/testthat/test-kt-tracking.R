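# Spot detection, linking, drift correction, sister pairing, velocities,
# classification, and grouped statistics.

test_that("detection returns nothing on blank images and finds clean spots", {
  expect_equal(nrow(detect_spots(matrix(0, 32, 32), threshold = 1)), 0L)
  xs <- 0:23
  img <- 100 * exp(-0.5 * ((outer(rep(1, 24), xs) - 10.30)^2 +
                             (outer(xs, rep(1, 24)) - 7.60)^2) / 1.3^2)
  d <- detect_spots(img, threshold = 10)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$x - 10.30), 0.1)
  expect_lt(abs(d$y - 7.60), 0.1)
  img2 <- img + 100 * exp(-0.5 * ((outer(rep(1, 24), xs) - 10.30)^2 +
                                    (outer(xs, rep(1, 24)) - 17.60)^2) / 1.3^2)
  expect_equal(nrow(detect_spots(img2, threshold = 10)), 2L)
})

test_that("static spots yield one zero-displacement track each", {
  det <- data.frame(x = c(3, 10), y = c(5, 5), intensity = 1)
  tracks <- link_tracks(rep(list(det), 4), max_disp = 1)
  expect_equal(length(unique(tracks$track)), 2L)
  for (id in unique(tracks$track)) {
    sub <- tracks[tracks$track == id, ]
    expect_equal(nrow(sub), 4L)
    expect_equal(diff(range(sub$x)), 0)
  }
})

test_that("the gate prevents identity swaps between parallel movers", {
  frames <- lapply(0:5, function(t)
    data.frame(x = c(0 + 0.3 * t, 0 + 0.3 * t), y = c(0, 3), intensity = 1))
  tracks <- link_tracks(frames, max_disp = 1)
  expect_equal(length(unique(tracks$track)), 2L)
  ys <- tapply(tracks$y, tracks$track, function(v) diff(range(v)))
  expect_true(all(ys == 0))  # no track jumps between the two lines
})

test_that("a single-frame disappearance is bridged into one track", {
  det <- data.frame(x = 5, y = 5, intensity = 1)
  frames <- list(det, det, det[0, ], det, det)
  tracks <- link_tracks(frames, max_disp = 1)
  expect_equal(length(unique(tracks$track)), 1L)
  expect_equal(sort(tracks$frame), c(1, 2, 4, 5))
})

test_that("drift correction recovers known shifts and flags pure noise", {
  base <- matrix(stats::rnorm(64 * 64), 64, 64)
  for (i in 1:3)  # smooth so the correlation peak is well-formed
    base <- (base + base[c(2:64, 1), ] + base[c(64, 1:63), ] +
               base[, c(2:64, 1)] + base[, c(64, 1:63)]) / 5
  frames <- array(0, dim = c(64, 64, 2))
  frames[, , 1] <- base
  frames[, , 2] <- base[c(62:64, 1:61), c(60:64, 1:59)]  # shift (+3, +5)
  dr <- correct_drift(frames)
  expect_lt(abs(dr$dx[2] - 5), 0.5)
  expect_lt(abs(dr$dy[2] - 3), 0.5)
  same <- array(rep(base, 2), dim = c(64, 64, 2))
  dr0 <- correct_drift(same)
  expect_equal(dr0$dx[2], 0, tolerance = 1e-6)
  expect_equal(dr0$dy[2], 0, tolerance = 1e-6)
  noise <- array(stats::rnorm(64 * 64 * 2), dim = c(64, 64, 2))
  expect_warning(drn <- correct_drift(noise), "low correlation")
  expect_equal(drn$dx[2], 0)
})

test_that("five-point velocities are exact for polynomials up to degree 4", {
  t <- -2:8
  expect_equal(five_point_velocity(3 * t, dt = 1)[3:9], rep(3, 7))
  v3 <- five_point_velocity(t^3, dt = 1)
  expect_equal(v3[which(t == 1)], 3)
  t4 <- -5:5
  v4 <- five_point_velocity(t4^4, dt = 1)
  expect_equal(v4[which(t4 == 0)], 0)
  k <- 0:10
  for (deg in 0:4) {
    tt <- 0.5 * k  # samples every dt = 0.5
    v <- five_point_velocity(tt^deg, dt = 0.5)
    truth <- if (deg == 0) rep(0, length(k)) else deg * tt^(deg - 1)
    expect_equal(v[3:9], truth[3:9], tolerance = 1e-12)
  }
  expect_error(five_point_velocity(1:4, 1), "at least 5")
})

test_that("tracking and pairing recover the simulated sisters", {
  correct <- reported <- 0
  errs <- c(); swaps <- c()
  for (s in c(41, 42, 44)) {
    mv <- gen_movie(n_pairs = 6, n_frames = 25, seed = s,
                    spot_photons = 2000)
    tm <- track_movie(mv)
    pr <- pair_sisters(tm$tracks)
    acc <- pairing_accuracy(mv, tm$tracks, pr$pairs)
    correct <- correct + acc["correct"]; reported <- reported + acc["reported"]
    swaps <- c(swaps, swap_rate(mv, tm$tracks))
    err <- unlist(lapply(seq_len(25), function(fr) {
      d <- tm$detections[[fr]]
      tt <- mv$truth[mv$truth$frame == fr, ]
      vapply(seq_len(nrow(tt)), function(k)
        min(sqrt((d$x - tt$x_um[k])^2 + (d$y - tt$y_um[k])^2)), numeric(1))
    }))
    errs <- c(errs, err / mv$pixel_size_um)
    # a track never appears in two pairs
    expect_equal(anyDuplicated(c(pr$pairs$track_a, pr$pairs$track_b)), 0L)
  }
  expect_gte(correct / reported, 0.9)
  expect_lt(mean(errs), 0.2)
  expect_lt(mean(swaps), 0.02)
})

test_that("distant tracks stay unpaired under the distance gate", {
  mk <- function(x0) data.frame(track = NA, frame = 1:10,
                                x = x0 + 0.01 * sin(1:10), y = 0,
                                intensity = 1)
  a <- mk(0); a$track <- 1L
  b <- mk(10); b$track <- 2L
  pr <- pair_sisters(rbind(a, b))
  expect_equal(nrow(pr$pairs), 0L)
  expect_setequal(pr$unpaired, c(1L, 2L))
})

test_that("pairing is symmetric in track order", {
  mv <- gen_movie(n_pairs = 3, n_frames = 20, seed = 50, render = FALSE)
  tr <- mv$truth
  tracks <- data.frame(
    track = as.integer(interaction(tr$pair, tr$sister)),
    frame = tr$frame, x = tr$x_um, y = tr$y_um, intensity = 1)
  p1 <- pair_sisters(tracks)
  rev_tracks <- tracks
  rev_tracks$track <- max(tracks$track) + 1L - tracks$track
  p2 <- pair_sisters(rev_tracks)
  expect_equal(nrow(p1$pairs), nrow(p2$pairs))
  key <- function(p, tracks_df) sort(apply(p$pairs, 1, function(r)
    paste(sort(c(r[["track_a"]], r[["track_b"]])), collapse = "-")))
  expect_equal(length(key(p1)), length(key(p2)))
})

test_that("classification labels leading sisters, plate zones, and poleward sisters", {
  # pair translating left with the left sister (a) in front
  n <- 9
  kk <- data.frame(pair = 1, frame = 1:n,
                   xa = 10 - 0.2 * (1:n), ya = 0,
                   xb = 11 - 0.2 * (1:n), yb = 0,
                   kk_um = 1)
  out <- classify_pair(kk, dt_s = 1)
  expect_true(all(out$leading[3:(n - 2)] == "a"))
  # plate thresholds at 1 and 2.5 um from the midplane of the poles
  poles <- rbind(c(-5, 0), c(5, 0))
  mkpair <- function(x) data.frame(pair = 1, frame = 1, xa = x, ya = 0,
                                   xb = x, yb = 1, kk_um = 1)
  expect_equal(classify_pair(mkpair(0.5), poles = poles)$plate_a, "centered")
  expect_equal(classify_pair(mkpair(3.0), poles = poles)$plate_a,
               "off_centered")
  expect_equal(classify_pair(mkpair(1.5), poles = poles)$plate_a, "mid")
  # monopolar: the sister nearer the pole is poleward
  mono <- classify_pair(mkpair(2), pole = c(0, 0))
  expect_equal(mono$poleward, "a")
})

test_that("grouping uses equal-count quantile bins with ordered means", {
  d <- data.frame(v = rep(1, 10))
  g <- group_stats(d, "v", 1)
  expect_equal(nrow(g), 1L)
  expect_equal(g$sem, 0)
  d2 <- data.frame(v = seq_len(40))
  g2 <- group_stats(d2, "v", 4)
  expect_true(all(abs(g2$n - 10) <= 1))
  expect_true(all(diff(g2$mean) > 0))
  expect_error(group_stats(data.frame(v = 1:2), "v", 5), "fewer")
})
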
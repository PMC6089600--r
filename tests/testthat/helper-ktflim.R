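# Shared fixtures: run the detection/linking/pairing chain on a generated
# movie and map tracks back to ground-truth identities.

robust_threshold <- function(img) stats::median(img) + 8 * stats::mad(img)

track_movie <- function(movie, max_disp = 0.5) {
  nf <- dim(movie$frames)[3]
  dets <- lapply(seq_len(nf), function(i) {
    d <- detect_spots(movie$frames[, , i],
                      threshold = robust_threshold(movie$frames[, , i]),
                      window = 7)
    d$x <- d$x * movie$pixel_size_um
    d$y <- d$y * movie$pixel_size_um
    d
  })
  list(detections = dets, tracks = link_tracks(dets, max_disp = max_disp))
}

# truth identity ("pair sister") of the nearest true kinetochore for one
# track row
truth_identity <- function(movie, frame, x, y) {
  tt <- movie$truth[movie$truth$frame == frame, ]
  k <- which.min((tt$x_um - x)^2 + (tt$y_um - y)^2)
  paste(tt$pair[k], tt$sister[k])
}

track_truth_pairs <- function(movie, tracks, id) {
  sub <- tracks[tracks$track == id, ]
  vapply(seq_len(nrow(sub)), function(r)
    truth_identity(movie, sub$frame[r], sub$x[r], sub$y[r]), character(1))
}

# identity-swap rate: fraction of frame-to-frame links whose mapped truth
# identity changes
swap_rate <- function(movie, tracks) {
  swaps <- 0L; links <- 0L
  for (id in unique(tracks$track)) {
    ids <- track_truth_pairs(movie, tracks, id)
    if (length(ids) < 2) next
    swaps <- swaps + sum(ids[-1] != ids[-length(ids)])
    links <- links + length(ids) - 1L
  }
  if (links == 0L) return(0)
  swaps / links
}

pairing_accuracy <- function(movie, tracks, pairs) {
  if (nrow(pairs) == 0L) return(c(correct = 0L, reported = 0L))
  first_pair <- function(id) {
    sub <- tracks[tracks$track == id, ][1, ]
    tt <- movie$truth[movie$truth$frame == sub$frame, ]
    tt$pair[which.min((tt$x_um - sub$x)^2 + (tt$y_um - sub$y)^2)]
  }
  ok <- vapply(seq_len(nrow(pairs)), function(i)
    first_pair(pairs$track_a[i]) == first_pair(pairs$track_b[i]), logical(1))
  c(correct = sum(ok), reported = nrow(pairs))
}
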
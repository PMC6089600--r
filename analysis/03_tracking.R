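#!/usr/bin/env Rscript
# Track the simulated movie: detect spots, link tracks, pair sisters,
# classify leading/trailing, and summarize K-K distances.

library(ktflim)
frames_list <- tiff::readTIFF("results/movie.tif", all = TRUE)
frames <- simplify2array(frames_list)
truth <- read.csv("results/movie_truth.csv")
pixel_size <- 0.107

dets <- lapply(seq_len(dim(frames)[3]), function(i) {
  img <- frames[, , i]
  d <- detect_spots(img, threshold = median(img) + 8 * mad(img), window = 7)
  d$x <- d$x * pixel_size; d$y <- d$y * pixel_size
  d
})
tracks <- link_tracks(dets, max_disp = 0.5)
write.csv(tracks, "results/tracks.csv", row.names = FALSE)
pairing <- pair_sisters(tracks)
write.csv(pairing$kk, "results/pairs_kk.csv", row.names = FALSE)

lab <- do.call(rbind, lapply(split(pairing$kk, pairing$kk$pair),
                             classify_pair, dt_s = 13))
write.csv(lab, "results/pairs_classified.csv", row.names = FALSE)

kk_mean <- mean(pairing$kk$kk_um)
cat(sprintf(
  "%d tracks, %d sister pairs; mean K-K distance %.2f um (generator: untreated 1.19 +/- 0.19).\n",
  length(unique(tracks$track)), nrow(pairing$pairs), kk_mean))
cat(sprintf("Leading-sister labels assigned on %d of %d pair-frames.\n",
            sum(!is.na(lab$leading)), nrow(lab)))
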
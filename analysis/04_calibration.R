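#!/usr/bin/env Rscript
# Geometric Monte Carlo calibration: the slope relating measured FRET
# fraction to true NDC80 binding fraction, and FRET detectability vs
# NDC80-microtubule distance.

library(ktflim)
geom <- lattice_geometry()

cal <- calibrate_slope(geom, f_label = 0.261, R0 = 5.90, reps = 30L,
                       seed = 20260104L)
write.csv(cal$per_fb, "results/calibration_points.csv", row.names = FALSE)
write.csv(data.frame(slope = cal$slope, ci_lo = cal$ci95[1],
                     ci_hi = cal$ci95[2]),
          "results/calibration_slope.csv", row.names = FALSE)

det <- detectability_vs_distance(geom, stand_offs = c(0, 4, 8, 12, 15),
                                 reps = 10L, seed = 20260105L)
write.csv(det, "results/detectability.csv", row.names = FALSE)

cat(sprintf(
  "Calibration slope %.3f (bootstrap 95%% CI %.3f-%.3f) with this coarse-grained geometry;\n",
  cal$slope, cal$ci95[1], cal$ci95[2]))
cat("the reference atomistic calibration gives 0.42 +/- 0.08 — see the methods vignette\n")
cat("for why the lattice stand-in runs slightly high.\n")
cat(sprintf("FRET detectability (mean dBIC) drops from %.0f at contact to %.0f at 15 nm.\n",
            det$mean_delta_bic[1], det$mean_delta_bic[nrow(det)]))
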
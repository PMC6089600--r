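#!/usr/bin/env Rscript
# Generate the synthetic datasets used throughout the analysis: a
# no-acceptor control decay, a set of per-kinetochore mixture decays, a
# sister-pair movie, a tension-model table, FCS curves, and drug-response
# time courses. Everything carries its ground truth.

library(ktflim)
dir.create("results", showWarnings = FALSE)
seed <- 20260101L

# TCSPC decays: donor-only control (3.75 ns) and a FlAsH-labeled mixture
# (3.71 / 0.75 ns, FRET fraction 0.13), a few hundred photons per
# kinetochore as in the FLIM movies, 1e5 for aggregates
ctrl <- gen_decay(decay_model("single", tau_D = 3.75, noise_A = 1),
                  config = sim_config(seed = seed, photons_per_decay = 1e5))
write_decay_csv(ctrl, "results/decay_control.csv")
mix <- decay_model("double", tau_D = 3.71, tau_FRET = 0.75, f_FRET = 0.13,
                   noise_A = 1)
agg <- gen_decay(mix, config = sim_config(seed = seed + 1,
                                          photons_per_decay = 1e5))
write_decay_csv(agg, "results/decay_aggregate.csv")

# sister-kinetochore movie (untreated K-K distribution)
mv <- gen_movie(n_pairs = 6, n_frames = 25, condition = "untreated",
                spot_photons = 2000, seed = seed)
write_movie(mv, "results/movie.tif", "results/movie_truth.csv")

# tension-model table at the fitted parameters, with a linear Aurora-B vs
# K-K relation
tb <- gen_tension_table(tension_model_params(),
                        list(intercept = 14, slope = -8), n = 11,
                        noise_sd = 0.005, dkk_range = c(0.25, 1.625),
                        seed = seed)
write.csv(tb, "results/tension_table.csv", row.names = FALSE)

# FCS curves: calibration dye (known C, D) and labeled peptide
lags <- 10^seq(-6, 0, length.out = 80)
ref <- gen_fcs_curve("reference",
                     list(V_eff_um3 = 0.364, w_xy_um = 0.278, G_inf = 0.001,
                          C_molar = 97e-9, D_um2s = 435), lags,
                     noise_sd = 2e-4, seed = seed)
write_fcs_csv(ref, "results/fcs_reference.csv")

# drug-response time courses at the reference fit values
tc_up <- gen_timecourse("rising", 0.088, 3.26, 0.089,
                        seq(-5, 20, by = 0.5), 0.01, seed = seed)
write.csv(tc_up, "results/timecourse_binding.csv", row.names = FALSE)
tc_dn <- gen_timecourse("decaying", 0.17, 1.95, 0.37,
                        seq(-5, 15, by = 0.5), 0.01, seed = seed + 2)
write.csv(tc_dn, "results/timecourse_sensor.csv", row.names = FALSE)

cat("Simulated: control + aggregate decays, a", mv$img_size, "px movie with",
    length(unique(mv$truth$pair)), "sister pairs,",
    "a tension table, FCS curves, and two time courses under results/.\n")
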
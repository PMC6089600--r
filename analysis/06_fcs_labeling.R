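#!/usr/bin/env Rscript
# FCS calibration and the labeling-fraction chain: focal volume from the
# reference dye, molecular brightness of the labeled peptide, and the
# fraction of labeled beta-tubulin from the reference measurement rates.

library(ktflim)
ref_curve <- read_fcs_csv("results/fcs_reference.csv")
geo <- fit_reference_fcs(ref_curve, known_C = 97e-9, known_D = 435)

lags <- 10^seq(-6, 0, length.out = 80)
pep <- gen_fcs_curve("brightness",
                     list(N = 20, tau_diff_s = 2e-4,
                          w_ratio2 = (geo$w_xy_nm / geo$w_z_nm)^2,
                          G_inf = 5e-4, count_rate = 4668,
                          background_rate = 0),
                     lags, noise_sd = 2e-4, seed = 20260107L)
br <- fit_brightness_fcs(pep, geo)

conc <- concentration_from_rate(9.6e4, br$brightness_s1, geo$V_eff_um3)
chain <- labeling_fraction(conc, polymer_fraction = 36, total_tubulin = 20)

out <- data.frame(
  quantity = c("V_eff_um3", "w_xy_nm", "brightness_s1",
               "conc_polymer_labeled_uM", "conc_total_labeled_uM",
               "labeled_fraction_pct"),
  value = c(geo$V_eff_um3, geo$w_xy_nm, br$brightness_s1, conc,
            chain$conc_total_labeled, chain$fraction))
write.csv(out, "results/labeling_chain.csv", row.names = FALSE)

cat(sprintf("Focal volume %.3f um^3, w_xy %.0f nm (generator: 0.364, 278).\n",
            geo$V_eff_um3, geo$w_xy_nm))
cat(sprintf(
  "Brightness %.1f s^-1 -> polymer-bound labeled tubulin %.2f uM -> total %.2f uM -> %.1f%% of beta-tubulin labeled.\n",
  br$brightness_s1, conc, chain$conc_total_labeled, chain$fraction))
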
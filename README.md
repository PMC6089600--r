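# ktflim

Quantifying NDC80–microtubule binding in living cells from FLIM-FRET data.

The NDC80 complex is the main coupler between kinetochores and spindle
microtubules (kMTs), and the fraction of NDC80 complexes bound to kMTs is
regulated by centromere tension through Aurora B kinase. `ktflim`
implements the quantitative machinery needed to measure and model that
regulation from time-correlated single-photon-counting (TCSPC)
fluorescence-lifetime (FLIM) data of an mTurquoise2-NDC80 donor and
FlAsH-labeled tubulin acceptors:

- **Bayesian decay inference** (`gen_decay`, `fit_mle`, `infer_posterior`,
  `combine_posteriors`). A photon-arrival histogram `y` is modeled by the
  IRF-convolved mixture
  `g(t) = (1 - f_FRET) exp(-t/tau_D) + f_FRET exp(-t/tau_FRET)` with a
  uniform background component; the posterior
  `p(theta | y) ∝ prod_i P_i(theta)^{y_i}` under a uniform prior is
  evaluated on a grid (<= 3 free parameters) or by
  Metropolis-within-Gibbs sampling. Posteriors from groups of kinetochores
  are multiplied and marginalized to estimate the group FRET fraction
  `f_FRET`.
- **FRET-to-binding calibration** (`lattice_geometry`, `sample_distances`,
  `mixed_lifetime`, `calibrate_slope`). A coarse-grained cylindrical-lattice
  model of the microtubule surface samples donor–acceptor distance vectors;
  donor lifetimes follow the multi-acceptor quenching law
  `tau(r) = tau_D / (1 + sum_labeled (R0/r_i)^6)` with Bernoulli site
  labeling. Simulated decays across binding fractions give the linear
  conversion `f_FRET = a * f_bound`; `fret_to_binding` inverts it with the
  measured slope a = 0.42.
- **Kinetochore tracking** (`detect_spots`, `link_tracks`, `correct_drift`,
  `pair_sisters`, `five_point_velocity`, `classify_pair`, `group_stats`):
  sub-pixel centroids, gated nearest-neighbor linking, FFT drift
  correction, sister pairing by separation and velocity correlation, and
  leading/trailing, plate-zone, and poleward classification.
- **The tension model** (`active_aurora`, `phos_fraction`,
  `binding_fraction`, `binding_from_concentration`, `fit_phos_binding`,
  `fit_conc_binding`, `ode_steady_state_oracle`). Aurora B autoactivation
  in trans gives a piecewise active concentration
  (`A* - K` below the threshold `A*`, `[A] - K` above); phosphorylation
  follows `f_phos = (1 + Kphos/[A_active])^-1`; binding follows
  `f_bound = (1 + K0 + K0' f_phos)^-1`. Closed forms are cross-checked
  against direct ODE integration.
- **FCS labeling-fraction pipeline** (`fit_reference_fcs`,
  `fit_brightness_fcs`, `concentration_from_rate`, `labeling_fraction`):
  focal-volume and molecular-brightness calibration and the arithmetic that
  yields the fraction of labeled beta-tubulin.
- **Synthetic data with ground truth** (`gen_decay`, `gen_movie`,
  `gen_tension_table`, `gen_fcs_curve`, `gen_timecourse`) so every stage is
  testable without external data, and a pipeline driver (`run_pipeline`)
  that chains simulation, lifetime fixing, per-kinetochore posteriors,
  K-K-distance grouping, and conversion to binding fractions.

## Worked example

```r
library(ktflim)

# simulate a FlAsH-labeled kinetochore decay at the measured lifetimes
cfg <- sim_config(seed = 7, photons_per_decay = 1e4)
h <- gen_decay(decay_model("double", tau_D = 3.71, tau_FRET = 0.75,
                           f_FRET = 0.13, noise_A = 1), config = cfg)

# infer the FRET fraction with both lifetimes fixed
post <- infer_posterior(h, decay_model("double", tau_D = 3.71,
                                       tau_FRET = 0.75,
                                       noise_A = NA_real_))
posterior_mean(post)           # 0.189
posterior_sd(post)             # 0.028
fret_to_binding(0.13)          # 0.3095 — i.e. 31% of NDC80 bound
```

The posterior mean (here 0.189 +/- 0.028 for a single 10^4-photon decay
generated at 0.13, about 2 posterior SD from the truth) is noisy per
kinetochore; multiplying
posteriors across a group of kinetochores (`combine_posteriors`) shrinks
the SEM like 1/sqrt(n). Dividing the measured FRET fraction by the
calibration slope 0.42 converts it to the fraction of NDC80 complexes
bound to kMTs: 0.13 -> 31%.

## Analysis workflow

The `analysis/` directory holds numbered drivers that exercise the package
end to end on synthetic data and write tables under `results/`:

1. `01_simulate.R` — decays, a sister-pair movie, tension table, FCS
   curves, time courses (all with ground truth)
2. `02_flim_fit.R` — lifetime fixing, FRET-fraction posterior, model
   selection
3. `03_tracking.R` — detection, linking, pairing, classification
4. `04_calibration.R` — geometric calibration slope and FRET
   detectability vs NDC80-kMT distance
5. `05_tension_model.R` — binding-model fits and time-course fits
6. `06_fcs_labeling.R` — FCS calibration and the labeling-fraction chain

Run them in order with `Rscript analysis/01_simulate.R`, etc.

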
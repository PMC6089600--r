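---
title: "Methods: Bayesian FLIM-FRET quantification of NDC80-kMT binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian FLIM-FRET quantification of NDC80-kMT binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models implemented in `ktflim`, the choices
behind their defaults, what the synthetic-data generators do and do not
emulate, and the package's known limitations.

## The measurement problem

The fraction of NDC80 complexes bound to kinetochore microtubules (kMTs)
cannot be read off an intensity image. FLIM-FRET makes it measurable: a
cyan donor (mTurquoise2) on the NDC80 complex decays single-exponentially
with lifetime $\tau_D \approx 3.75$ ns when free, and with a much shorter
lifetime when close enough to a FlAsH acceptor on the tubulin lattice. A
kinetochore's photon-arrival histogram is therefore a two-exponential
mixture whose short-lifetime amplitude $f_{FRET}$ counts the donors
engaged in FRET. Because only ~26% of tubulin is labeled, $f_{FRET}$
underestimates the bound fraction; a simulation-based calibration supplies
the conversion slope.

## Decay model and discretization

Time is discretized on the fine grid on which the IRF is measured
(bin width $\tilde{\Delta t}$, default 3.125 ps); the detector histogram
uses coarse bins of `adc_ratio` = 16 fine bins (50 ps), 250 bins spanning
a 12.5 ns window (80 MHz repetition; 3.3 donor lifetimes, so truncation is
mild and is handled exactly by normalization). The model decay is the
discrete convolution of the (integer-shifted) IRF with
$A\,g_\theta + (1-A)$, where $g_\theta$ is the single- or two-exponential
decay law and $1-A$ is background spread uniformly over the window. Fine
bins are Riemann-summed into coarse bins and normalized to per-bin
probabilities $P_i(\theta)$.

Two numerical points. First, likelihood evaluations are linear in the
mixture weights, so the per-lifetime convolutions are computed once and
reused across the $f_{FRET} \times A$ grid. Second, the short-lifetime
search range is capped at 2.5 ns: as $\tau_{FRET} \to \tau_D$ the
two-exponential model becomes degenerate and unconstrained maximum
likelihood wanders into that ridge; FRET states that close to the donor
lifetime are not resolvable as a separate component at realistic photon
counts, so the cap is an identifiability guard, matching the posterior
grid.

## Likelihood, posterior, and combination

The likelihood is multinomial over bins,
$L(\theta) = \prod_i P_i(\theta)^{y_i}$ (the total-count factor is
constant and dropped). With a uniform prior, the posterior is evaluated on
a dense grid when at most three parameters are free — $f_{FRET}$ on 201
points of $[0,1]$, amplitude $A$ on 21 points of $[0.8, 1]$, lifetimes on
0.02-0.025 ns steps — and otherwise by Metropolis-within-Gibbs (5,000
draws after 1,000 burn-in, adaptive proposals during burn-in, split-chain
diagnostic). Grid and MCMC agree on two-parameter problems within combined
uncertainty (tested).

Per-kinetochore posteriors are combined by multiplying the marginal
$f_{FRET}$ densities over the shared grid and renormalizing; the mean and
SD of the product are the group estimate and SEM. The product of $n$
identical unimodal posteriors shrinks the SD like $1/\sqrt{n}$ (tested).
Near-disjoint posteriors (pairwise Bhattacharyya coefficient < 0.05)
trigger a conflict warning rather than silently averaging.

The measurement procedure mirrors practice: the donor lifetime is fixed
from a no-acceptor control, the short lifetime from cell-aggregated
histograms (aggregation is by summing histograms, which weights cells by
photon count), then per-kinetochore posteriors are computed with both
lifetimes fixed. `run_pipeline()` chains these stages deterministically
from one seed.

## Model selection

Single- vs two-exponential fits are compared with
$\Delta BIC = BIC_{1exp} - BIC_{2exp}$, $BIC = k \ln n - 2 \ln L$ with $n$
the photon count; positive values favor the two-exponential model and an
exact tie reports the single-exponential one (parsimony).

## Geometric FRET calibration

The atomistic conformational ensembles behind the reference calibration
are replaced by a coarse-grained cylindrical lattice: microtubule radius
12.5 nm, 13 protofilaments, 4 nm monomer rise with a 3-start helical
stagger, acceptor anchors at the beta-tubulin C-termini jittered by a
1.5 nm Gaussian tether, the donor offset 2.5 nm radially from the
CH-domain anchor, binding split 50/50 between inter- and intra-dimer
interfaces, and the 12 nearest anchors retained. Bound donors get the
multi-acceptor lifetime
$\tau(\vec r) = \tau_D / (1 + \sum_i I_i (R_0/r_i)^6)$ with
$I_i \sim \mathrm{Bernoulli}(f_{label})$, $f_{label} = 0.261$,
$R_0 = 5.90$ nm; decays are amplitude-weighted (a quenched donor emits
proportionally fewer photons), Poisson-sampled at 10,000 expected photons,
and fit with the two-exponential model ($\tau_D$ fixed). The
origin-constrained regression of fitted $f_{FRET}$ on true $f_b$ gives the
conversion slope, with a bootstrap CI over replicates.

**Known limitation.** With these defaults the slope comes out at
0.51-0.53, above the reference atomistic value 0.42 +/- 0.08. The lattice
stand-in places the donor only ~2.5 nm from the nearest acceptor anchor
when bound and leaves ~5 of the 12 anchors within quenching range, which
produces a broader intermediate-lifetime distribution — and hence a larger
short-component amplitude — than the atomistic ensemble. The geometry
constants are configurable, but the defaults are fixed design choices and
are not adjusted to reproduce the reference slope; the package therefore
uses the measured 0.42 for `fret_to_binding()` and reports the geometric
slope as what the coarse-grained model actually yields. The
distance-detectability analysis is insensitive to this: $\Delta BIC$ flips
sign with stand-off distance in agreement with the reported ~8 nm cutoff.

## The tension model

Aurora B activates in trans and is deactivated by phosphatases; for each
pool the active steady state is $\max([A_x] - K_x, 0)$, giving total
active Aurora B $A^* - K$ below the threshold $A^* $ and $[A] - K$ above.
NDC80 phosphorylation equilibrates at
$f_{phos} = (1 + K_{phos}/[A_{active}])^{-1}$ and binding at
$f_{bound} = (1 + K_0 + K_0' f_{phos})^{-1}$ (the binding constant is
linearized in $f_{phos}$, valid for the small in-vivo range
$f_{phos} \lesssim 1/9$). The closed forms are verified against direct
ODE integration of the kinetic scheme over a parameter lattice to 1e-6.

Fits use Levenberg-Marquardt least squares, weighted by 1/SEM^2 when SEMs
are given (unweighted otherwise), with $A^* \ge K$ enforced by the
reparameterization $A^* = K + e^\eta$; standard errors come from the fit
covariance (delta method for $A^*$). Data lying entirely on one branch of
the piecewise model are flagged rather than silently fit. The per-pool
constants are not separately identifiable from binding data — only the
combined $(K, A^*)$ is fit.

Calibration maps are exact two-anchor linear forms: sensor non-FRET
fraction 0.540 -> $f_{phos} = 1/9$ and 0.368 -> 0 (the map is kept in
its exact two-anchor form rather than as pre-collapsed coefficients,
whose rounding would be inconsistent with the anchors); INCENP intensity is
normalized as $(I - I_{bg})/(\bar I_{mid} - I_{bg})$ so the mean midpoint
intensity corresponds to the 10 uM peak Aurora B concentration. Drug
time courses are fit with indicator-gated exponentials
$A(1 - e^{-I(t\ge0)t/\tau}) + c$ (rising) and $A e^{-I(t\ge0)t/\tau} + c$
(decaying).

## Tracking

Detection takes strict local maxima above threshold and refines them with
intensity-above-local-minimum centroids in a 7 px window (<0.1 px error on
clean spots). Linking is greedy nearest-neighbor with a displacement gate
and single-frame gap bridging — adequate for sparse kinetochores, and a
documented simplification relative to global assignment. Drift is
estimated by FFT cross-correlation of consecutive frames with quadratic
sub-pixel peak interpolation; low-correlation frames yield a zero offset
and a warning. Sister pairing gates on mean separation (0.5-2.5 um),
separation stability (SD < 0.35 um; sister separation is
tension-constrained while unrelated kinetochores drift apart), and
frame-to-frame velocity correlation (>= 0.5; sisters share the
pair-center motion), resolving conflicts by best correlation. Velocities
use the five-point stencil, exact for polynomials to degree four.
Coordinates are 0-based pixels with centers at integers and a 107 nm
default pixel size; classification thresholds are 1 um (centered) and
2.5 um (off-centered) from the metaphase plate.

## Synthetic data: what it does and does not emulate

Generators are pure functions of (parameters, seed) with deterministic
sub-streams. Decays are Poisson draws from the convolved model with the
expected total photon count as the amplitude parameter (default 300 per
kinetochore-timepoint, matching the few-hundred-photon regime of the FLIM
movies). The movie generator places sister pairs with a 2.4 um minimum
separation, oscillates pair centers sinusoidally (0.5 um amplitude, 150 s
period — about 1.3 um/min peak speed) with anti-phase K-K breathing
(0.15 um, 75 s) around condition-preset K-K means (untreated 1.19 +/-
0.19 um, taxol 0.90 +/- 0.10, STLC 0.87 +/- 0.10, 9A-Hec1 1.36 +/- 0.21),
and renders 2D Gaussian spots (sigma 1.3 px) with Poisson shot noise and
Gaussian read noise. It does not emulate spindle morphology, z-structure
(projections are 2D), photobleaching, or non-exponential donor
photophysics; passing tests on these data show the estimators are correct
under the stated model, not that real spindles meet its assumptions.
Problem sizes in the test suite (e.g. 10^4-10^5-photon decays, 100-150
posterior replicates, 30-replicate calibrations, six-pair movies) were
chosen so the full suite exercises every claim at desk scale.

## FCS and the labeling fraction

The reference fit uses the two-photon diffusion model
$G(\tau) = \frac{1}{V_{eff}\chi^2 C}(1 + 8D\tau/w_{xy}^2)^{-1}
(1 + 8D\tau/w_z^2)^{-1/2} + G_\infty$ with
$w_z = (2/\pi^{3/2}) V_{eff}/w_{xy}^2$ (this convention is isolated in
one function so an alternate convention is a one-line change). The
brightness fit
fixes the geometry and fits the molecule number $N$; brightness is the
background-corrected count rate over $N$, with
$\chi^2 = (S/(S+B))^2$ adopted as the background correction factor
(configurable). Concentrations convert via 1 uM = 602.214
molecules/um^3. The polymer photon rate is the in-mask mean minus the
in-mask histogram mode (Freedman-Diaconis bins by default); segmentation
uses Otsu thresholding, morphological closing, and the largest connected
component — a deliberate simplification of contour-based segmentation,
since only the in-mask mean and mode enter downstream. The labeling chain
then scales by the polymerized percentage and the total tubulin pool:
1.88 uM -> 5.22 uM -> 26.1% on the reference inputs.

## Degenerate inputs and tie-breaks

Empty histograms error; all-identical grouping values collapse to one
group; pairing reports unpaired tracks; boundary estimates ($f_{FRET}$ at
0, $\tau$ at bounds, zero FCS amplitude) warn or flag rather than return
silently; clipping (negative intensities, binding fractions above 1) always
warns. BIC ties report the simpler model.
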
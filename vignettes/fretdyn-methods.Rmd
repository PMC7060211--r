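---
title: "Resolving exchanging conformational states by hybrid fluorescence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving exchanging conformational states by hybrid fluorescence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretdyn)
```

## The problem

Proteins such as T4 lysozyme interconvert between conformational states on
microsecond-to-millisecond timescales. A sparsely populated state that
exchanges quickly with the major conformers is invisible to most structural
methods: crystallography averages over the lattice, and a single
fluorescence observable rarely constrains both the number of states and
their exchange rates. The strategy implemented here combines four
fluorescence views of the same molecule-scale process:

1. **Single-molecule MFD burst analysis** — freely diffusing labelled
   molecules cross a confocal volume; each burst yields an intensity-based
   FRET efficiency `E` and a fluorescence-averaged donor lifetime
   `<tau_D(A)>_F`. Their joint 2D histogram, read against *FRET-lines*,
   indicates how many states there are and whether they exchange during a
   transit.
2. **Filtered FCS** — micro-time patterns of the states act as matched
   filters; species cross-correlation functions expose the kinetic
   relaxation times with high contrast.
3. **Ensemble TCSPC** — high-statistics fluorescence decays are modelled as
   superpositions of normal-distributed donor-acceptor distances, with
   species fractions shared globally across all labelling variants.
4. **Dye-model screening** — accessible-contact-volume (ACV) clouds turn
   candidate structural models into predicted mean inter-dye distances,
   ranked against the experimental distance sets per state.

A three-state linear kinetic chain C1 &#8644; C2 &#8644; C3 ties the
pieces together: fFCS supplies the two relaxation times, the global decay
fit supplies the equilibrium fractions, and the rate constants follow by
analytic inversion — up to a two-fold ambiguity that burst-histogram
comparison against simulated experiments resolves.

## Models and procedures

### Photon-stream simulation (`sim_config()`, `simulate_photon_stream()`)

Molecules diffuse by Gaussian displacement steps inside a periodic box at
least ten times the focal radii, so the concentration in the open detection
region stays constant. The detection profile is a 3D Gaussian with 1/e^2
radii `w_xy`, `w_z`; the instantaneous detected rate of a molecule in state
`s` is `Q_s exp(-2x^2/w_xy^2 - 2y^2/w_xy^2 - 2z^2/w_z^2)`. State switching
is a continuous-time Markov chain resolved *exactly* inside every diffusion
step (dwell times are exponential in the total exit rate, successors drawn
proportionally to the outgoing rates), so microsecond kinetics are not
aliased by the ~3 microsecond diffusion step; when a molecule is too far
from the focus to emit detectably, the chain is propagated by the exact
one-step transition matrix `exp(K dt)` instead of event by event. Photon
colour follows the state's FRET efficiency (with optional crosstalk and
direct acceptor excitation), and micro-times are drawn from the
state-quenched donor decay (green), the transfer-plus-acceptor cascade
(red), or a flat distribution (background), convolved with a Gaussian IRF
and discretised to 4096 TCSPC channels per repetition period.

Default conditions emulate the experiments the package was built around: a
0.54 ms diffusion time (w_xy = 0.5 um, D = 0.116 um^2/ms), 150 kHz
molecular brightness at the focus, 4 ns donor and 1.7 ns acceptor
lifetimes, a 0.25 ns IRF, a 32 ns repetition period and three conformers
with FRET efficiencies 0.35/0.55/0.85 exchanging over a linear chain with
equilibrium fractions 0.44/0.38/0.18 (rates 120, 140, 2.2, 4.6 per ms give
relaxation times of about 4 us and 230 us). What the generator does *not*
emulate — triplet blinking, acceptor photophysics, detector afterpulsing,
saturation — bounds what passing tests show about real data: they validate
the analysis chain, not the instrument corrections.

One master seed drives everything; per-molecule child seeds are derived
deterministically, so identical configurations reproduce identical streams.

### Burst analysis and FRET-lines

Burst selection is a sliding-window search (defaults: 120 us window, at
least 10 neighbours, at least 60 photons per burst — typical MFD settings,
all configurable). Efficiencies use
`E = F_A / (F_A + gamma F_D)` after background subtraction and crosstalk
correction. The burst lifetime is the truncated-window maximum-likelihood
estimate of a single exponential applied to the green micro-times measured
from the IRF peak; the window opens 3 IRF widths before the peak so the
symmetric IRF spread cancels from the arrival-time mean instead of
truncating the fast decays (cutting at the peak would bias mixtures long).

The static FRET-line is the locus of single-conformer bursts, parametric in
distance with Gaussian linker broadening `sigma_link`; the dynamic
FRET-line connects two exchanging states through the moment relation
`tau_x = tau_1' tau_2' / (tau_1' + tau_2' - tau_F)`. A population centred
on the dynamic line, right-shifted from the static line, is the model-free
signature of sub-millisecond exchange.

Histogram comparison between experimental and simulated burst sets uses a
chi-square distance on normalized 1D/2D histograms with a bootstrap null
built from the simulated set itself. The binning (61 x 61 over
E in [-0.1, 1.1] and lifetime in [0, tau_D0 + 0.5 ns]) and the bootstrap
construction are this package's declared choices.

### Filtered FCS

Filters are weighted-least-squares solutions
`W = (M' D M)^-1 M' D`, `D = diag(1/total)`, over stacked
(detector, micro-time) channels; they are unbiased by construction:
applying the species-i filter to the expected pure-species-j pattern
returns delta_ij times the species photon number. For synthetic data the
patterns come from the generator's closed-form state decays; for real data
the intended source is sub-ensemble decays of the limiting burst
populations. Correlation uses an exact photon-pair accumulator on a
quasi-logarithmic lag grid (16 lags per cascade, doubling width, first lag
four sync periods). For each cascade, photon weights are first aggregated
on a grid of half the cascade's bin width — the usual multiple-tau
coarsening, which keeps the pair count tractable without biasing lags
longer than the bin width. Uncertainties are standard deviations over eight
stream segments. The fitted model is the standard
3D-diffusion-times-kinetics form
`G(t_c) = (1/N) (1 + t_c/t_d)^-1 (1 + t_c/(s^2 t_d))^-1/2 (1 + sum_i A_i exp(-t_c/t_Ri)) + G_inf`,
with negative cross-correlation amplitudes carrying the anti-correlation
dip and relaxation times shared across curves in global fits. Whether a
second relaxation time is *statistically demanded* is decided by an F-test
between nested fits — the package's operational form of the kinetic
argument that two relaxation times imply at least three exchanging states.
Because at high photon statistics per-mille-level systematics of the
diffusion part of the curve would otherwise masquerade as a slow
"relaxation", the nested kinetic comparison is made inside the kinetic lag
window (up to ~25 relaxation times) with the diffusion time frozen at its
full-lag-range estimate (`t_diff_fixed`), and kinetics-grade simulations
use a 1 us integrator step so that the quasi-static intensity sampling
stays well below the kinetic correlation scale.

### Ensemble decay fitting

The FRET-induced donor decay of a state is
`F(t) = x_D0 f_D(t) + (1 - x_D0) sum_i x_i Int p_i(R) f_D(t) exp(-t k_FRET(R)) dR`
with `k_FRET(R) = (1/tau_D0)(R0/R)^6` and `p_i` a normal distance
distribution truncated at R >= 1 A. The distance integral uses 441
equidistant nodes over the mean +/- 5 widths — far below 1e-4 relative
error against adaptive quadrature. The fitted model per dataset is the
decay convolved (circularly, matching pulsed excitation) with the measured
IRF plus scattered light and a flat background; these three linear
coefficients are profiled analytically per curve by weighted least squares.
Weights are Poisson (`sigma = sqrt(max(counts, 1))`, zero-count channels
retained). Because this Neyman weighting is biased at near-empty channels,
realistic fixtures include the dark-count floor every measured decay has;
fit ranges are configurable per dataset.

The global fit shares the species fractions across datasets and the donor
lifetime spectrum between each dataset's DA and DOnly curves, while the
distances and widths stay dataset-specific. The optimizer is
Levenberg-Marquardt on the variance-stabilised residuals with an analytic
Jacobian in the Kaufman variable-projection approximation (profiled linear
coefficients held fixed, Jacobian columns projected out of the active
linear span); restarts from random draws guard the multi-modal
three-component surface. Components are reported sorted by ascending mean
distance to break label switching.

Parameter uncertainty comes from two routes. *Support-plane analysis* pins
one parameter per grid point and re-optimizes the rest; the confidence
region is bounded by the F-test threshold
`chi2r_min (1 + p/(n-p) F_{1-alpha}(p, n-p))` with `p` free parameters and
`n` fitted channels, and distance profiles yield asymmetric statistical
errors as the shortest and longest distance below the threshold. This
convention is deliberately conservative for single parameters, which is
the behaviour the published analyses of this kind report. *MCMC* samples
the exact Poisson likelihood around a converged single-dataset fit with an
adaptive random-walk Metropolis sampler (covariance adaptation plus
acceptance-rate targeting during burn-in, chains reproducible under a
seed); marginal histograms visualize the statistical spread of distances
and fractions.

A note on identifiability: a single dataset constrains the three mean
distances well but the individual widths and fractions only weakly — many
(fraction, width) combinations produce nearly identical decays. This is
exactly why fractions are shared across the whole variant network in the
global analysis, and why the support-plane intervals on single-dataset fits
are wide. The round-trip tests assert coverage of the means, not pinpoint
recovery of every parameter.

### Kinetic network treatment

`relaxation_spectrum()` diagonalises the rate matrix; `invert_three_state()`
solves the inverse problem from (t_R1, t_R2, x1, x2, x3) via the eigenvalue
sum and product, returning both physical roots — the fast-C1C2 solution
first, degenerate double roots merged at 1e-6 relative. Cyclic topologies
are representable as `rate_network`s but deliberately unsupported by the
inversion (the linear-chain assumption is load-bearing). Free-energy
landscapes use `dG0 = -kT ln(k_ji/k_ij)` and barriers
`dG0+ = -kT ln(k_ij/k0)` with the arbitrary reference prefactor
`k0 = 1e3/ms`.

### Dye clouds and structure screening

ACV clouds are computed on a grid (default 0.9 A; the toy-ensemble tests
use 1.2 A, which changes mean distances by well under the 0.5 A
grid-convergence bound): Dijkstra geodesics over the 26-neighbourhood
emulate the flexible linker (clearance at least half the linker width,
path length at most the linker length), a voxel joins the volume if any of
the three dye-sphere radii fits, and the shell within 3 A of the heavy-atom
surface forms the contact volume, re-weighted so its total weight equals
the trapped fraction `x_trapped = r_inf/r_0`. Dye presets carry the
standard Alexa488 (20/4.5/5-4.5-1.5 A) and Alexa647 (22/4.5/11-3-3.5 A)
geometries. Two cloud summaries matter: the mean-position distance `R_mp`
and the pairwise mean `<R_DA>` that ensemble TCSPC actually measures; the
package calibrates the empirical third-order polynomial between them from
its own cloud simulations, since no universal coefficients exist.

Screening computes `chi2_r,FPS` per structure and state, dividing each
residual by the uncertainty side matching its sign, and reports rankings
plus the regression of experimental on model distances. Structure ensembles
are clustered by complete-linkage on pairwise C-alpha RMSD after Kabsch
superposition, cut at 1.8 A, with medoid representatives.

### The kappa-squared uncertainty budget

Residual anisotropies set wobbling-in-cone order parameters
`S_i = sqrt(r_inf,i / r_0)`. Per Monte-Carlo draw both cone axes are
oriented uniformly at random with respect to the donor-acceptor axis and
the fast intra-cone wobble is averaged in closed form (axial second-moment
algebra), which reproduces the required limits exactly: fully mobile dyes
give kappa^2 = 2/3 identically, fully static isotropic dyes average to 2/3.
(A fixed donor cone axis would not satisfy the static isotropic limit —
its conditional mean is (1 + 3 cos^2 theta)/3 — hence both axes are
randomized.) The kappa^2 distribution maps to apparent-distance ratios
`xi = (3 kappa^2/2)^(-1/6)`; the standard deviation of xi is the relative
distance precision, its mean minus one the accuracy, and the total distance
uncertainty combines dye-model, kappa^2, reference and (asymmetric)
statistical terms in quadrature. With site-specific labelling and a
measured donor-only reference, the dye-model and reference terms are zero.

## Numerical choices and degenerate inputs

* Distance quadrature: 441 equidistant nodes, truncation at R >= 1 A,
  weights renormalised; widths are log-parameterised, distances bounded to
  [5, 500] A inside the optimizer.
* Convolution is circular over the full period, matching pulsed excitation;
  the optional IRF time shift is applied as a Fourier phase.
* The photon-pair correlator's normalization uses the finite-duration
  overlap correction, so an uncorrelated stream gives G = 0 at all lags.
* Empty streams, all-zero IRFs, absorbing or disconnected networks, buried
  attachment sites, rank-deficient filter patterns and negative rates all
  raise immediate, specific errors rather than propagating.
* Test problem sizes are chosen to exercise the statistics they assert:
  1000 random networks for the inversion, 50 decay replicates at 1e7
  counts (512-channel histograms), 15-30 s photon streams at 150 kHz
  brightness, 1e6 kappa^2 samples.

## Known limitations

* The burst lifetime estimator is a single-exponential MLE; for strongly
  multi-exponential bursts it estimates the fluorescence-weighted mean
  lifetime with a small period-wrap bias (about 0.05 ns under the default
  conditions).
* Polarization is collapsed to two spectral detectors in the simulator;
  polarization-resolved filter construction on real data is out of scope.
* The decay fit's analytic Jacobian covers single-donor-lifetime fits
  without free IRF shift; richer configurations fall back to numeric
  differentiation (slower, same results).
* Photon streams are exchanged as CSV plus JSON sidecar; binary
  time-tagged formats are not read.
* No triplet/blinking photophysics and no PIE/ALEX sorting.

## A compact end-to-end run

```{r, eval = FALSE}
cfg <- pipeline_config(duration_s = 10, decay_counts = 3e6, seed = 1)
report <- run_pipeline(cfg)
report$stages$ffcs$t_R_us        # relaxation times from fFCS
report$stages$decays$fractions   # shared species fractions
report$stages$kinetics$solutions # the two candidate rate matrices
```

The pipeline records a provenance block (configuration hash, seed, package
version) with every run; identical configurations reproduce identical
reports.
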
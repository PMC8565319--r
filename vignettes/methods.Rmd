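---
title: "Models and methods behind trfkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trfkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trfkin)
```

## The measurement problem

trfkin analyses pre-steady-state annealing of a FRET-labelled nucleic-acid
hairpin (a donor/quencher-labelled stem-loop, SL) with its complementary
strand (P) into an extended duplex (ED), promoted by a nucleic-acid chaperone
peptide. Two complementary observables are supported:

* **Droplet time-resolved FRET (TRF-DmF).** Reagents are mixed in water-in-oil
  microdroplets that propagate along a channel; the distance from the mixing
  junction divided by the droplet speed gives the reaction time T (seconds).
  At each T a full donor fluorescence decay (nanoseconds) is recorded. Because
  each coexisting species has a distinct decay signature, the decay amplitudes
  resolve the *concentrations of individual species* along the reaction.
* **Stopped-flow transient fluorescence intensity (Tr-FI).** A single
  brightness-weighted intensity trace per mixing experiment; species enter
  only through the sum \(I(t) = s \sum_j I_j [X_j](t)\).

## Decay model and reconvolution

A multiexponential decay switched on at the excitation time \(t_0\) and blurred
by a Gaussian instrument response of width \(\sigma\) has the closed form

\[
A(t) = C + \sum_i \frac{A_i}{2}
 \exp\!\Big(\frac{\sigma^2}{2\tau_i^2}\Big)
 \exp\!\Big(-\frac{t-t_0}{\tau_i}\Big)
 \Big[1 + \mathrm{erf}\Big(\frac{t-t_0-\sigma^2/\tau_i}{\sigma\sqrt2}\Big)\Big],
\]

with a constant offset \(C\) for the detector dark counts. `model_decay()`
evaluates this in log space (`log(1+erf)` via the Gaussian CDF's log tail), so
lifetimes down to tens of picoseconds never overflow, and is verified against
a brute-force numerical convolution oracle to 1e-6 relative in the tests.
Goodness of fit is the Poisson-weighted chi-square
\(\chi^2=\sum_i (y_i - f_i)^2/\max(y_i,1)\); the `max(y_i, 1)` floor is our
documented choice for empty bins (the Poisson variance estimate is undefined
at zero counts), and both the raw sum and \(\chi^2/(N-n_{free})\) are
reported.

`fit_decay()` uses variable projection: amplitudes and offset enter linearly
and are profiled out by weighted *nonnegative* least squares, so the nonlinear
search runs only over \((\log\tau_i, t_0, \log\sigma)\). This enforces the
positivity constraints without penalties and is markedly better conditioned
than a joint fit. Components are added one at a time until the reduced
chi-square improves by less than 0.02 (the source analysis only states "until
the fit converges"; 0.02 is our documented threshold, configurable).
A seeded 5-start multi-start guards against local minima.

## Window stitching

The streak camera records each decay in three windows (1, 5, 20 ns by
default) whose Gaussian IRF width scales linearly with the window
(\(\sigma(w) = 10\,\mathrm{ps}\cdot w/1\,\mathrm{ns}\)). `stitch_windows()`
appends non-overlapping segments, rescaling each longer window by the ratio
of *mean count levels* over the overlap with the already-stitched trace.
Levels rather than raw bin sums are compared because windows have different
bin widths; with the default nested bin grids (1000/1000/800 bins) the
comparison uses exactly coincident bin centres, so a noiseless self-test
recovers unit scale factors to machine precision. Per-bin IRF widths and the
applied scale factors (which enter the variance model) are retained.

One subtlety is physical, not numerical: segments from different windows have
different IRF widths, so a stitched trace is *not* a single scaled copy of
one underlying function — the short-lifetime components carry a
window-dependent weight \(\exp(\sigma^2/2\tau_i^2)\). All multi-curve fits in
trfkin therefore give every stitched segment its own free scale and offset
while sharing the physical parameters, which is exactly equivalent to fitting
the windowed acquisitions jointly. With a single shared scale instead, the
noiseless three-species decomposition shows a ~2-4% fraction bias; the
segment-aware model removes it exactly.

## Species signatures and global decomposition

Reference measurements fix the signatures: the equilibrated hairpin is a
triexponential \(F_{SL}(t)=\sum_{i=1}^3 A_i e^{-t/\tau_i}\) with
\(\sum A_i = 1\) (amplitudes 0.46/0.44/0.10, lifetimes 0.11/0.71/2.66 ns in
the validated reference table), the equilibrated duplex a monoexponential
\(F_{ED}(t)=e^{-t/\tau_{ED}}\) with \(\tau_{ED} = 4.19\) ns.
`fit_signatures()` fits all reference curves globally (shared lifetimes and
amplitude pattern, free per-curve scale/offset). During decomposition the
signatures are frozen: the hairpin conformers interconvert far faster than
the annealing reaction, so residual free hairpin always decays with the same
signature. Refitting them per mixture curve is deliberately not offered.

Mixture curves at reaction time T are decomposed as

\[
F_2(t, T) = (1-\alpha-\beta)\,F_{SL}(t) + \beta\,e^{-t/\tau_{IC}} +
\alpha\,F_{ED}(t),
\]

with per-curve \(\alpha\) (duplex fraction) and \(\beta\) (intermediate
fraction) and a *single* intermediate lifetime \(\tau_{IC}\) shared by every
curve of every experiment. Decay amplitudes are identified with molar
fractions directly — no brightness correction in the decay-amplitude domain —
which is the standard modelling assumption for this observable. For fixed
\(\tau_{IC}\) the model is linear in the nonnegative species contributions,
so \(\alpha,\beta\ge 0\) and \(\alpha+\beta\le1\) hold by construction
(fractions are ratios of NNLS coefficients), and \(\tau_{IC}\) — the only
global nonlinear parameter — is profiled on a deterministic log grid
(default 25 points over 0.005-1 ns) refined by golden-section search. A
deterministic one-dimensional profile cannot be trapped in the local minima
that motivate multi-start elsewhere, so the "multi-start stability" guard is
exercised in the tests across independent data seeds instead. Its standard
error comes from the profile curvature, inflated by the square root of the
reduced chi-square. A \(\tau_{IC}\) landing at the search boundary is
flagged and warned about.

The simpler two-species model \(F_1 = (1-\alpha)F_{SL} + \alpha F_{ED}\)
(`decompose_one_step()`) is retained as the diagnostic: when data contain a
short-lived intermediate, its fit leaves systematic early-time residuals and
a worse chi-square, which is how the ~45 ps intermediate reveals itself.

## Kinetic schemes

Two mass-action schemes are fit with rates shared across experiments:

* two-step: \(SL + P \rightleftharpoons IC \rightarrow ED\)
  (rates \(k_1\) in M\(^{-1}\)s\(^{-1}\); \(k_{-1}, k_f\) in s\(^{-1}\));
* three-step: \(SL + P \rightleftharpoons IC_1 \rightleftharpoons IC_2
  \rightarrow ED\) (additional \(k_2, k_{-2}\)).

Concentrations are micromolar internally; \(k_1\) is accepted and reported in
M\(^{-1}\)s\(^{-1}\) with an explicit unit conversion. The chaperone is not an
explicit species — its effect is absorbed in the rates. Mixing dead time
(milliseconds) is neglected; T = 0 is the mixing event. `derived_constants()`
reports \(K = k_1/k_{-1}\) and, for the three-step scheme, the effective
pre-equilibrium annealing rate \(k_{\mathrm{eff}} = k_1 k_2 / k_{-1}\)
(the combination that reproduces the published 1.7e5 M\(^{-1}\)s\(^{-1}\)
worked example from the three-step rate table).

Integration uses an adaptive Dormand-Prince RK45 with rtol 1e-8 / atol 1e-12,
implemented twice: a compiled stepper (used by default — kinetic fits
evaluate thousands of trajectories across numerical Jacobians and
multi-starts) and a pure-R reference implementation; both land exactly on the
requested output times, agree with each other to solver tolerance, and are
cross-checked against a matrix-exponential oracle for the pseudo-first-order
linearized scheme. Runge-Kutta steps preserve the two linear conservation
laws (labelled and complementary strand totals) to rounding error.

`fit_concentration_trajectories()` (droplet mode) fits shared
\((k_1, k_{-1}, k_f)\) to SL/IC/ED concentrations with absolute (uM)
residuals by default, matching the roughly constant dispersion of
decomposition-derived concentrations; relative weighting is available.
Because association can be effectively instantaneous on the sampled grid,
the fit profiles the objective along \(k_1\) at fixed \(K\) and flags
\(k_1\) as a lower bound when the profile is flat (relative chi-square change
below 1% over a 10x increase). `fit_intensity_traces()` (stopped-flow mode)
fits shared rates and brightnesses with the duplex brightness fixed at 1 and
per-trace scales profiled out analytically; any parameter can be held fixed
(e.g. the near-dark first intermediate at \(I_{IC1} = 0.01\), its lifetime
being a hundredth of the duplex lifetime). \(k_{-2}\) is bounded below by 0
(log parameterization) and reported as an upper bound when it collapses to
the boundary. Both fitters are Levenberg-Marquardt in log-parameter space
with seeded multi-starts; standard errors come from the Jacobian at the
optimum scaled by the residual mean square.

Two constraints of the intensity fit deserve note. First, relative
brightnesses are bounded above at 1.5: the duplex is the fully unquenched
state, so a species outshining it is unphysical — and without the bound the
three-step model has a degenerate solution branch (a very bright IC2
compensating a vanishing \(k_{-1}\)) at indistinguishable residuals.
Second, the three-step fit does not rely on random multi-start alone: it
first fits the robust two-step model and inverts the pre-equilibrium
reduction \(k_1^{eff} = k_1 k_2/(k_{-1}+k_2)\) over a small deterministic
grid of \((k_{-1}, k_2/k_{-1})\) to build structured starting points; the
best of these basins wins. Rate searches are bounded to physically sensible
windows (first-order rates below the mixing-time resolution, \(k_1\)
below diffusion control), which also keeps the explicit integrator away from
pathologically stiff trial parameters.

## What the synthetic instrument emulates

`generate_trf_experiment()` / `generate_trfi_traces()` generate every input
the pipelines consume, from stated parameters and seeds only:

* windowed acquisition (1/5/20 ns) with window-scaled Gaussian IRF
  (10/50/200 ps) and the excitation origin at 0.1 ns;
* photon budget 1e6 counts per window acquisition (the real per-curve totals
  are unpublished; this budget reproduces the stated 5-10% relative
  uncertainty on decomposed concentrations and is documented as that choice);
* a uniform dark-count background of 2% of the budget, giving the ~tens of
  counts per bin baseline a streak-camera photocathode produces;
* Poisson photon noise, seeded per curve; all outputs are bit-reproducible
  given (design, seed);
* ten propagation times log-spaced over 0.1-10 s, the span reachable at the
  instrument's droplet speeds (7-80 mm/s) and channel lengths;
* species fractions evolved by the kinetic schemes; in the decay domain the
  bright second intermediate IC2 emits with the duplex lifetime (the two are
  spectroscopically indistinguishable there), so three-step truths map IC2
  into the duplex signature — configurable, to probe identifiability;
* stopped-flow traces on a 1000-point log-spaced grid from 0.05 s (a typical
  stopped-flow dead time) to 500 s with 1% relative Gaussian noise,
  emulating a stopped-flow digitizer's point count;
* pre-mix hairpin references tagged as "negative" propagation time, entering
  signature fitting only, never decomposition.

Not emulated: droplet hydrodynamics, surfactant/salt interface perturbations
(the generator assumes the validated 150 mM NaCl regime), photobleaching,
detector afterpulsing, spectral structure. A green round-trip test therefore
establishes correctness of the estimators under the stated noise model, not
robustness to instrument artefacts outside it.

## Numerical choices and edge cases

* Decay bins are bin centres; default grids are nested across windows
  (1000/1000/800 bins) so stitching can compare coincident samples.
* Amplitudes/offsets: nonnegative by active-set NNLS; lifetimes, IRF width,
  rates, brightnesses: positive via log transforms; fraction pairs: softmax
  parameterization of the simplex in segment-aware decomposition.
* Component ordering is canonical (increasing lifetime, ties by amplitude).
* Empty bins: variance floor of one count (configurable).
* All-zero curves, mismatched lengths, missing windows, empty overlaps,
  non-simplex fractions, negative rates and out-of-range droplet speeds are
  rejected with typed error messages ("data error", "invalid parameter",
  "stitching error"), which the CLI maps to distinct exit codes.
* The t0 of reference fits is shared across curves within an experiment;
  whether the original analysis shared t0/sigma per curve is unstated, so
  this default is our documented choice (per-bin sigma is always taken from
  window metadata).

## Known limitations

* One intermediate lifetime in the decay domain: a second bright intermediate
  is indistinguishable from duplex by lifetime, so it is not modelled there.
* The droplet trajectory fit supports the two-step scheme only — with IC2
  counted as duplex, the decay-domain observable cannot separate the
  three-step rates.
* File-based (non-simulated) TRF pipelines treat all mixture curves as one
  experiment per run.
* Uncertainties are curvature-based (local, Gaussian); no bootstrap or
  profile intervals beyond the k1/tau_IC profiles described above.
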
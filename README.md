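# trfkin

Transient time-resolved FRET analysis of protein-promoted nucleic-acid
annealing kinetics.

## The problem

A FRET-labelled DNA/RNA hairpin (stem-loop, **SL** — donor and quencher held
close, strongly quenched multiexponential decay) anneals with its
complementary strand (**P**) into an extended duplex (**ED** — large
donor-quencher distance, unquenched monoexponential decay), a reaction
promoted by a nucleic-acid chaperone peptide and proceeding through transient
intermediate complexes (**IC**) that cannot be isolated. Two pre-steady-state
observables resolve this reaction:

* **droplet-microfluidic time-resolved FRET**: reagents mix in water-in-oil
  microdroplets; the propagation distance from the mixing junction divided by
  the droplet speed gives the reaction time `T`, and at each `T` a full donor
  fluorescence decay is recorded in three streak-camera windows (1/5/20 ns).
  Decay amplitudes resolve the *concentrations of each species* along the
  reaction — including a near-dark early intermediate with a ~45 ps donor
  lifetime that intensity detection cannot see;
* **stopped-flow transient fluorescence intensity**: a single
  brightness-weighted trace per mixing experiment.

trfkin implements the full analysis chain for both, plus a synthetic
instrument that generates every input from stated parameters and seeds:

1. analytic Gaussian-IRF reconvolution fitting of multiexponential decays
   (`model_decay()`, `fit_decay()`), with Poisson-weighted
   \(\chi^2 = \sum_i (y_i - f_i)^2 / \max(y_i, 1)\);
2. multi-window stitching (`stitch_windows()`);
3. reference signature fitting (`fit_signatures()`) and global three-species
   decomposition
   \(F_2(t,T) = (1-\alpha-\beta) F_{SL}(t) + \beta e^{-t/\tau_{IC}} + \alpha F_{ED}(t)\)
   with one shared intermediate lifetime \(\tau_{IC}\)
   (`decompose_two_step_global()`, `to_concentrations()`);
4. mass-action kinetic modelling of the two-step scheme
   \(SL + P \rightleftharpoons IC \rightarrow ED\) and the three-step scheme
   \(SL + P \rightleftharpoons IC_1 \rightleftharpoons IC_2 \rightarrow ED\)
   (`simulate_scheme()`, compiled adaptive RK45), fitted globally to
   species trajectories (`fit_concentration_trajectories()`) or to intensity
   traces with per-species brightnesses (`fit_intensity_traces()`);
5. synthetic data generation (`generate_trf_experiment()`,
   `generate_trfi_traces()`) and end-to-end pipelines with a CLI
   (`run_trf_pipeline()`, `run_trfi_pipeline()`, `inst/scripts/trfkin`).

## Worked example

Simulate a droplet mixing experiment (3.6 uM labelled hairpin vs 12 uM
complement) at known rates, then recover everything from the synthetic decay
curves alone:

```r
library(trfkin)

des    <- experiment_design(SL0 = 3.6, P0 = 12, seed = 42)
truth  <- kinetic_params(k1 = 1e5, k_m1 = 2.857, kf = 1.75)  # K = 3.5e4 M^-1
exp1   <- generate_trf_experiment(des, truth)

sig <- fit_signatures(unlist(exp1$reference$windows[1:2], recursive = FALSE),
                      unlist(exp1$reference$windows[3:4], recursive = FALSE))
dec <- decompose_two_step_global(exp1$stitched, sig)
dec
#> Three-species decomposition: 10 curves, tau_IC = 0.04336 ns (+/- 0.0012), reduced chi2 = 1.0110
#>          T_s    frac_SL    frac_IC     frac_ED
#> 1  0.1000000 0.90312684 0.08811480 0.008758353
#> 2  0.1668101 0.85720448 0.12131353 0.021481989
#> ...

conc <- to_concentrations(dec, total_labeled = 3.6)
fit  <- fit_concentration_trajectories(list(list(
          init = initial_conditions(3.6, 12),
          data = data.frame(T_s = conc$T_s, conc_SL = conc$conc_SL,
                            conc_IC = conc$conc_IC, conc_ED = conc$conc_ED))))
fit
#> Kinetic parameters (two_step)
#>   k1 = 9.834e+04 M^-1 s^-1, k-1 = 2.754 s^-1, kf = 1.755 s^-1
#>   K = k1/k-1 = 3.571e+04 M^-1 (+/- 9.1e+02)
#>   residual mean square = 0.0002801
```

The decomposition finds the ~0.045 ns intermediate lifetime from the decay
curves alone (0.0434 ns here), and the kinetic fit recovers the generating
equilibrium constant (`K = 3.57e4` vs truth `3.5e4 M^-1`) and duplex
formation rate (`kf = 1.755` vs `1.75 s^-1`) from ten noisy time points.

The same run end-to-end from a config file:

```sh
Rscript inst/scripts/trfkin run-trf --config config.yaml --seed 1 --out out/
```

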
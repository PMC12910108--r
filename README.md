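# smkinetics

Single-molecule colocalization and FRET kinetics of polymerase–DNA
binding, with a ground-truth trajectory simulator.

## What this package is for

In two-color single-molecule TIRF experiments on non-homologous end
joining, a Cy3B-labeled primer-template DNA is tethered to a coverslip
and a Cy5-labeled DNA polymerase (Pol λ, with or without the Ku70/80
end-binding factor) visits it under 200 ms alternating-laser excitation.
Two readouts carry the kinetics:

* **Colocalization**: bursts of acceptor intensity at a DNA spot mark
  polymerase visits. First binding times across molecules follow
  `F(t) = A·(1 − e^{−k_obs·t})`, giving the observed binding rate
  `k_obs` and the percent bound `A`; event durations decay exponentially
  with the bound dwell time τ.
* **FRET**: with the donor 11 nt from the primer-template junction,
  binding sets an efficiency E ≈ 0.6 that steps down ~0.1 per
  incorporated nucleotide. The duration of the E decrease is the
  nucleotide-incorporation dwell, and the Gaussian mean μ of per-event
  E decreases divided by 0.1 is the average number of nucleotides
  incorporated (μ = 0.4 → 4 nt).

The package implements the full analysis chain — spot detection,
channel registration, drift correction, background-corrected intensity
extraction, two-color colocalization, ALEX corrections
(`E = (F_DA − l·F_DD − d·F_AA) / (F_corr + γ·F_DD)`), photobleach
truncation, threshold-based event calling, and the exponential /
Gaussian / isotherm fits — plus a simulator that generates noisy
three-channel trajectories (and synthetic TIFF movies) from known
kinetic ground truths, so every stage is testable without bench data.
Bulk observables are covered too: four-box gel-lane quantification with
extension time courses, and MST-style titrations fit to a
depletion-corrected 1:1 binding isotherm for K_D.

## Worked example

Simulate the "+Ku" colocalization condition from its shipped fixture
(500 molecules, 180 s movies; ground truth: k = 0.03 s⁻¹, 71% bound,
τ = 2.7 s), call events at the 50-photon threshold, and fit:

```r
library(smkinetics)

sc     <- scenario_conditions("coloc_pol_ku")
sim    <- simulate_colocalization(sc)
events <- call_colocalization(sim$trajectories, threshold = 50)
ft     <- first_binding_times(events, unique(sim$trajectories$molecule_id),
                              observation_window = sc$movie_length)
fit_binding_cdf(ft, n_boot = 0)
#> <kin_fit> model: binding-cdf  n = 500 ( 137 censored )
#>            term   estimate std.error
#>  bound_fraction 0.73097720        NA
#>           k_obs 0.02780867        NA

fit_dwell_exponential(events$duration_s, cutoff = 0.4, n_boot = 200)
#> <kin_fit> model: dwell-exp  n = 1667
#>  term estimate std.error
#>   tau   2.5976 0.0636216
```

The recovered binding rate (0.028 s⁻¹), bound fraction (0.73) and dwell
(2.60 s) sit within a few percent of the simulation ground truths. The
`cutoff = 0.4` tells the dwell MLE that events shorter than two frames
are undetectable, removing the truncation bias. The FRET side runs the
correction → event-calling → fitting chain:

```r
scf   <- scenario_conditions("fret_pol_ku")   # 2.4 s incorporation, 4 nt
simf  <- simulate_fret(scf)
trace <- compute_efret(simf$trajectories,
                       correction_factors(scf$leakage, scf$direct_excitation,
                                          scf$gamma),
                       background = scf$background)
ev    <- call_fret_events(trace)
mag   <- fit_delta_e_gaussian(ev$delta_e, n_boot = 0)
mag
#> <kin_fit> model: gaussian  n = 186
#>   term  estimate   std.error
#>     mu 0.3732832 0.005313135
#>  sigma 0.0724615 0.003767094

nucleotides_from_delta_e(tidy(mag)$estimate[1])
#> [1] 3.732832
```

i.e. the pipeline reads back ~3.7 of the 4 simulated incorporations of
0.1 E each (the small shortfall is the single-frame blur discussed in
the methods vignette). Fit objects support `tidy()`, `glance()` and
`autoplot()`; `run_pipeline()` chains simulate → correct → call → fit
across conditions from a YAML config and writes a deterministic results
JSON with fold changes between conditions.

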
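---
title: "Models and methods behind smkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smkinetics)
```

smkinetics analyzes two-color single-molecule TIRF experiments in which a
Cy3B-labeled primer-template DNA is tethered to a surface and visited by a
Cy5-labeled DNA polymerase, under 200 ms alternating-laser excitation
(ALEX). Two assay geometries are supported: a *colocalization* geometry,
where the donor dye sits far from the primer-template junction and
polymerase visits are read out as intensity bursts in the acceptor
channel, and a *FRET* geometry, where the donor sits 11 nucleotides from
the junction so that a bound polymerase produces a FRET efficiency of
about 0.6 that steps down by about 0.1 for every incorporated nucleotide.
Because raw bench data for such experiments are rarely portable, the
package pairs every analysis stage with a generative simulator whose
ground truths are the fitted kinetic constants of the study conditions,
so the full chain — imaging, corrections, event calling, fitting — can be
exercised and validated end to end.

## The generative model

Each simulated molecule is an independent DNA spot observed for a movie
of length `movie_length` (default 180 s, three minutes per field of
view) at one 200 ms excitation cycle per frame. Both emission channels
of a cycle share the cycle's timestamp; the per-channel alternative
(400 ms effective sampling) was considered and rejected because the
event-duration conventions downstream equate five frames with one
second, which only holds on the 200 ms cycle base.

**Binding.** A molecule is a *binder* with probability `bound_fraction`.
Binders wait an `Exponential(k_bind)` time for their first polymerase
arrival. In the colocalization simulator every binding lasts
`Exponential(tau_dwell)` and, after dissociation, the next arrival again
waits `Exponential(k_bind)` — first arrivals are the fitted quantity, so
rebinding only needs to exist, not to be separately parameterized. In
the FRET simulator each molecule hosts at most one productive binding:
the incorporation event consumes the primer, so a later rebinding could
not reproduce the starting FRET state.

**Incorporation.** While bound in the FRET geometry, the ideal
efficiency starts at `e_start` and decreases by `delta_e_per_nt` at each
of `n_nucleotides` incorporations; per-nucleotide waits are
`Exponential(t_incorporation / n_nucleotides)`, making the total
incorporation time an Erlang sum with mean `t_incorporation`. After the
last incorporation the polymerase dissociates after an
`Exponential(tau_dwell)` residual dwell. Incorporation is irreversible:
the ideal E never increases within a bound period.

**Photophysics.** Ideal channel means while bound are
`F_DD = (1 - E) * photon_budget` and
`F_DA_ideal = gamma * E * photon_budget`, so that
`F_DD + F_DA_ideal / gamma` equals the photon budget exactly — the
conservation law the tests assert. The recorded FRET channel is
distorted as

```
F_DA = F_DA_ideal + leakage * F_DD + direct_excitation * F_AA
```

before shot noise. `F_AA` is constant at the photon budget while the
acceptor is present. Each dye bleaches in a single exponential step;
acceptor bleach dequenches the donor, donor bleach silences `F_DD` and
the FRET pathway. Defaults: leakage 0.1, direct excitation 0.05, gamma
1.2, photon budget 500 (FRET) or 200 (colocalization), background 10
photons/frame/channel — an order of magnitude below the 50-photon event
threshold — and bleach lifetimes of 600 s per dye, typical of Cy3B/Cy5
under PCA/PCD oxygen scavenging with a redox pair, which keeps
truncation of few-second events below ten percent.

**Camera integration.** Counts are occupancy-weighted averages over each
exposure, then Poisson-sampled: a camera integrates photons over the
full 200 ms, so a dwell that covers half a frame contributes half its
photons to it. This matters quantitatively — point-sampling at frame
instants loses roughly twice as many sub-two-frame binding events,
biasing the observed binding rate low. The price is that frames
straddling a state change hold intermediate values; exactness claims
(noiseless staircase recovery) therefore apply to frames fully inside
constant-E segments, which the tests select via the ground-truth event
list.

With `noise = FALSE` the simulators return exact expected counts with
zero background, which the closure and inversion tests rely on.

What the generator deliberately does not emulate: dye blinking (the
upstream analysis removes bleaching rather than modeling blinking),
diffusing background particles, stage drift during an acquisition
(drift is exercised separately in the imaging tests), non-Poisson camera
noise (EMCCD excess noise would only rescale the photon budget), and
sequence-dependent incorporation pausing. Passing tests therefore show
that the analysis chain recovers known kinetics from data with correct
first-order photophysics — not that it is robust to every pathology of
real movies.

## Imaging stages

The minimal imaging pipeline mirrors the four stages named for the
upstream automated tool: camera alignment, drift correction, spot
detection, and local background-corrected intensity extraction.

* **Spot detection** finds strict local maxima above an intensity floor,
  refines them to sub-pixel positions by background-subtracted
  centroiding, and filters on mask circularity and nearest-neighbor
  distance (both members of a too-close pair are discarded — neither
  intensity can be attributed cleanly). Circularity is
  `4 * pi * area / perimeter^2` on the half-maximum mask with the
  taxicab perimeter corrected by `pi / 4`; a pixelated boundary
  overestimates a smooth perimeter by `4 / pi`, and without the
  correction a perfect disc would score ~0.62 and the conventional 0.7
  threshold would reject everything. Defaults (minimum circularity 0.7,
  nearest-neighbor distance 5 px, colocalization distance 2 px ≈ one
  PSF sigma) are package choices: the upstream description names the
  criteria but not the values.
* **Registration** is a least-squares affine fit to at least three
  non-collinear fiducial pairs, with the RMS residual reported.
* **Drift** is measured per frame by FFT cross-correlation against a
  reference (default: pixelwise temporal median of the first ten
  frames), with parabolic sub-pixel refinement of the correlation peak.
* **Extraction** sums a 3 px disc and subtracts the median level of a
  5–7 px annulus times the disc area; the median keeps a neighboring
  spot in the annulus from biasing the background.

## FRET corrections

The standard ALEX sequence is applied per frame: leakage and direct
excitation are subtracted first, then gamma weights the donor in the
denominator,

```
F_corr = F_DA - l * F_DD - d * F_AA
E      = F_corr / (F_corr + gamma * F_DD)
```

Frames at or after a detected photobleaching step in either dye channel
are marked invalid and excluded (not imputed). Bleach steps are found by
maximizing the two-segment between-group sum of squares and accepted
only when the post-step mean falls inside the shot-noise band around the
camera background and the step height exceeds three shot-noise standard
deviations — the latter guard keeps flat background traces from
producing spurious changepoints.

The upstream description applies these corrections but does not say how
the factors were obtained; `estimate_factors()` implements the standard
single-species calibration (leakage from donor-only molecules, direct
excitation from acceptor-only molecules) and estimates gamma from
acceptor-bleach transitions, falling back to 1.0 with a warning when
fewer than five usable transitions exist. Calibration ratios require the
camera background to be subtracted first; the `background` argument
exists because a 10-photon offset on a 500-photon signal would otherwise
bias the leakage estimate by several points.

## Event calling

**Colocalization events** are maximal runs of frames above the 50-photon
acceptor threshold. Runs separated by fewer than three sub-threshold
frames are merged — the "at least three frames between successive
events" separation rule read as a merge rather than a discard, which
preserves dwell mass when shot noise drops a single frame below
threshold mid-event. Merged runs shorter than two frames are discarded.
An independent brute-force scanner reimplements these rules naively and
the test suite requires exact agreement on a thousand random traces.

**FRET events** are maximal runs of valid frames with E in the
quantitative window [0.3, 0.8] (the linear range of the dye pair), at
least five frames (1 s) long, shorter than 20 s, and with a strictly
negative ordinary-least-squares slope of E versus time. The same
three-frame merge rule is applied to out-of-window gaps: at the study
design point the staircase passes through a level at exactly 0.3, where
shot noise puts every other frame below the window floor, and without
merging the caller fragments one incorporation event into pieces,
biasing the recovered dwell about 20% low. Because the substrate is
single-turnover, the default keeps only the earliest qualifying event
per molecule (`events_per_molecule = "first"`); residual in-window
excursions after the real event are level-noise artifacts, and at the
three-incorporation design point they would otherwise contribute
near-zero FRET-change values to the magnitude histogram.

**Measuring the FRET decrease.** The magnitude `delta_e` supports three
estimators. The literal endpoint reading, `E(first) - E(last)` of the
in-window run, cannot exceed the window height: a four-nucleotide event
starting at 0.6 ends at 0.2, below the window floor, so the endpoint
reading saturates near 0.3 while the physical decrease is 0.4 — the
published per-condition magnitudes are only consistent with a measure
that reaches the terminal level. The default `"plateau"` method
therefore measures from a robust start level (the maximum of the first
three run frames — the staircase top may be visible for a single frame
when the first incorporation is fast, and the run's entry frame is a
partial-occupancy transition) down to the terminal level, estimated as
the median of the valid post-run frames while the trace still shows
signal (E above 0.1). When the terminal level sits below the window
floor, the event end is also refined to the point where the trace
settles at that level, removing the early-termination bias of the
window rule. With no usable plateau (immediate dissociation, bleach, or
movie end) the method falls back to robust endpoints. `"endpoint"` and
`"fit"` (drop of the OLS line) remain available, and the
endpoint-method caller is the one checked against the brute-force
oracle.

## Fitting

* **Binding.** The observed binding rate and bound fraction come from
  first binding times with right censoring at the window end. The
  default estimator maximizes the censored-mixture likelihood (a
  molecule binds at all with probability A, then at `Exponential(k)`);
  the classical least-squares fit of the empirical cumulative
  fraction-bound curve to `A(1 - exp(-k t))` is retained as
  `method = "ls"` and both estimates are always reported. The MLE is
  preferred because a 180 s window spans only ~1.8 time constants at
  k = 0.01 s⁻¹, where the curve fit must extrapolate the plateau and
  becomes visibly biased. A saturation warning fires when essentially
  all events fall in the first frame.
* **Dwells.** The primary dwell estimator is the left-truncated
  exponential MLE, `tau = mean(d) - cutoff`, with the cutoff set to the
  detection minimum (two frames, 0.4 s, for colocalization dwells).
  Incorporation dwells are fitted with cutoff 0: the total
  incorporation time is an Erlang sum, not exponential at zero, and the
  five-frame minimum removes under 2% of its mass at the study
  conditions, so the exponential truncation correction would
  overcorrect by ~20%. A histogram least-squares mode with
  Freedman–Diaconis bins reproduces the classical procedure; the 20 s
  upper cutoff is treated as outlier rejection, not as right truncation
  in the likelihood.
* **FRET-change magnitude.** Gaussian MLE (sample mean and SD), with a
  binned mode available; the mean divided by the 0.1-per-nucleotide
  calibration step gives the average number of nucleotides incorporated.
* **Standard errors** are analytic where exact (exponential, Gaussian)
  and otherwise come from a seeded nonparametric bootstrap (default 200
  resamples for the slower curve fits, 1000 for the cheap ones).
* **Binding isotherms.** MST-style titrations are fit to the 1:1 model
  with ligand depletion; the quadratic mass balance is evaluated in the
  conjugate form `2L / (s + sqrt(s^2 - 4LT))`, which is numerically
  stable and reproduces the hyperbolic limit exactly as the target
  concentration vanishes. The response maps linearly between free and
  bound levels, a documented substitute for the vendor normalization,
  and is sign-agnostic. The default series is the 19-point two-fold
  dilution from 200 µM (down to ~0.763 nM).
* **Gel lanes.** Four-box quantification divides each species box by the
  whole lane; the residual is reported so fractions always sum to one.
  Mean extension uses representative counts 0 / 3 / 10.5 per box — bin
  midpoints, since the source does not state how a mean was formed from
  three bins.

## Problem sizes and determinism

The shipped condition fixtures simulate 500 molecules (colocalization)
or 300 molecules (FRET) over 180 s movies — the sizes at which the
recovery tests run, chosen so the whole suite completes in about two
minutes while leaving every recovered parameter's sampling error well
inside the 15% recovery band. All randomness flows from scenario seeds;
`run_pipeline()` fans a single configuration seed out to per-condition
child seeds (`derive_seed()`), so a rerun reproduces its results JSON
byte for byte while stages remain independently rerunnable.

## Known limitations

* The stated event rules cap what is observable: incorporation steps
  faster than one 200 ms frame blur into transition frames, so the
  recovered FRET-change magnitude is mildly biased low (~0.03 at the
  four-nucleotide design point) however the start level is estimated.
* A level sitting exactly on the 0.3 window floor is intrinsically
  knife-edged; the merge rule and plateau refinement remove most, not
  all, of the resulting truncation.
* The bound-fraction/rate pair is weakly identified when the window
  covers few binding time constants; at k = 0.01 s⁻¹ and 180 s the MLE
  still carries ~12% relative standard error at 500 molecules. This is
  a property of the design, not the estimator.
* `detect_bleach()` fits a single changepoint per channel; a trace with
  two genuine steps (e.g. acceptor bleach followed by donor bleach in
  `F_DD`) reports only the dominant one.
* The gamma calibration needs acceptor-bleach transitions within bound,
  otherwise-stable stretches; with long-lived dyes and short movies it
  falls back to 1.0 rather than guessing.
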
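# unwindr

Simulation and analysis of helicase DNA-unwinding kinetics at
strand-specific protein barriers.

Replicative helicases like CMG unwind DNA by steric exclusion: the motor
tracks the leading-strand template and excludes the lagging strand. A
protein block on the leading strand arrests the helicase; a block on the
lagging strand is either bypassed freely or — when the protein stabilizes
the duplex, as a covalently trapped methyltransferase does — induces a
transient pause. `unwindr` is for researchers quantifying this behaviour
from the two standard assays:

* **ensemble fluorescence unwinding curves** (quencher-release,
  single-turnover), analyzed with the m-step sequential kinetic model

  $$f_{ss}(t) = 1 - \sum_{r=1}^{m} \frac{(k_{obs}t)^{r-1}}{(r-1)!}\,
  e^{-k_{obs}t}$$

  (the Erlang(m, k_obs) completion-time CDF; `m = 2` by default), with
  `k_obs` fitting, model-based normalization, and barrier-induced delay
  estimation as a difference of interpolated half-unwinding times;

* **single-molecule RPA-accumulation traces** from surface-tethered
  substrates: completion (signal-drop) detection, intensity-to-bp
  calibration, pause calling near a barrier with a 30-s discernibility
  threshold and a 1 bp/s rate floor, fork-rate estimation with pauses
  excised, truncation-corrected exponential fits of pause durations, and
  population summaries (fractions paused / stalled / completed).

A stochastic simulator (`simulate_trace()`, `simulate_ensemble()`)
generates traces and curves with the statistical structure the analyses
assume — population rate spread 8.2 ± 4.2 bp/s, exponential pauses (mean
4.63 min) at a lagging-strand duplex-stabilizing block 800 bp into a
2.7-kb substrate, permanent arrest at a leading-strand block, partial
barrier occupancy, completion-triggered signal drop — so every estimator
is validated by parameter recovery against a known truth channel. A
band-intensity module (`band_fraction()`, `percent_unwound_series()`)
covers gel densitometry arithmetic.

## Worked example

Simulate 420 molecules on a lagging-strand methyltransferase-blocked
substrate and run the full pipeline:

```r
library(unwindr)

trs <- simulate_traces(helicase_params(), barrier_mh_lag(), 420,
                       sim_config(), seed = 42)
an  <- analyze_traces(trs, substrate_length_bp = 2700,
                      barrier = barrier_mh_lag())
an$summary
#> population of 420 molecules
#>   completed : 98.3%   stalled: 0.0%   ambiguous: 1.7%
#>   paused    : 21.9%
#>   rate      : 8.18 +/- 3.40 bp/s (n = 413 fully unwound)
#>   pauses    : mean 5.10 +/- 0.53 min (n = 92)
```

The recovered mean fork rate (8.18 bp/s) matches the configured
population mean (8.2 bp/s); 21.9% of molecules show a discernible
(>30 s) pause near the barrier — the observable fraction implied by a
29% underlying pause probability once sub-threshold and sub-noise pauses
are excluded — and the pooled truncation-corrected exponential fit
returns the pause mean (5.10 ± 0.53 min against a configured 4.63 min).

Fit an ensemble curve:

```r
cv <- simulate_ensemble(helicase_params(k_obs = 0.35), NULL, 2000,
                        sim_config(duration_s = 1800),
                        noise_sd = 0.02, seed = 1)
fit_kobs(cv, m = 2)
#> m-step kinetic fit (m = 2)
#>   k_obs      : 0.3453 +/- 0.0031 /min
#>   amplitude  : 0.9923   baseline: 0.006976
#>   residual   : 0.0202 (rms, normalized scale)
```

See the vignette (`vignettes/helicase-unwinding-kinetics.Rmd`) for the
model, the detection limits of pause calling, and all design choices.

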
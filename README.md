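# rnaptransit

Analysis and simulation of RNA polymerase transit through protein
roadblocks, from single-molecule tether-extension records.

During transcription elongation, an *E. coli* elongation complex (EC) that
runs into a DNA-bound protein — a *lac* repressor bound at an operator, or
a cleavage-deficient EcoRI — pauses until it gets past. It can transit
**passively**, waiting for the roadblock to dissociate on its own (rate
`k3`), or **actively**, executing cycles of backtracking (rate `k1`) and
recovery (rate `k2`, stimulated by the transcript-cleavage factor GreA)
that ram the EC into the roadblock with a probability `P1` of dislodging it
per encounter. The effective pathway rates are

```
k_passive = k3          k_active = k1 / (1 + k1/k2) = 1 / (1/k1 + 1/k2)
```

and their ratio separates three regimes (passive, hybrid, active) with
qualitatively different — and experimentally observed — responses to force
direction and GreA.

The package provides, as separately usable modules:

- **kinetics**: a discrete-time (1 s) six-state kinetic Monte Carlo
  simulator of the pause at a roadblock (`simulate_ensemble()`,
  `generate_pause_sample()`), closed-form pathway rates (`k_active()`,
  `k_passive()`), a Michaelis–Menten GreA model (`grea_adjusted_k2()`), a
  regime classifier (`classify_regime()`), and a deliberately naive
  line-by-line reference implementation used as an independent oracle;
- **step detection**: exact minimisation of the total-variation step cost
  `sum (y - yhat)^2 + lambda * sum |yhat_{i+1} - yhat_i|` on noisy
  extension traces (`fit_steps()`), with robust noise estimation and an
  automatic penalty;
- **alignment**: dwell-time histograms and per-bead linear rescaling
  against promoter / roadblock / terminator landmarks
  (`dwell_histogram()`, `optimize_scale()`, `apply_scale()`);
- **pause analysis**: roadblock pause extraction with the ±20 nm (60 bp)
  window and 20 s threshold (`extract_pauses()`), Kaplan–Meier CCDFs,
  right-censored exponential and two-exponential mixture fits with
  bootstrap CIs (`fit_exp_single()`, `fit_exp_double()`,
  `select_model()`), and passage fractions with Wilson intervals;
- **model fitting**: simulation-based fitting of the kinetic parameters to
  condition-grouped pause-time distributions with common random numbers
  (`fit_global()`), per-condition Welch adequacy tests, and qualitative
  regime reports (`regime_report()`);
- **synthetic data**: a trace generator with full ground-truth annotations
  (`generate_trace()`, `generate_cohort()`) and an end-to-end pipeline
  (`run_pipeline()`), used to validate every stage round-trip.

## Worked example

Simulate a small two-condition cohort of synthetic tether-extension
records, then run the full analysis chain (step fit → align → extract →
censored exponential fit):

```r
library(rnaptransit)

rows <- list(
  list(label = "opposing_Gre0", n_traces = 8,
       condition = condition("LacI-O1", "opposing", 0.2, grea_uM = 0),
       params = kinetic_params(k1 = 0.02, k2 = 0.002, k3 = 0.02, p1 = 0.05),
       gen = trace_gen_config(noise_sd = 3, obs_window = 1800)),
  list(label = "assisting_Gre0", n_traces = 8,
       condition = condition("LacI-O1", "assisting", 0.2, grea_uM = 0),
       params = kinetic_params(k1 = 0, k2 = 0.002, k3 = 0.02, p1 = 0.05),
       gen = trace_gen_config(noise_sd = 3, obs_window = 1800)))

rep <- run_pipeline(run_config(rows, master_seed = 11))
print(rep)
#> Pipeline report (config 19fd406e)
#>   16 traces -> 13 roadblock pauses
#>   opposing_Gre0: tau = 88.3 s [42.3, 145.9], model: single
#>   assisting_Gre0: tau = 102.8 s [45.1, 179.3], model: single
```

Thirteen of the sixteen traces yielded a roadblock-classified pause (the
rest paused for less than the 20 s threshold); each condition's pause
lifetime `tau` is the censored maximum-likelihood estimate with a 90%
parametric-bootstrap interval. The generating parameters put this
roadblock in the passive regime, where assisting and opposing force give
similar lifetimes unless backtracking goes unrescued:

```r
p <- kinetic_params(k1 = 0.02, k2 = 0.002, k3 = 0.02, p1 = 0.05)
classify_regime(p)
#> Transit regime: passive (k_active/k_passive = 0.0909091)
simulate_ensemble(p, 10000, seed = 1)
#> Transit ensemble: 10000 trajectories
#>   mean pause 262.9 s | transit 100.0% | censored 0.0% | dislodged 4.8% | mean cycles 0.47
```

The opposing-force mean (263 s) is far above the ~50 s of the
corresponding assisting-force model (`k1 = 0`): with slow recovery, every
backtrack costs ~500 s, which is exactly the long-tailed
(double-exponential) signature the passive regime predicts for the
opposing / no-GreA condition.

## Command line

A thin CLI wraps the main stages (see `inst/exec/rnaptransit`):

```sh
rnaptransit simulate-pauses --k1 0.02 --k2 0.01 --k3 0.01 --p1 0.1 \
    --n 1000 --seed 1 --obs-window 1800 --out sample.tsv
rnaptransit detect-steps --in trace.tsv --lambda auto --out stepped.tsv
rnaptransit extract-pauses --in aligned.tsv --operator-bp 709 --out records.tsv
rnaptransit fit-exp --in records.tsv --model auto --out fit.json
```

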
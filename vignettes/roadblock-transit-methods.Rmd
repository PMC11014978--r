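---
title: "Models and methods: RNA polymerase transit through protein roadblocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: RNA polymerase transit through protein roadblocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaptransit)
```

This vignette is the package's own account of the science it implements:
the kinetic model of roadblock transit and its discrete-time simulation,
the trace-analysis chain (step fitting, alignment, pause extraction), the
censored lifetime statistics, the simulation-based parameter fit, and —
importantly — the choices made where the design was genuinely open, what
the synthetic-data generator does and does not emulate, and the known
limitations. No empirical claim is made here that the test suite or the
acceptance script does not itself compute.

## 1. The six-state transit model

An elongation complex (EC) transcribing toward a DNA-bound roadblock
passes through six conceptual states: transcription before the encounter;
arrival at the roadblock; a backtracked state in which the RNA 3' end has
left the active site; a state in which the roadblock has dissociated
spontaneously; a "ramming" state in which an actively transcribing EC
presses on the roadblock; and transit past the roadblock. Two pathways
connect arrival to transit:

* the **passive** pathway — the EC waits, transcriptionally engaged, and
  proceeds when the roadblock dissociates (rate $k_3$); its effective rate
  is $k_\mathrm{passive} = k_3$;
* the **active / reciprocating** pathway — the EC backtracks (rate
  $k_1$), recovers (rate $k_2$), and rams the roadblock, dislodging it
  with probability $P_1$ per encounter; one backtrack–recovery cycle takes
  $1/k_1 + 1/k_2$ on average, so the cycling rate is
  $k_\mathrm{active} = k_1/(1 + k_1/k_2)$.

The ratio $k_\mathrm{active}/k_\mathrm{passive}$ defines three regimes
(`classify_regime()`, thresholds 0.1 and 10 by default — the thresholds
are a classifier convention, not physics; the regimes' defining behaviours
are reproduced far from the boundaries). GreA rescues backtracked ECs by
stimulating transcript cleavage; it enters the model exclusively through
the recovery rate via a Michaelis–Menten form
$k_2(G) = k_{2,\mathrm{basal}} + k_{2,\mathrm{cat}}\,G/(K_m + G)$
(`grea_adjusted_k2()`). Force direction enters through backtracking:
assisting force prevents it ($k_1 = 0$), opposing or zero force permits
it; force *magnitude* (0.2–5 pN) has no effect in the model, mirroring
the experimental finding that direction, not magnitude, matters.

### Discrete-time dynamics

The simulator (`simulate_single()`, `simulate_ensemble()`) is a literal
discrete-time walk with step $\Delta t = 1$ s, capped at
$t_\mathrm{max} = 5000$ s. Per step, in order: a bound roadblock
dissociates with probability $1 - e^{-k_3 \Delta t}$; then the EC state
updates (pre-encounter → ramming; at-roadblock → backtracked with
probability $1 - e^{-k_1 \Delta t}$ while the roadblock is bound,
otherwise transit; backtracked → ramming with probability
$1 - e^{-k_2 \Delta t}$; ramming → transit with probability $P_1$ while
bound — falling back to the at-roadblock state on failure — or transit
unconditionally once the roadblock is gone); then time advances. Three
consequences of taking the update rules as printed:

* every pause lasts at least $2\Delta t$ (the walk needs one step to reach
  the ramming state and one to leave it), so with $P_1 = 1$ all pauses are
  exactly 2 s — an analytic corner the tests pin;
* the first dislodging attempt happens at $t = 2\Delta t$, on first
  contact, with the same $P_1$ as post-recovery attempts;
* in the limit $k_1 = 0,\ P_1 = 0$ the walk reduces to two mandatory steps
  plus a geometric wait, with mean
  $2\Delta t + \Delta t (1-p)^2/p$, $p = 1 - e^{-k_3\Delta t}$
  (`passive_limit_mean()`); this closed form and a deliberately naive
  line-by-line R transcription of the update rules
  (`simulate_single_reference()`) are the simulator's two independent
  oracles.

Results are reported as $\Delta t$-dependent by design; no continuous-time
(Gillespie) variant is attempted. A roadblock, once dissociated, never
re-binds (supported experimentally by heparin controls). Trajectories
still at the roadblock at $t_\mathrm{max}$, or at the observation window
in `generate_pause_sample()`, are right-censored ("indefinitely
stalled").

The compiled simulator draws from counter-based per-trajectory streams
(a splitmix64 hash of master seed and trajectory index), so ensembles are
reproducible, order-independent, and reusable as common random numbers
across objective evaluations during fitting. The reference implementation
deliberately uses R's own RNG instead — the two implementations share no
random-number machinery, which is what makes their distributional
agreement (two-sample KS) an informative check.

## 2. Step fitting: exact total-variation denoising

Tether-extension records are piecewise-flat with sharp jumps, blurred by
Gaussian tracking noise. `fit_steps()` minimises
$$\sum_i (y_i - \hat y_i)^2 + \lambda \sum_i |\hat y_{i+1} - \hat y_i|$$
*exactly* — the cost function, not any particular published heuristic, is
the contract — using a dynamic program over clipped piecewise-quadratic
value functions (O(n)). Two independent oracles verify exactness in the
tests: exhaustive enumeration of all segmentations and jump-sign patterns
(each candidate has closed-form block means
$m_b = \bar y_b + \lambda(s_b - s_{b-1})/(2 w_b)$) for $n \le 12$, and
the dual box-constrained QP solved by L-BFGS-B for longer series.

Numerical notes:

* $\lambda = 0$ reproduces the input; $\lambda$ beyond the
  total-variation budget returns the segment mean.
* Gap samples (NaN) contribute to neither term; maximal finite runs are
  fitted independently with no penalty across gaps (`split_on_gaps()`).
* The exact minimiser *shrinks*: boundary blocks move by
  $\lambda/(2w)$ toward their neighbours, and refitting shrinks again, so
  level-wise idempotence is impossible in principle. What is preserved
  under refitting — and what the tests assert — is the breakpoint
  structure and monotonicity on monotone staircases.

**Penalty selection** is not specified by the source method, so the
package uses a universal-threshold form
$\lambda = c\,\hat\sigma\sqrt{2\ln n}$ with
$\hat\sigma = \mathrm{mad}(\Delta y)/\sqrt 2$ (`estimate_noise()`,
`default_lambda()`). The multiplier was fixed once by a calibration
experiment on synthetic staircases (steps of $\ge 3\hat\sigma$, dwell
60 s): $c \in [0.75, 2]$ recovered $\ge 95\%$ of true steps within two
samples with essentially no spurious steps, and $c = 1$ — the plain
universal threshold — was adopted. (The spec's paraphrase of the noise
estimator, "MAD ÷ 1.4826√2", is dimensionally inconsistent for a raw MAD
and would fail its own Monte-Carlo check; the standard
Gaussian-consistent form above is what the package implements and what
that check validates.)

## 3. Alignment: dwell histograms and the expansion factor

Bead-to-bead variation in size and magnetisation scales each record by an
unknown factor. Each stepped trace is converted to a dwell-time histogram
(1 nm bins by default; each sample deposits its 1 s into the bin of its
fitted level, so total dwell is conserved exactly), and a grid search
over the expansion factor $a$ (step 0.001) maximises the dwell captured
near the landmark positions — promoter, operator, terminator — with the
shift $b$ fixed at 0 because the transcription start pins the origin. A
joint $(a, b)$ search remains available behind a flag.

Two deliberate departures from a literal reading of the source
procedure, both recorded in the decisions ledger:

* **Objective kernel.** "Maximum pause durations at the landmark
  positions" is not a formula. A hard ±20 nm window makes the objective
  *flat* over a ±5–10% range of $a$ (any $a$ that keeps the three peaks
  inside their windows captures the same dwell), which is incompatible
  with sub-1% recovery of $a$. The package therefore weights each dwell
  contribution by a triangular kernel $1 - |x - \ell|/w$ over the same
  window, which is maximised exactly when the peaks sit *on* the
  landmarks. With this kernel the median $|a \cdot a_\mathrm{true} - 1|$
  across synthetic beads is a few parts in $10^4$.
* **Search range.** The generator applies
  $\mathrm{extension} = a_\mathrm{true}\cdot\mathrm{nm/bp}\cdot\mathrm{position}$
  with $a_\mathrm{true} \in [0.75, 1]$, so the *recovered* factor is
  $1/a_\mathrm{true} \in [1, 1.33]$; the default search range
  $[0.70, 1.40]$ covers both that range and the experimentally reported
  $[0.75, 1]$ with margin.

`apply_scale()` then maps levels to template coordinates in bp (origin at
the transcription start, increasing in the direction of transcription;
opposing-force records, whose extension decreases, are sign-flipped), with
1 bp = 1/3 nm by default so that ±20 nm is exactly ±60 bp. The B-DNA rise
(0.34 nm/bp) can be substituted.

## 4. Pause extraction and censored lifetime statistics

A roadblock-associated pause is dwell at fitted levels within ±60 bp of
the operator lasting at least 20 s; shorter dwell is classified
ubiquitous and excluded. Because the EC *transits* the 120 bp window in
~12 s at typical velocities, counting all in-window samples would inflate
every duration by the transit time; the extraction rule is therefore:

1. sub-steps with dwell ≥ 5 s inside the window are pause components
   (1–3 s steps are ordinary transit);
2. successive components merge into one pause when their levels agree
   within 9 bp (backtracking excursions and step-fit plateau wiggle stay
   within a few bp; transit moves 10 bp per sample at the default
   velocity) and only brief in-window steps separate them;
3. the pause spans first-to-last component, including short interior
   wiggle runs, and extends outward over adjacent short runs whose level
   stays within 9 bp of the pause level (step-fit corner fragments);
4. a pause reaching the end of the record is right-censored
   (`stalled_censored`), or may be labelled `terminated_at_roadblock` for
   high-salt EC dissociation; both count as non-passage in
   `passage_fraction()` (Wilson 95% interval).

The 5 s and 9 bp constants were fixed once by the round-trip calibration
experiment (generate → fit → align → extract at 2 nm noise; ≥ 95% of
≥ 20 s injected pauses recovered within 2 s) and are arguments, not
magic numbers. Residual duration error is dominated by the step fit's
corner rounding where the gentle approach ramp meets the plateau, and is
±1–2 s at 2 nm noise; at 4 nm noise it can exceed 2 s, which is why the
round-trip guarantee is stated for noise ≤ 2 nm.

**CCDFs** (fraction of pauses longer than $t$) use the Kaplan–Meier
estimator by default — censored pauses stay in the at-risk set up to
their censoring time — with simple truncation (dropping censored records,
as in the "excluding indefinite stalls" panels) available as an
alternative; both modes are exposed throughout, with `drop_censored()`
reproducing the truncation analyses.

**Exponential fits.** The censored single-exponential MLE has the closed
form $\hat\tau = (\text{total observed time})/(\text{number of events})$;
its 90% interval is a seeded parametric bootstrap (1000 resamples drawn
from $\mathrm{Exp}(\hat\tau)$, re-censored by the sample's own censoring
scheme — the bootstrap method is a package choice, the source states
none). Calibration: over 500 synthetic samples ($n = 50$, $\tau = 150$)
the interval covers the truth ~90% of the time. The two-component
mixture (`fit_exp_double()`) is a censored EM with expected-residual-life
M-steps and ≥ 5 seeded starts; components are reported fast-first, and
degenerate convergence (weight at 0/1, or components within 5%) falls
back to the single model. `select_model()` compares by AIC with ties to
the simpler model. A least-squares-on-CCDF route would be a legitimate
alternative backend; on uncensored synthetic data the MLE and the CCDF
least-squares estimate agree to well within 10%, which is why the MLE is
the sole default.

## 5. Simulation-based model fitting

`fit_global()` fits, per roadblock, the parameter set
$(k_1, k_{2,\mathrm{Gre}-}, k_{2,\mathrm{Gre}+}, k_3, P_1)$ shared across
that roadblock's conditions under the map: assisting force ⇒ $k_1 = 0$;
GreA acts only on $k_2$; force magnitude is excluded from the
parameterisation. With a single GreA concentration per dataset the two
Michaelis–Menten constants are not separable, so the GreA+ recovery rate
is fitted directly as a second $k_2$.

The discrepancy per condition (`distribution_distance()`) is the
two-sample KS statistic on uncensored durations — scale-free, which
matters when conditions differ in lifetime by an order of magnitude —
plus a squared difference of censored ("indefinitely stalled")
fractions; the experimental 20 s threshold is applied to the *simulated*
durations first, for like-with-like comparison. A binned χ² would be the
natural alternative; KS was chosen to avoid bin-width tuning. The search
is a coarse log-grid scan followed by Nelder–Mead on
$(\log k_1, \log k_2, \log\Delta k_2, \log k_3, \mathrm{logit} P_1)$,
with one fixed master seed supplying common random numbers to every
objective evaluation (the objective is then deterministic and the simplex
is not chasing Monte Carlo noise). Conditions are canonically ordered
internally, so the fit is invariant to input order.

Adequacy is reported per condition as a two-sided Welch $t$-test between
uncensored simulated and observed durations — the test operates on
durations, not binned CCDFs, a stated interpretation choice. Parameter
recovery on synthetic four-condition datasets (200 pauses each)
identifies the generating regime in ≥ 9/10 seeded replicates for all
three regimes, with $k_3$ typically within 25%.

`regime_report()` turns a fit into the qualitative predictions that
distinguish the regimes: in the passive regime, opposing/GreA− pauses are
much longer than the other three (similar) conditions and the
opposing/GreA− distribution prefers a double exponential — two stochastic
clocks, roadblock dissociation and backtrack recovery, with distinct
rates; in the hybrid regime opposing/GreA− > assisting > opposing/GreA+;
in the active regime opposing force *shortens* pauses relative to
assisting and GreA shortens them further. The packaged
`regime_example_params()` sets place the model at rate ratios of ~0.09,
~1 and ~50 respectively; these are illustrative stated-world values (the
fitted values for the actual roadblocks live in supplementary material
that is not part of this package's inputs).

## 6. The synthetic-data generator: what it emulates, and what not

`generate_trace()` builds a record the analysis chain should succeed on
*if and only if it is correct*: monotone latent progress at 10 bp/s
(elongation velocity is unstated in the source; it affects only synthetic
data, never inference), a 180 s pre-NTP promoter dwell, Poisson
ubiquitous pauses (1 per 200 bp, 3 s exponential mean), one roadblock
pause at the operator drawn from the kinetic model and censored by the
remaining observation window (1800 s for LacI-O1/O2, 3600 s otherwise), a
terminal dwell at the terminator, a per-bead scale factor, Gaussian noise
(4 nm default), and optional NaN gaps at NTP addition. All ground truth is
annotated, and cohorts are bit-reproducible from a master seed.

Deliberate idealisations — hence what a green round-trip test does *not*
establish:

* **No ubiquitous pause within ±30 bp of the operator.** A short pause
  immediately adjacent to the roadblock pause is physically merged into
  the roadblock-region dwell and no analysis could separate them; at the
  stated pause rate such events alone would exceed the round-trip
  criterion's failure budget. The generator therefore keeps the injected
  pause identifiable (configurable via `rb_exclusion_bp`), which mirrors
  the experimental classification in which all near-operator dwell *is*
  the roadblock pause. Real records do not enjoy this guarantee.
* One roadblock pause per trace, no re-binding (heparin-control
  justified), no torsion, no force–extension nonlinearity, no drift, no
  bead-tracking artefacts beyond i.i.d. Gaussian noise and clean gaps.
* The sampling rate is 1 s, matching the simulator's $\Delta t$; sub-second
  pause structure is invisible by construction.

## 7. Determinism and seeds

Every stochastic stage takes an explicit seed; the pipeline derives
per-trace and per-stage seeds deterministically from one master seed
(`run_config()`), records the seed and a canonical-JSON MD5 hash of the
configuration in every output, and restores R's global RNG state after
internal seeded sections. Re-running a configuration is bit-identical.

## 8. Known limitations

* Pause durations are resolved to the 1 s sampling grid; durations and
  their errors below ~2 samples are not meaningful.
* The step fit's corner rounding biases very short pauses (tens of
  seconds) by a sample or two where the ramp meets the plateau; lifetime
  estimates, which are dominated by long pauses, are insensitive to this.
* `fit_global()` explores a 5-parameter space with a coarse grid plus
  local refinement; it recovers regimes reliably, but individual
  parameters — especially $P_1$ and the split between $k_1$ and $k_2$ —
  can trade off against each other at realistic sample sizes
  (identifiability, not optimisation, is the binding constraint).
* The t-max cap makes all moments $\Delta t$- and cap-dependent in the
  active/assisting corner where most trajectories censor.
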
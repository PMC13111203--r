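---
title: "Models and methods behind perchtask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind perchtask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perchtask)
```

perchtask is a desk-scale implementation of a cued postural-perturbation
paradigm for mice: a head-free mouse stands bipedally on a perch, licks a
spout for water, and the behavioral box is translated backward for 200 ms,
either unpredictably or preceded by a 1-s tone. This vignette is the
package's own account of the models it implements, the free choices that
had to be made where the paradigm's published description leaves room, and
what the simulation-based validation does and does not establish.

## The task state machine

The rig is a three-state machine driven by licks (behavioral input) and
timers (virtual input):

* **INTERTRIAL.** After each trial, an inter-trial interval is drawn
  uniformly from 10–15 s, plus a 20-s penalty when the trial aborted. The
  LED turns on at the later of the interval end and 5 s after the last
  lick; any lick during the interval restarts that 5-s no-lick gate. The
  gate is implemented this way because a "refrain from licking for 5 s"
  rule is only enforceable as a sliding deadline.
* **READY.** The LED is on; the first lick starts the trial and is
  rewarded immediately (2 µL).
* **ACTIVE.** Every lick restarts a 600-ms lick-grace timer; a lick-free
  period *strictly* longer than 600 ms aborts the trial at
  `last lick + 600 ms`. Licks at least 1,100 ms after the previous reward
  are rewarded, which caps rewards at `1 + floor(7500 / 1100) = 7` per
  trial. The trial completes at exactly 7.5 s.

Simultaneous events at the same millisecond are resolved in a fixed order:
trial-max timer, then licks, then the lick-grace timer. Putting licks
ahead of the grace timer is deliberate: it makes a lick exactly at the
600-ms deadline keep the trial alive, which is the strict reading of
"a lick-free period of more than 600 ms ends the trial". The water timer
is not a stimulus; its ≥ 1,100-ms condition is evaluated whenever a lick
arrives. The clock is a discrete 1-ms tick and every configured duration
is an integer number of ticks.

### Trial types and scheduling

Trial types are CUE (74%), NOCUE (13%) and BLANK (13%), drawn
independently — except that a trial aborted *before its stimulus* is
repeated: before the cue onset for CUE trials, before the scheduled
perturbation onset for NOCUE trials. BLANK trials have no stimulus at
all, so a *virtual* perturbation onset is drawn for them exactly as for
real perturbations and the repetition rule is applied against it. This
keeps the rule total across types; the virtual onset is stored in the
trial record but never emitted as an event.

The perturbation is scheduled at the trial's first lick plus a delay from
an exponential distribution of mean 1 s *conditioned* on [2.5 s, 6 s],
sampled by inverse CDF. "Truncated" could in principle also mean a
shifted or rescaled law; conditioning is the standard reading and is what
the package implements. The conditional mean is

$$ a + m - \frac{(b-a)\,e^{-(b-a)/m}}{1 - e^{-(b-a)/m}} \approx 3.391
\text{ s} \quad (m = 1, a = 2.5, b = 6), $$

which the tests verify against numerical integration of the truncated
density. The delay clock does not pause if licking lapses: an abort
simply pre-empts the perturbation. A trial that aborts before its
scheduled onset receives no platform movement (this is what makes the
repetition rule observable); one that aborts during the 200-ms movement
still sees the platform finish, so `PERT_OFF` can fall after `TRIAL_END`.

### The platform profile

Only the displacement amplitude (7/12/18 mm), duration (200 ms) and peak
velocity (60/100/140 mm/s) of the translation are specified. The package
models the velocity waveform as a **symmetric trapezoid**, the unique
symmetric piecewise-linear profile consistent with all three printed
triples, with ramp time $t_r = T - A/v_p$ on each side. Feasibility
requires $v_pT/2 < A < v_pT$, and violations are reported naming the
violated bound. The displacement series is the exact closed-form integral
(not a numeric cumsum), so the terminal displacement equals the amplitude
to machine precision, and the time grid includes the two ramp kink times
so the peak velocity is always represented exactly. The return movement
(~57 mm/s, during the inter-trial interval) is recorded in the
configuration but not simulated kinematically.

## The virtual mouse

The synthetic agent exists so that every downstream stage is testable
without animal data. It emulates, with free parameters:

* **Licking** as a gamma renewal process (shape 10, mean 150 ms ≈ 7 Hz,
  the cadence of mouse licking). The paradigm itself never models
  licking; it only constrains it through the 600-ms window.
* **Trial initiation** latency (gamma, mean 1.5 s) that lengthens by
  15 ms per trial, emulating declining engagement across a session.
* **The perturbation-induced lick pause**, the behavioral core: at
  perturbation onset the agent stops licking for a lognormal duration
  whose log-location decreases by `cue_effect` on cued trials, by
  `session_effect` per session (learning across days) and by
  `trial_effect` per trial (negative by default, so pauses lengthen
  late in a session — fatigue). The trial survives iff licking resumes
  within the 600-ms grace window. This maps the lognormal pause onto a
  binary success through a threshold, so a target cue odds ratio has a
  closed-form calibration (`calibrate_cue_effect()`):
  $\delta = \sigma\,(\Phi^{-1}(p_1) - \Phi^{-1}(p_0))$ with
  $p_0 = \Phi((\log 600 - \mu)/\sigma)$ and $\mathrm{odds}(p_1) =
  \mathrm{OR} \cdot \mathrm{odds}(p_0)$.
* **The nose-distance response**: baseline ~18 mm plus white frame noise
  (SD 1 mm); after a latency drawn uniformly from 50–100 ms the distance
  rises (half-cosine) to a peak at the end of the 200-ms movement, then
  decays exponentially with a 350-ms constant, making recovery slower
  than the rise. Peak amplitudes are Gaussian (truncated at 0) around a
  linear law: 52 mm, minus 6.5 mm on cued trials, minus 2.5 mm per
  session, plus 0.12 mm per trial. These magnitudes were chosen once as
  realistic for the paradigm (tens of mm, cue benefit of several mm)
  and are what the linear-model recovery experiments treat as truth.
* **Tracking imperfections**: 1% of frames get likelihood < 0.9 and
  displaced coordinates, exercising the interpolation/flagging path. An
  optional anticipatory-crouch term (cue-period lowering of posture)
  exists but defaults to off, since the paradigm reports such
  pre-perturbation changes only anecdotally.

Pause and response amplitude are drawn independently; the paradigm
implies they are correlated but does not quantify it, and nothing
downstream depends on the coupling.

What the generator does **not** emulate: biomechanics (center of mass,
tail, limb kinematics), image-level tracking error structure (its noise
is white, real tracking error is autocorrelated and pose-dependent),
satiety-driven session termination (sessions are fixed-length; the
study's median 83 trials is the default), and manual aborts for
wrong-facing mice. Passing tests therefore establish that the *analysis
pipeline* is correct and well-calibrated under the stated generative
laws — not that real mice behave like the agent.

## Kinematic quantification

The pipeline order is fixed: likelihood handling → Euclidean nose–spout
distance → 450-px cap → baseline → onset exclusion → windowed summary.

* **Calibration** is a single isotropic 0.18 mm/px (450 px = 81 mm).
* **Cap before baseline**: the 450-px cap (81 mm) is applied to the raw
  distance, and the baseline (mean over 250–2,250 ms pre-onset) is
  computed from the capped trace.
* **Windows** are closed intervals on the 5-ms frame grid; the onset
  frame is the nearest frame at or after the perturbation onset. With an
  onset off the frame grid the baseline window holds exactly
  (2250 − 250)/5 = 400 frames.
* **Onset exclusion** tests the *raw* capped value at the onset frame
  against 225 px, strictly — the criterion describes a posture (ducking
  down), not a deviation from baseline.
* **The maximum nose distance** is computed on the baseline-subtracted
  capped trace over [onset, onset + 250 ms]. Whether the published
  maximum was taken on the raw or baseline-referenced trace is not
  stated; baseline-referenced is the default here because the baseline
  is explicitly "used for subtraction", and `raw = TRUE` restores the
  other reading. Mean, median and area-under-trace summaries are
  available over the same window.
* **Tracking flags**: sub-threshold likelihood runs of at most 10 frames
  are linearly interpolated; longer runs flag the trial (the study fixed
  such trials by manual annotation, which a simulator cannot do).

## Outcomes and session summaries

A trial is a **success** if at least one reward falls strictly after
`PERT_OFF`. The paradigm is described both as "after the perturbation"
and "after the end of the perturbation"; the end-referenced reading is
the default (`after = "onset"` switches). Session success proportions
carry Clopper–Pearson exact binomial intervals by default — "estimated
based on the binomial distribution" does not name a method, and the
exact interval is the conservative standard; Wilson is available by
flag. The sliding-window success uses a centered 10-trial window
(shrinking at the edges; the published window width is not stated).

## Mixed-effects models

Per animal, the package fits

$$ D = \beta_0 + \beta_{cue}\,cue + \beta_{trial}\,trial +
\beta_{session}\,session + u_{session} + \varepsilon $$

for the maximum nose distance (REML, via lme4) and the same fixed-effect
structure on the logit of success (Laplace, binomial). The written model
also includes $u_{trial(session)}$, a random intercept for trials nested
within session. With one observation per trial that term is confounded
with $\varepsilon$ in the linear model, so it is off by default and
`include_trial_re = TRUE` fits it with an automatic, warning-carrying
fallback when the variance collapses; for the logistic model an
observation-level intercept is statistically meaningful and is likewise
available but off by default. The trial index enters uncentered, so
coefficients read as per-trial multipliers, and the cue indicator is 0
for NOCUE and 1 for CUE.

Inference: the linear model reports Satterthwaite t-tests (via lmerTest)
rather than plain Wald z — with ~11 sessions the z approximation for
between-session effects is anticonservative, and the package's own null
calibration (below) requires honest type-I rates; the logistic model
reports Wald z and exponentiated coefficients with Wald 95% intervals.
No multiple-testing correction is applied. Convergence uses bobyqa with
up to 1e5 function evaluations; |coefficient| > 15 on the logit scale is
treated as complete separation and reported as such.

## Parameter recovery and calibration

`recovery_experiment()` simulates datasets at known truth, refits, and
tabulates bias, RMSE, CI coverage and rejection rates. Its default
generative route draws the per-trial table directly from the agent's
pause law (`simulate_trial_table()`): trial types, lognormal pauses,
success by the 600-ms threshold, and amplitudes from the linear law plus
a session random intercept (SD 3 mm) for the linear model. This is the
same law the event engine implements trial by trial — the direct route
exists because the implied logistic truth is exact there (the cue effect
is calibrated in closed form) and because it keeps 200-replicate
experiments inside minutes; cross-module tests verify at smaller sizes
that the engine route and the direct route agree in law.

The shipped validation uses 200 replicates of 11 sessions × 83 trials
(~800 perturbation trials, the study's scale): coverage of a true cue
odds ratio of 2.0 must be at least 90% (nominal 95%), and with all
amplitude effects zeroed the per-effect rejection rate must sit inside a
3-SE binomial band around 5%. Module tests run smaller designs (2–15
sessions, 10–80 trials) to stay fast.

## Numerical and degenerate-input choices

* One master seed spawns named Mersenne-Twister substreams (trial-type,
  delay, ITI, agent), so adding draws to one consumer never perturbs the
  others; identical (config, agent, seed) give byte-identical logs.
* Degenerate truncation bounds (`lo == hi`) return the bound exactly;
  infeasible profile triples and invalid probability vectors are errors,
  not warnings.
* Gamma/lognormal draws are rounded to the 1-ms tick with a 1-ms floor.
* An agent that never licks yields a session with zero trials and the
  LED left on, not an error.
* Empty baseline or summary windows flag the trial (missing video)
  rather than aborting the analysis.

## Known limitations

* The event engine is pure R; ~0.6 s per 83-trial session is fast enough
  for validation work but not for very large sweeps.
* The logistic truth under non-zero session/trial pause effects is not
  available in closed form, so coverage experiments calibrate those
  effects to zero.
* Synthetic pose tracks are 2D distances dressed as coordinates along a
  fixed direction; they exercise the format and the pipeline, not
  pose-estimation failure modes.
* The deposited-data benchmarks (per-animal cue coefficients) require
  downloading the archived dataset and exporting it to the package's
  trial-table schema; they are not reproducible offline.
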
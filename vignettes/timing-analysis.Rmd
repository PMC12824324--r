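---
title: "Dissociating clock distortion from motor slowing in rodent timing tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating clock distortion from motor slowing in rodent timing tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronobeh)
```

## The scientific problem

Drugs that slow an animal down pose an interpretive trap for interval-timing
experiments: a movement that lasts longer can reflect a distorted internal
clock (the animal misjudges time) or slowed motor execution (the animal knows
the time but moves slowly). `chronobeh` implements an analysis stack for three
behavioural preparations that, together, can dissociate the two accounts:

1. **Fixed-interval (peak-interval) schedule.** Two levers must be displaced
   simultaneously above 2.6 cm and held 750 ms; only the first such press
   30 s after the previous reward is rewarded. The distribution of presses
   across the 30 s interval indexes *perception* of elapsed time on the tens
   of seconds scale.
2. **Two-interval production schedule.** Holds of 1250 or 750 ms are required
   in alternating 20-trial blocks (sessions start with the longest). The
   produced hold indexes *production* of intervals at the hundreds of
   milliseconds scale. Because overshoot is measured against two different
   requirements, additive (motor) and proportional (timing) lengthening
   make different predictions (below).
3. **Treadmill spatiotemporal sequence.** A stereotyped front-back-front
   locomotor sequence must last at least 7 s before the animal re-enters a
   goal zone 10 cm from the front wall, across belt speeds of 27-33 cm/s.
   Sequence duration indexes timing; the peak speed of the final
   acceleration indexes motor capacity; the structure of the phases reveals
   compensatory strategies.

The package converts raw traces (250 samples/s lever positions; 100
samples/s treadmill positions) into events, trials, metrics and rank-based
statistics, and pairs the analysis side with a seeded generative simulator so
that every inference rule can be exercised, calibrated and falsified without
animal data.

## The dissociation logic

Let $m$ be the planned hold margin above the requirement $T$ (ms). Overshoot
is the time the levers stay pressed past reward; overshoot *fraction* is
overshoot divided by $T$ (150 ms is a fraction 0.2 of 750 ms but 0.12 of
1250 ms).

* Under **motor slowing**, dose adds a $T$-independent increment $\Delta$
  (a slowed release): fraction increments are $\Delta/750$ and
  $\Delta/1250$, whose ratio is $1250/750 \approx 1.67$.
* Under **timing scaling**, dose multiplies the produced interval by a
  factor $s$: fraction increments are both $\approx s$, ratio $1$.

`classify_production_mode()` pools the increments over all non-control doses
and thresholds the short-over-long ratio at the geometric midpoint
$\sqrt{1250/750} \approx 1.29$. On simulated cohorts of 8 sessions per dose
and 100 trials per session (the scale of a cohort of eight animals with two
injections per dose), the discriminator recovers the generative mode in 99
of 100 seeded runs in this package's acceptance suite.

## Generative models

The simulator is first-class, tested code: its defaults define the study
conditions under which the analysis stack is validated.

### Subjective time and the fixed-interval press model

Subjective time runs at `clock_gain` times objective time, so pressing
organised around a subjective 30 s target concentrates at objective
$t_{peak} = 30/\texttt{clock\_gain}$: a gain of 0.75 (slow clock) puts the
press-rate peak at 40 s, a gain above 1 (fast clock) pulls it before 30 s.
Presses are of two kinds:

* *checking presses* from an inhomogeneous Poisson process whose rate is a
  low baseline plus a Gaussian bump at $t_{peak}$ with scalar spread
  $\sigma = w\, t_{peak}$ ($w$ the Weber fraction), with a sustained floor
  after $t_{peak}$ has passed unrewarded (expectation-violation pressing);
* *timed full attempts* (above-spatial holds of $T$ + margin) planned at
  $\mathcal{N}(t_{peak}, \sigma)$ and retried until the 30 s gate rewards
  one.

A design choice deserves emphasis: the dose ladder defaults to clock gains
*above* one. In this preparation the drugged animals' presses spread across
the whole interval, begin early, and the peri-reward peak moves below 30 s —
the signature of an accelerated (noisier) subjective clock, i.e. an
overestimation of elapsed time. A slowed-clock ladder (gains below 1) is
fully supported by the same machinery — it produces late, spread pressing
with peaks beyond 30 s — but it is not what the modelled phenomena look
like, and with a veridical 30 s gate it cannot move the reward-anchored peak
below 30 s. The gain semantics themselves (subjective rate multiplier) are
direction-neutral.

The peri-reward histogram pools press onsets around every reward
(window $[-30, +5]$ s, 1 s bins, presses/trial/bin). For peak-interval
recovery the schedule-triggering press of each trial is excluded: it is
present by construction on every trial and carries no timing information;
leaving it in anchors an artifactual mode at the reward. The peak interval
is the maximum of the 3-bin moving-average-smoothed rate within the
pre-reward window (ties to the earliest bin), expressed as $30 + t_{rel}$.
The AUC integrates the rate (as a step function over bins) across
$[-30, 0]$ s; both raw counts and normalised rates were candidates, and
rates were chosen so sessions of different lengths are comparable.

### Hold production

Each attempt draws a produced hold
$(T \cdot d_{time} + m + \Delta_{motor})(1 + w Z)$, $Z$ standard normal.
In `motor_slowing` mode $\Delta_{motor} = \ell\,(1/\texttt{motor\_scale}-1)$
with $\ell$ the control release-initiation lag (default 300 ms), an
interval-independent increment; in `timing_scaling` mode
$d_{time} = 1/\texttt{clock\_gain}$, a proportional one. Draws below $T$
are failed attempts, retried as the schedule dictates — they are recorded,
because uncensored attempt durations are what make the planned margin
recoverable without truncation bias (`recover_planned_margin()` takes the
median attempt excess below the 300 ms reaction-time threshold; excesses
beyond it are reactions to the reward, which the generator produces on a
configurable fraction of trials).

The multiplicative noise makes produced intervals scalar by construction:
SD/mean equals the Weber fraction. The default $w = 0.10$ is at the lower
end of the 0.1-0.2 range typical of well-trained rodents on these time
scales; it was chosen once, as the trained-animal condition, together with
the rest of the ladder (clock gains 1.00-1.60, motor scales 1.00-0.50
across doses 0-0.2 mg/kg).

### Lever biomechanics

Presses are trapezoids: linear rise and fall at
$26 \cdot \texttt{motor\_scale}$ cm/s, plateau near 3.0 cm (3.5 cm physical
maximum), inter-lever onset lag $\mathcal{N}(0, 20\,\mathrm{ms})$, and
correlated positional jitter (white noise smoothed over 3 samples, SD
0.003 cm — the scale of transducer/ADC noise). Jitter interacts with the
4 ms finite-difference speed metric: broadband noise of amplitude $a$ adds
$\mathcal{O}(a \cdot f_s)$ cm/s to speed estimates, so the jitter amplitude
is a real modelling commitment, not a cosmetic one.

One subtlety makes detection exact: the schedule clock acts on the
*digitized* trace, so the generator quantizes joint-press onsets to the
250 Hz grid before applying the 30 s gate and computing reward times. On
noise-free sessions detected rewards then equal generated rewards exactly,
and with noise they match to one sample.

### Treadmill kinematics

Each trial is planned backwards from a timed duration target
($7\,\mathrm{s} + 0.15\,\mathrm{s}$ margin, CV 0.04 — reusing the lever
tasks' Weber fraction here would give a 1 s spread, far wider than trained
animals' duration variability on this task): passive transport rearward at
belt speed to a rear point (78 cm minus up to 1.5 cm of trial-to-trial
variation), a trotting hold, and a final acceleration with a triangular
ground-frame speed profile peaking at
$2.8 \cdot \texttt{belt\_speed} \cdot \texttt{motor\_scale}$ cm/s. The
linear belt-speed coupling reproduces the observed belt-speed/peak-speed
relationship in the ground frame (a fixed leg-speed template would predict
the opposite sign). When the attainable peak falls, the generator
compensates to keep duration near 7 s by shortening the hold or by stopping
the transport early (never reaching the rear), matching the two strategies
seen in slowed animals; kinematically unreachable plans raise errors rather
than truncating.

## Analysis-side numerical choices

* **Press detection**: onset at the upward crossing of 0.1 cm; release only
  below 0.1 − 0.02 cm (hysteresis against chatter); within a press the
  longest contiguous span at or above 2.6 cm is the hold; spans are
  half-open $[on, off)$ at sample resolution. Continuous threshold
  satisfaction is enforced during holds (sub-threshold dips end the hold).
* **Trial timing conventions**: all event times in seconds from session
  start; the first fixed-interval gate opens at $t = 0$; reward latency is
  instantaneous at threshold satisfaction.
* **Effort** is the bilateral mean of above-touch press durations of all
  presses in a trial's window, so per-trial efforts sum exactly to the
  session's attributed press time.
* **BMOV** is reported as the variance (s²) of absolute onset lags; its
  square root is the same quantity in seconds — figures in the field are
  ambiguous between the two, so aggregation keeps both.
* **Treadmill segmentation** runs on centred-difference velocity smoothed
  with a 50 ms boxcar. Transport ends at the half-amplitude crossing of the
  belt speed (symmetric kernels put that crossing on the corner); the
  acceleration onset anchors at the fastest front-ward sample and walks
  backward to a 4 cm/s crossing, extrapolating the speed ramp to zero —
  robust to jitter spikes, and exact to a sample or two on clean traces.
  Hold tolerance is 3 cm/s; the rear zone is positions beyond 60 cm; trial
  start is the goal-zone exit after the previous reward. Strategy
  thresholds are control 5th percentiles (scale-free), with z-score
  tie-breaking when both criteria fire.
* **Statistics**: all rank tests use mid-ranks; tie correction enters
  through the total rank mean square (exact under ties, and identical to
  the textbook correction). Unbalanced two-way designs use Type-II sums of
  squares on ranks from nested least-squares fits — the original balanced
  formulation does not define this case, so it is a documented package
  choice. The rank LSD post hoc follows the Conover formulation, gated on
  omnibus significance with no further multiplicity correction. The KS
  normality screen estimates the reference moments from the data and is
  therefore conservative (no Lilliefors correction); it is descriptive.
  Missing metric values (e.g. correlations on zero-variance windows) are
  excluded from aggregates, never imputed.

## What the tests do and do not show

The test suite validates the machinery under the generator's conditions:
oracle equivalence of the rank tests (exact enumeration; rank-transform
ANOVA to 1e-10), type-I calibration of the two-way rank test (2000 null
replicates of a balanced 2 × 5 design with 10 observations per cell),
parameter recovery (planned margin within 10 % over 100 simulations; motor
scale within 5 % from max-speed ratios at 100 trials/session; strictly
decreasing recovered peak intervals along the clock ladder), the
mode-discrimination accuracy above, and treadmill compensation (duration
within 0.3 s of 7 s while peak speed falls monotonically with dose, with at
least 90 % strategy-label recovery). Simulation sizes (100-120 trials per
session, 2000-replicate calibrations, 100-run discrimination sweeps) are
the package's chosen validation scale.

The generator emulates press bouts, hold productions and three-phase
locomotion with stationary parameters. It does not emulate learning
dynamics within or across sessions, satiation drift, licking or reward
consumption behaviour, pharmacokinetic time courses, video artefacts, or
between-animal variability (sessions are exchangeable; there is no
rat-level random effect, and the statistics accordingly treat trials and
sessions as independent — a known limitation of the modelled analysis
stack). Passing tests therefore demonstrate the correctness and calibration
of the analysis rules, not that real data meet their assumptions.
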
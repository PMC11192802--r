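---
title: "Detecting signal loss during prolonged hypoxemic episodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting signal loss during prolonged hypoxemic episodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satloss)
```

## The problem

Closed-loop automated oxygen control (AOC) titrates the fraction of inspired
oxygen (FiO₂) of a preterm infant from the pulse-oximetry oxygen saturation
(SpO₂). Pulse oximetry intermittently loses signal quality — motion, poor
perfusion, probe displacement — and during such **signal loss (SL)** the
controller cannot see the patient. The controller family modeled here
responds by setting FiO₂ to a *back-up* value that tracks **baseline FiO₂**,
a slowly-updated estimate of the infant's normoxemic oxygen requirement.
When SL strikes in the middle of a **prolonged hypoxemic episode (pHE)**,
that fallback withdraws exactly the extra oxygen the episode demands.
`satloss` provides the machinery to quantify how often this happens and what
it does to episode morphology, plus a fully ground-truthed simulator so
every stage can be validated without access to patient recordings.

## Event definitions and detection

All detection operates on a uniformly sampled recording (default 1 Hz) of
SpO₂ (percent), a boolean signal-validity flag, and set FiO₂. Intervals are
half-open `[start, end)` in seconds, so adjacent runs partition time without
double counting.

* **Candidate episode.** Starts at the first *valid* sample with SpO₂ below
  90% whose predecessor is a valid sample at or above 90% (or the recording
  start); ends at the start of the first subsequent run of at least 8 s of
  consecutive valid samples with SpO₂ ≥ 90%. Invalid samples never open an
  episode, never count toward recovery, and reset an in-progress recovery
  run — recovery must be 8 s of *confirmed* readings. An episode that never
  recovers is flagged censored and excluded from duration statistics, which
  would otherwise be undefined.
* **Prolonged hypoxemic episode.** A candidate qualifies when it contains at
  least 30 s of valid SpO₂ < 80%. By default this time is **cumulative**
  across the episode; a strictly **contiguous** variant is available
  (`detection_config(hypox_time_mode = "CONTIGUOUS")`). Cumulative is the
  default because SL frequently overlaps the episode nadir: a contiguous
  rule would disqualify episodes whose hypoxemia is merely interrupted by
  dropout, which is the very phenomenon under study.
* **Recovery threshold.** The episode terminates on sustained SpO₂ ≥ 90%,
  not on return *into* the 90–95% band: values above 95% equally end the
  episode (they are evidence of recovery, possibly over-recovery).
* **Signal-loss period.** A maximal run of invalid samples. The SpO₂ of the
  last valid sample before the run and the first valid sample after it are
  recorded; the latter is classified against the target range with
  *inclusive* bounds (90 and 95 are "within").
* **Hyperoxemic overshoot.** The first run of consecutive valid samples at
  SpO₂ ≥ 97% whose onset lies within 120 s after episode recovery and whose
  duration, after clipping the run to that window, reaches 8 s. One
  overshoot is reported per episode (delay after recovery, absolute
  duration, duration as a percentage of the 120-s window), matching the
  one-row-per-episode reporting convention of clinical summary tables.

Every detector is validated against an independent brute-force scanner (a
plain per-sample loop with explicit window re-checks) on hundreds of random
traces; they must agree on every boundary, duration and annotation exactly.

## The controller simulator

Three behaviors are modeled exactly as specified for the study controller:

1. **SL fallback**: at every invalid sample the set FiO₂ equals the back-up
   FiO₂; titration resumes from that value at the first valid sample.
2. **Baseline update**: every `baseline_update_interval_s` (default 300 s)
   the baseline moves a fraction `approach_fraction` (default α = 0.5) of
   the way toward the mean set FiO₂ over the trailing `trailing_window_s`
   (default 900 s): `B ← B + α(m − B)`. With a constant trailing mean this
   converges geometrically, `B_n = m − (m − B₀)(1 − α)ⁿ`, which the tests
   check in closed form. α is configurable because only the asymptotic
   wording of the update — not its rate — is public; exponential approach is
   the simplest scheme consistent with it. Back-up FiO₂ tracks the baseline
   (the study configuration); a fixed manual back-up is configurable.
3. **Cap**: the set FiO₂ is clamped to `[0.21, min(1, baseline + 0.15)]` at
   every step.

The titration law *between* these behaviors is deliberately a surrogate: a
proportional controller with gain `gain_per_pct` (default 0.002 FiO₂ per
percent SpO₂ error per 1-s step) toward a 92.5% setpoint. The vendor's
increment/decrement scheduling is proprietary, and no conclusion drawn by
this package depends on it — the analyses exercise the fallback, the
baseline dynamics and the cap, all of which are public. The gain default
makes a deep desaturation reach the cap within seconds, which is the regime
in which the fallback matters.

## The synthetic cohort generator

`cohort_spec()` defaults encode the study conditions: 24 infants, 12.7 h of
recording each at 1 Hz, episodes arriving as a Poisson process at 3 per
12.7 h, signal loss in two-thirds of episodes with 1–2 periods per episode
(probability 0.6 of two, giving median 2, quartiles 1–2), overshoots after
20% of episodes, background SL occupying 5% of recording time under 2-s
oximeter averaging and 1% under 8-s averaging, and a normoxemic baseline of
93 ± 1.5% SpO₂. The oximeter's output rate is not public; 1 Hz is the common
bedside export rate and all reported durations are whole seconds.

**Durations.** Episode durations are drawn per SL group from lognormals
matched to the reported median (quartile) summaries — 135 (112–228) s with
SL, 81 (58–116) s without — via `lognormal_from_median_iqr()`
(μ = log median, σ = IQR width on the log scale over `2·qnorm(0.75)`). Their
1:2 mixture has an overall median near the reported 119 s. A pooled
single-distribution model is selectable.

**SL time.** The time under SL within an episode is drawn as a *relative
fraction* of episode duration (logit-normal matched to 40 (18–61)% of
episode time), so the reported absolute SL time emerges jointly with
duration. The fraction shares a Gaussian factor with the episode-duration
draw (`sl_duration_coupling`, default 0.35): signal loss suspends titration
and prolongs episodes, so the two are positively dependent. The coupling
value calibrates the *planted* SL-time median to the reported 51 s after the
qualification constraint (below) trims what short episodes can host; joint
dependence of this kind is visible in the reported group medians but its
strength is not published, so it is exposed as a single tunable parameter.

**Morphology and noise.** An episode is a piecewise-linear descent from just
below the entry threshold to a nadir (drawn uniformly from 72–78%), a nadir
plateau sized to guarantee at least 31 s below 80% by construction, and a
recovery ramp. Gaussian noise is added everywhere but *clipped so planted
geometry survives it*: normoxemic samples stay at or above 90%, samples
planted below 80% stay below 80%, within-episode samples stay below 90%, and
overshoot samples stay at or above 97%. Consequently detection boundaries
equal the planted ground truth exactly, with or without noise — which is
what makes recall/precision exactly measurable. The price is that the
generator does not produce *ambiguous* boundaries (sensor jitter across
thresholds, drifting baselines, artifacts that mimic desaturations): a
perfect score on synthetic data bounds algorithmic correctness, not
performance on real recordings.

**SL placement.** Thirty below-80 samples are protected so the episode still
qualifies as prolonged after validity flags are cleared; SL periods are
placed adjacent to the protected nadir block (the reported pattern — SL
starts at low-80s SpO₂), with the first and last episode samples kept valid
and at least one valid sample between periods. A uniform-over-episode
placement is selectable, since the true joint distribution of SL onset and
episode phase is unreported. Requested SL that exceeds what the episode can
host is truncated, never allowed to disqualify the episode.

**Averaging mode.** Recordings alternate between the 2-s and 8-s oximeter
averaging modes by infant index; the mode modulates the background SL
fraction only. `apply_moving_average()` (a trailing, causal mean over valid
samples) is provided to emulate averaging on raw traces, but is not applied
on top of planted events — that would smear the planted boundaries and break
the exact ground-truth contract.

**Determinism.** Each infant's stream is seeded from
`(rng_seed, infant_index)`, so cohorts are reproducible recording-by-
recording and byte-identical on disk across reruns.

## Statistics

Summaries follow the clinical convention: median (quartile 1 to quartile 3)
for continuous variables — linear interpolation between order statistics by
default, with the weighted-average variant used by common commercial
software selectable — and n (%) with half-away-from-zero integer rounding
for counts. Group contrasts use the Mann–Whitney U test (exact by
enumeration when the combined sample is ≤ 12 without ties, otherwise the
normal approximation with tie and continuity corrections) and, for 2×2
tables, Pearson's χ² without continuity correction unless any expected count
falls below 5, in which case Fisher's exact test (point-probability rule) is
used. The before/after-SL SpO₂ comparison is run unpaired by convention,
with a paired Wilcoxon signed-rank alternative available. No multiplicity
correction is applied, and no per-infant random-effects structure is
modeled; episodes are treated as the analysis unit throughout.

## Numerical choices and degenerate inputs

* Quantities are compared with a 10⁻⁹-second slack where float arithmetic
  meets the integer sample grid.
* Empty inputs are first-class: an all-valid recording yields an empty SL
  table; a trace never below 90% yields no candidates; an empty SL group
  suppresses group comparisons with a warning rather than erroring.
* `percent()` rounds halves away from zero; over a mutually exclusive family
  of two or three categories (the table's families) the integer percentages
  therefore sum to 100 ± 1.
* Censored episodes are excluded downstream; an SL period straddling an
  episode boundary is clipped to the episode for per-episode SL time.

## Problem sizes used in validation

The test suite validates detector/oracle agreement on 100 random traces of
up to 2 h and recovers planted events from two 120-infant cohorts (zero and
default noise, ~340 planted episodes each); the acceptance script generates
200-infant cohorts so that the recovered medians are stable to a few
seconds. These sizes are the package's choice of a comfortable
signal-to-noise point for median estimates (standard error ~2–3 s on the
SL-time median).

## Known limitations

* The titration law is a surrogate; set-FiO₂ *trajectories* between SL
  events are qualitative, even though fallback, baseline and cap behavior
  are exact.
* The generator's valid hypoxemic time in SL episodes is reduced by the SL
  overlap itself (detection counts only valid samples), so the "time below
  80%" contrast between SL and no-SL episodes in synthetic cohorts runs
  opposite to what real recordings show; real episodes with SL are deeper
  *and* longer in ways the planted morphology does not emulate.
* Manual FiO₂ overrides are representable as exogenous set-points but
  disabled by default; overshoots attributable to them are not
  distinguished.
* No bradycardia/apnea channels, no waveform-level signal quality, no
  vendor binary formats.
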
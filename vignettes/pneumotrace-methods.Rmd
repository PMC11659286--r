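---
title: "Methods: simulation, segmentation and scoring in pneumotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, segmentation and scoring in pneumotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumotrace)
```

# Scope

pneumotrace analyses rodent cardiorespiratory recordings from two
acquisition paradigms: whole-body barometric plethysmography of adult mice
run through a five-period gas-challenge protocol (room air, 5% CO2
hypercapnia, room air, 10% O2 hypoxia, room air), and face-mask
pneumotachography of neonatal pups subjected to repeated anoxic challenges
until autoresuscitation fails. The package covers the full chain: raw
multichannel traces, breath and heartbeat segmentation, calm-breath
selection, apnea/sigh calling, chemoreflex epoch metrics with flow-through
respirometry (VO2), autoresuscitation trial scoring, and a linear
mixed-effects statistical layer with Tukey HSD contrasts. A seeded
synthetic-trace generator with analytic ground truth exercises every stage.

# The synthetic-trace generator

Breathing is rendered as a concatenation of breath cycles. Each cycle is a
half-sinusoid inspiratory lobe of duration $T_i = 0.35\,T$ followed by an
exponentially damped sinusoidal expiratory lobe,
$-b\,\sin(\pi u)\,e^{-3u}$ with $u \in [0, 1)$ over $T_e = 0.65\,T$. The
expiratory amplitude is scaled so that every cycle integrates to zero: a
flow-like signal must move as much gas out as in, and the balance keeps the
baseline stable under high-pass filtering. Cycle period and amplitude are
jittered log-free with coefficients of variation `rate_cv` (default 0.05)
and `amp_cv` (default 0.08).

Events are programmed deterministically: `round(rate/100 * n_breaths)`
sighs and apneas are placed at seeded positions. A sigh replaces a breath's
amplitude with `sigh_amp_factor` (default 2.5) times the programmed mean
amplitude; an apnea stretches that breath's interbreath interval (IBI) to
`apnea_ibi_factor` (default 2.5) times its local IBI. Both factors are
constrained to at least 2, so every programmed event satisfies the
detector's relative-threshold definitions by construction, and both default
to 2.5 so programmed events clear the calling threshold (factor 2) with a
margin of 0.5.

The adult gas channels follow first-order washout toward each period's
inflow fraction with time constant $\tau = V/Q$ (default chamber volume 450
mL at 198 mL/min flow, so $\tau \approx 136$ s; the chamber volume is not
reported for the original rig and 450 mL is a typical mouse chamber).
Animal metabolism depresses steady-state chamber O2 below the inflow
fraction by $\dot{V}O_2 / Q$, which is exactly the flow-through
respirometry mass balance the analysis stage inverts. The anoxic mixture of
the neonatal protocol is rendered as 3% CO2 / 97% N2; the source protocol
prints a nitrogen fraction that does not close the sum to one, which we
treat as typographical.

Neonatal sessions render, per trial: eupneic breathing up to the anoxic
switch, cessation after the programmed induction time, a gasp train at
cumulative programmed intervals (defaults: gasp latency 42 s, one further
gasp 12 s later, matching the scale of reported group means), and - for
recovering trials - resumption of breathing whose instantaneous rate
follows $VF(t) = VF_{floor} + (VF_{base} - VF_{floor})(1 - e^{-t/\tau_{VF}})$
from the first gasp. Heart rate decays toward its floor during anoxia
(time constant 10 s) and recovers analogously from the first gasp. The next
challenge starts 300 s (five minutes) after the first gasp, the recovery
hold of the original protocol. Ground truth stores the closed-form recovery
latencies
$t^* = -\tau \ln\!\left(1 - \frac{f\,x_{base} - x_{floor}}{x_{base} - x_{floor}}\right)$
for fractions $f$ of baseline.

The heartbeat appears twice: as a low-amplitude additive sinusoid riding on
the breath channel (`cardiac_amp`, default 2-5% of breath amplitude) and,
in the neonatal generator, as a dedicated `cardiac` channel - mirroring
rigs that record heart rate separately from airflow.

Cohorts draw per-animal generative parameters as
`grand_mean + group_effect*[GF] + sex_effect*[M] + N(0, animal_sd)`, with
per-observation `N(0, residual_sd)` noise wherever repeated measures are
drawn; `sim_outcome_table()` is the outcome-level view used by the
statistical validation, where rendering waveforms would add nothing.

What the generator does *not* emulate: plethysmograph acoustics, humidity
and temperature drift, movement artifacts beyond amplitude/period jitter,
analyser drift, or any mortality mechanism beyond the terminal trial's
`recovers = FALSE` flag. Passing tests therefore demonstrate correctness of
the algorithms against the stated waveform family and noise model, not
robustness to every failure mode of real recordings.

# Breath segmentation

Breaths are delimited by upward zero crossings of the band-filtered breath
signal (2nd-order Butterworth high-pass at 0.1 Hz against drift, 4th-order
low-pass at 20 Hz for cycle delimitation; all filtering is zero-phase with
mirror padding). Ties at an exact zero resolve to the earlier sample.
Candidate cycles with inspiratory amplitude below 0.25 times the session's
robust (95th percentile) candidate amplitude, or shorter than `min_tt`
(default 50 ms), are merged into their predecessor; thresholds are relative,
which makes detection invariant to uniform gain.

The coarse crossing is then refined by fitting the canonical cycle shape -
half-sine inspiration plus damped-sine expiration - to the candidate cycle
by Gauss-Newton least squares over (inspiratory amplitude, expiratory
amplitude, onset, $T_i$, $T_e$), on a mildly smoothed signal (2nd-order
low-pass at 25 Hz). The raw crossing of a smoothed convex corner is biased
early by the smoothing kernel; fitting the whole cycle removes that bias
and averages sample noise over every informative sample. A second pass
re-fits each breath with a quadratic penalty pulling the nuisance
parameters toward the session's median shape (weights set by residual
variance over the robust between-breath variance, and capped at half the
likelihood information so the prior can inform but never dominate). The
onset itself is never penalised. On 100 seeded 60-s sessions at the default
2% measurement noise, detected onsets match programmed onsets one-to-one
within one sample period; at 15% noise, recall and precision remain ~0.97.

A breath's offset is the next onset unless a genuine pause follows the
expiratory lobe (gap longer than half the median IBI), in which case the
offset stays at the expiratory end: on gap-free breathing $T_i + T_e$ tiles
the span exactly and $60/\overline{TT}$ reproduces the breathing rate,
while an apneic breath keeps a normal $TT$ and an IBI that carries the
pause. End-expiratory pause partitioning is deliberately out of scope.

Calm breaths: a breath is calm iff, within a centred 21-breath rolling
window, its cycle duration and amplitude both lie within $[1/k, k]$ times
the window median ($k = 2$), and it does not fall inside a movement-artifact
span (1-s windows whose RMS exceeds 3 times the session median RMS). The
rule is scale-free, deterministic, and reduces to "all calm" on clean
data; with fewer breaths than the window, whole-session medians are used
and a note is logged. "Calm" has no published operational definition for
this pipeline's ancestor software, so this is a deliberate re-specification.

# Heartbeats

The cardiac channel (dedicated if present, else the breath channel) is
band-passed at 4-12 Hz (240-720 beats/min, the neonatal mouse range),
peaks above 0.3 times the robust band amplitude are kept subject to a
refractory period of 0.6 times the running median inter-beat interval, and
peak times get sub-sample parabolic refinement. The instantaneous rate
$60/\mathrm{IBI}$ is interpolated onto a uniform 10 Hz grid; grid points
farther than 5 s from any beat are undefined rather than an error, because
heart rate legitimately vanishes from the airflow signal during apnea. A
limitation worth stating: with the harmonic-rich synthetic waveform, a
few-percent cardiac ripple on the breath channel is masked by breathing
harmonics inside the cardiac band, so quantitative heart-rate claims are
validated on the dedicated channel.

# Tidal volume

`VT = V_inject * (deflection / deflection_inject) * C`, with the classic
barometric temperature/humidity correction
$C = \frac{T_R (P_B - P_C)}{T_R (P_B - P_C) - T_C (P_B - P_R)}$
(temperatures in kelvin; $P_C$, $P_R$ saturated water-vapour pressures at
chamber and body temperature, Magnus form). Body temperature per breath is
interpolated linearly between the pre- and post-session rectal readings -
the only temperature observations the protocol produces. A missing
calibration degrades gracefully to the uncalibrated inspiratory integral
with a provenance flag.

# Apneas, sighs and rates

Within one gas epoch, the reference is the arithmetic mean over calm
breaths (all breaths, with a log note, when none is calm). A sigh is a
breath with amplitude at least twice the reference amplitude; an apnea is
an IBI at least twice the reference IBI; both comparisons are inclusive.
The epoch scope matters: hypercapnia and hypoxia shift breathing enough
that a session-wide mean would mis-scale thresholds across conditions.
Rates are exact ratios scaled to events per 100 breaths, with square-root
convenience columns because rates are analysed on the square-root scale.
No sigh/apnea exclusion interaction is imposed: a breath may participate in
both definitions.

# Chemoreflex epochs and metabolics

The five gas periods yield seven analysis epochs: the last 300 s of each
room-air period, each challenge's initial reflex window (120 s starting
when the chamber gas reaches 90% of its step toward target - computed in
closed form from the washout, or at the switch marker when no gas channel
exists), and each challenge's steady state (last 300 s). These windows are
not prescribed by the source protocol; they are bounded, reproducible
choices exposed in the configuration. Switch times come from markers when
present, otherwise from the first halfway crossing of the relevant gas
channel.

VO2 is the flow-through mass balance `flow * (FiO2 - FeO2) / weight` with
FeO2 the mean chamber O2 fraction over the (steady-state) epoch; an
optional one-point respiratory-exchange-ratio correction is off by default.
Negative VO2 is reported with a warning, never clipped: silently clipping
would mask analyser drift. Note that during reflex windows the chamber has
not equilibrated, so the mass-balance figure there is biased by the washout
transient (hypoxic reflex epochs can even report negative values); the
steady-state epochs are the metabolically interpretable ones.

Condition summaries are computed over calm breaths: $V_f = 60/\overline{TT}$,
$V_T$ the mean calibrated tidal volume, $V_E = V_f V_T$ identically (the
identity holds on every emitted row), per-gram variants, timing means, and
the epoch's event rates. Epochs with fewer than 20 calm breaths are omitted
with a logged reason - the package's operationalisation of per-condition
quality exclusion. Percent change is
$100 (x_{ss} - x_{ra}) / x_{ra}$ per animal and variable, hypercapnia
referenced to the first room-air period and hypoxia to the second - the
room-air period immediately preceding each challenge - so that slow drift
across the 100-min session does not masquerade as a chemoreflex.

# Autoresuscitation scoring

Trials are delimited by `anoxia_<i>` markers. Baseline $V_f$, $V_T$, $V_E$,
HR are means over calm breaths / defined heart rate in the last 120 s
before the first switch. Apnea onset is the offset of the last breath
followed by at least 10 s without a detected breath (the cessation
threshold is not prescribed anywhere; 10 s is config-exposed), and the
induction length is measured from the switch. Gasps are isolated
breath-like deflections after apnea onset: amplitude at least 0.5 times the
baseline mean and at least 1 s of preceding quiescence. "Gasp frequency"
is reported both as the inter-gasp interval in seconds and as its
reciprocal in gasps/min, covering both readings of that ambiguous term.

Recovery latencies are measured from the first gasp - the start of the
recovery period - on 10 Hz grids: heart rate from the beat series,
ventilatory frequency from interbreath intervals (gasps included). The
reported pair is HR to 63% and VF to 50% of baseline (the other two
combinations are computed alongside), the first grid crossing refined by
linear interpolation. Decoupling is exactly
`lat_hr63 - lat_vf50`; negative values mean the heart recovered faster
than breathing. A trial survives iff both reported latencies are defined
before the next challenge; `episodes_survived` counts survived trials. An
alternative latency origin (return to room air) is selectable.

Because VF is tracked through interbreath intervals, its crossing time
inherits the breathing-period jitter: the validation tolerance is derived
a priori as one grid step + one breath period at the threshold + 3 sigma of
the period CV translated through the recovery slope (about 3-4 s at the
default parameters), while HR latencies on the dedicated channel are tight
to a few hundred milliseconds.

# Statistics

Each outcome is fitted by REML as
`transform(y) ~ group * sex (+ timepoint) + (1 | animal_id)` - the random
intercept per animal is the minimal structure consistent with repeated
measures; nothing richer is identifiable from per-trial or pre/post data.
Tukey HSD contrasts run over all cells of the fixed-effect design with
Satterthwaite degrees of freedom (the method is named in every report
header), and unadjusted contrasts are carried alongside so the guarantee
`p_tukey >= p_unadjusted` is checkable per row. A singular random-effect
fit falls back to a fixed-effects-only linear model with a prominent
warning; a saturated zero-variance fit reports p = 1 rather than NaN.

Transforms: the preset table maps inspiratory duration, tidal volume, and
apnea/sigh rates to square root; expiratory and cycle duration, ventilatory
frequency, ventilation, VO2 and VE/VO2 to log10; everything else stays raw.
Automatic mode refits each candidate and picks the highest residual QQ
correlation, ties broken toward raw; candidates undefined for the data are
skipped with a note.

Validation of the stack is simulation-based: under the global null
(zero effects, 6 animals per cell, 5 observations each, animal SD = residual
SD = 0.5) the fraction of 500 replicates with any Tukey-adjusted contrast
below 0.05 lands at the nominal level (measured 0.038-0.054 across seeds);
with a programmed group effect of 1.0 at 12 animals per cell, the
Satterthwaite Wald interval covers the truth in ~95-98 of 100 replicates.
Covariates (e.g. age, weight) can be added but none is asserted by default.

# Numerical choices and problem sizes

Validation runs render 60-s single-animal traces and full multi-trial
neonatal sessions at 100 Hz (the generators support higher rates); gas-only
respirometry checks run at 5 Hz. Filters are zero-phase Butterworth with
mirror padding; the Gauss-Newton refinement runs at most 12 iterations with
an analytic Jacobian and falls back to the coarse crossing on divergence.
Degenerate inputs degrade deliberately: zero-variance channels yield empty
tables with warnings, absent calibrations flag uncalibrated volumes,
unscoreable trials carry NA metrics, and epochs failing quality thresholds
are omitted with logged reasons rather than silently filled.

# Known limitations

Reproduction of the original study's printed group statistics requires its
deposited raw recordings and the exact (unpublished) reflex/steady-state
windowing of its analysis software; the bundled generator validates the
algorithms, not those numbers. The calm-breath rule and the apnea-cessation
threshold are re-specifications of undocumented criteria. Heart-rate
extraction from a combined airflow channel is limited by breathing
harmonics in the cardiac band. The event-rate scale ("per 100 breaths") is
a convention; comparisons against figures plotted on an unstated scale
need a calibration factor.
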
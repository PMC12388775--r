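---
title: "Methods: automatic cycle selection and nasal-resistance computation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic cycle selection and nasal-resistance computation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhinoflow)
```

## The measurement problem

Rhinomanometry quantifies nasal obstruction as the ratio of transnasal
pressure (Pa) to nasal airflow (cm³/s) during quiet breathing. A measurement
session records both channels at 100 Hz; each respiratory cycle (one
inspiration followed by one expiration, positive flow = inspiration) yields
one estimate of each resistance indicator. In practice many recorded cycles
are unusable: breaths that saturate the sensors or never reach the 150 Pa
reference pressure, spans where the breathing mask is not worn properly
(one-signed signals, dead channels, slow ambient drift), and multiple
superimposed breaths. Traditionally a clinician discards these by eye;
`rhinoflow` automates the whole chain — segmentation, artifact rejection,
resampling/averaging, and computation of four resistance indicators — so the
result is reproducible and interference-resistant.

## Cycle segmentation

After subtracting the per-channel mean of the first 2 s (the sensor
baseline; `remove_dc()`), segmentation streams through the **flow** channel:

* **Start.** The sum of every five consecutive samples is monitored. A
  positive sum marks inspiratory data; the cycle starts at the first
  strictly positive sample inside the firing window. (Trimming the leading
  non-positive samples is our resolution of an ambiguity in the summation
  rule: it guarantees every emitted cycle begins with a positive-flow run.)
* **End.** The cycle ends at `x_prev` when two consecutive samples satisfy
  `x_prev * x_last < 0` with `x_prev < 0` — the expiration-to-inspiration
  alternation. Exact zeros are non-crossings.

Two robustness refinements, both reusing the same five-sample summation
device, are needed because the plain two-sample end rule is noise-brittle:

* a *mature* candidate (older than `min_cycle_s`, default 0.5 s) only ends
  when the trailing five-sample sum is negative, i.e. expiration is
  established — otherwise a single noise dip at the near-zero
  inspiration→expiration transition truncates the cycle to its inspiratory
  half;
* a *young* candidate closes on the plain alternation, so a false start on
  baseline noise dies within a few samples and is discarded as too short,
  instead of swallowing the next true onset.

With these choices, per-boundary recall against simulator ground truth
(start or end matched within ±5 samples) is ≈0.99 at the default 2% noise;
the stricter both-ends-of-the-same-cycle metric is slightly lower, limited
by noise at near-zero crossings of low-amplitude breaths. The segmentation
contract is incremental: emitted cycles are immutable values, so validation
of one cycle may proceed while later samples are still being scanned without
changing any result.

The final cycle of a recording can never be emitted: the end rule requires a
later positive sample. The simulator therefore offers a `tail_s` baseline
segment, and acquisition protocols should keep recording briefly after the
last breath.

## Effective-cycle validation

A segmented cycle is *effective* iff all four clauses hold (bounds
inclusive):

* dominant frequency of the pressure channel in `[MINFT, MAXFT]`,
* dominant frequency of the flow channel in `[MINFT, MAXFT]`,
* pressure peak-to-peak (VPP) in `[MINPVT, MAXPVT]`,
* flow VPP in `[MINFVT, MAXFVT]`.

The defaults (0.12–0.6 Hz, 300–1000 Pa, 100–1650 cm³/s) are the optimum of
an exhaustive grid search on a physician-labeled corpus; normal adult
breathing sits at 0.2–0.5 Hz, and the 300 Pa floor is twice the 150 Pa
reference pressure, so every accepted cycle can support the classic
resistance computation. We apply the frequency clause to each channel
separately — the stricter of the two possible readings, and the one matching
how the thresholds are labeled ("pressure and flow").

**Dominant frequency.** The mean-removed cycle is *periodically extended*
(tiled) to 16384 samples before the FFT; the dominant frequency is the
largest-magnitude non-DC bin, with resolution 100/16384 ≈ 0.0061 Hz — finer
than the 0.01 Hz threshold grid step. Tiling rather than zero-padding is a
deliberate numerical choice: a segmented cycle is one period of the
breathing signal, and the magnitude argmax of a single zero-padded period
sits visibly *below* the fundamental (≈17% low; the positive- and
negative-frequency sinc lobes interfere), whereas periodic extension
recovers the fundamental to within one bin. A constant channel has no
dominant frequency and fails its FFT clause.

## Resampling and averaging

Accepted cycles differ in length, so before averaging each channel is fitted
with a **natural cubic spline** over unit-spaced knots at sample indices
`1..Ln` (zero second derivative at both end knots, standard tridiagonal
solve) and evaluated on the fixed grid `I_1 = 1`, `I_{j+1} = I_j + Ln/2000`,
giving exactly 2000 points. Note that the last grid point
`1 + 1999·Ln/2000 = Ln + 1 − Ln/2000` exceeds `Ln` whenever `Ln < 2000`
(always, at 100 Hz); evaluation beyond the last knot extends linearly with
the end-knot slope — the conventional natural-spline extension, identical to
`stats::spline(method = "natural")` — and the overshoot is under one index
unit. Averaging is pointwise per channel.

## Resistance indicators

All indicators are computed separately per phase after `split_phases()`
(split at the first index where flow turns and stays negative for ≥2
samples; the expiratory segment is negated internally so every calculator
sees positive magnitudes, and all reported resistances are positive):

* **Mean resistance** `R = P_ref / V_pred` with `P_ref = 150` Pa: the first
  adjacent sample pair whose pressures straddle 150 Pa is found and the flow
  is interpolated along their connecting line. Weak breaths that never reach
  150 Pa are reported not-computable.
* **Vertex resistance** `R = |P_vertex| / |V_vertex|` at the earliest sample
  of maximal |flow|.
* **Effective resistance** `R = P_eff / V_eff`, the ratio of RMS pressure to
  RMS flow (trapezoidal integration over the phase duration). The defining
  integral is an AC-power mean square; we take its square root, since
  otherwise the ratio would not carry resistance units.
* **Broms resistance**: the pressure–flow curve is scaled to polar
  coordinates (`x = |v|/100 cm³/s`, `y = |p|/100 Pa`, so the radius-2 circle
  crosses the axes at 200 units), points with `|r − 2| ≤ 0.25` are selected,
  the angle law `v = v0 + c·r` is fitted by ordinary least squares, and
  `R = tan(v0 + 2c)`. The axis normalization is not standardized in the
  literature; both unit scalings and the band half-width are configuration
  (`broms_unit_pa`, `broms_unit_cm3s`, `broms_band`).

Routing (`compute_all()`): mean and Broms resistance are computed per cycle
on the raw effective cycles and averaged across cycles; vertex and effective
resistance are computed on the pointwise average of the resampled cycles
(the 4-phase-rhinomanometry convention of averaging repeated tests before
reading off the loop). Per-cycle values of all four indicators are also
returned for stability analysis. A 4-phase resistance at or above 0.75
Pa/(cm³/s) is interpreted as obstructed (`interpret_severity()`), below as
normal; 0.75 itself is classified obstructed.

## The synthetic breath simulator

No recordings are distributed with clinical corpora of this kind, so the
package carries a seeded generator whose defaults state the world the tests
run in:

* flow is a pair of raised-sine half waves, inspiratory fraction 0.45, with
  the two half-wave amplitudes balanced so the flow integral vanishes
  (inhaled volume = exhaled volume) while the peak-to-peak span stays
  `2 × flow_amp`;
* pressure follows the orifice law `p = k·v·|v|` with `k` set so the
  pressure peak matches `pressure_amp_pa` — this produces the curved
  pressure–flow loop of real rhinomanometry and makes the four indicators
  genuinely distinct;
* Gaussian noise, sd = 2% of each channel's half-amplitude, is added per
  channel;
* unset parameters are drawn per cycle: frequency U(0.2, 0.5) Hz, pressure
  VPP U(350, 900) Pa, flow VPP U(150, 1500) cm³/s — strictly inside the
  default thresholds, emulating a cooperative subject.

Interference scenarios (all parameters exposed as `scenario_params`; none
are quantified in the clinical literature, so the defaults are stated
stand-ins chosen once):

* *saturated*: amplitudes scaled 3× and hard-clipped at ±600 Pa /
  ±1800 cm³/s (an assumed sensor full scale), so the clipped pressure VPP
  (≥1025 Pa) always exceeds the 1000 Pa ceiling;
* *weak*: the breath rescaled to a 100 Pa pressure half-amplitude (pressure
  never reaches ±150 Pa), flow scaled by the square root of the same factor
  per the orifice law;
* *not worn properly* — `one_signed`: one phase is lost and the retained
  phase attenuated by a leak factor 0.5 (a leaky seal cannot build normal
  pressure), which keeps the one-sided pressure VPP below 300 Pa under
  default amplitudes; `zeroed`: one channel is dead (0.5-unit residual ADC
  noise); `drift`: both channels replaced by one full period of 0.05 Hz
  ambient drift with independent random phases;
* *multiple breaths*: a 1.2 Hz burst (above the 0.6 Hz band edge) at half
  the flow amplitude is superimposed on one or both phases, whose base peak
  is reduced to 70%; pressure is re-derived from the composite flow.

What the generator does *not* emulate: patient-to-patient waveform
variability, correlated (non-white) sensor noise, composite simultaneous
interferences, nonstationary breathing rates within a recording, and any
hardware transfer function. A green test therefore establishes that the
algorithms implement their contracts on signals with the stated structure —
not clinical performance on real patients. Saturated, weak, zeroed and
(under default amplitudes) one-signed cycles are rejected with probability
1 by construction; drift and multiple-breath cycles are only mostly
rejected, mirroring the per-scenario accuracies reported for this class of
classifier (rejection of multiple breaths in particular hinges on how much
the burst distorts the spectrum).

## Threshold grid search and stability analysis

`grid_search()` evaluates classification accuracy for every ordered
(min, max) pair combination on three axes (frequency step 0.01 Hz as in the
original tuning; VPP steps default 50 units), with per-cycle features
computed once. Ties are broken toward the widest frequency interval, then
the widest pressure-VPP and flow-VPP intervals — maximizing the admitted
range of genuine breathing.

`within_group_sd()` reproduces the stability analysis: per group of repeated
measurements, the sample (n−1) standard deviation of each indicator across
cycles, with the SD distribution across groups summarized by median and IQR.
Quantiles use linear interpolation (R type 7); the convention is recorded in
the output because IQR values depend on it. The package's stability test
builds mixed groups (four effective cycles of one synthetic subject plus
drift and one-signed interference cycles) and verifies that filtering
shrinks the median within-group SD at least twofold for every indicator ×
phase — a deliberately conservative twin of the much larger reductions
reported clinically, since the synthetic interference levels are stand-ins.

## Defaults at a glance

| parameter | default | units | why |
|---|---|---|---|
| sampling rate | 100 | Hz | acquisition hardware; ≫ Nyquist for 0.2–0.5 Hz breathing |
| baseline window | 2 | s | DC estimate from pre-breathing idle samples |
| `min_cycle_s` | 0.5 | s | shortest credible cycle (< period of the 0.6 Hz ceiling) |
| FFT length | 16384 | samples | 0.0061 Hz resolution < 0.01 Hz threshold step |
| thresholds | 0.12–0.6 Hz, 300–1000 Pa, 100–1650 cm³/s | | grid-search optimum on the labeled corpus |
| `p_ref_pa` | 150 | Pa | clinical reference pressure |
| resample length | 2000 | points | fixed-length cycles for averaging |
| Broms `r_ref`, band | 2, 0.25 | radial units | radius-2 convention; band is a stand-in |
| Broms axis units | 100 Pa, 100 cm³/s | per radial unit | radius-2 circle at 200 Pa / 200 cm³/s |
| severity cutoff | 0.75 | Pa/(cm³/s) | clinical normal/obstructed boundary |

## Known limitations

* Boundary localization degrades for breaths near the low end of the
  amplitude envelope, where sample-to-sample slope at the zero crossings is
  comparable to the noise floor.
* The Broms axis normalization is a convention; `tan(v_pred)` equals a
  resistance only under the chosen scaling, so Broms values are comparable
  across sessions only with identical `broms_unit_*` settings.
* The full default search grid (~10⁷ combinations) is exhaustive by design
  and slow in pure R; narrow the grid or coarsen the VPP steps for
  interactive use.
* Published clinical performance numbers (recall/precision on the 280-cycle
  corpus, 45-group stability medians) are not reproducible here because
  those recordings are not public; the test suite runs scaled-down synthetic
  twins instead.
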
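---
title: "Methods: pediatric c-VEMP normative values in vempnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pediatric c-VEMP normative values in vempnorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vempnorm)
```

## The measurement and its normalization

A cervical vestibular evoked myogenic potential (c-VEMP) is a short-latency
inhibitory modulation of the tonic sternocleidomastoid EMG evoked by a loud
low-frequency stimulus — here a 750 Hz tone burst of 4 ms (one carrier cycle
each of rise, plateau and fall) delivered at 4/s, by air conduction (AC,
TDH39 headphones) or bone conduction (BC, B71 mastoid vibrator). The
response is biphasic: a positive peak P near 13 ms and a negative peak N
near 19 ms, read on a 50-ms window from stimulus onset.

Raw peak-to-peak amplitude scales with how hard the muscle contracts, so it
is normalized by the tonic EMG level (mean rectified EMG over the recording
window, target band 100–500 µV) to give the dimensionless **amplitude ratio
PN/EMG**. The amplitude ratio at a fixed reference level (dial 100 dB HL,
i.e. 86 dB nHL BC / 88 dB nHL AC), the response threshold on a 5-dB
staircase, the P/N latencies, and the interaural asymmetry of the ratio are
the quantities for which normative limits are constructed.

Stimulus levels live on four dB scales. Conversions are affine per
transducer, taken from the device calibration chart: for BC,
nHL = HL − 14 and FL = HL + 49; for AC, nHL = HL − 12 and SPL = HL + 9
(`hl_to_nhl()`, `hl_to_physical()`). Deriving these offsets from the
RETSPL standards is deliberately out of scope; they are stored constants.

## The reference-interval model

Amplitude ratios are positive and right-skewed, and both their level and
spread change with age. `fit_ref_model()` follows the Royston–Wright
age-specific reference-interval approach, the method recommended for
growth-type references:

1. **Normalizing transform.** A Box-Cox transform
   $B = ((y+\delta)^\lambda - 1)/\lambda$ (log for $\lambda = 0$) removes
   the skew. $\lambda$ is chosen by profiling the exact Gaussian
   log-likelihood — including the Jacobian term
   $(\lambda - 1)\sum \log y$ — over a grid ($[-2, 2]$ in steps of 0.05 by
   default).
2. **Mean curve.** The mean of $B$ is a fractional polynomial (FP) of age:
   powers from $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$, degree at most 2, power
   0 meaning $\log(\text{age})$ and a repeated power $p$ meaning
   $\{a^p, a^p\log a\}$. Inside the $\lambda$ profile the best FP is chosen
   by residual sum of squares (i.e. maximum likelihood over the class); at
   the selected $\lambda$ the final degree is pruned by a closed-test
   deviance procedure at $\alpha = 0.05$, so simpler curves are kept unless
   complexity pays for itself.
3. **SD curve.** $\sqrt{\pi/2}\,|\text{residual}|$ is an unbiased estimator
   of a Gaussian SD, and is regressed on an FP of age (degree at most 1,
   constant allowed). One weighted-least-squares reweighting pass
   (weights $1/\sigma^2(a)$) refits the mean, after which the SD is
   re-estimated. The SD curve is always rescaled to its maximum-likelihood
   scale, i.e. so that $\tfrac1n\sum Z_i^2 = 1$ on the training data; this
   is also what makes the grid profile agree with brute-force joint
   likelihood optimization.
4. **Z-scores and centiles.** $Z = (B - \mu(a))/\sigma(a)$ must be standard
   normal under a correct model; `gof_check()` tests this with Shapiro–Wilk
   at $\alpha = 0.05$ plus the requirement that neither $Z$ nor $|Z|$
   correlates with age beyond 0.1. The $p$-th centile on the measurement
   scale is the inverse transform of $\mu(a) + z_p\,\sigma(a)$
   (`centile()`); when $\lambda x + 1 \le 0$ the inverse is clamped at zero
   with a warning.

The underlying reference-interval literature also allows a third
(kurtosis-type) parameter via a modulus-exponential family; this package
deliberately restricts itself to the Box-Cox-normal sub-family — skewness
handled by $\lambda$, no separate kurtosis parameter — because the fitted
quantities exposed here (age-specific mean, SD, and extreme centiles) are
all expressible within it. The full family is an extension hook, not a
default.

**Stratification.** Models are fitted per sex within each conduction mode.
$\lambda$ is shared across the two sexes of a mode by maximizing the summed
profile log-likelihoods (`fit_reference_models()`); at roughly a hundred
ears per sex stratum a shared transform is markedly more stable than two
independently profiled ones, while the mean and SD curves remain fully
sex-specific. Right and left ears are pooled as independent observations,
which is justified by their high intraclass correlation and can be revisited
via the `icc()` diagnostics. Records below 0.5 years are excluded before
fitting (infants this young are not in the modeled domain, mirroring
standard practice of excluding the youngest outliers), and predictions
outside the fitted age domain are refused rather than extrapolated.

If the fitted SD curve goes non-positive anywhere on the age domain the fit
falls back to a constant (RMS) SD with a warning — at small per-stratum
sample sizes an FP1 SD curve can otherwise dip below zero outside the bulk
of the data.

## Classification criteria

`classify_subject()` evaluates the normality criteria for children: each
ear's amplitude ratio inside the age- and sex-specific 5th–95th centile
band; interaural ratio asymmetry $100(R-L)/(R+L)$ below the configured
limit; threshold at or below the cutoff (default 85 dB nHL, about
95 dB HL) with an interaural threshold difference of at most 5 dB; and
P-wave latency in 12.6–13.8 ms. The default asymmetry limit is 35%, with
32% — the empirical whole-population 5–95% band — available as a
configuration choice; both values circulate in the normative literature and
the package deliberately exposes the cut as configuration rather than
resolving it. Criteria with missing inputs are reported as indeterminate
(`NA`), never as failures, and the overall verdict is the conjunction of
the available flags.

## What the synthetic generator emulates

`sample_cohort()` draws latent subject truths with the statistical
structure the analysis assumes, so that every downstream stage is a genuine
recovery problem:

* **Maturation.** The mean amplitude ratio follows
  $m(a) = s\,[b + g\,(a/t)\,e^{1-a/t}]\,e^{-d\,(a-t)_+}$: a rapid early
  rise peaking at $t = 5$ years (inside the 4–6-year window where pediatric
  ratios peak), then a slow decline. The decline is multiplicative —
  a rate $d$ per year — rather than linear in ratio units, so the curve
  stays positive across the whole 0.5–62-year domain. Air conduction is
  markedly age-dependent; bone conduction flatter with a faster late
  decline; males run 15–20% above females.
* **Variability.** Subject and ear effects are log-normal
  ($\eta_{subj} + \eta_{ear}$ on the log scale, total SD
  $\tau = 0.35$), keeping ratios positive and right-skewed — precisely the
  skew the Box-Cox step must undo. The split
  $\mathrm{var}(\eta_{subj}) = \rho\tau^2$,
  $\mathrm{var}(\eta_{ear}) = (1-\rho)\tau^2$ makes the interaural
  correlation of log ratios exactly $\rho$ (default 0.85). Subject effects
  of the two modes share a common component (correlation 0.6).
* **Thresholds.** $\theta_0 - \theta_1\,\text{ratio} + \varepsilon$
  ($\theta_0$ = 86 dB nHL AC / 84 BC, $\theta_1$ = 4 dB per ratio unit,
  $\varepsilon$ SD 2.5 dB), quantized to the mode's 5-dB staircase grid —
  larger responses have lower thresholds, and threshold estimates can only
  take grid values.
* **Latencies.** $t_P = 12.8 + 0.05\,a + N(0, 0.4^2)$ ms and
  $t_N = t_P + 6.3 + N(0, 0.8^2)$ ms: a weak upward age drift on the scale
  of published pediatric latency tables.
* **Absent responses.** From age 15 on, BC responses are absent with
  probability 0.15 (both ears together), reproducing the adolescent/adult
  loss of bone-conducted responses; absent is a finding, encoded by an
  explicit sentinel, not missing data.

`synth_epoch()` builds each stimulus-locked epoch as band-limited Gaussian
background EMG plus, above threshold, a biphasic pair of Gaussian bumps of
half-width 2 ms at $t_P$ and $t_N$. Two conventions matter:

* **EMG convention.** `emg_uv` is the *rectified-mean* EMG — the quantity
  the recording device displays and the 100–500 µV target band refers to.
  The Gaussian background is therefore synthesized with RMS
  $\mathrm{emg} \cdot \sqrt{\pi/2}$, so its rectified mean equals
  `emg_uv` and the PN/EMG ratio round-trips without a folded-normal bias
  factor.
* **Growth.** The noiseless peak-to-peak amplitude is
  $\text{ratio} \cdot \text{emg} \cdot g(\text{level})$ with $g$ zero below
  threshold, rising linearly from 0 at threshold − 5 dB to 1 at the
  reference level (span floored at one 5-dB step), clamped to $[0,1]$. No
  published growth function exists for these stimuli; linear-in-dB over the
  staircase span is the simplest shape consistent with a threshold and a
  saturated reference response.

The background is white Gaussian noise smoothed with a 0.1-ms Gaussian
kernel — a broadband spectrum on the order of the evoked-potential
amplifier band — and rescaled to the target RMS. Sessions synthesize the
full staircase per ear and mode: two replicate averages per level at 50
epochs (the acquisition count used for threshold determination), plus two
replicate averages at the reference level at the group's standard count
(25 in children, 50 in adults) for between-subject feature comparison, with
per-subject derived seed streams so a fixed master seed reproduces every
sample byte for byte.

What the generator does **not** emulate: physiological EMG spectra and
nonstationarity, testing-position effects on EMG amplitude (the
normalization is assumed to absorb them), artifact epochs, transducer
frequency response, and longitudinal within-subject change. Passing
recovery tests on this generator therefore demonstrates the estimators'
correctness under the stated statistical structure, not their robustness to
every property of real recordings.

## Feature extraction choices

* The EMG level of a trace is quantified over the post-response 50–150 ms
  segment by default, so the evoked response itself does not contaminate
  the normalizer; the window is configurable because recording systems
  differ in whether they use pre-stimulus, whole-window or
  response-excluded EMG.
* P is the maximum in 8–18 ms and N the minimum in [P + 2, 30] ms; the
  windows bracket published pediatric latency ranges with margin. Peak
  *latencies* are picked on a copy smoothed with a 1-ms Gaussian kernel;
  peak *amplitudes* are then read from the raw trace, averaged over
  ±0.3 ms around the picked latencies (cursor-style), which avoids the
  systematic attenuation smoothing would impose on a 2-ms-wide peak.
  A response is "present" when the peak-to-peak amplitude exceeds 3 times
  a robust (MAD) noise scale estimated outside the response window.
* "Reproducible on two successive trials" is quantified as: both traces
  carry a detected response, their smoothed mean-centered 0–50 ms segments
  correlate at $r \ge 0.7$, and the P latencies agree within 2 ms. The
  smoothing inside the correlation is essential: on raw 25–50-epoch
  averages the correlation is dominated by out-of-band noise and would
  reject visibly identical responses; smoothing to the response bandwidth
  is the quantitative analogue of judging reproducibility on the displayed
  (visually smoothed) averages.
* The staircase estimator descends in 5-dB steps while levels replicate,
  reports the lowest replicable level as the threshold, switches to the
  ascending branch when the start level fails, and reports "absent" when
  nothing replicates up to the device ceiling.

## Problem sizes and numerical conventions

The recovery suites run at the scale of the normative study itself: cohorts
of 118 children (236 ears) for reference-model recovery, repeated over 100
seeds; 200 simulated ears for the staircase accuracy check; 2000 pairs for
interaural correlation recovery. Empirical asymmetry limits use type-7
quantiles (linear interpolation between order statistics), recorded in the
output metadata. ICC defaults to the one-way random-effects,
absolute-agreement, single-measurement form (ears within subject), with
two-way forms behind a flag; published pediatric values (≈0.84–0.88) are
descriptive context, not recovery targets, since the raw cohort is not
deposited. Group-comparison hypothesis tests (Wilcoxon, paired t, Welch,
Cochran–Mantel–Haenszel) are standard library routines and are not wrapped.

All randomness flows from explicit seeds; `run_pipeline()` writes every
artifact with locale-independent formatting and a manifest of MD5 content
hashes, and a repeated run with the same configuration reproduces identical
bytes.

## Known limitations

* The Box-Cox-normal sub-family cannot absorb residual kurtosis; strata
  failing `gof_check()` on symmetric-tail grounds would need the extended
  family.
* FP selection is sample-size dependent by design (closed test), so
  refitting with substantially more data may legitimately change the
  selected powers — curves agree over the central ages, edges move most.
* The staircase estimator's accuracy degrades for ears whose amplitude
  ratio is so low (≲ 0.6) that no level replicates at the study's epoch
  counts; such ears are reported absent rather than given an unreliable
  number.
* Age-varying latency reference bands are not modeled; the latency
  criterion is a fixed range.
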
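---
title: "Methods: quantitative EEG desynchronization and disconnection analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative EEG desynchronization and disconnection analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qeegpipe)
```

This vignette documents the models, estimators and numerical choices behind
`qeegpipe`, in the spirit of a statistical-methods appendix. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The analysis problem

Rodent pharmaco-EEG studies of psychedelic compounds quantify two
signatures: *desynchronization* — a broadband drop in absolute spectral
power during behavioral inactivity — and *disconnection* — a drop in
between-electrode functional connectivity, summarized per animal by a
global functional connectivity (GFC) scalar. Twelve epidural electrodes
over frontal, motor, parietal, auditory and temporal cortex (six
left/right homologous pairs) are recorded at 250 Hz against an olfactory
reference; behavioral activity is co-registered; compounds are injected
after a 10-min baseline, and analysis windows at 20–30, 50–60 and
80–90 min capture the drug's time course. Treatment is a between-subject
factor because each animal is recorded once.

## Signal model assumed by the estimators

All estimators treat the accepted signal segments as zero-mean,
second-order stationary within an epoch. Welch averaging (2-s Hann
windows, 50 % overlap, per-window demeaning) gives auto- and cross-spectra
on a 0.5-Hz grid; 2 s is the shortest window resolving the 1-Hz analysis
bins, which bounds the variance of the spectral estimates given the
roughly 120 s of signal an epoch contributes. Windows are fitted inside
segments, never across a gap.

**Band convention.** The six canonical bands share printed edges (4, 8,
12, 25, 30 Hz). They are resolved half-open — a bin at the edge belongs to
the upper band — with gamma closed at 40 Hz, so the bands partition bins
1–40 exactly and band powers are additive. The 0.5-Hz grid is folded into
1-Hz bins by summing the two grid frequencies k − 0.5 and k into bin k.

**Lagged coherence.** With cross-spectrum $S_{xy}$ and auto-spectra
$S_{xx}, S_{yy}$,
$$\mathrm{LC}(f) = \frac{\mathrm{Im}(S_{xy})^2}
  {S_{xx}S_{yy} - \mathrm{Re}(S_{xy})^2} \in [0, 1],$$
the standard form that discards the zero-lag component: any instantaneous
linear mixture of independent sources (volume conduction, a shared
reference) has exactly zero lagged coherence. The vendor software the
field uses does not publish its formula; this definition matches the
metric's stated intent and is the documented stand-in. Band values average
bin-wise LC weighted by $\sqrt{S_{xx}S_{yy}}$ so that bins with
negligible power cannot dominate; a denominator below $10^{-12}$ yields 0
(degenerate bin).

**Connectivity change and GFC.** Per subject, cell-wise
$\Delta = \log(\mathrm{LC}_{epoch}/\mathrm{LC}_{baseline})$ (the Box-Cox
ratio transform at $\lambda = 0$). Cells with LC below $10^{-3}$ in either
epoch are masked rather than producing extreme logs. GFC is the unweighted
mean of the unmasked cells across all 66 pairs and 6 bands, undefined
(flagged) below 50 % coverage. An alternative reading of the published
normalization — difference of logs of *group means* rather than per-cell
per-subject log ratios — was considered; the per-subject form is the one
compatible with a subject-level GFC entering a repeated-measures ANOVA.
The KDE of pooled changes uses a Gaussian kernel whose *standard
deviation* is 0.5 (our interpretation of the stated kernel "width"); the
evaluation grid spans the observed range ± 4 bandwidths, slightly wider
than the minimum, so the trapezoid integral is 1 within $10^{-3}$ even
when samples sit at the grid edge.

**Equal effective data per epoch.** The finite-sample null bias of the
lagged-coherence estimator scales with the reciprocal of the Welch window
count, so if a subject's epochs contribute different amounts of selected
signal, every weakly coherent cell of $\log(\mathrm{LC}_{epoch}/
\mathrm{LC}_{baseline})$ inherits a *coherent* offset
$\approx \log(n_{baseline}/n_{epoch})$ — a per-subject drift that dominates
the variance of the GFC mean. The pipeline therefore truncates each
subject's accepted segments so every epoch hosts exactly the subject's
minimum window count (`equalizeWindows = TRUE`, the default), the
coherence-analysis analogue of equalizing trial counts across conditions.

## Segment selection

The published workflow selects a 10-s artifact-free exemplar *visually*
and then applies a semiautomatic amplitude criterion with reliability
thresholds. Reproducibility forbids a human in the loop, so the exemplar
is the 10 usable seconds with the lowest across-channel peak amplitude.
"1.25 of maximal amplitude" is enforced per channel against the exemplar's
per-channel maximum. Scanning proceeds in 1-s steps (matching the
per-second reliability blocks), accepting chronologically until the 120-s
target. The vendor's split-half and test-retest reliabilities are
unpublished; we define both as symmetric power-agreement ratios
$1 - |m_1 - m_2|/(m_1 + m_2)$ on mean squared per-second RMS, interleaved
(odd/even seconds) versus sequential halves, keeping the ≥ 0.9 threshold
semantics. If the accepted set fails a threshold, the second with the most
deviant power (largest $|m - \mathrm{median}|$) is dropped and the check
repeated — a deterministic tie-break-free rule. Epochs retaining under
30 s are rejected. Sleep-suspect and handling periods are excluded exactly
like artifacts. Lowering the amplitude factor can only shrink the accepted
set (monotonicity), which the suite verifies.

## The mixed ANOVA

qEEG responses are normalized per subject as log ratios to the subject's
own baseline, which yields three within-levels (the three post windows) —
this is what makes the treatment:time interaction carry
$(k-1)(t-1) = 6$ df in a four-arm design. (The behavioral ANOVA keeps
baseline as a fourth level, since inactivity durations are compared
directly between baseline and treatment intervals.) Sums of squares come
from explicit projections: the between-subject stratum splits subject
means into treatment and subject-within-group error; the within stratum
splits subject-centered residuals sequentially into time, treatment:time
and subject × time error. Unbalanced arms are accepted (achieved dfs are
reported); subjects with incomplete cells are dropped with a message.
Greenhouse–Geisser $\hat\varepsilon$ comes from the pooled within-group
covariance via
$(\sum\lambda_i)^2 / ((t-1)\sum\lambda_i^2)$ of the double-centered
matrix, clamped to $[1/(t-1), 1]$; a centered trace below $10^{-9}$ of the
total variance is declared degenerate. Within-effect p values multiply
both dfs by $\hat\varepsilon$. Post-hocs are pooled-variance two-sample t
tests of all pairwise group contrasts at each time level, Bonferroni
corrected by the number of comparisons actually performed (the published
family is not stated; the family size is configurable via the gate
argument). They run only when the interaction is significant. The GFC
rule: significant interaction → per-time post-hocs; otherwise significant
treatment main effect → time-collapsed pairwise comparisons read as an
overall GFC effect; otherwise no effect.

Numerical contract, enforced by oracle tests: F statistics agree with an
independent explicit least-squares fit to $10^{-8}$ relative on random
small designs; the SS decomposition is exact; $\hat\varepsilon$ matches
the textbook element-wise formula to $10^{-10}$; the GG-corrected
interaction test's type-I error sits inside the binomial 95 % interval of
0.05 under a spherical null. `boxcoxRatio` uses `expm1` so the general-λ
branch converges to the log branch (the analytic gap is
$\lambda\log^2 r/2$, which fixes the achievable tolerance at any given
λ).

## Topographic maps

"3-D spline mapping" is implemented as exact (non-penalized) thin-plate
spline interpolation on the flattened (anterior, lateral) skull
coordinates; a true head-surface model is out of scope. Exactness gives
reproduction of the electrode values and of affine fields to numerical
precision, and linearity in the data lets one basis matrix serve all
subjects. The grid covers the electrode bounding box plus a 1-mm margin
at 0.25-mm resolution (configurable; coarser grids are used in tests),
masked to the convex hull + margin, and built symmetrically so mirrored
inputs give mirrored maps. At each grid point the group contrast is tested
with the same mixed-ANOVA machinery and binned at p < 0.05/0.01/0.001. No
correction is applied across grid points — the published convention
corrects across comparisons, not map pixels — and that choice is recorded
in the output.

## The synthetic-data generator

Each channel is a sum over bands of band-limited Gaussian noise — white
noise shaped by the squared-magnitude response of a 4th-order Butterworth
bandpass, applied in the frequency domain with zero phase — plus a 1/f
background (flattened below 0.5 Hz) and white sensor noise. Coupled pairs
share a source with variance fraction *w*; the second channel receives it
through a pure delay (rounded to whole samples), so the cross-spectrum is
$w\,S_b(f)\,e^{-i2\pi f\tau}$ in closed form and the lagged-coherence
target is computable analytically — the ground truth is derived from the
mixing weights, delays and component spectra, never estimated from the
realized signal, and is evaluated on the same 0.5-Hz grid and band
aggregation the estimators use. Drug effects are per-epoch multiplicative
gains (band power, coupling fraction) applied as step functions that
switch at the post-administration window starts; each gain-constant
stretch is synthesized independently in the frequency domain (sources
drawn as complex Gaussian spectral coefficients on the band's numerical
support, cut at $10^{-4}$ of the peak squared magnitude), which keeps
every stretch exactly stationary at a per-subject cost of about a second.
Zero-lag couplings with nonzero weight, lags at or beyond the band's
center period, per-channel shared fractions above 1, and schedules longer
than the recording are rejected with errors, never clipped.

Defaults are fixed once as the study conditions: 250 Hz; band RMS
amplitudes 40/30/20/12/9/8 µV (delta through gamma, the low-frequency
dominance typical of rodent cortical surface EEG); 10 µV 1/f background;
2 µV sensor noise; couplings on all six homologous pairs (w = 0.4) and the
ipsilateral fronto-parieto-temporal chains (w = 0.18) in every band with
conduction delays shrinking from 16 ms (delta) to 4 ms (gamma). An early
sparser default left 94 % of pair × band cells with zero true coherence,
which made GFC a mean of pure log-ratio noise — unrepresentative of real
recordings, where coherence is measurable across the montage — and was
widened to the present structure on those grounds. Activity episodes
(uniform 5–15 s, exponential gaps, target fraction configurable) add
>40-Hz EMG-like noise (30 µV) and biphasic movement transients
(~300 µV, 2/min) so both the inactivity filter and the amplitude criterion
are exercised. Output is quantized at 16 bits over ±500 µV using the
half-range convention (LSB = 500/2¹⁶ µV = 7.63 nV/bit): the emulated
hardware's printed resolution and bit depth are mutually inconsistent
under the usual full-range convention (which would give 15.26 nV/bit), and
we match the printed resolution.

**What the generator does not emulate:** biophysical dipoles and volume
conduction (couplings are purely delayed shares, so zero-lag leakage
exists only if injected through a mixing matrix), non-stationarity within
an epoch, sleep architecture, electrode impedance drift, and line noise.
Passing parameter-recovery tests therefore shows the *estimators* are
correct under the stated model, not that real recordings satisfy that
model.

## Problem sizes used in tests and the acceptance script

Recovery runs use two arms of 8 subjects and a compressed schedule of four
120-s epochs (administration at 120 s). The published protocol records
600-s epochs but analyses only ~120 s of selected signal per epoch, so the
compressed schedule matches the effective data volume per epoch while
keeping 20-replicate simulations around ten minutes on one CPU. The
desynchronization arm multiplies all band powers by 0.6 in E1–E2; the
disconnection effect multiplies coupling fractions by 0.7 in all three
post windows. Null calibrations (type-I error) run on directly simulated
spherical Gaussian designs (500 replicates), which needs no signal
synthesis.

## Known limitations

* The reliability metrics and the lagged-coherence formula are documented
  stand-ins for unpublished vendor definitions; absolute values may differ
  from vendor output even where decisions (≥ 0.9; band ranking) agree.
* GFC averages log ratios over cells whose estimates are noisy wherever
  true coherence is near zero; with many null cells the statistic is
  dominated by estimator noise (visible in the generator when coupling is
  sparse).
* The epoch-gain step model makes drug effects piecewise constant;
  pharmacokinetic ramps are not modeled.
* EDF storage re-quantizes to the EDF 16-bit convention (15.26 nV/bit over
  ±500 µV), so a write/read round trip is exact only to that step.
* Unbalanced designs use sequential (projection-order) sums of squares,
  matching `aov`; heavily unbalanced designs where Type-II/III sums would
  differ materially are outside the intended use.
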
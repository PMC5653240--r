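---
title: "Quantifying burst-and-pause firing and its dendritic signals"
author: "nociburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying burst-and-pause firing and its dendritic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nociburst)
```

## The scientific problem

Polymodal nociceptors — in *Drosophila* larvae, the Class IV
dendritic-arborization neurons of the body wall — respond to strong
thermal stimuli not with a smooth rate increase but with
*burst-and-pause* firing: short high-frequency spike triplets followed
by quiescent periods. These patterns are tightly coupled to
arbor-wide dendritic Ca²⁺ transients (L-type voltage-gated Ca²⁺
channels upstream, small-conductance Ca²⁺-activated K⁺ (SK) channels
shaping the pause downstream), and they matter behaviorally: larvae
whose nociceptors fire more bursts roll away from a heat probe sooner
and more often.

`nociburst` packages the quantitative machinery needed to study this
phenomenon: a spike-train burst detector and pause metrics, dendritic
Ca²⁺-transient detection and parametric onset estimation, ratiometric
FRET Cl⁻ quantification, a dendritic-coverage image score, the
statistical battery used for screen-style comparisons, and — because
the recordings themselves are not distributable — a synthetic-data
generator that reproduces the statistical structure the analysis
assumes, with known ground truth.

## The unconventional-spike detector

The unit of burst-and-pause firing is the *unconventional spike* (US):
within four sequential spikes, the first and second interspike
intervals (ISIs) are both **shorter than 9 ms** and the third ISI is
**longer than 20 ms**. The first three spikes form the US; the third
ISI is its *pause*. Both comparisons are strict, following the
"less than / longer than" wording of the definition (an ISI of
exactly 9 ms does not qualify), with a 10⁻⁹ ms guard so
floating-point representation can never flip a boundary case.

```{r us}
st <- SpikeTrain(c(0.100, 0.108, 0.116, 0.220), stimWindow = c(0, 1))
detectUS(st)
pausePeriods(detectUS(st), st)
```

Design choices the definition leaves open:

* **Overlap resolution.** Whether quadruples may share spikes is not
  specified. The detector scans left to right and resumes after a
  matched triple, so USs never share spikes. This greedy rule is
  deterministic and matches rasters in which each burst carries one
  mark. The suite proves it equivalent to brute-force quadruple
  enumeration (with the same greedy selection) on 500 random trains.
* **Pause exclusion.** USs that occur around stimulus shutdown and are
  not followed by another spike within the stimulus window have an
  undefined pause and are excluded from pause statistics.
* **ISI time course.** For the ISI_X table, ISI₀ is the ISI
  terminating at the first US's last spike, ISI₁ is the pause, and
  negative X counts through the ISIs preceding the US (ISI₋₁ ends at
  the US's first spike). For trials without USs the 11-ISI window is
  placed with the trial's minimum ISI at X = 0; this placement is a
  documented convention (the original description is ambiguous) and is
  flagged in the result's `window_convention` attribute.

Firing-rate fluctuations are quantified with a 100-ms centered boxcar
advanced in 10-ms steps (the exact estimator used on the original
recordings is not recoverable, so window and step are exposed).
`countRatePeaks()` counts local maxima of at least 25 Hz separated by
troughs below half the smaller flanking peak. The 25-Hz default sits
between the rate a single background spike contributes to the boxcar
(10 Hz) and that of a 3-spike burst (30 Hz).

## The calcium transient model and its fit

Dendritic Ca²⁺ transients are modeled as a double-exponential
rise-and-decay,

$$f_{Ca}(t) = A\,\bigl(1 - e^{-(t-t_0)/\tau_{on}}\bigr)\,
  e^{-(t-t_0)/\tau_{off}}, \quad t > t_0,$$

and exactly 0 for \(t \le t_0\). \(t_0\) is the onset, \(\tau_{on}\)
(bounded to 0.05–0.5 s) the rise time constant, \(\tau_{off}\)
(1.5–10 s) the decay time constant, and \(A \ge 0\) an amplitude
scale. Stepwise transients accompanying several USs are fitted as a
sum of components with per-component \(t_0\) and \(A\) and shared
time constants — the steps of one recording share kinetics, and
per-component time constants would be poorly constrained
(per-component values remain available).

Where the original analysis adjusted the time constants manually per
trial, `fitTransient()` replaces manual tuning with *bounded
multi-start Levenberg–Marquardt*: every onset initialization is tried
as given and shifted by one rise time constant either way, and the
lowest-RSS solution wins. For \(K > 1\) components the fit is
warm-started from the \(K-1\) solution plus a small component at the
largest residual; because a zero-amplitude extra component reproduces
the smaller model exactly, the RSS is non-increasing in the component
count (a tested invariant). A linear nuisance term \(c + b\,t\) is
fitted alongside by default; it is exactly zero on drift-free input
and absorbs any residual photobleaching trend, which otherwise biases
onset estimates late by ~10 ms at the generator's default bleach
rate. The closed-form peak location
\(t_0 + \tau_{on}\log(1 + \tau_{off}/\tau_{on})\) is verified against
the fitted model to within one sample.

```{r fit}
tt <- seq(0, 6, by = 0.01)
trace <- FluorTrace(tt, caTransientModel(tt, 0.1, 1.0, 0.1, 2.0),
                    baselineWindow = c(0, 1), stimWindow = c(1, 2),
                    unit = "dff")
fitTransient(trace, window = c(0.5, 6), t0Inits = 1.1)
```

### Normalization and event detection

ΔF/F₀ uses F₀ = the mean fluorescence over the final 100 ms before
stimulus onset (right-open, so the onset sample itself is excluded).
The slow fluorescence decline during imaging is removed by fitting a
linear trend (exponential optional — the original description states
only that the decay was subtracted, so the simplest adequate model is
the default) to samples outside detected events, padded by 1 s after
each event so the slow sub-threshold tail cannot bias the trend.

Transients are detected with a Schmitt trigger: an event opens when
the trace stays ≥ 4 baseline SDs above the baseline mean for two
consecutive samples and closes when it falls below 1 SD. The original
work cites the approach without numbers, so the multipliers are
documented defaults, not inferred values. The two-sample opening
requirement is part of the detector's operating point: with the SD
estimated from ~100 baseline samples, a single-sample rule has a
heavy-tailed (Student-t) false-positive rate of a few percent per
trace, while shot-like noise is uncorrelated between samples and real
transients (\(\tau_{on} \ge 50\) ms at 100 Hz) stay above threshold
for many samples. The suite verifies < 1% of pure-noise traces
produce any event.

## FRET Cl⁻ quantification

The SuperClomeleon ratio is
\((\mathrm{YFP}_{cell} - \mathrm{YFP}_{bg}) /
  (\mathrm{CFP}_{cell} - \mathrm{CFP}_{bg})\),
computed per frame from region *means* (region-size invariant), with
an error naming the first frame whose background-subtracted CFP is
non-positive. ΔR subtracts the baseline-window mean; ΔR_peak is the
maximum over the stimulus epoch. Because Cl⁻ binding quenches YFP,
a ratio increase is read as a fall in intracellular Cl⁻; the module
reports ratios only and leaves that inference to the user (no
calibration to absolute concentrations is attempted).

## Dendritic coverage score

Arbor micrographs are scored in four steps: (1) intensity inversion
and line enhancement — a light Gaussian pre-smoothing (σ = 1 px; the
Laplacian is a high-pass filter and would otherwise amplify pixel
noise ~4.5-fold), a 3×3 Laplacian, then an oriented semilinear line
operator (after VanderBrug's construction: centered 5-px line strip
mean minus parallel flank-strip means, maximum over 0°/45°/90°/135°,
clipped at zero — the 1976 construction admits variants, so strip
length and flank offset are parameters); (2) binarization at Otsu's
threshold by default; (3) a maximum filter (disc dilation, radius
2 px) to bridge separated dendrite segments, then connected-component
labeling that drops components under 30 px (spotted noise); (4) a
34 × 34 px (14 × 14 µm) grid anchored at the image origin, counting
squares that contain any foreground pixel; partial edge squares count
as full squares. The interactive manual correction used on real
micrographs is replaced by parameter overrides. On synthetic arbors
the pipeline reaches ~98% square-level agreement with ground truth.

## Statistics

`runComparison()` wraps Student's/Welch's/paired t, Wilcoxon rank-sum
and signed-rank tests (all two-sided; sidedness was unstated, and
two-sided is the conservative reading) with Bonferroni or Holm
correction over the listed contrasts — by default each group versus
the first, mirroring versus-control screen panels. Behavioral
response rates use exact Clopper–Pearson intervals by beta-quantile
inversion; `latencyCompare()` tests responder latencies by default
and offers a censored mode scoring non-responders as ties at the
window bound, since how non-responders entered the original latency
tests is unstated — both modes are reported side by side when it
matters. Spearman's ρ is always computed from midranks; its p-value
comes from `cor.test()` (exact for small untied samples, otherwise
the t-approximation).

## What the generators emulate — and what they do not

The synthetic module is first-class, tested code. Its defaults *are*
the study conditions wherever those are stated: burst ISIs of 4–8 ms
(inside the 9-ms bound), pauses from a gamma distribution (shape 3)
with median 104 ms for controls and 46.75 ms for the knockdown
regime, calcium onsets leading the first burst spike by
N(50 ms, 10 ms) truncated at zero, fit time constants 0.15 s / 2 s
inside the standard bounds, 100-Hz sampling, a 1-s stimulus inside a
3-s trial, latency medians 3.8/4.86/1.8 s with a 5-s observation
window, and a 34-px coverage grid.

Values the source does not state were fixed once, by explicit
operating-point analysis, and are exposed in configuration:

* **Background rates** — 1 Hz spontaneous, 3 Hz non-burst firing
  during the stimulus. The burst motifs carry the high-frequency
  content; these rates keep the expected number of chance
  quadruple-matches and chance 3-spikes-in-100-ms clusters well below
  one per trial, so detector output reflects embedded structure.
* **Calcium noise SD** — 0.5% ΔF/F₀, chosen so a single-US step
  (model peak 0.76 × 5% ≈ 3.8% ΔF/F₀) stands ~7.5 baseline SDs above
  the noise and is reliably caught at the 4-SD Schmitt threshold.
* **Photobleaching** — a linear decline of 2%/s across the whole
  recording (continuous excitation illumination); exponential decline
  is available. Recordings extend 6 s past the stimulus so the
  transient tail decays within the trace and the trend is
  identifiable from event-free samples.
* **Motif placement** — embedded bursts are spaced by at least one
  rate-analysis window (100 ms) when room allows, as in recorded
  trains where bursts are spread across the stimulus; background
  spikes are suppressed through each burst and its pause, and the
  spike terminating the pause is emitted exactly at the pause end, so
  embedded pauses are exactly recoverable (a leaky mode disables the
  suppression for robustness tests). Drawn pauses are truncated just
  above 20 ms so every embedded burst satisfies the detector's
  predicates.

The generators reproduce the *statistical* structure of the
recordings, not their physics: no membrane biophysics, no indicator
binding kinetics, no motion or focus drift in images, no correlated
(pink) noise, and rendered arbors are random trees rather than
genotype-specific morphologies. Passing recovery tests therefore
demonstrates that the analysis is correct and well-calibrated under
the assumed data model — not that it is robust to every artifact of
real recordings.

## Problem sizes and numerical choices

The validation suite runs the detector-oracle comparison on 500
random trains, pause/US recovery on 100 trials, onset-fit recovery on
50 noisy traces against a grid-search oracle (onset grid 10 ms,
amplitude solved in closed form per grid point), the lag recovery on
100 single-burst trials, amplitude coupling on 50 cohorts of 25
trials, the Schmitt false-positive rate on 1000 noise traces,
coverage on 20 synthetic arbors, Clopper–Pearson coverage on 5000
replicates, the Wilcoxon null on 2000 replicates, and cohort power on
200 replicates of 20-versus-34 trials — sizes at which every
stochastic check is stable across seeds. Fits use
`minpack.lm::nls.lm` with tight tolerances (1e-12) and at most 200
iterations; all generator randomness flows through explicit seeds and
`withr::with_seed`, so every result in this vignette and in
`scripts/acceptance.R` is bit-reproducible.

## Known limitations

* The non-US ISI-window placement and the Δt spike reference (first
  versus last spike of the first US; both implemented, first-spike
  default) are documented conventions, not recovered facts.
* Decay correction assumes the bleaching trend is identifiable from
  event-free samples; traces that are saturated with events end to
  end fall back to the fit's internal linear nuisance term.
* The coverage pipeline's agreement figure is measured on synthetic
  trees; real micrographs with dense crossings or uneven illumination
  will need the exposed threshold/bridge/component parameters, which
  replace the original GUI-based manual correction.
* Ratio traces are never converted to absolute Cl⁻ concentrations.
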
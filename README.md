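# nociburst

Quantitative analysis of **burst-and-pause firing** in polymodal
nociceptors (Class IV dendritic-arborization neurons of *Drosophila*
larvae) and of the dendritic signals that accompany it, for
electrophysiologists and imaging labs studying how bursting patterns
arise and what they do downstream.

The core quantity is the **unconventional spike (US)**: within four
sequential spikes, the first and second interspike intervals are both
shorter than 9 ms and the third is longer than 20 ms; the first three
spikes form the US and the third interval is its **pause**. Around
that detector the package provides:

* pause-period statistics, ISI time courses, firing-rate traces
  (100-ms boxcar) and fluctuation-peak counts, spontaneous rates;
* dendritic Ca²⁺ analysis: ΔF/F₀ = (Fₙ − F₀)/F₀ with photobleaching
  subtraction, Schmitt-trigger (4 SD open / 1 SD close) transient
  detection, and onset estimation by bounded multi-start least-squares
  fitting of the double-exponential model
  f(t) = A (1 − e^−(t−t₀)/τon) e^−(t−t₀)/τoff (τon ∈ 0.05–0.5 s,
  τoff ∈ 1.5–10 s), including stepwise multi-component fits;
* SuperClomeleon FRET Cl⁻ quantification
  (YFP − bg)/(CFP − bg), ΔR and ΔR_peak;
* a dendritic coverage score: line enhancement (Laplacian + oriented
  VanderBrug-style operator), Otsu binarization, gap bridging,
  speckle removal, and counting of occupied 34 × 34 px (14 × 14 µm)
  grid squares;
* the statistical battery for screen-style comparisons: t and
  Wilcoxon tests with Holm/Bonferroni correction, Spearman's ρ,
  Fisher's exact test, and Clopper–Pearson response-rate intervals;
* a seeded synthetic-data generator (spike trials with embedded burst
  motifs, calcium traces, FRET channel pairs, rendered arbors,
  behavioral cohorts with non-responders) with full ground truth, used
  throughout the test suite.

See the vignette (`vignettes/burst-pause-analysis.Rmd`) for the
models, parameter defaults, and design decisions.

## Worked example

Simulate a control-condition trial (three embedded bursts, gamma
pauses with 104-ms median), detect its USs, and estimate the calcium
onset:

```r
library(nociburst)

sim <- simulateSpikeTrial(trialGenParams(), seed = 42)
ev  <- detectUS(sim$train)
ev
#>   i1 i2 i3       t1       t2       t3  isi1_ms  isi2_ms following_isi_ms
#> 1  6  7  8 1.172194 1.179853 1.187175 7.659224 7.321791        140.04184
#> 2 10 11 12 1.481049 1.488797 1.495364 7.748302 6.566982        123.67952
#> 3 14 15 16 1.875285 1.880430 1.886506 5.144558 6.076384         90.81391

pausePeriods(ev, sim$train)
#> [1] 140.04184 123.67952  90.81391

ca  <- simulateCalciumTrace(sim, caGenParams(), seed = 42)
trc <- subtractDecay(ca$trace)
fit <- fitTransient(trc, window = c(0.8, 8), nComponents = 3)
fit
#> TransientFit: 3 component(s), tauOn=0.5 s, tauOff=1.73 s, rss=0.02067 [at bound]
#>   t0=1.104 s  A=0.1075
#>   t0=1.519 s  A=0.0901
#>   t0=4.13 s  A=0.004813

onsetLag(fit, ev) * 1000   # ms; negative = calcium leads the burst
#> [1] -67.67507
```

The three detected triples are exactly the embedded motifs (intra-burst
ISIs < 9 ms, following intervals > 20 ms), the pauses are the
generator's drawn values, and the fitted first-component onset leads
the first burst spike by ~68 ms — the generated lag for this trial was
64 ms (drawn from N(50, 10) ms). Cohort-level runs
(`runCohort()`) assemble per-trial metrics tables and apply the
configured tests across cohorts.

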
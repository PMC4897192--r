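---
title: "Chaotic global analysis of short RR series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chaotic global analysis of short RR series: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaoglob)
```

## The problem

Healthy heart rhythm is not metronomic: the beat-to-beat (RR) intervals of the
ECG fluctuate in a complex, broadband, arguably chaotic way, and a *loss* of
that complexity accompanies autonomic dysfunction in conditions such as chronic
obstructive pulmonary disease (COPD). Most nonlinear complexity measures need
long recordings; the "chaotic globals" approach instead scores a short series
(1000 beats, roughly 15 minutes) by applying statistics to its **power
spectrum**, where convergence is much faster, at the cost of discarding phase.

`chaoglob` implements that toolkit end to end:

1. **Preprocessing** (`read_rr()`, `filter_artefacts()`, `take_window()`):
   beat lists are read from monitor text exports, ectopic beats and artefacts
   removed, and exactly 1000 clean beats retained. A series is *eligible* when
   at least 1000 clean beats remain and more than 95% of raw beats survive
   filtering (the "sinus rhythm" criterion).
2. **Spectra** (`welch_psd()`, `mtm_psd()`): a Welch averaged periodogram
   (Hamming window, segment and FFT length 256, zero overlap, no detrending,
   one sample per beat) and a Thomson adaptive multitaper (DPSS, time-bandwidth
   3, five tapers, same 256-point grid).
3. **Chaotic globals** (`spectral_entropy()`, `sdfa()`, `smtm()`): three
   statistics of those spectra, each affinely rescaled so a pure sine scores 0
   and uniform random noise scores 1.
4. **Chaotic forward parameters** (`compute_cfp()`): the seven Euclidean
   combinations of the three globals (with the sDFA component reflected as
   `1 - sdfa`, since it responds to chaos in the opposite direction).
5. **Cohort statistics** (`cohort_report()`): per-CFP quartiles by the (n+1)
   rule, Anderson-Darling and Ryan-Joiner normality screens, two-group
   Kruskal-Wallis tests, and a correlation-matrix PCA of the subjects-by-CFP
   grid per group.

## The three-reference normalization

Each global is an affine rescaling of a raw statistic $T$ evaluated on three
spectra: a pure sine wave, uniformly distributed random noise (averaged over
`n_realizations = 50` seeded realizations to stabilize the upper anchor), and
the experimental series,

$$ G \;=\; \frac{T(\text{signal}) - T(\text{sine})}{\overline{T}(\text{random}) - T(\text{sine})}, $$

so the sine maps to 0, random noise to (approximately) 1, and an experimental
series in between. The raw statistics are:

* **Spectral entropy**: Shannon entropy $H = -\sum p_i \ln p_i$ of the
  sum-normalized Welch spectrum. A line spectrum has low entropy; a flat one
  approaches $\ln(129)$ on the 129-bin grid.
* **sDFA**: the detrended-fluctuation scaling exponent $\alpha$ computed on the
  Welch spectrum *with frequency bin as the abscissa* (integrated
  mean-subtracted profile, non-overlapping boxes, per-box linear detrend,
  log–log slope of the RMS residual). Box sizes: 8 log-spaced values in
  [4, 32] on the 129-bin spectrum — the widest range the `length/4` DFA
  constraint allows.
* **sMTM**: the area between the multitaper spectrum and its baseline (the
  spectrum minimum), which grows with the intensity of broadband noise.

### Why the series is standardized before comparison

An RR series has a mean (~800 ms) an order of magnitude above its fluctuations
(~40 ms). With the mean retained, the DC bin carries more than 99% of spectral
mass for *every* input, and all three raw statistics collapse onto values
determined by that common DC structure: in our measurements the sDFA exponents
of the sine, random and experimental spectra agreed to ~1e-5, so the
normalization above became a ratio of round-off noise. The globals are
therefore computed on the **standardized** series (zero mean, unit SD) and
compared against equally standardized references. Consequences we consider
features:

* the fixed points hold exactly (the sine reference itself returns 0);
* all three globals are exactly invariant to rescaling and shifting the input
  — they measure spectral *shape*, not amplitude or offset;
* the mean heart period, which carries no information about complexity, cannot
  leak into the score.

The spectral estimators themselves (`welch_psd()`, `mtm_psd()`) do **not**
remove the mean: a constant series shows a pure DC line, and users who want
raw spectra (e.g. to replot a subject's periodogram) get the unmodified
convention.

### Why sMTM uses the amplitude spectrum by default

"Area above the minimum" computed on the *power* spectrum of a standardized
series is dominated by a handful of near-line bins, and how the 256-point
frequency grid samples those peaks is essentially random (the grid is coarser
than the DPSS bandwidth for 1000-point tapers). Measured across uniform-noise
draws this made the normalized statistic useless (spread ±1.3 around its fixed
point) and even inverted the cohort effect. Computing the same
area-above-minimum on the **amplitude (root-power) spectrum** compresses the
peaks, keeps the broadband floor — the quantity sMTM is designed to sense —
visible in the area, and yields a stable fixed point (±0.2), a smooth monotone
response to added noise, and the expected cohort direction. The literal power
form remains available (`scale = "power"`), as does a zero baseline
(`baseline = "zero"`).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `nfft`, `segment_length` | 256 | Welch/MTM grid; 129 one-sided bins |
| sampling | 1 per beat | beats are unit-spaced samples; frequencies are cycles/beat |
| `nw`, `k` | 3, 5 | DPSS time-bandwidth and taper count (`k = 2nw - 1`) |
| `adapt_tol`, `max_iter` | 1e-10, 400 | Thomson adaptive-weight convergence; line-dominated spectra need ~110-210 passes |
| `sine_freq` | 0.125 | sine reference, bin-centred on the 256 grid |
| `n_realizations`, `seed` | 50, 42 | random-reference averaging and reproducibility |
| sDFA boxes | 4-32, 8 sizes | log-spaced, non-overlapping |
| `threshold_pct`, `window` | 0.20, 11 | artefact filter: moving-median deviation rule |
| analysis window | first 1000 beats | see "Open choices" below |
| `combination` | euclidean | CFP combining rule; `normalized_euclidean` divides by sqrt(member count) |
| quartile rule | type 6 | the (n+1) interpolation convention |

The Thomson weights are reported in normalized form
$\lambda_k b_k^2 / \sum_j \lambda_j b_j^2$, which lie in $[0,1]$ and sum to 1
at every frequency; convergence is declared when their largest change falls
below `adapt_tol`.

## Open choices and their rationale

* **Artefact filtering.** The original protocol used digital plus *manual*
  editing, which cannot be automated faithfully. We use a deterministic
  moving-median rule (window 11 beats, 20% threshold) standard in HRV
  preprocessing; removed beats are deleted, not interpolated, because the
  analysis treats beats as unit-spaced samples. Eligibility is a flag, not a
  gate: the CLI refuses ineligible input unless `--force`.
* **Which 1000 beats.** Whether the analyzed window should be the first or
  last 1000 clean beats of a longer recording is not fixed by the method;
  `take_window()` defaults to `first` and exposes `last`.
* **Welch segment length.** Only the FFT length is canonical; we read
  "Hamming window with FFT length 256" in the conventional way, segment length
  = FFT length. The symmetric (MATLAB-convention) Hamming window is used.
* **MTM taper length.** Tapers span the full 1000-beat series; eigenspectra
  are evaluated exactly on the 256-point grid by zero-padding to 1024 and
  decimating (every 4th bin).
* **"Median" entropy.** The intermediate entropy is described in the source
  literature as a median over the three test conditions; a literal median
  admits no normalization with the stated fixed points, so the experimental
  (middle) value enters the two-point map above.
* **CFP scale.** The Euclidean combination is not normalized by member count
  by default; `cfp1` can therefore exceed 1 (up to $\sqrt3$ for components at
  1). Cohort outputs record which combination produced them so tables from
  different rules are never mixed.
* **Ryan-Joiner p-values.** The published critical-value interpolation
  formulas are reliable only up to n ≈ 100 (beyond that the fitted 10%
  critical value exceeds 1). Because the RJ statistic with Blom plotting
  positions is exactly $\sqrt{W'}$ of Shapiro-Francia, p-values come from
  Royston's validated W′ approximation; the reported statistic remains the
  correlation.
* **PCA conventions.** Correlation-matrix PCA (eigenvalues sum to 7, so an
  eigenvalue of 4.1588 is 59.4% of variance and {4.1588, 2.8078} reach 99.5%);
  loading signs are fixed by making each component's largest-magnitude
  coefficient positive. Published loadings may use any sign convention, so
  only magnitudes are comparable across implementations.

## The synthetic cohort generator

`generate_demo_cohorts()` emulates the study design — 19 "normal" and 19
"COPD-like" resting supine recordings of 1000 beats — as

$$ RR_i = \bar{RR} + a_{LF}\sin(2\pi f_{LF} i + \phi_1)
        + a_{HF}\sin(2\pi f_{HF} i + \phi_2) + \sigma\,\varepsilon_i $$

with $f_{LF} = 0.10$ and $f_{HF} = 0.25$ cycles/beat (the conventional LF and
HF bands at typical resting rate), per-subject amplitudes drawn once with 20%
between-subject coefficient of variation, and everything deterministic per
(master seed, group, subject index). Frozen group settings:

* normal: $\bar{RR} = 800$ ms, $a_{LF} = 25$, $a_{HF} = 30$, $\sigma = 40$ ms;
* COPD-like: same baseline and LF, $a_{HF} = 12$, $\sigma = 15$ ms.

The COPD-like reduction — less broadband noise and less high-frequency
(vagally mediated) oscillation — is the simplest mechanism that produces the
clinical direction of interest, a decreased chaotic response. It is a
statistical stand-in, **not** a physiological model: real RR series have
respiratory coupling, nonstationarity, fractal long-range correlations, and
occasional ectopy, none of which are emulated (ectopics can be implanted
manually to exercise the filter). Passing the end-to-end tests therefore shows
the pipeline detects reduced broadband/HF content at realistic effect sizes
and sample sizes; it does not certify clinical performance on real cohorts.

## Numerical notes and problem sizes

* DPSS tapers come from the classical symmetric tridiagonal eigenproblem;
  concentrations from the sinc-kernel quadratic form. Both are cached per
  `(n, nw, k)`; the 1000-point basis is computed once per session (a few
  seconds) and reused everywhere. Agreement with an independent reference
  implementation is ~1e-10 relative (tapers, concentrations, and the adaptive
  spectrum on a frozen fixture).
* Degenerate inputs: a constant series yields a valid DC-line spectrum from
  both estimators, but the chaotic globals are undefined for it (zero
  variance) and error clearly, as does DFA on inputs with exactly zero
  fluctuations.
* Test-suite problem sizes are chosen to keep the full run within a few
  minutes while leaving comfortable statistical margins: fixed-point checks
  average 25-50 uniform draws (the mean's standard error is 3-6x smaller than
  the asserted tolerances), DFA theory checks use 100 series of length 4096,
  monotonicity sweeps use 5-10 levels x 4-8 seeds, and the discrimination
  study runs the full 19 + 19 pipeline across 20 master seeds.
* `sdfa` values slightly outside $[0,1]$ are expected for strongly
  line-dominated series (the experimental exponent can exceed the random
  reference's); they are reported as-is and combine through `1 - sdfa`
  without clipping.

## Limitations

* The globals characterize spectral shape at a fixed 256-bin resolution;
  series much longer than ~3000 beats gain nothing beyond better-averaged
  Welch segments.
* sDFA on 129 spectral bins is intrinsically noisy (box-size range is capped
  by the grid); its single-subject values scatter around the fixed points far
  more than spectral entropy does. Averaging over reference realizations
  stabilizes the anchors, not the subject's own value.
* The Kruskal-Wallis layer tests each CFP marginally with no multiplicity
  correction, mirroring the source analysis; with seven correlated CFPs the
  family-wise error is correspondingly higher.
* Two-column monitor exports are assumed whitespace-separated with RR in
  column 2; vendor binary formats are out of scope.
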
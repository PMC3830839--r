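---
title: "Statistical feature extraction for voice time series: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical feature extraction for voice time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Conventional classifiers need a rectangular instance-by-attribute matrix,
but a voice recording is a single long amplitude series — stochastic,
non-stationary, and of varying length.  `sfx` implements a hybrid
preprocessing pipeline that compresses each series into a fixed-length
vector that carries information from both the frequency domain (the
spectral envelope of the vocal tract) and the time domain (the trend and
volatility dynamics of the amplitude itself), followed by an ensemble
feature-selection stage and a standard evaluation suite.

## The feature model

Each labelled waveform is mapped to

\[
s = [\,\underbrace{c_1,\dots,c_{10}}_{\text{freq}},\;
      \underbrace{\bar X,\sigma,Q_1,Q_2,Q_3,K,\mathrm{IQR},S,
      \mathrm{RSS},\mathrm{resstd},\mathrm{volmean},\mathrm{volstd}}_{\text{whole series}},\;
      \underbrace{5\times n_\mathrm{seg}}_{\text{piecewise}},\;
      \underbrace{C}_{\text{DTW}}\,]
\]

so the width is \(u = 10 + 12 + 5 n_\mathrm{seg} + C\) — 124 at the
default 20 segments with two classes.  Attribute names (`cc_1…`,
`grad_1…`, `dtw_class_<label>`, …) are frozen API so selection masks are
portable between runs.

### Frequency block: LPC to cepstrum

Speech production is well approximated by an all-pole filter, so each
sample is modelled as a linear combination of its \(p\) predecessors.
The order follows the speech rule of thumb
\(p = \mathrm{round}(f_s/1000) + \gamma\) with \(\gamma \in \{2,3\}\)
compensating glottal roll-off: 12–13 at 10 kHz.  One model is fitted per
whole series — a Hamming taper over the entire signal, biased
autocorrelations at lags \(0..p\), and the Yule–Walker system solved by
Levinson–Durbin (a dense Toeplitz solve serves as the test oracle).  The
sign convention is \(\hat x(n)=\sum_i a_i x(n-i)\) with \(R\,a = r\), so
an AR(2) simulation is recovered with the textbook signs.

Predictor coefficients have high variance, so the feature vector uses the
cepstrum of the fitted all-pole spectrum instead, via the recursion
\(c_1=a_1\), \(c_n = a_n + \tfrac1n\sum_{k=1}^{n-1} k\,c_k\,a_{n-k}\).
The recursion is verified in the tests against the FFT real cepstrum of
the model spectrum (relative error below \(10^{-6}\); in practice it
agrees to machine precision).  The zeroth coefficient \(c_0=\ln G\) is an
energy term, not a spectral-shape term; the canonical frequency block
keeps exactly 10 shape coefficients, and \(c_0\) is exposed behind the
`include_c0` flag rather than silently appended.

### Whole-series statistics and the GARCH layer

The twelve whole-series statistics use the population standard deviation
\(\sigma = \sqrt{\tfrac1N\sum(x_t-\bar x)^2}\) and the moment-ratio
kurtosis \(K = \sum (x_t-\bar x)^4 / ((N-1)\sigma^4)\), which is
approximately 3 for Gaussian data; the excess form (−3) sits behind
`excess_kurtosis`.  Quantiles use linear interpolation between order
statistics (type 7) everywhere, for determinism.

Residual and volatility features come from an AR(1) mean equation with a
GARCH(1,1) conditional variance,
\(\sigma^2_t = \alpha_0 + \alpha_1 \epsilon^2_{t-1} + \beta_1
\sigma^2_{t-1}\), fitted by Gaussian maximum likelihood.  Numerical
choices that matter:

* **Parameterisation.** The optimiser works on an unconstrained scale:
  \(\omega = e^{\theta}\), persistence \(s=\mathrm{logit}^{-1}(\cdot)\in(0,1)\)
  and fraction \(\alpha/s=\mathrm{logit}^{-1}(\cdot)\), so
  \(\alpha+\beta<1\), \(\omega>0\) hold by construction and `converged =
  TRUE` can never report an explosive model.
* **Initialisation.** Deterministic starts (AR(1) OLS slope; persistence
  0.9 split 1:8 between \(\alpha\) and \(\beta\); \(\omega\) at 10% of the
  sample variance), two Nelder–Mead passes; fits are bit-reproducible.
* **Variance recursion** starts at the unconditional variance
  \(\omega/(1-\alpha-\beta)\); the likelihood loop is compiled (C++), the
  series-level recursion in R uses `stats::filter`.
* **Fitted range.** The AR(1) conditional mean defines \(\hat X_t\) for
  \(t\ge2\), so residual/volatility series have length \(N-1\) and RSS is
  summed over that range.  (Whether RSS should use the mean-equation
  fit or a GARCH-filtered value is ambiguous in the surrounding
  literature; the conditional mean is used and documented here.)
* **Fallback.** Estimation can be meaningless on degenerate input
  (constant segments, pathological tails).  Rather than aborting a
  pipeline run, such series fall back to model-free surrogates: residuals
  = mean-detrended series, volatility = rolling standard deviation
  (window 20, minimum 5 points), all-zero for constants.  The fallback is
  flagged on the returned object and never marked `converged`.

Simulation recovery — \((\alpha_0,\alpha_1,\beta_1)=(0.1,0.1,0.8)\) at
\(n=5000\), 20 replicates — is part of the acceptance suite (mean
absolute error per parameter ≈ 0.01, an order of magnitude inside the
0.1 tolerance).

### Piecewise block

The series is cut into `n_seg` contiguous pieces; when the length is not
divisible the first `N mod n_seg` pieces take the extra sample
(balanced-remainder rule — any deterministic convention would do, this one
keeps piece lengths within one sample of each other).  Each piece is
summarised by the OLS line \(s(t)=\beta t+\alpha+\epsilon\) over
\(t=0..n-1\): gradient \(\beta\), \(\mathrm{RSS}=\sum\epsilon^2\),
residual \(\sigma\), and volmean/volstd of a constant-mean GARCH(1,1)
fitted to \(\epsilon\).  The default `n_seg = 20` follows the calibration
that, for sentence-length recordings of about ten words, twenty segments
cut each word-level amplitude peak into a rising and a falling gradient.
The whole-series fit keeps its AR(1) mean, the segment fit drops it: the
segment trend is already removed by the OLS line, so the GARCH mean
equation would be redundant there.

### DTW block

The feature for class \(c\) is the mean DTW distance from the query to
the reference members of \(c\); a query that is itself a reference is
excluded from its own class average **by identity** (its `source_id`),
not by sample equality, and the divisor is the number of terms actually
summed.  Distances use the classic dynamic program with absolute local
cost, full window and no normalisation (compiled in C++; an exhaustive
warping-path enumeration is the test oracle).  Full-length DTW on 10–100 k
point series costs hours; every series is therefore mean-pooled to
`dtw_downsample = 500` points first — a deliberate deviation from running
DTW raw, chosen because mean pooling preserves the burst-scale shape that
the class distances measure at a small fraction of the cost.

At train/test time the reference set is the **training** corpus only, so
test-row features never see test labels; the tests verify that permuting
test labels leaves test features bit-identical.

## Feature selection

All information-theoretic selectors discretise features by equal-frequency
binning (10 bins), which is robust to heavy-tailed attributes such as RSS.

* **χ²** scores each feature by the statistic of its bin-by-class
  contingency table; the retained count is picked by CV over
  \(k\in\{10,20,30,u/2\}\), since a p-value cut is not meaningful after
  equal-frequency binning.
* **CFS** greedily maximises
  \(\mathrm{Merit}=k\bar r_{cf}/\sqrt{k+k(k-1)\bar r_{ff}}\) with
  symmetrical-uncertainty correlations, stopping at the first
  non-improving step.  A subtlety uncovered while testing: duplicating an
  already-selected feature leaves the merit unchanged at \(k=1\) but can
  *increase* it for larger subsets when the duplicated feature is better
  than the subset average — a property of the merit formula itself, not of
  the search.  The tests therefore assert the \(k=1\) identity and that
  the greedy search never terminates on a pure duplicated pair.
* **mRMR** greedily maximises \(I(x;c) - \frac{1}{|S|}\sum_{s\in S}
  I(x;s)\), first pick = max relevance; the greedy sequence is checked
  step-by-step against brute force.
* **WSA** is a binary wrapper around a bio-inspired search that balances
  group scouting (breadth) and individual prowl (depth).  The binary
  operators are the package's own adaptation of the Wolf Search
  heuristic to feature masks:
  each wolf (a feature mask) per iteration (a) prowls — evaluates one
  random neighbour at each Hamming distance \(1..r\) (visual radius
  \(r=3\)) and moves to the best fitter one; (b) joins the best fitter
  companion within visual range, adopting each differing bit with
  probability ½; (c) escapes with probability 0.25 by flipping a larger
  random bit set.  Fitness is stratified 5-fold CV accuracy with folds
  fixed per run and values cached per mask; the best mask ever evaluated
  is returned (elitist), and the search stops early once fitness reaches
  its ceiling of 1.  Defaults: 10 wolves, 50 iterations.
* **Ensemble** re-scores every method's mask on the *same* folds and
  takes the winner; ties break toward fewer features, then method order.
  Accuracy alone decides — time cost is reported but never trades against
  accuracy.

The wrapper's CV never predicts an instance from a model trained on it;
fold assignment is stratified and seeded.

## Classifiers and metrics

Three reference classifiers honour the plug-and-play contract
(`fit`/`predict`/scores): an information-gain decision tree (rpart,
information split, `minsplit` relaxed to 5 so corpus-scale folds can
split), nearest centroid, and a regularized linear discriminant (ridge on
the pooled covariance, so the collinear cepstral/piecewise blocks cannot
break it).  Scores from non-probabilistic classifiers are min-max
normalised per instance for ROC use.

The confusion matrix is oriented **rows = predicted**; transposing it
silently swaps precision and recall, hence the explicit convention.
κ uses \((P_a-P_e)/(1-P_e)\) with the documented convention at
\(P_e=1\).  Macro averages are the headline multiclass summary; weighted
averages are always reported alongside.  AUC uses the rank (Mann–Whitney)
formulation with midranks, which the tests show equals the trapezoidal
ROC area to \(10^{-9}\).

## The synthetic generator

Real voice corpora are external downloads, so the package generates
labelled voice-like signals: a harmonic stack at a class-specific
fundamental frequency (classes differ in f0 and harmonic amplitude
profile), multiplied by word-like raised-cosine amplitude bursts with
per-burst height jitter, plus GARCH(1,1) noise whose volatility
clustering mimics the bursty energy of speech.  Four presets mirror
common task regimes: `fm-like` (2 well-separated classes, f0 120 vs
220 Hz), `es-like` (4 overlapping classes), `si-like` (8 partially
overlapping classes), `lr-like` (3 classes).  Defaults are 4000 samples
at 10 kHz per instance — desk-scale stand-ins for sentence recordings.

What the generator does **not** emulate: phonetic content, formant
transitions, coarticulation, channel/microphone effects, or
between-speaker variability beyond f0 and envelope.  A passing
end-to-end test therefore demonstrates that the pipeline recovers
class structure that lives in pitch, spectral envelope and amplitude
dynamics — it does not certify performance on real corpora.

## Problem sizes used by the test and acceptance runs

Unit tests run on miniature configurations (5 segments, 60-point DTW
pooling, hundreds of samples).  The end-to-end comparison uses the
fm-like preset at 2 classes × 30 instances × 4000 samples with 5-fold CV,
averaged over five corpus seeds; oracle experiments use \(n=50{,}000\)
(LPC), \(n=5000\) × 20 replicates (GARCH), 200 random short pairs (DTW),
and exhaustive search over ≤ 7-feature matrices (CFS/WSA).  These sizes
were chosen so the whole suite reproduces on a single CPU in minutes
while leaving each estimator enough data to sit well inside its stated
tolerance.

## Known limitations

* GARCH(1,1) with Gaussian innovations only; heavier-tailed innovation
  distributions (common in speech) are absorbed by the volatility series
  rather than modelled.
* One LPC model per series: very long non-stationary recordings would
  conventionally be framed; the per-instance vector shape here requires a
  single fit.
* DTW mean pooling trades fine-scale warping sensitivity for speed; the
  pooled length is configurable.
* The WSA operator set is one reasonable binary adaptation of the
  heuristic; other faithful variants exist and can be swapped in behind
  the same wrapper interface.
* Equal-frequency binning with 10 bins is a fixed discretisation choice;
  selectors see ties collapsed on features with many repeated values.
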
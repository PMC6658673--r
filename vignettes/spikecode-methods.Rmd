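---
title: "Rate codes, temporal codes, and the information transmission rate"
author: "spikecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate codes, temporal codes, and the information transmission rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package addresses

A sensory neuron can signal a stimulus with how *often* it fires (a rate
code) or with *when* it fires (a temporal code). The two strategies have
very different energy budgets — spikes are metabolically expensive, and a
rate code spends them in proportion to the signal — so distinguishing them
matters for understanding sensory pathways such as the retino-thalamic
relay, where ON cells (driven by luminance increments) fire roughly three
times as often as OFF cells (driven by decrements).

`spikecode` operationalizes the distinction with two moving-window time
series computed from the same spike train:

* the **firing rate** \(F_R(t) = n_T/T\), the spike count in \([t, t+T)\)
  divided by the window length, in spikes/s;
* the **information transmission rate** \(\mathrm{ITR}(t)\), the entropy
  rate of the binarized response in the same window, in bits/s.

If the cell uses a rate code, the two series rise and fall together and
their Pearson correlation (PCC) is high. If information rides on spike
patterns at a roughly constant rate, the series decouple and the PCC is
low. The package provides the estimators, the moving-window machinery, the
trial averaging, and a synthetic-data module that generates both regimes
with known ground truth, so that every stage can be validated without any
recorded data.

## Encoding and the entropy-rate estimators

Spike times are binned at resolution \(\Delta\tau\) (default 1/80 s =
12.5 ms; ITR saturates near 80 bins/s for this class of data), writing 1
for a bin with at least one spike. A window of length \(T\) (default 5 s,
a compromise between estimator accuracy and local stationarity) is then a
binary word of \(L = fT = 400\) bits at the default resolution.

**Direct method.** For block lengths \(L\) the plug-in block entropy is
\(H(L) = -\sum_w P(w)\log_2 P(w)\) over overlapping \(L\)-bin words. For a
stationary ergodic source \(H(L)/L\) decreases to the entropy rate \(h\)
as \(L \to \infty\), and for Markov-like sources it is close to linear in
\(1/L\). The estimator therefore fits an unweighted least-squares line to
the points \((1/L,\, H(L)/L)\) and reports the intercept at \(1/L = 0\):

```{r}
library(spikecode)
sq <- simulate_markov_train(markov_spec(0.3, 0.4), 1e5, seed = 1)
est <- direct_method_rate(block_entropy_curve(sq), f = 80)
summary(est)
plot(est)   # H(L)/L against 1/L with the fitted line
```

Numerical choices, all visible in the code:

* **Undersampling guard.** A block length enters the fit only while the
  number of word positions is at least \(10 \cdot 2^{\min(L,\,L H_1)}\),
  where \(H_1\) is the single-bin entropy: roughly ten samples per word of
  the typical set, so sparse spike trains may use longer words than dense
  ones. On 400-bit windows of near-balanced sources this admits
  \(L = 1..5\); candidates default to \(L = 1..10\). In the moving-window
  series the guard is applied once per segment — every window has the same
  size, and letting the fitted \(L\)-set switch between neighbouring
  windows would inject artificial jitter into the series.
* **No bias correction.** Entropies are raw plug-in estimates; the direct
  method's extrapolation absorbs most of the finite-sample bias, and the
  validation below quantifies what remains.
* **Clamping.** On near-deterministic windows the fitted intercept can
  fall slightly outside \([0, 1]\) bits/bin; it is clamped and flagged
  (`clamped = TRUE`, counted per series in attribute `"n_clamped"`).
* Logarithms are base 2 throughout; rates are reported per symbol and per
  second (`rate_per_second = rate_per_symbol * f`).

**Lempel–Ziv cross-check.** The LZ76 exhaustive-history complexity
\(c(n)\), normalized as \(c(n)\log_2(n)/n\), is a consistent entropy-rate
estimator and serves as an independent check. The phrase count is computed
exactly via a suffix array, Kasai's LCP recursion and a
longest-previous-factor elimination (compiled code), which keeps
\(10^6\)-bin sequences tractable; the quadratic textbook scan is kept in
the test suite as the oracle for short strings. On the symmetric-chain
grid \(p = 0.1, \dots, 0.9\) at \(10^6\) bins both estimators agree with
the analytic rate to within 2%; the LZ76 normalization converges more
slowly on strongly asymmetric chains (approaching ~2% residual error at
the extreme corners of the \((p_{01}, p_{10})\) square), which is why the
direct method is the primary estimator and LZ76 the cross-check.

**The Markov oracle.** A two-state chain with transition probabilities
\(p_{01}, p_{10}\) has stationary law \(\pi_1 = p_{01}/(p_{01}+p_{10})\)
and entropy rate \(h = \pi_0 H_b(p_{01}) + \pi_1 H_b(p_{10})\), with exact
block entropies \(H(L) = H_b(\pi_1) + (L-1)h\). This gives closed-form
targets at every scale. It also supplies the canonical counter-example to
equating firing with information: the symmetric chain with
\(p = 0.95\) fires in half of all bins (\(\pi_1 = 0.5\), the firing rate
of a fair coin) yet emits nearly periodic `0101...` sequences carrying
only \(H_b(0.95) \approx 0.286\) bits/bin — less than a third of the fair
coin's 1 bit/bin.

Validation scales used by the tests and the acceptance script, chosen as
the smallest sizes at which the asymptotic claims are cleanly visible:
1000 replicate 400-bit windows with \(p_{01}, p_{10} \sim U(0.2, 0.5)\)
(moderately mixing chains) for the short-window error, where the mean
absolute relative error of the direct method stays within a few percent
(the acceptance script recomputes it, typically ~2.5%), and \(10^6\)-bin
chains for the consistency grid.

## The synthetic experiment

The generator reproduces the structure of a flashed-spot experiment: 8-s
stimulus segments at 160 frames/s in which **R**epeat segments (one frozen
luminance sample) are interleaved with **U**nique segments (fresh
samples), either alternating (`RU`, 128 + 128) or in `RRRRU` blocks.
Luminance frames are i.i.d. log-normal (`sdlog = 1`), the standard
heavy-tailed marginal of natural luminance with its temporal correlations
deliberately stripped; the per-frame parameters are configuration knobs,
not measured values. Analyses average over the repeat segments only, as
the repeat-trial protocol intends.

Two cell models realize the two coding regimes. Both share a
difference-of-Gaussians spot-size factor (center radius 0.6°, surround
radius 1.8°, surround weight 0.6, normalized to 1 at the optimal
diameter): small spots underdrive the receptive-field center, very large
spots recruit the suppressive surround. Defaults encode the ON/OFF
asymmetry: OFF cells at 5 spikes/s, ON cells at 15 spikes/s.

**Rate-code cells** are inhomogeneous Poisson with intensity
\(\lambda(t) = \max(0,\; r_0 + g\,s_\pm(t))\), where \(s_\pm\) is the
z-scored instantaneous luminance contrast signed by polarity, thinned by a
1-ms refractory period. Firing tracks the stimulus; information tracks
firing.

**Temporal-code cells** are burst-mode Markov emitters: bins are drawn
from a two-state chain whose stationary spike probability is pinned at
\(r_0\Delta\tau\) while the stimulus modulates the chain's persistence
\(\lambda(t) = 0.8\,\mathrm{logit}^{-1}(-g\,\bar s(t))\), with \(\bar s\)
the luminance integrated over a 0.3-s window and z-scored. Low effective
contrast pushes the cell into persistent burst firing (low entropy rate),
high contrast into independent tonic firing — the tonic/burst dichotomy of
thalamic relay cells, at an exactly fixed expected rate.

The burst-Markov construction was chosen over the more obvious
alternatives after both failed quantitative scrutiny. A renewal process
with stimulus-dependent shape (gamma ISIs at fixed mean) holds the
*long-run* rate fixed but not the *windowed count expectation*: by the
renewal boundary expansion \(E[N(T)] \approx T/\mu +
(\sigma^2-\mu^2)/2\mu^2\), windows of bursty ISIs systematically hold up
to ~1 extra spike, which hands the firing-rate series a reproducible
component correlated with the entropy signal — precisely what a temporal
code must not do. A jittered-lattice code (fixed spike grid,
stimulus-dependent timing noise) fails in the mirror way: with no count
noise left, a tiny stimulus-dependent boundary effect dominates the FR
series. Pinning the stationary law of a Markov emitter makes the expected
count of *every* window constant by construction, which is the property
the diagnostic actually requires.

## Time series, trial averaging, and the PCC

`sliding_metric_series()` computes one ITR or FR value per window start
\(t \in \{0, \delta, 2\delta, \dots\}\) (stride \(\delta\) defaults to one
bin, 12.5 ms), so an 8-s segment with \(T = 5\) s yields a 3-s usable
span and a 32-s segment a 27-s span. Block entropies are updated
incrementally as the window slides (one word leaves, one enters, per block
length), keeping a 128-trial analysis fast. `trial_average()` returns the
pointwise mean and descriptive SD over repeat trials plus a time-averaged
CV summary; `windowed_pcc()` traces the Pearson correlation of the
averaged ITR and FR series in 0.25-s moving windows, flagging (not
fabricating) zero-variance windows; `summary_pcc()` is the single
full-span correlation; `summarize_by_spot_size()` tabulates conditions
into small (< 1°), medium (1–2°) and large (> 2°) spot categories.

A statistical caution that shaped the regime-separation experiment: the
full-span PCC between two series smoothed by a 5-s window has very few
effective degrees of freedom (a 3-s span contains barely one independent
window), so the per-condition summary PCC of a signal-free FR series is a
wide lottery around zero no matter how many trials are averaged — PCC is
scale-free, so shrinking the FR noise amplitude does not help. The
regime-separation study therefore (i) uses 32-s repeat segments, the
long-block protocol span, and (ii) pools a battery of conditions per
regime — 3 cells x 3 spot sizes, each with its own frozen stimulus
(`regime_study_config()`) — and compares regime-level mean PCCs. Under the
frozen default seed the rate-code regime averages ~0.98 and the
temporal-code regime ~0.08, with every rate-code condition above every
temporal-code category summary; single temporal-code conditions can still
stray (one condition reaches ~0.87 in the default battery), which is the
expected residue of the few-degrees-of-freedom problem, not a failure of
the generator.

```{r}
st <- run_study(regime_study_config(seed = 1))
st$regime_summary
st$spot_summary
```

## What the synthetic data do and do not show

The generator emulates the trial protocol, the heavy-tailed decorrelated
luminance drive, the ON/OFF rate asymmetry, the center–surround spot-size
dependence, and two cleanly separated coding regimes. It does **not**
emulate temporal stimulus correlations, receptive-field spatial structure,
adaptation, spike-sorting artifacts, or the mixed codes real neurons
likely use; trial-to-trial variability is purely generative (Poisson or
Markov), so the synthetic CV% values are larger than the sub-2% figures
typical of averaged recordings. Passing the regime-separation test shows
the *pipeline* can discriminate the two strategies where ground truth is
known — it does not certify any particular claim about biological cells.

## Degenerate inputs and tie-breaks

Bins are left-closed half-open intervals anchored at the analysis start; a
spike exactly at the window end is excluded; off-grid window starts snap
down to the containing bin (recorded in attribute `"t_snap"`). Multiple
spikes per bin clip to 1 (counted in `"n_clipped"`); spikes outside the
requested span are ignored but counted (`"n_ignored"`). Windows where no
block length passes the guard raise an estimation-failure condition rather
than returning a number; zero-variance correlation windows are `NA` with a
flag. All generators are pure functions of their arguments and a seed, and
the pipeline derives per-segment seeds deterministically, so identical
configurations reproduce identical files byte for byte.

## Limitations

* The direct method inherits a small negative bias from plug-in entropies
  on short windows; at 400 bits it is the dominant error term (a few
  percent, quantified by the acceptance script) and is not corrected.
* The LZ76 normalization \(c(n)\log_2 n/n\) converges slowly off the
  symmetric diagonal of the Markov parameter square; treat it as a
  consistency check, not a precision estimator.
* Per-condition summary PCCs on 5-s windows are low-powered by
  construction (see above); interpret them only in pooled batteries.
* The temporal-code generator is one minimal realization of
  "pattern-not-rate" coding; real temporal codes (latency codes, phase
  codes) have structure this model does not attempt.
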
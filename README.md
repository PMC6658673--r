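# spikecode

Diagnosing neural coding strategies — rate code versus temporal code —
from single-unit spike trains, by comparing the **firing rate** with the
**information transmission rate** (ITR) of the same response.

Sensory neurons can signal a stimulus through how often they fire or
through the temporal arrangement of their spikes. The two strategies are
distinguishable information-theoretically: binarize the spike train at
resolution Δτ (a bin is 1 if it contains a spike), slide a window of
length T over the response, and compare

* `F_R(t) = n_T / T` — the spike count in `[t, t+T)` over the window
  length, in spikes/s, and
* `ITR(t)` — the entropy rate of the binarized window, in bits/s,
  estimated by the *direct method*: fit a least-squares line to the
  normalized block entropies `(1/L, H(L)/L)` and extrapolate to the
  intercept at `1/L = 0`, where
  `H(L) = -Σ_w P(w) log2 P(w)` over overlapping L-bin words.

A high moving-window Pearson correlation (PCC) between the two series
indicates a rate code (information rides on spike frequency); a low one
indicates a temporal code (information rides on pattern at a roughly
constant rate). A two-state Markov source makes the dissociation exact: a
symmetric chain with transition probability 0.95 per bin fires in half of
all bins — the firing rate of a fair coin — yet its nearly periodic
`0101...` output carries only `Hb(0.95) ≈ 0.286` bits/bin against the
coin's 1 bit/bin.

The package provides, in base R with a small compiled core:

* encoding: spike-time binning, window extraction, overlapping word
  counts (`bin_spikes`, `extract_window`, `count_words`);
* information: plug-in entropies, the direct-method estimator
  (`direct_method_rate`, an S3 model object with `print`/`summary`/
  `coef`/`residuals`/`plot` methods), an exact LZ76-complexity
  cross-check (`lz76_rate`), plug-in mutual information, and closed-form
  Markov oracles (`markov_stationary`, `markov_entropy_rate`,
  `markov_block_entropy`);
* time series: moving-window ITR/FR series, trial averaging, windowed
  and full-span PCC, spot-size category summaries;
* synthetic data: decorrelated natural-luminance stimuli, repeat/unique
  trial protocols (`RU`, `RRRRU`), inhomogeneous-Poisson rate-code cells
  and burst-mode Markov temporal-code cells with ON/OFF polarity and
  center–surround spot-size dependence;
* pipeline: YAML-configured simulate/analyze/validate runs with CSV/JSON
  outputs and deterministic seeding (`run_simulate`, `run_analyze`,
  `run_study`, `run_validate`).

## Worked example

Estimate the entropy rate of a Markov spike source and compare it with
the analytic value:

```r
library(spikecode)
spec <- markov_spec(p01 = 0.3, p10 = 0.4)   # bin width 12.5 ms
markov_entropy_rate(spec)
#> <itr_estimate> analytic: 0.9197 bits/bin = 73.58 bits/s (f = 80/s)

sq  <- simulate_markov_train(spec, n_bins = 1e5, seed = 1)
direct_method_rate(block_entropy_curve(sq), f = 80)
#> <itr_estimate> direct: 0.9206 bits/bin = 73.65 bits/s (f = 80/s)
lz76_rate(sq, f = 80)
#> <itr_estimate> lz76: 0.9384 bits/bin = 75.08 bits/s (f = 80/s)
```

The direct method lands within 0.1% of the analytic 0.9197 bits/bin and
the LZ76 cross-check within 2% at this length. The same machinery run end-to-end on
the synthetic experiment (3 cells × 3 spot sizes per coding regime, 128
repeat trials of 32-s segments, T = 5 s windows):

```r
st <- run_study(regime_study_config(seed = 1))
st$regime_summary
#>          regime n   mean_pcc mean_itr   mean_fr
#> 1     rate_code 9 0.98136379 27.04663  5.505251
#> 2 temporal_code 9 0.08035782 44.37300 14.928472
```

Rate-code (OFF-like) cells show an ITR–FR correlation near 1; burst-mode
temporal-code (ON-like) cells fire three times faster, transmit more
bits, and show essentially no ITR–FR correlation — the coding-strategy
dichotomy the PCC diagnostic is designed to expose. `st$spot_summary`
breaks the same table into small/medium/large spot categories.

See `vignettes/spikecode-methods.Rmd` for the model assumptions, the
undersampling guard, estimator validation scales and known limitations.

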
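---
title: "Canonical response parameterization: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical response parameterization: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crp)
```

## The model

A stimulation session at one recorded site is a matrix $\mathbf{V}$ of $T$
timepoints by $K$ trials, each column the voltage over a window $[t_1,
t_2)$ after one stimulus. The working model is that every trial contains a
common, stimulus-locked component of fixed shape, scaled per trial, plus
everything else:

$$V_k(t) = \alpha_k\, C(t) + \varepsilon_k(t),$$

where $C(t)$ has unit L2 norm over the *response window* $[t_1, \tau_R)$,
$\alpha_k$ is a scalar projection weight, and $\varepsilon_k$ collects
measurement noise and brain activity not locked to the stimulus. The
modeling assumptions are that $\varepsilon$ has zero expectation and
comparable energy across trials; neither is enforced — by construction the
*sample* inner product $\sum_t C(t)\varepsilon_k(t)$ is exactly zero, so
the decomposition is an orthogonal projection regardless.

Three stages estimate the pieces.

**Duration.** The semi-normalized cross-projection
$P(k,l) = \sum_t \tilde V_k(t) V_l(t) / f_s$ (with $\tilde V_k = V_k /
|V_k|$, units $\mu V\cdot s$) measures how much of trial $l$ lies along the
direction of trial $k$. The mean $\bar S$ of the $K^2 - K$ non-self
projections, recomputed as the window end $t_2$ sweeps a grid, traces a
profile $\bar S(t_2)$; its earliest maximum is the response duration
$\tau_R$. Semi-normalization is the point: with both trials normalized the
statistic favors early transients and cannot accumulate evidence over
time, with neither normalized large-amplitude trials dominate. With one
side normalized, shared structure accumulates and, once traces return to
baseline, uncorrelated samples contribute nothing on average — noiseless
profiles plateau after the feature instead of decaying, and a sustained
offset (a baselining artifact) grows without bound, which is why baseline
fidelity matters so much (below).

**Shape.** Over $[t_1, \tau_R)$, $C(t)$ is the leading principal direction
of the truncated matrix. Since $T_R \gg K$, the $T_R \times T_R$ timepoint
covariance is unaffordable directly; the linear-kernel-PCA exchange
eigendecomposes the $K \times K$ Gram matrix $\mathbf{V}^\top\mathbf{V} =
\mathbf{F}\boldsymbol{\xi}^2\mathbf{F}^\top$ instead and maps back with $x_1
= \mathbf{V} f_1 / \xi_1$. (The mapping scaled by the inverse singular
value is the dimensionally consistent one; it reproduces $C = u$ exactly on
rank-one matrices $u w^\top$, which the tests assert.) The first component
is kept; higher Gram eigenvalues are exposed read-only for diagnostics. The
unit-normalized mean trace is available as an alternative (`method =
"mean_trace"`); on outlier-contaminated sessions it absorbs the outlier,
raising $\alpha'$ while lowering SNR and explained variance relative to the
principal direction — the tests reproduce that ordering on seeded
simulations.

**Per-trial parameters.** With $|C| = 1$, $\alpha_k = \sum_t C(t) V_k(t)$,
$\varepsilon_k = V_k - \alpha_k C$, and per trial: $\alpha'_k = \alpha_k /
\sqrt{T_R}$ ($\mu V$, an RMS-like amplitude over the significant window),
noise $\sqrt{\varepsilon_k^\top\varepsilon_k}$, SNR $\alpha_k /
\sqrt{\varepsilon_k^\top\varepsilon_k}$, and explained variance $1 -
\varepsilon_k^\top\varepsilon_k / V_k^\top V_k$, which equals
$\mathrm{SNR}^2/(1+\mathrm{SNR}^2)$ identically. The scalings by
$\sqrt{T_R}$ (not $T_R$) and the square root in the noise term are the
dimensionally coherent readings and are what make $\alpha'$ carry
microvolts and SNR stay dimensionless.

## Significance

Two tests are reported. *Extraction significance* asks whether any
reproducible structure exists: a two-sided one-sample t-test of
cross-projections against zero. The full set of $K^2-K$ values counts each
unordered trial pair twice (once per normalization direction), which
inflates the test — on null data the t statistic's variance is ~1.3–2×
too large. Inference therefore uses a *balanced half-selection*: exactly
one orientation per unordered pair, each trial serving as the normalized
member as close to half the time as possible. The paper-level description
leaves the concrete orientation open; this implementation uses a
deterministic circular tournament (pair $(k,l)$ oriented with $k$
normalized iff $(l-k) \bmod K \le \lfloor (K-1)/2 \rfloor$, diametral
pairs for even $K$ split alternately) so that no randomness enters the
statistics. *Parameterization significance* t-tests the $\alpha_k$ against
zero ($K-1$ df). Degenerate zero-variance samples report $p$ as exactly 0
(or 1 when the mean is also zero) with a flag rather than erroring.

### Calibration, and a winner's curse at $\tau_R$

`null_calibration()` pushes thousands of pure-noise surrogate sessions
(brown or white, $K = 10$, $T = 2048$ at 2048 Hz by default) through the
full pipeline. Two facts emerged that shape the defaults:

* At any **fixed** window end, half-selection extraction p-values on white
  noise are uniform on $(0,1)$ (e.g. 2000 sets: KS $p = 0.88$, 4.7% below
  0.05).
* Scored **at the per-set $\tau_R$**, they are strongly anti-conservative
  (~25% below 0.05 on white noise): $\tau_R$ is the argmax of the very
  mean the t-test evaluates, a textbook winner's curse. No implementation
  detail removes this; it is intrinsic to testing at a data-selected
  window.

The harness therefore scores at the full window by default (`at = "full"`)
and returns both p-value vectors so the bias is inspectable. Practically:
quote extraction significance at $\tau_R$ as a descriptive strength-of-
structure summary, but base calibrated claims (or null-session screening)
on a fixed window.

Brown noise adds a second, smaller caveat. A length-2048 random-walk trial
has only ~6 effective dimensions (participation ratio of its covariance
spectrum), so the 45 selected projections drawn from 10 such trials are
mutually dependent. The 5% tail stays accurate (fraction of null $p <
0.05$ sits inside the binomial band around 0.05), but the full null
distribution is measurably non-uniform — a KS test at $n = 2000$ detects
the shape deviation ($D \approx 0.08$). White-noise surrogates do not
show this; treat brown-noise KS flatness as approximate, tail calibration
as reliable.

## Artifact rejection

Each trial $k$ participates in $2(K-1)$ projections (both directions).
Comparing them against all projections *not* involving $k$ with a pooled
two-sample t-test flags trials whose shared structure is significantly
*below* the rest; the one-directional flag means a "too representative"
trial is never rejected. Two group definitions circulate (all
non-involving projections vs the half-selection restricted to the others);
the figure-level operational definition — all non-involving values — is the
default, with the other behind `others = "half"`. Rejection
(`reject_and_rerun()`) drops the single worst flagged trial, re-runs the
whole pipeline, and repeats; it refuses to go below 4 trials. The default
threshold $p < 10^{-6}$ sits between the two printed uses of the technique
(detection at $1.8\times10^{-6}$; batch rejection at $10^{-10}$) and flags
essentially zero trials on null sessions (≥99% of 500 white-noise sessions
flag-free in the tests). Detection defaults to full-window projections,
since artifacts outside the response window still corrupt extraction.

## The synthetic generator — what it does and does not emulate

`synth_spec()`/`make_session()` produce the validation conditions:
piecewise-analytic features (square, split square, ramps, triangle, sine
variants) placed on the sample grid by index arithmetic; brown noise built
as the cumulative sum of uniform$(-0.5, 0.5)$ deviates with the expanding
cumulative mean subtracted, z-scored to variance 1 (log–log spectral slope
≈ −2); white noise likewise variance-1. With noise, the signal template is
variance-normalized and multiplied by the signal-to-noise ratio, then added
to an independent variance-1 noise realization per trial — the ratio is an
amplitude-scale ratio between variance-matched components, the most literal
reading of the mixing description, applied consistently. Defaults (100 ms,
100 μV square; 3:1 brown noise; $K = 10$; 2048 Hz; 1 s window) are the
stated validation condition, with per-trial ratio grids (1.2–3.0 in 0.2
steps, and the harsher 0.38–2.94 set) supported for variable-SNR designs.

What passing these tests shows: duration recovery, amplitude recovery,
shape fidelity, significance calibration under the stated noise models.
What they cannot show: behavior under stimulation artifact bleed-through,
line noise, non-stationary baselines, trial-to-trial latency jitter, or
true neural variability in response shape — real recordings have all of
these, and only baseline offsets are explicitly handled (below).

One idealization deserves emphasis: with independent noise per trial, the
*single-session* rank correlation between recovered per-trial SNR and an
injected 1.2–3.0 grid averages only ~0.57 (the grid step is smaller than
the estimator's spread); the association is exact (Spearman ρ = 1) for the
per-position median over 100 seeded sessions, and that is the form the
acceptance checks assert.

## Numerical and interface choices

* **Window convention**: half-open $[t_1, t_2)$ on the sample grid, sample
  index $\mathrm{round}((\tau_k + t) f_s)$, so $T$ is deterministic and
  identical across trials. Defaults $t_1 = 15$ ms (clear of stimulation
  artifact), $t_2 = 1$ s.
* **Profile grid**: every sample from 10 samples after $t_1$ to the window
  end; the 10-sample floor avoids degenerate near-single-sample
  normalizations. $\tau_R$ is stable under 2× grid decimation (tested).
  Computation is incremental via cumulative pair products, $O(TK^2)$
  total.
* **Ties and bounds**: earliest maximizer wins (a later equal value adds
  nothing); uncertainty bounds are the contiguous run around the peak
  where the profile exceeds 98% of its peak. A peak on the last grid
  point raises a `boundary_peak` warning — the true duration may exceed
  the window. A late resurgence of structure only moves $\tau_R$ if it
  creates a strictly higher maximum.
* **Baseline**: the offset estimator is the per-trial median (robust to
  the response deflection itself) over a far-from-stimulus window (default
  last 20% of the epoch), tolerance 5 μV; correction is explicit and
  opt-in, because the core pipeline deliberately does not demean —
  demeaning is itself a baselining decision the analyst should own. A
  20 μV common offset turns pure noise into an apparently significant
  "response"; subtracting the estimated offsets removes it (tested).
* **Sign convention**: a principal direction has arbitrary sign; $C$ is
  anchored to non-negative projection onto the mean trace, falling back to
  a non-negative value at the largest-magnitude sample. Identical inputs
  give bit-identical output.
* **Gram symmetrization**: $(G + G^\top)/2$ before eigendecomposition
  guards against floating-point asymmetry.
* **Degenerate inputs**: non-finite samples are rejected at construction;
  zero-norm trials error by name; all-zero trials get explained variance 0
  with a flag instead of NaN; all-zero truncated matrices error.
* **Determinism**: JSON summaries use fixed field order and 10 significant
  digits, so identical runs are byte-identical; epoch files round-trip
  bit-identically via full-precision text.

## Problem sizes used in the checks

The bundled tests and the acceptance script run entirely on generated
data: 2000 surrogate sessions per noise model for calibration ($K = 10$,
$T = 2048$), 200 random matrices for the kernel-trick equivalence, 100
seeded sessions each for duration coverage and the SNR grid, and 500 null
sessions for the artifact false-positive rate — sizes chosen so the whole
suite completes in a few minutes on one CPU while leaving the binomial and
KS checks adequately powered.

## Limitations

The method does not parameterize feature timing: onset latency
($\tau_B$) estimation is deliberately out of scope, and temporal dilation
of a response between conditions is not tracked (time-warping would be the
natural extension). Changes confined to one deflection of a multiphasic
response are absorbed into $\varepsilon$ rather than tracked as shape
change; the residual re-parameterization path (`reparameterize_residuals()`
followed by a fresh extraction) is the supported way to look for
perturbation-induced structure. And, as discussed above, extraction
significance at $\tau_R$ should not be read as a calibrated p-value.
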
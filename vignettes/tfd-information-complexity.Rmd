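---
title: "Information complexity of time-frequency distributions: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information complexity of time-frequency distributions: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfdinfo)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the conventions chosen where several
readings were defensible, the numerical safeguards, and what the shipped
tests do and do not demonstrate about real recordings.

## 1. From a frame to distributions

The unit of analysis is a `signal_frame`: one real-valued time series with
its sample rate. The default study conditions used throughout the package
are frames of 16384 samples at 16 kHz (about one second), analysed with a
Hann window of 512 samples hopped by 128 (75% overlap), and Rényi order
$\alpha = 3$. These defaults are what `window_spec()`, `info_config()` and
`experiment_config()` return when called without arguments.

Three energy decompositions become probability distributions by
normalization to unit sum:

* **Spectral** $P_F$: the one-sided power spectrum of the whole frame. Bins
  $k = 0,\dots,L/2$ are kept; DC and Nyquist are retained without energy
  doubling. Since every distribution is renormalized, the one-sided
  convention has no effect on any information measure.
* **Spectrogram** $P_S$: $S[n,k] = |\mathrm{STFT}_h[n,k]|^2$ normalized
  over all $M\times N$ cells. The STFT uses no zero-padding; the last
  partial window is dropped; frame times are stamped at window centers and
  bin frequencies are $k f_s/N_W$.
* **Reassigned spectrogram** $P_R$: each spectrogram cell's energy is moved
  to the nearest grid node of its local energy centroid
  $$\hat t = t + \mathrm{Re}\frac{\mathrm{STFT}_{th}}{\mathrm{STFT}_h},
    \qquad
    \hat\omega = \omega - \mathrm{Im}\frac{\mathrm{STFT}_{dh}}{\mathrm{STFT}_h},$$
  computed from three transforms sharing one phase reference (the phase
  factor cancels in the ratios): the window $h$, its time-weighted
  companion $t\,h$ (time measured in seconds from the window center) and
  its time derivative $dh/dt$. For the Hann family the derivative is
  analytic; other families use a central finite difference (one-sample
  step), which is accurate to second order and documented per family.

**Reassignment numerics.** Cells whose STFT magnitude falls below
$10^{-12}$ of the frame maximum are masked: their centroid ratio is a
quotient of near-zeros, so their (negligible) energy stays at the original
cell rather than being scattered. Centroids landing outside the grid are
clipped to the boundary cell by default (`boundary = "clip"`), which makes
reassignment exactly energy-conserving — the property the tests assert to
$10^{-9}$ relative; `"drop"` is available when leakage off the grid should
be discarded instead. Exact half-cell ties round toward the lower index so
the operation is deterministic across platforms.

**What reassignment buys.** Its benefit is *concentration*: energy gathers
onto the ridges of tonal and FM components. The package quantifies this as
the energy-weighted mean deviation of the TFD from the true
instantaneous-frequency line (for a noiseless 500–4000 Hz chirp under the
default window: about 28 Hz for the spectrogram against 15 Hz after
reassignment). A per-frame *centroid* comparison would show nothing: for a
symmetric window the spectrogram centroid is already an unbiased ridge
estimator, and snapping energy to grid nodes leaves the reassigned
centroid with a sub-bin quantization offset. Concentration, not centroid
bias, is the right lens.

## 2. The column-stochastic decomposition and its ergodic pair

A second two-dimensional construction normalizes each analysis window's
spectrum separately: $P_{SC}[n,k] = S[n,k] / (M \sum_k S[n,k])$. The matrix
$A = M\,P_{SC}$ is right stochastic, and when it is square and regular its
powers converge to a rank-one matrix $\Omega$ whose rows all equal the
stationary vector $\Pi$ ($\Pi A = \Pi$).

Three conventions make this construction consistent:

* **The ergodic limit lives on $A$, not $P_{SC}$.** $P_{SC}$ itself sums to
  one overall, so its powers vanish; only the row-stochastic $A$ has a
  meaningful limit. When $\Omega$ is treated as a distribution (for
  entropy) it is renormalized by $1/M$ to unit mass on $M^2$ cells. Under
  exactly this reading the entropy identities
  $$H_{\mathrm{norm}}(\Omega/M) = \tfrac12\bigl(1 + H_{\mathrm{norm}}(\Pi)\bigr),
    \qquad
    H^{(\alpha)}(\Omega/M) = \log_2 M + H^{(\alpha)}(\Pi)$$
  hold to machine precision for every converged decomposition (a property
  the suite checks over random positive matrices), with the Rényi maximum
  $2\log_2 M$ attained at uniform $\Pi$.
* **Square coarse-graining.** A spectrogram under the default settings has
  $M = 125$ windows and $N = 257$ bins, so the stochastic matrix is not
  square. For the $\Omega/\Pi$ features the package first aggregates the
  longer axis into as many contiguous equal groups as the shorter axis has
  cells (`square_tfd()`), summing energies. Coarse-graining the frequency
  axis to the time resolution is a package convention; it preserves total
  energy and the row-normalization structure.
* **Floors.** An additive floor of $10^{-300}$ precedes every row
  normalization, so a window with tiny-but-nonzero energy never produces
  $0/0$; a window with literally zero energy raises an error naming the
  window. The $0\log 0 = 0$ convention applies in all entropies.

The stationary vector is found by power iteration from the uniform vector
(tolerance $10^{-12}$ in $L_1$, capped at $10^5$ iterations), cross-checked
against the eigen-solver in the tests. A fixed point of one start is not
evidence of regularity — the identity matrix fixes *every* vector — so
convergence additionally requires a second, perturbed start to reach the
same limit; periodic or reducible chains are reported as non-converged.

## 3. Information measures: conventions where the algebra forks

* **Normalization constant.** Normalized entropies divide by
  $\log_2(\#\text{cells})$; on a 2-D support the count is $MN$ (the index
  runs over flattened pairs), keeping normalized entropies in $[0,1]$.
* **Euclidean disequilibrium.** The squared form
  $D_{SQ} = \sum(p_i - q_i)^2$ is used, matching the algebraic identity
  $\sum p_i^2 - 1/N$ against the uniform reference.
* **Total variation.** $D_{TV} = \tfrac14\bigl(\sum|p_i-q_i|\bigr)^2$, the
  squared total-variation distance scaled so disjoint point masses score 1.
* **JSD inside complexities** enters in bits without further scaling: its
  1-bit bound already keeps the product bounded, and the choice is fixed
  here so feature values are comparable across runs.
* **Geometric-mean Rényi–JSD.** The combined term of
  $J^{(\alpha)}(P,Q) = H^{(\alpha)}(PQ) - \tfrac12(H^{(\alpha)}(P) +
  H^{(\alpha)}(Q))$ is computed as
  $H^{(\alpha)}(PQ) = \frac{1}{1-\alpha}\log_2 \sum (p_i q_i)^{\alpha/2}$ —
  the element-wise geometric mean $\sqrt{p_i q_i}$ raised to $\alpha$. This
  is the only convention that reproduces the three-cell worked case
  ($P$ uniform on 3, $Q = (\tfrac14,\tfrac14,\tfrac12)$, $\alpha=2$:
  $H^{(2)}(PQ) = \log_2 3$ and $J^{(2)} = \ln 3/\ln 2 - \tfrac32 \approx
  0.0849$) and it matches the Cauchy–Schwarz structure that guarantees
  $J^{(\alpha)} \ge 0$ for $\alpha > 1$ with equality iff $P = Q$. The
  combined array need not sum to one; that inconsistency is the point of
  the construction.
* **Symmetrized Rényi divergence.** Against the uniform reference the
  package implements (and tests) the identity
  $$D^{(\alpha)}(P,U) + D^{(\alpha)}(U,P)
    = \frac{\log_2 N}{1-\alpha} - H^{(\alpha)}(P)
      - \frac{\alpha}{1-\alpha} H^{(1-\alpha)}(P),$$
  which follows directly from $H^{(\beta)} = \frac{1}{1-\beta}\log_2\sum
  p^\beta$ and verifies numerically to $10^{-10}$. The symmetrized form is
  provided for completeness but never used as a disequilibrium at
  $\alpha > 1$, where one-sided absolute-continuity failures make it
  infinite.
* **Quadratic approximation of $J^{(\alpha)}$.** For $Q = P + \delta\rho$
  the gradient-only form
  $-\tfrac14 \sum (\partial H^{(\alpha)}/\partial p_i)\,\delta\rho_i^2/d_i$
  is implemented with the divisor $d_i$ taken from the base ($P$, the
  formula as stated) or the perturbed ($Q$, the worked evaluation)
  distribution; on the three-cell case these give $1/(16\ln 2) \approx
  0.0902$ and $1/(18\ln 2) \approx 0.0802$ respectively. A caution
  established while validating the package: expanding $J^{(\alpha)}$ fully
  shows the second-order term is
  $-\frac{\alpha^2}{8}\,\frac{\sum p^{\alpha-2}\delta\rho^2 -
  (\sum p^{\alpha-1}\delta\rho)^2/\sum p^\alpha}{(1-\alpha)\sum p^\alpha \ln 2}$,
  which coincides with the gradient-only form exactly when the base is
  uniform (the cross term vanishes) *and* $\alpha = 2$ (where
  $\alpha^2/8 = \alpha/4$). In that regime the remainder is $o(\|\delta\rho\|^2)$
  — the suite verifies the ratio $|J - J_{\mathrm{quad}}|/\varepsilon^2$
  vanishing over $\varepsilon = 10^{-2}, 10^{-3}, 10^{-4}$ — while for
  other orders or non-uniform bases the gradient-only form is a useful but
  only first-of-two-terms approximation with an $O(\varepsilon^2)$
  residual.

## 4. The 30-feature registry

No canonical enumeration of the feature set exists beyond its count, so
the package fixes and versions one: for each support $P_F$, $P_S$, $P_R$,
the four Shannon-family characteristics $H$, $C_{SQ}$, $C_{JSD}$,
$C_{TV}$ and the five Rényi-family ones $H^{(\alpha)}$,
$C^{(\alpha)}_{SQ}$, $C^{(\alpha)}_{JSD}$, $C^{(\alpha)}_{J^{(\alpha)}}$,
$C^{(\alpha)}_{TV}$ (27 features), plus the normalized $H(\Omega)$,
$H^{(\alpha)}(\Omega)$ and $H^{(\alpha)}(\Pi)$ of the column-stochastic
spectrogram (3 more). Every complexity multiplies the *normalized* entropy
of its family by the disequilibrium against the uniform reference on the
same support. All 30 values are invariant to amplitude scaling of the
input frame — asserted for the full registry in the tests. `feature_table()`
materializes batches as one CSV row per frame with a trailing label column.

## 5. Synthetic signal models

The generators define the study conditions; their defaults are fixed, not
tuning knobs.

* **Harmonic sums** $x(t) = \sum_{n=0}^{K-1} A_n \sin(2\pi(f_0 + n\Delta
  f)t + \phi_n)$. Phases are explicit parameters (zero by default) so both
  the closed-form model and the randomized experiments are reproducible.
  Components at or above Nyquist are rejected as aliasing errors.
* **LFM chirps** with instantaneous frequency $f(t) = ct + f_0$,
  $c = (f_1 - f_0)/T$; the analytic-signal phase-derivative oracle in the
  tests confirms the law to better than 1% away from the frame edges.
* **Band-limited Gaussian noise** by deterministic spectral masking:
  out-of-band DFT coefficients of a white Gaussian sequence are zeroed and
  the signal transformed back. Band confinement is then exact (the tests
  require at least 99.9% of energy in a 1–3 kHz band) with no filter-design
  ambiguity, at the cost of the mild time-domain ringing any ideal
  band-limitation implies.
* **Vessel cavitation model**
  $x(t) = (1 + \sum_{n=1}^{K} A_n \sin(2\pi n f_0 t))\,w_c(t) + w_e(t)$:
  broadband cavitation noise $w_c$ (1–3 kHz by default) amplitude-modulated
  by the shaft-rate tonal scale, plus ambient white noise $w_e$ scaled to
  the requested SNR of the modulated term. The envelope multiplies only
  $w_c$; $w_e$ is additive. Default modulation amplitudes are 0.25 with
  blade-rate multiples (every $m$-th harmonic, $m = 4$ blades) boosted to
  0.5 — a package convention standing in for the unstated amplitude law of
  shaft/blade tonal scales. Over-modulation (negative envelope) is allowed
  and messaged, not an error.
* **Exact SNR mixing.** `mix_at_snr()` rescales the signal in closed form
  so the time-domain energy ratio meets the request exactly (by Parseval
  this equals the spectral-power ratio); the noise frame passes through
  untouched as the $\Gamma_0$ hypothesis. `snr_db = -Inf` produces the
  null pair used for calibration checks.

All stochastic generators draw from substreams derived as
`(master_seed, index)` so every experiment is bit-reproducible and frames
are mutually independent.

## 6. The detection experiment and its desk scale

For each SNR on a grid, `run_detection_experiment()` scores $Q$ hypothesis
pairs — white Gaussian noise alone versus a freshly randomized model signal
mixed into that same noise — on every selected feature, then reduces the
two score samples to:

* **AUC-ROC**, computed rank-based (the Mann–Whitney statistic, ties one
  half) rather than from histograms, avoiding binning bias; histograms
  (Freedman–Diaconis) are kept only as optional diagnostics. Entropy-type
  features *fall* when a signal appears, so orientation is auto-flipped to
  keep AUC $\ge 0.5$, with the flip recorded.
* **Detection probability** at a fixed false-alarm rate (default
  $p_{fa} = 0.05$): the threshold is the empirical $1 - p_{fa}$ quantile of
  the noise-only scores after orientation — a Neyman–Pearson-style
  operating point chosen because no threshold rule is otherwise canonical.

Per-pair randomization fills the unstated laws with documented ones:
harmonic signals draw $K$ uniformly from 20–50 with unit amplitudes,
uniform phases, fundamental in $(0.01, 0.03) f_s$ and top component in
$(0.25, 0.45) f_s$; chirps draw both end frequencies uniformly in
$(0.05, 0.45) f_s$; vessels use the fixed default parameters with fresh
noise seeds. SNR is enforced per frame.

The suite runs this study at desk scale — $Q = 150$–200 pairs per SNR
point, chosen so the full test suite completes in about a minute on one
core — and asserts *orderings and trends*, not absolute AUC values, which
at production scale ($Q$ in the tens of thousands) would carry far smaller
Monte-Carlo error: AUC non-decreasing in SNR (at most one inversion per
feature); time-frequency features dominating spectral ones for chirps;
the reverse ordering for stationary harmonic sums at low SNR; and chance
behaviour (AUC $\approx 0.5$, $P_{rd} \approx p_{fa}$) in the null case.

**H/C planes.** `hc_points()` maps frames to (normalized entropy,
complexity) pairs for any support/measure combination. The tests check
class-separation on synthetic classes: white noise versus two-tone
mixtures separate by hundreds of pooled within-class standard deviations
on the spectrogram support; and for two *structured* classes (two-tone
versus chirp mixtures at 0 dB) the reassigned support increases the
centroid separation over the plain spectrogram. That last comparison is
deliberately made between structured classes: reassignment also sharpens
pure noise into spurious local concentrations, so against a noise class it
does not widen an already enormous gap.

## 7. What the synthetic conditions do not show

The generators emulate controlled laboratory versions of the signals of
interest: stationary tonal scales, ideal linear sweeps, stationary
cavitation modulation, spectrally flat ambient noise. Real recordings add
propagation effects (multipath, Doppler, fading), non-Gaussian and
non-stationary ambient noise, overlapping sources and recording-chain
artifacts — none of which are modelled here. Passing the shipped tests
therefore demonstrates the correctness of the measures and the qualitative
behaviour of the features under clean conditions, not field performance.
Classification of real corpora is explicitly out of the package's test
surface: `feature_table()` exports the 30-feature CSV that an external
gradient-boosting (or any tabular) learner consumes, but no trained model
ships and no accuracy claims are made.

Other known limitations: WAV is the only audio container (first channel
of multichannel files, with a message); resampling through the polyphase
resampler is the one stage where floating-point results may vary across
platforms, so byte-identical output claims are per-platform; the ergodic
features require the square coarse-graining convention of Section 2; and
the closed-form short-term entropy of idealized single-component
spectrograms is represented in the package only through its testable
consequence — one added well-separated component raises the order-3
spectrogram Rényi entropy by one bit (the suite asserts $1 \pm 0.2$).
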
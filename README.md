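# tfdinfo

Information-complexity features of time-frequency distributions for acoustic
signal detection and classification.

## What problem this package addresses

Passive-acoustic monitoring — of ship-radiated noise, of marine mammals, of
any source picked up by a hydrophone — reduces to two statistical questions:
*is a structured signal present in this noise?* (detection) and *which class
of source produced it?* (classification). Plain spectral statistics answer
these well for stationary tonal sources but fail for signals whose frequency
content moves during the observation window (FM sweeps, cavitation
modulation, vocalisations). `tfdinfo` computes a family of
information-theoretic features on **time-frequency distributions** (TFDs) —
the spectrogram and its sharpened variant, the **reassigned spectrogram** —
where such signals concentrate energy that noise spreads uniformly.

It is aimed at researchers and engineers building detectors or
feature-based classifiers for underwater, bioacoustic or industrial audio,
and ships everything needed to study the features without any external data:
synthetic signal generators with exact SNR control and a seeded Monte-Carlo
detection harness.

## The quantities at the core

Every feature is computed from a discrete probability distribution obtained
by normalizing an energy decomposition of a frame `x`:

* `P_F[k] = F[k] / Σ F` — the one-sided power spectrum (1-D);
* `P_S[n,k] = S[n,k] / ΣΣ S` — the spectrogram `S = |STFT|²` (2-D);
* `P_R` — likewise for the reassigned spectrogram, in which each cell's
  energy is moved to its local energy centroid
  `t̂ = t + Re(STFT_th/STFT_h)`, `ω̂ = ω − Im(STFT_dh/STFT_h)`;
* `P_SC[n,k] = S[n,k] / (M·Σ_k S[n,k])` — the column-stochastic form, whose
  row-stochastic matrix `M·P_SC` has (for regular square cases) an ergodic
  limit `Ω` with every row equal to the stationary vector `Π`.

On each support the package evaluates, against the uniform reference `Q`
(the spectral signature of white noise):

* entropies — normalized Shannon `H(P)` and Rényi
  `H^(α)(P) = log₂(Σ pᵅ)/(1−α)` (default order α = 3);
* disequilibria — squared Euclidean `Σ(p−q)²`, squared total variation
  `¼(Σ|p−q|)²`, Jensen–Shannon divergence, and the geometric-mean
  Rényi–Jensen–Shannon divergence
  `J^(α)(P,Q) = H^(α)(PQ) − ½(H^(α)(P)+H^(α)(Q))` with
  `H^(α)(PQ) = log₂(Σ (p·q)^(α/2))/(1−α)`;
* statistical complexities — products `C = H · D`, which vanish both for
  pure order (a tone: `H = 0`) and for pure disorder (white noise: `D = 0`)
  and so flag structured signals.

The canonical registry holds 30 features per frame: 9 characteristics on
each of `P_F`, `P_S`, `P_R`, plus the entropies `H(Ω)`, `H^(α)(Ω)`,
`H^(α)(Π)` of the ergodic pair.

## Worked example

Mix a linear FM chirp into white Gaussian noise at −5 dB, extract features,
and run a miniature detection sweep:

```r
library(tfdinfo)
fs <- 16000
chirp <- gen_chirp(chirp_params(f_start = 800, f_end = 4000, duration = 1), fs)
noise <- band_noise(c(0, fs / 2), length = 16000, sample_rate = fs, seed = 7)
pair  <- mix_at_snr(chirp, noise, snr_db = -5)

fv <- feature_vector(pair$mixture_frame, info_config(alpha = 3))
round(fv[c("H_PF", "CTV_PF", "H_PS", "CTV_PS", "H_PR", "CTValpha_PR")], 4)
#>        H_PF      CTV_PF        H_PS      CTV_PS        H_PR CTValpha_PR
#>      0.9511      0.1336      0.9120      0.1776      0.8653      0.2210
```

The normalized entropies sit below the white-noise ceiling (≈ 0.95 for
`P_F`, ≈ 0.96 for `P_S` at this frame length) and the total-variation
complexities rise above their noise baselines — most strongly on the
reassigned support, where the chirp's ridge is sharpest.

```r
cfg <- experiment_config("chirp", q_frames = 50, snr_grid = c(-15, -5),
                         features = c("CTV_PF", "CTV_PS"), master_seed = 1)
run_detection_experiment(cfg)$curves
#>   feature snr_db    auc  prd flipped n_frames
#> 1  CTV_PF    -15 0.6212 0.12   FALSE       50
#> 2  CTV_PS    -15 0.9604 0.88   FALSE       50
#> 3  CTV_PF     -5 0.8892 0.82   FALSE       50
#> 4  CTV_PS     -5 1.0000 1.00   FALSE       50
```

`auc` is the rank probability that a signal-present score beats a
noise-only score; `prd` the detection probability at a 5% false-alarm rate.
For chirps the spectrogram-based complexity dominates its spectral
counterpart across the SNR sweep — the time-frequency support captures the
moving frequency content that the whole-frame spectrum smears.

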
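# coinfoPE

Synergistic and redundant coding of auditory prediction errors across the
cortical hierarchy: Gaussian-copula mutual information, co-information
charts with permutation maximum statistics, multivariate (decoder-based)
co-information, and a brain-constrained six-area oddball network simulator.

## The problem

During an auditory oddball sequence, an unexpected (deviant) tone evokes a
prediction-error (PE) response visible in two markers: the event-related
potential (ERP, the mismatch-negativity deflection at ~150–250 ms) and a
broadband (BB) high-frequency power increase that tracks local spiking.
Both markers appear in many cortical areas. This package quantifies *how*
that distributed information is organized using co-information,

```
coI(X;Y;S) = I(X;S) + I(Y;S) − I(X,Y;S)
```

with S the trial class (standard/deviant) and X, Y two neural signals
(two timepoints of one channel, one timepoint each of two channels, or two
decoders' decision values). Positive co-I = redundancy (shared PE
information); negative co-I = synergy (extra information only in the joint
response). All MI terms use a bias-corrected Gaussian-copula estimator
(rank-normal scores + parametric Gaussian model, in bits), and all maps are
thresholded by label-permutation maximum statistics at a family-wise error
rate of 0.05. A leaky-integrator network of six cortical areas (A1, AB, PB;
PF, PM, M1) with sparse topographic wiring reproduces the oddball
experiment in silico and shows that temporo-frontal *synergy* requires the
feedback/recurrent (and "jumping") connections: cutting them (the
feedforward-only ablation) leaves redundancy intact but eliminates synergy.

Everything runs on synthetic data with analytically known ground truth; no
external recordings are required.

## Worked example

```r
library(coinfoPE)

# a synthetic roving-oddball recording: 20 tone frequencies, trains of
# 3/5/11 identical 64-ms tones at 503 ms SOA, with injected ERP and
# broadband deviance effects on one temporal and one frontal channel
rec <- gen_oddball_recording(oddball_grammar("roving"), n_trains = 120,
                             n_channels = 8, seed = 4)

# ERP marker: CAR -> 500 Hz -> 1-40 Hz zero-phase -> [-100,350) ms epochs
erp <- balance_trials(erp_extract(rec), seed = 1)

# per-channel MI with 1000-permutation maximum statistics (FWER 0.05)
mm  <- mi_map(erp, n_perm = 1000, seed = 1)
sel <- select_channels(mm$series, erp$regions)
max(mm$mi[1, ])                      # 0.383  (bits/sample, effect channel)
bits_per_second(max(mm$mi[1, ]), erp$fs)   # 191.5 bits/second
max(mm$mi[2, ])                      # 0.071  (CAR leakage only)
sel$best                             # temporal = 1, frontal = 5

# co-information between the best temporal and frontal channels
ch <- spatiotemporal_coi_chart(erp, sel$best["temporal"],
                               sel$best["frontal"], n_perm = 1000,
                               seed = 1, decim = 4)
sum(ch$sig_redundant)                # 325 cells share PE information
sum(ch$sig_synergistic)              # 0 (the injected effects are common-source)

# ground-truth check: the +-rho correlation-flip ensemble has a closed-form
# target, coI = 0.5*log2(1 - rho^2) = -0.737 bits at rho = 0.8
g <- gen_gaussian_trials(gaussian_coding_spec(5e4, "synergistic", rho = 0.8))
coinformation(g$epochs$data[, 1, 1], g$epochs$data[, 2, 1], g$epochs$labels)
#> -0.7415  (analytic truth -0.7370)
```

The MI peak of 0.38 bits/sample on the effect channel against ~0.07 on a
no-effect channel is what channel selection keys on; in the co-I chart,
red/positive cells mark time pairs where the two channels share PE
information and blue/negative cells mark time pairs whose joint readout
carries extra information.

The numbered scripts under `analysis/` run the full study: synthetic task
generation (`01`), marker extraction and channel selection (`02`), temporal
and spatio-temporal co-I charts with cross-recording aggregation (`03`),
multivariate co-I (`04`), the FC/FF/NN network-architecture ablation at the
full 25 x 25-cells-per-area scale (`05`), and SSIM chart comparison with
pixel-shuffle surrogates (`06`). Each writes its tables under `results/`.

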
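---
title: "Redundant and synergistic prediction-error coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redundant and synergistic prediction-error coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coinfoPE)
```

## The scientific question

When an unexpected tone interrupts a predictable sequence, the brain
produces a prediction-error (PE) response that is visible in at least two
electrophysiological markers: the event-related potential (ERP; the
mismatch-negativity deflection peaking roughly 150--250 ms post-onset) and a
broadband (BB) increase in high-frequency spectral power that tracks
aggregate local spiking. Both markers appear in many cortical areas at once.
The question this package addresses is *how* that distributed information is
organized: do auditory and frontal signals carry the *same* PE information
(redundancy), or does their trial-by-trial relationship carry *extra*
information that neither signal has alone (synergy)?

The instrument is co-information,

$$\mathrm{coI}(X;Y;S) \;=\; I(X;S) + I(Y;S) - I(X,Y;S),$$

where $S$ is the binary trial class (standard vs deviant) and $X$, $Y$ are
two neural signals — two timepoints of one channel (temporal charts), one
timepoint each of two channels (spatio-temporal charts), or two decoders'
decision values (multivariate charts). Positive co-I is redundancy; negative
co-I is synergy.

## The MI estimator

All MI terms use a Gaussian-copula estimator: each response dimension is
rank-transformed to standard-normal scores ($z_i = \Phi^{-1}(r_i/(n+1))$,
ties broken by stable input order so the transform is deterministic), and MI
is computed from a parametric Gaussian model as the difference between the
pooled-score entropy and the label-weighted class-conditional entropies.
Entropies use covariance log-determinants with the analytic small-sample
correction based on the expected log-determinant of a Wishart matrix
(digamma terms). Properties that matter here:

* the estimate is a *lower bound* on the true MI and exactly invariant to
  strictly monotone transforms of each dimension;
* the residual null bias is small (measured < 0.005 bits at n = 500 trials)
  and is handled by the permutation null in any case;
* negative estimates are floored at zero *for reporting only*; permutation
  nulls use the raw values, since flooring would bias null quantiles.

The estimator assumes the copula of the joint is adequately captured by a
Gaussian — by construction it cannot see higher-order dependence beyond the
correlation structure of the normal scores. MI is reported in bits per
sample; at 500 Hz, 0.01 bits/sample corresponds to 5 bits/second
(`bits_per_second()`).

## Statistical control

Significance uses label-permutation maximum statistics. For an MI time
series, each of 1000 permutations contributes its maximum over all tested
timepoints (or all channels and timepoints, in `mi_map()`), and the 95th
percentile of those maxima is the threshold: the family-wise error rate over
the whole family is 0.05. Co-I charts are two-sided; the chart machinery
runs the maximum statistic separately on the chart maximum (redundancy) and
minimum (synergy) at the 97.5th/2.5th percentiles, so the total FWER is
still about 0.05. Whether to threshold one- or two-sided per sign was a
genuinely open design choice; the two-sided split is recorded in each
chart's metadata. A single permutation stream is shared across all cells of
one chart, preserving the cross-cell dependence that maximum statistics
rely on.

## Signal extraction

The ERP path is: common-average reference, anti-aliased decimation to
500 Hz, zero-phase 4th-order Butterworth band-pass (1--40 Hz; the order is
configurable, only the band is scientifically fixed), epoching to the
half-open window $[-100, 350)$ ms (225 samples at 500 Hz, onset at sample
51), and subtraction of the 100 ms pre-onset mean per trial.

The BB path estimates a time-resolved PSD per epoch with 100 ms windows at
50% overlap; within each window three half-length Hann-tapered sub-segments
are averaged — the frequency resolution drops to ~20 Hz, but the
periodogram variance reduction is what lets the spectral PCA isolate a
broadband component instead of noise. Trial PSDs are divided by the
condition-pooled mean power per frequency, log-transformed, and the
across-frequency covariance is eigendecomposed. The first principal
spectral component is oriented so its mean loading above 100 Hz is
positive, making "more broadband power" positive; the projection is
z-scored per trial, passed through $e^x - 1$, and baseline-corrected. PSD
window length, taper scheme and the PCA frequency range are exposed as
configuration with these defaults.

## Multivariate co-information

Per-channel analyses can miss information spread across a region. The
multivariate route trains a linear-discriminant classifier per timepoint on
all channels of a region, with stratified 10-fold cross-validation, and
keeps the out-of-fold decision values (the signed pre-threshold discriminant
score). The same folds are reused across timepoints of a region so temporal
comparisons share partitions. Covariances are shrunk toward a scaled
identity with a Ledoit-Wolf estimate because channel counts can approach the
fold-training size. The joint-information term of the multivariate co-I is
the maximum of three lower bounds: the larger single-region MI, the MI of
the 2-D decision-value pair, and the MI of a joint decoder trained on both
regions' channels (the only one of the three that can actively capture
between-region synergy).

Significance of multivariate charts needs care: out-of-fold decision values
of cross-validated decoders are weakly coupled to their *training* labels
even when the data carry no information (the familiar cross-validation
dependence), so permuting labels against fixed decision values is
anticonservative — measured on null data, MI against the true labels ran
~70% above MI against permuted labels. The chart machinery therefore
retrains every decoder (both regions at every timepoint, and the joint
decoder of every timepoint pair) on each permutation's labels, with
re-stratified folds, which restores exchangeability and the nominal
family-wise error rate. This makes multivariate charts substantially more
expensive than channel-level charts; the `decim` and `n_perm` arguments are
the runtime controls.

## The network model

The simulator implements six areas — A1, AB, PB (temporal) and PF, PM, M1
(frontal) — each a 25 x 25 grid of excitatory graded-response
leaky-integrator cells with adaptation ("neuronal fatigue") plus a matched
inhibitory layer. Per step (10 ms):

* membrane potentials integrate synaptic input, external input and uniform
  white noise with time constant `tau_m`;
* inhibitory potentials integrate the local neighbourhood mean of
  excitatory output (`tau_i`, 5 x 5 kernel);
* outputs are a sigmoid of potential minus adaptation, local inhibition and
  an area-wide global inhibition term;
* adaptation integrates toward `k_adapt * output` with slow `tau_a`.

Projections are sparse, topographic and probabilistic: a synapse from a cell
to a cell at toroidal grid distance $d$ exists with probability
$p_0 e^{-d^2/2\sigma_d^2}$ and weight uniform on $[0, 0.1]$ (the toroidal
boundary avoids edge effects; the boundary handling was an open choice).
Three architectures differ only in which projection classes exist: FC has
reciprocal next-neighbour links within each lobe, the long-distance PB-PF
link, higher-order "jumping" links between non-adjacent areas, and
within-area recurrent links; FF keeps only the feedforward directions (all
feedback and recurrent links cut); NN keeps adjacent-area links and
recurrents but no jumping links.

### Calibration

Three parameters are treated as tunable (the adaptation gain, the local
inhibition gain, and the between-area link strength; `tune_network()` is the
grid-search helper). The defaults (`k_adapt = 3`, `k_local_inh = 2`,
`w_between_gain = 4`, with sigmoid threshold 0.55 and global inhibition
gain 3) were chosen so that, at the full 25 x 25 scale, (i) a single area
shows clear stimulus-specific adaptation within 8 repetitions and a deviant
release, (ii) deviance information propagates into the frontal areas, and
(iii) the fully connected network operates near criticality — spontaneous
fluctuations reverberate through the feedback loops. That last property is
the mechanism behind the headline result: reverberation makes late frontal
activity retain the early temporal trial-to-trial fluctuation after the
class-mean response has decayed, which is exactly the "explaining-away"
geometry that produces negative co-I. Cutting the feedback and recurrent
links (FF) removes the reverberation and with it the synergy, while leaving
feedforward information transfer (and hence redundancy) intact.

The roving protocol mirrors the experimental grammar at the 10 ms/step
mapping: trials of 10 baseline + 20 stimulus + 20 inter-trial steps (SOA
50 steps ~ 500 ms); stimuli are 12 random patterns of 31 A1 cells (~5%);
each deviant is preceded by 6--10 identical standards; the last standard and
the following deviant of each train are recorded, 50 of each per run. Tones
never occur in silence — trains follow each other continuously — so the
repetition probe that verifies adaptation also precedes its test train with
a warm-up train of a different pattern. Epochs span steps -10..+34 around
onset ($[-100, 350)$ ms at 100 Hz), and the recorded signal per area is the
sum of its excitatory firing rates.

## What the synthetic data does and does not emulate

The Gaussian generators provide *exact* targets for the estimator: the
class-conditional correlation sign-flip construction ($\pm\rho$, identical
standard-normal marginals) has Gaussian-model joint MI
$-\tfrac12\log_2(1-\rho^2)$ and therefore co-I $+\tfrac12\log_2(1-\rho^2)$,
e.g. $-0.737$ bits at $\rho = 0.8$ — chosen precisely because it gives a
closed-form oracle with no Monte-Carlo integration. The oddball emulation
injects a difference-of-Gaussians ERP deflection (peak configurable,
default 180 ms) and a variance gain on a 70--200 Hz band-limited carrier,
with additive per-channel-independent Gaussian noise: the simplest shapes
with the right latencies and bands. Real recordings differ in ways the
generators deliberately ignore — volume conduction and shared noise across
electrodes, non-stationary artifacts, 1/f background spectra, electrode
geometry. Passing tests therefore certify the *estimators and statistics*,
not robustness to every property of real ECoG. Real-data effect sizes and
SNR are not published for these markers, so the injected effect sizes are
free parameters with defaults large enough to be comfortably detectable at
~100 trials.

## Numerical choices and degenerate inputs

* Copula scores of constant input are undefined: degenerate-rank inputs
  raise an error rather than silently producing zeros.
* Singular covariances are ridge-regularized ($10^{-9}\,\mathrm{tr}/d$, or
  a determinant floor in the vectorized 2-D kernel) with a warning.
* The diagonal of a temporal chart is defined as the MI at that timepoint —
  the joint of a variable with itself is degenerate, and the MI is the limit
  of $\mathrm{coI}(x; x+\varepsilon; S)$ as $\varepsilon \to 0$.
* Channel-selection ties (equal peak MI) resolve to the lower channel
  index.
* Chart images for SSIM are min-max normalized on the common scale of the
  pair; SSIM uses the 11 x 11 Gaussian window ($\sigma = 1.5$), standard
  stabilization constants, dynamic range 1, averaged over fully-interior
  windows. Surrogates shuffle pixel positions of the second image.
* All randomness is seed-controlled; the same seed reproduces bit-identical
  outputs everywhere (generators, folding, permutations, wiring,
  simulation noise).

## Problem sizes used in the test suite

The suite exercises full-scale components where they are fast (the
estimator oracles at $10^5$ trials; the full 25 x 25-grid network for
adaptation and cell-count checks) and scaled-down versions elsewhere, as the
package's own choice of test conditions: FWER calibration uses 200 null
datasets of 100 trials x 20 channels x 50 timepoints with 1000
permutations; the architecture-ablation property uses five 3-run cohorts
per architecture at a 15 x 15 per-area grid (the qualitative FC/FF contrast
is the same as at 25 x 25, where the `analysis/` drivers run it) with
400-permutation statistics on charts decimated to a 23 x 23 grid; chart
unit tests use 10--60 timepoints. The analysis drivers under `analysis/` run the same pipeline at
presentation scale.

## Known limitations

* The estimator is a Gaussian-copula lower bound; strongly non-Gaussian
  joint dependence (beyond monotone marginal transforms) is invisible to it.
* Co-I is a single scalar decomposition; no partial-information-decomposition
  lattice is attempted, and no cluster-based statistics are offered.
* The network is not a learned model: weights are random draws under
  anatomical constraints, and the dynamics are calibrated, not fitted.
  Conclusions are about architecture classes (FC vs FF vs NN), not about
  quantitative response magnitudes.
* The published similarity scores between real and simulated charts are not
  reproducible without the real recordings; the comparison machinery is
  validated against an independent reference implementation and by null
  calibration instead.
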
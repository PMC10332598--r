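---
title: "Unsupervised vocal repertoire discovery with auto-encoder embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised vocal repertoire discovery with auto-encoder embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Many animal communication systems are transcribed as sequences of
discrete units drawn from a *vocal repertoire*. Cataloguing such a
repertoire by hand is laborious and subjective; `vocclust` assists it by
clustering detected vocalisations by acoustic similarity, so that an
analyst reviews a handful of candidate clusters instead of thousands of
individual units. The pipeline is:

1. fixed-duration spectrograms around each annotated unit centre;
2. a convolutional auto-encoder whose bottleneck embeds each unit;
3. UMAP dimensionality reduction;
4. HDBSCAN density clustering;
5. agreement / clusterability / annotation-effort metrics.

This vignette documents the model, its assumptions, every tunable
parameter that matters, and the design decisions taken where several
reasonable options existed.

## Spectrogram preprocessing

Each detected unit is represented by a window of fixed duration `T`
centred on the annotation centre (onset + duration/2 when only onset and
duration are given; 0-based sample indexing; half-open windows;
out-of-file regions zero-padded). `T` is a dataset-level constant chosen
as the **third quartile of the annotated unit durations**
(`compute_sample_duration()`, linear-interpolation quantiles): long
enough to contain most units entirely, short enough not to drown brief
units in context. The window is z-normalised so recording gain does not
enter the representation.

The STFT uses unpadded Hann windows of `nfft` samples. The hop is not a
free parameter: to obtain exactly `n_time` (default 128) columns it is

```
hop = (T * fs - nfft) / n_time
```

rounded to the nearest sample. Taken literally this framing yields
`n_time + 1` full frames; the trailing frame is dropped, preserving
onset alignment. Frequency bins are reduced to `n_mels` (default 128)
rows either by a 128-filter Mel bank spanning 0 to Nyquist (triangular
filters, Slaney scale and area normalisation — no variant is canonical,
this one is the common library default) or, for a linear layout, by
max-pooling contiguous FFT-bin groups, independent of `nfft`. Note that
128 Mel filters against a 129-bin FFT (e.g. `nfft = 256`) leaves some
low-frequency filters without any FFT bin; those rows are identically
zero, which is harmless downstream but worth knowing when inspecting
spectrograms.

Output sizes are constrained to `k_f * 2^n` by `k_t * 2^n` (defaults
`k = 4`, `n = 5`, i.e. 128 x 128) because the decoder reconstructs by
`n` successive factor-2 upsamplings.

Dynamic-range compression is one of:

* `none` — raw magnitudes;
* `log` — `log(mag / max(mag) + 1e-8)`; the epsilon is relative to the
  spectrogram's maximum so the compression is gain-invariant;
* `pcen` — per-channel energy normalisation with the standard
  parameters (gain 0.98, bias 2, power 0.5, eps 1e-6, 400 ms time
  constant at the configured frame rate).

Mel layout with log compression is the recommended first choice; the
best compression is dataset-specific. After compression, magnitudes are
z-normalised **per spectrogram** (a per-batch flag exists; per-unit
normalisation makes units comparable regardless of their SNR, which is
what a similarity-based clustering needs). Constant inputs map to all
zeros rather than dividing by zero. An optional stationary-noise step
(`denoise = TRUE`) subtracts each frequency row's median over time,
clipping at zero: stationary tones and broadband floors vanish while
transient vocalisation energy survives.

Sampling rates are harmonised to the most common rate in the dataset
(ties resolved towards the lower rate) by polyphase FIR resampling
(`signal::resample`).

The whole-spectrogram baseline (`baseline_spectrogram_features()`)
represents each unit by a 32 x 32 spectrogram flattened to 1024
independent features. It is produced by 4 x 4 max-pooling of the
standard 128 x 128 pipeline output — one code path, same `T`, `fs` and
`nfft` — so baseline and auto-encoder comparisons differ only in the
representation.

## The auto-encoder

The encoder is five convolutional blocks, 3 x 3 kernels, stride 2.
Channel width starts at `base_channels` (32 in the reference
configuration) and doubles each block, except the last: its width is
`bottleneck_dim / 16` so that flattening its 4 x 4 output yields exactly
the requested bottleneck dimension (256 by default) without an extra
dense layer. Blocks 1-4 apply batch normalisation then ReLU; block 5 is
linear. The decoder mirrors this: the embedding is reshaped to a
4 x 4 map, then five stages of {factor-2 nearest-neighbour upsampling +
two (conv + BN + ReLU) blocks} — two convolutions per stage give a
larger receptive field than one — followed by a final linear 3 x 3
convolution back to one channel. The output activation is linear
because inputs are z-normalised and therefore signed.

Training uses Adam (learning rate 1e-3, the optimiser's standard
default) on shuffled mini-batches of 128 spectrograms. Training stops
when the median loss over the last 1000 steps has not decreased
relative to the previous 1000 (`should_stop()`; equality stops), with a
hard `max_steps` cap guaranteeing termination. All randomness (weight
initialisation, batch order) derives from one seed, so runs are exactly
reproducible on one machine.

Two reconstruction losses are available. `mse` is the plain mean squared
error. `perceptual` compares feature maps of a *frozen* convolutional
feature extractor applied to input and reconstruction, emphasising
salient spectro-temporal structure (the vocalisation contour) over
diffuse background energy. The extractor is pluggable: any frozen
layer stack works. The package default is a fixed-seed random-weight
VGG-style stack (`feature_extractor()`); random convolutional features
are an established, dependency-free variant of the perceptual loss, and
an ImageNet-trained extractor can be substituted by loading its weights
into the same structure. With the identity extractor the perceptual
loss reduces exactly to MSE, which the tests exploit as an oracle.

The convolution, batch-norm, ReLU and upsampling kernels are compiled
(im2col + GEMM via RcppArmadillo) and backpropagation is verified
against numerical differentiation in the test suite.

## Projection and clustering

The bottleneck embedding is reduced with UMAP before clustering —
density estimation suffers in 256 dimensions. Eight output dimensions
are the working default for clustering and two for visualisation;
neighbourhood size (15) and minimum distance (0.1) stay at the
reference implementation's defaults, since only the output
dimensionality is worth tuning in this application. The UMAP seed is a
required argument surfaced in all outputs: projections are otherwise
run-to-run stochastic.

HDBSCAN clusters the projection with generic settings that transfer
across repertoires: `min_cluster_size = 10`, `min_samples = 3`,
`cluster_selection_epsilon = 0.1`, `leaf` selection. Leaf selection
returns the finest-grained dense leaves of the condensed tree — it
splits rather than merges, which suits repertoires with many similar
types; `eom` (excess of mass) is the right choice for graded
repertoires where leaf over-fragments (this is observable on synthetic
data, see Limitations). Points in no dense region receive the noise
sentinel `-1`.

The projection runs in the reference `umap-learn` implementation
through a file-based bridge (data crosses as CSV keyed by vocalisation
id). HDBSCAN is implemented natively in R (`hdbscan_labels()`): core
distances over `min_samples` neighbours, exact Prim minimum spanning
tree of the mutual-reachability graph, single-linkage hierarchy,
condensation at `min_cluster_size`, stability-based EOM or leaf
selection, and the epsilon search that replaces clusters separating
below `cluster_selection_epsilon` by their lowest ancestor above it.
All computations are exact and O(n^2), appropriate up to a few thousand
units. The test suite cross-checks the partition against scikit-learn's
HDBSCAN on unambiguous geometries. (On ambiguous, noise-dominated data
the mutual-reachability graph has many tied edge weights, the minimum
spanning tree is not unique, and any two correct implementations can
legitimately disagree.)

## Evaluation metrics

**NMI.** Agreement between expert labels `L` and clusters `C` is the
mutual information — the KL divergence of the joint label/cluster
distribution from the product of its marginals — normalised by the
arithmetic mean of the two entropies: `NMI = 2 * I(L;C) / (H(L) + H(C))`,
1 for a perfect match, 0 for independence. Entropies use natural logs
(the base cancels). Unlabelled units are always excluded; noise-assigned
units are excluded by default (`noise = "singletons"` keeps them as
one-point clusters — both conventions are defensible, and the choice is
surfaced rather than hidden). If both partitions are single-category the
statistic is defined as 1, with a warning. Labels occurring fewer than
20 times are demoted to unlabelled before evaluation (exactly 20 is
kept): such rarities are often labelling errors and cannot be evaluated
meaningfully.

**Hopkins.** Repertoire discreteness is the Hopkins statistic
`H = sum(u) / (sum(u) + sum(w))` with `m = 100`: `u` are
nearest-data-neighbour distances of `m` reference points drawn from a
normal distribution matched to the data's per-dimension mean and
standard deviation (full covariance via a flag), `w` are
nearest-other-neighbour distances of `m` data points sampled without
replacement. `H` near 0.5 means normal-like (unclusterable) structure;
near 1 means discrete clumps. It is computed on the 2-D UMAP projection
by default, matching how embeddings are visually inspected;
dimensionality is configurable.

**Annotation effort.** A cluster is *discriminant* when at least 90% of
its labelled members share one type (boundary inclusive): an analyst
can bulk-annotate it after inspecting a sample. The report gives the
total cluster count, the percentage of discriminant clusters among
clusters with at least one labelled member (clusters containing only
unlabelled units cannot be assessed and are excluded), the percentage
of *all* units — labelled or not — sitting in discriminant clusters
(the share of the dataset annotated for free), and the number of label
types never covered by a discriminant cluster.

## The synthetic repertoire generator

Real benchmark corpora are large and external; the generator emulates
their structure so every stage is testable offline. A repertoire of
`n_types` unit types is built from three contour families (constant
tone, linear chirp up 30%, sinusoidal FM at ±8%/25 Hz) cycled across
types, with base frequencies spread over 0.8-3.5 kHz, 1-3 harmonics
(amplitude 1/h), and Hann amplitude envelopes. Intra-type variability
is log-normal jitter (3% by default) on frequency and normal jitter on
duration (60 ± 8 ms). Units are placed on a silence-gapped timeline,
scaled to a common RMS, and white (or 1/f pink) Gaussian noise is added
so that each unit's SNR matches the requested value (20 dB by default)
to within measurement error. Defaults — 32 kHz sampling, `nfft = 256`,
`T = 0.1` s — mirror a songbird recording configuration, the smallest
and fastest of the preset geometries.

Every unit derives its own RNG stream from the master seed through a
counter (`unit_seed()`), so a single unit is reproducible in isolation
and rendering order cannot leak randomness across units. `graded = TRUE`
quadruples the jitter and compresses all types into an overlapping
1.5-2.2 kHz band, emulating a graded repertoire: both Hopkins and NMI
drop measurably relative to the discrete mode, reproducing the
qualitative signature of graded natural repertoires (e.g. humpback
song units).

What the generator does **not** emulate: reverberation and propagation
effects, overlapping vocalisations, amplitude modulation diversity,
non-stationary noise, and any species-specific acoustics. Passing
end-to-end tests on synthetic repertoires therefore demonstrates that
the machinery recovers planted discrete structure at realistic SNR —
not that it matches expert labels on any particular real corpus.

## Problem sizes in the test suite

The shipped tests favour geometry variants that exercise identical code
at lower cost: most auto-encoder tests run on 32 x 32 spectrograms
(`k = 1`, `n = 5`) with 4 base channels, and the end-to-end recovery
test uses the full 128 x 128 geometry with 8 base channels, a 256-D
bottleneck, mini-batches of 32 and a few hundred training steps — a
deliberately small model on a 240-unit repertoire. The reference
configuration (32 base channels, batches of 128, median stop rule over
1000-step windows) is the package default for real corpora.

## Known limitations

* **Leaf selection on small, clean repertoires.** With only a few dozen
  units per type, UMAP clumps retain internal density structure and
  leaf selection can split one type into two or three pure sub-clusters
  (NMI is penalised by the extra cluster entropy even though purity is
  perfect). `eom` merges these back and is consistently the better
  choice on small synthetic repertoires; on large real corpora the
  generic leaf settings are the better default. The end-to-end tests
  run the generic leaf settings to keep faith with the recommended
  configuration.
* **Batch-norm with small batches.** Running statistics converge slowly
  when training uses few steps; inference-mode embeddings computed from
  a barely-trained model reflect initialisation more than data.
* **Bridge determinism.** UMAP with a fixed seed is single-threaded and
  deterministic, but results can differ across umap-learn versions;
  the seed and all clustering parameters are recorded in run manifests
  so any run can be replayed.
* **Scale.** The compiled-kernel auto-encoder is adequate for corpora
  of a few thousand units on one CPU; it does not use a GPU.
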
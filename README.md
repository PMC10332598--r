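# vocclust

Unsupervised clustering of animal vocal repertoires from deep audio
embeddings.

## The problem

Bioacousticians transcribe animal acoustic communication as sequences of
discrete units (vocalisation types) drawn from a *vocal repertoire*.
Building that catalogue by hand — listening to thousands of detected
units and deciding type boundaries — is slow and subjective. `vocclust`
implements a repertoire-discovery pipeline that groups detected
vocalisations by acoustic similarity so an analyst reviews clusters, not
individual units:

```
WAV + annotation CSV
  → fixed-size log-Mel spectrograms (k·2ⁿ × k·2ⁿ, default 128 × 128)
  → convolutional auto-encoder bottleneck embedding (default 256-D)
  → UMAP projection (default 8-D)
  → HDBSCAN density clustering (leaf selection, noise-aware)
  → NMI / Hopkins / annotation-effort report
```

The auto-encoder — five stride-2 convolution blocks mirrored by five
upsample-and-convolve blocks — is trained per dataset with Adam on
batches of 128 spectrograms, under either a pixel MSE loss or a
*perceptual* loss (MSE between feature maps of a frozen convolutional
extractor), stopping when the median loss over the last 1000 steps stops
decreasing. Cluster/label agreement is scored with normalised mutual
information,

    NMI(L; C) = 2 · I(L; C) / (H(L) + H(C)),

repertoire discreteness with the Hopkins statistic (m = 100, normal
reference matched to the data moments), and annotation effort with the
share of *discriminant* clusters (≥ 90% of labelled members from one
type), the share of units inside them, and the number of missed labels.
Only three dataset-specific settings are required — sampling rate `fs`,
FFT window `NFFT` and sample duration `T` (the third quartile of unit
durations) — and named presets ship for six species configurations from
songbirds (32 kHz, NFFT 256, T 0.1 s) to humpback whales (11.025 kHz,
NFFT 1024, T 2 s).

A synthetic repertoire generator (harmonic stacks with tone / chirp /
FM contours, controlled jitter and SNR, white or pink noise) makes the
whole pipeline testable end to end without any field recordings.

## Worked example

Generate a synthetic 3-type repertoire, run the full pipeline with a
compact auto-encoder, and read the report:

```r
library(vocclust)

spec <- repertoire_spec(n_types = 3, snr_db = 20, seed = 1)
ds   <- render_dataset(spec, n_per_type = 40, dir = tempfile("demo"))

report <- run_pipeline(
  ds$annotations, spectrogram_preset("bengalese_finch"),
  base_channels = 8, loss = "mse", train_steps = 150,
  batch_size = 32, seed = 1
)
report
#> Repertoire clustering report
#>   120 units -> 4 clusters (+7 noise)
#>   NMI 0.915 | Hopkins 0.984 | 100.0% discriminant | 94.2% clustered | 0 labels missed
```

Reading: the 120 units were grouped into 4 clusters (one type split
into two pure sub-clusters — leaf selection splits rather than merges)
with 7 units left as noise; agreement with the ground-truth types is
NMI 0.915 (a perfect match gives 1, independence 0); the 2-D projection
is strongly clusterable (Hopkins 0.98; 0.5 means unstructured); every
cluster is discriminant (≥ 90% label purity), 94% of all units sit in
discriminant clusters, and no type was missed — an analyst could
annotate this dataset by inspecting four clusters.

The same stages are available from the shell via `exec/vocclust`
(`synth`, `spectro`, `train`, `embed`, `project`, `cluster`,
`evaluate`, `report`), each writing a JSON manifest with settings,
seeds and input checksums so any run can be replayed.

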
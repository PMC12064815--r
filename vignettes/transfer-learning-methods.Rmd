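---
title: "Transfer learning and knowledge distillation for bird sound classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning and knowledge distillation for bird sound classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirpdistill)
```

## The problem

Community sound archives hold hundreds of thousands of bird recordings, but
their labels are *weak*: each recording names one primary species, sometimes a
few secondary (background) species, and never the time at which anything
vocalises. Secondary labels are, in addition, incomplete — many audible
background species are simply not annotated. This package implements a
complete, desk-scale training and evaluation pipeline for multi-species bird
classifiers under exactly these conditions: spectrogram front-ends with
3-second chunking, waveform augmentation, three transfer strategies
(deep finetuning, shallow finetuning, knowledge distillation), weak-label
target construction, segment selection, and recording-level chunk-pooled
evaluation. Everything is exercised end-to-end on a built-in synthetic
soundscape generator, so the full pipeline is testable without any external
download.

## Model and objectives

A classifier $f$ maps a model input $X$ (a log-mel spectrogram) to per-class
logits; a final activation $\delta$ (softmax for single-label, sigmoid for
multi-label) turns logits into scores.

**Deep finetuning** minimises the standard supervised loss
$L(X, y) = L_g(\delta(f(X)), y)$, with $L_g$ cross-entropy (single-label,
paired with softmax) or binary cross-entropy (multi-label, paired with
sigmoid). All parameters train.

**Shallow finetuning** splits $f = f_2 \circ f_1$ into a frozen backbone
$f_1$ (a fixed feature extractor) and a trainable head $f_2$, minimising
$L_g(\delta(f_2(f_1(X))), y)$. In this package the head is the final dense
layer; the backbone boundary is part of the model contract and checksummed
in tests.

**Knowledge distillation** trains a student $f_s$ against a frozen teacher
$f_t$:
$$L(X, y) = \lambda\, L_g(\delta(f_s(X)), y) +
 (1-\lambda)\, L_{kd}(\delta(f_s(X)), \delta(f_t(X)/\tau)),$$
with $\lambda = 0.5$ and temperature $\tau = 1$ by default. $L_{kd}$ is the
KL divergence for single-label training and binary cross-entropy against the
teacher's sigmoid outputs for multi-label. Three details are deliberate:

* the temperature divides the **teacher logits only**, exactly as the
  objective above is written (classical distillation tempers both sides —
  we follow the stated form, and $\tau = 1$ makes the distinction moot at
  the default);
* no $\tau^2$ rescaling of the distillation term is applied;
* **consistent teaching**: at every step the teacher and the student consume
  the *identical* augmented input. The trainer checksums the input fed to
  both forward passes and reports the invariant with the training log.

The reduction identities are guaranteed bit-exactly: $\lambda = 1$ recovers
plain ground-truth training and $\lambda = 0$ pure distillation.

## Front-end

Audio is processed in contiguous, non-overlapping 3 s chunks; a trailing
remainder is zero-padded to full length and kept (late vocalisations are not
discarded). Two spectrogram presets are built in, both 128 mel bands:
16 kHz / window 400 / hop 160 / FFT 512, and 32 kHz / window 800 / hop 320 /
FFT 1024. Under left-aligned framing with no centre padding,
$n_\text{frames} = 1 + \lfloor (N - \text{win}) / \text{hop} \rfloor$, both
presets map a 3 s input to exactly **298 frames** — this is asserted exactly
in the tests, and it is the reason the no-centering convention was chosen
(centred framing would give 301). A third preset is a 48 kHz raw-waveform
pass-through with no spectrogram, for architectures that embed their own
spectrogram stem; the tiny reference architectures in this package consume
mel inputs only, so that preset is exercised at the front-end level.

Where the framing convention pinned down the frame count, other spectrogram
details are underdetermined and were fixed once as package defaults, all
configurable: periodic Hann window, power spectrum, Slaney-style mel
filterbank with area normalisation over $[0, f_s/2]$, log compression
$\log(m + 10^{-10})$, and per-spectrogram mean/sd standardisation (guarded
for silent input) before model entry.

## Augmentation

Both augmentations operate on raw waveforms *before* spectrogram conversion,
on the fly:

* **MixUp** with probability 0.6: waveforms and targets are combined
  convexly with $\text{lam} \sim \text{Beta}(\alpha, \alpha)$. The Beta
  shape is not specified by the method statement; we default to the common
  symmetric $\alpha = 0.2$. Partners are drawn uniformly from the batch;
  any pair may mix; multi-label mixed targets are clamped at 1.
* **Background noise** with probability 0.5, scaled to a random SNR drawn
  uniformly from $[3, 30]$ dB: the gain is
  $g = (\text{rms}_s/\text{rms}_n)\,10^{-\text{snr}/20}$, verified post hoc
  to reproduce the requested SNR to within $10^{-6}$ dB. Noise windows are
  random crops of pool clips (tiled when short). A silent signal skips the
  augmentation with a warning; labels are never changed by noise.

When both fire, MixUp is applied first. No clipping is applied anywhere in
training (floating point throughout). A single seeded RNG stream drives all
draws, so augmented batches are bit-reproducible.

## Reference architectures

The original large pretrained networks are out of scope by design; the
transfer methodology is architecture-generic, so the package ships three
deliberately tiny stand-ins sharing one backbone/head contract: a band-feature
network (per-band time-mean and time-max of the standardised spectrogram into
a dense ReLU layer), a small CNN (one 3×3 convolution on a pooled
spectrogram, time pooling that *preserves the frequency axis* — which carries
the species information — then a dense layer), and a single-block patch
transformer (linear patch embedding + learned positions, one softmax
attention head, residual FFN, mean pooling). All are trained by a hand-rolled
Adam on analytically derived gradients; every architecture's backward pass is
verified against finite differences in the test suite. Cross-architecture
distillation (CNN→transformer and transformer→CNN) is exercised in both
directions.

A fourth model is the **template teacher**: a band-feature network whose
weights are *constructed*, not trained — hidden unit $k$ reads the time-max
band energy around species $k$'s base frequency relative to the across-band
mean (so broadband noise yields no evidence), and the noise class wins via a
constant bias when no band is active. On the generator's well-separated
species it is close to Bayes-optimal, which makes it a controlled reference
teacher for distillation experiments.

## Weak labels, curation, evaluation

Targets are built from recording-level annotations: single-label mode
one-hots the primary species; multi-label mode adds secondary species at
full weight 1 when enabled (the method contrast is inclusion vs exclusion,
not weighting). A dedicated noise class ("no birds present") is mutually
exclusive with species labels within one target and is otherwise treated as
a regular class. Species curation keeps species with ≥ 10 recordings
(inclusive); data regimes are low (< 50), medium (50–200 inclusive), high
(> 200).

Evaluation is recording-level throughout: each 3 s chunk is scored, and the
recording's score per class is the **maximum** over its chunks — appropriate
for weak labels, since a species detected in any chunk is present in the
recording. Metrics: macro/micro F1 (single-label, argmax with lowest-index
tie-break), per-class average precision and mAP (classes with no positives
excluded), macro AUROC via the rank statistic with half-tie counting,
micro-averaged precision/recall at an inclusive threshold (default 0.2), the
foreground/background recall contrast on recordings with exactly two
labelled species, and AP stratified by data regime. Every metric has an
independent brute-force oracle in the test suite (rank enumeration, pairwise
counting, confusion enumeration) agreeing to $10^{-9}$.

## Segment selection

Weakly labelled recordings contain many bird-free chunks. The energy route
scores each chunk's 500–10,000 Hz spectral energy against the recording's
**mean** chunk band-energy and keeps chunks at or above the ratio threshold
(default 1), always retaining the top-scoring chunk. The mean — not the
median — is the reference because under an exact median the median chunk
always scores exactly 1 and silence could never be discarded from
mostly-silent recordings; the mean satisfies all the intended behaviours
(silent chunks dropped, uniform recordings fully kept, decisions invariant
to global gain). The machine-learning route is an injected scorer plus a
strict `score > 0.3` rule (strictness configurable), with no bundled
pretrained tagger so the package stays download-free. Retained chunks
inherit the recording's annotation unchanged.

## The synthetic world

The generator emulates the statistical structure of archive data, not its
acoustics: species are frequency-modulated tones with distinct base
frequencies spread over 1–7 kHz, Hann-enveloped, placed at random onsets
over a white-noise floor. Focal recordings have one full-gain primary and
0–2 background species attenuated by 15 dB (the focal salience gap); each
background species enters the annotation only with probability
`secondary_label_completeness` (default 0.5), modelling missing secondary
labels. Soundscapes draw 1–6 concurrent species at comparable gains from a
decaying polyphony distribution. Recordings-per-species follow a
deterministic truncated Zipf law (`round(max_count * k^-s)`, default
`s = 1.2`, `max_count = 250`), chosen deterministic rather than sampled so
regime coverage (low/medium/high) is reproducible; the default scene spans
all three regimes. Noise-only clips carry the noise class. Test-split
annotations are generated with *complete* secondary labels — the configured
incompleteness applies to the train split — so held-out precision/recall are
measured against full truth, mirroring curated test sets.

What a green test does establish: the pipeline's contracts (losses,
freezing, consistent teaching, pooling, metrics) are correct, and the
method-level *directions* reproduce — e.g. training with incomplete
secondary labels raises recall and costs precision at a 0.2 threshold
relative to primary-only training. What it does not establish: absolute
performance on real bird audio, robustness to natural sound variability, or
any species-level ecology. The calls are tones; real vocal repertoires,
overlapping harmonics and recorder artefacts are all absent.

## Numerical choices and degenerate inputs

* Log arguments are clamped at $10^{-12}$ inside losses; losses are always
  finite.
* Softmax is computed with max subtraction; KL in nats.
* Standardisation guards silent spectrograms (sd < $10^{-8}$ ⇒ centre only).
* Argmax ties break to the lowest class index, deterministically.
* Resampling is Fourier (band-limited); identity resampling is exact.
* Adam defaults: learning rate 1e-3 for head-only, 1e-4 for full training
  (the method statement never fixes optimiser or rates); no early stopping —
  a fixed epoch budget from config.
* WAV I/O is 16-bit PCM (the only audio codec available without external
  dependencies); amplitudes are clamped only at serialisation.

## Known limitations

Tiny reference models trained on tonal synthetic data cannot say anything
about large-architecture behaviour (attention patchout, attention pooling)
or about real-world score calibration, which is explicitly out of scope.
The energy detector is a documented stand-in for the original unpublished
heuristic. FLAC input is not supported in this build.
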
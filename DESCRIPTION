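Package: chirpdistill
Title: Transfer Learning and Knowledge Distillation for Bird Sound Classification
Version: 0.1.0
Authors@R:
    person("Avian", "Acoustics Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale framework for training and evaluating multi-species
    bird sound classifiers from weakly labelled recordings. Provides
    mel-spectrogram front-ends with 3-second chunking, waveform-domain MixUp and
    SNR-controlled background-noise augmentation, tiny reference classifier
    architectures (convolutional, patch-transformer, and band-feature networks)
    with a shared freeze/finetune contract, three transfer strategies (deep
    finetuning, shallow finetuning, and teacher-student knowledge distillation
    with consistent teaching), secondary-label target construction, energy-based
    segment selection for weak labels, chunk-pooled recording-level evaluation
    (F1, mAP, AUROC, thresholded precision/recall, data-regime stratification),
    and a deterministic synthetic soundscape generator so that every pipeline
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
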
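Package: hspfam
Title: Heat Shock Protein Family Classification from Combined Sequence Features
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based classification of heat shock proteins (HSPs) into
    the six chaperone families (HSP20, HSP40, HSP60, HSP70, HSP90, HSP100).
    Implements four protein feature encoders: split amino acid composition
    with golden-ratio segmentation (SAAC), dipeptide composition (DC), the
    conjoint triad feature over a 7-group reduced alphabet (CTF), and the
    pseudo-average chemical shift (PseACS) computed from averaged backbone
    NMR chemical shifts. Class imbalance is handled by a from-scratch SMOTE
    oversampler that balances every minority family up to the majority
    count; classification uses a one-versus-one RBF-kernel support vector
    machine with (cost, gamma) grid search; evaluation covers jackknife
    (leave-one-out) and independent-set protocols with per-class
    sensitivity, specificity, Matthews correlation coefficient and accuracy
    plus overall accuracy. A synthetic-data generator produces imbalanced
    multi-class protein datasets with controllable compositional divergence
    so the full pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
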
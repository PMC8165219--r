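Package: peprank
Title: Ranking-Based Convolutional Models for Peptide-MHC Class I Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Allele-specific prioritization of peptide-MHC class I binding via
    learning to rank. Provides IC50 affinity normalization, qualitative
    level mapping and majority-vote deduplication of affinity tables;
    BLOSUM62/one-hot/learned residue encodings with dual-end position
    embeddings for variable-length peptides; two convolutional scoring
    architectures with self-attention pooling (local kernels, and local plus
    global kernels over middle-padded 15-mers); three pairwise hinge ranking
    losses and a piecewise mean-square loss; SGD training with
    validation-driven learning-rate decay, early stopping and cross-validated
    grid search; ranking evaluation metrics (average rank, hit rate, AUC,
    truncated ROC) with a hybrid model-selection score; attention-weight
    motif recovery; and a synthetic affinity-table generator with planted
    anchor motifs for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
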
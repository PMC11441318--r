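Package: protdistill
Title: Multi-Teacher Knowledge Distillation for Protein Sequence Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of multi-teacher knowledge distillation
    for protein language models. A small T5-style transformer encoder is
    pre-trained on amino-acid sequences under a joint objective combining a
    masked-language-modeling loss with a Kullback-Leibler distillation loss
    against fixed, offline teacher models, with per-instance adaptive teacher
    selection learned by a REINFORCE policy over logistic teacher weights.
    Includes tokenization and FASTA handling, an offline teacher-output store,
    synthetic teachers and planted-motif corpus generators, per-protein
    embedding by global average pooling, and a two-layer perceptron
    fine-tuning pipeline with k-fold cross-validation for binary, multiclass,
    multi-label and regression tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    glmnet,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
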
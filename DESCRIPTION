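Package: rbpattn
Title: RNA-Binding Protein Binding-Site Prediction with Pre-Norm Self-Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies fixed-length RNA fragments as bound or unbound by an
    RNA-binding protein using a multi-descriptor sequence encoding (k-tuple
    nucleotide frequency patterns, sliding-window distributed embeddings, and
    trainable 3-mer context embeddings), a convolutional feature-unification
    encoder, and a pre-normalized residual self-attention classifier trained
    end to end.  Includes the post-norm residual variant for ablation, a
    gradient-depth profiler contrasting the two wirings, stability and
    ablation study drivers, a synthetic motif-planting benchmark generator,
    and a command-line interface.  All results are tibbles; fitted models
    support tidy() and glance() and each result type has an autoplot() method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
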
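# rbpattn

Classify RNA fragments as bound or unbound by an RNA-binding protein
(RBP) from sequence alone.  CLIP-Seq-derived benchmarks frame this as
binary classification of fixed-length (~101 nt) fragments over
{A, C, G, U}; `rbpattn` implements an end-to-end classifier for that task
whose deep feature extractor is built entirely on self-attention, plus the
study machinery (ablations, stability runs, gradient profiling) and a
synthetic motif-planting generator so everything is testable without
external downloads.

## The model

Each fragment is encoded by three per-position descriptors:

* **KNFP** — the k-tuple nucleotide frequency pattern: for k = 1, 2, 3,
  position i carries the global relative frequency
  p(w) = count(w) / (n − k + 1) of the k-mer w starting at i;
* **distributed window embeddings** — a PV-DM (doc2vec-style) model over
  overlapping width-10 words, maximizing the average log-probability of
  each centre word given its context words and a document vector;
* **trainable 3-mer context embeddings** — overlapping 3-mer tokens
  looked up in an embedding table learned end to end (a stand-in for a
  pretrained genomic language model; a frozen per-token table can be
  imported instead).

A feature-unification encoder (per-descriptor 1-D convolution → batch
norm → ReLU, then concatenation and a 1×1 projection) produces the fused
feature z ∈ R^{L×d}, which flows through pre-norm residual self-attention
blocks

    p   = z + MHA(LN(z)),        z_s = p + FFN(LN(p)),

with LN(z) = ((z − μ)/√(σ² + ε)) ⊙ γ + β and scaled dot-product
multi-head attention softmax(QKᵀ/√d_h)V.  Pre-norm wiring keeps an
identity term in ∂ε/∂x_l, so gradients reach every block undiminished;
the post-norm variant x_{l+1} = LN(x_l + F(x_l)) is included for
ablation, and `gradient_depth_profile()` demonstrates the difference
numerically.  Mask-aware mean pooling and a softmax head yield the
binding probability.  Training uses Adam (weight decay 3e-4), batch
size 64, initial learning rate 3e-3 decayed tenfold every 2 epochs —
reported metrics are ACC, AUC (mid-rank Mann–Whitney), precision and
recall.

## Worked example

```r
library(rbpattn)

# a small synthetic task: 60-nt fragments, planted exact 8-mer UGCAUGCA
data <- simulate_binding_sites(n = 400, length = 60,
                               motif = motif_spec("UGCAUGCA", mutation_rate = 0),
                               seed = 1)
fit <- rbp_fit(data, rbp_config(length = 60, epochs = 8), seed = 1)
fit
#> <rbp_fit>  2 blocks (pre-norm), d=128, heads=8, descriptors: knfp+seq2vec+kmer_context
#>   trained 8 epochs on 320 sequences (seed 1, split 97bb1edf)
#>   held-out (n=80): ACC 0.887  AUC 0.962  precision 0.860  recall 0.925

glance(fit)     # one-row held-out summary
tidy(fit)       # per-epoch loss / ACC / AUC
autoplot(fit)   # training curves

predict(fit, data[c(1, 201), c("id", "seq")])
#> # A tibble: 2 × 2
#>   id       score
#>   <chr>    <dbl>
#> 1 pos_0001 0.534
#> 2 neg_0001 0.484
```

The held-out AUC (0.962) is the probability that a random bound fragment
outscores a random unbound one.  On the package's default study task —
n = 2000 fragments of 101 nt with a 10%-mutated motif, trained for the
full 10-epoch protocol — the pipeline reaches held-out AUC 0.909
(ACC 0.842) in about ten minutes on one CPU.  Ablations and stability
studies come from the same interface:

```r
ablate(data, "descriptor", rbp_config(epochs = 3), seed = 7)   # 4 matched-seed rows
ablate(data, "norm_style", rbp_config(epochs = 3), seed = 7)   # pre vs post
stability_run(data, rbp_config(epochs = 3), n_runs = 10)       # seed-series dispersion
```

A command-line interface wraps the same functions
(`inst/cli/rbpattn simulate | train | predict | encode | ablate |
stability`); every command writes its fully resolved configuration next
to its outputs, and rerunning from that file with the same seed
reproduces results bit-identically.

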
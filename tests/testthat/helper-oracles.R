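# Independent brute-force oracles and small fixtures.  Every oracle here is
# written as directly as possible (dictionary counts, explicit double loops,
# all-pairs enumeration) so it shares no code path with the implementation
# it checks.

random_rna <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Dictionary-count k-mer frequencies: walk every window, count in a named
# table, divide by the window count.
oracle_kmer_freq <- function(seq, k) {
  n <- nchar(seq)
  kmers <- rbpattn:::all_kmers(k)
  counts <- stats::setNames(numeric(length(kmers)), kmers)
  if (n < k) return(counts)
  for (i in seq_len(n - k + 1L)) {
    w <- substr(seq, i, i + k - 1L)
    if (w %in% names(counts)) counts[w] <- counts[w] + 1
  }
  counts / (n - k + 1L)
}

# Scalar layer-norm: loop over components of one vector.
oracle_layer_norm <- function(z, gamma = rep(1, length(z)),
                              beta = rep(0, length(z)), eps = 0) {
  M <- length(z)
  mu <- sum(z) / M
  v <- sum((z - mu)^2) / M
  out <- numeric(M)
  for (i in seq_len(M)) {
    out[i] <- (z[i] - mu) / sqrt(v + eps) * gamma[i] + beta[i]
  }
  out
}

# Explicit O(L^2) attention: form every score with scalar loops, softmax
# each row, mix value vectors, concatenate heads, project.
oracle_attention <- function(z, p, mask = rep(TRUE, nrow(z))) {
  L <- nrow(z)
  d <- p$d
  h <- p$heads
  dh <- d / h
  denom <- if (identical(p$scale, "model_dim")) sqrt(d) else sqrt(dh)
  Q <- z %*% p$Wq + matrix(p$bq, L, d, byrow = TRUE)
  K <- z %*% p$Wk + matrix(p$bk, L, d, byrow = TRUE)
  V <- z %*% p$Wv + matrix(p$bv, L, d, byrow = TRUE)
  H <- matrix(0, L, d)
  for (hh in seq_len(h)) {
    cols <- ((hh - 1) * dh + 1):(hh * dh)
    for (i in seq_len(L)) {
      s <- rep(-Inf, L)
      for (j in seq_len(L)) {
        if (mask[j]) s[j] <- sum(Q[i, cols] * K[j, cols]) / denom
      }
      a <- exp(s - max(s))
      a <- a / sum(a)
      for (j in seq_len(L)) {
        if (a[j] > 0) H[i, cols] <- H[i, cols] + a[j] * V[j, cols]
      }
    }
  }
  H %*% p$Wo + matrix(p$bo, L, d, byrow = TRUE)
}

# All-pairs Mann-Whitney AUC with ties counted half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Small model configuration keeping unit-test fits to a few seconds.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(length = 30L, dim = 16L, heads = 2L, blocks = 1L, ffn_dim = 32L,
         encoder_channels = 8L, seq2vec_dim = 8L, context_dim = 8L,
         seq2vec_epochs = 3L, epochs = 3L, batch_size = 16L),
    list(...))
  do.call(rbp_config, args)
}

tiny_dataset <- function(n = 80L, length = 30L, seed = 7L,
                         mutation_rate = 0) {
  simulate_binding_sites(n = n, length = length,
                         motif = motif_spec("UGCAUGCA",
                                            mutation_rate = mutation_rate),
                         seed = seed)
}
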
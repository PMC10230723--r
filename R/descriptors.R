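# Per-position sequence descriptors.
#
# Three descriptors feed the fusion encoder:
#   * knfp        — k-tuple nucleotide frequency pattern (k = 1, 2, 3): the
#                   global relative frequency of the k-mer starting at each
#                   position, 3 channels;
#   * seq2vec     — distributed-memory embeddings of width-10 sliding-window
#                   words (see seq2vec.R);
#   * kmer_context — overlapping 3-mer tokens looked up in a trainable
#                   embedding table (stand-in for a pretrained language-model
#                   token representation; the 3-mer tokenization itself is
#                   retained).
#
# All descriptor matrices for one sequence share the position count L and
# carry zero rows wherever the window/token is incomplete or touches a pad.

#' K-tuple nucleotide frequency vector
#'
#' Relative frequencies of the 4^k overlapping k-mers of a sequence, in
#' lexicographic order A < C < G < U.  The denominator is the number of
#' windows, n - k + 1 (n = number of non-pad residues); windows containing
#' the `N` sentinel are excluded from the numerator, so the vector sums to 1
#' exactly when the sequence is fully determined.
#'
#' @param seq A residue string over \{A,C,G,U,N\}.
#' @param k Tuple size, 1, 2 or 3.
#' @param n_real Number of leading non-pad positions (defaults to the full
#'   string length).
#' @return Numeric vector of length 4^k.  All-zero when `n_real < k`.
#' @export
#' @examples
#' kmer_frequency_vector("AGCU", 1)
kmer_frequency_vector <- function(seq, k, n_real = nchar(seq)) {
  stopifnot(k %in% 1:3)
  out <- numeric(4^k)
  names(out) <- all_kmers(k)
  if (n_real < k) return(out)
  codes <- seq_to_codes(substr(seq, 1L, n_real))
  ids <- kmer_ids(codes, k)
  ids <- ids[!is.na(ids)]
  counts <- tabulate(ids + 1L, nbins = 4L^k)
  out[] <- counts / (n_real - k + 1L)
  out
}

#' Pooled 84-dimensional KNFP vector
#'
#' Concatenation of the k = 1, 2, 3 frequency vectors (4 + 16 + 64 = 84
#' components), one vector per sequence.  Auxiliary global variant of the
#' per-position [knfp_encode()].
#'
#' @inheritParams kmer_frequency_vector
#' @return Named numeric vector of length 84.
#' @export
knfp_global <- function(seq, n_real = nchar(seq)) {
  unlist(lapply(1:3, function(k) kmer_frequency_vector(seq, k, n_real)))
}

#' Per-position KNFP descriptor matrix
#'
#' Row i carries, for k = 1, 2, 3, the global relative frequency (from
#' [kmer_frequency_vector()]) of the k-mer that starts at position i.
#' Positions where the k-mer would run past the last real residue, or whose
#' window touches an `N`, carry 0 in that channel.
#'
#' @inheritParams kmer_frequency_vector
#' @param length Matrix position count L (defaults to `nchar(seq)`).
#' @return L x 3 numeric matrix (channels k = 1, 2, 3).
#' @export
knfp_encode <- function(seq, length = nchar(seq), n_real = nchar(seq)) {
  L <- as.integer(length)
  out <- matrix(0, L, 3L)
  colnames(out) <- paste0("k", 1:3)
  if (n_real < 1L) return(out)
  codes <- seq_to_codes(substr(seq, 1L, min(n_real, L)))
  for (k in 1:3) {
    if (n_real < k) next
    freq <- kmer_frequency_vector(seq, k, n_real)
    ids <- kmer_ids(codes, k)
    keep <- !is.na(ids)
    rows <- seq_along(ids)[keep]
    out[rows, k] <- freq[ids[keep] + 1L]
  }
  out
}

#' Sliding-window word tokenization
#'
#' Cuts a sequence into overlapping fixed-width words (default width 10,
#' stride 1), the tokenization unit of the distributed-embedding descriptor.
#'
#' @inheritParams kmer_frequency_vector
#' @param width Window width in residues.
#' @param stride Step between window starts.
#' @return Character vector of `max(0, floor((n - width)/stride) + 1)` words.
#' @export
#' @examples
#' tokenize_window("ACGUACGUACGU", width = 10)
tokenize_window <- function(seq, width = 10L, stride = 1L, n_real = nchar(seq)) {
  stopifnot(is_count(width), is_count(stride))
  n <- n_real
  if (n < width) return(character(0))
  starts <- seq.int(1L, n - width + 1L, by = stride)
  substring(seq, starts, starts + width - 1L)
}

#' Overlapping k-mer tokenization
#'
#' Stride-1 overlapping k-mers (default k = 3), the token unit of the
#' context-embedding descriptor.
#'
#' @inheritParams tokenize_window
#' @param k Token width.
#' @return Character vector of `max(0, n - k + 1)` tokens.
#' @export
#' @examples
#' kmer_tokenize("AGCUA")
kmer_tokenize <- function(seq, k = 3L, n_real = nchar(seq)) {
  tokenize_window(seq, width = k, stride = 1L, n_real = n_real)
}

#' Create a 3-mer context-embedding table
#'
#' A (4^k + 1) x dim embedding matrix covering every k-mer over
#' \{A,C,G,U\} plus an UNK row for tokens containing ambiguity sentinels.
#' The table is trained end to end with the classifier by default; a frozen
#' table of precomputed per-token embeddings can be imported instead with
#' [read_embedding_table()].
#'
#' @param dim Embedding width.
#' @param k Token width.
#' @param learnable Whether gradients flow into the table during training.
#' @param init `"glorot"` for random init (seeded by the active RNG) or
#'   `"zero"`.
#' @return A `context_table` list with fields `tokens`, `embedding`
#'   ((4^k + 1) x dim matrix, last row = UNK), `k`, `dim`, `learnable`.
#' @export
context_embedding_table <- function(dim = 64L, k = 3L, learnable = TRUE,
                                    init = c("glorot", "zero")) {
  init <- match.arg(init)
  tokens <- all_kmers(k)
  n <- length(tokens) + 1L
  emb <- if (init == "zero") matrix(0, n, dim) else glorot(n, dim)
  rownames(emb) <- c(tokens, "UNK")
  structure(list(tokens = tokens, embedding = emb, k = as.integer(k),
                 dim = as.integer(dim), learnable = learnable),
            class = "context_table")
}

#' Integer token ids for the context-embedding descriptor
#'
#' Maps each position of a standardized sequence to a 1-based row of the
#' context table: position i gets the id of the k-mer starting at i, the UNK
#' id if that k-mer contains `N`, and 0 where no complete k-mer fits
#' (trailing positions and pads; these yield zero descriptor rows).
#'
#' @inheritParams knfp_encode
#' @param table A [context_embedding_table()].
#' @return Integer vector of length L.
#' @export
context_token_ids <- function(seq, table, length = nchar(seq),
                              n_real = nchar(seq)) {
  L <- as.integer(length)
  k <- table$k
  ids <- integer(L)
  if (n_real >= k) {
    codes <- seq_to_codes(substr(seq, 1L, min(n_real, L)))
    kid <- kmer_ids(codes, k)
    unk <- length(table$tokens) + 1L
    vals <- ifelse(is.na(kid), unk, kid + 1L)
    ids[seq_along(kid)] <- vals
  }
  ids
}

#' Look up context embeddings for a token sequence
#'
#' @param tokens Character vector of k-mer tokens (e.g. from
#'   [kmer_tokenize()]).
#' @param table A [context_embedding_table()].
#' @param length Output position count L (defaults to the token count; rows
#'   beyond the token count are zero).
#' @return L x dim numeric matrix.
#' @export
context_embed <- function(tokens, table, length = base::length(tokens)) {
  stopifnot(inherits(table, "context_table"))
  L <- as.integer(length)
  out <- matrix(0, L, table$dim)
  if (base::length(tokens) == 0L) return(out)
  if (any(nchar(tokens) != table$k)) {
    stopf("All tokens must have width %d to match the table.", table$k)
  }
  idx <- match(tokens, table$tokens)
  idx[is.na(idx)] <- base::length(table$tokens) + 1L  # UNK
  n <- min(base::length(tokens), L)
  out[seq_len(n), ] <- table$embedding[idx[seq_len(n)], , drop = FALSE]
  out
}

#' Import a frozen per-token embedding table from TSV
#'
#' File format: one row per token, `token<TAB>v1<TAB>...<TAB>vD`, no header.
#' Tokens absent from the file fall back to a zero row; an UNK row may be
#' supplied under the literal token `UNK`.
#'
#' @param path TSV path.
#' @param k Token width (validated against the file's tokens).
#' @return A frozen (`learnable = FALSE`) `context_table`.
#' @export
read_embedding_table <- function(path, k = 3L) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  toks <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (any(nchar(setdiff(toks, "UNK")) != k)) {
    stopf("Embedding file tokens must have width %d.", k)
  }
  tab <- context_embedding_table(dim = ncol(vals), k = k, learnable = FALSE,
                                 init = "zero")
  hit <- match(c(tab$tokens, "UNK"), toks)
  found <- !is.na(hit)
  tab$embedding[found, ] <- vals[hit[found], , drop = FALSE]
  tab
}

#' Export an embedding table to TSV
#'
#' @param table A `context_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(table, path) {
  df <- data.frame(token = c(table$tokens, "UNK"), table$embedding,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
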
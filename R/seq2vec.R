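# Distributed-memory sequence embeddings (doc2vec-style PV-DM).
#
# Each sequence is tokenized into overlapping width-10 words; a PV-DM model
# then learns word vectors by predicting each center word from the mean of
# its context-word vectors plus a per-document vector, trained with negative
# sampling.  The per-document vector is what distinguishes the model from
# plain word2vec.  Training runs on the input dataset's own training split
# (no external corpus is required), single-threaded and bit-reproducible
# under a fixed seed.

#' Train a PV-DM sequence-embedding model
#'
#' @param corpus A list of character vectors (one word sequence per
#'   document, e.g. from [tokenize_window()]), or a sequence tibble with a
#'   `seq` column which is tokenized internally.
#' @param dim Embedding width D.
#' @param window Context radius in words on each side of the center word.
#' @param epochs Number of passes over the corpus.
#' @param negative Number of negative samples per center word.
#' @param alpha,min_alpha Initial and final SGD learning rate (linear decay
#'   over all scheduled updates).
#' @param width,stride Tokenization parameters applied when `corpus` is a
#'   sequence tibble; recorded on the model so [embed_sequence()] can reuse
#'   them.
#' @param seed Integer seed; identical inputs and seed reproduce the trained
#'   vectors exactly.
#' @return A `seq2vec_model` list: `vocabulary` (character vector, index =
#'   row of `word_vectors`), `word_vectors` (|V| x D), `doc_vectors`, `dim`,
#'   `width`, `stride`, `window`, `epochs`, `seed`.
#' @export
train_seq2vec <- function(corpus, dim = 64L, window = 5L, epochs = 20L,
                          negative = 5L, alpha = 0.025, min_alpha = 1e-4,
                          width = 10L, stride = 1L, seed = 42L) {
  if (is.data.frame(corpus)) {
    n_real <- corpus[["n_real"]] %||% nchar(corpus$seq)
    corpus <- purrr::map2(corpus$seq, n_real,
                          ~ tokenize_window(.x, width, stride, n_real = .y))
  }
  stopifnot(is.list(corpus))
  corpus <- purrr::map(corpus, as.character)
  words <- unlist(corpus, use.names = FALSE)
  if (length(words) == 0L) {
    stopf("Empty vocabulary: the corpus contains no words (all documents shorter than the window?).")
  }
  vocab <- unique(words)  # first-appearance order: deterministic
  counts <- tabulate(match(words, vocab), nbins = length(vocab))
  docs <- purrr::map(corpus, ~ match(.x, vocab) - 1L)

  fit <- .s2v_train_cpp(docs, length(vocab), as.numeric(counts),
                        as.integer(dim), as.integer(window),
                        as.integer(epochs), as.integer(negative),
                        alpha, min_alpha, as.numeric(seed))
  structure(list(vocabulary = vocab,
                 word_vectors = fit$word_vectors,
                 doc_vectors = fit$doc_vectors,
                 dim = as.integer(dim), width = as.integer(width),
                 stride = as.integer(stride), window = as.integer(window),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "seq2vec_model")
}

#' Per-position embedding matrix of one sequence
#'
#' Row i is the trained word vector of the window starting at position i
#' (pure lookup, no inference); trailing rows where no full window fits, pad
#' rows, and out-of-vocabulary windows are zero.  OOV windows only occur
#' when the model was trained on a different corpus; their count is returned
#' in the `oov` attribute and a warning is raised.
#'
#' @param model A [train_seq2vec()] model.
#' @param seq Residue string.
#' @param length Output position count L.
#' @param n_real Number of non-pad positions.
#' @param warn_oov Emit a warning when out-of-vocabulary windows are hit.
#' @return L x dim matrix with an `oov` attribute (integer count).
#' @export
embed_sequence <- function(model, seq, length = nchar(seq),
                           n_real = nchar(seq), warn_oov = TRUE) {
  stopifnot(inherits(model, "seq2vec_model"))
  L <- as.integer(length)
  out <- matrix(0, L, model$dim)
  words <- tokenize_window(seq, model$width, model$stride, n_real = n_real)
  oov <- 0L
  if (base::length(words) > 0L) {
    idx <- match(words, model$vocabulary)
    hit <- !is.na(idx)
    oov <- sum(!hit)
    rows <- seq.int(1L, by = model$stride, length.out = base::length(words))
    out[rows[hit], ] <- model$word_vectors[idx[hit], , drop = FALSE]
  }
  if (oov > 0L && warn_oov) {
    warn(sprintf("%d window(s) were out of vocabulary and embedded as zero rows.", oov))
  }
  attr(out, "oov") <- oov
  out
}

#' Export seq2vec word vectors as TSV
#'
#' Portable dump, one row per word: `word<TAB>v1...<TAB>vD`.
#'
#' @param model A `seq2vec_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seq2vec <- function(model, path) {
  df <- data.frame(word = model$vocabulary, model$word_vectors)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
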
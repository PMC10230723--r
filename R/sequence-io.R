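# Sequence input/output, alphabet normalization, length standardization and
# the stratified train/test split.
#
# Datasets are plain tibbles with columns `id`, `seq` and (when labeled)
# `label` (integer 0/1, 1 = bound fragment).  The residue alphabet after
# normalization is {A, C, G, U}, with "N" as the sentinel for masked
# ambiguity codes and right-padding; descriptor builders emit zero rows at
# every position whose window touches an N.

#' Read RNA/DNA sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble, upper-casing residues and normalizing
#' the alphabet to \{A, C, G, U\}.  CLIP-Seq benchmark files are commonly
#' distributed as DNA, so T is mapped to U under the default policies.
#'
#' @param path Path to a FASTA file.
#' @param alphabet_policy One of:
#'   \describe{
#'     \item{`"mask_unknown"`}{(default) map T/t to U, then replace any other
#'       non-ACGU character with the sentinel `N`.  Descriptors emit all-zero
#'       feature rows wherever a window touches an `N`.}
#'     \item{`"map_dna"`}{map T/t to U; any remaining non-ACGU character is an
#'       error naming its position.}
#'     \item{`"strict"`}{no mapping at all; any character outside ACGU is an
#'       error.}
#'   }
#' @return A tibble with columns `id` (character) and `seq` (character).
#'   Multi-line record bodies are concatenated; records appear in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path,
                       alphabet_policy = c("mask_unknown", "map_dna", "strict")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  info <- file.info(path)
  if (info$size == 0) {
    return(tibble(id = character(0), seq = character(0)))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stopf("Malformed FASTA file %s: %s", path, conditionMessage(e))
  )
  ids <- names(set)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0L) {
    stopf("FASTA record %d ('%s') has an empty sequence body.",
          empty[1L], ids[empty[1L]])
  }
  seqs <- normalize_alphabet(seqs, alphabet_policy)
  tibble(id = ids, seq = unname(seqs))
}

normalize_alphabet <- function(seqs, policy) {
  if (policy %in% c("mask_unknown", "map_dna")) {
    seqs <- chartr("T", "U", seqs)
  }
  bad <- regexpr("[^ACGU]", seqs)
  offenders <- which(bad > 0L)
  if (length(offenders) > 0L) {
    if (policy == "mask_unknown") {
      seqs <- gsub("[^ACGU]", "N", seqs)
    } else {
      i <- offenders[1L]
      stopf("Sequence %d contains character '%s' outside {A,C,G,U} at position %d (policy '%s').",
            i, substr(seqs[i], bad[i], bad[i]), bad[i], policy)
    }
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param data Tibble with columns `id` and `seq`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 70L) {
  set <- Biostrings::BStringSet(data$seq)
  names(set) <- data$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a two-column id/label TSV
#'
#' @param path Path to a tab-separated file with columns `id` and `label`
#'   (0/1).
#' @param header Whether the file has a header line.
#' @return Tibble with columns `id` (character), `label` (integer).
#' @export
read_labels <- function(path, header = TRUE) {
  df <- read.table(path, sep = "\t", header = header,
                   colClasses = c("character", "integer"))
  names(df) <- c("id", "label")
  if (!all(df$label %in% c(0L, 1L))) {
    stopf("Labels must be 0 or 1; found: %s",
          paste(unique(setdiff(df$label, 0:1)), collapse = ", "))
  }
  as_tibble(df)
}

#' Load a labeled dataset from positive and negative FASTA files
#'
#' @param positive_path,negative_path FASTA files holding bound (label 1) and
#'   unbound (label 0) fragments.
#' @inheritParams read_fasta
#' @return Labeled tibble with columns `id`, `seq`, `label`.
#' @export
read_labeled_fasta <- function(positive_path, negative_path,
                               alphabet_policy = "mask_unknown") {
  pos <- read_fasta(positive_path, alphabet_policy)
  neg <- read_fasta(negative_path, alphabet_policy)
  bind_rows(
    mutate(pos, label = 1L),
    mutate(neg, label = 0L)
  )
}

#' Standardize all sequences to a common length
#'
#' The per-position descriptor stack requires fixed-length fragments.
#' Over-length sequences are center-truncated (binding sites in CLIP-derived
#' benchmarks are centered by construction); under-length sequences are
#' right-padded.
#'
#' @param data Sequence tibble (columns `id`, `seq`, optionally `label`).
#' @param length Target length L.
#' @param pad_policy One of `"pad_N_as_zero"` (right-pad with the `N`
#'   sentinel; padded positions are flagged via `n_real` and yield zero
#'   descriptor rows), `"pad_repeat"` (tile the sequence cyclically, natural
#'   for circular RNA fragments; no flagged positions), or `"error"`.
#' @return The input tibble with `seq` of length `length` and a new integer
#'   column `n_real` giving the number of leading non-pad positions.
#' @export
standardize_length <- function(data, length = 101L,
                               pad_policy = c("pad_N_as_zero", "pad_repeat", "error")) {
  pad_policy <- match.arg(pad_policy)
  stopifnot(is_count(length))
  L <- as.integer(length)
  n <- nchar(data$seq)
  if (pad_policy == "error" && any(n != L)) {
    i <- which(n != L)[1L]
    stopf("Sequence '%s' has length %d, expected %d (pad_policy = 'error').",
          data$id[i], n[i], L)
  }
  out_seq <- character(nrow(data))
  n_real <- integer(nrow(data))
  for (i in seq_len(nrow(data))) {
    s <- data$seq[i]
    ni <- n[i]
    if (ni == L) {
      out_seq[i] <- s
      n_real[i] <- L
    } else if (ni > L) {
      off <- (ni - L) %/% 2L
      out_seq[i] <- substr(s, off + 1L, off + L)
      n_real[i] <- L
    } else if (pad_policy == "pad_repeat") {
      out_seq[i] <- substr(strrep(s, ceiling(L / ni)), 1L, L)
      n_real[i] <- L
    } else {
      out_seq[i] <- paste0(s, strrep("N", L - ni))
      n_real[i] <- ni
    }
  }
  data$seq <- out_seq
  data$n_real <- n_real
  data
}

#' Stratified train/test split
#'
#' Splits a labeled dataset into train and test parts, preserving the class
#' balance: the train part receives `round(train_frac * n)` records of each
#' label.  The same seed always reproduces the identical split.
#'
#' @param data Labeled tibble (`id`, `seq`, `label`).
#' @param train_frac Fraction of each class assigned to the train part.
#' @param seed Integer seed controlling the split.
#' @return A list with elements `train` and `test` (tibbles), carrying a
#'   `split_hash` attribute (hash of the sorted train ids) for
#'   matched-comparison logging.
#' @export
split_dataset <- function(data, train_frac = 0.8, seed = 42L) {
  check_fraction(train_frac, "train_frac")
  if (is.null(data$label) || anyNA(data$label)) {
    stopf("split_dataset() requires a fully labeled dataset.")
  }
  counts <- table(factor(data$label, levels = c(0L, 1L)))
  if (any(counts < 2L)) {
    stopf("Each label class needs at least 2 records to stratify (have %d negatives, %d positives).",
          counts[["0"]], counts[["1"]])
  }
  idx <- seq_len(nrow(data))
  train_idx <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(lab) {
      pool <- idx[data$label == lab]
      sample(pool, size = round(train_frac * length(pool)))
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  out <- list(train = data[train_idx, , drop = FALSE],
              test = data[setdiff(idx, train_idx), , drop = FALSE])
  attr(out, "split_hash") <- hash(sort(out$train$id))
  out
}
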
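# Shared internal helpers: alphabet coding, seeded RNG scoping, small checks.

RNA_BASES <- c("A", "C", "G", "U")

# Map residues to integer codes A=0, C=1, G=2, U=3; anything else (the N
# sentinel for masked ambiguity codes, pad filler) becomes NA.
seq_to_codes <- function(seq) {
  x <- utf8ToInt(seq)
  codes <- rep(NA_integer_, length(x))
  codes[x == 65L] <- 0L  # A
  codes[x == 67L] <- 1L  # C
  codes[x == 71L] <- 2L  # G
  codes[x == 85L] <- 3L  # U
  codes
}

codes_to_seq <- function(codes) {
  paste(RNA_BASES[codes + 1L], collapse = "")
}

# All k-mers over {A,C,G,U} in lexicographic order (A < C < G < U).
all_kmers <- function(k) {
  grids <- rev(rep(list(RNA_BASES), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

# Integer id (0-based) of the k-mer starting at each position, NA where the
# window is incomplete or touches a non-ACGU character.
kmer_ids <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(integer(0))
  id <- codes[seq_len(n - k + 1L)]
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      id <- id * 4L + codes[(1L + j):(n - k + 1L + j)]
    }
  }
  id
}

stopf <- function(...) abort(sprintf(...))

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 1

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stopf("`%s` must be a single number strictly between 0 and 1.", name)
  }
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Glorot-uniform init, drawn from the active RNG stream.
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)  # m recycles down columns = per-row subtraction
  e / rowSums(e)
}

# Row-recycled column operations; faster than sweep() on large matrices.
add_rowvec <- function(x, b) x + rep(b, each = nrow(x))
mul_rowvec <- function(x, g) x * rep(g, each = nrow(x))
sub_rowvec <- function(x, b) x - rep(b, each = nrow(x))
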
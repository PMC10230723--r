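# Model assembly: configuration, parameter initialization, descriptor
# feature building, and the batched forward/backward pass that ties the
# descriptor branches, fusion encoder, self-attention stack and classifier
# head together.

#' Model and training configuration
#'
#' All tunable settings of the pipeline with their defaults.  Model sizes
#' (width 128, 8 heads, 2 pre-norm blocks, FFN width 512) are chosen to keep
#' desk-scale training fast; the optimizer protocol (Adam, weight decay
#' 3e-4, batch 64, initial rate 3e-3 decaying tenfold every 2 epochs)
#' follows the published training recipe this package implements.
#'
#' @param length Standardized fragment length L.
#' @param descriptors Subset of `c("knfp", "seq2vec", "kmer_context")` to
#'   enable; disabled branches contribute zero matrices downstream.
#' @param encoder_channels Unified branch channel count C_u.
#' @param encoder_kernel Odd convolution kernel size of each branch.
#' @param dim Model width d of the fused feature and attention stack.
#' @param heads,blocks,ffn_dim Attention stack shape.
#' @param norm_style `"pre"` (default) or `"post"` residual wiring.
#' @param positional Add a learned positional embedding to the fused
#'   feature (the attention itself is position-agnostic).
#' @param dropout Dropout rate on the two residual sub-layer outputs during
#'   training.
#' @param attn_scale `"per_head"` (score scaling by sqrt(d/h)) or
#'   `"model_dim"` (sqrt(d)).
#' @param residual_scale Initialization multiplier on the residual-branch
#'   output projections; values below 1 start the stack near the identity
#'   and keep the first high-learning-rate epochs stable.
#' @param embed_norm Apply a layer norm to the fused feature (after the
#'   positional embedding) before the attention stack; stabilizes the scale
#'   of what the stack consumes.
#' @param clip_norm Global gradient-norm ceiling applied before each Adam
#'   update (`Inf` disables).  A divergence guard for the aggressive
#'   initial learning rate; it leaves the optimizer and schedule untouched.
#' @param seq2vec_dim,seq2vec_width,seq2vec_window,seq2vec_epochs Embedding
#'   descriptor settings (word width 10 over the sequence, PV-DM context
#'   radius 5 words, 20 epochs).
#' @param context_dim Width of the trainable 3-mer context-embedding table.
#' @param epochs,batch_size,initial_rate,weight_decay,lr_decay_factor,lr_decay_every
#'   Training protocol.
#' @param threshold Score threshold for ACC/precision/recall.
#' @param train_frac Train fraction of the stratified split.
#' @param pad_policy Length-standardization policy, see
#'   [standardize_length()].
#' @return A `rbp_config` list.
#' @export
rbp_config <- function(length = 101L,
                       descriptors = c("knfp", "seq2vec", "kmer_context"),
                       encoder_channels = 128L, encoder_kernel = 3L,
                       dim = 128L, heads = 8L, blocks = 2L, ffn_dim = 512L,
                       norm_style = c("pre", "post"), positional = TRUE,
                       dropout = 0.1,
                       attn_scale = c("per_head", "model_dim"),
                       residual_scale = 0.1, embed_norm = TRUE,
                       clip_norm = 1,
                       seq2vec_dim = 64L, seq2vec_width = 10L,
                       seq2vec_window = 5L, seq2vec_epochs = 20L,
                       context_dim = 64L,
                       epochs = 10L, batch_size = 64L, initial_rate = 3e-3,
                       weight_decay = 3e-4, lr_decay_factor = 0.1,
                       lr_decay_every = 2L,
                       threshold = 0.5, train_frac = 0.8,
                       pad_policy = "pad_N_as_zero") {
  descriptors <- match.arg(descriptors, several.ok = TRUE)
  cfg <- list(
    length = as.integer(length), descriptors = descriptors,
    encoder_channels = as.integer(encoder_channels),
    encoder_kernel = as.integer(encoder_kernel),
    dim = as.integer(dim), heads = as.integer(heads),
    blocks = as.integer(blocks), ffn_dim = as.integer(ffn_dim),
    norm_style = match.arg(norm_style), positional = positional,
    dropout = dropout, attn_scale = match.arg(attn_scale),
    residual_scale = residual_scale,
    embed_norm = embed_norm, clip_norm = clip_norm,
    seq2vec_dim = as.integer(seq2vec_dim),
    seq2vec_width = as.integer(seq2vec_width),
    seq2vec_window = as.integer(seq2vec_window),
    seq2vec_epochs = as.integer(seq2vec_epochs),
    context_dim = as.integer(context_dim),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    initial_rate = initial_rate, weight_decay = weight_decay,
    lr_decay_factor = lr_decay_factor,
    lr_decay_every = as.integer(lr_decay_every),
    threshold = threshold, train_frac = train_frac,
    pad_policy = pad_policy
  )
  structure(cfg, class = "rbp_config")
}

DESCRIPTOR_ORDER <- c("knfp", "seq2vec", "kmer_context")

# Initialize all learnable parameters from the active RNG stream.
init_model <- function(config, context_table = NULL) {
  L <- config$length
  cu <- config$encoder_channels
  embed <- context_table %||%
    context_embedding_table(dim = config$context_dim, k = 3L, learnable = TRUE)
  branches <- list(
    knfp = encoder_branch_params(3L, cu, config$encoder_kernel),
    seq2vec = encoder_branch_params(config$seq2vec_dim, cu, config$encoder_kernel),
    kmer_context = encoder_branch_params(config$context_dim, cu, config$encoder_kernel)
  )
  structure(list(
    embed = embed,
    branches = branches,
    fusion = fusion_params(cu, config$dim, 3L),
    pos = if (config$positional) matrix(rnorm(L * config$dim, sd = 0.02), L, config$dim),
    embed_ln = if (isTRUE(config$embed_norm))
      list(gamma = rep(1, config$dim), beta = rep(0, config$dim)),
    stack = transformer_params(config$dim, config$heads, config$blocks,
                               config$ffn_dim, config$norm_style,
                               scale = config$attn_scale,
                               residual_scale = config$residual_scale %||% 1),
    head = classifier_head(config$dim, init = "zero"),
    config = config
  ), class = "rbp_model")
}

# Precompute the static per-sequence features of a standardized dataset:
# KNFP matrices, seq2vec window embeddings (single vectorized vocabulary
# lookup), and context-token id rows for the trainable embedding branch.
build_features <- function(data, s2v_model, config) {
  L <- config$length
  N <- nrow(data)
  n_real <- data[["n_real"]] %||% nchar(data$seq)

  knfp <- matrix(0, N * L, 3L)
  if ("knfp" %in% config$descriptors) {
    for (i in seq_len(N)) {
      knfp[((i - 1L) * L + 1L):(i * L), ] <-
        knfp_encode(data$seq[i], length = L, n_real = n_real[i])
    }
  }

  s2v <- matrix(0, N * L, config$seq2vec_dim)
  oov <- 0L
  if ("seq2vec" %in% config$descriptors) {
    w <- s2v_model$width
    per <- pmax(0L, pmin(n_real, L) - w + 1L)
    starts <- (seq_len(N) - 1L) * L
    rows <- unlist(lapply(seq_len(N), function(i) {
      if (per[i] > 0L) starts[i] + seq_len(per[i]) else integer(0)
    }), use.names = FALSE)
    words <- unlist(lapply(seq_len(N), function(i) {
      tokenize_window(data$seq[i], w, 1L, n_real = min(n_real[i], L))
    }), use.names = FALSE)
    idx <- match(words, s2v_model$vocabulary)
    hit <- !is.na(idx)
    oov <- sum(!hit)
    s2v[rows[hit], ] <- s2v_model$word_vectors[idx[hit], , drop = FALSE]
  }

  tok <- matrix(0L, N, L)
  if ("kmer_context" %in% config$descriptors) {
    tab <- context_embedding_table(dim = 1L, k = 3L, init = "zero")
    for (i in seq_len(N)) {
      tok[i, ] <- context_token_ids(data$seq[i], tab, length = L,
                                    n_real = min(n_real[i], L))
    }
  }

  list(ids = data$id, labels = data[["label"]] %||% rep(NA_integer_, N),
       knfp = knfp, s2v = s2v, tok = tok,
       n_real = pmin(n_real, L),
       N = N, L = L, oov = oov)
}

# Row indices of samples `s` in a sample-major (N*L) feature matrix.
batch_rows <- function(s, L) {
  rep((s - 1L) * L, each = L) + rep(seq_len(L), length(s))
}

# Forward pass over a batch of sample indices.  Returns probabilities, loss
# (when labels are present) and, if `keep_cache`, everything backward needs.
model_fw <- function(model, feat, s, training = FALSE, keep_cache = training) {
  cfg <- model$config
  L <- feat$L
  B <- length(s)
  rows <- batch_rows(s, L)
  mask_lb <- outer(seq_len(L), feat$n_real[s], `<=`)  # L x B
  mask <- as.vector(mask_lb)                          # sample-major (B*L)
  n_real <- feat$n_real[s]
  idx <- conv_index(B, L, cfg$encoder_kernel)

  enabled <- cfg$descriptors
  zero_branch <- matrix(0, B * L, cfg$encoder_channels)
  caches <- list()

  branches_out <- list()
  for (br in DESCRIPTOR_ORDER) {
    if (!br %in% enabled) {
      branches_out[[br]] <- zero_branch
      next
    }
    x <- switch(br,
      knfp = feat$knfp[rows, , drop = FALSE],
      seq2vec = feat$s2v[rows, , drop = FALSE],
      kmer_context = {
        # feat$tok is N x L; transpose the slice for sample-major order
        ids <- as.vector(t(feat$tok[s, , drop = FALSE]))
        caches$ctx_ids <- ids
        rbind(0, model$embed$embedding)[ids + 1L, , drop = FALSE]
      })
    bf <- branch_fw(x, model$branches[[br]], B, L, training = training, idx = idx)
    model$branches[[br]]$bn_state <- bf$state
    branches_out[[br]] <- bf$y
    caches[[paste0("branch_", br)]] <- bf$cache
  }

  fu <- fuse_fw(branches_out[DESCRIPTOR_ORDER], model$fusion)
  z <- fu$y
  if (!is.null(model$pos)) {
    z <- z + model$pos[rep(seq_len(L), B), , drop = FALSE]
  }
  en <- NULL
  if (!is.null(model$embed_ln)) {
    en <- ln_fw(z, model$embed_ln$gamma, model$embed_ln$beta)
    z <- en$y
  }
  st <- stack_fw(z, model$stack, B, L, mask, training = training,
                 dropout = cfg$dropout)
  hf <- head_fw(st$y, model$head, B, L, mask, n_real)

  out <- list(probs = hf$probs, model = model, B = B, L = L)
  labels <- feat$labels[s]
  if (!anyNA(labels)) {
    ce <- softmax_ce_fw(hf$logits, labels)
    out$loss <- ce$loss
  }
  if (keep_cache) {
    out$cache <- list(fu = fu$cache, en = en, st = st, hf = hf, mask = mask,
                      n_real = n_real, s = s, labels = labels,
                      caches = caches, branches_enabled = enabled)
  }
  out
}

# Backward pass; returns gradients in the same nesting as the parameters.
model_bw <- function(model, fw) {
  cfg <- model$config
  B <- fw$B; L <- fw$L
  ch <- fw$cache
  grads <- list()

  dlogits <- softmax_ce_bw(fw$probs, ch$labels)
  hb <- head_bw(ch$hf, model$head, dlogits, B, L, ch$mask, ch$n_real)
  grads$head <- list(Wc = hb$dWc, bc = hb$dbc)

  sb <- stack_bw(model$stack, ch$st, hb$dx)
  grads$stack <- list(blocks = sb$block_grads, final_ln = sb$final_grads)
  dz <- sb$dx

  if (!is.null(model$embed_ln)) {
    eb <- ln_bw(ch$en$cache, dz)
    grads$embed_ln <- list(gamma = eb$dgamma, beta = eb$dbeta)
    dz <- eb$dx
  }

  if (!is.null(model$pos)) {
    grads$pos <- rowsum(dz, group = rep(seq_len(L), B), reorder = FALSE)
  }

  fb <- fuse_bw(ch$fu, dz)
  grads$fusion <- list(W = fb$dW, b = fb$db)

  grads$branches <- list()
  for (j in seq_along(DESCRIPTOR_ORDER)) {
    br <- DESCRIPTOR_ORDER[j]
    if (!br %in% ch$branches_enabled) next
    bb <- branch_bw(ch$caches[[paste0("branch_", br)]], fb$dbranches[[j]])
    grads$branches[[br]] <- bb$grads
    if (br == "kmer_context" && isTRUE(model$embed$learnable)) {
      ids <- ch$caches$ctx_ids
      keep <- ids > 0L
      if (any(keep)) {
        dE <- matrix(0, nrow(model$embed$embedding), ncol(model$embed$embedding))
        agg <- rowsum(bb$dx[keep, , drop = FALSE], group = ids[keep])
        dE[as.integer(rownames(agg)), ] <- agg
        grads$embed <- dE
      }
    }
  }
  grads
}

# ---- trainable-parameter registry ----------------------------------------

# Paths (lists of names/indices) of every trainable tensor of a model.
model_param_paths <- function(model) {
  cfg <- model$config
  paths <- list()
  add <- function(...) paths[[length(paths) + 1L]] <<- list(...)
  if ("kmer_context" %in% cfg$descriptors && isTRUE(model$embed$learnable)) {
    add("embed", "embedding")
  }
  for (br in intersect(DESCRIPTOR_ORDER, cfg$descriptors)) {
    add("branches", br, "W"); add("branches", br, "b")
    add("branches", br, "bn", "gamma"); add("branches", br, "bn", "beta")
  }
  add("fusion", "W"); add("fusion", "b")
  if (!is.null(model$pos)) add("pos")
  if (!is.null(model$embed_ln)) {
    add("embed_ln", "gamma"); add("embed_ln", "beta")
  }
  for (i in seq_along(model$stack$blocks)) {
    for (leaf in list(c("ln1", "gamma"), c("ln1", "beta"),
                      c("attn", "Wq"), c("attn", "bq"),
                      c("attn", "Wk"), c("attn", "bk"),
                      c("attn", "Wv"), c("attn", "bv"),
                      c("attn", "Wo"), c("attn", "bo"),
                      c("ln2", "gamma"), c("ln2", "beta"),
                      "W1", "b1", "W2", "b2")) {
      paths[[length(paths) + 1L]] <- c(list("stack", "blocks", i), as.list(leaf))
    }
  }
  if (!is.null(model$stack$final_ln)) {
    add("stack", "final_ln", "gamma"); add("stack", "final_ln", "beta")
  }
  add("head", "Wc"); add("head", "bc")
  paths
}

get_path <- function(x, path) {
  for (k in path) {
    x <- x[[k]]
    if (is.null(x)) return(NULL)
  }
  x
}

set_path <- function(x, path, value) {
  if (length(path) == 1L) {
    x[[path[[1L]]]] <- value
    return(x)
  }
  x[[path[[1L]]]] <- set_path(x[[path[[1L]]]], path[-1L], value)
  x
}

# Grad nesting differs slightly from the parameter nesting for the stack
# (blocks live under grads$stack$blocks with attn sub-list) and the
# embedding (plain matrix under grads$embed); translate a parameter path to
# the matching grad path.
grad_path <- function(path) {
  if (identical(path[[1L]], "embed")) return(list("embed"))
  path
}
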
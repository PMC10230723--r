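# The sequence self-attention stack: scaled dot-product multi-head
# attention, position-wise feed-forward sub-layers, and residual wiring in
# either pre-norm form (x + F(LN(x)); the default, which keeps an identity
# gradient path through any number of blocks) or post-norm form
# (LN(x + F(x)); kept for ablation).
#
# Exported functions operate on a single L x d matrix; internal *_fw/*_bw
# variants run on sample-major (B*L) x d batches and cache what the
# backward pass needs.

#' Multi-head attention parameters
#'
#' @param d Model width (must be divisible by `heads`).
#' @param heads Number of attention heads h.
#' @param init `"glorot"` for random init (drawn from the active RNG
#'   stream) or `"zero_residual"`, which zeroes the output projection so a
#'   pre-norm residual block starts as the identity map.
#' @param scale `"per_head"` (default) scales attention scores by
#'   `1/sqrt(d/h)`; `"model_dim"` uses `1/sqrt(d)`.
#' @param residual_scale Multiplier applied to the randomly initialized
#'   output projection.  Shrinking the residual branches at init keeps a
#'   fresh stack close to the identity and stabilizes the first
#'   high-learning-rate epochs; 1 disables the shrinkage.
#' @return An `attention_params` list.
#' @export
attention_params <- function(d, heads, init = c("glorot", "zero_residual"),
                             scale = c("per_head", "model_dim"),
                             residual_scale = 1) {
  init <- match.arg(init)
  scale <- match.arg(scale)
  if (d %% heads != 0L) stopf("Model width %d is not divisible by %d heads.", d, heads)
  p <- list(
    Wq = glorot(d, d), bq = rep(0, d),
    Wk = glorot(d, d), bk = rep(0, d),
    Wv = glorot(d, d), bv = rep(0, d),
    Wo = if (init == "zero_residual") matrix(0, d, d) else
      residual_scale * glorot(d, d),
    bo = rep(0, d),
    heads = as.integer(heads), d = as.integer(d), scale = scale
  )
  structure(p, class = "attention_params")
}

attn_denom <- function(p) {
  if (identical(p$scale, "model_dim")) sqrt(p$d) else sqrt(p$d / p$heads)
}

mha_fw <- function(x, p, B, L, mask = NULL, keep_weights = FALSE) {
  d <- p$d; h <- p$heads; dh <- d %/% h
  if (is.null(mask)) mask <- rep(TRUE, B * L)
  Q <- linear_fw(x, p$Wq, p$bq)
  K <- linear_fw(x, p$Wk, p$bk)
  V <- linear_fw(x, p$Wv, p$bv)
  sc <- 1 / attn_denom(p)
  H <- matrix(0, B * L, d)
  A <- vector("list", B * h)  # per (sample, head) weight matrices
  for (b in seq_len(B)) {
    r <- ((b - 1L) * L + 1L):(b * L)
    mb <- mask[r]
    if (!any(mb)) stopf("Attention contract violated: all %d positions of sample %d are masked.", L, b)
    for (hh in seq_len(h)) {
      hc <- ((hh - 1L) * dh + 1L):(hh * dh)
      S <- tcrossprod(Q[r, hc, drop = FALSE], K[r, hc, drop = FALSE]) * sc
      if (!all(mb)) S[, !mb] <- -Inf
      Ab <- softmax_rows(S)
      A[[(b - 1L) * h + hh]] <- Ab
      H[r, hc] <- Ab %*% V[r, hc, drop = FALSE]
    }
  }
  y <- linear_fw(H, p$Wo, p$bo)
  list(y = y,
       cache = list(x = x, Q = Q, K = K, V = V, H = H, A = A,
                    B = B, L = L, mask = mask, sc = sc, p = p))
}

mha_bw <- function(cache, dy) {
  p <- cache$p
  d <- p$d; h <- p$heads; dh <- d %/% h
  B <- cache$B; L <- cache$L
  dWo <- crossprod(cache$H, dy)
  dbo <- colSums(dy)
  dH <- tcrossprod(dy, p$Wo)
  dQ <- matrix(0, B * L, d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    r <- ((b - 1L) * L + 1L):(b * L)
    for (hh in seq_len(h)) {
      hc <- ((hh - 1L) * dh + 1L):(hh * dh)
      Ab <- cache$A[[(b - 1L) * h + hh]]
      dHb <- dH[r, hc, drop = FALSE]
      dA <- tcrossprod(dHb, cache$V[r, hc, drop = FALSE])
      dV[r, hc] <- crossprod(Ab, dHb)
      dS <- Ab * (dA - rowSums(dA * Ab))  # masked entries have A == 0
      dQ[r, hc] <- (dS %*% cache$K[r, hc, drop = FALSE]) * cache$sc
      dK[r, hc] <- crossprod(dS, cache$Q[r, hc, drop = FALSE]) * cache$sc
    }
  }
  x <- cache$x
  dx <- tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  list(dx = dx,
       grads = list(Wq = crossprod(x, dQ), bq = colSums(dQ),
                    Wk = crossprod(x, dK), bk = colSums(dK),
                    Wv = crossprod(x, dV), bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

#' Scaled dot-product multi-head self-attention
#'
#' Per head, attention weights are `softmax(q k^T / denom)` with masked
#' (pad) keys excluded from the softmax; the per-head mixtures of value
#' vectors are concatenated and output-projected.
#'
#' @param z L x d input matrix.
#' @param params An [attention_params()].
#' @param mask Optional logical vector of length L; `FALSE` marks pad
#'   positions excluded as keys.  All-masked input is an error.
#' @param keep_weights If `TRUE`, attach the L x L x heads attention-weight
#'   array as attribute `"weights"`.
#' @return L x d output matrix.
#' @export
multi_head_attention <- function(z, params, mask = NULL, keep_weights = FALSE) {
  z <- as.matrix(z)
  L <- nrow(z)
  fw <- mha_fw(z, params, B = 1L, L = L, mask = mask)
  out <- fw$y
  if (keep_weights) {
    attr(out, "weights") <- array(unlist(fw$cache$A), c(L, L, params$heads))
  }
  out
}

#' Residual transformer block parameters
#'
#' One attention + feed-forward block with its two layer norms, in pre-norm
#' or post-norm wiring.
#'
#' @inheritParams attention_params
#' @param d_ff Hidden width of the position-wise feed-forward sub-layer.
#' @param norm_style `"pre"` or `"post"`.
#' @param eps Layer-norm epsilon.
#' @return A `block_params` list.
#' @export
block_params <- function(d, heads, d_ff = 4L * d,
                         norm_style = c("pre", "post"),
                         init = c("glorot", "zero_residual"),
                         scale = c("per_head", "model_dim"), eps = 1e-5,
                         residual_scale = 1) {
  norm_style <- match.arg(norm_style)
  init <- match.arg(init)
  structure(list(
    norm_style = norm_style,
    ln1 = list(gamma = rep(1, d), beta = rep(0, d)),
    attn = attention_params(d, heads, init = init, scale = match.arg(scale),
                            residual_scale = residual_scale),
    ln2 = list(gamma = rep(1, d), beta = rep(0, d)),
    W1 = glorot(d, d_ff), b1 = rep(0, d_ff),
    W2 = if (init == "zero_residual") matrix(0, d_ff, d) else
      residual_scale * glorot(d_ff, d),
    b2 = rep(0, d),
    d = as.integer(d), d_ff = as.integer(d_ff), eps = eps
  ), class = "block_params")
}

ffn_fw <- function(x, p) {
  h1 <- linear_fw(x, p$W1, p$b1)
  r <- relu_fw(h1)
  list(y = linear_fw(r$y, p$W2, p$b2), cache = list(x = x, r = r, p = p))
}

ffn_bw <- function(cache, dy) {
  p <- cache$p
  dW2 <- crossprod(cache$r$y, dy)
  db2 <- colSums(dy)
  dr <- tcrossprod(dy, p$W2)
  dh1 <- relu_bw(cache$r$cache, dr)
  list(dx = tcrossprod(dh1, p$W1),
       dW1 = crossprod(cache$x, dh1), db1 = colSums(dh1),
       dW2 = dW2, db2 = db2)
}

block_fw <- function(x, p, B, L, mask = NULL, training = FALSE, dropout = 0) {
  if (p$norm_style == "pre") {
    n1 <- ln_fw(x, p$ln1$gamma, p$ln1$beta, p$eps)
    at <- mha_fw(n1$y, p$attn, B, L, mask)
    ad <- dropout_fw(at$y, dropout, training)
    mid <- x + ad$y
    n2 <- ln_fw(mid, p$ln2$gamma, p$ln2$beta, p$eps)
    ff <- ffn_fw(n2$y, p)
    fd <- dropout_fw(ff$y, dropout, training)
    y <- mid + fd$y
    list(y = y, cache = list(style = "pre", n1 = n1, at = at, ad = ad,
                             n2 = n2, ff = ff, fd = fd))
  } else {
    at <- mha_fw(x, p$attn, B, L, mask)
    ad <- dropout_fw(at$y, dropout, training)
    s1 <- x + ad$y
    n1 <- ln_fw(s1, p$ln1$gamma, p$ln1$beta, p$eps)
    ff <- ffn_fw(n1$y, p)
    fd <- dropout_fw(ff$y, dropout, training)
    s2 <- n1$y + fd$y
    n2 <- ln_fw(s2, p$ln2$gamma, p$ln2$beta, p$eps)
    list(y = n2$y, cache = list(style = "post", at = at, ad = ad, n1 = n1,
                                ff = ff, fd = fd, n2 = n2))
  }
}

block_bw <- function(p, cache, dy) {
  g <- list()
  if (cache$style == "pre") {
    dmid <- dy
    dff_out <- dropout_bw(cache$fd$cache, dy)
    fb <- ffn_bw(cache$ff$cache, dff_out)
    g$W1 <- fb$dW1; g$b1 <- fb$db1; g$W2 <- fb$dW2; g$b2 <- fb$db2
    l2 <- ln_bw(cache$n2$cache, fb$dx)
    g$ln2 <- list(gamma = l2$dgamma, beta = l2$dbeta)
    dmid <- dmid + l2$dx
    dat_out <- dropout_bw(cache$ad$cache, dmid)
    ab <- mha_bw(cache$at$cache, dat_out)
    g$attn <- ab$grads
    l1 <- ln_bw(cache$n1$cache, ab$dx)
    g$ln1 <- list(gamma = l1$dgamma, beta = l1$dbeta)
    dx <- dmid + l1$dx
  } else {
    l2 <- ln_bw(cache$n2$cache, dy)
    g$ln2 <- list(gamma = l2$dgamma, beta = l2$dbeta)
    ds2 <- l2$dx
    dff_out <- dropout_bw(cache$fd$cache, ds2)
    fb <- ffn_bw(cache$ff$cache, dff_out)
    g$W1 <- fb$dW1; g$b1 <- fb$db1; g$W2 <- fb$dW2; g$b2 <- fb$db2
    dn1 <- ds2 + fb$dx
    l1 <- ln_bw(cache$n1$cache, dn1)
    g$ln1 <- list(gamma = l1$dgamma, beta = l1$dbeta)
    ds1 <- l1$dx
    dat_out <- dropout_bw(cache$ad$cache, ds1)
    ab <- mha_bw(cache$at$cache, dat_out)
    g$attn <- ab$grads
    dx <- ds1 + ab$dx
  }
  list(dx = dx, grads = g)
}

#' Apply one pre-norm residual block
#'
#' Computes `p = z + MHA(LN(z))` followed by `z_s = p + FFN(LN(p))`.  With
#' zero-initialized output projections this is exactly the identity map.
#'
#' @param z L x d input matrix.
#' @param params A [block_params()] with `norm_style = "pre"`.
#' @param mask Optional logical pad mask of length L.
#' @return L x d output matrix.
#' @export
prenorm_block <- function(z, params, mask = NULL) {
  stopifnot(params$norm_style == "pre")
  block_fw(as.matrix(z), params, B = 1L, L = nrow(z), mask = mask)$y
}

#' Apply one post-norm residual block
#'
#' Computes `y = x + F(x)` then `LN(y)` for the attention sub-layer and
#' again for the feed-forward sub-layer.  Unlike the pre-norm wiring this is
#' not the identity at zero init (the final layer norm always acts).
#'
#' @param x_l L x d input matrix.
#' @param params A [block_params()] with `norm_style = "post"`.
#' @param mask Optional logical pad mask of length L.
#' @return L x d output matrix.
#' @export
postnorm_block <- function(x_l, params, mask = NULL) {
  stopifnot(params$norm_style == "post")
  block_fw(as.matrix(x_l), params, B = 1L, L = nrow(x_l), mask = mask)$y
}

#' Full transformer stack parameters
#'
#' @inheritParams block_params
#' @param blocks Number of residual blocks.
#' @param final_norm Apply a last layer norm after the final block
#'   (defaults to `TRUE` for pre-norm stacks, the standard wiring, and
#'   `FALSE` for post-norm).
#' @param seed Optional seed; when given, initialization is drawn under it
#'   without disturbing the caller's RNG.
#' @return A `transformer_params` list with elements `blocks` (list of
#'   [block_params()]) and `final_ln` (or `NULL`).
#' @export
transformer_params <- function(d, heads, blocks = 2L, d_ff = 4L * d,
                               norm_style = c("pre", "post"),
                               init = c("glorot", "zero_residual"),
                               scale = c("per_head", "model_dim"),
                               final_norm = NULL, eps = 1e-5, seed = NULL,
                               residual_scale = 1) {
  norm_style <- match.arg(norm_style)
  init <- match.arg(init)
  scale <- match.arg(scale)
  final_norm <- final_norm %||% (norm_style == "pre")
  build <- function() {
    list(
      blocks = lapply(seq_len(blocks), function(i)
        block_params(d, heads, d_ff, norm_style, init, scale, eps,
                     residual_scale = residual_scale)),
      final_ln = if (final_norm) list(gamma = rep(1, d), beta = rep(0, d)),
      d = as.integer(d), norm_style = norm_style, eps = eps
    )
  }
  p <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(p, class = "transformer_params")
}

stack_fw <- function(x, stack, B, L, mask = NULL, training = FALSE, dropout = 0) {
  caches <- vector("list", length(stack$blocks))
  for (i in seq_along(stack$blocks)) {
    st <- block_fw(x, stack$blocks[[i]], B, L, mask, training, dropout)
    x <- st$y
    caches[[i]] <- st$cache
  }
  fl <- NULL
  if (!is.null(stack$final_ln)) {
    fl <- ln_fw(x, stack$final_ln$gamma, stack$final_ln$beta, stack$eps)
    x <- fl$y
  }
  list(y = x, caches = caches, final_cache = fl)
}

# Returns the input gradient, per-block parameter gradients, the gradient at
# each block input (for the depth profiler) and the gradient at the last
# block's output (the profiler's d(loss)/d(x_L)).
stack_bw <- function(stack, fwd, dy) {
  if (!is.null(fwd$final_cache)) {
    fb <- ln_bw(fwd$final_cache$cache, dy)
    final_grads <- list(gamma = fb$dgamma, beta = fb$dbeta)
    dy <- fb$dx
  } else {
    final_grads <- NULL
  }
  d_out_last <- dy
  n <- length(stack$blocks)
  block_grads <- vector("list", n)
  input_grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    bb <- block_bw(stack$blocks[[i]], fwd$caches[[i]], dy)
    block_grads[[i]] <- bb$grads
    dy <- bb$dx
    input_grads[[i]] <- dy
  }
  list(dx = dy, block_grads = block_grads, final_grads = final_grads,
       input_grads = input_grads, d_out_last = d_out_last)
}

#' Classifier head parameters
#'
#' Mask-aware mean pooling over positions followed by an affine map to two
#' logits and a softmax.
#'
#' @param d Model width.
#' @param init `"glorot"`, or `"zero"` to start from uninformative logits
#'   (the head then learns before it back-propagates noise into the stack).
#' @return A `classifier_head` list (`Wc` d x 2, `bc`).
#' @export
classifier_head <- function(d, init = c("glorot", "zero")) {
  init <- match.arg(init)
  W <- if (init == "zero") matrix(0, d, 2L) else glorot(d, 2L)
  structure(list(Wc = W, bc = rep(0, 2L)), class = "classifier_head")
}

pool_fw <- function(x, B, L, mask, n_real) {
  xm <- x * mask
  pooled <- rowsum(xm, group = rep(seq_len(B), each = L), reorder = FALSE)
  pooled / n_real
}

head_fw <- function(x, head, B, L, mask, n_real, labels = NULL) {
  if (any(n_real == 0L)) stopf("Classification contract violated: a sample has no unmasked positions.")
  pooled <- pool_fw(x, B, L, mask, n_real)
  logits <- linear_fw(pooled, head$Wc, head$bc)
  probs <- softmax_rows(logits)
  list(pooled = pooled, logits = logits, probs = probs)
}

head_bw <- function(fw, head, dlogits, B, L, mask, n_real) {
  dWc <- crossprod(fw$pooled, dlogits)
  dbc <- colSums(dlogits)
  dpooled <- tcrossprod(dlogits, head$Wc)
  dx <- dpooled[rep(seq_len(B), each = L), , drop = FALSE] *
    (mask / rep(n_real, each = L))
  list(dx = dx, dWc = dWc, dbc = dbc)
}

#' Classify one position-indexed feature matrix
#'
#' @param z_s L x d feature matrix (e.g. a transformer stack output).
#' @param head A [classifier_head()].
#' @param mask Optional logical pad mask of length L (pads are excluded
#'   from pooling).
#' @return Named probability pair `c(p_unbound, p_bound)` summing to 1.
#' @export
classify <- function(z_s, head, mask = NULL) {
  z_s <- as.matrix(z_s)
  L <- nrow(z_s)
  mask <- if (is.null(mask)) rep(TRUE, L) else as.logical(mask)
  fw <- head_fw(z_s, head, B = 1L, L = L, mask = mask, n_real = sum(mask))
  c(p_unbound = fw$probs[1L, 1L], p_bound = fw$probs[1L, 2L])
}

#' Gradient depth profile of a transformer stack
#'
#' Backpropagates a classification loss through the stack on one input and
#' records the gradient norm of the loss with respect to every block input,
#' plus the norm at the last block's output.  Under pre-norm wiring with
#' zero-initialized residual projections, the gradient reaching every block
#' input is exactly the gradient at the stack output (the identity term of
#' the residual path); under post-norm wiring each layer norm reshapes it.
#'
#' @param stack A [transformer_params()].
#' @param z L x d input matrix.
#' @param mask Optional logical pad mask of length L.
#' @param label Class label (0/1) used for the probing cross-entropy loss.
#' @param seed Seed for the probe head's initialization.
#' @return Tibble (class `rbp_grad_profile`) with columns `layer`,
#'   `grad_norm`, `norm_style`, `finite`; the raw per-block gradient
#'   matrices are attached as attribute `"grads"` (last element = gradient
#'   at the last block's output).
#' @export
gradient_depth_profile <- function(stack, z, mask = NULL, label = 1L, seed = 7L) {
  stopifnot(inherits(stack, "transformer_params"))
  z <- as.matrix(z)
  L <- nrow(z)
  d <- ncol(z)
  mask <- if (is.null(mask)) rep(TRUE, L) else as.logical(mask)
  head <- with_seed(seed, classifier_head(d))
  fwd <- stack_fw(z, stack, B = 1L, L = L, mask = mask, training = FALSE)
  hf <- head_fw(fwd$y, head, 1L, L, mask, sum(mask))
  dlogits <- softmax_ce_bw(hf$probs, as.integer(label))
  hb <- head_bw(hf, head, dlogits, 1L, L, mask, sum(mask))
  bwd <- stack_bw(stack, fwd, hb$dx)
  norms <- vapply(bwd$input_grads, function(g) sqrt(sum(g * g)), numeric(1))
  out_norm <- sqrt(sum(bwd$d_out_last^2))
  res <- tibble(
    layer = c(paste0("block_", seq_along(norms)), "output"),
    depth = c(seq_along(norms), length(norms) + 1L),
    grad_norm = c(norms, out_norm),
    norm_style = stack$norm_style,
    finite = is.finite(c(norms, out_norm))
  )
  attr(res, "grads") <- c(bwd$input_grads, list(bwd$d_out_last))
  class(res) <- c("rbp_grad_profile", class(res))
  res
}
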
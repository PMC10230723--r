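# Numeric core: layer primitives with hand-derived forward/backward passes.
#
# Batches of position-indexed features are stored as dense (B*L) x C
# matrices, sample-major (rows (b-1)*L + 1 ... b*L hold sample b).  Every
# *_fw() returns the output plus the cache its matching *_bw() needs; *_bw()
# consumes the upstream gradient and returns the input gradient and the
# parameter gradients.  Everything is deterministic given R's RNG state.

linear_fw <- function(x, W, b) {
  add_rowvec(x %*% W, b)
}

# ---- layer normalization (per row over channels, population variance) ----

ln_fw <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- add_rowvec(mul_rowvec(xhat, gamma), beta)
  list(y = y, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

ln_bw <- function(cache, dy) {
  xhat <- cache$xhat
  dxhat <- mul_rowvec(dy, cache$gamma)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx,
       dgamma = colSums(dy * xhat),
       dbeta = colSums(dy))
}

#' Layer normalization
#'
#' Standardizes each position's channel vector to zero mean and unit
#' (population) variance, then applies the learned gain and bias:
#' \eqn{\hat z = ((z - \mu)/\sqrt{\sigma^2 + \epsilon}) \odot \gamma + \beta}.
#'
#' @param z Numeric vector (one position) or matrix (positions x channels;
#'   normalized independently per row).
#' @param gamma,beta Gain and bias vectors of length M (the channel count).
#' @param eps Variance floor guarding constant inputs.
#' @return Same shape as `z`.
#' @export
#' @examples
#' layer_norm(c(1, 2, 3))
layer_norm <- function(z, gamma = NULL, beta = NULL, eps = 1e-5) {
  vec <- is.null(dim(z))
  x <- if (vec) matrix(z, 1L) else as.matrix(z)
  M <- ncol(x)
  gamma <- gamma %||% rep(1, M)
  beta <- beta %||% rep(0, M)
  y <- ln_fw(x, gamma, beta, eps)$y
  if (vec) drop(y) else y
}

# ---- batch normalization (per channel over batch x positions) ----

bn_fw <- function(x, p, state, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    xc <- sub_rowvec(x, mu)
    v <- colMeans(xc * xc)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- sub_rowvec(x, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- mul_rowvec(xc, inv)
  y <- add_rowvec(mul_rowvec(xhat, p$gamma), p$beta)
  list(y = y, state = state,
       cache = list(xhat = xhat, inv = inv, gamma = p$gamma, training = training))
}

bn_bw <- function(cache, dy) {
  xhat <- cache$xhat
  dxhat <- mul_rowvec(dy, cache$gamma)
  if (cache$training) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- mul_rowvec(sub_rowvec(dxhat, m1) - mul_rowvec(xhat, m2), cache$inv)
  } else {
    dx <- mul_rowvec(dxhat, cache$inv)
  }
  list(dx = dx, dgamma = colSums(dy * xhat), dbeta = colSums(dy))
}

# ---- ReLU / dropout ----

relu_fw <- function(x) {
  pos <- x > 0
  list(y = x * pos, cache = pos)
}

relu_bw <- function(cache, dy) dy * cache

dropout_fw <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  keep <- (matrix(runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(y = x * keep, cache = keep)
}

dropout_bw <- function(cache, dy) {
  if (is.null(cache)) dy else dy * cache
}

# ---- 1-D convolution over positions ("same" padding) ----

# Row-gather index for a (B, L) batch and odd kernel size: column j holds,
# for every row, the source row at position offset j - (K+1)/2, or 0 where
# the offset leaves the sample (treated as a zero row).
conv_index <- function(B, L, kernel) {
  stopifnot(kernel %% 2L == 1L)
  half <- (kernel - 1L) %/% 2L
  t_idx <- rep(seq_len(L), B)
  base <- rep((seq_len(B) - 1L) * L, each = L)
  idx <- matrix(0L, B * L, kernel)
  for (j in seq_len(kernel)) {
    off <- j - half - 1L
    src <- t_idx + off
    ok <- src >= 1L & src <= L
    idx[ok, j] <- base[ok] + src[ok]
  }
  idx
}

im2col <- function(x, idx) {
  xp <- rbind(0, x)  # row 1 = zero row for out-of-range taps
  cols <- lapply(seq_len(ncol(idx)), function(j) xp[idx[, j] + 1L, , drop = FALSE])
  do.call(cbind, cols)
}

conv1d_fw <- function(x, W, b, idx) {
  xc <- im2col(x, idx)
  list(y = linear_fw(xc, W, b), cache = list(xc = xc, idx = idx, W = W,
                                             c_in = ncol(x)))
}

conv1d_bw <- function(cache, dy) {
  dW <- crossprod(cache$xc, dy)
  db <- colSums(dy)
  dxc <- tcrossprod(dy, cache$W)
  c_in <- cache$c_in
  idx <- cache$idx
  dx <- matrix(0, nrow(dy), c_in)
  for (j in seq_len(ncol(idx))) {
    cols <- ((j - 1L) * c_in + 1L):(j * c_in)
    ok <- idx[, j] > 0L
    # within one tap the source rows are distinct, so plain indexed add works
    dx[idx[ok, j], ] <- dx[idx[ok, j], , drop = FALSE] + dxc[ok, cols, drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- softmax cross-entropy over 2 classes ----

softmax_ce_fw <- function(logits, labels) {
  probs <- softmax_rows(logits)
  n <- nrow(logits)
  picked <- probs[cbind(seq_len(n), labels + 1L)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  list(loss = loss, probs = probs)
}

softmax_ce_bw <- function(probs, labels) {
  n <- nrow(probs)
  d <- probs
  d[cbind(seq_len(n), labels + 1L)] <- d[cbind(seq_len(n), labels + 1L)] - 1
  d / n
}
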
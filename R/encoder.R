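# Feature-unification encoder: each descriptor branch is a same-padding 1-D
# convolution over positions, batch normalization per channel, and ReLU;
# the branches are then concatenated channel-wise and projected to the
# model width by a 1x1 convolution.  Branch order in the concatenation is
# fixed: knfp, seq2vec, kmer_context.  Disabled branches contribute zero
# matrices so the downstream network never changes shape during descriptor
# ablations.

#' Encoder branch parameters
#'
#' @param c_in Input channel count of the descriptor.
#' @param c_out Unified channel count C_u shared by all branches.
#' @param kernel Odd convolution kernel size.
#' @param init `"glorot"` (active RNG stream) or `"identity"`, which sets a
#'   kernel-size-1 convolution to the identity map (requires
#'   `c_in == c_out`); useful for testing.
#' @return An `encoder_branch` list of parameters plus batch-norm running
#'   state.
#' @export
encoder_branch_params <- function(c_in, c_out = 128L, kernel = 3L,
                                  init = c("glorot", "identity")) {
  init <- match.arg(init)
  if (kernel %% 2L != 1L) stopf("Convolution kernel size must be odd, got %d.", kernel)
  if (init == "identity") {
    stopifnot(c_in == c_out, kernel == 1L)
    W <- diag(c_out)
  } else {
    W <- glorot(kernel * c_in, c_out)
  }
  structure(list(
    W = W, b = rep(0, c_out),
    bn = list(gamma = rep(1, c_out), beta = rep(0, c_out)),
    bn_state = list(mean = rep(0, c_out), var = rep(1, c_out)),
    c_in = as.integer(c_in), c_out = as.integer(c_out),
    kernel = as.integer(kernel)
  ), class = "encoder_branch")
}

branch_fw <- function(x, p, B, L, training = FALSE, momentum = 0.1, eps = 1e-5,
                      idx = NULL) {
  if (ncol(x) != p$c_in) {
    stopf("Descriptor has %d channels but the branch expects %d.", ncol(x), p$c_in)
  }
  idx <- idx %||% conv_index(B, L, p$kernel)
  cv <- conv1d_fw(x, p$W, p$b, idx)
  bn <- bn_fw(cv$y, p$bn, p$bn_state, training, momentum, eps)
  rl <- relu_fw(bn$y)
  list(y = rl$y, state = bn$state,
       cache = list(cv = cv$cache, bn = bn$cache, rl = rl$cache))
}

branch_bw <- function(cache, dy) {
  drl <- relu_bw(cache$rl, dy)
  bb <- bn_bw(cache$bn, drl)
  cb <- conv1d_bw(cache$cv, bb$dx)
  list(dx = cb$dx,
       grads = list(W = cb$dW, b = cb$db,
                    bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

#' Encode one descriptor matrix through its branch
#'
#' Same-length 1-D convolution over positions, batch normalization over the
#' batch-by-position axis per channel, then ReLU (output is non-negative).
#' In inference mode (`training = FALSE`) batch norm uses the stored running
#' statistics and the branch is a deterministic function of its input.
#'
#' @param m L x c_in descriptor matrix (a single sequence).
#' @param branch An [encoder_branch_params()].
#' @param training Use batch statistics (`TRUE`) or running statistics.
#' @return L x c_out non-negative matrix.
#' @export
encode_descriptor <- function(m, branch, training = FALSE) {
  m <- as.matrix(m)
  branch_fw(m, branch, B = 1L, L = nrow(m), training = training)$y
}

#' Fusion parameters (1x1 convolution over concatenated branches)
#'
#' @param c_u Per-branch channel count.
#' @param d Model width of the fused feature.
#' @param n_branches Number of descriptor branches (fixed layout of 3).
#' @return A `fusion_params` list.
#' @export
fusion_params <- function(c_u = 128L, d = 128L, n_branches = 3L) {
  structure(list(W = glorot(n_branches * c_u, d), b = rep(0, d),
                 c_u = as.integer(c_u), d = as.integer(d),
                 n_branches = as.integer(n_branches)),
            class = "fusion_params")
}

fuse_fw <- function(branches, p) {
  xc <- do.call(cbind, branches)
  list(y = linear_fw(xc, p$W, p$b), cache = list(xc = xc, p = p))
}

fuse_bw <- function(cache, dy) {
  p <- cache$p
  dxc <- tcrossprod(dy, p$W)
  splits <- split.default(seq_len(ncol(cache$xc)),
                          rep(seq_len(p$n_branches), each = p$c_u))
  list(dbranches = lapply(splits, function(cols) dxc[, cols, drop = FALSE]),
       dW = crossprod(cache$xc, dy), db = colSums(dy))
}

#' Fuse encoded descriptor branches into the unified feature
#'
#' Channel-wise concatenation in the order knfp, seq2vec, kmer_context,
#' followed by a 1x1 convolution to the model width.  Disabled branches are
#' passed as zero matrices so the output shape is independent of which
#' descriptors are enabled.
#'
#' @param branches List of three L x c_u matrices.
#' @param params A [fusion_params()].
#' @return L x d fused feature matrix.
#' @export
fuse_branches <- function(branches, params) {
  L <- unique(vapply(branches, nrow, integer(1)))
  if (length(L) != 1L) stopf("All branches must share the position count; got %s.",
                             paste(vapply(branches, nrow, integer(1)), collapse = ", "))
  fuse_fw(lapply(branches, as.matrix), params)$y
}
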
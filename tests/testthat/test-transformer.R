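test_that("layer norm matches the scalar oracle and handles edge cases", {
  expect_equal(layer_norm(c(1, 2, 3), eps = 0),
               c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-10)
  # constant input maps to beta
  expect_equal(layer_norm(rep(4, 6), beta = rep(0.5, 6)), rep(0.5, 6))
  # gain zero returns beta regardless of input
  expect_equal(layer_norm(rnorm(5), gamma = rep(0, 5), beta = 1:5), 1:5,
               tolerance = 1e-12)
  withr::with_seed(1, {
    for (rep in 1:50) {
      M <- sample(2:24, 1)
      z <- rnorm(M, sd = runif(1, 0.1, 5))
      g <- rnorm(M); b <- rnorm(M)
      expect_equal(layer_norm(z, g, b, eps = 0), oracle_layer_norm(z, g, b),
                   tolerance = 1e-10)
    }
  })
})

test_that("normalized output has zero mean and unit variance per position", {
  withr::with_seed(2, {
    z <- matrix(rnorm(8 * 12, mean = 3, sd = 2), 8)
    y <- layer_norm(z, eps = 1e-12)
    expect_equal(rowMeans(y), rep(0, 8), tolerance = 1e-10)
    expect_equal(apply(y, 1, function(r) mean(r^2)), rep(1, 8),
                 tolerance = 1e-6)
  })
})

test_that("attention reduces to the value vector for L = 1 and is uniform for identical rows", {
  p <- withr::with_seed(3, attention_params(d = 8, heads = 2))
  z1 <- matrix(rnorm(8), 1)
  out <- multi_head_attention(z1, p, keep_weights = TRUE)
  expect_equal(drop(attr(out, "weights")), rep(1, 2))  # one key per head
  # pre-projection head output equals that position's value vector
  v <- z1 %*% p$Wv + matrix(p$bv, 1, 8, byrow = TRUE)
  expect_equal(out, v %*% p$Wo + matrix(p$bo, 1, 8, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)

  zid <- matrix(rep(rnorm(8), each = 5), 5)
  outu <- multi_head_attention(zid, p, keep_weights = TRUE)
  w <- attr(outu, "weights")
  expect_equal(as.vector(w), rep(1 / 5, length(w)), tolerance = 1e-12)
  expect_equal(outu, outu[rep(1, 5), ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("attention equals the explicit double-loop oracle across shapes, masks and scalings", {
  withr::with_seed(4, {
    for (trial in 1:50) {
      h <- sample(c(1L, 2L, 4L), 1)
      d <- h * sample(1:4, 1)
      L <- sample(2:8, 1)
      sc <- sample(c("per_head", "model_dim"), 1)
      p <- attention_params(d, h, scale = sc)
      z <- matrix(rnorm(L * d), L)
      mask <- rep(TRUE, L)
      if (L > 2 && trial %% 3 == 0) mask[sample(L, 1)] <- FALSE
      got <- multi_head_attention(z, p, mask = mask, keep_weights = TRUE)
      expect_equal(got, oracle_attention(z, p, mask), tolerance = 1e-6,
                   ignore_attr = TRUE)
      # weight rows sum to 1 and lie in the convex hull of unmasked keys
      w <- attr(got, "weights")
      expect_equal(apply(w, c(1, 3), sum), matrix(1, L, h), tolerance = 1e-12)
      expect_true(all(w >= 0))
    }
  })
  # all-masked input violates the contract
  p <- withr::with_seed(5, attention_params(4, 2))
  expect_error(multi_head_attention(matrix(rnorm(8), 2), p,
                                    mask = c(FALSE, FALSE)), "masked")
})

test_that("attention is permutation-equivariant (no internal positional encoding)", {
  withr::with_seed(6, {
    p <- attention_params(d = 8, heads = 2)
    L <- 7
    z <- matrix(rnorm(L * 8), L)
    perm <- sample(L)
    out <- multi_head_attention(z, p)
    out_perm <- multi_head_attention(z[perm, ], p)
    expect_equal(out_perm, out[perm, ], tolerance = 1e-10)
  })
})

test_that("pre-norm blocks are the identity at zero init, post-norm blocks are not", {
  d <- 12
  z <- withr::with_seed(7, matrix(rnorm(5 * d), 5))
  pre <- withr::with_seed(8, block_params(d, 2, 24, "pre", init = "zero_residual"))
  expect_identical(prenorm_block(z, pre), z)
  # 12 stacked zero-initialized blocks remain the identity
  st <- transformer_params(d, 2, blocks = 12, d_ff = 24, norm_style = "pre",
                           init = "zero_residual", final_norm = FALSE, seed = 9)
  out <- z
  for (b in st$blocks) out <- prenorm_block(out, b)
  expect_identical(out, z)

  post <- withr::with_seed(8, block_params(d, 2, 24, "post", init = "zero_residual"))
  y <- postnorm_block(z, post)
  expect_false(isTRUE(all.equal(y, z)))
  # zero sub-layers reduce the post-norm block to LN of LN
  ln1 <- layer_norm(z, post$ln1$gamma, post$ln1$beta, post$eps)
  expect_equal(y, layer_norm(ln1, post$ln2$gamma, post$ln2$beta, post$eps),
               tolerance = 1e-12)
  # LN fixed point: already-normalized input passes through (eps -> 0)
  post0 <- post; post0$eps <- 0
  zn <- t(apply(z, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2))))
  expect_equal(postnorm_block(zn, post0), zn, tolerance = 1e-8)
})

test_that("generic blocks match an independent step-by-step recomputation", {
  d <- 10
  z <- withr::with_seed(10, matrix(rnorm(6 * d), 6))
  for (style in c("pre", "post")) {
    p <- withr::with_seed(11, block_params(d, 2, 20, style))
    got <- if (style == "pre") prenorm_block(z, p) else postnorm_block(z, p)
    ln <- function(x, lp) t(apply(x, 1, oracle_layer_norm,
                                  gamma = lp$gamma, beta = lp$beta, eps = p$eps))
    ffn <- function(x) {
      h <- pmax(x %*% p$W1 + matrix(p$b1, nrow(x), length(p$b1), byrow = TRUE), 0)
      h %*% p$W2 + matrix(p$b2, nrow(x), d, byrow = TRUE)
    }
    want <- if (style == "pre") {
      mid <- z + oracle_attention(ln(z, p$ln1), p$attn)
      mid + ffn(ln(mid, p$ln2))
    } else {
      s1 <- ln(z + oracle_attention(z, p$attn), p$ln1)
      ln(s1 + ffn(s1), p$ln2)
    }
    expect_equal(got, want, tolerance = 1e-6)
    expect_false(isTRUE(all.equal(got, z)))
  }
})

test_that("softmax head produces valid, mask-aware probabilities", {
  d <- 6
  head <- withr::with_seed(12, classifier_head(d))
  z <- withr::with_seed(13, matrix(rnorm(9 * d), 9))
  pr <- classify(z, head)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_true(all(pr > 0 & pr < 1))

  # zero pooled vector with zero weights -> (0.5, 0.5)
  head0 <- list(Wc = matrix(0, d, 2), bc = c(0, 0))
  expect_equal(unname(classify(z, head0)), c(0.5, 0.5))
  # large logit gap saturates
  headt <- list(Wc = matrix(0, d, 2), bc = c(50, -50))
  expect_equal(unname(classify(z, headt)), c(1, 0), tolerance = 1e-12)
  # hand-set pooled vector against a direct exp/normalize computation
  mask <- c(rep(TRUE, 4), rep(FALSE, 5))
  pooled <- colMeans(z[1:4, ])
  logits <- drop(pooled %*% head$Wc) + head$bc
  expect_equal(unname(classify(z, head, mask = mask)),
               unname(exp(logits) / sum(exp(logits))), tolerance = 1e-12)
  expect_error(classify(z, head, mask = rep(FALSE, 9)), "no unmasked")
})

test_that("full stack forward matches an independent step-by-step oracle on a toy input", {
  d <- 8
  st <- transformer_params(d, 2, blocks = 2, d_ff = 16, norm_style = "pre",
                           seed = 14)
  z <- withr::with_seed(15, matrix(rnorm(3 * d), 3))
  got <- rbpattn:::stack_fw(z, st, B = 1L, L = 3L,
                            mask = rep(TRUE, 3))$y
  x <- z
  for (p in st$blocks) {
    ln <- function(v, lp) t(apply(v, 1, oracle_layer_norm, gamma = lp$gamma,
                                  beta = lp$beta, eps = p$eps))
    mid <- x + oracle_attention(ln(x, p$ln1), p$attn)
    h <- pmax(ln(mid, p$ln2) %*% p$W1 +
                matrix(p$b1, 3, length(p$b1), byrow = TRUE), 0)
    x <- mid + h %*% p$W2 + matrix(p$b2, 3, d, byrow = TRUE)
  }
  x <- t(apply(x, 1, oracle_layer_norm, gamma = st$final_ln$gamma,
               beta = st$final_ln$beta, eps = st$eps))
  expect_equal(got, x, tolerance = 1e-6)
})
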
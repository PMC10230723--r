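test_that("k-mer frequency vectors match the dictionary-count oracle and worked examples", {
  expect_equal(unname(kmer_frequency_vector("AAAA", 1)), c(1, 0, 0, 0))
  v <- kmer_frequency_vector("AGCU", 1)
  expect_equal(unname(v), rep(0.25, 4))
  v2 <- kmer_frequency_vector("AGCU", 2)
  expect_equal(unname(v2[c("AG", "GC", "CU")]), rep(1 / 3, 3))
  expect_equal(sum(v2 > 0), 3L)
  expect_length(kmer_frequency_vector("ACGUACG", 3), 64L)

  withr::with_seed(1, {
    for (rep in 1:25) {
      s <- random_rna(sample(3:60, 1))
      for (k in 1:3) {
        got <- kmer_frequency_vector(s, k)
        expect_equal(unname(got), unname(oracle_kmer_freq(s, k)))
        if (nchar(s) >= k) expect_equal(sum(got), 1, tolerance = 1e-12)
      }
    }
  })
})

test_that("short and masked sequences yield documented degenerate vectors", {
  expect_equal(sum(kmer_frequency_vector("AC", 3)), 0)
  # an N voids the windows that touch it but keeps the denominator
  v <- kmer_frequency_vector("ACNGU", 1)
  expect_equal(sum(v), 4 / 5)
})

test_that("per-position KNFP layout follows the global-frequency-at-start rule", {
  m <- knfp_encode("AAAA")
  expect_equal(m[, "k1"], rep(1, 4))
  expect_equal(m[, "k2"], c(1, 1, 1, 0))
  expect_equal(m[, "k3"], c(1, 1, 0, 0))

  m2 <- knfp_encode("AGCU")
  expect_equal(m2[, "k1"], rep(0.25, 4))

  # values are frequencies, so they live in [0, 1]
  withr::with_seed(2, {
    s <- random_rna(40)
    m3 <- knfp_encode(s)
    expect_true(all(m3 >= 0 & m3 <= 1))
    # palindrome check on the k = 1 channel: reversal permutes rows only
    pal <- "ACGUUGCA"
    expect_equal(sort(knfp_encode(pal)[, "k1"]),
                 sort(knfp_encode(paste(rev(strsplit(pal, "")[[1]]), collapse = ""))[, "k1"]))
  })

  # all-pad input gives a zero matrix
  expect_equal(knfp_encode("NNNN", n_real = 0), matrix(0, 4, 3),
               ignore_attr = TRUE)

  # pooled global variant has 4 + 16 + 64 components summing to 3
  g <- knfp_global("ACGUACGUAC")
  expect_length(g, 84L)
  expect_equal(sum(g), 3)
})

test_that("window tokenization obeys the count formula and boundaries", {
  expect_length(tokenize_window(random_rna(12), 10), 3L)
  expect_equal(tokenize_window("ACGUACGUAC", 10), "ACGUACGUAC")
  expect_length(tokenize_window(random_rna(9), 10), 0L)
  withr::with_seed(3, {
    for (rep in 1:20) {
      n <- sample(1:40, 1)
      w <- sample(1:12, 1)
      st <- sample(1:3, 1)
      words <- tokenize_window(random_rna(n), w, st)
      expect_length(words, max(0, floor((n - w) / st) + 1))
    }
  })
})

test_that("3-mer tokenization produces overlapping stride-1 tokens", {
  expect_equal(kmer_tokenize("AGCUA"), c("AGC", "GCU", "CUA"))
  expect_length(kmer_tokenize("ACG"), 1L)
  expect_length(kmer_tokenize("AC"), 0L)
})

test_that("context embedding covers all 3-mers, zero-fills trailing rows, and round-trips via TSV", {
  tab <- withr::with_seed(4, context_embedding_table(dim = 8))
  expect_equal(nrow(tab$embedding), 65L)  # 64 trinucleotides + UNK
  toks <- kmer_tokenize(strrep("ACGU", 26))  # 104-nt sequence, 102 tokens
  m <- context_embed(toks[1:99], tab, length = 101)
  expect_equal(dim(m), c(101L, 8L))
  expect_true(all(m[100:101, ] == 0))
  # identical tokens produce identical populated rows
  m2 <- context_embed(rep("ACG", 5), tab)
  expect_true(all(m2 == m2[rep(1, 5), ]))
  # unknown token goes to UNK row
  mu <- context_embed("ANG", tab)
  expect_equal(drop(mu), unname(tab$embedding[65, ]))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_embedding_table(tab, tsv)
  frozen <- read_embedding_table(tsv)
  expect_false(frozen$learnable)
  expect_equal(frozen$embedding, tab$embedding, ignore_attr = TRUE,
               tolerance = 1e-12)
  # frozen table and learnable table with identical values agree at forward
  expect_equal(context_embed(toks[1:10], frozen),
               context_embed(toks[1:10], tab), tolerance = 1e-12)
})

test_that("context token ids mark UNK and incomplete windows", {
  tab <- context_embedding_table(dim = 2)
  ids <- context_token_ids("ACGNA", tab)
  expect_equal(ids[4:5], c(0L, 0L))       # no complete 3-mer fits
  expect_equal(ids[2:3], c(65L, 65L))     # windows touching N -> UNK
  expect_gt(ids[1], 0L)
})
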
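test_that("FASTA reading maps DNA to RNA, concatenates wrapped bodies, and preserves order", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", ">s2 extra header words", "ACG", "UAC"), fa)
  out <- read_fasta(fa, "map_dna")
  expect_equal(out$id, c("s1", "s2"))
  expect_equal(out$seq, c("ACGU", "ACGUAC"))
  expect_equal(nchar(out$seq[2]), 6L)

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0L)
})

test_that("alphabet policies behave as documented", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGTN"), fa)
  expect_equal(read_fasta(fa, "mask_unknown")$seq, "ACGUN")
  expect_error(read_fasta(fa, "map_dna"), "outside \\{A,C,G,U\\}")
  expect_error(read_fasta(fa, "strict"), "outside \\{A,C,G,U\\}")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGU", ">b", ">c", "AC"), bad)
  expect_error(read_fasta(bad), "empty sequence body")
})

test_that("FASTA round-trip reproduces ids and residues exactly", {
  d <- simulate_binding_sites(n = 30, length = 73, seed = 3)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(d, fa)
  back <- read_fasta(fa)
  expect_identical(back$id, d$id)
  expect_identical(back$seq, d$seq)
})

test_that("length standardization pads, flags, truncates centrally and can tile", {
  d <- tibble::tibble(id = c("a", "b", "c"),
                      seq = c("ACGUACG", "ACGUA", "ACGUACGUA"))
  out <- standardize_length(d, 7, "pad_N_as_zero")
  expect_equal(nchar(out$seq), rep(7L, 3))
  expect_equal(out$seq[1], "ACGUACG")      # identity at target length
  expect_equal(out$n_real[1], 7L)
  expect_equal(out$seq[2], "ACGUANN")      # right-padded, 2 flagged positions
  expect_equal(out$n_real[2], 5L)
  expect_equal(out$seq[3], "CGUACGU")      # center 7 of 9: offset floor(2/2)=1
  expect_equal(out$n_real[3], 7L)

  # center-truncation offset for n=9, L=5 keeps residues 3..7
  out5 <- standardize_length(d[3, ], 5)
  expect_equal(out5$seq, "GUACG")

  rep_out <- standardize_length(d[2, ], 7, "pad_repeat")
  expect_equal(rep_out$seq, "ACGUAAC")     # cyclic tiling, no flagged pads
  expect_equal(rep_out$n_real, 7L)

  expect_error(standardize_length(d, 7, "error"), "length")
})

test_that("stratified split preserves per-label counts, partitions, and is seed-deterministic", {
  d <- simulate_binding_sites(n = 100, length = 20, seed = 5)
  parts <- split_dataset(d, 0.8, seed = 11)
  expect_equal(nrow(parts$train), 80L)
  expect_equal(nrow(parts$test), 20L)
  expect_equal(sum(parts$train$label == 1), 40L)
  expect_equal(sum(parts$test$label == 1), 10L)
  # partition: disjoint and exhaustive
  expect_length(intersect(parts$train$id, parts$test$id), 0L)
  expect_setequal(c(parts$train$id, parts$test$id), d$id)

  again <- split_dataset(d, 0.8, seed = 11)
  expect_identical(parts$train$id, again$train$id)
  expect_identical(attr(parts, "split_hash"), attr(again, "split_hash"))
  other <- split_dataset(d, 0.8, seed = 12)
  expect_false(identical(parts$train$id, other$train$id))

  # 50/50 on a 10-record set keeps balance
  small <- d[c(1:5, 51:55), ]
  half <- split_dataset(small, 0.5, seed = 1)
  expect_equal(sum(half$train$label == 1), sum(half$train$label == 0))

  single <- d[c(1, 51:60), ]
  expect_error(split_dataset(single, 0.8), "at least 2 records")
})

test_that("label TSV reading validates binary labels", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlabel", "a\t1", "b\t0"), tsv)
  lab <- read_labels(tsv)
  expect_equal(lab$label, c(1L, 0L))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlabel", "a\t2"), bad)
  expect_error(read_labels(bad), "0 or 1")
})
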
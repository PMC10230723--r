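test_that("learning-rate schedule decays tenfold every two epochs from 3e-3", {
  cfg <- rbp_config()
  expect_equal(lr_at_epoch(0, cfg), 3e-3)
  expect_equal(lr_at_epoch(1, cfg), 3e-3)
  expect_equal(lr_at_epoch(2, cfg), 3e-4)
  expect_equal(lr_at_epoch(5, cfg), 3e-5)
  e <- 0:12
  expect_true(all(diff(lr_at_epoch(e, cfg)) <= 0))  # non-increasing
})

test_that("metrics match the all-pairs Mann-Whitney oracle and worked examples", {
  m <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))
  expect_equal(m$auc, 0.75)

  perfect <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$acc, 1)

  ties <- compute_metrics(c(1, 0, 1, 0), rep(0.3, 4))
  expect_equal(ties$auc, 0.5)

  withr::with_seed(1, {
    for (rep in 1:100) {
      n <- sample(4:40, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), sample(1:3, 1))  # force some ties
      got <- compute_metrics(labels, scores)
      expect_equal(got$auc, oracle_auc(labels, scores), tolerance = 1e-12)
    }
  })

  # independent library cross-check of the rank-statistic AUC
  if (requireNamespace("pROC", quietly = TRUE)) {
    withr::with_seed(3, {
      labels <- c(0, 1, sample(0:1, 40, replace = TRUE))
      scores <- round(rnorm(42), 1)
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                            direction = "<")))
      expect_equal(compute_metrics(labels, scores)$auc, ref,
                   tolerance = 1e-12)
    })
  }

  # AUC is invariant to monotone transforms of the scores
  withr::with_seed(2, {
    labels <- sample(0:1, 30, replace = TRUE, prob = c(0.4, 0.6))
    scores <- rnorm(30)
    expect_equal(compute_metrics(labels, scores)$auc,
                 compute_metrics(labels, plogis(3 * scores))$auc)
  })

  # degenerate cases
  expect_warning(one <- compute_metrics(c(1, 1), c(0.2, 0.6)), "one class")
  expect_true(is.na(one$auc))
  expect_equal(one$acc, 0.5)
  none <- compute_metrics(c(1, 0), c(0.1, 0.2), threshold = 0.5)
  expect_false(none$precision_defined)
  expect_equal(none$precision, 0)
})

test_that("training is seed-reproducible and zero epochs returns the initialized model", {
  d <- tiny_dataset(n = 40)
  cfg <- tiny_config(epochs = 2)
  f1 <- rbp_fit(d, cfg, seed = 3)
  f2 <- rbp_fit(d, cfg, seed = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$test_scores$score, f2$test_scores$score)
  f3 <- rbp_fit(d, cfg, seed = 4)
  expect_false(identical(f1$history$loss, f3$history$loss))

  f0 <- rbp_fit(d, tiny_config(epochs = 0), seed = 3)
  expect_equal(nrow(f0$history), 0L)
  expect_true(all(is.finite(f0$metrics$auc)))
})

test_that("a short fit learns an easy planted motif above chance", {
  d <- tiny_dataset(n = 120, length = 30)
  fit <- rbp_fit(d, tiny_config(epochs = 6), seed = 5)
  expect_gt(fit$metrics$auc, 0.7)
  # trained model scores its training positives above its negatives
  preds <- predict(fit, d)
  expect_gt(mean(preds$score[d$label == 1]), mean(preds$score[d$label == 0]))
  # tidy/glance accessors
  expect_equal(nrow(tidy(fit)), 6L)
  expect_named(glance(fit),
               c("acc", "auc", "precision", "recall", "n_train", "n_test",
                 "seed", "split_hash"))
})

test_that("training aborts with a diagnostic on single-class data", {
  d <- tiny_dataset(n = 30)
  d$label <- 1L
  expect_error(rbp_fit(d, tiny_config(), seed = 1), "at least 2 records")
})

test_that("descriptor ablation produces matched-seed 4-row tables; norm ablation 2 rows", {
  d <- tiny_dataset(n = 48)
  cfg <- tiny_config(epochs = 1, seq2vec_epochs = 2)
  tab_n <- ablate(d, "norm_style", cfg, seed = 6)
  expect_equal(nrow(tab_n), 2L)
  expect_setequal(tab_n$config, c("pre", "post"))
  expect_equal(length(unique(tab_n$split_hash)), 1L)

  tab_d <- ablate(d, "descriptor", cfg, seed = 6)
  expect_equal(nrow(tab_d), 4L)
  expect_setequal(tab_d$config, c("knfp", "seq2vec", "kmer_context", "fused"))
  expect_equal(length(unique(tab_d$split_hash)), 1L)
  expect_equal(length(unique(tab_d$seed)), 1L)
  expect_type(attr(tab_d, "report"), "character")
})

test_that("stability runs report per-run metrics and dispersion", {
  d <- tiny_dataset(n = 48)
  cfg <- tiny_config(epochs = 1, seq2vec_epochs = 2)
  tab <- stability_run(d, cfg, n_runs = 2, seed = 9)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$seed, c(9L, 10L))
  s <- attr(tab, "summary")
  expect_true(is.finite(s$sd_auc))
  # degenerate control: same seed twice gives zero dispersion
  same <- dplyr::bind_rows(tab[1, ], tab[1, ])
  expect_equal(stats::sd(same$auc), 0)
})

test_that("gradient depth profile separates pre-norm and post-norm wirings", {
  d <- 12
  z <- withr::with_seed(20, matrix(rnorm(6 * d), 6))
  pre <- transformer_params(d, 2, blocks = 12, d_ff = 24, norm_style = "pre",
                            init = "zero_residual", final_norm = FALSE, seed = 21)
  gp <- gradient_depth_profile(pre, z)
  expect_equal(nrow(gp), 13L)
  expect_true(all(gp$finite))
  g <- attr(gp, "grads")
  # the identity term: every block input receives exactly the output gradient
  for (i in 1:12) expect_identical(g[[i]], g[[13]])

  post <- transformer_params(d, 2, blocks = 12, d_ff = 24, norm_style = "post",
                             init = "zero_residual", seed = 21)
  gpp <- gradient_depth_profile(post, z)
  gpost <- attr(gpp, "grads")
  expect_false(identical(gpost[[1]], gpost[[13]]))
  expect_gt(max(gpp$grad_norm) - min(gpp$grad_norm), 0)

  # randomly initialized pre-norm stack still keeps a non-vanishing
  # first-block gradient (additive identity path)
  prer <- transformer_params(d, 2, blocks = 8, d_ff = 24, norm_style = "pre",
                             seed = 22)
  gpr <- gradient_depth_profile(prer, z)
  expect_gt(gpr$grad_norm[1], 0)
  expect_true(all(gpr$finite))
})

test_that("checkpoints round-trip and detect config mismatches", {
  d <- tiny_dataset(n = 40)
  fit <- rbp_fit(d, tiny_config(epochs = 1), seed = 2)
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, ck)
  back <- load_checkpoint(ck)
  expect_identical(glance(back), glance(fit))
  expect_identical(predict(back, d[1:4, c("id", "seq")]),
                   predict(fit, d[1:4, c("id", "seq")]))
  # tamper with the sidecar -> version error
  side <- jsonlite::read_json(paste0(ck, ".json"))
  side$config_hash <- "corrupt"
  jsonlite::write_json(side, paste0(ck, ".json"), auto_unbox = TRUE)
  expect_error(load_checkpoint(ck), "mismatch")
})
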
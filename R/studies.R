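# Study drivers: repeated-run stability, matched-seed ablations, and their
# soft comparison reports.  Comparative outcomes (pre vs post dispersion,
# fused vs single-descriptor AUC) are stochastic claims, so they are
# reported, never hard-asserted.

#' Repeated-run stability study
#'
#' Retrains the model `n_runs` times with seeds `seed + 0 ... seed +
#' n_runs - 1` (fresh stratified splits each run) and reports the per-run
#' metrics and their dispersion, optionally for several residual-wiring
#' styles on the same seed series.
#'
#' @param data Labeled sequence tibble.
#' @param config A [rbp_config()].
#' @param n_runs Number of repeats (>= 2).
#' @param seed Base seed.
#' @param norm_styles Character vector of wiring styles to run (subset of
#'   `c("pre", "post")`); both styles share the seed series so the
#'   comparison is paired.
#' @param verbose Print per-run progress.
#' @return Tibble (class `rbp_stability`) with one row per run: `norm_style`,
#'   `run`, `seed`, `split_hash`, `acc`, `auc`, `precision`, `recall`.  A
#'   per-style dispersion summary tibble is attached as attribute
#'   `"summary"`.
#' @export
stability_run <- function(data, config = rbp_config(), n_runs = 10L,
                          seed = 42L, norm_styles = config$norm_style,
                          verbose = FALSE) {
  stopifnot(n_runs >= 2L)
  rows <- list()
  for (style in norm_styles) {
    cfg <- config
    cfg$norm_style <- style
    for (r in seq_len(n_runs) - 1L) {
      fit <- rbp_fit(data, cfg, seed = seed + r)
      rows[[length(rows) + 1L]] <- mutate(
        fit$metrics[, c("acc", "auc", "precision", "recall")],
        norm_style = style, run = r + 1L, seed = seed + r,
        split_hash = fit$split_hash, .before = 1L)
      if (verbose) message(sprintf("%s-norm run %d/%d: AUC %.3f",
                                   style, r + 1L, n_runs, fit$metrics$auc))
    }
  }
  out <- bind_rows(rows)
  summary <- out %>%
    group_by(.data$norm_style) %>%
    summarise(n_runs = n(), mean_auc = mean(.data$auc),
              sd_auc = stats::sd(.data$auc), .groups = "drop")
  attr(out, "summary") <- summary
  class(out) <- c("rbp_stability", class(out))
  out
}

#' Matched-seed ablation study
#'
#' Trains configurations differing only along one axis, with identical
#' seeds and therefore identical splits, and reports one metrics row per
#' configuration.
#'
#' * `axis = "norm_style"`: 2 rows, pre-norm vs post-norm residual wiring.
#' * `axis = "descriptor"`: 4 rows, each single descriptor vs all three
#'   fused.
#'
#' A qualitative comparison (which configuration led, and by how much) is
#' attached as attribute `"report"` — it is descriptive output, not an
#' assertion, because single-run orderings are stochastic.
#'
#' @param data Labeled sequence tibble.
#' @param axis `"norm_style"` or `"descriptor"`.
#' @param config Base [rbp_config()].
#' @param seed Seed shared by every configuration (split and training).
#' @param verbose Print per-configuration progress.
#' @return Tibble (class `rbp_ablation`) with columns `config`, `acc`,
#'   `auc`, `precision`, `recall`, `seed`, `split_hash`.
#' @export
ablate <- function(data, axis = c("norm_style", "descriptor"),
                   config = rbp_config(), seed = 42L, verbose = FALSE) {
  axis <- match.arg(axis)
  variants <- if (axis == "norm_style") {
    list(pre = list(norm_style = "pre"), post = list(norm_style = "post"))
  } else {
    list(knfp = list(descriptors = "knfp"),
         seq2vec = list(descriptors = "seq2vec"),
         kmer_context = list(descriptors = "kmer_context"),
         fused = list(descriptors = c("knfp", "seq2vec", "kmer_context")))
  }
  rows <- imap(variants, function(mods, name) {
    cfg <- config
    for (k in names(mods)) cfg[[k]] <- mods[[k]]
    fit <- rbp_fit(data, cfg, seed = seed)
    if (verbose) message(sprintf("%s: AUC %.3f", name, fit$metrics$auc))
    mutate(fit$metrics[, c("acc", "auc", "precision", "recall")],
           config = name, .before = 1L) %>%
      mutate(seed = as.integer(seed), split_hash = fit$split_hash)
  })
  out <- bind_rows(rows)
  report <- if (axis == "norm_style") {
    sprintf("pre-norm AUC %.3f vs post-norm AUC %.3f (pre - post = %+.3f) on matched seed %d",
            out$auc[out$config == "pre"], out$auc[out$config == "post"],
            out$auc[out$config == "pre"] - out$auc[out$config == "post"], seed)
  } else {
    single <- out$auc[out$config != "fused"]
    sprintf("fused AUC %.3f vs best single-descriptor AUC %.3f (%s) on matched seed %d",
            out$auc[out$config == "fused"], max(single),
            out$config[out$config != "fused"][which.max(single)], seed)
  }
  attr(out, "axis") <- axis
  attr(out, "report") <- report
  class(out) <- c("rbp_ablation", class(out))
  out
}
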
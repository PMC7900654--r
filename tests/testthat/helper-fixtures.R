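# Shared fixtures. The trained benchmark model is expensive, so it is built
# once per test run and cached for every test that interprets it.

.fixture_env <- new.env(parent = emptyenv())

# Structure-necessary synthetic benchmark + a compact model trained on it.
trained_benchmark <- function() {
  if (is.null(.fixture_env$fit)) {
    bench <- make_benchmark(synthetic_spec(seed = 21), seed = 21)
    cfg <- train_config(base_lr = 0.003, max_epochs = 20, patience = 20,
                        batch_size = 16L, warmup_steps = 20L, seed = 1)
    model <- build_model(model_config(channels = 8L, fc_hidden = 32L),
                         seed = 1)
    .fixture_env$fit <- train_model(model, bench$split, cfg)
    .fixture_env$bench <- bench
  }
  list(fit = .fixture_env$fit, bench = .fixture_env$bench)
}

# Miniature configuration for oracle-level checks (fast forward/backward).
mini_config <- function(L = 21L, dropout = c(0, 0), ...) {
  model_config(L = L, D = 5L, conv_kernel = c(3L, 3L), channels = 4L,
               se_reduction = 2L, res2_kernel = c(3L, 3L), res1_kernel = 3L,
               fc_hidden = 16L, dropout = dropout, ...)
}

# Wrap a scores vector as a one-transcript reactivity profile list.
prof1 <- function(id, scores, condition = "A", replicate = "rep1") {
  stats::setNames(list(list(transcript_id = id, condition = condition,
                            replicate = replicate, scores = scores)), id)
}

# Multi-transcript profile list from a named list of score vectors.
prof_list <- function(scores_by_tx, condition = "A", replicate = "rep1") {
  out <- lapply(names(scores_by_tx), function(id)
    list(transcript_id = id, condition = condition, replicate = replicate,
         scores = scores_by_tx[[id]]))
  stats::setNames(out, names(scores_by_tx))
}

# A tiny deterministic transcriptome with full reactivity coverage.
toy_transcriptome <- function(n = 4, len = 150, seed = 5) {
  withr::with_seed(seed, {
    tx <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
            collapse = ""), character(1))
    names(tx) <- paste0("tx", seq_len(n))
    tx
  })
}
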
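test_that("generation is deterministic and respects a zero planting rate", {
  spec0 <- synthetic_spec(n_transcripts = 10, length = 300, plant_rate = 0,
                          seed = 4)
  d1 <- generate_synthetic(spec0)
  d2 <- generate_synthetic(spec0)
  expect_identical(d1, d2)
  expect_equal(nrow(d1$peaks), 0)
  expect_equal(nrow(d1$truth$planted), 0)
})

test_that("every emitted peak contains the planted consensus", {
  spec <- synthetic_spec(n_transcripts = 30, length = 400, seed = 9)
  d <- generate_synthetic(spec)
  expect_gt(nrow(d$peaks), 0)
  for (i in seq_len(nrow(d$peaks))) {
    tx <- d$peaks$transcript_id[i]
    sub <- substr(d$transcripts[[tx]], d$peaks$start[i] + 1, d$peaks$end[i])
    expect_true(grepl(spec$motif, sub, fixed = TRUE))
  }
  # and peaks only on transcripts whose planted site is bound
  tr <- d$truth$planted
  expect_true(all(d$peaks$transcript_id %in%
                    tr$transcript_id[tr$bound]))
  # chance occurrences are scrubbed: motif count equals planted count
  hits <- vapply(names(d$transcripts), function(tx)
    length(gregexpr(spec$motif, d$transcripts[[tx]],
                    fixed = TRUE)[[1]][gregexpr(spec$motif,
                                                d$transcripts[[tx]],
                                                fixed = TRUE)[[1]] > 0]),
    numeric(1))
  expect_equal(sum(hits), nrow(tr))
})

test_that("two-state reactivity separates by more than 0.4 at defaults", {
  spec <- synthetic_spec(n_transcripts = 10, length = 400, plant_rate = 0,
                         seed = 2)
  d <- generate_synthetic(spec)
  # reconstruct states from the merged profile against the truth threshold
  all_scores <- unlist(lapply(d$merged$A, function(p) p$scores))
  hi <- all_scores[all_scores >= 0.4]
  lo <- all_scores[all_scores < 0.4]
  expect_gt(mean(hi, na.rm = TRUE) - mean(lo, na.rm = TRUE), 0.4)
})

test_that("written files re-parse to the in-memory dataset", {
  d <- withr::local_tempdir()
  spec <- synthetic_spec(n_transcripts = 6, length = 300, n_svs = 2,
                         n_var_in_svs = 1, n_var_outside = 1,
                         n_var_same = 1, seed = 6)
  res <- generate_synthetic(spec, out_dir = d)
  tx <- read_transcriptome(file.path(d, "transcripts.fa"))
  expect_identical(tx, res$transcripts)
  rr <- read_reactivity(file.path(d, "shape_A_rep1.tsv"), "A", "rep1")
  expect_equal(lapply(rr, `[[`, "scores"),
               lapply(res$reactivity$A$rep1, `[[`, "scores"),
               tolerance = 1e-9)
  pk <- read_peaks(file.path(d, "peaks.bed"))
  expect_equal(pk$signal, res$peaks[order(res$peaks$transcript_id,
                                          res$peaks$start), ]$signal,
               tolerance = 1e-9)
  vv <- read_variants(file.path(d, "variants.tsv"))
  expect_equal(nrow(vv), nrow(res$variants))
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$planted$bound, res$truth$planted$bound)
})

test_that("planted structure flips carry window L1 above the effect floor", {
  spec <- synthetic_spec(n_transcripts = 10, length = 300, plant_rate = 0,
                         n_svs = 10, seed = 3)
  d <- generate_synthetic(spec)
  for (i in seq_len(nrow(d$truth$svs))) {
    s <- d$truth$svs[i, ]
    a <- d$merged$A[[s$transcript_id]]$scores[(s$start + 1):s$end]
    b <- d$merged$B[[s$transcript_id]]$scores[(s$start + 1):s$end]
    expect_gt(mean(abs(a - b), na.rm = TRUE),
              (spec$unpaired_mean - spec$paired_mean) - 0.35)
  }
})

test_that("structure-necessary labels defeat a sequence-only oracle", {
  bench <- make_benchmark(synthetic_spec(n_transcripts = 60, length = 400,
                                         seed = 15), seed = 15)
  # oracle classifier: does the window contain the consensus?
  has_motif <- function(part) {
    vapply(seq_along(part$y), function(i) {
      dec <- decode_site(part$X[i, , ])
      as.numeric(grepl("GCAUG", dec$sequence, fixed = TRUE))
    }, numeric(1))
  }
  y <- c(bench$split$train$y, bench$split$validation$y)
  s <- c(has_motif(bench$split$train), has_motif(bench$split$validation))
  expect_lt(compute_auroc(y, s), 0.9)   # sequence alone cannot separate
  expect_gt(compute_auroc(y, s), 0.6)   # but carries real signal

  # with no structure requirement the same oracle is nearly perfect
  bench2 <- make_benchmark(synthetic_spec(n_transcripts = 40, length = 400,
                                          structure_context = "none",
                                          seed = 16), seed = 16)
  y2 <- c(bench2$split$train$y, bench2$split$validation$y)
  s2 <- c(has_motif(bench2$split$train), has_motif(bench2$split$validation))
  expect_gt(compute_auroc(y2, s2), 0.95)
})

test_that("negative windows never intersect positive sites", {
  bench <- make_benchmark(synthetic_spec(n_transcripts = 40, length = 400,
                                         seed = 18), seed = 18)
  pos <- bench$positives
  neg <- bench$negatives
  for (i in seq_len(nrow(neg))) {
    p <- pos[pos$transcript_id == neg$transcript_id[i], , drop = FALSE]
    if (nrow(p) == 0) next
    expect_false(any(pmax(neg$start[i], p$start) < pmin(neg$end[i], p$end)))
  }
})
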
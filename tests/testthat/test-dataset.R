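test_that("replicate normalization min-max rescales with degenerate rule", {
  pk <- function(sig) data.frame(transcript_id = "tx1",
                                 start = seq(0, by = 200,
                                             length.out = length(sig)),
                                 end = seq(50, by = 200,
                                           length.out = length(sig)),
                                 signal = sig, replicate = "rep1",
                                 stringsAsFactors = FALSE)
  expect_equal(normalize_replicate(pk(c(2, 4, 6)))$signal, c(0, 0.5, 1))
  expect_equal(normalize_replicate(pk(5))$signal, 1.0)
  expect_equal(normalize_replicate(pk(c(0, 10)))$signal, c(0, 1))
})

test_that("overlap merging uses >= 1 nt under half-open coordinates", {
  pk <- data.frame(transcript_id = "tx1", start = c(10L, 25L),
                   end = c(30L, 40L), signal = c(0.5, 0.7),
                   replicate = "rep1", stringsAsFactors = FALSE)
  m <- merge_replicates(pk)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end, m$signal), c(10, 40, 1.2))

  # book-ended intervals share no nucleotide: not merged
  pk2 <- data.frame(transcript_id = "tx1", start = c(10L, 20L),
                    end = c(20L, 30L), signal = c(1, 1),
                    replicate = "rep1", stringsAsFactors = FALSE)
  expect_equal(nrow(merge_replicates(pk2)), 2)
})

test_that("chained overlaps merge to their transitive closure", {
  pk <- data.frame(transcript_id = "tx1", start = c(0L, 9L, 14L),
                   end = c(10L, 15L, 20L), signal = c(1, 2, 3),
                   replicate = "rep1", stringsAsFactors = FALSE)
  # oracle: brute-force pairwise merging to fixpoint
  iv <- pk[, c("start", "end", "signal")]
  repeat {
    done <- TRUE
    for (i in seq_len(nrow(iv) - 1)) {
      for (j in seq(i + 1, nrow(iv))) {
        if (max(iv$start[i], iv$start[j]) < min(iv$end[i], iv$end[j])) {
          iv$start[i] <- min(iv$start[i], iv$start[j])
          iv$end[i] <- max(iv$end[i], iv$end[j])
          iv$signal[i] <- iv$signal[i] + iv$signal[j]
          iv <- iv[-j, ]
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) break
  }
  m <- merge_replicates(pk)
  expect_equal(nrow(m), nrow(iv))
  expect_equal(c(m$start, m$end, m$signal),
               c(iv$start, iv$end, iv$signal))
})

test_that("length unification is center-preserving with stated tie-breaks", {
  expect_equal(unify_length(100, 201, 1000), c(100L, 201L))   # already 101
  expect_equal(unify_length(100, 203, 1000), c(101L, 202L))   # trim 103 -> 101
  expect_equal(unify_length(100, 199, 1000), c(99L, 200L))    # expand 99 -> 101
  # clamped at the 5' end, shortfall carried right
  expect_equal(unify_length(0, 11, 1000), c(0L, 101L))
  # transcript shorter than the site: whole transcript
  expect_equal(unify_length(10, 20, 80), c(0L, 80L))
})

test_that("positive selection filters coverage then keeps top signals", {
  tx <- toy_transcriptome(n = 10, len = 400)
  full <- prof_list(lapply(tx, function(s) rep(0.5, nchar(s))))
  none <- prof_list(lapply(tx, function(s) rep(NA_real_, nchar(s))))
  set.seed(2)
  pk <- data.frame(transcript_id = names(tx), start = 100L, end = 150L,
                   signal = runif(10), stringsAsFactors = FALSE)
  sel <- select_positives(pk, tx, full, k = 5)
  # sort oracle: exactly the 5 largest distinct signals
  expect_equal(sel$signal, sort(pk$signal, decreasing = TRUE)[1:5])
  expect_true(all(sel$end - sel$start == 101))
  expect_error(select_positives(pk, tx, none, k = 5), "coverage")
  # a single peak with coverage 35/101 < 0.40 leaves nothing
  part <- full
  part$tx1$scores[] <- NA
  part$tx1$scores[1:35] <- 0.5
  expect_error(select_positives(pk[pk$transcript_id == "tx1", ], tx, part,
                                k = 5, min_coverage = 0.40), "coverage")
})

test_that("negative sampling is seeded, covered and avoids positives", {
  tx <- toy_transcriptome(n = 6, len = 300)
  rea <- prof_list(lapply(tx, function(s) rep(0.5, nchar(s))))
  pos <- data.frame(transcript_id = "tx1", start = 50L, end = 151L,
                    stringsAsFactors = FALSE)
  n1 <- sample_negatives(tx, rea, pos, n = 50, seed = 9)
  n2 <- sample_negatives(tx, rea, pos, n = 50, seed = 9)
  expect_identical(n1, n2)
  expect_true(all(n1$end - n1$start == 101))
  on_tx1 <- n1[n1$transcript_id == "tx1", ]
  expect_false(any(pmax(on_tx1$start, 50L) < pmin(on_tx1$end, 151L)))
  expect_error(sample_negatives(tx, rea, pos, n = 1e6, seed = 1),
               "eligible")
})

test_that("encoding is one-hot + reactivity with -1 for missing, invertible", {
  m <- encode_site("ACGU", c(0.2, NA, 1, 0), L = 4)
  expect_equal(m[, 1:4], diag(4), ignore_attr = TRUE)
  expect_equal(m[, 5], c(0.2, -1, 1, 0))
  mN <- encode_site("ANGU", rep(0.5, 4), L = 4)
  expect_equal(unname(mN[2, 1:4]), rep(0, 4))
  expect_error(encode_site("ACXU", rep(0.5, 4), L = 4), "invalid letter")

  dec <- decode_site(m)
  expect_identical(dec$sequence, "ACGU")
  expect_equal(dec$scores, c(0.2, NA, 1, 0))

  # shorter-than-L input is N-padded symmetrically
  mp <- encode_site("ACG", c(0.1, 0.2, 0.3), L = 7)
  expect_equal(unname(mp[1:2, 5]), c(-1, -1))
  expect_identical(decode_site(mp)$sequence, "NNACGNN")
})

test_that("dataset assembly enforces the class ratio and stratified split", {
  tx <- toy_transcriptome(n = 20, len = 400)
  rea <- prof_list(lapply(tx, function(s) rep(0.5, nchar(s))))
  pos <- data.frame(transcript_id = names(tx)[1:10], start = 100L,
                    end = 201L, stringsAsFactors = FALSE)
  neg <- data.frame(transcript_id = rep(names(tx), 3),
                    start = rep(c(0L, 150L, 250L), each = 20),
                    stringsAsFactors = FALSE)
  neg$end <- neg$start + 101L
  sp <- assemble_dataset(pos, neg, tx, rea, neg_ratio = 2, seed = 4)
  y_all <- c(sp$train$y, sp$validation$y)
  expect_equal(sum(y_all == 1), 10)
  expect_equal(sum(y_all == 0), 20)
  # stratified 4:1 per class, remainder to train
  expect_equal(sum(sp$validation$y == 1), 2)
  expect_equal(sum(sp$validation$y == 0), 4)
  expect_length(intersect(sp$train$ids, sp$validation$ids), 0)
  sp2 <- assemble_dataset(pos, neg, tx, rea, neg_ratio = 2, seed = 4)
  expect_identical(sp$train$ids, sp2$train$ids)
  expect_error(assemble_dataset(pos, neg[1:5, ], tx, rea, neg_ratio = 2,
                                seed = 1), "negatives")
})
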
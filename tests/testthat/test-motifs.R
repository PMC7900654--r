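test_that("structure binarization respects the >= 0.233 boundary", {
  expect_equal(binarize_structure(c(0.233, 0.0, 0.232, 1, NA)),
               c("U", "P", "P", "U", "."))
})

test_that("a degenerate window corpus yields one near-one-hot motif", {
  windows <- replicate(8, list(seq = "GCAUGA", struct = "UUUUUU"),
                       simplify = FALSE)
  mots <- build_motifs(windows)
  expect_length(mots, 1)
  m <- mots[[1]]
  expect_equal(m$weight, 1.0)
  expect_true(all(abs(colSums(m$seq_pwm) - 1) < 1e-9))
  expect_true(all(apply(m$seq_pwm, 2, max) > 0.95))
  expect_identical(m$consensus, "GCAUGA")
  expect_true(all(m$struct_pwm["U", ] > 0.95))
})

test_that("one-mismatch k-mers join one cluster; distant ones do not", {
  w <- list(list(seq = "GCAUGA", struct = "UUUUUU"),
            list(seq = "GCAUGC", struct = "UUUUUU"))
  expect_length(build_motifs(w), 1)
  w2 <- list(list(seq = "GCAUGA", struct = "UUUUUU"),
             list(seq = "AAAAAA", struct = "PPPPPP"))
  expect_length(build_motifs(w2, merge_cor = 0.99), 2)
})

test_that("greedy clustering replays the exhaustive pairwise oracle", {
  kmers <- c("GCAUGA", "GCAUGC", "GCAUGG", "AAAAAA", "AAAAAC", "UUUUUU",
             "UUUAUU", "CCCCCC", "GGGGGG", "ACGUAC")
  struct <- rep("UUUUUU", length(kmers))
  windows <- lapply(seq_along(kmers), function(i)
    list(seq = kmers[i], struct = struct[i]))
  mots <- build_motifs(windows, merge_cor = 1.01)  # disable PWM merging
  # oracle: replay greedy rule with explicit distances at offsets -1,0,1
  ham_at <- function(a, b, off) {
    ia <- seq_len(6); ib <- ia + off; ok <- ib >= 1 & ib <= 6
    sum(strsplit(a, "")[[1]][ok] != strsplit(b, "")[[1]][ib[ok]])
  }
  compatible <- function(a, b) {
    any(vapply(c(0, -1, 1), function(off) ham_at(a, b, off) <= 1,
               logical(1)))
  }
  # equal counts: seeding order is lexicographic
  remaining <- sort(kmers)
  oracle_clusters <- list()
  while (length(remaining) > 0) {
    seed <- remaining[1]
    members <- remaining[vapply(remaining, function(x)
      x == seed || compatible(seed, x), logical(1))]
    oracle_clusters[[length(oracle_clusters) + 1]] <- members
    remaining <- setdiff(remaining, members)
  }
  expect_length(mots, length(oracle_clusters))
  sizes <- sort(vapply(oracle_clusters, length, integer(1)))
  supports <- sort(vapply(mots, function(m) as.integer(m$support),
                          integer(1)))
  expect_equal(supports, sizes)
})

test_that("weight enrichment agrees with the hypergeometric tail oracle", {
  # toy table: 30 member k-mers of 100 vs a 10% baseline
  p_pkg <- fisher_p_greater(30, 70, 10, 90)
  # oracle: explicit tail enumeration with choose()
  p_oracle <- sum(vapply(30:40, function(x)
    choose(100, x) * choose(100, 40 - x), numeric(1))) / choose(200, 40)
  expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  expect_equal(p_pkg,
               fisher.test(matrix(c(30, 70, 10, 90), 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               tolerance = 1e-9)

  windows <- c(replicate(60, list(seq = "GCAUGA", struct = "UUUUUU"),
                         simplify = FALSE),
               replicate(10, list(seq = "AAACCC", struct = "PPPPPP"),
                         simplify = FALSE))
  mots <- enrich_motifs(build_motifs(windows))
  expect_lt(mots[[1]]$enrichment_p, 0.05)
  expect_true(mots[[1]]$significant)
})

test_that("match scores equal the direct log10 product", {
  uni <- list(seq_pwm = matrix(0.25, 4, 6,
                               dimnames = list(c("A", "C", "G", "U"), NULL)),
              struct_pwm = matrix(0.5, 2, 6,
                                  dimnames = list(c("U", "P"), NULL)))
  expect_equal(score_match(uni, "ACGUAC", "UUPPUP"), 6 * log10(0.125),
               tolerance = 1e-12)
  expect_equal(round(score_match(uni, "GGGGGG", "PPPPPP"), 4), -5.4185)

  # one-hot motif scores 0 on its own consensus without pseudocount
  oh <- list(seq_pwm = matrix(0, 4, 6,
                              dimnames = list(c("A", "C", "G", "U"), NULL)),
             struct_pwm = matrix(0, 2, 6,
                                 dimnames = list(c("U", "P"), NULL)))
  cons <- c("G", "C", "A", "U", "G", "A")
  for (j in 1:6) oh$seq_pwm[cons[j], j] <- 1
  oh$struct_pwm["U", ] <- 1
  expect_equal(score_match(oh, "GCAUGA", "UUUUUU"), 0)

  # random PWM vs brute-force double loop
  set.seed(9)
  sq <- matrix(runif(24), 4, 6, dimnames = list(c("A", "C", "G", "U"), NULL))
  sq <- sweep(sq, 2, colSums(sq), "/")
  st <- matrix(runif(12), 2, 6, dimnames = list(c("U", "P"), NULL))
  st <- sweep(st, 2, colSums(st), "/")
  m <- list(seq_pwm = sq, struct_pwm = st)
  kmer <- "ACGUGU"; skmer <- "UPUPUP"
  acc <- 0
  for (j in 1:6) {
    acc <- acc + log10(sq[substr(kmer, j, j), j]) +
      log10(st[substr(skmer, j, j), j])
  }
  expect_equal(score_match(m, kmer, skmer), unname(acc), tolerance = 1e-12)
  expect_true(is.na(score_match(m, "ACGUNN", "UPUPUP")))
})

test_that("scanning p-values match the exhaustive rank on a toy", {
  tx <- toy_transcriptome(n = 1, len = 105, seed = 13)
  rea <- prof_list(lapply(tx, function(s)
    rep(c(0.8, 0.05), length.out = nchar(s))))
  set.seed(2)
  sq <- matrix(runif(24), 4, 6, dimnames = list(c("A", "C", "G", "U"), NULL))
  m <- list(seq_pwm = sweep(sq, 2, colSums(sq), "/"),
            struct_pwm = matrix(0.5, 2, 6,
                                dimnames = list(c("U", "P"), NULL)))
  n_null <- 5000
  sc <- scan_motif(m, tx, rea, n_null = n_null, seed = 7)
  expect_equal(nrow(sc), 100)
  # exhaustive oracle: exact rank over all covered positions
  exact_p <- vapply(sc$R, function(r) mean(sc$R >= r), numeric(1))
  expect_true(all(abs(sc$empirical_p - exact_p) <= 2 / (n_null + 1) + 0.02))
  # monotone: higher R never gets a larger p
  ord <- order(sc$R)
  expect_true(all(diff(sc$empirical_p[ord]) <= 1e-12))
  sc2 <- scan_motif(m, tx, rea, n_null = n_null, seed = 7)
  expect_identical(sc, sc2)
})

test_that("motif distance matches its closed form and a summation oracle", {
  uni <- list(seq_pwm = matrix(0.25, 4, 6), struct_pwm = matrix(0.5, 2, 6))
  expect_equal(motif_distance(uni, uni), 0)
  a <- uni; b <- uni
  a$seq_pwm[, 1] <- c(1, 0, 0, 0); b$seq_pwm[, 1] <- c(0, 1, 0, 0)
  expect_equal(motif_distance(a, b), sqrt(2))
  set.seed(4)
  m1 <- list(seq_pwm = matrix(runif(24), 4, 6),
             struct_pwm = matrix(runif(12), 2, 6))
  m2 <- list(seq_pwm = matrix(runif(24), 4, 6),
             struct_pwm = matrix(runif(12), 2, 6))
  acc <- 0
  for (i in 1:4) for (j in 1:6) acc <- acc + (m1$seq_pwm[i, j] -
                                                m2$seq_pwm[i, j])^2
  for (r in 1:2) for (j in 1:6) acc <- acc + (m1$struct_pwm[r, j] -
                                                m2$struct_pwm[r, j])^2
  expect_equal(motif_distance(m1, m2), sqrt(acc), tolerance = 1e-12)
  short <- list(seq_pwm = matrix(0.25, 4, 5), struct_pwm = matrix(0.5, 2, 5))
  expect_error(motif_distance(uni, short), "dimension")
})

test_that("hierarchical clustering reproduces an average-linkage oracle", {
  set.seed(6)
  mk <- function() {
    sq <- matrix(runif(24), 4, 6); sq <- sweep(sq, 2, colSums(sq), "/")
    st <- matrix(runif(12), 2, 6); st <- sweep(st, 2, colSums(st), "/")
    list(seq_pwm = sq, struct_pwm = st)
  }
  motifs <- replicate(5, mk(), simplify = FALSE)
  motifs[[2]] <- motifs[[1]]           # identical pair must merge first
  for (i in seq_along(motifs)) motifs[[i]]$name <- paste0("m", i)
  cl <- cluster_motifs(motifs)
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  expect_equal(cl$hclust$height[1], 0)
  first <- sort(cl$hclust$labels[-cl$hclust$merge[1, ]])
  expect_equal(first, c("m1", "m2"))
  expect_match(cl$newick, "^\\(")

  # independent oracle: naive average-linkage agglomeration on the matrix
  d <- cl$dist
  active <- as.list(seq_len(5))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_len(length(active) - 1)) {
      for (j in seq(i + 1, length(active))) {
        h <- mean(d[active[[i]], active[[j]]])
        if (h < bh) { bh <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, bh)
    active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
    active[[best[2]]] <- NULL
  }
  expect_equal(sort(cl$hclust$height), sort(heights), tolerance = 1e-12)
  expect_error(cluster_motifs(motifs[1]), ">= 2")
})

test_that("structure-aware scanning is more specific than sequence alone", {
  d <- generate_synthetic(synthetic_spec(n_transcripts = 40, length = 400,
                                         seed = 33))
  # integrative motif for GCAUG-in-unpaired-context (width 6: motif + one
  # free flank column); the sequence-only variant carries a flat structure
  # PWM so only the sequence term discriminates
  cons <- c("G", "C", "A", "U", "G")
  sq <- matrix(0.03, 4, 6, dimnames = list(c("A", "C", "G", "U"), NULL))
  for (j in 1:5) sq[cons[j], j] <- 0.91
  sq[, 6] <- 0.25
  st_int <- matrix(c(rep(c(0.9, 0.1), 5), 0.5, 0.5), 2, 6,
                   dimnames = list(c("U", "P"), NULL))
  st_flat <- matrix(0.5, 2, 6, dimnames = list(c("U", "P"), NULL))
  integrative <- list(seq_pwm = sq, struct_pwm = st_int)
  seq_only <- list(seq_pwm = sq, struct_pwm = st_flat)

  truth <- d$truth$planted
  bound_key <- paste(truth$transcript_id[truth$bound],
                     truth$motif_start[truth$bound])
  count_fp <- function(motif) {
    sc <- scan_motif(motif, d$transcripts, d$merged$A, n_null = 1000,
                     seed = 3)
    key <- paste(sc$transcript_id, sc$start)
    tp_scores <- sc$R[key %in% bound_key]
    thr <- min(tp_scores)        # matched threshold: full recall of scored
    sum(sc$R >= thr & !(key %in% bound_key))
  }
  fp_int <- count_fp(integrative)
  fp_seq <- count_fp(seq_only)
  expect_lt(fp_int, fp_seq)
})
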
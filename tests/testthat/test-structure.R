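test_that("replicate-noise estimation uses nearest-rank quantiles", {
  # grid 0.00 ... 0.99: the nearest-rank 95th percentile is 0.94
  grid <- seq(0, 0.99, by = 0.01)
  r1 <- prof1("tx1", rep(0, 100))
  r2 <- prof1("tx1", grid)                   # L1 distances = grid
  d <- abs(r1$tx1$scores - r2$tx1$scores)
  expect_equal(sort(d)[95], 0.94)
  expect_equal(estimate_noise(r1, r2), 0.94)

  # identical replicates give zero noise
  expect_equal(estimate_noise(r1, r1), 0)
  # constant distances return the constant
  r3 <- prof1("tx1", rep(0.2, 100)); r4 <- prof1("tx1", rep(0.5, 100))
  expect_equal(estimate_noise(r3, r4), 0.3)
  # too few pooled positions
  expect_error(estimate_noise(prof1("tx1", rep(0.5, 50)),
                              prof1("tx1", rep(0.6, 50))), ">= 100")
})

test_that("binomial window p-values equal the exact tail sum", {
  # oracle: explicit tail with choose(), checked at 1e-10
  tail_sum <- function(k, m, p) {
    sum(vapply(k:m, function(j)
      choose(m, j) * p^j * (1 - p)^(m - j), numeric(1)))
  }
  for (m in 10:20) for (k in 0:m) {
    expect_equal(stats::pbinom(k - 1, m, 0.05, lower.tail = FALSE),
                 tail_sum(k, m, 0.05), tolerance = 1e-10)
  }
  expect_equal(round(tail_sum(4, 20, 0.05), 4), 0.0159)  # passes alpha 0.05
  expect_equal(round(tail_sum(3, 20, 0.05), 4), 0.0755)  # fails alpha 0.05
})

test_that("identical condition profiles yield no variable sites", {
  p <- prof_list(list(tx1 = runif(100), tx2 = runif(100)))
  svs <- call_svs(p, p, delta_s_noise = 0.1, delta_l1 = 0.05)
  expect_equal(nrow(svs), 0)
})

test_that("a planted window difference is called as one variable site", {
  base <- rep(0.1, 200)
  other <- base
  other[81:100] <- 0.8
  pa <- prof1("tx1", base)
  pb <- prof1("tx1", other)
  svs <- call_svs(pa, pb, delta_s_noise = 0.2, delta_l1 = 0.05)
  expect_equal(nrow(svs), 1)
  expect_true(svs$start <= 80 && svs$end >= 100)
  expect_lt(svs$p_value, 0.05)
  # sites are disjoint per transcript by construction
  expect_true(all(svs$end > svs$start))
})

test_that("variant classification follows the riboSNitch definition", {
  svs <- data.frame(transcript_id = "tx1", start = 10L, end = 30L,
                    stringsAsFactors = FALSE)
  vars <- data.frame(
    transcript_id = rep("tx1", 12),
    position = rep(c(12L, 15L, 20L, 50L, 60L, 70L), each = 2),
    condition = rep(c("A", "B"), 6),
    allele = c("G", "A", "C", "U", "A", "G",   # differing, inside SVS
               "G", "C", "U", "A",             # differing, outside
               "G", "G"),                      # same allele
    stringsAsFactors = FALSE)
  calls <- classify_variants(vars, svs, c("A", "B"))
  expect_equal(nrow(calls), 5)                 # same-allele excluded
  expect_equal(sum(calls$label == "riboSNitch"), 3)
  expect_equal(sum(calls$label == "VSS"), 2)
  expect_setequal(calls$position[calls$label == "riboSNitch"],
                  c(12L, 15L, 20L))
  expect_error(classify_variants(vars, svs, c("A", "X")), "unknown condition")
})

test_that("overlap odds ratios match enumeration and apply the correction", {
  null_or <- overlap_odds_ratio(10, 10, 10, 10)
  expect_equal(null_or$odds_ratio, 1)
  expect_gte(null_or$p_value, 0.5)

  o <- overlap_odds_ratio(8, 2, 2, 8)
  expect_equal(o$odds_ratio, 16)
  # oracle: explicit hypergeometric enumeration
  p_oracle <- sum(vapply(8:10, function(x)
    choose(10, x) * choose(10, 10 - x), numeric(1))) / choose(20, 10)
  expect_equal(o$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(o$p_value,
               fisher.test(matrix(c(8, 2, 2, 8), 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               tolerance = 1e-9)

  # Haldane-Anscombe correction keeps zero-cell tables finite
  z <- overlap_odds_ratio(0, 10, 5, 5)
  expect_true(is.finite(z$odds_ratio))
  expect_equal(z$odds_ratio, (0.5 / 10.5) / (5.5 / 5.5))
})

test_that("recovery is monotone in the planted effect size", {
  n_recovered <- vapply(c(0.2, 0.4, 0.6), function(effect) {
    base <- rep(0.2, 300)
    other <- base
    other[101:120] <- base[101:120] + effect
    svs <- call_svs(prof1("t", base), prof1("t", other),
                    delta_s_noise = 0.15, delta_l1 = 0.05)
    nrow(svs)
  }, numeric(1))
  expect_true(all(diff(n_recovered) >= 0))
})
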
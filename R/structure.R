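# Comparative-structure statistics: replicate-noise calibration, sliding
# window binomial test for structurally variable sites (SVS) between two
# conditions, and riboSNitch vs VSS classification of variants.

#' Estimate the per-nucleotide replicate-noise threshold
#'
#' Pools the per-nucleotide L1 distances |s1 - s2| between replicate
#' reactivity profiles (positions where both replicates are non-missing) and
#' returns the nearest-rank 95th percentile, the threshold above which a
#' cross-condition difference is counted as a structurally variable
#' nucleotide.
#'
#' @param rep1,rep2 named lists of profiles for the two replicates (same
#'   transcripts).
#' @param quantile_p percentile (default 0.95).
#' @return scalar threshold \code{delta_s_noise}.
#' @export
estimate_noise <- function(rep1, rep2, quantile_p = 0.95) {
  d <- unlist(lapply(names(rep1), function(tx) {
    a <- rep1[[tx]]$scores; b <- rep2[[tx]]$scores
    ok <- !is.na(a) & !is.na(b)
    abs(a[ok] - b[ok])
  }))
  if (length(d) < 100) {
    stop("need >= 100 pooled replicate positions to estimate noise (have ",
         length(d), ")")
  }
  nearest_rank_quantile(d, quantile_p)
}

# Per-window mean L1 distances between two condition profiles for every
# transcript; windows need >= min_valid jointly covered positions.
all_window_l1 <- function(profiles_a, profiles_b, window = 20L,
                          min_valid = 10L) {
  unlist(lapply(names(profiles_a), function(tx) {
    a <- profiles_a[[tx]]$scores; b <- profiles_b[[tx]]$scores
    n <- length(a)
    if (n < window) return(numeric(0))
    d <- abs(a - b)
    ok <- as.numeric(!is.na(d))
    d0 <- ifelse(is.na(d), 0, d)
    csd <- c(0, cumsum(d0)); cso <- c(0, cumsum(ok))
    nw <- n - window + 1L
    m <- cso[(window + 1):(window + nw)] - cso[1:nw]
    s <- csd[(window + 1):(window + nw)] - csd[1:nw]
    (s / m)[m >= min_valid]
  }))
}

#' Estimate the window-level structural-variation threshold
#'
#' Nearest-rank 90th percentile of the per-window mean L1 distances between
#' two conditions, pooled over all transcripts.
#'
#' @param profiles_a,profiles_b condition profiles.
#' @param window window size (default 20).
#' @param min_valid minimum jointly covered positions per window.
#' @param quantile_p percentile (default 0.90).
#' @return scalar threshold \code{delta_l1}.
#' @export
estimate_delta_l1 <- function(profiles_a, profiles_b, window = 20L,
                              min_valid = 10L, quantile_p = 0.90) {
  wl <- all_window_l1(profiles_a, profiles_b, window, min_valid)
  if (length(wl) == 0) stop("no windows with sufficient joint coverage")
  nearest_rank_quantile(wl, quantile_p)
}

#' Call structurally variable sites between two conditions
#'
#' Slides 20-nt windows (1-nt step) over jointly covered positions. In each
#' window with at least \code{min_valid} valid positions, counts the
#' structurally variable nucleotides (per-nucleotide L1 above
#' \code{delta_s_noise}) and computes the exact binomial tail
#' \code{P(K >= k)} under \code{Binomial(m, rate)}. Windows with p <
#' \code{alpha} and mean L1 > \code{delta_l1} are merged into disjoint
#' sites.
#'
#' @param profiles_a,profiles_b condition profiles.
#' @param delta_s_noise per-nucleotide threshold from [estimate_noise()].
#' @param delta_l1 window threshold from [estimate_delta_l1()].
#' @param window,alpha,min_valid window size, significance level, minimum
#'   valid positions.
#' @param rate binomial success rate; 0.05 is forced by defining
#'   \code{delta_s_noise} as the top-5\% replicate-noise quantile.
#' @param bh apply Benjamini-Hochberg correction across windows instead of
#'   raw p-values (off by default).
#' @return data.frame of sites: transcript_id, start, end, mean_l1,
#'   p_value (the most significant member window).
#' @export
call_svs <- function(profiles_a, profiles_b, delta_s_noise, delta_l1,
                     window = 20L, alpha = 0.05, min_valid = 10L,
                     rate = 0.05, bh = FALSE) {
  win_rows <- list()
  for (tx in names(profiles_a)) {
    a <- profiles_a[[tx]]$scores; b <- profiles_b[[tx]]$scores
    n <- length(a)
    if (n < window) next
    d <- abs(a - b)
    valid <- !is.na(d)
    d0 <- ifelse(valid, d, 0)
    var_nt <- as.numeric(valid & d0 > delta_s_noise)
    csd <- c(0, cumsum(d0)); cso <- c(0, cumsum(as.numeric(valid)))
    csv <- c(0, cumsum(var_nt))
    nw <- n - window + 1L
    m <- cso[(window + 1):(window + nw)] - cso[1:nw]
    s <- csd[(window + 1):(window + nw)] - csd[1:nw]
    k <- csv[(window + 1):(window + nw)] - csv[1:nw]
    ok <- m >= min_valid
    if (!any(ok)) next
    p <- stats::pbinom(k[ok] - 1, m[ok], rate, lower.tail = FALSE)
    win_rows[[tx]] <- data.frame(
      transcript_id = tx, start = which(ok) - 1L,
      end = which(ok) - 1L + window, mean_l1 = (s / m)[ok], p_value = p,
      stringsAsFactors = FALSE)
  }
  if (length(win_rows) == 0) {
    warning("no windows with joint reactivity coverage")
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), mean_l1 = numeric(),
                      p_value = numeric()))
  }
  wins <- do.call(rbind, win_rows)
  padj <- if (bh) stats::p.adjust(wins$p_value, "BH") else wins$p_value
  hits <- wins[padj < alpha & wins$mean_l1 > delta_l1, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(hits[, c("transcript_id", "start", "end", "mean_l1", "p_value")])
  }
  sites <- merge_intervals(hits[, c("transcript_id", "start", "end")])
  sites$mean_l1 <- NA_real_; sites$p_value <- NA_real_
  for (i in seq_len(nrow(sites))) {
    mem <- hits$transcript_id == sites$transcript_id[i] &
      overlaps(hits$start, hits$end, sites$start[i], sites$end[i])
    sites$mean_l1[i] <- max(hits$mean_l1[mem])
    sites$p_value[i] <- min(hits$p_value[mem])
  }
  rownames(sites) <- NULL
  sites
}

#' Classify differing-allele variants as riboSNitches or VSSs
#'
#' A variant with different alleles between the condition pair that lies
#' inside a structurally variable site is a putative riboSNitch; a
#' differing-allele variant outside every SVS is a variation of stable
#' structure (VSS). Same-allele variants are excluded from the output.
#'
#' @param variants long-format data.frame from [read_variants()].
#' @param svs SVS data.frame from [call_svs()].
#' @param conditions character vector of the two condition names.
#' @return data.frame: transcript_id, position, allele_a, allele_b, label.
#' @export
classify_variants <- function(variants, svs, conditions) {
  stopifnot(length(conditions) == 2)
  if (!all(conditions %in% variants$condition)) {
    stop("unknown condition name: ",
         paste(setdiff(conditions, variants$condition), collapse = ", "))
  }
  va <- variants[variants$condition == conditions[1], ]
  vb <- variants[variants$condition == conditions[2], ]
  key <- function(d) paste(d$transcript_id, d$position)
  common <- intersect(key(va), key(vb))
  va <- va[match(common, key(va)), ]
  vb <- vb[match(common, key(vb)), ]
  differs <- va$allele != vb$allele
  va <- va[differs, ]; vb <- vb[differs, ]
  if (nrow(va) == 0) {
    return(data.frame(transcript_id = character(), position = integer(),
                      allele_a = character(), allele_b = character(),
                      label = character()))
  }
  in_svs <- vapply(seq_len(nrow(va)), function(i) {
    s <- svs[svs$transcript_id == va$transcript_id[i], , drop = FALSE]
    nrow(s) > 0 && any(va$position[i] >= s$start & va$position[i] < s$end)
  }, logical(1))
  out <- data.frame(transcript_id = va$transcript_id,
                    position = va$position,
                    allele_a = va$allele, allele_b = vb$allele,
                    label = ifelse(in_svs, "riboSNitch", "VSS"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Odds ratio and one-sided Fisher p for a 2 x 2 overlap table
#'
#' \code{OR = (a/b)/(c/d)} with the Haldane-Anscombe 0.5 correction applied
#' to every cell when any cell is zero; the p-value is the exact one-sided
#' hypergeometric tail \code{P(X >= a)} on the uncorrected table.
#'
#' @param a,b,c,d the table cells (e.g. riboSNitches overlapping / not
#'   overlapping a reference set, and background SNVs overlapping / not).
#' @return list with \code{odds_ratio} and \code{p_value}.
#' @export
overlap_odds_ratio <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d == 0) stop("empty table")
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  list(odds_ratio = or, p_value = fisher_p_greater(a, b, c, d))
}
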
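# Integrative sequence-and-structure motifs: built from high-attention
# windows of confidently bound sites, as paired 4 x 6 sequence and 2 x 6
# structure PWMs with a weight; scanned over the transcriptome with a
# log10 likelihood-ratio score against a seeded empirical null; clustered
# hierarchically on PWM Euclidean distance.

SEQ_LETTERS <- c("A", "C", "G", "U")
STRUCT_LETTERS <- c("U", "P")   # unpaired / paired

#' Binarize reactivity scores into unpaired/paired states
#'
#' \code{"U"} (unpaired) for score >= threshold, \code{"P"} (paired) below;
#' missing scores become \code{"."} and are excluded from k-mer extraction.
#' The default threshold 0.233 is the median reactivity of the original
#' transcriptome-wide score distribution; pass
#' \code{threshold = median(scores, na.rm = TRUE)} to recalibrate on a
#' dataset.
#'
#' @param scores numeric reactivity vector (NA = missing).
#' @param threshold unpaired/paired cutoff (default 0.233).
#' @return character vector over \{U, P, .\}.
#' @export
binarize_structure <- function(scores, threshold = 0.233) {
  ifelse(is.na(scores), ".", ifelse(scores >= threshold, "U", "P"))
}

#' Collect high-attention windows for motif construction
#'
#' Sites with predicted binding probability > \code{min_prob} contribute
#' their top-20\% attention windows (merged); each window carries its
#' sequence and binarized structure strings.
#'
#' @param sites data.frame with transcript_id, start, end, probability.
#' @param saliency list of saliency maps (from [smoothgrad()]), parallel to
#'   \code{sites} rows.
#' @param transcripts named character vector.
#' @param reactivity named list of profiles.
#' @param min_prob probability cutoff (default 0.8).
#' @param threshold structure binarization cutoff.
#' @return list of windows, each with \code{seq} and \code{struct} strings.
#' @export
collect_windows <- function(sites, saliency, transcripts, reactivity,
                            min_prob = 0.8, threshold = 0.233) {
  keep <- which(sites$probability > min_prob)
  if (length(keep) == 0) stop("no sites with probability > ", min_prob)
  out <- list()
  for (i in keep) {
    sal <- saliency[[i]]
    resp <- sal$seq_response + sal$struct_response
    hars <- find_hars(resp, mode = "top20pct")
    tx <- sites$transcript_id[i]
    s0 <- sites$start[i]
    for (r in seq_len(nrow(hars))) {
      a <- s0 + hars$start[r]; b <- s0 + hars$end[r]
      seq_w <- substr(transcripts[[tx]], a + 1, b)
      str_w <- paste(binarize_structure(
        reactivity[[tx]]$scores[(a + 1):b], threshold), collapse = "")
      out[[length(out) + 1]] <- list(seq = seq_w, struct = str_w)
    }
  }
  out
}

# Hamming distance between equal-length strings (as character vectors).
hamming <- function(a, b) sum(a != b)

# Best-offset comparison of two k-mer pairs: try offsets -1, 0, +1 of `b`
# against `a`, ignore overhanging positions, and return whether any offset
# satisfies both tolerances (preferring lower sequence then structure
# distance).
kmer_compatible <- function(seq_a, str_a, seq_b, str_b, seq_tol, struct_tol) {
  for (off in c(0L, -1L, 1L)) {
    ia <- seq_along(seq_a)
    ib <- ia + off
    ok <- ib >= 1 & ib <= length(seq_b)
    ds <- hamming(seq_a[ok], seq_b[ib[ok]])
    dt <- hamming(str_a[ok], str_b[ib[ok]])
    if (ds <= seq_tol && dt <= struct_tol) return(off)
  }
  NA_integer_
}

# Build column-stochastic PWMs from aligned member k-mers with counts.
pwm_from_members <- function(members, k, pseudocount) {
  seq_counts <- matrix(0, 4, k, dimnames = list(SEQ_LETTERS, NULL))
  str_counts <- matrix(0, 2, k, dimnames = list(STRUCT_LETTERS, NULL))
  for (m in members) {
    pos_a <- seq_len(k)
    pos_b <- pos_a + m$offset
    ok <- pos_b >= 1 & pos_b <= k
    for (j in which(ok)) {
      seq_counts[m$seq[pos_b[j]], pos_a[j]] <-
        seq_counts[m$seq[pos_b[j]], pos_a[j]] + m$count
      str_counts[m$struct[pos_b[j]], pos_a[j]] <-
        str_counts[m$struct[pos_b[j]], pos_a[j]] + m$count
    }
  }
  norm <- function(m) sweep(m + pseudocount, 2, colSums(m + pseudocount), "/")
  list(seq_pwm = norm(seq_counts), struct_pwm = norm(str_counts))
}

# Pearson correlation of two motifs' stacked PWM cells at the best offset
# in {-1, 0, 1}; used to merge near-duplicate motifs. Returns the best
# correlation and the offset achieving it (columns of m2 shifted by
# `offset` relative to m1).
motif_similarity <- function(m1, m2) {
  stack <- function(m) rbind(m$seq_pwm, m$struct_pwm)
  a <- stack(m1); b <- stack(m2)
  k <- ncol(a)
  best <- list(cor = -Inf, offset = 0L)
  for (off in -1:1) {
    ja <- seq_len(k); jb <- ja + off
    ok <- jb >= 1 & jb <= k
    if (sum(ok) < 2) next
    v1 <- as.vector(a[, ja[ok]]); v2 <- as.vector(b[, jb[ok]])
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0) next
    r <- stats::cor(v1, v2)
    if (r > best$cor) best <- list(cor = r, offset = off)
  }
  best
}

#' Build integrative motifs from high-attention windows
#'
#' Enumerates all k-mers (sequence + binarized structure) in the windows,
#' skipping any containing N or a missing-structure position, then greedily
#' clusters them seeded by descending k-mer frequency: a k-mer joins a
#' cluster if, at the best offset in \{-1, 0, +1\} (overhangs ignored), its
#' sequence Hamming distance to the seed is <= \code{seq_tol} and its
#' structure Hamming distance <= \code{struct_tol}. Cluster members are
#' aligned at their offsets and tallied into PWMs with a pseudocount.
#' Near-duplicate motifs (stacked-PWM Pearson correlation > 0.8 at the best
#' offset) are merged. The motif weight is its member k-mer frequency over
#' the total k-mer count.
#'
#' @param windows list from [collect_windows()].
#' @param k k-mer length (default 6).
#' @param seq_tol,struct_tol Hamming tolerances (defaults 1 and 2).
#' @param pseudocount added to every PWM cell before normalization.
#' @param merge_cor correlation threshold for merging similar motifs.
#' @return list of motifs sorted by weight (each with \code{seq_pwm},
#'   \code{struct_pwm}, \code{weight}, \code{support}, \code{consensus}).
#' @export
build_motifs <- function(windows, k = 6L, seq_tol = 1L, struct_tol = 2L,
                         pseudocount = 0.01, merge_cor = 0.8) {
  kmers <- list()
  for (w in windows) {
    n <- nchar(w$seq)
    if (n < k) next
    for (s in 1:(n - k + 1)) {
      sq <- substr(w$seq, s, s + k - 1)
      st <- substr(w$struct, s, s + k - 1)
      if (grepl("N", sq, fixed = TRUE) || grepl(".", st, fixed = TRUE)) next
      key <- paste0(sq, "/", st)
      kmers[[key]] <- (kmers[[key]] %||% 0L) + 1L
    }
  }
  if (length(kmers) == 0) stop("no valid k-mers in the windows")
  counts <- unlist(kmers)
  total <- sum(counts)
  ord <- order(-counts, names(counts))       # frequency desc, then lexical
  keys <- names(counts)[ord]
  counts <- counts[ord]
  split_key <- strsplit(keys, "/", fixed = TRUE)
  seqs <- lapply(split_key, function(x) strsplit(x[1], "")[[1]])
  strs <- lapply(split_key, function(x) strsplit(x[2], "")[[1]])

  assigned <- rep(FALSE, length(keys))
  clusters <- list()
  for (i in seq_along(keys)) {
    if (assigned[i]) next
    members <- list(list(seq = seqs[[i]], struct = strs[[i]],
                         count = counts[i], offset = 0L))
    assigned[i] <- TRUE
    if (i < length(keys)) {
      for (j in seq(i + 1, length(keys))) {
        if (assigned[j]) next
        off <- kmer_compatible(seqs[[i]], strs[[i]], seqs[[j]], strs[[j]],
                               seq_tol, struct_tol)
        if (!is.na(off)) {
          assigned[j] <- TRUE
          members[[length(members) + 1]] <-
            list(seq = seqs[[j]], struct = strs[[j]], count = counts[j],
                 offset = off)
        }
      }
    }
    clusters[[length(clusters) + 1]] <- members
  }

  make_motif <- function(members) {
    pw <- pwm_from_members(members, k, pseudocount)
    support <- sum(vapply(members, function(m) m$count, numeric(1)))
    c(pw, list(weight = support / total, support = support,
               consensus = paste(SEQ_LETTERS[apply(pw$seq_pwm, 2, which.max)],
                                 collapse = "")))
  }
  motifs <- lapply(clusters, make_motif)

  # merge near-duplicate PWMs (internal analog of a motif-comparison step);
  # the absorbed cluster's member offsets are re-expressed in the keeper's
  # column frame so the combined PWM stays aligned
  repeat {
    merged <- FALSE
    if (length(motifs) >= 2) {
      for (a in seq_len(length(motifs) - 1)) {
        for (b in seq(a + 1, length(motifs))) {
          sim <- motif_similarity(motifs[[a]], motifs[[b]])
          if (sim$cor > merge_cor) {
            shifted <- lapply(clusters[[b]], function(m) {
              m$offset <- m$offset + sim$offset
              m
            })
            clusters[[a]] <- c(clusters[[a]], shifted)
            clusters[[b]] <- NULL
            motifs <- lapply(clusters, make_motif)
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  motifs <- motifs[order(-vapply(motifs, function(m) m$weight, numeric(1)))]
  for (i in seq_along(motifs)) motifs[[i]]$name <- paste0("motif_", i)
  motifs
}

#' Test motif weights for enrichment over a uniform baseline
#'
#' For each of the top \code{top} motifs by weight, compares its member
#' k-mer count against the expectation that the top motifs share weight
#' equally (baseline 10\%), with a one-sided Fisher's exact test; motifs
#' with p < 0.05 are flagged significant.
#'
#' @param motifs list from [build_motifs()].
#' @param top number of motifs tested (default 10).
#' @param baseline expected weight under the uniform null (default 0.10).
#' @return the motifs with \code{enrichment_p} and \code{significant} added.
#' @export
enrich_motifs <- function(motifs, top = 10L, baseline = 0.10) {
  if (length(motifs) == 0) stop("no motifs")
  total <- sum(vapply(motifs, function(m) m$support, numeric(1))) /
    sum(vapply(motifs, function(m) m$weight, numeric(1)))
  for (i in seq_len(min(top, length(motifs)))) {
    a <- motifs[[i]]$support
    b <- round(total) - a
    c_ <- round(baseline * total)
    d_ <- round(total) - c_
    motifs[[i]]$enrichment_p <- fisher_p_greater(a, b, c_, d_)
    motifs[[i]]$significant <- motifs[[i]]$enrichment_p < 0.05 &&
      motifs[[i]]$weight > baseline
  }
  motifs
}

# One-sided (enrichment) Fisher p: hypergeometric tail P(X >= a) for the
# table [a b; c d] conditioned on its margins.
fisher_p_greater <- function(a, b, c, d) {
  m <- a + b; n <- c + d; kk <- a + c
  lo <- max(0, kk - n); hi <- min(kk, m)
  if (a > hi) return(0)
  sum(stats::dhyper(a:hi, m, n, kk))
}

#' Log10 likelihood-ratio score of a motif at one window
#'
#' \code{R = sum_j log10 p_seq[i(j), j] + sum_j log10 p_struct[r(j), j]};
#' pseudocounted PWMs keep R finite. Windows containing N or a missing
#' structure state return NA (skipped by the scanner).
#'
#' @param motif integrative motif.
#' @param seq_kmer,struct_kmer strings of the motif's width over
#'   \{A,C,G,U\} and \{U,P\}.
#' @return numeric score (NA if the window is unscorable).
#' @export
score_match <- function(motif, seq_kmer, struct_kmer) {
  k <- ncol(motif$seq_pwm)
  sq <- strsplit(seq_kmer, "")[[1]]
  st <- strsplit(struct_kmer, "")[[1]]
  stopifnot(length(sq) == k, length(st) == k)
  si <- match(sq, SEQ_LETTERS)
  ri <- match(st, STRUCT_LETTERS)
  if (anyNA(si) || anyNA(ri)) return(NA_real_)
  sum(log10(motif$seq_pwm[cbind(si, seq_len(k))])) +
    sum(log10(motif$struct_pwm[cbind(ri, seq_len(k))]))
}

#' Scan a transcriptome with an integrative motif
#'
#' Scores every position whose k-window is fully covered by reactivity and
#' free of N; the empirical null is the score at \code{n_null} positions
#' sampled uniformly (with replacement) from the covered positions, and
#' \code{empirical_p = (#null >= R + 1) / (n_null + 1)}.
#'
#' @param motif integrative motif.
#' @param transcripts named character vector.
#' @param reactivity named list of profiles.
#' @param n_null null sample count (default 200000).
#' @param seed RNG seed.
#' @param threshold structure binarization cutoff.
#' @return data.frame: transcript_id, start (0-based), R, empirical_p.
#' @export
scan_motif <- function(motif, transcripts, reactivity, n_null = 200000L,
                       seed = 1, threshold = 0.233) {
  k <- ncol(motif$seq_pwm)
  rows <- list()
  for (tx in names(transcripts)) {
    seq_chars <- strsplit(transcripts[[tx]], "")[[1]]
    sc <- reactivity[[tx]]$scores
    n <- length(seq_chars)
    if (n < k) next
    str_chars <- binarize_structure(sc, threshold)
    si <- match(seq_chars, SEQ_LETTERS)
    ri <- match(str_chars, STRUCT_LETTERS)
    # rolling sum of per-position, per-column log-probabilities
    score <- rep(0, n - k + 1)
    valid <- rep(TRUE, n - k + 1)
    for (j in seq_len(k)) {
      pos <- j:(n - k + j)
      sj <- si[pos]; rj <- ri[pos]
      bad <- is.na(sj) | is.na(rj)
      valid <- valid & !bad
      contrib <- rep(NA_real_, length(pos))
      okp <- !bad
      contrib[okp] <- log10(motif$seq_pwm[cbind(sj[okp], j)]) +
        log10(motif$struct_pwm[cbind(rj[okp], j)])
      score <- score + ifelse(okp, contrib, 0)
    }
    if (!any(valid)) next
    rows[[tx]] <- data.frame(transcript_id = tx,
                             start = which(valid) - 1L,
                             R = score[valid], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("fewer than k covered positions")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  null_scores <- with_seed(seed,
    out$R[sample.int(nrow(out), n_null, replace = TRUE)])
  ns <- sort(null_scores)
  # #null >= R  ==  n_null - #null < R
  n_ge <- n_null - findInterval(out$R, ns, left.open = TRUE)
  out$empirical_p <- (n_ge + 1) / (n_null + 1)
  out
}

#' Euclidean distance between two integrative motifs
#'
#' Square root of the summed squared differences over all sequence-PWM and
#' structure-PWM cells.
#'
#' @param m1,m2 motifs of equal width.
#' @return nonnegative distance, zero iff identical.
#' @export
motif_distance <- function(m1, m2) {
  if (!all(dim(m1$seq_pwm) == dim(m2$seq_pwm)) ||
      !all(dim(m1$struct_pwm) == dim(m2$struct_pwm))) {
    stop("motif dimension mismatch")
  }
  sqrt(sum((m1$seq_pwm - m2$seq_pwm)^2) +
         sum((m1$struct_pwm - m2$struct_pwm)^2))
}

#' Hierarchically cluster motifs on PWM Euclidean distance
#'
#' Average-linkage agglomeration; the dendrogram is also returned as a
#' newick string.
#'
#' @param motifs list of >= 2 motifs.
#' @return list with \code{hclust}, \code{dist} and \code{newick}.
#' @export
cluster_motifs <- function(motifs) {
  if (length(motifs) < 2) stop("need >= 2 motifs to cluster")
  n <- length(motifs)
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dm[i, j] <- dm[j, i] <- motif_distance(motifs[[i]], motifs[[j]])
  }
  labels <- vapply(seq_along(motifs), function(i)
    motifs[[i]]$name %||% paste0("motif_", i), character(1))
  rownames(dm) <- colnames(dm) <- labels
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  list(hclust = hc, dist = dm,
       newick = ape::write.tree(ape::as.phylo(hc)))
}
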
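# From raw CLIP peaks + reactivity to labeled, encoded, split training data.
# Positive sites: per-replicate min-max normalization, >=1 nt overlap merging
# with summed signals, 101-nt center-preserving unification, >=40% reactivity
# coverage, top-5000 by signal. Negatives: random 101-nt windows avoiding
# positives. Encoding: one-hot A/C/G/U + reactivity channel (missing = -1).

SITE_LEN <- 101L

#' Min-max normalize peak signals within one replicate
#'
#' Rescales signals to \[0,1\] within the replicate; if all signals are equal
#' every signal maps to 1.0.
#'
#' @param peaks data.frame of peaks from a single replicate.
#' @return the same data.frame with rescaled \code{signal}; order unchanged.
#' @export
normalize_replicate <- function(peaks) {
  if (nrow(peaks) < 1) stop("normalize_replicate: no peaks")
  rng <- range(peaks$signal)
  peaks$signal <- if (rng[1] == rng[2]) rep(1.0, nrow(peaks)) else
    (peaks$signal - rng[1]) / (rng[2] - rng[1])
  peaks
}

#' Merge normalized peaks across replicates
#'
#' Peaks on the same transcript overlapping by at least 1 nt are merged into
#' the union interval with the summed signal; the result is non-overlapping
#' per transcript.
#'
#' @param peaks data.frame of normalized peaks (all replicates together).
#' @return merged data.frame with columns transcript_id, start, end, signal.
#' @export
merge_replicates <- function(peaks) {
  merged <- merge_intervals(peaks[, c("transcript_id", "start", "end", "signal")],
                            sum_col = "signal")
  merged[, c("transcript_id", "start", "end", "signal")]
}

#' Unify a peak to a fixed site length, preserving the center
#'
#' Excess length is trimmed floor(delta/2) from the left and ceiling(delta/2)
#' from the right; deficits are expanded symmetrically the same way. Intervals
#' are clamped to the transcript, carrying any shortfall to the other side;
#' transcripts shorter than \code{L} yield the whole transcript (flanks are
#' padded at encoding time).
#'
#' @param start,end 0-based half-open peak interval.
#' @param transcript_length length of the host transcript.
#' @param L target site length (odd; default 101).
#' @return integer vector \code{c(start, end)}.
#' @export
unify_length <- function(start, end, transcript_length, L = SITE_LEN) {
  stopifnot(L %% 2 == 1, start >= 0, end > start)
  if (transcript_length < L) return(c(0L, as.integer(transcript_length)))
  len <- end - start
  delta <- len - L
  if (delta > 0) {
    start <- start + delta %/% 2
    end <- end - (delta - delta %/% 2)
  } else if (delta < 0) {
    add <- -delta
    start <- start - add %/% 2
    end <- end + (add - add %/% 2)
  }
  # clamp to the transcript, carrying the shortfall to the other side
  if (start < 0) { end <- end - start; start <- 0L }
  if (end > transcript_length) {
    start <- start - (end - transcript_length)
    end <- transcript_length
  }
  start <- max(0L, start)
  c(as.integer(start), as.integer(end))
}

# Fraction of site positions with non-missing reactivity. `scores` is the
# whole-transcript profile; the site may have been clamped shorter than L,
# in which case pad positions count as missing.
site_coverage <- function(scores, start, end, L = SITE_LEN) {
  s <- scores[(start + 1):end]
  sum(!is.na(s)) / L
}

#' Select positive training sites
#'
#' Keeps unified peaks whose reactivity coverage (fraction of the 101
#' positions with a non-missing score) is at least \code{min_coverage}, then
#' returns the top \code{k} by signal.
#'
#' @param peaks merged peak data.frame.
#' @param transcripts named character vector of sequences.
#' @param reactivity named list of profiles (one condition/merged replicate).
#' @param k number of sites to keep (default 5000).
#' @param min_coverage minimum coverage (default 0.40).
#' @param L site length.
#' @return data.frame of unified positive sites, signal-descending.
#' @export
select_positives <- function(peaks, transcripts, reactivity, k = 5000,
                             min_coverage = 0.40, L = SITE_LEN) {
  iv <- t(mapply(function(tx, s, e)
    unify_length(s, e, nchar(transcripts[[tx]]), L),
    peaks$transcript_id, peaks$start, peaks$end))
  peaks$start <- iv[, 1]
  peaks$end <- iv[, 2]
  cov <- mapply(function(tx, s, e)
    site_coverage(reactivity[[tx]]$scores, s, e, L),
    peaks$transcript_id, peaks$start, peaks$end)
  peaks <- peaks[cov >= min_coverage, , drop = FALSE]
  if (nrow(peaks) == 0) {
    stop("no peaks pass the coverage filter; lower min_coverage")
  }
  peaks <- peaks[order(-peaks$signal), , drop = FALSE]
  peaks <- utils::head(peaks, k)
  rownames(peaks) <- NULL
  peaks
}

#' Sample negative sites from the whole transcriptome
#'
#' Draws \code{n} windows of length \code{L} uniformly over all transcript
#' positions, requiring reactivity coverage >= \code{min_coverage} and zero
#' overlap with any positive site. Reproducible given \code{seed}.
#'
#' @param transcripts named character vector.
#' @param reactivity named list of profiles.
#' @param positives data.frame of positive sites.
#' @param n number of negatives (default 10000).
#' @param min_coverage minimum coverage.
#' @param seed RNG seed.
#' @param L window length.
#' @return data.frame with transcript_id, start, end.
#' @export
sample_negatives <- function(transcripts, reactivity, positives, n = 10000,
                             min_coverage = 0.40, seed = 1, L = SITE_LEN) {
  # enumerate every eligible window once, then sample uniformly
  elig <- lapply(names(transcripts), function(tx) {
    tl <- nchar(transcripts[[tx]])
    if (tl < L) return(NULL)
    starts <- 0:(tl - L)
    sc <- reactivity[[tx]]$scores
    ok_cov <- vapply(starts, function(s)
      sum(!is.na(sc[(s + 1):(s + L)])) / L >= min_coverage, logical(1))
    pos <- positives[positives$transcript_id == tx, , drop = FALSE]
    ok_pos <- vapply(starts, function(s)
      !any(overlaps(s, s + L, pos$start, pos$end)), logical(1))
    keep <- starts[ok_cov & ok_pos]
    if (length(keep) == 0) return(NULL)
    data.frame(transcript_id = tx, start = keep, stringsAsFactors = FALSE)
  })
  elig <- do.call(rbind, elig)
  if (is.null(elig) || nrow(elig) < n) {
    stop("only ", if (is.null(elig)) 0 else nrow(elig),
         " eligible negative windows; requested ", n)
  }
  idx <- with_seed(seed, sample.int(nrow(elig), n))
  out <- elig[idx, , drop = FALSE]
  out$end <- out$start + L
  rownames(out) <- NULL
  out
}

#' Encode a site as a 101 x 5 sequence-and-structure matrix
#'
#' Columns 1-4 one-hot encode A/C/G/U (all-zero for N or flank padding);
#' column 5 is the reactivity score in \[0,1\], with missing scores encoded
#' as exactly -1.
#'
#' @param sequence site sequence (length <= L; shorter sites are the result
#'   of clamping on short transcripts and are N-padded symmetrically).
#' @param scores reactivity over the same positions (NA = missing).
#' @param L site length.
#' @return an L x 5 numeric matrix.
#' @export
encode_site <- function(sequence, scores, L = SITE_LEN) {
  chars <- strsplit(sequence, "")[[1]]
  stopifnot(length(chars) == length(scores), length(chars) <= L)
  if (length(chars) < L) {      # pad flanks with N / missing
    add <- L - length(chars)
    left <- add %/% 2
    right <- add - left
    chars <- c(rep("N", left), chars, rep("N", right))
    scores <- c(rep(NA, left), scores, rep(NA, right))
  }
  bad <- !chars %in% c("A", "C", "G", "U", "N")
  if (any(bad)) stop("invalid letter '", chars[which(bad)[1]], "' in site")
  m <- matrix(0, nrow = L, ncol = 5,
              dimnames = list(NULL, c("A", "C", "G", "U", "icshape")))
  for (j in 1:4) m[chars == c("A", "C", "G", "U")[j], j] <- 1
  m[, 5] <- ifelse(is.na(scores), -1, scores)
  m
}

#' Decode an encoded site back to sequence and scores
#' @param m L x 5 matrix from [encode_site()].
#' @return list with \code{sequence} and \code{scores} (NA for missing).
#' @export
decode_site <- function(m) {
  letters4 <- c("A", "C", "G", "U")
  seq <- apply(m[, 1:4, drop = FALSE], 1, function(r) {
    i <- which(r == 1)
    if (length(i) == 1) letters4[i] else "N"
  })
  scores <- ifelse(m[, 5] == -1, NA, m[, 5])
  list(sequence = paste(seq, collapse = ""), scores = scores)
}

# Encode a list of site intervals against a transcriptome + reactivity set.
# Returns a 3d array (n_sites x L x 5) plus site ids.
encode_sites <- function(sites, transcripts, reactivity, L = SITE_LEN) {
  n <- nrow(sites)
  X <- array(0, dim = c(n, L, 5))
  ids <- character(n)
  for (i in seq_len(n)) {
    tx <- sites$transcript_id[i]
    s <- sites$start[i]; e <- sites$end[i]
    seq_i <- substr(transcripts[[tx]], s + 1, e)
    sc_i <- reactivity[[tx]]$scores[(s + 1):e]
    X[i, , ] <- encode_site(seq_i, sc_i, L)
    ids[i] <- paste0(tx, ":", s, "-", e)
  }
  list(X = X, ids = ids)
}

#' Assemble a labeled, stratified train/validation split
#'
#' Negatives are subsampled to \code{neg_ratio} times the positive count;
#' both classes are split 4:1 (train:validation) independently under the
#' seed, with the remainder going to train.
#'
#' @param positives,negatives site data.frames.
#' @param transcripts,reactivity inputs for encoding.
#' @param neg_ratio negatives per positive (default 2).
#' @param split_frac training fraction (default 0.8, i.e. 4:1).
#' @param seed RNG seed.
#' @param L site length.
#' @return list with \code{train}, \code{validation} (each \code{X} n x L x 5,
#'   \code{y} labels, \code{ids}), and \code{seed}.
#' @export
assemble_dataset <- function(positives, negatives, transcripts, reactivity,
                             neg_ratio = 2, split_frac = 0.8, seed = 1,
                             L = SITE_LEN) {
  n_pos <- nrow(positives)
  n_neg_want <- n_pos * neg_ratio
  if (nrow(negatives) < n_neg_want) {
    stop("need ", n_neg_want, " negatives, have ", nrow(negatives))
  }
  with_seed(seed, {
    negatives <- negatives[sample.int(nrow(negatives), n_neg_want), ,
                           drop = FALSE]
    enc_pos <- encode_sites(positives, transcripts, reactivity, L)
    enc_neg <- encode_sites(negatives, transcripts, reactivity, L)
    split_class <- function(n) {
      n_val <- floor(n * (1 - split_frac) + 1e-9)
      val <- sample.int(n, n_val)
      list(train = setdiff(seq_len(n), val), val = val)
    }
    sp <- split_class(n_pos)
    sn <- split_class(nrow(negatives))
    bind <- function(pi, ni) {
      X <- array(0, dim = c(length(pi) + length(ni), L, 5))
      if (length(pi)) X[seq_along(pi), , ] <- enc_pos$X[pi, , , drop = FALSE]
      if (length(ni)) X[length(pi) + seq_along(ni), , ] <-
          enc_neg$X[ni, , , drop = FALSE]
      list(X = X,
           y = c(rep(1, length(pi)), rep(0, length(ni))),
           ids = c(enc_pos$ids[pi], enc_neg$ids[ni]))
    }
    list(train = bind(sp$train, sn$train),
         validation = bind(sp$val, sn$val),
         seed = seed)
  })
}
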
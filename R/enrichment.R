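# Generic enrichment statistics: permutation tests of annotation overlap
# with region sets, the rare-vs-common odds ratio, and directional group
# comparisons of enrichment values.

# Count annotation positions falling inside query regions.
# `annotation` is a data.frame(transcript_id, position); `regions` is a
# data.frame(transcript_id, start, end), 0-based half-open.
count_in_regions <- function(regions, annotation) {
  total <- 0L
  for (tx in unique(regions$transcript_id)) {
    pos <- sort(annotation$position[annotation$transcript_id == tx])
    if (length(pos) == 0) next
    r <- regions[regions$transcript_id == tx, , drop = FALSE]
    total <- total + sum(findInterval(r$end - 1L, pos) -
                           findInterval(r$start - 1L, pos))
  }
  total
}

#' Permutation test of annotation enrichment in a region set
#'
#' Counts annotation positions inside the query regions, then draws
#' \code{n} resamples of equally many, length-matched regions uniformly
#' over the universe and recounts. The enrichment value is
#' observed / mean(resampled); the p-value is rank-based with the +1
#' correction, \code{(1 + #\{resample >= observed\}) / (n + 1)} for
#' enrichment (mirrored for depletion).
#'
#' @param query_regions data.frame(transcript_id, start, end).
#' @param annotation data.frame(transcript_id, position), 0-based.
#' @param universe named integer vector of transcript lengths from which
#'   random regions may be drawn.
#' @param n number of resamples (default 1000).
#' @param seed RNG seed.
#' @param alternative \code{"greater"} (enrichment) or \code{"less"}.
#' @return list: statistic, value, p_value, n_permutations, seed, observed,
#'   null_mean.
#' @export
permutation_enrichment <- function(query_regions, annotation, universe,
                                   n = 1000L, seed = 1,
                                   alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  n <- as.integer(n)
  widths <- query_regions$end - query_regions$start
  tx_names <- names(universe)
  max_w <- max(widths)
  if (!any(universe >= max_w)) {
    stop("universe has no transcript long enough for a resampled region")
  }
  observed <- count_in_regions(query_regions, annotation)
  # annotation positions on a concatenated coordinate axis (one global
  # offset per transcript) let every resample be counted with findInterval
  offsets <- c(0, cumsum(as.numeric(universe)))[seq_along(universe)]
  names(offsets) <- tx_names
  gann <- sort(offsets[annotation$transcript_id] + annotation$position)
  null_counts <- with_seed(seed, {
    total <- integer(n)
    for (w in unique(widths)) {
      nw <- sum(widths == w)
      elig <- universe >= w
      slots <- universe[elig] - w + 1L
      cum <- c(0, cumsum(as.numeric(slots)))
      draws <- sample(cum[length(cum)], n * nw, replace = TRUE)
      ti <- findInterval(draws - 1, cum, left.open = FALSE)
      # draw d in transcript ti at local start (d - cum[ti] - 1), 0-based
      gstart <- offsets[names(slots)[ti]] + (draws - cum[ti] - 1)
      cnt <- findInterval(gstart + w - 0.5, gann) -
        findInterval(gstart - 0.5, gann)
      total <- total + as.integer(rowsum(cnt, rep(seq_len(n), each = nw)))
    }
    total
  })
  null_mean <- mean(null_counts)
  value <- if (null_mean > 0) observed / null_mean else Inf
  p <- if (alternative == "greater") {
    (1 + sum(null_counts >= observed)) / (n + 1)
  } else {
    (1 + sum(null_counts <= observed)) / (n + 1)
  }
  list(statistic = "enrichment_ratio", value = value, p_value = p,
       n_permutations = n, seed = seed, observed = observed,
       null_mean = null_mean)
}

#' Odds ratio of rare versus common variant enrichment
#'
#' \code{OR = (rare_in_query / rare_random_mean) /
#' (common_in_query / common_random_mean)}, with the Haldane-Anscombe
#' correction on zero cells; one-sided Fisher p on the rounded 2 x 2 table.
#'
#' @param rare_in_query,rare_random_mean,common_in_query,common_random_mean
#'   observed counts and random-region mean counts.
#' @return list with \code{odds_ratio} and \code{p_value}.
#' @export
rare_vs_common_odds <- function(rare_in_query, rare_random_mean,
                                common_in_query, common_random_mean) {
  stopifnot(rare_in_query >= 0, common_in_query >= 0)
  if (rare_random_mean <= 0 || common_random_mean <= 0) {
    stop("random-region means must be positive")
  }
  num <- rare_in_query / rare_random_mean
  den <- common_in_query / common_random_mean
  if (rare_in_query == 0 || common_in_query == 0) {
    num <- (rare_in_query + 0.5) / (rare_random_mean + 0.5)
    den <- (common_in_query + 0.5) / (common_random_mean + 0.5)
  }
  p <- fisher_p_greater(rare_in_query, round(rare_random_mean),
                        common_in_query, round(common_random_mean))
  list(odds_ratio = num / den, p_value = p)
}

#' Pairwise one-sided Welch t-tests between groups
#'
#' Compares every ordered pair of groups with a one-sided (greater) Welch
#' two-sample t-test, e.g. enrichment odds ratios of the
#' SequenceAndStructure HAR group against the single-component groups.
#'
#' @param values_by_group named list of numeric vectors (>= 2 values each).
#' @return data.frame: group1, group2, t, df, p_value for the hypothesis
#'   mean(group1) > mean(group2).
#' @export
group_compare <- function(values_by_group) {
  ns <- vapply(values_by_group, length, integer(1))
  if (any(ns < 2)) {
    stop("every group needs >= 2 values; offending group: ",
         names(values_by_group)[ns < 2][1])
  }
  gn <- names(values_by_group)
  out <- list()
  for (i in seq_along(gn)) for (j in seq_along(gn)) {
    if (i == j) next
    tt <- stats::t.test(values_by_group[[i]], values_by_group[[j]],
                        alternative = "greater", var.equal = FALSE)
    out[[length(out) + 1]] <- data.frame(
      group1 = gn[i], group2 = gn[j],
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
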
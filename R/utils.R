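#' @keywords internal
"_PACKAGE"

# All coordinates inside the package are 0-based half-open [start, end).
# Converters to/from 1-based closed exist only at file boundaries.

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a child seed from a base seed and an offset, kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Convert a binding probability to a reverse-sigmoid binding score
#'
#' Applies the logit transform S = -ln(1/P - 1), turning a predicted binding
#' probability into an unbounded quantitative binding score. Probabilities are
#' clipped to \code{[1e-7, 1 - 1e-7]} so the score stays finite.
#'
#' @param p numeric vector of probabilities.
#' @return numeric vector of scores; 0 corresponds to P = 0.5.
#' @examples
#' probability_to_score(0.5)            # 0
#' probability_to_score(1 / (1 + exp(-2)))  # 2
#' @export
probability_to_score <- function(p) {
  stopifnot(is.numeric(p))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -log(1 / p - 1)
}

# Merge 0-based half-open intervals that overlap by >= 1 nt, per transcript.
# `df` needs columns transcript_id, start, end (optionally signal, summed).
merge_intervals <- function(df, sum_col = NULL) {
  if (nrow(df) == 0) return(df)
  out <- lapply(split(df, df$transcript_id), function(d) {
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    res <- data.frame(
      transcript_id = d$transcript_id[1],
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      stringsAsFactors = FALSE
    )
    if (!is.null(sum_col)) {
      rv <- S4Vectors::mcols(red)$revmap
      res[[sum_col]] <- vapply(rv, function(ix) sum(d[[sum_col]][ix]), numeric(1))
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$transcript_id, out$start), , drop = FALSE]
}

# Does interval [s1,e1) overlap [s2,e2) by at least 1 nt?
overlaps <- function(s1, e1, s2, e2) pmax(s1, s2) < pmin(e1, e2)

# Nearest-rank empirical quantile: the ceiling(p*n)-th smallest value.
nearest_rank_quantile <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}
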
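# SmoothGrad saliency maps and high-attention-region (HAR) extraction.
# The attribution is M(x) = x (.) mean_n g(x + N(0, sigma^2)) with
# g(x) = d output / d input computed by backpropagation in eval mode.

#' SmoothGrad saliency map for one encoded site
#'
#' Draws \code{n} noisy copies of the input, averages the input gradients of
#' the predicted binding probability, and multiplies elementwise by the
#' input. With \code{n = 1, noise_std = 0} this reduces to plain
#' gradient-times-input.
#'
#' @param model trained model.
#' @param x encoded site (L x D matrix).
#' @param n number of noisy samples (default 10).
#' @param noise_std Gaussian noise standard deviation (default 0.15).
#' @param seed RNG seed for the noise draws.
#' @param guided use guided backpropagation (positive-gradient gating at
#'   ReLUs) instead of plain gradients.
#' @return list with \code{attribution} (L x D), \code{seq_response},
#'   \code{struct_response} (length-L), \code{probability} and the smoothing
#'   parameters.
#' @export
smoothgrad <- function(model, x, n = 10L, noise_std = 0.15, seed = 1,
                       guided = FALSE) {
  if (n < 1) stop("n must be >= 1")
  L <- nrow(x); D <- ncol(x)
  Xb <- with_seed(seed, {
    noise <- if (noise_std > 0) {
      array(stats::rnorm(n * L * D, 0, noise_std), c(n, L, D))
    } else array(0, c(n, L, D))
    sweep(noise, c(2, 3), x, "+")
  })
  fw <- forward_pass(model, Xb, "eval", keep_cache = TRUE)
  bw <- backward_pass(model, fw$cache, rep(1, n), guided = guided)
  g <- apply(bw$dX, c(2, 3), mean)
  attribution <- x * g
  resp <- component_response(attribution)
  list(attribution = attribution,
       seq_response = resp$seq_response,
       struct_response = resp$struct_response,
       probability = forward_pass(model, x, "eval")$y,
       n = n, noise_std = noise_std, seed = seed)
}

#' Reduce an L x 5 attribution to sequence and structure response tracks
#'
#' The sequence response at a position is the sum of the positive parts of
#' the four one-hot channel attributions; the structure response is the
#' absolute attribution of the reactivity channel.
#'
#' @param attribution L x 5 matrix.
#' @return list with \code{seq_response} and \code{struct_response}.
#' @export
component_response <- function(attribution) {
  list(seq_response = rowSums(pmax(attribution[, 1:4, drop = FALSE], 0)),
       struct_response = abs(attribution[, 5]))
}

# Means of all sliding windows of `window` over `x` at step 1.
window_means <- function(x, window) {
  cs <- c(0, cumsum(x))
  n <- length(x) - window + 1L
  (cs[(window + 1):(window + n)] - cs[1:n]) / window
}

#' Find high-attention regions in a response track
#'
#' Scans 20-nt windows at 1-nt steps. In \code{"single"} mode the window
#' with the highest mean response is returned (leftmost on ties). In
#' \code{"top20pct"} mode the top 20\% of windows by mean response are
#' retained (count rounded up) and overlapping ones merged into disjoint
#' intervals.
#'
#' @param response numeric length-L response track.
#' @param window window size (default 20).
#' @param mode \code{"single"} or \code{"top20pct"}.
#' @param top_frac fraction retained in top20pct mode.
#' @return data.frame with start, end (0-based half-open within the site)
#'   and mean_response.
#' @export
find_hars <- function(response, window = 20L, mode = c("single", "top20pct"),
                      top_frac = 0.2) {
  mode <- match.arg(mode)
  L <- length(response)
  stopifnot(L >= window)
  wm <- window_means(response, window)
  if (mode == "single") {
    s <- which.max(wm) - 1L     # which.max is leftmost on ties
    return(data.frame(start = s, end = s + window, mean_response = wm[s + 1]))
  }
  n_keep <- ceiling(top_frac * length(wm))
  keep <- order(-wm)[seq_len(n_keep)]
  df <- data.frame(transcript_id = "site", start = keep - 1L,
                   end = keep - 1L + window, stringsAsFactors = FALSE)
  merged <- merge_intervals(df)
  merged$mean_response <- vapply(seq_len(nrow(merged)), function(i)
    mean(response[(merged$start[i] + 1):merged$end[i]]), numeric(1))
  merged[, c("start", "end", "mean_response")]
}

#' Group sequence and structure HARs of one site
#'
#' Sequence and structure HARs overlapping by at least 1 nt are labeled
#' \code{SequenceAndStructure}; the rest keep their single-component label.
#'
#' @param seq_hars,struct_hars HAR data.frames from [find_hars()].
#' @return data.frame with start, end, component, group.
#' @export
group_hars <- function(seq_hars, struct_hars) {
  tag <- function(d, comp) {
    if (nrow(d) == 0) return(NULL)
    d$component <- comp
    d
  }
  sh <- tag(seq_hars, "sequence")
  th <- tag(struct_hars, "structure")
  label <- function(d, other, only_label) {
    if (is.null(d)) return(NULL)
    d$group <- vapply(seq_len(nrow(d)), function(i) {
      if (!is.null(other) &&
          any(overlaps(d$start[i], d$end[i], other$start, other$end))) {
        "SequenceAndStructure"
      } else only_label
    }, character(1))
    d
  }
  out <- rbind(label(sh, th, "SequenceOnly"),
               label(th, sh, "StructureOnly"))
  rownames(out) <- NULL
  out[, c("start", "end", "component", "group", "mean_response")]
}
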
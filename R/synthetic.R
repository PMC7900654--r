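# Seeded generator of synthetic transcriptomes with planted binding rules:
# i.i.d. ACGU background (chance motif occurrences are mutated away so every
# consensus occurrence is planted), a block-wise paired/unpaired architecture,
# two-state reactivity with replicate noise and missing values, peaks emitted
# for bound sites, a second condition with planted structure flips, and
# variant tables with known riboSNitch/VSS labels. Ground truth is returned
# (and serialized as JSON) for every planted feature.

#' Specification of a synthetic benchmark dataset
#'
#' @param n_transcripts number of transcripts (default 200).
#' @param length transcript length in nt (default 500).
#' @param motif planted sequence consensus (default "GCAUG").
#' @param structure_context structure state required for binding at the
#'   motif: \code{"unpaired"}, \code{"paired"} or \code{"none"} (sequence
#'   alone suffices).
#' @param plant_rate probability that a transcript carries a planted motif.
#' @param bound_fraction fraction of planted motifs placed in the required
#'   context (the rest are decoys in the opposite context).
#' @param unpaired_mean,paired_mean reactivity means of the two states,
#'   chosen so the 0.233 binarization threshold separates them.
#' @param reactivity_noise,replicate_noise Gaussian sds of the condition
#'   profile and of each replicate around it.
#' @param missing_rate per-position probability of a missing score.
#' @param n_svs number of transcripts given a planted 20-nt structure flip
#'   in condition B.
#' @param svs_width width of the planted flip (default 20).
#' @param n_var_in_svs,n_var_outside,n_var_same planted variant counts:
#'   differing alleles inside a planted flip, differing alleles outside any
#'   flip, and same-allele controls.
#' @param seed RNG seed.
#' @return a \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_transcripts = 200L, length = 500L,
                           motif = "GCAUG",
                           structure_context = c("unpaired", "paired", "none"),
                           plant_rate = 1.0, bound_fraction = 0.5,
                           unpaired_mean = 0.7, paired_mean = 0.1,
                           reactivity_noise = 0.1, replicate_noise = 0.05,
                           missing_rate = 0.1, n_svs = 0L, svs_width = 20L,
                           n_var_in_svs = 0L, n_var_outside = 0L,
                           n_var_same = 0L, seed = 1L) {
  structure_context <- match.arg(structure_context)
  stopifnot(plant_rate >= 0, plant_rate <= 1, bound_fraction >= 0,
            bound_fraction <= 1, missing_rate >= 0, missing_rate < 1,
            grepl("^[ACGU]+$", motif))
  if (nchar(motif) > length) stop("motif longer than transcripts")
  structure(as.list(environment()), class = "synthetic_spec")
}

# Replace chance occurrences of the consensus outside planted sites by
# mutating one base, so motif occurrences and ground truth stay consistent.
scrub_motif <- function(seq_chars, motif_chars, keep_start) {
  k <- length(motif_chars)
  n <- length(seq_chars)
  repeat {
    hits <- integer(0)
    if (n >= k) {
      for (s in 1:(n - k + 1)) {
        if (all(seq_chars[s:(s + k - 1)] == motif_chars) &&
            !identical(s, keep_start)) hits <- c(hits, s)
      }
    }
    if (length(hits) == 0) return(seq_chars)
    for (s in hits) {
      js <- s:(s + k - 1)
      if (!is.null(keep_start)) {          # never touch the planted motif
        js <- setdiff(js, keep_start:(keep_start + k - 1))
      }
      j <- if (length(js) == 1) js else sample(js, 1)
      seq_chars[j] <- sample(setdiff(c("A", "C", "G", "U"), seq_chars[j]), 1)
    }
  }
}

state_to_reactivity <- function(state, spec) {
  mu <- ifelse(state == "U", spec$unpaired_mean, spec$paired_mean)
  pmin(pmax(mu + stats::rnorm(length(mu), 0, spec$reactivity_noise), 0), 1)
}

#' Generate a synthetic dataset with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir if non-NULL, write FASTA, reactivity tables (2 conditions
#'   x 2 replicates + per-condition merged), peaks BED, a variants TSV and
#'   a ground-truth JSON into this directory.
#' @return list with \code{transcripts}, \code{reactivity} (nested
#'   condition/replicate lists), \code{merged} (per-condition profiles),
#'   \code{peaks}, \code{variants}, \code{truth}.
#' @export
generate_synthetic <- function(spec, out_dir = NULL) {
  motif_chars <- strsplit(spec$motif, "")[[1]]
  k <- length(motif_chars)
  with_seed(spec$seed, {
    transcripts <- character(spec$n_transcripts)
    names(transcripts) <- sprintf("tx%04d", seq_len(spec$n_transcripts))
    states_a <- states_b <- vector("list", spec$n_transcripts)
    planted <- list(); svs_truth <- list(); peak_rows <- list()
    svs_tx <- if (spec$n_svs > 0) {
      sample(names(transcripts), min(spec$n_svs, spec$n_transcripts))
    } else character(0)

    for (ti in seq_len(spec$n_transcripts)) {
      tx <- names(transcripts)[ti]
      len <- spec$length
      sq <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
      # block-wise paired/unpaired architecture
      st <- character(0)
      cur <- sample(c("U", "P"), 1)
      while (length(st) < len) {
        st <- c(st, rep(cur, sample(15:40, 1)))
        cur <- if (cur == "U") "P" else "U"
      }
      st <- st[1:len]

      has_site <- stats::runif(1) < spec$plant_rate && len >= k + 120
      mstart <- NA_integer_; context <- NA_character_; bound <- FALSE
      if (has_site) {
        mstart <- sample(60:(len - k - 60), 1)   # 1-based start
        sq[mstart:(mstart + k - 1)] <- motif_chars
        in_required <- stats::runif(1) < spec$bound_fraction
        context <- if (spec$structure_context == "none") {
          sample(c("U", "P"), 1)
        } else if (in_required == (spec$structure_context == "unpaired")) {
          "U"
        } else "P"
        ctx_lo <- max(1, mstart - 5); ctx_hi <- min(len, mstart + k + 4)
        st[ctx_lo:ctx_hi] <- context
        bound <- spec$structure_context == "none" ||
          context == ifelse(spec$structure_context == "unpaired", "U", "P")
      }
      sq <- scrub_motif(sq, motif_chars, if (has_site) mstart else NULL)
      transcripts[ti] <- paste(sq, collapse = "")
      states_a[[ti]] <- st

      stb <- st
      if (tx %in% svs_tx) {
        repeat {
          s0 <- sample(30:(len - spec$svs_width - 30), 1)
          if (!has_site ||
              !overlaps(s0 - 1, s0 - 1 + spec$svs_width,
                        mstart - 6, mstart + k + 4)) break
        }
        stb[s0:(s0 + spec$svs_width - 1)] <-
          ifelse(stb[s0:(s0 + spec$svs_width - 1)] == "U", "P", "U")
        svs_truth[[tx]] <- data.frame(
          transcript_id = tx, start = s0 - 1L,
          end = s0 - 1L + spec$svs_width, stringsAsFactors = FALSE)
      }
      states_b[[ti]] <- stb

      if (has_site) {
        planted[[tx]] <- data.frame(
          transcript_id = tx, motif_start = mstart - 1L,
          motif_end = mstart - 1L + k, context = context, bound = bound,
          stringsAsFactors = FALSE)
        if (bound) {
          for (rep_id in c("rep1", "rep2")) {
            ps <- max(0L, mstart - 1L - sample(20:45, 1))
            pe <- min(len, mstart - 1L + k + sample(20:45, 1))
            quality <- 2 + stats::rnorm(1, 0, 1)
            peak_rows[[length(peak_rows) + 1]] <- data.frame(
              transcript_id = tx, start = ps, end = pe,
              signal = 10 * stats::plogis(quality), replicate = rep_id,
              stringsAsFactors = FALSE)
          }
        }
      }
    }

    # reactivity: one biological base profile per transcript (state means +
    # profile noise); condition B keeps the base value wherever the state is
    # unchanged and redraws only flipped positions, so cross-condition
    # differences outside planted changes reflect technical (replicate)
    # noise alone; each replicate adds its own noise; missing positions are
    # dropped independently
    add_reps <- function(base) {
      reps <- lapply(c("rep1", "rep2"), function(r) {
        s <- pmin(pmax(base + stats::rnorm(length(base), 0,
                                           spec$replicate_noise), 0), 1)
        s[stats::runif(length(s)) < spec$missing_rate] <- NA
        s
      })
      names(reps) <- c("rep1", "rep2")
      reps
    }
    cond_a <- vector("list", spec$n_transcripts)
    cond_b <- vector("list", spec$n_transcripts)
    for (ti in seq_len(spec$n_transcripts)) {
      base_a <- state_to_reactivity(states_a[[ti]], spec)
      base_b <- base_a
      flip <- which(states_b[[ti]] != states_a[[ti]])
      if (length(flip) > 0) {
        base_b[flip] <- state_to_reactivity(states_b[[ti]][flip], spec)
      }
      cond_a[[ti]] <- add_reps(base_a)
      cond_b[[ti]] <- add_reps(base_b)
    }
    wrap <- function(cond, cname, rname) {
      out <- lapply(seq_along(cond), function(ti)
        list(transcript_id = names(transcripts)[ti], condition = cname,
             replicate = rname, scores = cond[[ti]][[rname]]))
      names(out) <- names(transcripts)
      out
    }
    merge_reps <- function(cond, cname) {
      out <- lapply(seq_along(cond), function(ti) {
        m <- rowMeans(cbind(cond[[ti]]$rep1, cond[[ti]]$rep2), na.rm = TRUE)
        m[is.nan(m)] <- NA
        list(transcript_id = names(transcripts)[ti], condition = cname,
             replicate = "merged", scores = m)
      })
      names(out) <- names(transcripts)
      out
    }
    reactivity <- list(
      A = list(rep1 = wrap(cond_a, "A", "rep1"),
               rep2 = wrap(cond_a, "A", "rep2")),
      B = list(rep1 = wrap(cond_b, "B", "rep1"),
               rep2 = wrap(cond_b, "B", "rep2")))
    merged <- list(A = merge_reps(cond_a, "A"), B = merge_reps(cond_b, "B"))

    peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
      data.frame(transcript_id = character(), start = integer(),
                 end = integer(), signal = numeric(),
                 replicate = character())
    planted_df <- if (length(planted)) do.call(rbind, planted) else
      data.frame(transcript_id = character(), motif_start = integer(),
                 motif_end = integer(), context = character(),
                 bound = logical())
    svs_df <- if (length(svs_truth)) do.call(rbind, svs_truth) else
      data.frame(transcript_id = character(), start = integer(),
                 end = integer())
    rownames(peaks) <- rownames(planted_df) <- rownames(svs_df) <- NULL

    variants <- plant_variants(spec, transcripts, svs_df)

    truth <- list(planted = planted_df, svs = svs_df,
                  variants = variants$truth, seed = spec$seed)
    res <- list(transcripts = transcripts, reactivity = reactivity,
                merged = merged, peaks = peaks, variants = variants$table,
                truth = truth)
    if (!is.null(out_dir)) write_synthetic(res, out_dir)
    res
  })
}

# Plant variants: differing alleles inside planted SVS windows (expected
# riboSNitches), differing alleles outside (expected VSSs), and same-allele
# controls (excluded by classification).
plant_variants <- function(spec, transcripts, svs_df) {
  rows <- list(); truth <- list()
  pick_base <- function() sample(c("A", "C", "G", "U"), 1)
  add <- function(tx, pos, differ, expected) {
    a1 <- pick_base()
    a2 <- if (differ) sample(setdiff(c("A", "C", "G", "U"), a1), 1) else a1
    rows[[length(rows) + 1]] <<- data.frame(
      transcript_id = tx, position = pos,
      condition = c("A", "B"), allele = c(a1, a2), stringsAsFactors = FALSE)
    truth[[length(truth) + 1]] <<- data.frame(
      transcript_id = tx, position = pos, expected = expected,
      stringsAsFactors = FALSE)
  }
  if (spec$n_var_in_svs > 0 && nrow(svs_df) > 0) {
    for (i in seq_len(spec$n_var_in_svs)) {
      r <- svs_df[1 + (i - 1) %% nrow(svs_df), ]
      add(r$transcript_id, r$start + sample.int(r$end - r$start, 1) - 1L,
          TRUE, "riboSNitch")
    }
  }
  if (spec$n_var_outside > 0) {
    txs <- names(transcripts)
    for (i in seq_len(spec$n_var_outside)) {
      repeat {
        tx <- sample(txs, 1)
        pos <- sample.int(nchar(transcripts[[tx]]), 1) - 1L
        s <- svs_df[svs_df$transcript_id == tx, , drop = FALSE]
        if (nrow(s) == 0 || !any(pos >= s$start & pos < s$end)) break
      }
      add(tx, pos, TRUE, "VSS")
    }
  }
  if (spec$n_var_same > 0) {
    for (i in seq_len(spec$n_var_same)) {
      tx <- sample(names(transcripts), 1)
      add(tx, sample.int(nchar(transcripts[[tx]]), 1) - 1L, FALSE,
          "excluded")
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(transcript_id = character(), position = integer(),
                    condition = character(), allele = character()),
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(transcript_id = character(), position = integer(),
                    expected = character()))
}

# Serialize a generated dataset into the package's file formats.
write_synthetic <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_transcriptome(res$transcripts, file.path(out_dir, "transcripts.fa"))
  for (cn in names(res$reactivity)) {
    for (rn in names(res$reactivity[[cn]])) {
      write_reactivity(res$reactivity[[cn]][[rn]],
                       file.path(out_dir, sprintf("shape_%s_%s.tsv", cn, rn)))
    }
    write_reactivity(res$merged[[cn]],
                     file.path(out_dir, sprintf("shape_%s_merged.tsv", cn)))
  }
  write_peaks(res$peaks, file.path(out_dir, "peaks.bed"))
  write_variants(res$variants, file.path(out_dir, "variants.tsv"))
  jsonlite::write_json(res$truth, file.path(out_dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(out_dir)
}

#' Build a labeled benchmark split from a synthetic dataset
#'
#' Runs the real data-preparation pipeline on the generated peaks
#' (per-replicate normalization, overlap merging, 101-nt unification,
#' coverage filtering, top-k selection), adds decoy windows (planted motif
#' in the wrong structure context) and random sampled windows as negatives
#' at \code{neg_ratio} per positive, and assembles a stratified 4:1 split.
#'
#' @param spec a [synthetic_spec()] (needs both bound and decoy sites unless
#'   \code{structure_context = "none"}).
#' @param condition which condition's reactivity to use (default "A").
#' @param neg_ratio negatives per positive.
#' @param seed RNG seed for negative sampling and the split.
#' @return list with \code{data} (the generated dataset), \code{split},
#'   \code{positives}, \code{negatives}.
#' @export
make_benchmark <- function(spec, condition = "A", neg_ratio = 2, seed = 1L) {
  data <- generate_synthetic(spec)
  reactivity <- data$merged[[condition]]
  if (nrow(data$peaks) == 0) stop("no bound sites generated; benchmark empty")
  norm <- do.call(rbind, lapply(split(data$peaks, data$peaks$replicate),
                                normalize_replicate))
  merged_peaks <- merge_replicates(norm)
  positives <- select_positives(merged_peaks, data$transcripts, reactivity,
                                k = 5000)
  # decoy negatives: planted motifs in the non-binding context
  decoys <- data$truth$planted[!data$truth$planted$bound, , drop = FALSE]
  neg_decoy <- NULL
  if (nrow(decoys) > 0) {
    iv <- t(vapply(seq_len(nrow(decoys)), function(i) {
      ctr <- (decoys$motif_start[i] + decoys$motif_end[i]) %/% 2
      unify_length(max(0, ctr - 50), ctr + 51,
                   nchar(data$transcripts[[decoys$transcript_id[i]]]))
    }, integer(2)))
    neg_decoy <- data.frame(transcript_id = decoys$transcript_id,
                            start = iv[, 1], end = iv[, 2],
                            stringsAsFactors = FALSE)
    cov <- vapply(seq_len(nrow(neg_decoy)), function(i)
      site_coverage(reactivity[[neg_decoy$transcript_id[i]]]$scores,
                    neg_decoy$start[i], neg_decoy$end[i]), numeric(1))
    neg_decoy <- neg_decoy[cov >= 0.4, , drop = FALSE]
  }
  n_random <- max(0, nrow(positives) * neg_ratio -
                    if (is.null(neg_decoy)) 0 else nrow(neg_decoy))
  neg_rand <- if (n_random > 0) {
    avoid <- rbind(positives[, c("transcript_id", "start", "end")],
                   if (!is.null(neg_decoy)) neg_decoy[, c("transcript_id",
                                                          "start", "end")])
    sample_negatives(data$transcripts, reactivity, avoid,
                     n = n_random, seed = derive_seed(seed, 11L))
  } else NULL
  negatives <- rbind(neg_decoy,
                     if (!is.null(neg_rand))
                       neg_rand[, c("transcript_id", "start", "end")])
  split <- assemble_dataset(positives, negatives, data$transcripts,
                            reactivity, neg_ratio = neg_ratio,
                            seed = derive_seed(seed, 13L))
  list(data = data, split = split, positives = positives,
       negatives = negatives)
}
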
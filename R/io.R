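# Readers and writers for the external formats the toolkit touches.
# Internal convention everywhere: 0-based half-open coordinates; RNA alphabet
# {A,C,G,U,N}; missing reactivity is NA (never a number in [0,1]).

#' Read a transcriptome from a FASTA file
#'
#' Sequences are uppercased and DNA input (T) is converted to U; any letter
#' outside \{A,C,G,U,N\} is an error, as is a duplicated record id.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences (names are transcript ids),
#'   in file order.
#' @export
read_transcriptome <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate transcript id in FASTA: ", dup[1])
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    stop("invalid letters in transcript ", ids[which(bad)[1]],
         " (only A, C, G, U/T, N allowed)")
  }
  names(seqs) <- ids
  seqs
}

#' Write a transcriptome to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_transcriptome <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read per-nucleotide reactivity profiles
#'
#' Each row of the tab-separated file is \code{transcript_id<TAB>length<TAB>}
#' followed by \code{length} comma-separated scores in \[0,1\], with the token
#' \code{NULL} marking a missing value. Missing values are returned as NA.
#'
#' @param path reactivity table.
#' @param condition,replicate metadata labels attached to every profile.
#' @return list of profiles, each a list with \code{transcript_id},
#'   \code{condition}, \code{replicate} and numeric \code{scores} (NA =
#'   missing); named by transcript id.
#' @export
read_reactivity <- function(path, condition = "cond1", replicate = "rep1") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed reactivity row ", i)
    len <- as.integer(f[2])
    toks <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    if (length(toks) != len) {
      stop("row ", i, " (", f[1], "): declared length ", len,
           " but ", length(toks), " values")
    }
    scores <- suppressWarnings(as.numeric(ifelse(toks == "NULL", NA, toks)))
    bad <- which(!is.na(scores) & (scores < 0 | scores > 1))
    if (length(bad) > 0) {
      stop("row ", i, " (", f[1], "): score out of [0,1] at value ", bad[1])
    }
    ids[i] <- f[1]
    out[[i]] <- list(transcript_id = f[1], condition = condition,
                     replicate = replicate, scores = scores)
  }
  names(out) <- ids
  out
}

#' Write reactivity profiles in the package's tabular dialect
#' @param profiles list as returned by [read_reactivity()].
#' @param path output file.
#' @export
write_reactivity <- function(profiles, path) {
  lines <- vapply(profiles, function(p) {
    toks <- ifelse(is.na(p$scores), "NULL",
                   formatC(p$scores, format = "g", digits = 15))
    paste(p$transcript_id, length(p$scores), paste(toks, collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read RBP binding peaks from a BED-like file
#'
#' Columns: transcript_id, start, end, signal and optionally replicate
#' (default \code{"rep1"}). Coordinates are 0-based half-open. Output is
#' sorted by (transcript_id, start).
#'
#' @param path peak file (tab-separated, no header).
#' @return data.frame with columns transcript_id, start, end, signal,
#'   replicate.
#' @export
read_peaks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(df) < 4) stop("peak file needs >= 4 columns")
  names(df)[1:4] <- c("transcript_id", "start", "end", "signal")
  if (ncol(df) >= 5) {
    names(df)[5] <- "replicate"
    df$replicate[is.na(df$replicate) | df$replicate == ""] <- "rep1"
  } else df$replicate <- "rep1"
  df <- df[, c("transcript_id", "start", "end", "signal", "replicate")]
  if (any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1]
    stop("peak row ", i, ": end <= start")
  }
  if (any(df$signal < 0)) stop("negative peak signal at row ",
                               which(df$signal < 0)[1])
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write binding peaks to a BED-like file
#' @param peaks data.frame as from [read_peaks()].
#' @param path output file.
#' @export
write_peaks <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a variant table for riboSNitch analysis
#'
#' Long-format TSV with header columns \code{transcript_id}, \code{position}
#' (0-based), \code{condition}, \code{allele}; rows for the same
#' (transcript, position) across conditions form one variant call.
#'
#' @param path variant table.
#' @return data.frame with one row per (variant, condition).
#' @export
read_variants <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "condition", "allele")
  if (!all(need %in% names(df))) {
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  }
  key <- paste(df$transcript_id, df$position)
  ncond <- tapply(df$condition, key, function(x) length(unique(x)))
  if (any(ncond < 2)) {
    stop("variant with fewer than 2 conditions: ", names(ncond)[ncond < 2][1])
  }
  df
}

#' Write variants in the long TSV dialect read by [read_variants()]
#' @param variants data.frame.
#' @param path output file.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- integrative motif serialization -------------------------------------
# MEME-minimal text for the 4x6 sequence PWM, extended with a parallel
# "structure-probability matrix" block (rows U = unpaired, P = paired) and
# the motif weight.

#' Write integrative motifs to a MEME-style text file
#'
#' @param motifs a single motif (list with \code{seq_pwm} 4xW, rows
#'   A/C/G/U; \code{struct_pwm} 2xW, rows U/P; \code{weight}; optionally
#'   \code{support}, \code{enrichment_p}, \code{name}) or a list of motifs.
#' @param path output file.
#' @export
write_motifs <- function(motifs, path) {
  if (!is.null(motifs$seq_pwm)) motifs <- list(motifs)
  lines <- c("MEME version 4", "", "ALPHABET= ACGU", "")
  for (k in seq_along(motifs)) {
    m <- motifs[[k]]
    w <- ncol(m$seq_pwm)
    if (any(abs(colSums(m$seq_pwm) - 1) > 1e-6) ||
        any(abs(colSums(m$struct_pwm) - 1) > 1e-6)) {
      stop("motif ", k, ": PWM columns must sum to 1")
    }
    name <- if (!is.null(m$name)) m$name else paste0("motif_", k)
    support <- if (!is.null(m$support)) m$support else 0L
    ep <- if (!is.null(m$enrichment_p)) m$enrichment_p else NA_real_
    fmt_rows <- function(pwm) {
      apply(t(pwm), 1, function(r)
        paste(formatC(r, format = "g", digits = 12), collapse = " "))
    }
    lines <- c(lines,
      paste("MOTIF", name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= %s",
              w, support, formatC(ep, format = "g", digits = 12)),
      fmt_rows(m$seq_pwm),
      sprintf("structure-probability matrix: alength= 2 w= %d", w),
      fmt_rows(m$struct_pwm),
      paste0("weight= ", formatC(m$weight, format = "g", digits = 15)),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read integrative motifs written by [write_motifs()]
#' @param path motif file.
#' @return list of motifs.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  if (length(starts) == 0) stop("no MOTIF blocks in ", path)
  parse_matrix <- function(at, nrows) {
    rows <- lines[(at + 1):(at + nrows)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"), as.numeric,
                  numeric(length(strsplit(trimws(rows[1]), "\\s+")[[1]]))))
    t(m)  # stored row-per-position; return letters x positions
  }
  lapply(starts, function(s) {
    name <- sub("^MOTIF ", "", lines[s])
    hdr <- lines[s + 1]
    w <- as.integer(sub(".* w= (\\d+).*", "\\1", hdr))
    support <- as.integer(sub(".* nsites= (\\d+).*", "\\1", hdr))
    ep <- suppressWarnings(as.numeric(sub(".* E= ([^ ]+).*", "\\1", hdr)))
    seq_pwm <- parse_matrix(s + 1, w)
    rownames(seq_pwm) <- c("A", "C", "G", "U")
    sp_at <- s + 1 + w + 1
    struct_pwm <- parse_matrix(sp_at, w)
    rownames(struct_pwm) <- c("U", "P")
    wline <- lines[sp_at + w + 1]
    weight <- as.numeric(sub("^weight= ", "", wline))
    list(name = name, seq_pwm = seq_pwm, struct_pwm = struct_pwm,
         weight = weight, support = support, enrichment_p = ep)
  })
}
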
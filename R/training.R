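# Optimization loop with Adam, linear learning-rate warmup, global gradient
# clipping, per-epoch validation AUROC model selection and early stopping;
# evaluation metrics; sliding-window whole-transcriptome prediction.

#' Training configuration
#'
#' @param base_lr base learning rate (default 0.001).
#' @param batch_size mini-batch size (default 64).
#' @param max_epochs maximal epoch count (default 200).
#' @param patience early-stopping patience in epochs (default 20).
#' @param grad_clip global gradient max-norm (default 5.0).
#' @param warmup_steps optimizer steps of linear LR ramp 0 -> base_lr
#'   (default 500).
#' @param pos_weight positive-class loss weight p_c (default 2).
#' @param lambda L2 penalty (default 1e-6).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and epsilon.
#' @param seed RNG seed for shuffling and dropout.
#' @return a \code{train_config} list.
#' @export
train_config <- function(base_lr = 0.001, batch_size = 64L, max_epochs = 200L,
                         patience = 20L, grad_clip = 5.0, warmup_steps = 500L,
                         pos_weight = 2, lambda = 1e-6, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8, seed = 1L) {
  stopifnot(base_lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1,
            grad_clip > 0, patience <= max_epochs)
  structure(as.list(environment()), class = "train_config")
}

# Scale a gradient list so its global L2 norm is at most `max_norm`.
clip_gradients <- function(grads, max_norm) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (nrm > max_norm) grads <- lapply(grads, function(g) g * (max_norm / nrm))
  grads
}

#' Train a model
#'
#' Adam with linear warmup and global-norm gradient clipping; after every
#' epoch the validation AUROC is computed in eval mode and the parameters of
#' the best-AUROC epoch are retained; training stops after \code{patience}
#' epochs without improvement or at \code{max_epochs}.
#'
#' @param model model from [build_model()].
#' @param data dataset split from [assemble_dataset()] (or any list with
#'   \code{train}/\code{validation}, each holding \code{X} and \code{y}).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch metrics.
#' @return list with the best \code{model}, \code{history} data.frame
#'   (epoch, train_loss, val_auroc), \code{best_auroc}, \code{best_epoch}.
#' @export
train_model <- function(model, data, cfg = train_config(), verbose = FALSE) {
  yv <- data$validation$y
  if (length(unique(yv)) < 2) {
    stop("validation set must contain both classes (AUROC undefined)")
  }
  Xtr <- data$train$X; ytr <- data$train$y
  n <- dim(Xtr)[1]
  m_state <- lapply(model$params, function(w) array(0, dim(w) %||% length(w)))
  v_state <- lapply(model$params, function(w) array(0, dim(w) %||% length(w)))
  step <- 0L
  best <- list(auroc = -Inf, epoch = 0L, params = model$params,
               state = model$state)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_auroc = numeric())
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0; nb <- 0L
      for (s in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[s:min(n, s + cfg$batch_size - 1L)]
        fw <- forward_pass(model, Xtr[idx, , , drop = FALSE], "train",
                           keep_cache = TRUE)
        model <- fw$model
        ls <- bce_loss(fw$y, ytr[idx], model$params, cfg$pos_weight,
                       cfg$lambda)
        bw <- backward_pass(model, fw$cache, ls$dy)
        grads <- add_l2_grad(bw$grads, model$params, cfg$lambda)
        grads <- clip_gradients(grads, cfg$grad_clip)
        step <- step + 1L
        lr <- cfg$base_lr * min(1, step / cfg$warmup_steps)
        bc1 <- 1 - cfg$adam_beta1^step
        bc2 <- 1 - cfg$adam_beta2^step
        for (nm in names(model$params)) {
          g <- grads[[nm]]
          m_state[[nm]] <- cfg$adam_beta1 * m_state[[nm]] +
            (1 - cfg$adam_beta1) * g
          v_state[[nm]] <- cfg$adam_beta2 * v_state[[nm]] +
            (1 - cfg$adam_beta2) * g^2
          model$params[[nm]] <- model$params[[nm]] -
            lr * (m_state[[nm]] / bc1) / (sqrt(v_state[[nm]] / bc2) +
                                            cfg$adam_eps)
        }
        epoch_loss <- epoch_loss + ls$loss; nb <- nb + 1L
      }
      yhat <- predict_batch(model, data$validation$X)
      auroc <- compute_auroc(yv, yhat)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = epoch_loss / nb,
                                           val_auroc = auroc))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val AUROC %.4f",
                        epoch, epoch_loss / nb, auroc))
      }
      if (auroc > best$auroc) {
        best <- list(auroc = auroc, epoch = epoch, params = model$params,
                     state = model$state)
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }
  })
  model$params <- best$params
  model$state <- best$state
  list(model = model, history = history, best_auroc = best$auroc,
       best_epoch = best$epoch)
}

#' Rank-based AUROC with midrank tie handling
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return AUROC in \[0,1\].
#' @export
compute_auroc <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC needs both classes")
  r <- rank(scores)                           # midranks on ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (trapezoidal)
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return AUPRC in \[0,1\].
#' @export
compute_auprc <- function(labels, scores) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || sum(labels == 0) == 0) stop("AUPRC needs both classes")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / n1
  # evaluate only at distinct-threshold boundaries (last index of each tie run)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  prec <- prec[keep]; rec <- rec[keep]
  rec0 <- c(0, rec[-length(rec)])
  prec0 <- c(prec[1], prec[-length(prec)])
  sum((rec - rec0) * (prec + prec0) / 2)
}

#' Evaluate a model on a labeled sample set
#' @param model trained model.
#' @param samples list with \code{X} and \code{y}.
#' @return list with \code{auroc} and \code{auprc}.
#' @export
evaluate_model <- function(model, samples) {
  yhat <- predict_batch(model, samples$X)
  list(auroc = compute_auroc(samples$y, yhat),
       auprc = compute_auprc(samples$y, yhat))
}

#' Sliding-window whole-transcriptome binding prediction
#'
#' Transcripts are split into 101-nt windows at 20-nt steps (the final window
#' is clamped to end at the transcript end; transcripts shorter than the
#' window yield a single padded window). Windows with reactivity coverage
#' below \code{min_coverage} are skipped. Windows with probability >=
#' \code{threshold} are flagged as predicted binding sites.
#'
#' @param model trained model.
#' @param transcripts named character vector.
#' @param reactivity named list of profiles.
#' @param window,step window size and step.
#' @param threshold binding-call probability threshold (default 0.5).
#' @param min_coverage coverage filter (set 0 to disable).
#' @param merge merge overlapping flagged windows into maximal site
#'   intervals, returned as attribute \code{"sites"}.
#' @return data.frame of windows: transcript_id, start, end, probability,
#'   score (reverse sigmoid), is_site.
#' @export
predict_transcriptome <- function(model, transcripts, reactivity,
                                  window = 101L, step = 20L, threshold = 0.5,
                                  min_coverage = 0.4, merge = FALSE) {
  rows <- list()
  for (tx in names(transcripts)) {
    tl <- nchar(transcripts[[tx]])
    starts <- if (tl < window) 0L else {
      s <- seq(0L, tl - window, by = step)
      if (s[length(s)] != tl - window) s <- c(s, tl - window)
      s
    }
    ends <- pmin(starts + window, tl)
    sc <- reactivity[[tx]]$scores
    cov <- vapply(seq_along(starts), function(i)
      sum(!is.na(sc[(starts[i] + 1):ends[i]])) / window, numeric(1))
    keep <- cov >= min_coverage
    if (!any(keep)) next
    df <- data.frame(transcript_id = tx, start = starts[keep],
                     end = ends[keep], stringsAsFactors = FALSE)
    enc <- encode_sites(df, transcripts, reactivity, L = window)
    df$probability <- predict_batch(model, enc$X)
    rows[[tx]] <- df
  }
  if (length(rows) == 0) {
    out <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), probability = numeric())
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out$score <- probability_to_score(out$probability)
  out$is_site <- out$probability >= threshold
  if (merge) {
    flagged <- out[out$is_site, c("transcript_id", "start", "end")]
    attr(out, "sites") <- if (nrow(flagged)) merge_intervals(flagged) else
      flagged
  }
  out
}

#' Classify predicted windows between two conditions
#'
#' A window qualifying (probability >= threshold) in both conditions is a
#' common binding site; qualifying in exactly one, a dynamic site of that
#' condition.
#'
#' @param pred_a,pred_b window data.frames from [predict_transcriptome()]
#'   over the same transcriptome.
#' @param threshold probability threshold (default 0.5).
#' @return list with data.frames \code{common}, \code{dynamic_a},
#'   \code{dynamic_b} and a \code{counts} vector.
#' @export
compare_conditions <- function(pred_a, pred_b, threshold = 0.5) {
  key <- function(d) paste0(d$transcript_id, ":", d$start, "-", d$end)
  ka <- key(pred_a); kb <- key(pred_b)
  common_keys <- intersect(ka, kb)
  pa <- pred_a[match(common_keys, ka), ]
  pb <- pred_b[match(common_keys, kb), ]
  in_a <- pa$probability >= threshold
  in_b <- pb$probability >= threshold
  cols <- c("transcript_id", "start", "end")
  res <- list(common = pa[in_a & in_b, cols],
              dynamic_a = pa[in_a & !in_b, cols],
              dynamic_b = pb[in_b & !in_a, cols])
  res$counts <- vapply(res[1:3], nrow, integer(1))
  res
}
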
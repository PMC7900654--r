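# Top-level dispatcher and the end-to-end demo workflow. The package's
# interface is its exported functions; `rbpnet_run()` maps subcommand names
# onto them for scripted use (a thin Rscript wrapper ships in
# inst/scripts/rbpnet-cli.R), and `run_demo()` chains the whole pipeline on
# a small seeded benchmark and reports summary metrics.

#' Read a YAML configuration file for pipeline parameters
#'
#' Convenience loader: the returned named list can be passed as the
#' \code{args} of [rbpnet_run()] or spliced into the constructors
#' ([synthetic_spec()], [model_config()], [train_config()]).
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Dispatch a named pipeline step
#'
#' @param command one of \code{"simulate"}, \code{"prepare"}, \code{"train"},
#'   \code{"predict"}, \code{"compare"}, \code{"saliency"}, \code{"motif"},
#'   \code{"svs"}, \code{"ribosnitch"}, \code{"enrich"}, \code{"demo"}.
#' @param args named list of arguments passed to the underlying function.
#' @return the underlying function's value, invisibly a manifest attached as
#'   attribute \code{"manifest"}.
#' @export
rbpnet_run <- function(command, args = list()) {
  fns <- list(
    simulate = function(a) generate_synthetic(do.call(synthetic_spec,
                                                      a$spec %||% list()),
                                              out_dir = a$out),
    prepare = function(a) do.call(make_benchmark, a),
    train = function(a) do.call(train_model, a),
    predict = function(a) do.call(predict_transcriptome, a),
    compare = function(a) do.call(compare_conditions, a),
    saliency = function(a) do.call(smoothgrad, a),
    motif = function(a) do.call(build_motifs, a),
    svs = function(a) do.call(call_svs, a),
    ribosnitch = function(a) do.call(classify_variants, a),
    enrich = function(a) do.call(permutation_enrichment, a),
    demo = function(a) do.call(run_demo, a)
  )
  if (!command %in% names(fns)) {
    stop("unknown command '", command, "'; available: ",
         paste(names(fns), collapse = ", "))
  }
  res <- fns[[command]](args)
  attr(res, "manifest") <- list(command = command,
                                args = args[setdiff(names(args),
                                                    c("X", "data"))],
                                package_version =
                                  as.character(utils::packageVersion("rbpnet")),
                                timestamp = format(Sys.time(), tz = "UTC"))
  res
}

#' Run the end-to-end demo workflow
#'
#' Simulates a small structure-necessary benchmark, prepares and trains a
#' compact model, predicts over the transcriptome, extracts saliency maps
#' and HARs, builds integrative motifs, calls structurally variable sites
#' between the two simulated conditions and classifies planted variants.
#' All randomness flows from \code{seed}; rerunning with the same seed
#' reproduces the summary exactly.
#'
#' @param seed integer seed.
#' @param n_transcripts,length,epochs problem size knobs (defaults sized for
#'   a fast interactive run).
#' @param verbose print progress.
#' @return named list of summary metrics.
#' @export
run_demo <- function(seed = 1L, n_transcripts = 60L, length = 400L,
                     epochs = 12L, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  spec <- synthetic_spec(n_transcripts = n_transcripts, length = length,
                         n_svs = max(3L, n_transcripts %/% 10),
                         n_var_in_svs = 3L, n_var_outside = 2L,
                         n_var_same = 1L, seed = derive_seed(seed, 1L))
  say("simulate + prepare ...")
  bench <- make_benchmark(spec, seed = derive_seed(seed, 2L))
  say("train ...")
  model <- build_model(model_config(channels = 8L, fc_hidden = 32L),
                       seed = derive_seed(seed, 3L))
  cfg <- train_config(base_lr = 0.003, max_epochs = epochs,
                      patience = epochs, batch_size = 16L,
                      warmup_steps = 20L, seed = derive_seed(seed, 4L))
  fit <- train_model(model, bench$split, cfg)
  metrics <- list(val_auroc = fit$best_auroc)
  say("predict ...")
  pred <- predict_transcriptome(fit$model, bench$data$transcripts,
                                bench$data$merged$A, merge = TRUE)
  metrics$n_predicted_sites <- sum(pred$is_site)
  say("saliency + motifs ...")
  # motif construction from the model's most confident true validation
  # sites (the demo's transcriptome is too small for whole-transcriptome
  # site discovery to be precise)
  val <- bench$split$validation
  yv <- predict_batch(fit$model, val$X)
  tp <- which(val$y == 1 & yv >= 0.5)
  tp <- tp[order(-yv[tp])][seq_len(min(12, length(tp)))]
  site_df <- data.frame(
    transcript_id = sub(":.*", "", val$ids[tp]),
    start = as.integer(sub(".*:(\\d+)-.*", "\\1", val$ids[tp])),
    end = as.integer(sub(".*-", "", val$ids[tp])),
    probability = yv[tp], stringsAsFactors = FALSE)
  sals <- lapply(seq_along(tp), function(i)
    smoothgrad(fit$model, val$X[tp[i], , ],
               seed = derive_seed(seed, 100L + i)))
  hars <- lapply(sals, function(s) find_hars(s$seq_response, mode = "single"))
  metrics$mean_har_response <- mean(vapply(hars, function(h)
    h$mean_response[1], numeric(1)))
  windows <- tryCatch(
    collect_windows(site_df, sals, bench$data$transcripts,
                    bench$data$merged$A, min_prob = 0.5),
    error = function(e) NULL)
  if (!is.null(windows) && length(windows) > 0) {
    motifs <- tryCatch(build_motifs(windows), error = function(e) NULL)
    metrics$n_motifs <- length(motifs)
    metrics$top_motif_consensus <- if (length(motifs)) motifs[[1]]$consensus
      else NA_character_
  } else {
    metrics$n_motifs <- 0L
    metrics$top_motif_consensus <- NA_character_
  }
  say("structure variation ...")
  noise <- estimate_noise(bench$data$reactivity$A$rep1,
                          bench$data$reactivity$A$rep2)
  dl1 <- estimate_delta_l1(bench$data$merged$A, bench$data$merged$B)
  svs <- call_svs(bench$data$merged$A, bench$data$merged$B, noise, dl1)
  metrics$n_svs_called <- nrow(svs)
  calls <- classify_variants(bench$data$variants, svs, c("A", "B"))
  metrics$n_ribosnitch <- sum(calls$label == "riboSNitch")
  metrics$n_vss <- sum(calls$label == "VSS")
  metrics$seed <- seed
  metrics
}
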
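#' Run the full integration pipeline
#'
#' Orchestrates preprocessing, two-stage cross-batch clustering, network
#' training and (when true type labels are present) metric evaluation on one
#' dataset. Stages run in order:
#'
#' 1. [preprocess()] — QC, normalisation, HVG selection, scaling, PCA.
#' 2. [cross_batch_cluster()] — per-batch Leiden, MNN pairing with
#'    random-walk expansion, cluster graph, spectral partitioning.
#' 3. [train_network()] and [embed_cells()] — residual network trained with
#'    the tuplet margin loss on the global cluster labels.
#' 4. [evaluate_integration()] — metric report, only if `type_label` exists.
#'
#' With a fixed `cfg$rng_seed`, two runs on the same input produce identical
#' global cluster labels and corrected embeddings.
#'
#' @param ds A raw-count `bn_dataset`.
#' @param cfg A [bn_config()].
#' @param out_dir Optional directory; when given, the corrected embedding
#'   and labels are written there as `corrected.csv` and the metric report
#'   as `metrics.json`.
#' @param verbose Print per-stage progress.
#' @return A list of class `bn_run` with `embedding` (corrected),
#'   `pca` (the PCA embedding), `clusters` (the clustering stage output),
#'   `model`, `report` (a `bn_metric_report` or `NULL`), and `config`.
#' @export
run_pipeline <- function(ds, cfg = bn_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(ds, "bn_dataset"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  say("[preprocess] %d cells x %d genes", nrow(ds$matrix), ncol(ds$matrix))
  prep <- preprocess(ds, cfg)

  say("[cluster] Leiden (res %.1f) + MNN (k=%d, T=%d) + spectral",
      cfg$leiden_resolution, cfg$knn_k, cfg$walk_steps)
  cl <- cross_batch_cluster(prep$embedding, prep$dataset$batch, cfg)
  say("[cluster] %d initial clusters -> %d global groups, %d MNN pairs",
      length(unique(cl$initial$assignment)), cl$global$n_groups,
      nrow(cl$pairs))

  say("[train] %d epochs, batch %d, k_tuple %d", cfg$epochs, cfg$batch_size,
      cfg$k_tuple)
  spec <- network_spec(ncol(prep$embedding$coords), cfg$embed_dim)
  model <- train_network(prep$embedding, cl$global$assignment, spec, cfg)
  corrected <- embed_cells(model, prep$embedding)

  report <- NULL
  if (!is.null(prep$dataset$type_label)) {
    say("[evaluate] computing metric report")
    report <- evaluate_integration(
      corrected, prep$dataset$batch, prep$dataset$type_label,
      pred = cl$global$assignment,
      seed = derive_seed(cfg$rng_seed, "metrics"),
      k_lisi = cfg$k_lisi, k_kl = cfg$k_kl)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_result(corrected, cl$global$assignment,
                file.path(out_dir, "corrected.csv"))
    if (!is.null(report))
      jsonlite::write_json(unclass(report),
                           file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  say("[done] %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(list(embedding = corrected, pca = prep$embedding,
                 dataset = prep$dataset, clusters = cl, model = model,
                 report = report, config = cfg),
            class = "bn_run")
}

#' @export
print.bn_run <- function(x, ...) {
  cat(sprintf("<bn_run> %d cells, %d global clusters, embed dim %d\n",
              nrow(x$embedding$coords), x$clusters$global$n_groups,
              ncol(x$embedding$coords)))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
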
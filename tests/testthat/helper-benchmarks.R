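# Heavy seeded benchmark runs shared between acceptance properties
# (memoized so the planted-anomaly and ablation checks reuse fits).

.bench_cache <- new.env(parent = emptyenv())

holdout_auc_bench <- function(dataset, seed, epochs, batch_size,
                              ablate = character(), ...) {
  fold <- split_folds(dataset, k = 5, seed = seed)[[1]]
  fit <- gladet(subset_graphs(dataset, fold$train_ids), epochs = epochs,
                batch_size = batch_size, seed = seed, ablate = ablate, ...)
  test <- subset_graphs(dataset, fold$test_ids)
  evaluate_auc(graph_labels(test), predict(fit, test))
}

motif_bench_auc <- function(seed, ablate = character()) {
  key <- paste0("motif", seed, paste(ablate, collapse = ""))
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- holdout_auc_bench(
      generate_motif_set(400, 80, "local", seed = seed),
      seed, epochs = 50, batch_size = 64, ablate = ablate)
  .bench_cache[[key]]
}
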
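#' Cross-validated anomaly-detection experiment
#'
#' For each repeat and each of `k` stratified folds: anomalies are removed
#' from the training folds (one-class protocol), a [gladet()] model is
#' trained on the remaining normal graphs, every graph of the held-out fold
#' (normal and anomalous) is scored, and the ROC AUC is computed. Repeats
#' reseed both the fold shuffle and the model initialization.
#'
#' @param dataset A [graph_dataset()] containing both classes.
#' @param k Number of folds (default 5).
#' @param repeats Number of seeded repeats (default 1).
#' @param seed Base seed; repeat r uses `seed + 7919 * (r - 1)`.
#' @param train_anomaly_count Number of anomalous graphs from the training
#'   folds to recycle INTO training (default 0, the strict one-class
#'   protocol; a sensitivity knob for contamination studies).
#' @param test_anomaly_count Cap on the number of anomalous graphs kept in
#'   each test fold (default `Inf`: keep all; a sensitivity knob for
#'   anomaly-scarce test sets).
#' @param ... Passed to [gladet()] (epochs, batch_size, ablate, ...).
#' @return An object of class `"gladet_cv"`: list with `reports` (one data
#'   frame per fold x repeat: graph_id, label, score, plus fold/seed/auc
#'   attributes), `histories` (per-fold training loss breakdowns), `auc`
#'   (vector), `summary` (mean and sd), `k`, `repeats`.
#' @export
gladet_cv <- function(dataset, k = 5L, repeats = 1L, seed = 1L,
                      train_anomaly_count = 0L, test_anomaly_count = Inf, ...) {
  labs <- graph_labels(dataset)
  ids <- graph_ids(dataset)
  if (length(unique(labs)) < 2L)
    stop("evaluation error: dataset must contain both normal and anomalous graphs")
  reports <- list()
  histories <- list()
  aucs <- numeric(0)
  for (r in seq_len(repeats)) {
    seed_r <- seed + 7919L * (r - 1L)
    folds <- split_folds(dataset, k, seed_r)
    for (fs in folds) {
      train_ids <- fs$train_ids
      if (train_anomaly_count > 0L) {
        # contamination study: recycle removed anomalies into training
        pool <- setdiff(ids[labs == 1L], fs$test_ids)
        train_ids <- c(train_ids, head(pool, train_anomaly_count))
      }
      train <- subset_graphs(dataset, train_ids)
      if (train_anomaly_count == 0L)
        stopifnot(all(graph_labels(train) == 0L))     # protocol assertion
      else
        train$graphs <- lapply(train$graphs,
                               function(g) { g$label <- 0L; g })
      fit <- gladet(train, seed = seed_r + fs$fold_index, ...)
      test_ids <- fs$test_ids
      if (is.finite(test_anomaly_count)) {
        anom <- intersect(test_ids, ids[labs == 1L])
        drop <- setdiff(anom, head(anom, test_anomaly_count))
        test_ids <- setdiff(test_ids, drop)
      }
      test <- subset_graphs(dataset, test_ids)
      sc <- predict(fit, test)
      rep_df <- data.frame(graph_id = graph_ids(test),
                           label = graph_labels(test), score = unname(sc))
      auc <- evaluate_auc(rep_df$label, rep_df$score)
      attr(rep_df, "fold_index") <- fs$fold_index
      attr(rep_df, "seed") <- seed_r
      attr(rep_df, "auc") <- auc
      reports[[length(reports) + 1L]] <- rep_df
      histories[[length(histories) + 1L]] <- fit$history
      aucs <- c(aucs, auc)
    }
  }
  structure(list(reports = reports, histories = histories, auc = aucs,
                 summary = c(mean = mean(aucs), sd = stats::sd(aucs)),
                 k = k, repeats = repeats, seed = seed),
            class = "gladet_cv")
}

#' @export
print.gladet_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d repeat(s): AUC %.3f +/- %.3f (%d folds)\n",
              x$k, x$repeats, x$summary["mean"],
              if (is.na(x$summary["sd"])) 0 else x$summary["sd"],
              length(x$auc)))
  invisible(x)
}

#' @export
plot.gladet_cv <- function(x, ...) {
  graphics::boxplot(x$auc, ylab = "held-out AUC",
                    main = sprintf("%d-fold CV x %d repeats", x$k, x$repeats), ...)
  graphics::points(jitter(rep(1, length(x$auc)), amount = 0.05), x$auc, pch = 19)
  invisible(x)
}
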
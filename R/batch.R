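#' Pad and stack graphs into fixed-size batch tensors
#'
#' Pads each graph's adjacency and feature matrices with zeros to
#' `max_nodes` rows/columns and stacks them into arrays, with a node-validity
#' mask marking real nodes. Nodes keep their original order; padding is
#' deterministic.
#'
#' @param graphs List of [glad_graph()] objects sharing a feature dimension.
#' @param max_nodes Padded size; every graph must have `n_nodes <= max_nodes`.
#' @return An object of class `"batched_graphs"`: list with
#'   `adjacency_stack` (B x M x M array), `feature_stack` (B x M x d array),
#'   `node_mask` (B x M 0/1 matrix), `labels`, `graph_ids`, `n_nodes`.
#' @export
pad_and_batch <- function(graphs, max_nodes) {
  B <- length(graphs)
  if (B == 0L) stop("empty batch")
  d <- ncol(graphs[[1]]$features)
  for (g in graphs)
    if (g$n_nodes > max_nodes)
      stop("graph ", g$graph_id, " has ", g$n_nodes,
           " nodes, exceeding max_nodes = ", max_nodes)
  A <- array(0, c(B, max_nodes, max_nodes))
  X <- array(0, c(B, max_nodes, d))
  mask <- matrix(0, B, max_nodes)
  for (b in seq_len(B)) {
    n <- graphs[[b]]$n_nodes
    A[b, seq_len(n), seq_len(n)] <- graphs[[b]]$adjacency
    if (d > 0) X[b, seq_len(n), ] <- graphs[[b]]$features
    mask[b, seq_len(n)] <- 1
  }
  structure(list(adjacency_stack = A, feature_stack = X, node_mask = mask,
                 labels = vapply(graphs, function(g) g$label, integer(1)),
                 graph_ids = vapply(graphs, function(g) g$graph_id, integer(1)),
                 n_nodes = vapply(graphs, function(g) g$n_nodes, integer(1))),
            class = "batched_graphs")
}

#' Recover the list of graphs from a batch
#' @param batch A `batched_graphs` object.
#' @return List of [glad_graph()] objects equal to the batch's sources.
#' @export
unbatch <- function(batch) {
  lapply(seq_along(batch$labels), function(b) {
    n <- batch$n_nodes[b]
    glad_graph(batch$adjacency_stack[b, seq_len(n), seq_len(n), drop = FALSE][1, , ],
               if (dim(batch$feature_stack)[3] > 0)
                 matrix(batch$feature_stack[b, seq_len(n), ], nrow = n)
               else NULL,
               label = batch$labels[b], graph_id = batch$graph_ids[b])
  })
}

#' Anomaly-free cross-validation folds
#'
#' Stratified-by-label shuffled partition into `k` folds under a seed. Each
#' fold's training ids are the NORMAL (label 0) graphs of the other k-1
#' folds — the one-class training protocol removes anomalies from training —
#' while its test ids are all graphs of the held-out fold. Stratification
#' guarantees every test fold contains both classes whenever the dataset
#' has at least `k` graphs of each class.
#'
#' @param dataset A [graph_dataset()].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List of `k` fold splits, each a list with `fold_index`
#'   (0-based), `train_ids`, `test_ids`.
#' @export
split_folds <- function(dataset, k = 5L, seed = 1L) {
  k <- as.integer(k)
  m <- length(dataset$graphs)
  if (k < 2L) stop("k must be >= 2")
  if (m < k) stop("configuration error: ", m, " graphs cannot form ", k, " folds")
  ids <- graph_ids(dataset)
  labs <- graph_labels(dataset)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fold_of <- integer(m)
  for (lab in unique(labs)) {
    idx <- which(labs == lab)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep_len(seq_len(k), length(idx))   # round-robin deal
  }
  lapply(seq_len(k), function(f) {
    test <- ids[fold_of == f]
    if (length(test) == 0L) stop("configuration error: fold ", f - 1L, " is empty")
    list(fold_index = f - 1L,
         train_ids = ids[fold_of != f & labs == 0L],
         test_ids = test)
  })
}
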
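#' Construct a single graph
#'
#' A graph is stored as a symmetric, hollow (zero-diagonal) 0/1 adjacency
#' matrix plus an optional node-feature matrix and a binary anomaly label.
#' Self-loops are never stored; they are added internally by the encoder
#' (which operates on A + I).
#'
#' @param adjacency Square numeric matrix; symmetric, entries in \{0, 1\},
#'   zero diagonal.
#' @param features Numeric matrix with one row per node, or `NULL` for a
#'   feature-less graph (a zero-column matrix is stored).
#' @param label Integer 0 (normal) or 1 (anomalous).
#' @param graph_id Integer identifier within a dataset.
#' @return An object of class `"glad_graph"`: a list with elements
#'   `n_nodes`, `adjacency`, `features`, `label`, `graph_id`.
#' @export
glad_graph <- function(adjacency, features = NULL, label = 0L, graph_id = NA_integer_) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n < 1L || ncol(adjacency) != n)
    stop("adjacency must be a non-empty square matrix")
  if (!isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE)))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0))
    stop("adjacency must have a zero diagonal (self-loops are not stored)")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (is.null(features)) {
    features <- matrix(numeric(0), nrow = n, ncol = 0L)
  } else {
    features <- as.matrix(features)
    if (nrow(features) != n)
      stop("features must have one row per node (", n, " expected, got ",
           nrow(features), ")")
    storage.mode(features) <- "double"
  }
  label <- as.integer(label)
  if (!label %in% c(0L, 1L)) stop("label must be 0 (normal) or 1 (anomalous)")
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- NULL
  dimnames(features) <- NULL
  structure(list(n_nodes = n, adjacency = adjacency, features = features,
                 label = label, graph_id = as.integer(graph_id)),
            class = "glad_graph")
}

#' Number of edges of a graph
#' @param g A `glad_graph`.
#' @return Integer edge count (undirected, no self-loops).
#' @export
n_edges <- function(g) as.integer(sum(g$adjacency) / 2)

#' Construct a graph dataset
#'
#' An ordered collection of graphs sharing one feature dimensionality,
#' with dataset-level metadata (maximum node count, name).
#'
#' @param graphs List of `glad_graph` objects.
#' @param name Dataset name.
#' @param feature_source How the current features were obtained
#'   (`"none"`, `"attributes"`, `"node_labels"`, `"degree_onehot"`,
#'   `"degree_scalar"`, `"synthetic"`).
#' @return An object of class `"graph_dataset"`: list with `graphs`,
#'   `feature_dim`, `max_nodes`, `name`, `feature_source`.
#' @export
graph_dataset <- function(graphs, name = "dataset", feature_source = "none") {
  if (length(graphs) == 0L) stop("a graph_dataset needs at least one graph")
  dims <- vapply(graphs, function(g) ncol(g$features), integer(1))
  if (length(unique(dims)) != 1L)
    stop("all graphs must share the same feature dimensionality")
  for (i in seq_along(graphs))
    if (is.na(graphs[[i]]$graph_id)) graphs[[i]]$graph_id <- i
  structure(list(graphs = graphs,
                 feature_dim = dims[1],
                 max_nodes = max(vapply(graphs, function(g) g$n_nodes, integer(1))),
                 name = name,
                 feature_source = feature_source),
            class = "graph_dataset")
}

#' @export
print.graph_dataset <- function(x, ...) {
  labs <- graph_labels(x)
  cat("Graph dataset '", x$name, "': ", length(x$graphs), " graphs (",
      sum(labs == 1), " anomalous), feature dim ", x$feature_dim,
      " [", x$feature_source, "], max nodes ", x$max_nodes, "\n", sep = "")
  invisible(x)
}

#' @export
print.glad_graph <- function(x, ...) {
  cat("Graph #", x$graph_id, ": ", x$n_nodes, " nodes, ", n_edges(x),
      " edges, label ", x$label, "\n", sep = "")
  invisible(x)
}

#' Anomaly labels of a dataset
#' @param dataset A `graph_dataset`.
#' @return Integer vector of 0/1 labels in graph order.
#' @export
graph_labels <- function(dataset)
  vapply(dataset$graphs, function(g) g$label, integer(1))

#' Graph ids of a dataset
#' @param dataset A `graph_dataset`.
#' @return Integer vector of graph ids in graph order.
#' @export
graph_ids <- function(dataset)
  vapply(dataset$graphs, function(g) g$graph_id, integer(1))

#' Subset a dataset by graph id
#' @param dataset A `graph_dataset`.
#' @param ids Graph ids to keep (order preserved as given).
#' @return A `graph_dataset` with the selected graphs; `max_nodes` is kept
#'   from the parent dataset so train/test batches share geometry.
#' @export
subset_graphs <- function(dataset, ids) {
  all_ids <- graph_ids(dataset)
  idx <- match(ids, all_ids)
  if (anyNA(idx)) stop("unknown graph ids: ", paste(ids[is.na(idx)], collapse = ", "))
  out <- graph_dataset(dataset$graphs[idx], name = dataset$name,
                       feature_source = dataset$feature_source)
  out$max_nodes <- dataset$max_nodes
  out
}
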
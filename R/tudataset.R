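#' Read a graph set in the TUDataset multi-file layout
#'
#' Parses the de-facto standard plain-text layout used by the public
#' graph-classification dataset collections: `<name>_A.txt` (comma-separated
#' 1-based edge pairs), `<name>_graph_indicator.txt` (1-based graph id per
#' node), `<name>_graph_labels.txt`, and optionally
#' `<name>_node_attributes.txt` and/or `<name>_node_labels.txt`.
#'
#' Edges are undirected: an edge listed in either (or both) directions yields
#' a single undirected edge. Node attributes, when present, become the node
#' features; otherwise node labels are one-hot encoded; plain graphs with
#' neither are returned feature-less so that [degree_features()] can fill
#' them. The raw graph class labels are remapped to anomaly flags via
#' `anomaly_class` (raw labels in `anomaly_class` become 1, all others 0);
#' there is deliberately no default because which class counts as anomalous
#' is a dataset-level decision.
#'
#' @param directory_path Directory containing the files.
#' @param dataset_name Prefix `<name>` of the files.
#' @param anomaly_class Vector of raw graph labels to be flagged anomalous.
#' @return A [graph_dataset()] preserving file order.
#' @export
read_tudataset <- function(directory_path, dataset_name, anomaly_class) {
  fp <- function(suffix) file.path(directory_path, paste0(dataset_name, suffix))
  for (suffix in c("_A.txt", "_graph_indicator.txt", "_graph_labels.txt"))
    if (!file.exists(fp(suffix)))
      stop("TUDataset format error: missing mandatory file ",
           paste0(dataset_name, suffix))
  if (missing(anomaly_class))
    stop("anomaly_class is required: state which raw graph label(s) are anomalous")

  indicator <- scan(fp("_graph_indicator.txt"), what = integer(), quiet = TRUE)
  raw_labels <- scan(fp("_graph_labels.txt"), what = numeric(), quiet = TRUE)
  edges <- utils::read.table(fp("_A.txt"), sep = ",", col.names = c("u", "v"),
                             colClasses = "integer")
  m <- length(raw_labels)
  if (max(indicator) > m || min(indicator) < 1L)
    stop("TUDataset consistency error: graph indicator references graph outside 1..", m)

  node_ids <- seq_along(indicator)
  # first (0-based offset) node of each graph, for global -> local index maps
  sizes <- tabulate(indicator, nbins = m)
  if (any(sizes == 0L))
    stop("TUDataset consistency error: a graph has zero nodes")
  offsets <- cumsum(c(0L, sizes[-m]))

  if (any(edges$u < 1L | edges$u > length(node_ids) |
          edges$v < 1L | edges$v > length(node_ids)))
    stop("TUDataset consistency error: edge references a node outside 1..",
         length(node_ids))
  gu <- indicator[edges$u]
  gv <- indicator[edges$v]
  if (any(gu != gv))
    stop("TUDataset consistency error: edge connects nodes of different graphs")

  feats <- NULL
  feature_source <- "none"
  if (file.exists(fp("_node_attributes.txt"))) {
    feats <- as.matrix(utils::read.table(fp("_node_attributes.txt"), sep = ","))
    if (nrow(feats) != length(indicator))
      stop("TUDataset consistency error: node attribute rows != node count")
    feature_source <- "attributes"
  } else if (file.exists(fp("_node_labels.txt"))) {
    nl <- scan(fp("_node_labels.txt"), what = integer(), quiet = TRUE)
    if (length(nl) != length(indicator))
      stop("TUDataset consistency error: node label rows != node count")
    lev <- sort(unique(nl))
    feats <- matrix(0, length(nl), length(lev))
    feats[cbind(seq_along(nl), match(nl, lev))] <- 1
    feature_source <- "node_labels"
  }

  by_graph_edges <- split(seq_len(nrow(edges)), gu)
  graphs <- vector("list", m)
  for (g in seq_len(m)) {
    n <- sizes[g]
    A <- matrix(0, n, n)
    eidx <- by_graph_edges[[as.character(g)]]
    if (!is.null(eidx)) {
      u <- edges$u[eidx] - offsets[g]
      v <- edges$v[eidx] - offsets[g]
      if (any(u < 1L | u > n | v < 1L | v > n))
        stop("TUDataset consistency error: node index outside its graph's range ",
             "(graph ", g, ")")
      keep <- u != v               # stray self-loop lines are dropped
      A[cbind(u[keep], v[keep])] <- 1
      A <- pmax(A, t(A))           # OR-symmetrize
    }
    f <- if (is.null(feats)) NULL else feats[(offsets[g] + 1L):(offsets[g] + n), , drop = FALSE]
    graphs[[g]] <- glad_graph(A, f,
                              label = as.integer(raw_labels[g] %in% anomaly_class),
                              graph_id = g)
  }
  graph_dataset(graphs, name = dataset_name, feature_source = feature_source)
}

#' Write a graph set in the TUDataset multi-file layout
#'
#' Emits the same plain-text layout that [read_tudataset()] parses, with
#' 1-based node indices and every undirected edge listed in both directions
#' (the TU convention). Anomaly labels are written as raw graph labels 0/1,
#' so `read_tudataset(..., anomaly_class = 1)` round-trips the dataset.
#' Features, when present, are written as `_node_attributes.txt`.
#'
#' @param dataset A non-empty [graph_dataset()].
#' @param directory_path Output directory (created if needed).
#' @param name File prefix.
#' @return Invisibly, the vector of file paths written.
#' @export
export_tudataset <- function(dataset, directory_path, name = dataset$name) {
  if (!inherits(dataset, "graph_dataset") || length(dataset$graphs) == 0L)
    stop("export_tudataset needs a non-empty graph_dataset")
  dir.create(directory_path, showWarnings = FALSE, recursive = TRUE)
  fp <- function(suffix) file.path(directory_path, paste0(name, suffix))

  indicator <- integer(0); edge_lines <- character(0)
  offset <- 0L
  for (g in seq_along(dataset$graphs)) {
    gr <- dataset$graphs[[g]]
    indicator <- c(indicator, rep.int(g, gr$n_nodes))
    idx <- which(gr$adjacency == 1, arr.ind = TRUE)   # both directions
    if (nrow(idx) > 0)
      edge_lines <- c(edge_lines,
                      paste0(idx[, 1] + offset, ", ", idx[, 2] + offset))
    offset <- offset + gr$n_nodes
  }
  writeLines(edge_lines, fp("_A.txt"))
  writeLines(as.character(indicator), fp("_graph_indicator.txt"))
  writeLines(as.character(graph_labels(dataset)), fp("_graph_labels.txt"))
  written <- c(fp("_A.txt"), fp("_graph_indicator.txt"), fp("_graph_labels.txt"))
  if (dataset$feature_dim > 0) {
    feats <- do.call(rbind, lapply(dataset$graphs, function(g) g$features))
    writeLines(apply(feats, 1, function(r) paste(format(r, trim = TRUE, digits = 17),
                                                 collapse = ", ")),
               fp("_node_attributes.txt"))
    written <- c(written, fp("_node_attributes.txt"))
  }
  invisible(written)
}

#' Attach degree-derived node features
#'
#' For plain graphs without native attributes the node feature is derived
#' from its degree: either a one-hot indicator over `0..max_degree` (maximum
#' taken over the whole dataset, so all graphs share one feature space) or
#' the raw degree as a single scalar column.
#'
#' @param dataset A [graph_dataset()].
#' @param encoding `"onehot"` (default) or `"scalar"`.
#' @param force Replace existing features even if the dataset has native
#'   attributes.
#' @return The dataset with features replaced and `feature_source` updated.
#' @export
degree_features <- function(dataset, encoding = c("onehot", "scalar"), force = FALSE) {
  encoding <- match.arg(encoding)
  if (dataset$feature_dim > 0 && !force) return(dataset)
  degs <- lapply(dataset$graphs, function(g) as.integer(rowSums(g$adjacency)))
  dmax <- max(unlist(degs))
  for (i in seq_along(dataset$graphs)) {
    d <- degs[[i]]
    if (encoding == "onehot") {
      f <- matrix(0, length(d), dmax + 1L)
      f[cbind(seq_along(d), d + 1L)] <- 1
    } else {
      f <- matrix(as.numeric(d), ncol = 1L)
    }
    dataset$graphs[[i]]$features <- f
  }
  dataset$feature_dim <- if (encoding == "onehot") dmax + 1L else 1L
  dataset$feature_source <- paste0("degree_", encoding)
  dataset
}
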
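#' Motif specification for the synthetic two-ring benchmark
#'
#' The normal structural pattern is a small ring and a large ring joined by
#' bridge edges (the classic two-ring molecule surrogate). Anomalies are
#' planted against this pattern.
#'
#' @param small_ring Node count of the small ring (>= 3).
#' @param large_ring Node count of the large ring (>= 3).
#' @param bridge_edges Number of edges joining the two rings.
#' @return A list of class `"motif_spec"`.
#' @export
motif_spec <- function(small_ring = 3L, large_ring = 4L, bridge_edges = 1L) {
  if (small_ring < 3L || large_ring < 3L) stop("ring sizes must be >= 3")
  if (bridge_edges < 1L) stop("bridge_edges must be >= 1")
  structure(list(small_ring = as.integer(small_ring),
                 large_ring = as.integer(large_ring),
                 bridge_edges = as.integer(bridge_edges)),
            class = "motif_spec")
}

ring_adjacency <- function(n) {
  A <- matrix(0, n, n)
  i <- seq_len(n)
  j <- c(seq_len(n)[-1], 1L)
  A[cbind(i, j)] <- 1
  pmax(A, t(A))
}

# normal motif graph: small ring (nodes 1..s) + large ring (s+1..s+L) +
# bridge edges between them; optional benign jitter relocates one bridge.
motif_normal_adjacency <- function(spec, jitter = 0) {
  s <- spec$small_ring; L <- spec$large_ring
  n <- s + L
  A <- matrix(0, n, n)
  A[seq_len(s), seq_len(s)] <- ring_adjacency(s)
  A[(s + 1):n, (s + 1):n] <- ring_adjacency(L)
  bridges <- cbind(rep_len(seq_len(s), spec$bridge_edges),
                   s + rep_len(seq_len(L), spec$bridge_edges))
  if (jitter > 0 && stats::runif(1) < jitter) {
    b <- sample.int(nrow(bridges), 1L)
    bridges[b, ] <- c(sample.int(s, 1L), s + sample.int(L, 1L))
    bridges <- unique(bridges)
  }
  A[bridges] <- 1
  pmax(A, t(A))
}

# destroy the large-ring pattern by rewiring every link of one of its nodes
# to the small ring; node count is unchanged and the graph stays connected
# because only non-bridge large-ring nodes are eligible.
motif_local_anomaly <- function(A, spec) {
  s <- spec$small_ring; L <- spec$large_ring
  large <- (s + 1):(s + L)
  bridge_endpoints <- large[colSums(A[seq_len(s), large, drop = FALSE]) > 0]
  candidates <- setdiff(large, bridge_endpoints)
  if (length(candidates) == 0L) candidates <- large
  v <- candidates[sample.int(length(candidates), 1L)]
  A[v, ] <- 0; A[, v] <- 0
  targets <- sample.int(s, 2L)
  A[v, targets] <- 1; A[targets, v] <- 1
  A
}

# change the whole-graph pattern by attaching two extra nodes (a pendant
# two-node path hanging off the large ring).
motif_global_anomaly <- function(A, spec) {
  n <- nrow(A)
  B <- matrix(0, n + 2L, n + 2L)
  B[seq_len(n), seq_len(n)] <- A
  anchor <- spec$small_ring + sample.int(spec$large_ring, 1L)
  B[anchor, n + 1L] <- B[n + 1L, anchor] <- 1
  B[n + 1L, n + 2L] <- B[n + 2L, n + 1L] <- 1
  B
}

#' Generate the two-ring motif benchmark with planted anomalies
#'
#' Normal graphs share the two-ring motif of `spec`. Planted anomalies are:
#' `"local"` — all links of one large-ring node are rewired so the large-ring
#' pattern is destroyed while the node count is unchanged; `"global"` — two
#' extra nodes are attached, changing the whole-graph pattern; `"attribute"`
#' — normal topology but node features drawn from a mean-shifted Gaussian;
#' `"mixed"` — alternating local and global. Structural variants carry
#' degree one-hot features (computed dataset-wide); the attribute variant
#' carries Gaussian features (normal N(0,1), anomalous N(mu_shift,1) per
#' dimension).
#'
#' @param n_normal Number of normal graphs (>= 1).
#' @param n_anomalous Number of anomalous graphs (>= 0).
#' @param anomaly_type One of `"local"`, `"global"`, `"attribute"`, `"mixed"`.
#' @param spec A [motif_spec()].
#' @param jitter Probability of one benign bridge rewire in a normal graph.
#' @param mu_shift Mean shift of anomalous features (attribute variant).
#' @param attr_dim Feature dimension of the attribute variant.
#' @param seed Integer seed; generation is fully determined by it.
#' @return A [graph_dataset()] with ground-truth labels.
#' @export
generate_motif_set <- function(n_normal, n_anomalous = 0L,
                               anomaly_type = c("local", "global", "attribute", "mixed"),
                               spec = motif_spec(), jitter = 0, mu_shift = 2,
                               attr_dim = 4L, seed = 1L) {
  anomaly_type <- match.arg(anomaly_type)
  if (n_normal < 1L) stop("n_normal must be >= 1")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  attributed <- anomaly_type == "attribute"
  graphs <- vector("list", n_normal + n_anomalous)
  for (i in seq_len(n_normal)) {
    A <- motif_normal_adjacency(spec, jitter)
    f <- if (attributed) matrix(stats::rnorm(nrow(A) * attr_dim), nrow(A)) else NULL
    graphs[[i]] <- glad_graph(A, f, label = 0L, graph_id = i)
  }
  if (n_anomalous > 0) for (j in seq_len(n_anomalous)) {
    A <- motif_normal_adjacency(spec, jitter)
    type <- switch(anomaly_type,
                   mixed = if (j %% 2L == 1L) "local" else "global",
                   anomaly_type)
    if (type == "local") A <- motif_local_anomaly(A, spec)
    if (type == "global") A <- motif_global_anomaly(A, spec)
    f <- if (attributed) matrix(stats::rnorm(nrow(A) * attr_dim, mean = mu_shift), nrow(A)) else NULL
    graphs[[n_normal + j]] <- glad_graph(A, f, label = 1L, graph_id = n_normal + j)
  }
  ds <- graph_dataset(graphs, name = paste0("motif_", anomaly_type),
                      feature_source = if (attributed) "synthetic" else "none")
  if (!attributed) ds <- degree_features(ds, "onehot")
  ds
}

#' Generate an Erdos-Renyi contrast benchmark
#'
#' Normal graphs are G(n, p_normal), anomalous graphs G(n, p_anomalous);
#' degree one-hot features are attached dataset-wide. With
#' `p_normal == p_anomalous` the labels carry no signal (a null-control
#' benchmark); with well-separated densities any degree-sensitive detector
#' should separate the classes.
#'
#' @param n_normal,n_anomalous Graph counts per class.
#' @param n_nodes Nodes per graph (>= 3).
#' @param p_normal,p_anomalous Edge probabilities in (0, 1).
#' @param seed Integer seed.
#' @return A [graph_dataset()] with ground-truth labels.
#' @export
generate_er_contrast_set <- function(n_normal, n_anomalous, n_nodes = 20L,
                                     p_normal = 0.15, p_anomalous = 0.6, seed = 1L) {
  if (n_nodes < 3L) stop("n_nodes must be >= 3")
  if (p_normal <= 0 || p_normal >= 1 || p_anomalous <= 0 || p_anomalous >= 1)
    stop("edge probabilities must lie strictly in (0, 1)")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  er <- function(p) {
    A <- matrix(0, n_nodes, n_nodes)
    ut <- upper.tri(A)
    A[ut] <- as.numeric(stats::runif(sum(ut)) < p)
    pmax(A, t(A))
  }
  graphs <- c(lapply(seq_len(n_normal), function(i)
                glad_graph(er(p_normal), label = 0L, graph_id = i)),
              if (n_anomalous > 0)
                lapply(seq_len(n_anomalous), function(j)
                  glad_graph(er(p_anomalous), label = 1L, graph_id = n_normal + j)))
  degree_features(graph_dataset(graphs, name = "er_contrast"), "onehot")
}
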
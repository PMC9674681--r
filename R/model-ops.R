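#' One graph-convolution layer
#'
#' Computes `phi( D^{-1/2} (A + I) D^{-1/2} Z W )` restricted to the
#' masked-in nodes; masked-out rows are zero on output and never enter the
#' degree normalization. Isolated valid nodes have degree 1 (their
#' self-loop), so the normalization is always well defined.
#'
#' @param adjacency M x M matrix, hollow-symmetric on the valid block.
#' @param node_states M x h_in matrix.
#' @param weight h_in x h_out weight matrix (no bias, as in the standard
#'   GCN propagation rule).
#' @param activation `"relu"`, `"tanh"` or `"identity"`.
#' @param mask Length-M 0/1 vector of valid nodes (`NULL` = all valid).
#' @return M x h_out matrix.
#' @export
gcn_layer <- function(adjacency, node_states, weight, activation = "relu",
                      mask = NULL) {
  M <- nrow(adjacency)
  if (ncol(adjacency) != M || nrow(node_states) != M)
    stop("shape mismatch between adjacency and node_states")
  if (ncol(node_states) != nrow(weight))
    stop("shape mismatch between node_states and weight")
  if (is.null(mask)) mask <- rep(1, M)
  v <- which(mask == 1)
  act <- act_fun(activation)
  out <- matrix(0, M, ncol(weight))
  S <- norm_adj(adjacency[v, v, drop = FALSE])$S
  out[v, ] <- act$f(S %*% node_states[v, , drop = FALSE] %*% weight)
  out
}

#' Max-pooling graph readout
#'
#' Coordinate-wise maximum over the masked-in node representations: the
#' graph-level representation Z_G.
#'
#' @param Z_node M x h node representation matrix.
#' @param mask Length-M 0/1 vector (`NULL` = all valid).
#' @return Length-h vector.
#' @export
max_pool <- function(Z_node, mask = NULL) {
  if (is.null(mask)) mask <- rep(1, nrow(Z_node))
  v <- which(mask == 1)
  if (length(v) == 0L) stop("max_pool needs at least one valid node")
  maxpool_cache(Z_node[v, , drop = FALSE])$zG
}

#' Projection head
#'
#' Two-layer perceptron mapping a graph readout into the contrastive space.
#' The same (shared) head maps both the clean and the perturbed readout.
#'
#' @param Z_G Length-h readout vector.
#' @param params A parameter set as stored in a fitted [gladet()] model.
#' @return Length-`proj_dim` projected vector.
#' @export
project_head <- function(Z_G, params) {
  proj_cache(Z_G, params, act_fun(params$activation))$zp
}

#' Inner-product structure decoder
#'
#' `A_hat = sigmoid(Z_node Z_node^T)` on the masked-in block; masked-out
#' rows/columns are zero. The result is symmetric with entries strictly in
#' (0, 1) on the valid block.
#'
#' @param Z_node M x h node representations.
#' @param mask Length-M 0/1 vector (`NULL` = all valid).
#' @return M x M reconstructed adjacency.
#' @export
decode_structure <- function(Z_node, mask = NULL) {
  M <- nrow(Z_node)
  if (is.null(mask)) mask <- rep(1, M)
  v <- which(mask == 1)
  out <- matrix(0, M, M)
  out[v, v] <- sigmoid(tcrossprod(Z_node[v, , drop = FALSE]))
  out
}

#' Graph-convolutional attribute decoder
#'
#' Reconstructs node features by a GCN stack on the ORIGINAL graph's
#' normalized adjacency applied to the node representations (decoder
#' dimensions mirror the encoder, e.g. 128-256-d). The output layer applies
#' the activation unless the model was built with a linear decoder output
#' (`params$dec_linear`).
#'
#' @param adjacency The input graph's M x M adjacency (hollow, binary).
#' @param Z_node M x h node representations.
#' @param params Parameter set of a fitted model (uses `W_dec`).
#' @param mask Length-M 0/1 vector (`NULL` = all valid).
#' @return M x d reconstructed feature matrix; masked-out rows zero.
#' @export
decode_attributes <- function(adjacency, Z_node, params, mask = NULL) {
  M <- nrow(adjacency)
  if (is.null(mask)) mask <- rep(1, M)
  v <- which(mask == 1)
  act <- act_fun(params$activation)
  S <- norm_adj(adjacency[v, v, drop = FALSE])$S
  out <- matrix(0, M, ncol(params$W_dec[[length(params$W_dec)]]))
  out[v, ] <- gcn_stack(S, Z_node[v, , drop = FALSE], params$W_dec, act,
                        linear_last = isTRUE(params$dec_linear))$Z
  out
}

#' Encode a padded batch of graphs
#'
#' Runs the (optionally Gaussian-perturbed) shared GCN encoder over every
#' graph of a padded batch and max-pools the node representations.
#'
#' @param batch A [pad_and_batch()] result.
#' @param params Parameter set of a fitted model.
#' @param perturbed Use the weight-perturbed twin encoder.
#' @param eta Perturbation coefficient (ignored unless `perturbed`).
#' @param sigma `"empirical"` (per-layer sd of the weights) or a number.
#' @param seed Seed for the perturbation draw (required when `perturbed`).
#' @return List with `Z_node` (B x M x h array, masked-out rows zero) and
#'   `Z_G` (B x h matrix).
#' @export
encode_graphs <- function(batch, params, perturbed = FALSE, eta = 1,
                          sigma = "empirical", seed = NULL) {
  act <- act_fun(params$activation)
  Ws <- params$W_enc
  if (perturbed) {
    if (is.null(seed)) stop("a seed is required for the perturbed encoder")
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    Ws <- draw_perturbation(params, eta, sigma)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  B <- length(batch$labels)
  M <- ncol(batch$node_mask)
  h <- ncol(Ws[[length(Ws)]])
  Z_node <- array(0, c(B, M, h))
  Z_G <- matrix(0, B, h)
  for (b in seq_len(B)) {
    n <- batch$n_nodes[b]
    A <- matrix(batch$adjacency_stack[b, seq_len(n), seq_len(n)], n)
    X <- matrix(batch$feature_stack[b, seq_len(n), ], n)
    st <- gcn_stack(norm_adj(A)$S, X, Ws, act,
                    linear_last = isTRUE(params$enc_linear))
    Z_node[b, seq_len(n), ] <- st$Z
    Z_G[b, ] <- maxpool_cache(st$Z)$zG
  }
  list(Z_node = Z_node, Z_G = Z_G)
}

#' Re-encode a reconstructed graph through the shared encoder
#'
#' The decoded adjacency is used as a continuous weighted adjacency (no
#' thresholding): self-loops are added and degrees are its row sums. The
#' encoder weights are the SAME objects used on the input graph.
#'
#' @param A_hat M x M reconstructed adjacency (entries in (0,1) on the
#'   valid block).
#' @param X_hat M x d reconstructed features.
#' @param params Parameter set of a fitted model.
#' @param mask Length-M 0/1 vector (`NULL` = all valid).
#' @return List with `Z_node` (M x h, masked-out rows zero) and `Z_G`.
#' @export
encode_reconstruction <- function(A_hat, X_hat, params, mask = NULL) {
  M <- nrow(A_hat)
  if (is.null(mask)) mask <- rep(1, M)
  v <- which(mask == 1)
  act <- act_fun(params$activation)
  st <- gcn_stack(norm_adj(A_hat[v, v, drop = FALSE])$S,
                  X_hat[v, , drop = FALSE], params$W_enc, act,
                  linear_last = isTRUE(params$enc_linear))
  Z <- matrix(0, M, ncol(st$Z))
  Z[v, ] <- st$Z
  list(Z_node = Z, Z_G = maxpool_cache(st$Z)$zG)
}
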
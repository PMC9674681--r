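#' Graph reconstruction loss
#'
#' Squared Frobenius error of the structure and attribute reconstructions,
#' `||A - A_hat||_F^2 + ||X - X_hat||_F^2`, computed per graph over the
#' valid block and averaged over the batch. Diagonal adjacency entries are
#' excluded: self-loops are not data, so the decoder is not penalized for
#' them.
#'
#' @param A,A_hat Lists of per-graph adjacency matrices (input and decoded).
#' @param X,X_hat Lists of per-graph feature matrices (input and decoded).
#' @return Non-negative scalar, the batch-mean reconstruction error.
#' @export
reconstruction_loss <- function(A, A_hat, X, X_hat) {
  stopifnot(length(A) == length(A_hat), length(X) == length(X_hat),
            length(A) == length(X))
  vals <- vapply(seq_along(A), function(g) {
    DA <- (A[[g]] - A_hat[[g]])^2
    diag(DA) <- 0
    sum(DA) + sum((X[[g]] - X_hat[[g]])^2)
  }, numeric(1))
  mean(vals)
}

#' Contrastive loss over a minibatch of projected graph representations
#'
#' Temperature-scaled cosine-similarity cross-entropy: for anchor graph i
#' the positive pair is its clean and perturbed projections, and the
#' denominator sums over the N-1 other graphs of the minibatch. Following
#' the method's text, negatives default to the perturbed-encoder
#' representations (`negatives = "perturbed"`, pairs sim(Z_i, Z_hat_j));
#' `negatives = "unperturbed"` instead builds the denominator from clean
#' pairs sim(Z_i, Z_j), the variant the loss formula prints. The positive
#' pair is not part of the denominator, so the loss can be negative; no
#' clamping is applied.
#'
#' @param Z_proj N x p matrix of clean projected representations.
#' @param Z_hat_proj N x p matrix of perturbed projected representations.
#' @param tau Positive temperature.
#' @param negatives `"perturbed"` (default) or `"unperturbed"`.
#' @return Scalar, the minibatch-mean contrastive loss.
#' @export
contrastive_loss <- function(Z_proj, Z_hat_proj, tau = 0.2,
                             negatives = c("perturbed", "unperturbed")) {
  contrastive_parts(Z_proj, Z_hat_proj, tau, match.arg(negatives),
                    want_grad = FALSE)$value
}

# shared value/gradient implementation for the contrastive loss
contrastive_parts <- function(ZP, ZH, tau, negatives, want_grad = TRUE) {
  ZP <- as.matrix(ZP); ZH <- as.matrix(ZH)
  N <- nrow(ZP)
  if (N < 2L) stop("contrastive loss needs a minibatch of at least 2 graphs")
  if (tau <= 0) stop("tau must be positive")
  nZ <- sqrt(rowSums(ZP^2)); nH <- sqrt(rowSums(ZH^2))
  if (any(nZ == 0) || any(nH == 0))
    stop("zero-norm projected vector: cosine similarity undefined")
  Zn <- ZP / nZ; Hn <- ZH / nH
  C <- tcrossprod(Zn, Hn)                       # cos(Z_i, Z_hat_j)
  pos <- diag(C)
  Sm <- if (negatives == "perturbed") C else tcrossprod(Zn)
  E <- exp(Sm / tau); diag(E) <- 0
  den <- rowSums(E)
  value <- mean(-pos / tau + log(den))
  if (!want_grad) return(list(value = value))

  dZP <- matrix(0, N, ncol(ZP)); dZH <- matrix(0, N, ncol(ZH))
  # positive term: -(1/(tau N)) d cos(Z_i, Zh_i)
  cpos <- -1 / (tau * N)
  dZP <- dZP + cpos * (Hn - pos * Zn) / nZ
  dZH <- dZH + cpos * (Zn - pos * Hn) / nH
  # denominator: K_ij = E_ij / (den_i tau N), j != i
  K <- E / (den * tau * N)
  if (negatives == "perturbed") {
    dZP <- dZP + (K %*% Hn - rowSums(K * C) * Zn) / nZ
    dZH <- dZH + (crossprod(K, Zn) - colSums(K * C) * Hn) / nH
  } else {
    D <- tcrossprod(Zn)
    dZP <- dZP + (K %*% Zn - rowSums(K * D) * Zn) / nZ +
                 (crossprod(K, Zn) - colSums(K * D) * Zn) / nZ
  }
  list(value = value, dZP = dZP, dZH = dZH)
}

#' Node- and graph-level representation-error loss
#'
#' Mean (over graphs) of the per-node mean squared representation error
#' between the input graph and its re-encoded reconstruction (`L_node`),
#' plus the mean squared readout error (`L_graph`); `L3 = L_node + L_graph`.
#'
#' @param Z_node,Z_node_rec Lists of per-graph node representation matrices
#'   (input-side and reconstruction-side).
#' @param Z_G,Z_G_rec Matrices (one row per graph) of graph readouts.
#' @return List with `L_node`, `L_graph`, `L3`.
#' @export
error_loss <- function(Z_node, Z_node_rec, Z_G, Z_G_rec) {
  stopifnot(length(Z_node) == length(Z_node_rec))
  Z_G <- rbind(Z_G); Z_G_rec <- rbind(Z_G_rec)
  L_node <- mean(vapply(seq_along(Z_node), function(g)
    mean(rowSums((Z_node[[g]] - Z_node_rec[[g]])^2)), numeric(1)))
  L_graph <- mean(rowSums((Z_G - Z_G_rec)^2))
  list(L_node = L_node, L_graph = L_graph, L3 = L_node + L_graph)
}

#' Total training objective
#'
#' Unweighted sum of the reconstruction, contrastive, and representation-
#' error components, omitting any ablated component (`"cl"` drops the
#' contrastive term, `"node"` / `"graph"` drop the corresponding error
#' term).
#'
#' @param parts List with numeric `L1`, `L2`, `L_node`, `L_graph` (e.g. one
#'   row of a fitted model's history).
#' @param ablate Character subset of `c("node", "graph", "cl")`.
#' @return Scalar total loss.
#' @export
total_loss <- function(parts, ablate = character()) {
  bad <- setdiff(ablate, c("node", "graph", "cl"))
  if (length(bad)) stop("unknown ablation flag(s): ", paste(bad, collapse = ", "))
  if (all(c("node", "graph", "cl") %in% ablate))
    stop("configuration error: all objective components are ablated")
  parts$L1 +
    (if ("cl" %in% ablate) 0 else parts$L2) +
    (if ("node" %in% ablate) 0 else parts$L_node) +
    (if ("graph" %in% ablate) 0 else parts$L_graph)
}
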
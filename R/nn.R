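# Core dense per-graph forward machinery.
#
# Everything operates on a single graph's n x n valid block; padded batches
# are unpacked at the boundary. The encoder is the standard GCN layer
#   phi( D^{-1/2} (A + I) D^{-1/2}  Z  W )
# with no biases; degree normalization always includes the self-loop, so an
# isolated node has degree 1 and no division by zero can occur.

act_fun <- function(name) {
  switch(name,
    relu = list(f = function(x) pmax(x, 0), grad = function(pre) (pre > 0) * 1),
    tanh = list(f = tanh, grad = function(pre) 1 - tanh(pre)^2),
    identity = list(f = identity, grad = function(pre) array(1, dim(pre))),
    stop("unknown activation: ", name))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# symmetric degree normalization with self-loops; A may be binary or a
# continuous non-negative reconstruction
norm_adj <- function(A) {
  At <- A + diag(nrow(A))
  d <- rowSums(At)
  list(S = At / sqrt(outer(d, d)), d = d)
}

# stack of GCN layers; caches per-layer inputs for backprop.
# linear_last: last layer has no activation (attribute-decoder output).
gcn_stack <- function(S, X, Ws, act, linear_last = FALSE) {
  L <- length(Ws)
  layers <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    P <- S %*% H
    pre <- P %*% Ws[[l]]
    Hout <- if (l == L && linear_last) pre else act$f(pre)
    layers[[l]] <- list(Hin = H, P = P, pre = pre)
    H <- Hout
  }
  list(layers = layers, Z = H)
}

gcn_stack_backward <- function(stack, S, Ws, act, dZ, linear_last = FALSE,
                               need_dS = FALSE) {
  L <- length(Ws)
  dW <- vector("list", L)
  dH <- dZ
  dS <- if (need_dS) matrix(0, nrow(S), ncol(S)) else NULL
  for (l in rev(seq_len(L))) {
    lay <- stack$layers[[l]]
    dpre <- if (l == L && linear_last) dH else dH * act$grad(lay$pre)
    dW[[l]] <- crossprod(lay$P, dpre)
    dP <- tcrossprod(dpre, Ws[[l]])
    if (need_dS) dS <- dS + tcrossprod(dP, lay$Hin)
    dH <- crossprod(S, dP)
  }
  list(dW = dW, dX = dH, dS = dS)
}

# gradient of the loss w.r.t. a reconstruction adjacency that was degree-
# normalized: given G = dL/dS with S = At / sqrt(d_i d_j), At = A_hat + I,
# d = rowSums(At). Returns dL/dA_hat (all entries, diagonal included).
norm_adj_backward <- function(G, S, d) {
  ti <- -(rowSums(G * S) + colSums(G * S)) / (2 * d)
  G / sqrt(outer(d, d)) + matrix(ti, length(d), length(d))
}

maxpool_cache <- function(Z) {
  idx <- max.col(t(Z), ties.method = "first")
  list(zG = Z[cbind(idx, seq_len(ncol(Z)))], idx = idx)
}

maxpool_backward <- function(dzG, idx, n) {
  dZ <- matrix(0, n, length(dzG))
  dZ[cbind(idx, seq_along(dzG))] <- dzG
  dZ
}

proj_cache <- function(zG, params, act) {
  z <- matrix(zG, 1)
  q1pre <- z %*% params$Wp1 + params$bp1
  q1 <- act$f(q1pre)
  list(q1pre = q1pre, q1 = q1, zp = drop(q1 %*% params$Wp2 + params$bp2), zG = z)
}

proj_backward <- function(pc, params, act, dzp, grads) {
  dzp <- matrix(dzp, 1)
  grads$Wp2 <- grads$Wp2 + crossprod(pc$q1, dzp)
  grads$bp2 <- grads$bp2 + drop(dzp)
  dq1pre <- (dzp %*% t(params$Wp2)) * act$grad(pc$q1pre)
  grads$Wp1 <- grads$Wp1 + crossprod(pc$zG, dq1pre)
  grads$bp1 <- grads$bp1 + drop(dq1pre)
  list(grads = grads, dzG = drop(dq1pre %*% t(params$Wp1)))
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# All learnable parameters. Encoder dims d -> hidden_dims; attribute decoder
# mirrors them (hidden reversed -> d); two-layer projection head with biases
# (the GCN layers themselves carry none).
gladet_params <- function(feature_dim, hidden_dims = c(256L, 128L),
                          proj_dim = hidden_dims[length(hidden_dims)],
                          activation = "relu", dec_linear = FALSE,
                          enc_linear = TRUE) {
  enc_dims <- c(feature_dim, hidden_dims)
  dec_dims <- rev(enc_dims)
  W_enc <- lapply(seq_len(length(enc_dims) - 1L),
                  function(l) glorot(enc_dims[l], enc_dims[l + 1L]))
  W_dec <- lapply(seq_len(length(dec_dims) - 1L),
                  function(l) glorot(dec_dims[l], dec_dims[l + 1L]))
  h <- hidden_dims[length(hidden_dims)]
  list(W_enc = W_enc, W_dec = W_dec,
       Wp1 = glorot(h, proj_dim), bp1 = numeric(proj_dim),
       Wp2 = glorot(proj_dim, proj_dim), bp2 = numeric(proj_dim),
       hidden_dims = hidden_dims, proj_dim = proj_dim,
       feature_dim = feature_dim, activation = activation,
       dec_linear = dec_linear, enc_linear = enc_linear)
}

zero_grads <- function(params) {
  list(W_enc = lapply(params$W_enc, function(W) W * 0),
       W_dec = lapply(params$W_dec, function(W) W * 0),
       Wp1 = params$Wp1 * 0, bp1 = params$bp1 * 0,
       Wp2 = params$Wp2 * 0, bp2 = params$bp2 * 0)
}

# Gaussian weight-space perturbation of the encoder: W + eta * DW with
# DW ~ N(0, sigma_l^2); by default sigma_l is the empirical sd of W_l's
# entries at the moment of perturbation, scaling the noise to each layer.
draw_perturbation <- function(params, eta, sigma = "empirical") {
  lapply(params$W_enc, function(W) {
    s <- if (identical(sigma, "empirical")) stats::sd(as.vector(W)) else sigma
    W + eta * matrix(stats::rnorm(length(W), 0, s), nrow(W), ncol(W))
  })
}

# Full training forward pass for one graph (valid block only):
# encode -> pool -> project; perturbed twin (contrastive view);
# structure + attribute decoders; shared re-encoding of the reconstruction.
forward_graph <- function(A, X, params, W_enc_pert = NULL) {
  act <- act_fun(params$activation)
  el <- isTRUE(params$enc_linear)
  na <- norm_adj(A)
  enc <- gcn_stack(na$S, X, params$W_enc, act, linear_last = el)
  pool <- maxpool_cache(enc$Z)
  proj <- proj_cache(pool$zG, params, act)
  pert <- NULL
  if (!is.null(W_enc_pert)) {
    e <- gcn_stack(na$S, X, W_enc_pert, act, linear_last = el)
    p <- maxpool_cache(e$Z)
    pert <- list(enc = e, pool = p, proj = proj_cache(p$zG, params, act))
  }
  logits <- tcrossprod(enc$Z)
  A_hat <- sigmoid(logits)
  dec <- gcn_stack(na$S, enc$Z, params$W_dec, act,
                   linear_last = isTRUE(params$dec_linear))
  na2 <- norm_adj(A_hat)
  renc <- gcn_stack(na2$S, dec$Z, params$W_enc, act, linear_last = el)
  rpool <- maxpool_cache(renc$Z)
  list(na = na, enc = enc, pool = pool, proj = proj, pert = pert,
       A_hat = A_hat, dec = dec, na2 = na2, renc = renc, rpool = rpool)
}

# Backward pass for one graph. dzp / dzp_hat are the contrastive-loss
# gradients w.r.t. the projected vectors (zero vectors when ablated);
# wnode / wgraph are the prefactors of the representation-error terms
# (2/(N*n) and 2/N, or 0 when ablated); wrec is the reconstruction
# prefactor 2/N (0 when unused). Returns updated grads.
backward_graph <- function(fw, A, X, params, W_enc_pert, grads,
                           dzp, dzp_hat, wnode, wgraph, wrec) {
  act <- act_fun(params$activation)
  el <- isTRUE(params$enc_linear)
  n <- nrow(A)
  Z <- fw$enc$Z
  Zr <- fw$renc$Z
  h <- ncol(Z)

  dZ <- matrix(0, n, h)
  dZr <- matrix(0, n, h)
  if (wnode != 0) {
    E <- wnode * (Z - Zr)
    dZ <- dZ + E
    dZr <- dZr - E
  }
  dzG <- numeric(h); dzGr <- numeric(h)
  if (wgraph != 0) {
    e <- wgraph * (fw$pool$zG - fw$rpool$zG)
    dzG <- dzG + e
    dzGr <- dzGr - e
  }

  # projection heads (shared weights, both views)
  pb <- proj_backward(fw$proj, params, act, dzp, grads)
  grads <- pb$grads
  dzG <- dzG + pb$dzG
  if (!is.null(fw$pert)) {
    pbh <- proj_backward(fw$pert$proj, params, act, dzp_hat, grads)
    grads <- pbh$grads
    dZh <- maxpool_backward(pbh$dzG, fw$pert$pool$idx, n)
    bh <- gcn_stack_backward(fw$pert$enc, fw$na$S, W_enc_pert, act, dZh,
                             linear_last = el)
    for (l in seq_along(grads$W_enc))
      grads$W_enc[[l]] <- grads$W_enc[[l]] + bh$dW[[l]]
  }

  # re-encoder (shared encoder on the reconstruction graph)
  dZr <- dZr + maxpool_backward(dzGr, fw$rpool$idx, n)
  br <- gcn_stack_backward(fw$renc, fw$na2$S, params$W_enc, act, dZr,
                           linear_last = el, need_dS = TRUE)
  for (l in seq_along(grads$W_enc))
    grads$W_enc[[l]] <- grads$W_enc[[l]] + br$dW[[l]]
  dX_hat <- br$dX
  dA_hat <- norm_adj_backward(br$dS, fw$na2$S, fw$na2$d)

  # reconstruction loss terms (diagonal of A vs A_hat excluded)
  if (wrec != 0) {
    dA_rec <- wrec * (fw$A_hat - A)
    diag(dA_rec) <- 0
    dA_hat <- dA_hat + dA_rec
    dX_hat <- dX_hat + wrec * (fw$dec$Z - X)
  }

  # attribute decoder
  bd <- gcn_stack_backward(fw$dec, fw$na$S, params$W_dec, act, dX_hat,
                           linear_last = isTRUE(params$dec_linear))
  for (l in seq_along(grads$W_dec))
    grads$W_dec[[l]] <- grads$W_dec[[l]] + bd$dW[[l]]
  dZ <- dZ + bd$dX

  # structure decoder (Gram + sigmoid)
  dlogits <- dA_hat * fw$A_hat * (1 - fw$A_hat)
  dZ <- dZ + (dlogits + t(dlogits)) %*% Z

  # graph-level gradient through max pooling, then the encoder
  dZ <- dZ + maxpool_backward(dzG, fw$pool$idx, n)
  be <- gcn_stack_backward(fw$enc, fw$na$S, params$W_enc, act, dZ,
                           linear_last = el)
  for (l in seq_along(grads$W_enc))
    grads$W_enc[[l]] <- grads$W_enc[[l]] + be$dW[[l]]
  grads
}
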
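#' Fit a contrastive graph-autoencoder anomaly detector
#'
#' Trains the dual GCN autoencoder on NORMAL graphs only (one-class
#' protocol; any anomalous graph in `dataset` is an error). Each minibatch
#' runs the full forward pass — shared GCN encoder, Gaussian
#' weight-perturbed twin encoder, max-pool readout, shared projection head,
#' inner-product structure decoder, GCN attribute decoder, and re-encoding
#' of the reconstruction through the shared encoder — and minimizes the
#' unweighted sum of the reconstruction loss, the temperature-scaled
#' contrastive loss, and the node/graph representation-error loss, by Adam.
#' A trailing minibatch of size 1 is dropped (the contrastive loss is
#' undefined without negatives). All randomness (initialization, shuffling,
#' perturbation draws) is governed by `seed`; identical calls give
#' bit-identical fits in single-threaded mode.
#'
#' @param dataset A [graph_dataset()] of normal graphs with `feature_dim >= 1`
#'   (run [degree_features()] first for plain graphs).
#' @param epochs Number of epochs (>= 1; default 100).
#' @param batch_size Minibatch size (>= 2; default 300).
#' @param learning_rate Adam step size (default 1e-4).
#' @param eta Perturbation coefficient of the twin encoder (default 1).
#' @param tau Contrastive temperature (default 0.2).
#' @param hidden_dims Encoder layer widths after the input (default
#'   `c(256, 128)`, i.e. dims d-256-128; the attribute decoder mirrors them).
#' @param proj_dim Projection-head width (default: last hidden width).
#' @param activation `"relu"` (default), `"tanh"` or `"identity"`, applied
#'   to hidden layers.
#' @param encoder_output `"linear"` (default) leaves the final embedding
#'   layer unactivated, the standard convention for inner-product decoders:
#'   embeddings can be negative, so decoded edge probabilities can approach
#'   0 (with an all-ReLU encoder they are bounded below by 0.5 and the
#'   decoded graph is always dense). `"activation"` applies the activation
#'   on every layer.
#' @param decoder_output `"activation"` (default): the attribute decoder's
#'   output layer applies the activation, matching the GCN propagation rule
#'   on every layer; `"linear"` leaves it unactivated so signed features are
#'   reachable (needed for Gaussian attribute data, but it can de-activate
#'   the shared re-encoder on non-negative features).
#' @param negatives Contrastive negative pairing, see [contrastive_loss()].
#' @param sigma Perturbation scale: `"empirical"` (per-layer weight sd) or a
#'   positive number.
#' @param ablate Character subset of `c("node", "graph", "cl")`: objective
#'   components to drop.
#' @param seed Integer seed.
#' @param verbose Print per-epoch losses.
#' @return An object of class `"gladet"`: list with `params` (all weights),
#'   `config`, `history` (per-epoch loss breakdown data frame), `data_info`.
#' @seealso [predict.gladet()], [gladet_cv()], [evaluate_auc()]
#' @export
gladet <- function(dataset, epochs = 100L, batch_size = 300L,
                   learning_rate = 1e-4, eta = 1, tau = 0.2,
                   hidden_dims = c(256L, 128L),
                   proj_dim = hidden_dims[length(hidden_dims)],
                   activation = "relu",
                   encoder_output = c("linear", "activation"),
                   decoder_output = c("activation", "linear"),
                   negatives = c("perturbed", "unperturbed"),
                   sigma = "empirical", ablate = character(),
                   seed = 1L, verbose = FALSE) {
  negatives <- match.arg(negatives)
  encoder_output <- match.arg(encoder_output)
  decoder_output <- match.arg(decoder_output)
  if (!inherits(dataset, "graph_dataset")) stop("dataset must be a graph_dataset")
  if (any(graph_labels(dataset) != 0L))
    stop("one-class protocol violated: training data contains anomalous graphs")
  if (dataset$feature_dim < 1L)
    stop("graphs have no features; run degree_features() first")
  if (epochs < 1L) stop("configuration error: epochs must be >= 1")
  if (batch_size < 2L) stop("batch_size must be >= 2 (contrastive loss needs negatives)")
  total_loss(list(L1 = 0, L2 = 0, L_node = 0, L_graph = 0), ablate) # validates flags

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  params <- gladet_params(dataset$feature_dim, hidden_dims, proj_dim, activation,
                          dec_linear = decoder_output == "linear",
                          enc_linear = encoder_output == "linear")
  opt <- adam_init(params, learning_rate)
  m <- length(dataset$graphs)
  graphs <- dataset$graphs
  use_cl <- !("cl" %in% ablate)
  wN <- if ("node" %in% ablate) 0 else 1
  wG <- if ("graph" %in% ablate) 0 else 1

  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(m)
    starts <- seq(1L, m, by = batch_size)
    ep_parts <- NULL
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, m)]
      if (length(idx) < 2L) next                      # drop size-1 trailing batch
      step <- train_step(graphs[idx], params, eta, tau, sigma, negatives,
                         use_cl, wN, wG)
      opt <- adam_update(opt, params, step$grads)
      params <- opt$params
      ep_parts <- rbind(ep_parts, unlist(step$parts))
    }
    if (is.null(ep_parts))
      stop("configuration error: no usable minibatch (dataset too small?)")
    mp <- as.list(colMeans(ep_parts))
    mp$L_total <- total_loss(mp, ablate)
    history[[ep]] <- data.frame(epoch = ep, L1 = mp$L1, L2 = mp$L2,
                                L_node = mp$L_node, L_graph = mp$L_graph,
                                L3 = mp$L_node + mp$L_graph, L_total = mp$L_total)
    if (verbose)
      message(sprintf("epoch %3d  L1 %.4f  L2 %.4f  L3 %.4f  total %.4f",
                      ep, mp$L1, mp$L2, mp$L_node + mp$L_graph, mp$L_total))
  }

  structure(list(
    params = params,
    config = list(epochs = epochs, batch_size = batch_size,
                  learning_rate = learning_rate, eta = eta, tau = tau,
                  hidden_dims = hidden_dims, proj_dim = proj_dim,
                  activation = activation, encoder_output = encoder_output,
                  decoder_output = decoder_output, negatives = negatives,
                  sigma = sigma, ablate = ablate, seed = seed),
    history = do.call(rbind, history),
    data_info = list(n_train = m, feature_dim = dataset$feature_dim,
                     max_nodes = dataset$max_nodes, name = dataset$name,
                     feature_source = dataset$feature_source),
    call = match.call()), class = "gladet")
}

# one minibatch: forward all graphs, batch contrastive loss, backward all.
# W_pert overrides the perturbation draw (used by gradient checks).
train_step <- function(graphs, params, eta, tau, sigma, negatives,
                       use_cl, wN, wG, W_pert = NULL) {
  N <- length(graphs)
  if (use_cl && is.null(W_pert))
    W_pert <- draw_perturbation(params, eta, sigma)
  if (!use_cl) W_pert <- NULL
  fws <- lapply(graphs, function(g)
    forward_graph(g$adjacency, g$features, params, W_pert))

  l1 <- lnode <- lgraph <- 0
  for (b in seq_len(N)) {
    g <- graphs[[b]]; fw <- fws[[b]]
    DA <- (g$adjacency - fw$A_hat)^2; diag(DA) <- 0
    l1 <- l1 + sum(DA) + sum((g$features - fw$dec$Z)^2)
    lnode <- lnode + mean(rowSums((fw$enc$Z - fw$renc$Z)^2))
    lgraph <- lgraph + sum((fw$pool$zG - fw$rpool$zG)^2)
  }
  parts <- list(L1 = l1 / N, L_node = lnode / N, L_graph = lgraph / N)

  if (use_cl) {
    ZP <- do.call(rbind, lapply(fws, function(f) f$proj$zp))
    ZH <- do.call(rbind, lapply(fws, function(f) f$pert$proj$zp))
    cl <- contrastive_parts(ZP, ZH, tau, negatives)
    parts$L2 <- cl$value
  } else {
    parts$L2 <- 0
  }

  grads <- zero_grads(params)
  for (b in seq_len(N)) {
    g <- graphs[[b]]
    grads <- backward_graph(
      fws[[b]], g$adjacency, g$features, params, W_pert, grads,
      dzp = if (use_cl) cl$dZP[b, ] else numeric(params$proj_dim),
      dzp_hat = if (use_cl) cl$dZH[b, ] else numeric(params$proj_dim),
      wnode = wN * 2 / (N * g$n_nodes),
      wgraph = wG * 2 / N,
      wrec = 2 / N)
  }
  list(grads = grads, parts = parts[c("L1", "L2", "L_node", "L_graph")])
}

# --- flat-vector Adam over the parameter list -------------------------------

param_fields <- function(params)
  list(W_enc = params$W_enc, W_dec = params$W_dec,
       Wp1 = params$Wp1, bp1 = params$bp1, Wp2 = params$Wp2, bp2 = params$bp2)

flatten_params <- function(x) unlist(param_fields(x), use.names = FALSE)

unflatten_into <- function(params, v) {
  pos <- 0L
  take <- function(template) {
    k <- length(template)
    out <- v[(pos + 1L):(pos + k)]
    pos <<- pos + k
    if (is.matrix(template)) matrix(out, nrow(template), ncol(template)) else out
  }
  params$W_enc <- lapply(params$W_enc, take)
  params$W_dec <- lapply(params$W_dec, take)
  params$Wp1 <- take(params$Wp1); params$bp1 <- take(params$bp1)
  params$Wp2 <- take(params$Wp2); params$bp2 <- take(params$bp2)
  params
}

adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  k <- length(flatten_params(params))
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = numeric(k), v = numeric(k), t = 0L)
}

adam_update <- function(opt, params, grads) {
  g <- flatten_params(grads)
  th <- flatten_params(params)
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * g
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * g^2
  mhat <- opt$m / (1 - opt$beta1^opt$t)
  vhat <- opt$v / (1 - opt$beta2^opt$t)
  opt$params <- unflatten_into(params, th - opt$lr * mhat / (sqrt(vhat) + opt$eps))
  opt
}
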
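# graph constructors used throughout the suite

ring_graph <- function(n, label = 0L, id = NA_integer_) {
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), c(seq_len(n)[-1], 1L))] <- 1
  glad_graph(pmax(A, t(A)), label = label, graph_id = id)
}

triangle_graph <- function(...) ring_graph(3L, ...)

star_graph <- function(leaves) {
  A <- matrix(0, leaves + 1L, leaves + 1L)
  A[1, -1] <- 1; A[-1, 1] <- 1
  glad_graph(A)
}

path_graph <- function(n) {
  A <- matrix(0, n, n)
  A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- 1
  glad_graph(pmax(A, t(A)))
}

rand_graph <- function(n, p = 0.4, d = 3L, label = 0L, id = NA_integer_) {
  A <- matrix(0, n, n)
  ut <- upper.tri(A)
  A[ut] <- stats::rbinom(sum(ut), 1, p)
  glad_graph(pmax(A, t(A)), matrix(stats::rnorm(n * d), n),
             label = label, graph_id = id)
}

rand_params <- function(d = 3L, hidden = c(4L, 3L), proj = 3L,
                        activation = "relu", seed = 1L) {
  set.seed(seed)
  gladet:::gladet_params(d, hidden, proj, activation)
}

# independent scalar-loop oracles used by several test files

naive_contrastive <- function(ZP, ZH, tau, negatives) {
  cosv <- function(u, v) sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  N <- nrow(ZP)
  total <- 0
  for (i in seq_len(N)) {
    num <- exp(cosv(ZH[i, ], ZP[i, ]) / tau)
    den <- 0
    for (j in seq_len(N)) if (j != i) {
      den <- den + if (negatives == "perturbed")
        exp(cosv(ZP[i, ], ZH[j, ]) / tau)
      else
        exp(cosv(ZP[i, ], ZP[j, ]) / tau)
    }
    total <- total - log(num / den)
  }
  total / N
}

auc_pair_count <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + (p > n) + 0.5 * (p == n)
  wins / (length(pos) * length(neg))
}

# hand-written 2-graph TU fixture (triangle labelled 1, 4-cycle labelled 2),
# written file-by-file so it is independent of export_tudataset()
write_tu_fixture <- function(dir, name = "fix", with_attributes = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(s) file.path(dir, paste0(name, s))
  writeLines(c("1, 2", "2, 1", "2, 3", "3, 2", "1, 3", "3, 1",
               "4, 5", "5, 4", "5, 6", "6, 5", "6, 7", "7, 6", "4, 7", "7, 4"),
             fp("_A.txt"))
  writeLines(as.character(c(1, 1, 1, 2, 2, 2, 2)), fp("_graph_indicator.txt"))
  writeLines(c("1", "2"), fp("_graph_labels.txt"))
  if (with_attributes)
    writeLines(sprintf("%d.5, %d.0", 1:7, 7:1), fp("_node_attributes.txt"))
  invisible(dir)
}
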
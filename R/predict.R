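#' Anomaly scores for graphs under a fitted model
#'
#' The anomaly score of a graph is the representation error between the
#' input graph and its decoded reconstruction re-encoded through the shared
#' encoder:
#' `Score = (1/n) * sum_i ||Z_node,i - Z'_node,i||^2 + ||Z_G - Z'_G||^2`.
#' Scoring uses the unperturbed encoder only and is deterministic given the
#' fitted parameters; larger scores indicate more anomalous graphs.
#'
#' @param object A fitted [gladet()] model.
#' @param newdata A [graph_dataset()], a list of [glad_graph()]s, or a
#'   single `glad_graph`.
#' @param ... Unused.
#' @return Named numeric vector of non-negative scores (names = graph ids).
#' @export
predict.gladet <- function(object, newdata, ...) {
  graphs <- if (inherits(newdata, "graph_dataset")) newdata$graphs
            else if (inherits(newdata, "glad_graph")) list(newdata)
            else newdata
  d <- ncol(graphs[[1]]$features)
  if (d != object$params$feature_dim)
    stop("feature dimension mismatch: model expects ",
         object$params$feature_dim, ", data has ", d)
  scores <- vapply(graphs, function(g) score_graph(g, object$params), numeric(1))
  names(scores) <- vapply(graphs, function(g) g$graph_id, integer(1))
  scores
}

score_graph <- function(g, params) {
  fw <- forward_graph(g$adjacency, g$features, params)
  mean(rowSums((fw$enc$Z - fw$renc$Z)^2)) +
    sum((fw$pool$zG - fw$rpool$zG)^2)
}

#' Area under the ROC curve
#'
#' AUC of `scores` as a ranking statistic for `labels == 1`, computed by the
#' rank-sum (Wilcoxon) identity; ties are handled by the midrank convention,
#' so the value equals the pair-counting estimate (wins + half-ties) over
#' all (anomalous, normal) pairs.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores Numeric vector, same length.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("evaluation error: AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
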
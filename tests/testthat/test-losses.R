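test_that("reconstruction loss is zero at exact reconstruction and counts off-diagonals", {
  set.seed(1)
  g <- rand_graph(4, d = 2L)
  expect_equal(reconstruction_loss(list(g$adjacency), list(g$adjacency),
                                   list(g$features), list(g$features)), 0)
  # 2-node edgeless graph, A_hat all 0.5, features exact:
  # diagonals excluded -> 2 * 0.25 = 0.5
  A <- matrix(0, 2, 2)
  X <- matrix(rnorm(4), 2)
  expect_equal(reconstruction_loss(list(A), list(matrix(0.5, 2, 2)),
                                   list(X), list(X)), 0.5)
  # doubling the attribute residual quadruples the attribute term
  Xh <- X + 1
  l1 <- reconstruction_loss(list(A), list(A), list(X), list(Xh))
  l2 <- reconstruction_loss(list(A), list(A), list(X), list(X + 2))
  expect_equal(l2, 4 * l1)
  # batch mean: adding a perfectly reconstructed graph halves the loss
  half <- reconstruction_loss(list(A, A), list(matrix(0.5, 2, 2), A),
                              list(X, X), list(X, X))
  expect_equal(half, 0.25)
})

test_that("contrastive loss equals the brute-force pairwise loop", {
  set.seed(2)
  for (N in c(3, 5)) {
    ZP <- matrix(rnorm(N * 4), N)
    ZH <- matrix(rnorm(N * 4), N)
    for (neg in c("perturbed", "unperturbed")) {
      expect_equal(contrastive_loss(ZP, ZH, tau = 0.2, negatives = neg),
                   naive_contrastive(ZP, ZH, 0.2, neg), tolerance = 1e-9)
    }
  }
})

test_that("contrastive loss is scale invariant and zero for identical pairs", {
  set.seed(3)
  v <- rnorm(4)
  same <- rbind(v, v)
  expect_equal(contrastive_loss(same, same, tau = 0.2), 0)  # num = den = exp(1/tau)
  ZP <- matrix(rnorm(8), 2)
  ZH <- matrix(rnorm(8), 2)
  l <- contrastive_loss(ZP, ZH, tau = 0.5)
  expect_equal(contrastive_loss(3.7 * ZP, ZH, tau = 0.5), l, tolerance = 1e-12)
  expect_equal(contrastive_loss(ZP, 0.01 * ZH, tau = 0.5), l, tolerance = 1e-12)
})

test_that("contrastive loss strictly decreases in the positive-pair similarity", {
  # rotate the perturbed view of anchor 1 toward its clean view, negatives fixed
  angles <- seq(pi / 2, 0, length.out = 9)
  ZP <- rbind(c(1, 0), c(-1, 1))
  vals <- vapply(angles, function(a) {
    ZH <- rbind(c(cos(a), sin(a)), c(-1, 0.5))
    # clean-pair denominators so the negatives stay fixed along the sweep
    contrastive_loss(ZP, ZH, tau = 0.2, negatives = "unperturbed")
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("contrastive loss contract errors", {
  expect_error(contrastive_loss(matrix(1, 1, 2), matrix(1, 1, 2)), "at least 2")
  expect_error(contrastive_loss(rbind(c(0, 0), c(1, 1)), matrix(1, 2, 2)),
               "zero-norm")
  expect_error(contrastive_loss(matrix(1, 3, 2), matrix(1, 3, 2), tau = 0),
               "tau")
})

test_that("representation-error loss follows the printed per-graph means", {
  # single graph, single node, Z = (1,0), Z' = (0,1)
  el <- error_loss(list(rbind(c(1, 0))), list(rbind(c(0, 1))),
                   rbind(c(1, 0)), rbind(c(0, 1)))
  expect_equal(el$L_node, 2)
  expect_equal(el$L_graph, 2)
  expect_equal(el$L3, 4)
  # zero error
  el0 <- error_loss(list(rbind(c(1, 0))), list(rbind(c(1, 0))),
                    rbind(c(1, 0)), rbind(c(1, 0)))
  expect_equal(el0$L3, 0)
  # adding a zero-error graph halves both means
  el2 <- error_loss(list(rbind(c(1, 0)), rbind(c(1, 1))),
                    list(rbind(c(0, 1)), rbind(c(1, 1))),
                    rbind(c(1, 0), c(1, 1)), rbind(c(0, 1), c(1, 1)))
  expect_equal(el2$L_node, 1)
  expect_equal(el2$L_graph, 1)
})

test_that("the total objective sums enabled components only", {
  parts <- list(L1 = 1, L2 = 2, L_node = 1.5, L_graph = 1.5)
  expect_equal(total_loss(parts), 6)
  expect_equal(total_loss(parts, "cl"), 4)
  expect_equal(total_loss(parts, c("node", "graph")), 3)
  expect_equal(total_loss(parts, c("node", "cl")), 2.5)
  expect_error(total_loss(parts, c("node", "graph", "cl")), "configuration error")
  expect_error(total_loss(parts, "decoder"), "unknown ablation")
})
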
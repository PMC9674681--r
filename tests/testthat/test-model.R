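test_that("max pooling takes coordinate-wise maxima over valid nodes only", {
  Z <- rbind(c(1, 0), c(0, 1))
  expect_equal(max_pool(Z), c(1, 1))
  expect_equal(max_pool(rbind(c(2, -1))), c(2, -1))            # single node
  Z3 <- rbind(c(1, 5), c(9, 2), c(3, 3))
  expect_equal(max_pool(Z3, mask = c(1, 0, 1)), c(3, 5))       # row 2 masked out
  p <- c(3, 1, 2)
  expect_equal(max_pool(Z3[p, ]), max_pool(Z3))                # permutation invariant
  expect_error(max_pool(Z3, mask = c(0, 0, 0)), "valid node")
})

test_that("the structure decoder is a sigmoid Gram matrix on the valid block", {
  expect_equal(decode_structure(matrix(0, 3, 2)), matrix(0.5, 3, 3))
  set.seed(1)
  Z <- matrix(rnorm(12), 4)
  Ah <- decode_structure(Z)
  expect_identical(Ah, t(Ah))
  expect_true(all(Ah > 0 & Ah < 1))
  # two orthogonal unit rows
  U <- rbind(c(1, 0), c(0, 1))
  Au <- decode_structure(U)
  expect_equal(Au[1, 2], 0.5)
  expect_equal(Au[1, 1], 1 / (1 + exp(-1)), tolerance = 1e-12)
  # masked rows/cols zeroed
  Am <- decode_structure(Z, mask = c(1, 1, 1, 0))
  expect_true(all(Am[4, ] == 0) && all(Am[, 4] == 0))
})

test_that("the attribute decoder matches a hand-rolled two-step computation", {
  set.seed(2)
  params <- rand_params(d = 3L, hidden = c(4L, 3L))
  g <- rand_graph(3, 0.6, d = 3L)
  Z <- matrix(rnorm(9), 3)
  out <- decode_attributes(g$adjacency, Z, params)
  S <- gladet:::norm_adj(g$adjacency)$S
  hand <- pmax(S %*% pmax(S %*% Z %*% params$W_dec[[1]], 0) %*% params$W_dec[[2]], 0)
  expect_equal(out, hand, tolerance = 1e-12)
  expect_equal(dim(out), c(3L, 3L))
  # linear-output variant leaves the last layer unactivated
  params_lin <- params
  params_lin$dec_linear <- TRUE
  out_lin <- decode_attributes(g$adjacency, Z, params_lin)
  expect_equal(out_lin,
               S %*% pmax(S %*% Z %*% params$W_dec[[1]], 0) %*% params$W_dec[[2]],
               tolerance = 1e-12)
  # edgeless graph: reduces to a row-wise MLP
  out0 <- decode_attributes(matrix(0, 3, 3), Z, params)
  expect_equal(out0, pmax(pmax(Z %*% params$W_dec[[1]], 0) %*% params$W_dec[[2]], 0))
})

test_that("eta = 0 makes the perturbed branch bit-identical to the clean one", {
  set.seed(3)
  graphs <- lapply(1:3, function(i) rand_graph(4, d = 3L, id = i))
  params <- rand_params()
  b <- pad_and_batch(graphs, 4)
  clean <- encode_graphs(b, params)
  pert0 <- encode_graphs(b, params, perturbed = TRUE, eta = 0, seed = 7)
  expect_identical(clean, pert0)
  # and the projected positive-pair cosine is exactly 1
  zp <- project_head(clean$Z_G[1, ], params)
  zp0 <- project_head(pert0$Z_G[1, ], params)
  expect_identical(zp, zp0)
  expect_equal(sum(zp * zp0) / (sqrt(sum(zp^2)) * sqrt(sum(zp0^2))), 1,
               tolerance = 1e-15)
})

test_that("perturbed encoding is reproducible under a seed and differs across seeds", {
  set.seed(3)
  graphs <- lapply(1:3, function(i) rand_graph(4, d = 3L, id = i))
  params <- rand_params()
  b <- pad_and_batch(graphs, 4)
  p1 <- encode_graphs(b, params, perturbed = TRUE, eta = 1, seed = 5)
  p2 <- encode_graphs(b, params, perturbed = TRUE, eta = 1, seed = 5)
  expect_identical(p1, p2)
  p3 <- encode_graphs(b, params, perturbed = TRUE, eta = 1, seed = 6)
  expect_false(identical(p1, p3))
})

test_that("perturbation magnitude matches the half-normal mean", {
  set.seed(8)
  params <- rand_params(d = 10L, hidden = c(64L, 32L))
  ratios <- replicate(30, {
    Wp <- gladet:::draw_perturbation(params, eta = 1, sigma = "empirical")
    mean(vapply(seq_along(Wp), function(l) {
      s <- sd(as.vector(params$W_enc[[l]]))
      mean(abs(Wp[[l]] - params$W_enc[[l]])) / s
    }, numeric(1)))
  })
  expect_equal(mean(ratios), sqrt(2 / pi), tolerance = 0.02)
})

test_that("the projection head is shared between the two views", {
  set.seed(9)
  params <- rand_params()
  g <- rand_graph(5, d = 3L)
  Wp <- gladet:::draw_perturbation(params, eta = 1)
  fw <- gladet:::forward_graph(g$adjacency, g$features, params, Wp)
  # the perturbed view's projection equals applying the single shared head
  expect_identical(fw$pert$proj$zp, project_head(fw$pert$pool$zG, params))
  expect_length(fw$proj$zp, params$proj_dim)
})

test_that("re-encoding an exact reconstruction reproduces the clean representations", {
  set.seed(10)
  params <- rand_params()
  g <- rand_graph(5, d = 3L)
  b <- pad_and_batch(list(g), 5)
  clean <- encode_graphs(b, params)
  re <- encode_reconstruction(g$adjacency, g$features, params)
  expect_identical(re$Z_node, matrix(clean$Z_node[1, , ], 5))
  expect_identical(re$Z_G, clean$Z_G[1, ])
})
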
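test_that("reading the TU layout preserves graphs, order and labels", {
  dir <- withr::local_tempdir()
  write_tu_fixture(dir)
  ds <- read_tudataset(dir, "fix", anomaly_class = 2)
  expect_s3_class(ds, "graph_dataset")
  expect_length(ds$graphs, 2L)
  expect_equal(vapply(ds$graphs, function(g) g$n_nodes, integer(1)), c(3L, 4L))
  expect_equal(vapply(ds$graphs, n_edges, integer(1)), c(3L, 4L))
  expect_equal(ds$max_nodes, 4L)
  expect_equal(graph_labels(ds), c(0L, 1L))
  # adjacency is symmetric, hollow, binary by construction
  for (g in ds$graphs) {
    expect_identical(g$adjacency, t(g$adjacency))
    expect_true(all(diag(g$adjacency) == 0))
  }
  # total node count equals the indicator file's line count
  expect_equal(sum(vapply(ds$graphs, function(g) g$n_nodes, integer(1))),
               length(readLines(file.path(dir, "fix_graph_indicator.txt"))))
})

test_that("node attributes become features in file order", {
  dir <- withr::local_tempdir()
  write_tu_fixture(dir, with_attributes = TRUE)
  ds <- read_tudataset(dir, "fix", anomaly_class = 2)
  expect_equal(ds$feature_dim, 2L)
  expect_equal(ds$feature_source, "attributes")
  expect_equal(ds$graphs[[1]]$features[, 1], c(1.5, 2.5, 3.5))
  expect_equal(ds$graphs[[2]]$features[, 2], c(4, 3, 2, 1))
})

test_that("node labels are one-hot encoded when no attributes exist", {
  dir <- withr::local_tempdir()
  write_tu_fixture(dir)
  writeLines(as.character(c(0, 1, 0, 2, 2, 1, 0)),
             file.path(dir, "fix_node_labels.txt"))
  ds <- read_tudataset(dir, "fix", anomaly_class = 2)
  expect_equal(ds$feature_dim, 3L)
  expect_equal(ds$graphs[[1]]$features,
               rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0)))
})

test_that("missing mandatory files and broken indices are rejected", {
  dir <- withr::local_tempdir()
  write_tu_fixture(dir)
  expect_error(read_tudataset(dir, "fix"), "anomaly_class")
  file.remove(file.path(dir, "fix_graph_indicator.txt"))
  expect_error(read_tudataset(dir, "fix", anomaly_class = 2),
               "graph_indicator")

  dir2 <- withr::local_tempdir()
  write_tu_fixture(dir2)
  # an edge joining nodes of two different graphs
  cat("1, 5\n", file = file.path(dir2, "fix_A.txt"), append = TRUE)
  expect_error(read_tudataset(dir2, "fix", anomaly_class = 2),
               "different graphs")

  dir3 <- withr::local_tempdir()
  write_tu_fixture(dir3)
  cat("1, 99\n", file = file.path(dir3, "fix_A.txt"), append = TRUE)
  expect_error(read_tudataset(dir3, "fix", anomaly_class = 2), "outside")
})

test_that("duplicate and one-directional edge lines are OR-merged", {
  dir <- withr::local_tempdir()
  fp <- function(s) file.path(dir, paste0("m", s))
  writeLines(c("1, 2", "1, 2", "2, 3"), fp("_A.txt"))   # dup + one-directional
  writeLines(c("1", "1", "1"), fp("_graph_indicator.txt"))
  writeLines("1", fp("_graph_labels.txt"))
  ds <- read_tudataset(dir, "m", anomaly_class = 9)
  expect_equal(n_edges(ds$graphs[[1]]), 2L)
  expect_identical(ds$graphs[[1]]$adjacency, t(ds$graphs[[1]]$adjacency))
})

test_that("export then read round-trips a dataset (1-based indices on disk)", {
  ds <- generate_motif_set(3, 2, "global", seed = 11)
  dir <- withr::local_tempdir()
  export_tudataset(ds, dir, "rt")
  back <- read_tudataset(dir, "rt", anomaly_class = 1)
  expect_length(back$graphs, length(ds$graphs))
  expect_equal(vapply(back$graphs, function(g) g$n_nodes, integer(1)),
               vapply(ds$graphs, function(g) g$n_nodes, integer(1)))
  expect_equal(vapply(back$graphs, n_edges, integer(1)),
               vapply(ds$graphs, n_edges, integer(1)))
  expect_equal(graph_labels(back), graph_labels(ds))
  expect_equal(back$graphs[[2]]$adjacency, ds$graphs[[2]]$adjacency)
  expect_equal(back$graphs[[2]]$features, ds$graphs[[2]]$features)
  edges <- read.table(file.path(dir, "rt_A.txt"), sep = ",")
  expect_true(min(edges) >= 1)   # TU files are 1-based
  expect_error(export_tudataset(list(), withr::local_tempdir()), "non-empty")
})

test_that("degree features follow the stated encodings", {
  tri <- graph_dataset(list(triangle_graph()))
  oh <- degree_features(tri, "onehot")
  expect_equal(oh$feature_dim, 3L)                 # dataset max degree 2
  expect_equal(oh$graphs[[1]]$features,
               matrix(rep(c(0, 0, 1), each = 3), 3))

  st <- degree_features(graph_dataset(list(star_graph(3))), "scalar")
  expect_equal(st$graphs[[1]]$features, matrix(c(3, 1, 1, 1), ncol = 1))

  pa <- degree_features(graph_dataset(list(path_graph(3))), "onehot")
  expect_equal(pa$graphs[[1]]$features,
               rbind(c(0, 1, 0), c(0, 0, 1), c(0, 1, 0)))

  # native attributes are kept unless forced
  dir <- withr::local_tempdir()
  write_tu_fixture(dir, with_attributes = TRUE)
  ds <- read_tudataset(dir, "fix", anomaly_class = 2)
  expect_equal(degree_features(ds)$feature_source, "attributes")
  expect_equal(degree_features(ds, force = TRUE)$feature_source, "degree_onehot")
})
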
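test_that("louvain finds the exhaustive-search optimum on two bridged triangles", {
  g <- two_triangles_bridge()
  cl <- louvain_cluster(g, granularity = 1, weighted = FALSE, seed = 1)
  expect_equal(length(cl$sizes), 2)
  expect_equal(unname(cl$label_of[c("a", "b", "c")]),
               rep(cl$label_of[["a"]], 3))
  expect_equal(unname(cl$label_of[c("d", "e", "f")]),
               rep(cl$label_of[["d"]], 3))
  # independent oracle: maximise modularity over all 203 partitions
  parts <- all_partitions(6)
  expect_length(parts, 203)
  best <- max(vapply(parts, function(p) direct_modularity(g, p), numeric(1)))
  expect_equal(cl$quality, best, tolerance = 1e-12)
  expect_equal(cl$quality, 5 / 14, tolerance = 1e-12)   # 2*(3/7 - (7/14)^2)
})

test_that("edgeless graphs give singletons with Q = 0; cliques give one cluster", {
  g0 <- graph_new(letters[1:5])
  cl0 <- louvain_cluster(g0, 1)
  expect_equal(length(cl0$sizes), 5)
  expect_equal(cl0$quality, 0)
  pairs <- t(utils::combn(letters[1:6], 2))
  kq <- graph_new(edges = data.frame(from = pairs[, 1], to = pairs[, 2]))
  clq <- louvain_cluster(kq, 1, seed = 2)
  expect_equal(length(clq$sizes), 1)
})

test_that("louvain partitions are hard, contiguously named and size-ordered", {
  pp <- planted_partition_graph(c(30, 20, 10), 0.4, 0.02, seed = 5)
  cl <- louvain_cluster(pp$graph, 1, seed = 5)
  expect_setequal(names(cl$label_of), pp$graph$nodes)
  expect_equal(names(cl$sizes), paste("Cluster", seq_along(cl$sizes)))
  expect_true(all(diff(cl$sizes) <= 0))
  expect_equal(sum(cl$sizes), n_nodes(pp$graph))
  # quality is at least the singleton partition's
  q_singleton <- modularity_q(pp$graph, stats::setNames(pp$graph$nodes,
                                                        pp$graph$nodes))
  expect_gte(cl$quality, q_singleton)
})

test_that("louvain is reproducible per seed and recovers planted blocks", {
  pp <- planted_partition_graph(rep(20, 4), 0.3, 0.02, seed = 3)
  a <- louvain_cluster(pp$graph, 1, seed = 7)
  b <- louvain_cluster(pp$graph, 1, seed = 7)
  expect_identical(a, b)
  hits <- 0
  for (s in 1:20) {
    pp <- planted_partition_graph(rep(20, 4), 0.3, 0.02, seed = s)
    cl <- louvain_cluster(pp$graph, 1, seed = s)
    if (ari(cl$label_of[names(pp$labels)], pp$labels) >= 0.95) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("granularity moves cluster count in the expected direction", {
  pp <- planted_partition_graph(rep(16, 4), 0.5, 0.05, seed = 2)
  n_lo <- length(louvain_cluster(pp$graph, 0.3, seed = 1)$sizes)
  n_hi <- length(louvain_cluster(pp$graph, 2.5, seed = 1)$sizes)
  expect_lte(n_lo, n_hi)
})

test_that("mcl separates bridged triangles and matches the dense oracle", {
  g <- two_triangles_bridge()
  cl <- mcl_cluster(g, granularity = 2)
  expect_equal(length(cl$sizes), 2)
  oracle <- dense_mcl_oracle(g, 2)
  expect_equal(ari(cl$label_of[g$nodes], oracle[g$nodes]), 1)
  expect_equal(sort(unname(cl$label_of[c("a", "b", "c")])),
               rep(cl$label_of[["a"]], 3))
})

test_that("disconnected cliques are never merged at any inflation", {
  mk <- function(prefix) {
    p <- t(utils::combn(paste0(prefix, 1:4), 2))
    data.frame(from = p[, 1], to = p[, 2], weight = 1)
  }
  g <- graph_new(edges = rbind(mk("x"), mk("y")))
  for (infl in c(1.3, 2, 5)) {
    cl <- mcl_cluster(g, infl)
    expect_equal(length(cl$sizes), 2)
    expect_equal(unname(cl$label_of["x1"] == cl$label_of["x4"]), TRUE)
    expect_equal(unname(cl$label_of["x1"] == cl$label_of["y1"]), FALSE)
  }
})

test_that("higher inflation never coarsens the clustering", {
  pp <- planted_partition_graph(rep(20, 4), 0.3, 0.02, seed = 4)
  counts <- vapply(c(1.4, 2, 4, 6), function(infl)
    length(mcl_cluster(pp$graph, infl)$sizes), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("mcl assigns every node exactly once with size-ordered names", {
  pp <- planted_partition_graph(rep(15, 3), 0.4, 0.03, seed = 8)
  cl <- mcl_cluster(pp$graph, 1.7)
  expect_setequal(names(cl$label_of), pp$graph$nodes)
  expect_true(all(diff(cl$sizes) <= 0))
  expect_equal(sum(cl$sizes), n_nodes(pp$graph))
})

test_that("aggregate_by_cluster averages the clustered axis", {
  m <- matrix(c(1, 2, 3, 4,
                3, 4, 5, 6,
                10, 10, 10, 10,
                20, 20, 20, 20), 4, 4, byrow = TRUE,
              dimnames = list(c("r1", "r2", "r3", "r4"), paste0("s", 1:4)))
  lab <- c(r1 = "Cluster 1", r2 = "Cluster 1", r3 = "Cluster 2",
           r4 = "Cluster 2")
  agg <- aggregate_by_cluster(data_matrix(m), lab, margin = "rows")
  expect_equal(agg$values["Cluster 1", ],
               stats::setNames(c(2, 3, 4, 5), paste0("s", 1:4)))
  expect_equal(agg$values["Cluster 2", ],
               stats::setNames(c(15, 15, 15, 15), paste0("s", 1:4)))
  # singleton clusters: identity up to reordering
  single <- stats::setNames(paste("Cluster", 1:4), rownames(m))
  agg1 <- aggregate_by_cluster(data_matrix(m), single, margin = "rows")
  expect_equal(unname(agg1$values), unname(m))
  # columns-as-elements aggregation
  labc <- stats::setNames(c("Cluster 1", "Cluster 1", "Cluster 2", "Cluster 2"),
                          paste0("s", 1:4))
  aggc <- aggregate_by_cluster(data_matrix(m), labc, margin = "columns")
  expect_equal(unname(aggc$values[, "Cluster 1"]), c(1.5, 3.5, 10, 20))
  expect_error(aggregate_by_cluster(data_matrix(m), lab[1:2], "rows"),
               "no cluster label")
})
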
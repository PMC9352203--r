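clique_edges <- function(prefix, n) {
  p <- t(utils::combn(n, 2))
  data.frame(from = paste0(prefix, p[, 1]), to = paste0(prefix, p[, 2]),
             weight = 1)
}

offset_clearances <- function(layout) {
  off <- layout$component_offsets
  if (nrow(off) < 2) return(numeric(0))
  d <- as.matrix(stats::dist(off[, c("x", "y", "z")]))
  rr <- outer(off$radius, off$radius, "+")
  (d - rr)[upper.tri(d)]
}

test_that("a single node sits at the origin; a single edge relaxes to ideal length", {
  one <- force_layout(graph_new("solo"), seed = 1)
  expect_equal(unname(one$coords["solo", ]), c(0, 0, 0))
  expect_true(one$converged)
  pair <- graph_new(edges = data.frame(from = "a", to = "b", weight = 1))
  l <- force_layout(pair, dims = 3, seed = 2, ideal_length = 1)
  expect_true(l$converged)
  d <- sqrt(sum((l$coords["a", ] - l$coords["b", ])^2))
  expect_gt(d, 0.95)
  expect_lt(d, 1.05)
})

test_that("layouts are bit-identical for a fixed seed, different across seeds", {
  g <- random_test_graph(30, 0.2, seed = 5)
  a <- force_layout(g, seed = 11)
  b <- force_layout(g, seed = 11)
  expect_identical(a$coords, b$coords)
  c3 <- force_layout(g, seed = 12)
  expect_false(identical(a$coords, c3$coords))
  # 2D layouts carry exactly two coordinates
  l2 <- force_layout(g, dims = 2, seed = 1)
  expect_equal(ncol(l2$coords), 2)
})

test_that("component bounding spheres are pairwise disjoint", {
  # forest of 50 path components of varying size
  set.seed(1)
  ed <- do.call(rbind, lapply(1:50, function(i) {
    n <- sample(1:6, 1)
    if (n == 1) return(NULL)
    data.frame(from = sprintf("c%02d_%d", i, 1:(n - 1)),
               to = sprintf("c%02d_%d", i, 2:n), weight = 1)
  }))
  g <- graph_new(sprintf("c%02d_1", 1:50), ed)
  l <- force_layout(g, seed = 3)
  expect_equal(nrow(l$component_offsets), length(graph_components(g)$sizes))
  expect_true(all(offset_clearances(l) > 0))
  # rank 0 (largest component) is centred at the origin
  expect_equal(unname(unlist(l$component_offsets[1, c("x", "y", "z")])),
               c(0, 0, 0))
})

test_that("components are arranged large-to-small from the centre outwards", {
  sizes <- c(12, 6, 3, 1)
  ed <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    n <- sizes[i]
    if (n == 1) return(NULL)
    clique_edges(sprintf("g%d_", i), n)
  }))
  g <- graph_new(sprintf("g%d_1", seq_along(sizes)), ed)
  l <- force_layout(g, seed = 2)
  off <- l$component_offsets
  centre_dist <- sqrt(off$x^2 + off$y^2 + off$z^2)
  expect_equal(centre_dist[1], 0)
  expect_true(all(diff(centre_dist) >= -1e-9))   # non-decreasing with rank
  expect_true(all(offset_clearances(l) > 0))
})

test_that("planted cliques end up internally tighter than their separation", {
  e <- rbind(clique_edges("x", 15), clique_edges("y", 15),
             data.frame(from = "x1", to = "y1", weight = 1))
  g <- graph_new(edges = e)
  wins <- 0
  for (s in 1:20) {
    l <- force_layout(g, seed = s)
    cx <- l$coords[paste0("x", 1:15), ]
    cy <- l$coords[paste0("y", 1:15), ]
    intra <- mean(c(stats::dist(cx), stats::dist(cy)))
    inter <- mean(as.matrix(stats::dist(l$coords))[paste0("x", 1:15),
                                                   paste0("y", 1:15)])
    if (intra < inter) wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("rigid motion of coordinates leaves edge-length statistics unchanged", {
  g <- random_test_graph(20, 0.3, seed = 7)
  l <- force_layout(g, seed = 7)
  len <- function(xy) {
    sqrt(rowSums((xy[g$edges$from, , drop = FALSE] -
                  xy[g$edges$to, , drop = FALSE])^2))
  }
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3)
  moved <- l$coords %*% rot
  moved <- sweep(moved, 2, c(5, -3, 2), "+")
  rownames(moved) <- rownames(l$coords)
  expect_equal(len(moved), len(l$coords), tolerance = 1e-9)
})

test_that("layout TSV export carries one row per node with coordinates", {
  g <- random_test_graph(8, 0.4, seed = 4)
  l <- force_layout(g, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_layout(l, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(back), n_nodes(g))
  expect_setequal(names(back), c("id", "x", "y", "z"))
  expect_equal(back$x[match(rownames(l$coords), back$id)],
               unname(l$coords[, "x"]))
})
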
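test_that("k-NN keeps an edge iff it is top-k for at least one endpoint", {
  tri <- graph_new(edges = data.frame(from = c("a", "b", "a"),
                                      to = c("b", "c", "c"),
                                      weight = c(3, 2, 1)))
  pruned <- knn_prune(tri, 1)
  expect_setequal(edge_key_df(pruned), c("a|b", "b|c"))
  # k >= max degree leaves the graph unchanged
  expect_equal(edge_key_df(knn_prune(tri, 5)), edge_key_df(tri))
  # star with distinct leaf weights, k = 1: every leaf keeps its only edge
  star <- graph_new(edges = data.frame(from = "hub", to = paste0("l", 1:5),
                                       weight = c(5, 4, 3, 2, 1) / 10))
  expect_equal(n_edges(knn_prune(star, 1)), 5)
})

test_that("k-NN contract holds on random graphs: union rule, max edge, idempotence", {
  for (seed in 1:10) {
    g <- random_test_graph(20, 0.4, seed)
    k <- 1 + (seed %% 4)
    p <- knn_prune(g, k)
    expect_equal(p$nodes, g$nodes)
    expect_lte(n_edges(p), k * n_nodes(g))
    # union rule: every kept edge is top-k of an endpoint; checked by rank
    ranks <- function(gr, id) {
      inc <- gr$edges$from == id | gr$edges$to == id
      w <- gr$edges$weight[inc]
      stats::setNames(rank(-w, ties.method = "min"), edge_key_df(gr)[inc])
    }
    for (key in edge_key_df(p)) {
      ends <- strsplit(key, "|", fixed = TRUE)[[1]]
      expect_true(ranks(g, ends[1])[key] <= k || ranks(g, ends[2])[key] <= k)
    }
    # every non-isolated node keeps its maximum-weight edge
    for (id in g$nodes) {
      inc <- g$edges$from == id | g$edges$to == id
      if (!any(inc)) next
      best <- edge_key_df(g)[inc][which.max(g$edges$weight[inc])]
      expect_true(best %in% edge_key_df(p))
    }
    # idempotence
    p2 <- knn_prune(p, k)
    expect_equal(p2$edges, p$edges)
  }
})

test_that("mutual k-NN is a subset of union k-NN", {
  g <- random_test_graph(15, 0.5, seed = 3)
  u <- knn_prune(g, 2)
  m <- knn_prune(g, 2, mutual = TRUE)
  expect_true(all(edge_key_df(m) %in% edge_key_df(u)))
})

test_that("edge filters drop failing edges but keep all nodes", {
  g <- graph_new(edges = data.frame(from = c("a", "b", "c"),
                                    to = c("b", "c", "d"),
                                    weight = c(0.2, 0.5, 0.9)))
  h <- filter_edges(g, ~ weight >= 0.5)
  expect_equal(n_edges(h), 2)
  expect_equal(h$nodes, g$nodes)
  expect_equal(edge_key_df(filter_edges(g, ~ weight >= 0)), edge_key_df(g))
  # attribute-based rule: drop low-support edges (n < 3)
  g2 <- set_edge_attr(g, "n", c(1, 2, 7))
  h2 <- filter_edges(g2, ~ n >= 3)
  expect_equal(edge_key_df(h2), "c|d")
  expect_error(filter_edges(g, ~ frequency >= 3), "missing edge attribute.*frequency")
})

test_that("node filters use attribute values captured before removal", {
  path4 <- graph_new(edges = data.frame(from = paste0("p", 1:3),
                                        to = paste0("p", 2:4)))
  path4 <- add_degree_attr(path4)
  h <- filter_nodes(path4, ~ Degree >= 2)
  # single pass: middle nodes survive (degree computed on the input graph),
  # and so does the edge between them
  expect_setequal(h$nodes, c("p2", "p3"))
  expect_equal(edge_key_df(h), "p2|p3")
  expect_equal(filter_nodes(path4, ~ TRUE)$nodes, path4$nodes)
  expect_equal(n_nodes(filter_nodes(path4, ~ FALSE)), 0)
  expect_error(filter_nodes(path4, ~ PageRank > 0.1),
               "missing node attribute.*PageRank")
})

test_that("outlier-style combined rule removes poorly connected nodes only", {
  # nodes failing both criteria (max correlation < 0.85 AND degree < 10)
  # are dropped, mirroring the cell-network outlier filter
  set.seed(2)
  core <- sprintf("c%02d", 1:12)
  pairs <- t(utils::combn(core, 2))
  g <- graph_new(edges = data.frame(from = pairs[, 1], to = pairs[, 2],
                                    weight = stats::runif(nrow(pairs), 0.9, 1)))
  g <- add_edges(g, "outlier", "c01", 0.3)
  g <- add_degree_attr(g)
  rmax <- vapply(g$nodes, function(id) {
    inc <- g$edges$from == id | g$edges$to == id
    if (any(inc)) max(g$edges$weight[inc]) else -Inf
  }, numeric(1))
  g <- set_node_attr(g, "r_max", rmax)
  h <- filter_nodes(g, ~ !(r_max < 0.85 & Degree < 10))
  expect_setequal(h$nodes, core)
})

test_that("remove_components drops only small components, intact otherwise", {
  g <- graph_new(
    nodes = "iso",
    edges = data.frame(from = c("a", "a", "b", "c", "x"),
                       to   = c("b", "c", "c", "d", "y")))
  # sizes 4 (a-d), 2 (x,y), 1 (iso)
  h <- remove_components(g, 2)
  expect_setequal(h$nodes, c("a", "b", "c", "d", "x", "y"))
  h3 <- remove_components(g, 3)
  expect_setequal(h3$nodes, c("a", "b", "c", "d"))
  expect_setequal(edge_key_df(h3), c("a|b", "a|c", "b|c", "c|d"))
  expect_equal(remove_components(g, 1)$nodes, g$nodes)
  expect_equal(n_nodes(remove_components(g, 10)), 0)
})

test_that("contracting a matching path merges it into one labelled node", {
  p <- graph_new(edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                                    weight = 1))
  h <- contract_edges(p, ~ weight >= 0.5)
  expect_equal(h$nodes, "a")
  expect_equal(unname(get_node_attr(h, "members")), "a;b;c")
  expect_equal(unname(get_node_attr(h, "n_members")), 3)
  expect_equal(n_edges(h), 0)
})

test_that("contraction takes the quotient and collapses parallel edges", {
  sq <- graph_new(edges = data.frame(from = c("a", "b", "c", "d"),
                                     to   = c("b", "c", "d", "a"),
                                     weight = c(10, 1, 10, 2)))
  h <- contract_edges(sq, ~ weight >= 5)     # contracts ab and cd
  expect_setequal(h$nodes, c("a", "c"))
  expect_equal(n_edges(h), 1)                # two parallels collapsed
  expect_equal(h$edges$weight, 2)            # maximum of the parallel weights
  expect_equal(sum(get_node_attr(h, "n_members")), 4)
  # no matching edge: identity on nodes and the weighted edge set
  same <- contract_edges(sq, ~ weight > 100)
  expect_setequal(same$nodes, sq$nodes)
  expect_setequal(edge_key_df(same), edge_key_df(sq))
  ord <- match(edge_key_df(sq), edge_key_df(same))
  expect_equal(same$edges$weight[ord], sq$edges$weight)
})

test_that("contraction preserves total member count and sums additive columns", {
  g <- random_test_graph(15, 0.35, seed = 6)
  g <- set_node_attr(g, "count", as.numeric(seq_len(15)))
  h <- contract_edges(g, ~ weight > 0.5, additive = "count")
  expect_equal(sum(get_node_attr(h, "n_members")), 15)
  expect_equal(sum(get_node_attr(h, "count")), sum(1:15))
})

test_that("transform stacks compose in order and log element counts", {
  g <- random_test_graph(25, 0.3, seed = 9)
  stack <- list(list(name = "filter_edges", predicate = ~ weight >= 0.4),
                list(name = "knn", k = 2),
                list(name = "remove_components", min_nodes = 2))
  staged <- apply_stack(g, stack)
  manual <- remove_components(knn_prune(filter_edges(g, ~ weight >= 0.4), 2), 2)
  expect_equal(staged$nodes, manual$nodes)
  expect_equal(staged$edges, manual$edges)
  log <- attr(staged, "transform_log")
  expect_equal(nrow(log), 4)               # input + 3 steps
  expect_equal(log$edges[1], n_edges(g))
  # empty stack is the identity
  id <- apply_stack(g, list())
  expect_equal(id$edges, g$edges)
  expect_error(apply_stack(g, list(list(name = "explode"))),
               "unknown transform")
})

test_that("transforms never mutate their input graph", {
  g <- random_test_graph(12, 0.4, seed = 13)
  snapshot <- g
  invisible(knn_prune(g, 2))
  invisible(filter_edges(g, ~ weight > 0.5))
  invisible(remove_components(g, 3))
  invisible(contract_edges(g, ~ weight > 0.5))
  expect_identical(g, snapshot)
})
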
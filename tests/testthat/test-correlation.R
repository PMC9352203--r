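test_that("correlation matrix matches hand values and the scalar oracle", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  colnames(m) <- paste0("s", 1:3)
  r <- correlation_matrix(data_matrix(m))
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  m2 <- rbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  colnames(m2) <- paste0("s", 1:4)
  expect_equal(correlation_matrix(data_matrix(m2))["x", "y"], 0.8)
  expect_equal(naive_pearson(m2["x", ], m2["y", ]), 0.8)
})

test_that("pearson and spearman agree with the naive two-pass oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(stats::rnorm(200), 20, 10,
                dimnames = list(sprintf("r%02d", 1:20), sprintf("c%02d", 1:10)))
    for (method in c("pearson", "spearman")) {
      got <- correlation_matrix(data_matrix(m), method = method)
      want <- naive_correlation_matrix(m, method)
      expect_lt(max(abs(got - want)), 1e-12)
    }
  }
})

test_that("symmetry, unit diagonal and range hold with missing data", {
  set.seed(9)
  m <- matrix(stats::rnorm(120), 12, 10,
              dimnames = list(sprintf("r%02d", 1:12), sprintf("c%02d", 1:10)))
  m[sample(length(m), 25)] <- NA
  r <- correlation_matrix(data_matrix(m))
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 12))
  expect_true(all(abs(r[!is.na(r)]) <= 1))
})

test_that("pairs with fewer than 3 shared observations get no value", {
  m <- rbind(a = c(1, 2, NA, 4, 5),
             b = c(5, 3, NA, NA, NA),
             c = c(1, 2, 3, 4, 5))
  colnames(m) <- paste0("s", 1:5)
  r <- correlation_matrix(data_matrix(m))
  expect_true(is.na(r["a", "b"]))      # only 2 shared points
  expect_false(is.na(r["a", "c"]))
  g <- build_correlation_graph(data_matrix(m), r_min = -1, inclusive = TRUE,
                               drop_constant = FALSE)
  expect_false("a|b" %in% edge_key_df(g))
})

test_that("thresholded graph keeps exactly the passing pairs per polarity", {
  set.seed(1)
  base <- stats::rnorm(20)
  m <- rbind(A = base, B = 2 * base, C = -base, D = stats::rnorm(20))
  colnames(m) <- paste0("s", 1:20)
  g_pos <- build_correlation_graph(data_matrix(m), r_min = 0.9)
  expect_equal(edge_key_df(g_pos), "A|B")
  expect_equal(g_pos$edges$weight, 1)
  g_abs <- build_correlation_graph(data_matrix(m), r_min = 0.9,
                                   polarity = "absolute")
  expect_setequal(edge_key_df(g_abs), c("A|B", "A|C", "B|C"))
  # signed weights kept under absolute polarity
  expect_equal(sort(g_abs$edges$weight), c(-1, -1, 1))
  # oracle: full matrix then filter gives the same edge set
  r <- correlation_matrix(data_matrix(m))
  ut <- which(upper.tri(r) & r > 0.9, arr.ind = TRUE)
  expect_equal(nrow(ut), n_edges(g_pos))
})

test_that("strict threshold at r_min = 1 warns and yields no edges", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(g <- build_correlation_graph(data_matrix(m), r_min = 1),
                 "admits no edges")
  expect_equal(n_edges(g), 0)
  g_inc <- build_correlation_graph(data_matrix(m), r_min = 1, inclusive = TRUE)
  expect_equal(n_edges(g_inc), 1)
})

test_that("edge sets are monotone in the threshold", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- matrix(stats::rnorm(150), 15, 10,
                dimnames = list(sprintf("r%02d", 1:15), sprintf("c%02d", 1:10)))
    dm <- data_matrix(m)
    t1 <- stats::runif(1, -0.5, 0.5)
    t2 <- t1 + stats::runif(1, 0, 0.5)
    e1 <- edge_key_df(build_correlation_graph(dm, r_min = t1))
    e2 <- edge_key_df(build_correlation_graph(dm, r_min = t2))
    expect_true(all(e2 %in% e1))
  }
})

test_that("column permutation leaves the graph unchanged; row permutation renames", {
  set.seed(5)
  m <- matrix(stats::rnorm(100), 10, 10,
              dimnames = list(sprintf("r%02d", 1:10), sprintf("c%02d", 1:10)))
  dm <- data_matrix(m)
  g <- build_correlation_graph(dm, r_min = 0.2)
  gp <- build_correlation_graph(data_matrix(m[, sample(10)]), r_min = 0.2)
  expect_setequal(edge_key_df(g), edge_key_df(gp))
  perm <- sample(10)
  gr <- build_correlation_graph(data_matrix(m[perm, ]), r_min = 0.2)
  expect_setequal(edge_key_df(gr), edge_key_df(g))
})

test_that("spearman is invariant to strictly monotone per-row transforms", {
  set.seed(3)
  m <- matrix(stats::rnorm(80), 8, 10,
              dimnames = list(sprintf("r%02d", 1:8), sprintf("c%02d", 1:10)))
  r1 <- correlation_matrix(data_matrix(m), method = "spearman")
  m2 <- m
  m2[1, ] <- exp(m2[1, ])        # strictly increasing
  m2[2, ] <- m2[2, ]^3
  m2[3, ] <- 5 * m2[3, ] + 2
  r2 <- correlation_matrix(data_matrix(m2), method = "spearman")
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("blocked computation equals the unblocked graph", {
  set.seed(8)
  m <- matrix(stats::rnorm(300), 30, 10,
              dimnames = list(sprintf("r%02d", 1:30), sprintf("c%02d", 1:10)))
  dm <- data_matrix(m)
  g1 <- build_correlation_graph(dm, r_min = 0.3, block_size = 512)
  g2 <- build_correlation_graph(dm, r_min = 0.3, block_size = 7)
  expect_setequal(edge_key_df(g1), edge_key_df(g2))
  ord <- match(edge_key_df(g1), edge_key_df(g2))
  expect_equal(g2$edges$weight[ord], g1$edges$weight)
})

test_that("row annotations become node attributes on the graph", {
  pm <- planted_module_matrix(2, 3, 10, 0.9, seed = 2)
  g <- build_correlation_graph(pm$matrix, r_min = 0.5)
  expect_equal(get_node_attr(g, "Module"), pm$labels[g$nodes])
})
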
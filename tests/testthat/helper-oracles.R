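# Independent oracles and small generators used across the suite.  These
# deliberately re-derive results by brute force or direct formula evaluation,
# sharing no code with the package internals they check.

# Erdos-Renyi style random weighted graph on letter-number ids
random_test_graph <- function(n, p = 0.3, seed = 1, weighted = TRUE) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  g <- graph_new(ids)
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    hit <- stats::runif(ncol(pairs)) < p
    if (any(hit)) {
      w <- if (weighted) stats::runif(sum(hit), 0.1, 1) else rep(1, sum(hit))
      g <- add_edges(g, ids[pairs[1, hit]], ids[pairs[2, hit]], w)
    }
  }
  g
}

random_attributed_graph <- function(n, p = 0.3, seed = 1) {
  g <- random_test_graph(n, p, seed)
  set.seed(seed + 1000)
  g <- set_node_attr(g, "group",
                     sample(c("alpha", "beta", "gamma"), n, replace = TRUE),
                     kind = "categorical")
  g <- set_node_attr(g, "score", round(stats::rnorm(n), 4))
  if (n_edges(g))
    g <- set_edge_attr(g, "support",
                       as.numeric(sample(1:9, n_edges(g), replace = TRUE)))
  g
}

# naive two-pass scalar Pearson: explicit mean, then explicit sums
naive_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  unname(sxy / sqrt(sxx * syy))
}

naive_correlation_matrix <- function(m, method = "pearson") {
  if (method == "spearman")
    m <- t(apply(m, 1, function(r) {
      out <- rep(NA_real_, length(r)); ok <- !is.na(r)
      out[ok] <- rank(r[ok]); out
    }))
  n <- nrow(m)
  r <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    r[i, j] <- r[j, i] <- naive_pearson(m[i, ], m[j, ])
  dimnames(r) <- list(rownames(m), rownames(m))
  r
}

# adjacency list straight from the public edge table
edge_adjacency <- function(g) {
  n <- length(g$nodes)
  adj <- rep(list(integer()), n)
  eid <- rep(list(integer()), n)
  fi <- match(g$edges$from, g$nodes); ti <- match(g$edges$to, g$nodes)
  for (e in seq_along(fi)) {
    adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e]); eid[[fi[e]]] <- c(eid[[fi[e]]], e)
    adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e]); eid[[ti[e]]] <- c(eid[[ti[e]]], e)
  }
  list(adj = adj, eid = eid)
}

bfs_dist <- function(adj, s, n) {
  dist <- rep(-1L, n); dist[s] <- 0L; q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (u in adj[[v]]) if (dist[u] < 0L) { dist[u] <- dist[v] + 1L; q <- c(q, u) }
  }
  dist
}

# brute-force betweenness: enumerate every shortest path for every pair
brute_betweenness <- function(g) {
  n <- length(g$nodes)
  a <- edge_adjacency(g)
  node_bc <- stats::setNames(numeric(n), g$nodes)
  edge_bc <- numeric(nrow(g$edges))
  if (n < 2) return(list(nodes = node_bc, edges = edge_bc))
  for (s in seq_len(n - 1)) {
    dist <- bfs_dist(a$adj, s, n)
    for (t in (s + 1):n) {
      if (dist[t] < 0) next
      # enumerate shortest paths t -> s walking down the distance gradient
      paths <- list(list(nodes = t, edges = integer()))
      done <- list()
      while (length(paths)) {
        nxt <- list()
        for (p in paths) {
          v <- p$nodes[1]
          if (v == s) { done[[length(done) + 1]] <- p; next }
          for (k in seq_along(a$adj[[v]])) {
            u <- a$adj[[v]][k]
            if (dist[u] == dist[v] - 1L)
              nxt[[length(nxt) + 1]] <- list(nodes = c(u, p$nodes),
                                             edges = c(a$eid[[v]][k], p$edges))
          }
        }
        paths <- nxt
      }
      np <- length(done)
      for (p in done) {
        interior <- setdiff(p$nodes, c(s, t))
        node_bc[interior] <- node_bc[interior] + 1 / np
        edge_bc[p$edges] <- edge_bc[p$edges] + 1 / np
      }
    }
  }
  list(nodes = node_bc, edges = edge_bc)
}

# PageRank as the solution of the explicit linear system
solve_pagerank <- function(g, damping = 0.85, weighted = TRUE) {
  n <- length(g$nodes)
  A <- matrix(0, n, n)
  if (nrow(g$edges)) {
    fi <- match(g$edges$from, g$nodes); ti <- match(g$edges$to, g$nodes)
    w <- if (weighted) g$edges$weight else rep(1, nrow(g$edges))
    A[cbind(fi, ti)] <- A[cbind(fi, ti)] + w
    A[cbind(ti, fi)] <- A[cbind(ti, fi)] + w
  }
  out <- colSums(A)
  M <- matrix(1 / n, n, n)
  nz <- out > 0
  M[, nz] <- sweep(A[, nz, drop = FALSE], 2, out[nz], "/")
  p <- solve(diag(n) - damping * M, rep((1 - damping) / n, n))
  stats::setNames(p / sum(p), g$nodes)
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  recur <- function(prefix, maxc) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (c in seq_len(maxc + 1)) recur(c(prefix, c), max(maxc, c))
  }
  recur(integer(0), 0L)
  out
}

# direct modularity from the edge table (resolution 1, unit weights)
direct_modularity <- function(g, membership_idx) {
  m <- nrow(g$edges)
  fi <- match(g$edges$from, g$nodes); ti <- match(g$edges$to, g$nodes)
  deg <- tabulate(c(fi, ti), nbins = length(g$nodes))
  q <- 0
  for (c in unique(membership_idx)) {
    inc <- membership_idx == c
    e_c <- sum(inc[fi] & inc[ti])
    d_c <- sum(deg[inc])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# independent dense-matrix MCL run to convergence (no sharing with package)
dense_mcl_oracle <- function(g, inflation, weighted = TRUE,
                             prune = 1e-5, tol = 1e-8, max_iter = 200) {
  n <- length(g$nodes)
  A <- matrix(0, n, n)
  if (nrow(g$edges)) {
    fi <- match(g$edges$from, g$nodes); ti <- match(g$edges$to, g$nodes)
    w <- if (weighted) g$edges$weight else rep(1, nrow(g$edges))
    A[cbind(fi, ti)] <- w; A[cbind(ti, fi)] <- w
  }
  loop <- apply(A, 1, max); loop[loop <= 0] <- 1
  diag(A) <- loop
  cn <- function(M) { s <- colSums(M); s[s == 0] <- 1; sweep(M, 2, s, "/") }
  M <- cn(A)
  for (it in seq_len(max_iter)) {
    Mn <- cn(cn(M %*% M)^inflation)
    Mn[Mn < prune] <- 0
    Mn <- cn(Mn)
    if (max(abs(Mn - M)) < tol) { M <- Mn; break }
    M <- Mn
  }
  nz <- (M > 0) | t(M > 0)
  comp <- integer(n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L; q <- s; comp[s] <- cid
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nb <- which(nz[v, ] & comp == 0L); comp[nb] <- cid; q <- c(q, nb)
    }
  }
  stats::setNames(comp, g$nodes)
}

# two triangles joined by one bridge edge c--d
two_triangles_bridge <- function() {
  graph_new(edges = data.frame(
    from = c("a", "a", "b", "d", "d", "e", "c"),
    to   = c("b", "c", "c", "e", "f", "f", "d"),
    weight = 1))
}

edge_key_df <- function(g) paste(g$edges$from, g$edges$to, sep = "|")

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
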
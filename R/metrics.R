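# Node/edge analytics stored as attributes: PageRank, betweenness (nodes and
# edges, Brandes accumulation on hop-count shortest paths), eccentricity and
# degree.  Betweenness and eccentricity are computed per connected component;
# correlation weights are similarities, not distances, so shortest paths are
# unweighted throughout.

#' PageRank
#'
#' Power iteration on the damped random walk.  Undirected edges act as a
#' bidirectional pair; edge weights are the transition proportions out of a
#' node.  Teleportation is uniform over all nodes, and the walk mass of
#' dangling (isolated) nodes is redistributed uniformly, so the values sum
#' to 1.
#'
#' @param graph A `cgraph` (non-empty).
#' @param damping Damping factor; default 0.85.
#' @param weighted Use edge weights as transition proportions; default `TRUE`.
#' @param tol L1 convergence tolerance; default `1e-10`.
#' @param max_iter Iteration cap; exceeding it is an error reporting the
#'   residual.
#' @return Named numeric vector summing to 1.
#' @export
pagerank <- function(graph, damping = 0.85, weighted = TRUE,
                     tol = 1e-10, max_iter = 200) {
  n <- n_nodes(graph)
  if (!n) stop("empty graph")
  fi <- match(graph$edges$from, graph$nodes)
  ti <- match(graph$edges$to, graph$nodes)
  w <- if (weighted && n_edges(graph)) graph$edges$weight
       else rep(1, n_edges(graph))
  out_strength <- numeric(n)
  for (e in seq_along(w)) {
    out_strength[fi[e]] <- out_strength[fi[e]] + w[e]
    out_strength[ti[e]] <- out_strength[ti[e]] + w[e]
  }
  dangling <- out_strength == 0
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    contrib <- numeric(n)
    if (length(w)) {
      pf <- p[fi] / out_strength[fi]
      pt <- p[ti] / out_strength[ti]
      for (e in seq_along(w)) {
        contrib[ti[e]] <- contrib[ti[e]] + w[e] * pf[e]
        contrib[fi[e]] <- contrib[fi[e]] + w[e] * pt[e]
      }
    }
    dangle_mass <- sum(p[dangling])
    p_new <- (1 - damping) / n + damping * (contrib + dangle_mass / n)
    if (sum(abs(p_new - p)) < tol) {
      names(p_new) <- graph$nodes
      return(p_new / sum(p_new))
    }
    p <- p_new
  }
  stop(sprintf("PageRank did not converge in %d iterations (L1 residual %.3g)",
               max_iter, sum(abs(p_new - p))))
}

#' Betweenness centrality for nodes and edges
#'
#' Brandes' dependency accumulation over unweighted (hop-count) shortest
#' paths, computed within each component.  Scores are raw (unnormalised)
#' pair counts over unordered pairs; path endpoints are excluded from node
#' scores.
#'
#' @param graph A `cgraph`.
#' @return List with `nodes` (named numeric) and `edges` (numeric, aligned
#'   with the edge table).
#' @export
betweenness <- function(graph) {
  n <- n_nodes(graph)
  node_bc <- stats::setNames(numeric(n), graph$nodes)
  edge_bc <- numeric(n_edges(graph))
  if (n < 2 || !n_edges(graph))
    return(list(nodes = node_bc, edges = edge_bc))
  adjacency <- .adjacency(graph)
  for (s in seq_len(n)) {
    # BFS from s
    dist <- rep(-1L, n); sigma <- numeric(n)
    preds <- vector("list", n); pred_eid <- vector("list", n)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- integer(n); qh <- 1L; qt <- 1L; queue[1] <- s
    order_visited <- integer(0)
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      order_visited <- c(order_visited, v)
      nbrs <- adjacency$adj[[v]]
      eids <- adjacency$eid[[v]]
      for (k in seq_along(nbrs)) {
        u <- nbrs[k]
        if (dist[u] < 0L) {
          dist[u] <- dist[v] + 1L
          qt <- qt + 1L; queue[qt] <- u
        }
        if (dist[u] == dist[v] + 1L) {
          sigma[u] <- sigma[u] + sigma[v]
          preds[[u]] <- c(preds[[u]], v)
          pred_eid[[u]] <- c(pred_eid[[u]], eids[k])
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(order_visited)) {
      ps <- preds[[v]]
      for (k in seq_along(ps)) {
        u <- ps[k]
        c_share <- (sigma[u] / sigma[v]) * (1 + delta[v])
        delta[u] <- delta[u] + c_share
        edge_bc[pred_eid[[v]][k]] <- edge_bc[pred_eid[[v]][k]] + c_share
      }
      if (v != s) node_bc[v] <- node_bc[v] + delta[v]
    }
  }
  # each unordered pair counted from both endpoints
  list(nodes = node_bc / 2, edges = edge_bc / 2)
}

#' Eccentricity
#'
#' A node's maximum hop distance to any node of its own component; isolated
#' nodes score 0.  The edge value is the maximum of the endpoint values.
#'
#' @param graph A `cgraph`.
#' @return List with `nodes` (named numeric) and `edges` (numeric, aligned
#'   with the edge table).
#' @export
eccentricity <- function(graph) {
  n <- n_nodes(graph)
  ecc <- stats::setNames(numeric(n), graph$nodes)
  if (n && n_edges(graph)) {
    adjacency <- .adjacency(graph)
    for (s in seq_len(n)) {
      dist <- rep(-1L, n)
      dist[s] <- 0L
      queue <- integer(n); qh <- 1L; qt <- 1L; queue[1] <- s
      while (qh <= qt) {
        v <- queue[qh]; qh <- qh + 1L
        for (u in adjacency$adj[[v]]) {
          if (dist[u] < 0L) {
            dist[u] <- dist[v] + 1L
            qt <- qt + 1L; queue[qt] <- u
          }
        }
      }
      ecc[s] <- max(dist)
    }
  }
  e_val <- if (n_edges(graph)) {
    pmax(ecc[graph$edges$from], ecc[graph$edges$to])
  } else numeric(0)
  list(nodes = ecc, edges = unname(e_val))
}

#' Annotate a graph with computed metrics
#'
#' Stores the requested analytics as attribute columns: `Degree`,
#' `PageRank`, `Betweenness` (+ edge column `Edge Betweenness`),
#' `Eccentricity` (+ `Edge Eccentricity`).
#'
#' @param graph A `cgraph`.
#' @param metrics Any of `"degree"`, `"pagerank"`, `"betweenness"`,
#'   `"eccentricity"`.
#' @param ... Passed to [pagerank()].
#' @return The annotated graph.
#' @export
annotate_metrics <- function(graph,
                             metrics = c("degree", "pagerank", "betweenness",
                                         "eccentricity"),
                             ...) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if ("degree" %in% metrics)
    graph <- add_degree_attr(graph)
  if ("pagerank" %in% metrics)
    graph <- set_node_attr(graph, "PageRank", pagerank(graph, ...))
  if ("betweenness" %in% metrics) {
    bc <- betweenness(graph)
    graph <- set_node_attr(graph, "Betweenness", bc$nodes)
    graph <- set_edge_attr(graph, "Edge Betweenness", bc$edges)
  }
  if ("eccentricity" %in% metrics) {
    ec <- eccentricity(graph)
    graph <- set_node_attr(graph, "Eccentricity", ec$nodes)
    graph <- set_edge_attr(graph, "Edge Eccentricity", ec$edges)
  }
  graph
}
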
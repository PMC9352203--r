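# Graph clustering with a single "granularity" knob per algorithm:
#   - Louvain: granularity = resolution gamma in
#       Q(gamma) = sum_c [ e_c/m - gamma * (d_c / 2m)^2 ]
#     (weighted edge fractions e_c and strengths d_c); larger gamma favours
#     more, smaller clusters.
#   - MCL: granularity = the inflation exponent; larger inflation likewise
#     gives finer clusters.
# Both return a hard partition with clusters named "Cluster 1..N" in
# descending size order (ties broken by smallest member id).

.make_assignment <- function(graph, membership, quality = NA_real_) {
  # membership: integer vector aligned with graph$nodes
  ids <- graph$nodes
  groups <- split(ids, membership)
  min_member <- vapply(groups, function(g) g[order(g, method = "radix")][1],
                       character(1))
  ord <- order(-lengths(groups), min_member, method = "radix")
  label_of <- character(length(ids))
  for (ci in seq_along(ord)) {
    label_of[ids %in% groups[[ord[ci]]]] <- paste("Cluster", ci)
  }
  structure(list(
    label_of = stats::setNames(label_of, ids),
    sizes = stats::setNames(lengths(groups)[ord], paste("Cluster", seq_along(ord))),
    quality = quality
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d clusters over %d nodes",
              length(x$sizes), length(x$label_of)))
  if (!is.na(x$quality)) cat(sprintf(", modularity Q = %.4f", x$quality))
  cat("\nSizes:", paste(utils::head(x$sizes, 12), collapse = " "),
      if (length(x$sizes) > 12) "..." else "", "\n")
  invisible(x)
}

#' Modularity of a partition
#'
#' Weighted Newman-Girvan modularity with resolution `gamma`:
#' `Q = sum_c [ e_c/m - gamma * (d_c/2m)^2 ]` where `e_c` is the total
#' intra-cluster edge weight, `d_c` the total strength of the cluster's
#' nodes and `m` the total edge weight.
#'
#' @param graph A `cgraph`.
#' @param membership Cluster labels: a `cluster_assignment`, or a vector
#'   named by (or aligned with) node id.
#' @param gamma Resolution; default 1.
#' @param weighted Use edge weights (`TRUE`) or unit weights.
#' @return Modularity Q (0 for an edgeless graph).
#' @export
modularity_q <- function(graph, membership, gamma = 1, weighted = TRUE) {
  if (inherits(membership, "cluster_assignment"))
    membership <- membership$label_of
  if (!is.null(names(membership)))
    membership <- membership[graph$nodes]
  if (length(membership) != n_nodes(graph))
    stop("membership must cover every node")
  if (!n_edges(graph)) return(0)
  w <- if (weighted) graph$edges$weight else rep(1, n_edges(graph))
  m <- sum(w)
  comm <- as.integer(factor(membership))
  fi <- comm[match(graph$edges$from, graph$nodes)]
  ti <- comm[match(graph$edges$to, graph$nodes)]
  e_c <- tapply(w[fi == ti], fi[fi == ti], sum)
  strength <- numeric(max(comm))
  for (e in seq_along(w)) {
    strength[fi[e]] <- strength[fi[e]] + w[e]
    strength[ti[e]] <- strength[ti[e]] + w[e]
  }
  intra <- numeric(max(comm))
  if (length(e_c)) intra[as.integer(names(e_c))] <- e_c
  sum(intra / m - gamma * (strength / (2 * m))^2)
}

#' Louvain community detection
#'
#' Greedy multi-level modularity maximisation with resolution
#' `granularity`: repeated local-move sweeps (nodes visited in an order
#' shuffled by `seed`) until no move improves modularity by more than
#' `1e-9`, then aggregation of clusters into super-nodes, repeated until the
#' aggregated pass yields no further gain.
#'
#' @param graph A `cgraph` (non-empty).
#' @param granularity Resolution gamma (> 0); the paper-style knob where
#'   smaller values give fewer, larger clusters.  Default 1.
#' @param weighted Use edge weights; default `TRUE`.
#' @param seed Integer seed controlling the node visiting order; a fixed
#'   seed makes the run bit-reproducible.
#' @return A `cluster_assignment` with `quality` = final modularity.
#' @export
louvain_cluster <- function(graph, granularity = 1, weighted = TRUE, seed = 1) {
  if (!n_nodes(graph)) stop("empty graph")
  if (!is.numeric(granularity) || granularity <= 0)
    stop("Louvain granularity (resolution) must be > 0")
  if (!n_edges(graph)) {
    return(.make_assignment(graph, seq_len(n_nodes(graph)), quality = 0))
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))

  n0 <- n_nodes(graph)
  fi <- match(graph$edges$from, graph$nodes)
  ti <- match(graph$edges$to, graph$nodes)
  w <- if (weighted) graph$edges$weight else rep(1, n_edges(graph))
  membership0 <- seq_len(n0)   # node -> current flat community
  gamma <- granularity
  repeat {
    n <- max(membership0)
    # build aggregated edge list between current communities
    res <- .louvain_one_level(n, fi, ti, w, gamma)
    if (!res$improved) break
    # relabel and aggregate
    membership0 <- res$comm[membership0]
    agg <- .aggregate_edges(res$comm[fi], res$comm[ti], w)
    fi <- agg$fi; ti <- agg$ti; w <- agg$w
    # self-loops (intra-community weight) are retained in the aggregate and
    # handled by the local-move gain formula
    if (max(membership0) == n) break
  }
  q <- modularity_q(graph, stats::setNames(membership0, graph$nodes),
                    gamma = gamma, weighted = weighted)
  .make_assignment(graph, membership0, quality = q)
}

# one local-moving level over a multigraph given by (fi, ti, w); self-loops
# allowed.  Returns densely renumbered community vector and whether any node
# moved with positive gain.
.louvain_one_level <- function(n, fi, ti, w, gamma) {
  m2 <- 2 * sum(w)                      # 2m (self-loops count once in sum(w))
  # adjacency lists
  adj <- vector("list", n); aw <- vector("list", n)
  self_w <- numeric(n)
  for (e in seq_along(fi)) {
    a <- fi[e]; b <- ti[e]
    if (a == b) { self_w[a] <- self_w[a] + w[e]; next }
    adj[[a]] <- c(adj[[a]], b); aw[[a]] <- c(aw[[a]], w[e])
    adj[[b]] <- c(adj[[b]], a); aw[[b]] <- c(aw[[b]], w[e])
  }
  strength <- self_w * 2
  for (i in seq_len(n)) strength[i] <- strength[i] + sum(aw[[i]])
  comm <- seq_len(n)
  comm_strength <- strength
  improved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      nb <- adj[[i]]
      if (!length(nb)) next
      # weight from i to each neighbouring community
      wc <- tapply(aw[[i]], comm[nb], sum)
      comm_strength[ci] <- comm_strength[ci] - strength[i]
      w_own <- if (as.character(ci) %in% names(wc)) wc[[as.character(ci)]] else 0
      gain_stay <- w_own - gamma * strength[i] * comm_strength[ci] / m2
      best_c <- ci; best_gain <- gain_stay
      for (cn in as.integer(names(wc))) {
        if (cn == ci) next
        gain <- wc[[as.character(cn)]] -
          gamma * strength[i] * comm_strength[cn] / m2
        if (gain > best_gain + 1e-9) { best_gain <- gain; best_c <- cn }
      }
      comm_strength[best_c] <- comm_strength[best_c] + strength[i]
      if (best_c != ci) { comm[i] <- best_c; moved <- TRUE; improved_any <- TRUE }
    }
    if (!moved) break
  }
  dense <- match(comm, sort(unique(comm)))
  list(comm = dense, improved = improved_any)
}

# collapse a multigraph edge list by community, keeping self-loops
.aggregate_edges <- function(cf, ct, w) {
  lo <- pmin(cf, ct); hi <- pmax(cf, ct)
  key <- paste(lo, hi)
  s <- tapply(w, key, sum)
  parts <- strsplit(names(s), " ", fixed = TRUE)
  list(fi = as.integer(vapply(parts, `[[`, character(1), 1)),
       ti = as.integer(vapply(parts, `[[`, character(1), 2)),
       w = as.numeric(s))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Markov clustering (MCL)
#'
#' Markov clustering on the weighted adjacency matrix with self-loops added
#' (loop weight = the node's maximum incident weight, damping odd-cycle
#' parity effects).  Columns are normalised to a stochastic matrix, then
#' expansion (matrix squaring) alternates with inflation (entrywise power
#' `granularity`, renormalise).  Entries below `prune` are zeroed after each
#' inflation.  Iteration stops when the maximum absolute column change falls
#' below `tol` or after `max_iter` rounds (with a warning).  Clusters are
#' the connected components of the nonzero structure of the limit matrix;
#' should any node sit in two attractor systems it goes to the larger
#' cluster (tie: the one with the smallest member id).
#'
#' @param graph A `cgraph` (non-empty).
#' @param granularity Inflation exponent (> 1); larger = finer clusters.
#'   Default 2.
#' @param weighted Use edge weights; default `TRUE`.
#' @param prune Zero threshold applied after inflation; default `1e-5`.
#' @param tol Convergence tolerance on the max column change; default `1e-8`.
#' @param max_iter Iteration cap; default 100.
#' @return A `cluster_assignment` (quality is `NA`; MCL optimises no global
#'   objective).
#' @export
mcl_cluster <- function(graph, granularity = 2, weighted = TRUE,
                        prune = 1e-5, tol = 1e-8, max_iter = 100) {
  if (!n_nodes(graph)) stop("empty graph")
  if (!is.numeric(granularity) || granularity <= 1)
    stop("MCL granularity (inflation) must be > 1")
  n <- n_nodes(graph)
  A <- matrix(0, n, n)
  if (n_edges(graph)) {
    fi <- match(graph$edges$from, graph$nodes)
    ti <- match(graph$edges$to, graph$nodes)
    w <- if (weighted) graph$edges$weight else rep(1, n_edges(graph))
    A[cbind(fi, ti)] <- w
    A[cbind(ti, fi)] <- w
  }
  loop <- apply(A, 1, max)
  loop[loop <= 0] <- 1            # isolated nodes: unit self-loop
  diag(A) <- loop
  M <- .col_normalise(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M_new <- M %*% M                              # expansion
    M_new <- .col_normalise(M_new^granularity)    # inflation
    M_new[M_new < prune] <- 0
    M_new <- .col_normalise(M_new)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; interpreting current matrix")
  membership <- .interpret_mcl(M)
  .make_assignment(graph, membership)
}

.col_normalise <- function(M) {
  s <- colSums(M)
  s[s == 0] <- 1
  sweep(M, 2, s, "/")
}

# clusters = connected components of the nonzero structure (symmetrised)
.interpret_mcl <- function(M) {
  n <- nrow(M)
  nz <- (M > 0) | t(M > 0)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(nz[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Aggregate a data matrix by cluster
#'
#' Replaces the clustered axis by per-cluster means, e.g. averaging gene
#' expression over the cells in each cell cluster before building a gene
#' coexpression graph.
#'
#' @param dm A `data_matrix`.
#' @param assignment A `cluster_assignment` (or named label vector) over the
#'   clustered axis' ids.
#' @param margin `"rows"` if the clustered elements are matrix rows,
#'   `"columns"` if they are columns.
#' @return A `data_matrix` whose clustered axis holds one entry per cluster,
#'   in cluster-name order.
#' @export
aggregate_by_cluster <- function(dm, assignment, margin = c("rows", "columns")) {
  margin <- match.arg(margin)
  labels <- if (inherits(assignment, "cluster_assignment"))
    assignment$label_of else assignment
  x <- dm$values
  ids <- if (margin == "rows") rownames(x) else colnames(x)
  miss <- setdiff(ids, names(labels))
  if (length(miss))
    stop("no cluster label for: ", paste(utils::head(miss, 5), collapse = ", "))
  lab <- labels[ids]
  num <- suppressWarnings(as.integer(sub("^Cluster ", "", unique(labels))))
  lev <- if (anyNA(num)) {
    u <- unique(labels); u[order(u, method = "radix")]
  } else {
    unique(labels)[order(num)]
  }
  lev <- lev[lev %in% lab]
  if (margin == "rows") {
    agg <- t(vapply(lev, function(cl)
      colMeans(x[lab == cl, , drop = FALSE], na.rm = TRUE),
      numeric(ncol(x))))
    rownames(agg) <- lev
    data_matrix(agg)
  } else {
    agg <- vapply(lev, function(cl)
      rowMeans(x[, lab == cl, drop = FALSE], na.rm = TRUE),
      numeric(nrow(x)))
    colnames(agg) <- lev
    data_matrix(agg)
  }
}

#' Attach cluster labels as a node attribute
#'
#' @param graph A `cgraph`.
#' @param assignment A `cluster_assignment` covering the graph's nodes.
#' @param name Attribute column name, e.g. `"Louvain Cluster"`.
#' @return The graph with a categorical cluster attribute.
#' @export
set_cluster_attr <- function(graph, assignment, name = "Cluster") {
  set_node_attr(graph, name, assignment$label_of[graph$nodes],
                kind = "categorical")
}
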
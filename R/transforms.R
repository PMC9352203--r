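# The composable transform stack: k-NN edge pruning, edge/node filtering,
# small-component removal and edge contraction.  Every transform is pure --
# the input graph is returned untouched -- and predicates are one-sided
# formulas evaluated against the element attribute table, e.g.
# `~ weight >= 0.85` or `~ Degree >= 10`.

# evaluate a predicate (formula or function) against an attribute data frame
.eval_predicate <- function(predicate, attrs, scope) {
  if (inherits(predicate, "formula")) {
    vars <- all.vars(predicate)
    missing_vars <- setdiff(vars, names(attrs))
    if (length(missing_vars))
      stop("predicate references missing ", scope, " attribute(s): ",
           paste(missing_vars, collapse = ", "))
    res <- eval(predicate[[2]], envir = attrs, enclos = environment(predicate))
  } else if (is.function(predicate)) {
    res <- predicate(attrs)
  } else {
    stop("predicate must be a one-sided formula or a function")
  }
  res <- as.logical(res)
  res <- rep_len(res, nrow(attrs))
  res & !is.na(res)
}

.edge_attr_frame <- function(graph) {
  df <- cbind(data.frame(weight = graph$edges$weight), graph$edge_attrs)
  rownames(df) <- NULL
  df
}

.node_attr_frame <- function(graph) {
  df <- graph$node_attrs
  rownames(df) <- NULL
  cbind(data.frame(id = graph$nodes, stringsAsFactors = FALSE), df)
}

#' k-nearest-neighbour edge pruning
#'
#' Keeps an edge iff it ranks among the top-`k` weights of at least one of
#' its endpoints (the union rule), so no node is ever isolated by pruning and
#' every non-isolated node retains its maximum-weight edge.  Ties in weight
#' are broken by lexicographic edge identity for determinism.  With
#' `mutual = TRUE` the intersection rule is used instead (edge must be top-k
#' for both endpoints).
#'
#' @param graph A `cgraph`.
#' @param k Number of neighbours to keep per node (`k >= 1`).
#' @param mutual Use the mutual (intersection) rule; default `FALSE`.
#' @return The pruned graph; node set unchanged.
#' @examples
#' g <- graph_new(edges = data.frame(from = c("a", "b", "a"),
#'                                   to   = c("b", "c", "c"),
#'                                   weight = c(3, 2, 1)))
#' knn_prune(g, k = 1)$edges   # keeps a--b and b--c
#' @export
knn_prune <- function(graph, k, mutual = FALSE) {
  if (!is.numeric(k) || k < 1) stop("k must be >= 1")
  k <- as.integer(k)
  m <- n_edges(graph)
  if (!m) return(graph)
  # deterministic tie-break: lexicographic (from, to) after weight
  ekey <- .edge_key(graph$edges$from, graph$edges$to)
  ord_key <- order(graph$edges$from, graph$edges$to, method = "radix")
  tie_rank <- integer(m); tie_rank[ord_key] <- seq_len(m)
  adjacency <- .adjacency(graph)
  top <- matrix(FALSE, nrow = m, ncol = 2)  # hit per endpoint side
  hits <- integer(0)
  per_node_top <- vector("list", n_nodes(graph))
  for (i in seq_len(n_nodes(graph))) {
    eids <- adjacency$eid[[i]]
    if (!length(eids)) next
    w <- adjacency$w[[i]]
    o <- order(-w, tie_rank[eids])
    per_node_top[[i]] <- eids[o[seq_len(min(k, length(o)))]]
  }
  counts <- tabulate(unlist(per_node_top), nbins = m)
  keep <- if (mutual) counts >= 2L else counts >= 1L
  .drop_edges(graph, !keep)
}

#' Filter edges by predicate
#'
#' Removes edges whose predicate is false; nodes are kept (use
#' [filter_nodes()] or [remove_components()] to drop them).  The predicate is
#' a one-sided formula over `weight` and the edge attribute columns, or a
#' function of that data frame.
#'
#' @param graph A `cgraph`.
#' @param predicate E.g. `~ weight >= 0.5` or `~ n >= 3`.
#' @return The filtered graph.
#' @export
filter_edges <- function(graph, predicate) {
  keep <- .eval_predicate(predicate, .edge_attr_frame(graph), "edge")
  .drop_edges(graph, !keep)
}

#' Filter nodes by predicate
#'
#' Removes nodes whose predicate is false, along with their incident edges.
#' The predicate sees attribute values as they are when the call starts (one
#' pass, no cascade): removing low-degree nodes does not re-trigger on nodes
#' whose degree drops as a consequence.  Computed attributes such as `Degree`
#' must already be present (see [add_degree_attr()], [annotate_metrics()]).
#'
#' @param graph A `cgraph`.
#' @param predicate One-sided formula over node attribute columns (plus `id`),
#'   or a function of that data frame.
#' @return The filtered graph.
#' @export
filter_nodes <- function(graph, predicate) {
  keep <- .eval_predicate(predicate, .node_attr_frame(graph), "node")
  .induced_subgraph(graph, graph$nodes[keep])
}

#' Remove small components
#'
#' Deletes every connected component with fewer than `min_nodes` nodes; the
#' internal structure of surviving components is untouched.
#'
#' @param graph A `cgraph`.
#' @param min_nodes Minimum component size to keep (`>= 1`).
#' @return The filtered graph.
#' @export
remove_components <- function(graph, min_nodes) {
  if (!is.numeric(min_nodes) || min_nodes < 1) stop("min_nodes must be >= 1")
  comp <- graph_components(graph)
  keep_ranks <- which(comp$sizes >= min_nodes) - 1L
  keep <- graph$nodes[comp$component_of[graph$nodes] %in% keep_ranks]
  .induced_subgraph(graph, keep)
}

#' Contract matching edges
#'
#' Every edge whose predicate is true is contracted: the quotient is taken
#' over connected subgraphs of matching edges, so chains of matching edges
#' merge into a single node.  The merged node takes the lexicographically
#' smallest member id and carries a `members` text attribute (semicolon-
#' separated ids) plus a numeric `n_members` count.  Parallel edges arising
#' from the quotient collapse to one edge with the maximum weight;
#' self-loops are removed.
#'
#' Merged attribute values come from the smallest-id member, except columns
#' named in `additive` which are summed (for count-like attributes).
#'
#' @param graph A `cgraph`.
#' @param predicate Edge predicate, as in [filter_edges()].
#' @param additive Character vector of numeric attribute columns to sum
#'   across members.
#' @return The contracted graph.
#' @export
contract_edges <- function(graph, predicate, additive = character()) {
  match_e <- .eval_predicate(predicate, .edge_attr_frame(graph), "edge")
  n <- n_nodes(graph)
  if (!n) return(graph)
  # union-find over matching edges
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  fi <- match(graph$edges$from, graph$nodes)
  ti <- match(graph$edges$to, graph$nodes)
  for (e in which(match_e)) {
    a <- find(fi[e]); b <- find(ti[e])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  # representative = lexicographically smallest member id
  rep_id <- vapply(groups, function(ix) {
    ids <- graph$nodes[ix]
    ids[order(ids, method = "radix")][1]
  }, character(1))
  group_of <- integer(n)
  for (gi in seq_along(groups)) group_of[groups[[gi]]] <- gi

  new_nodes <- rep_id
  members <- vapply(groups, function(ix) {
    ids <- graph$nodes[ix]
    paste(ids[order(ids, method = "radix")], collapse = ";")
  }, character(1))
  n_members <- vapply(groups, length, integer(1))

  out <- graph_new(unname(new_nodes))
  # quotient edges: drop intra-group, collapse parallels keeping max weight
  gfrom <- new_nodes[group_of[fi]]
  gto <- new_nodes[group_of[ti]]
  keep <- gfrom != gto
  if (any(keep)) {
    cp <- .canonical_pairs(gfrom[keep], gto[keep])
    key <- .edge_key(cp$from, cp$to)
    w <- graph$edges$weight[keep]
    mx <- tapply(w, key, max)
    src_idx <- which(keep)
    # index of the max-weight representative edge per quotient edge, for attrs
    rep_edge <- vapply(names(mx), function(kk) {
      cand <- src_idx[key == kk]
      cand[which.max(w[key == kk])]
    }, integer(1))
    parts <- strsplit(names(mx), "\r", fixed = TRUE)
    out <- add_edges(out,
                     vapply(parts, `[[`, character(1), 1),
                     vapply(parts, `[[`, character(1), 2),
                     as.numeric(mx))
    # carry edge attributes from the max-weight representative
    if (ncol(graph$edge_attrs)) {
      okey <- .edge_key(out$edges$from, out$edges$to)
      ord <- match(okey, names(mx))
      for (col in names(graph$edge_attrs))
        out <- set_edge_attr(out, col, graph$edge_attrs[[col]][rep_edge][ord],
                             kind = unname(graph$attr_kinds$edges[col]))
    }
  }
  # node attributes: smallest-id member, or sum for additive columns
  for (col in names(graph$node_attrs)) {
    vals <- vapply(seq_along(groups), function(gi) {
      ix <- groups[[gi]]
      v <- graph$node_attrs[[col]][ix]
      if (col %in% additive && is.numeric(v)) {
        if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
      } else {
        ids <- graph$nodes[ix]
        v[order(ids, method = "radix")][1]
      }
    }, if (is.numeric(graph$node_attrs[[col]])) numeric(1) else character(1))
    names(vals) <- new_nodes
    out <- set_node_attr(out, col, vals,
                         kind = unname(graph$attr_kinds$nodes[col]))
  }
  out <- set_node_attr(out, "members",
                       stats::setNames(members, new_nodes), kind = "text")
  out <- set_node_attr(out, "n_members",
                       stats::setNames(as.numeric(n_members), new_nodes))
  out
}

#' Apply an ordered stack of transforms
#'
#' Mirrors an interactive transform stack: each spec is a list with a `name`
#' (`"knn"`, `"filter_edges"`, `"filter_nodes"`, `"remove_components"`,
#' `"contract_edges"`) and its parameters.  Transforms run in order; the
#' attached log records node/edge counts after each step.
#'
#' Filter parameters may be given either as a `predicate` formula or, for
#' convenience in configs, as `attribute` + `min`/`max` bounds
#' (`weight` for edges).
#'
#' @param graph A `cgraph`.
#' @param stack List of transform specs, e.g.
#'   `list(list(name = "knn", k = 3), list(name = "remove_components", min_nodes = 2))`.
#' @return The transformed graph with a `transform_log` attribute
#'   (data frame: step, transform, nodes, edges).
#' @export
apply_stack <- function(graph, stack) {
  log <- data.frame(step = 0L, transform = "input",
                    nodes = n_nodes(graph), edges = n_edges(graph),
                    stringsAsFactors = FALSE)
  known <- c("knn", "filter_edges", "filter_nodes", "remove_components",
             "contract_edges")
  for (i in seq_along(stack)) {
    spec <- stack[[i]]
    if (is.null(spec$name) || !spec$name %in% known)
      stop("unknown transform '", spec$name %||% "<missing>", "' at step ", i)
    pred <- spec$predicate %||% .bounds_predicate(spec)
    graph <- switch(spec$name,
      knn = knn_prune(graph, k = spec$k, mutual = spec$mutual %||% FALSE),
      filter_edges = filter_edges(graph, pred),
      filter_nodes = filter_nodes(graph, pred),
      remove_components = remove_components(graph, spec$min_nodes),
      contract_edges = contract_edges(graph, pred,
                                      additive = spec$additive %||% character())
    )
    log <- rbind(log, data.frame(step = i, transform = spec$name,
                                 nodes = n_nodes(graph), edges = n_edges(graph),
                                 stringsAsFactors = FALSE))
  }
  attr(graph, "transform_log") <- log
  graph
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build a predicate formula from attribute/min/max spec fields
.bounds_predicate <- function(spec) {
  if (is.null(spec$attribute) && is.null(spec$min) && is.null(spec$max))
    return(NULL)
  att <- spec$attribute %||% "weight"
  lo <- spec$min; hi <- spec$max
  f <- if (!is.null(lo) && !is.null(hi)) {
    bquote(.(as.name(att)) >= .(lo) & .(as.name(att)) <= .(hi))
  } else if (!is.null(lo)) {
    bquote(.(as.name(att)) >= .(lo))
  } else if (!is.null(hi)) {
    bquote(.(as.name(att)) <= .(hi))
  } else stop("attribute given without min/max bound")
  stats::as.formula(call("~", f))
}
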
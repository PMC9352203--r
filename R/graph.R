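# Core graph model: an undirected, weighted simple graph with stable string
# node identifiers and typed node/edge attribute tables.  All transforms and
# analytics in the package operate on this structure and return new copies;
# no function mutates its input.

#' Create a graph
#'
#' Builds an undirected weighted simple graph.  Node identity is an opaque
#' string; edges are unordered pairs with a real weight (default 1).
#' Re-adding an existing edge replaces its weight; self-loops are rejected.
#'
#' @param nodes Character vector of node identifiers (may be empty).
#' @param edges A data frame with columns `from`, `to` and optionally
#'   `weight`, or `NULL` for no edges.  Endpoints not listed in `nodes` are
#'   added automatically.
#' @return An object of class `cgraph`.
#' @examples
#' g <- graph_new(c("a", "b", "c"),
#'                data.frame(from = c("a", "b"), to = c("b", "c"),
#'                           weight = c(0.9, 0.5)))
#' n_edges(g)
#' @export
graph_new <- function(nodes = character(), edges = NULL) {
  g <- structure(
    list(
      nodes      = character(),
      edges      = data.frame(from = character(), to = character(),
                              weight = numeric(), stringsAsFactors = FALSE),
      node_attrs = data.frame(row.names = character()),
      edge_attrs = data.frame(),
      attr_kinds = list(nodes = character(), edges = character())
    ),
    class = "cgraph"
  )
  if (length(nodes)) g <- add_nodes(g, nodes)
  if (!is.null(edges) && nrow(edges)) {
    w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
    g <- add_edges(g, edges$from, edges$to, w)
  }
  g
}

#' @export
print.cgraph <- function(x, ...) {
  comp <- graph_components(x)
  cat(sprintf("<cgraph> %d nodes, %d edges, %d component%s\n",
              n_nodes(x), n_edges(x), length(comp$sizes),
              if (length(comp$sizes) == 1) "" else "s"))
  if (ncol(x$node_attrs))
    cat("  node attributes:", paste(names(x$node_attrs), collapse = ", "), "\n")
  if (ncol(x$edge_attrs))
    cat("  edge attributes:", paste(names(x$edge_attrs), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cgraph <- function(object, ...) {
  comp <- graph_components(object)
  deg <- node_degrees(object)
  structure(list(
    n_nodes = n_nodes(object), n_edges = n_edges(object),
    n_components = length(comp$sizes), component_sizes = comp$sizes,
    degree_summary = if (length(deg)) summary(deg) else NULL,
    weight_summary = if (n_edges(object)) summary(object$edges$weight) else NULL
  ), class = "summary.cgraph")
}

#' @export
print.summary.cgraph <- function(x, ...) {
  cat(sprintf("Graph: %d nodes, %d edges, %d components\n",
              x$n_nodes, x$n_edges, x$n_components))
  if (x$n_components)
    cat("Component sizes:",
        paste(utils::head(x$component_sizes, 10), collapse = " "),
        if (x$n_components > 10) "..." else "", "\n")
  if (!is.null(x$weight_summary)) {
    cat("Edge weights:\n"); print(x$weight_summary)
  }
  invisible(x)
}

#' Number of nodes / edges
#' @param graph A `cgraph`.
#' @return Integer count.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

# canonical unordered-pair orientation: from <= to in C-locale order
.canonical_pairs <- function(from, to) {
  from <- as.character(from); to <- as.character(to)
  swap <- .str_gt(from, to)
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  list(from = from, to = to)
}

# locale-independent string comparison helpers (radix order)
.str_gt <- function(a, b) {
  n <- length(a)
  if (!n) return(logical(0))
  idx <- seq_len(n)
  # rank each pair by radix sort of the two values
  vapply(idx, function(i) {
    order(c(a[i], b[i]), method = "radix")[1] == 2L
  }, logical(1))
}

.edge_key <- function(from, to) paste(from, to, sep = "\r")

#' Add nodes to a graph
#'
#' @param graph A `cgraph`.
#' @param ids Character vector of node ids; ids already present are ignored.
#' @return The updated graph.
#' @export
add_nodes <- function(graph, ids) {
  ids <- as.character(ids)
  if (anyNA(ids) || any(ids == ""))
    stop("node ids must be non-empty strings")
  new <- unique(ids[!ids %in% graph$nodes])
  if (!length(new)) return(graph)
  graph$nodes <- c(graph$nodes, new)
  if (ncol(graph$node_attrs)) {
    pad <- graph$node_attrs[rep(NA_integer_, length(new)), , drop = FALSE]
    rownames(pad) <- new
    graph$node_attrs <- rbind(graph$node_attrs, pad)
  } else {
    graph$node_attrs <- data.frame(row.names = c(rownames(graph$node_attrs), new))
  }
  graph
}

#' Add or update edges
#'
#' Edges are unordered: adding `(b, a)` after `(a, b)` replaces the weight of
#' the single edge a--b.  Self-loops are an error.  Endpoints absent from the
#' graph are created.
#'
#' @param graph A `cgraph`.
#' @param from,to Character vectors of endpoint ids.
#' @param weight Numeric weights, recycled; default 1.
#' @return The updated graph.
#' @export
add_edges <- function(graph, from, to, weight = 1) {
  from <- as.character(from); to <- as.character(to)
  if (length(from) != length(to)) stop("'from' and 'to' lengths differ")
  if (!length(from)) return(graph)
  weight <- rep_len(as.numeric(weight), length(from))
  if (any(!is.finite(weight))) stop("edge weights must be finite")
  loops <- from == to
  if (any(loops))
    stop("self-loops are not allowed (node ", from[loops][1], ")")
  graph <- add_nodes(graph, unique(c(from, to)))
  cp <- .canonical_pairs(from, to)
  # last occurrence wins within the batch
  key <- .edge_key(cp$from, cp$to)
  keep <- !duplicated(key, fromLast = TRUE)
  cp$from <- cp$from[keep]; cp$to <- cp$to[keep]
  weight <- weight[keep]; key <- key[keep]

  old_key <- .edge_key(graph$edges$from, graph$edges$to)
  hit <- match(key, old_key)
  upd <- !is.na(hit)
  if (any(upd)) graph$edges$weight[hit[upd]] <- weight[upd]
  if (any(!upd)) {
    add <- data.frame(from = cp$from[!upd], to = cp$to[!upd],
                      weight = weight[!upd], stringsAsFactors = FALSE)
    graph$edges <- rbind(graph$edges, add)
    if (ncol(graph$edge_attrs)) {
      pad <- graph$edge_attrs[rep(NA_integer_, sum(!upd)), , drop = FALSE]
      rownames(pad) <- NULL
      graph$edge_attrs <- rbind(graph$edge_attrs, pad)
    } else {
      graph$edge_attrs <- data.frame(matrix(nrow = nrow(graph$edges), ncol = 0))
    }
  }
  rownames(graph$edges) <- NULL
  graph
}

#' Node and edge attribute access
#'
#' Attribute columns are typed as `"numeric"`, `"categorical"` or `"text"`.
#' Numeric columns may contain `NA` for explicitly missing values; missing
#' values are excluded from encodings and statistics, never treated as zero.
#'
#' @param graph A `cgraph`.
#' @param name Attribute column name.
#' @param values For nodes, a vector named by node id (unnamed vectors must
#'   cover every node in order); for edges, a vector aligned with the edge
#'   table.
#' @param kind One of `"numeric"`, `"categorical"`, `"text"`; inferred from
#'   the value type when `NULL`.
#' @return `set_*` return the updated graph; `get_*` return the column
#'   (nodes: named by id).
#' @export
set_node_attr <- function(graph, name, values, kind = NULL) {
  col <- rep(if (is.numeric(values)) NA_real_ else NA_character_, n_nodes(graph))
  if (!is.null(names(values))) {
    unknown <- setdiff(names(values), graph$nodes)
    if (length(unknown))
      stop("unknown node ids in attribute '", name, "': ",
           paste(utils::head(unknown, 5), collapse = ", "))
    col[match(names(values), graph$nodes)] <- values
  } else {
    if (length(values) != n_nodes(graph))
      stop("unnamed attribute vector must have one value per node")
    col <- values
  }
  graph$node_attrs[[name]] <- col
  rownames(graph$node_attrs) <- graph$nodes
  graph$attr_kinds$nodes[[name]] <- .infer_kind(col, kind)
  graph
}

#' @rdname set_node_attr
#' @export
set_edge_attr <- function(graph, name, values, kind = NULL) {
  if (length(values) != n_edges(graph))
    stop("edge attribute must have one value per edge")
  if (!nrow(graph$edge_attrs))
    graph$edge_attrs <- data.frame(matrix(nrow = n_edges(graph), ncol = 0))
  graph$edge_attrs[[name]] <- values
  graph$attr_kinds$edges[[name]] <- .infer_kind(values, kind)
  graph
}

#' @rdname set_node_attr
#' @export
get_node_attr <- function(graph, name) {
  if (!name %in% names(graph$node_attrs))
    stop("no node attribute '", name, "'")
  stats::setNames(graph$node_attrs[[name]], graph$nodes)
}

#' @rdname set_node_attr
#' @export
get_edge_attr <- function(graph, name) {
  if (!name %in% names(graph$edge_attrs))
    stop("no edge attribute '", name, "'")
  graph$edge_attrs[[name]]
}

.infer_kind <- function(values, kind) {
  if (!is.null(kind)) {
    kind <- match.arg(kind, c("numeric", "categorical", "text"))
    if (kind == "numeric" && !is.numeric(values))
      stop("kind 'numeric' requires numeric values")
    return(kind)
  }
  if (is.numeric(values)) "numeric" else "categorical"
}

#' Connected components
#'
#' Partitions the node set by connectivity.  Component rank 0 is the largest
#' component; equal sizes are ordered by their lexicographically smallest
#' member id, so ranks are deterministic and insertion-order independent.
#'
#' @param graph A `cgraph`.
#' @return A list of class `component_index` with `component_of` (named
#'   integer vector of ranks, 0-based) and `sizes` (descending node counts).
#' @export
graph_components <- function(graph) {
  n <- n_nodes(graph)
  if (!n) {
    return(structure(list(component_of = stats::setNames(integer(), character()),
                          sizes = integer()),
                     class = "component_index"))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n_edges(graph)) {
    fi <- match(graph$edges$from, graph$nodes)
    ti <- match(graph$edges$to, graph$nodes)
    for (e in seq_along(fi)) {
      a <- find(fi[e]); b <- find(ti[e])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  sizes <- tabulate(root, nbins = n)
  roots <- which(sizes > 0)
  # smallest member id per root, for the deterministic tie-break
  min_member <- vapply(roots, function(r) {
    members <- graph$nodes[root == r]
    members[order(members, method = "radix")][1]
  }, character(1))
  ord <- order(-sizes[roots], min_member, method = "radix")
  rank_of_root <- integer(n)
  rank_of_root[roots[ord]] <- seq_along(roots) - 1L
  structure(list(
    component_of = stats::setNames(rank_of_root[root], graph$nodes),
    sizes = sizes[roots][ord]
  ), class = "component_index")
}

#' @export
print.component_index <- function(x, ...) {
  cat(sprintf("<component_index> %d components, sizes: %s%s\n",
              length(x$sizes),
              paste(utils::head(x$sizes, 12), collapse = " "),
              if (length(x$sizes) > 12) " ..." else ""))
  invisible(x)
}

#' Unweighted node degree
#'
#' @param graph A `cgraph`.
#' @return Named integer vector of degrees (0 for isolated nodes).
#' @export
node_degrees <- function(graph) {
  deg <- stats::setNames(integer(n_nodes(graph)), graph$nodes)
  if (n_edges(graph)) {
    t1 <- table(factor(graph$edges$from, levels = graph$nodes))
    t2 <- table(factor(graph$edges$to, levels = graph$nodes))
    deg <- stats::setNames(as.integer(t1 + t2), graph$nodes)
  }
  deg
}

#' Store node degree as the attribute column `Degree`
#' @param graph A `cgraph`.
#' @return Graph with a numeric node attribute `Degree`.
#' @export
add_degree_attr <- function(graph) {
  set_node_attr(graph, "Degree", as.numeric(node_degrees(graph)))
}

# subset a graph to a node set, keeping induced edges and attributes
.induced_subgraph <- function(graph, keep_nodes) {
  keep_nodes <- graph$nodes[graph$nodes %in% keep_nodes]
  ekeep <- graph$edges$from %in% keep_nodes & graph$edges$to %in% keep_nodes
  g <- graph
  g$nodes <- keep_nodes
  g$edges <- graph$edges[ekeep, , drop = FALSE]
  rownames(g$edges) <- NULL
  g$node_attrs <- graph$node_attrs[match(keep_nodes, graph$nodes), , drop = FALSE]
  rownames(g$node_attrs) <- keep_nodes
  g$edge_attrs <- graph$edge_attrs[ekeep, , drop = FALSE]
  rownames(g$edge_attrs) <- NULL
  g
}

# drop a set of edges by logical index, keeping nodes
.drop_edges <- function(graph, drop) {
  g <- graph
  g$edges <- graph$edges[!drop, , drop = FALSE]
  rownames(g$edges) <- NULL
  g$edge_attrs <- graph$edge_attrs[!drop, , drop = FALSE]
  rownames(g$edge_attrs) <- NULL
  g
}

# adjacency list as integer indices; returns list(adj, w) per node
.adjacency <- function(graph) {
  n <- n_nodes(graph)
  fi <- match(graph$edges$from, graph$nodes)
  ti <- match(graph$edges$to, graph$nodes)
  adj <- vector("list", n)
  wl <- vector("list", n)
  ei <- vector("list", n)
  if (length(fi)) {
    ends <- c(fi, ti)
    other <- c(ti, fi)
    w <- rep(graph$edges$weight, 2)
    eid <- rep(seq_along(fi), 2)
    o <- order(ends)
    ends <- ends[o]; other <- other[o]; w <- w[o]; eid <- eid[o]
    runs <- split(seq_along(ends), ends)
    for (k in names(runs)) {
      i <- as.integer(k)
      adj[[i]] <- other[runs[[k]]]
      wl[[i]] <- w[runs[[k]]]
      ei[[i]] <- eid[runs[[k]]]
    }
  }
  for (i in seq_len(n)) {
    if (is.null(adj[[i]])) { adj[[i]] <- integer(); wl[[i]] <- numeric(); ei[[i]] <- integer() }
  }
  list(adj = adj, w = wl, eid = ei)
}
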
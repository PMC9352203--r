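# Reading and writing graphs in the standard interchange formats: GML,
# GraphML, JSON graph, weighted edge lists and symmetric adjacency matrices.
# GML and GraphML parsing is delegated to igraph; the package converts
# between its own attribute-table model and igraph objects at the boundary.
# Formats that cannot carry attributes drop them with a warning, and every
# supported format round-trips node ids, the edge set and weights.

.supported_formats <- c("gml", "graphml", "json", "edgelist", "adjacency")
.unsupported_formats <- c("biopax", "owl", "cx", "cx2", "mat", "xlsx", "xls",
                          "dot")

.guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gml = "gml", graphml = "graphml", xml = "graphml",
         json = "json",
         tsv = "edgelist", txt = "edgelist", edges = "edgelist",
         csv = "adjacency",
         ext)
}

.check_format <- function(format) {
  if (format %in% .unsupported_formats)
    stop("format '", format, "' is not supported; supported formats: ",
         paste(.supported_formats, collapse = ", "))
  match.arg(format, .supported_formats)
}

#' Convert between the package graph and igraph
#'
#' @param graph A `cgraph`.
#' @return `as_igraph`: an undirected igraph object with `name` vertex
#'   attribute and `weight` edge attribute; `from_igraph`: a `cgraph`.
#'   Directed igraph edges are folded to undirected keeping the maximum
#'   weight; self-loops are dropped with a warning.
#' @export
as_igraph <- function(graph) {
  vertices <- data.frame(name = graph$nodes, stringsAsFactors = FALSE)
  for (col in names(graph$node_attrs)) vertices[[col]] <- graph$node_attrs[[col]]
  edges <- graph$edges
  for (col in names(graph$edge_attrs)) edges[[col]] <- graph$edge_attrs[[col]]
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' @rdname as_igraph
#' @param ig An igraph object.
#' @export
from_igraph <- function(ig) {
  if (igraph::is_directed(ig)) ig <- igraph::as_undirected(ig, mode = "collapse",
    edge.attr.comb = list(weight = "max", "first"))
  vs <- igraph::as_data_frame(ig, what = "vertices")
  es <- igraph::as_data_frame(ig, what = "edges")
  # canonical node id: label when present, else name, else decimal id
  ids <- if ("label" %in% names(vs) && !anyNA(vs$label) &&
             !anyDuplicated(vs$label)) {
    as.character(vs$label)
  } else if ("name" %in% names(vs)) {
    as.character(vs$name)
  } else if ("id" %in% names(vs)) {
    as.character(vs$id)
  } else {
    as.character(seq_len(nrow(vs)) - 1L)
  }
  lookup <- stats::setNames(ids, rownames(vs))
  if (nrow(es)) {
    es$from <- unname(lookup[as.character(es$from)])
    es$to <- unname(lookup[as.character(es$to)])
  }
  if (!"weight" %in% names(es)) {
    es$weight <- if ("value" %in% names(es)) as.numeric(es$value)
                 else rep(1, nrow(es))
  }
  loops <- nrow(es) && any(es$from == es$to)
  if (loops) {
    warning(sum(es$from == es$to), " self-loop(s) dropped on import")
    es <- es[es$from != es$to, , drop = FALSE]
  }
  # fold duplicate undirected pairs, keeping the maximum weight
  if (nrow(es)) {
    cp <- .canonical_pairs(es$from, es$to)
    key <- .edge_key(cp$from, cp$to)
    if (anyDuplicated(key)) {
      keep_idx <- vapply(split(seq_len(nrow(es)), key), function(ix)
        ix[which.max(es$weight[ix])], integer(1))
      es <- es[sort(keep_idx), , drop = FALSE]
    }
  }
  g <- graph_new(ids)
  if (nrow(es)) g <- add_edges(g, es$from, es$to, es$weight)
  attr_cols <- setdiff(names(vs), c("name", "id", "label"))
  for (col in attr_cols) {
    v <- vs[[col]]
    g <- set_node_attr(g, col, stats::setNames(v, ids))
  }
  if (nrow(es)) {
    okey <- .edge_key(g$edges$from, g$edges$to)
    cp <- .canonical_pairs(es$from, es$to)
    ord <- match(okey, .edge_key(cp$from, cp$to))
    for (col in setdiff(names(es), c("from", "to", "weight", "value")))
      g <- set_edge_attr(g, col, es[[col]][ord])
  }
  g
}

#' Read a graph file
#'
#' @param path Input file.
#' @param format One of `"gml"`, `"graphml"`, `"json"` (JSON graph),
#'   `"edgelist"` (2-3 column TSV/CSV, `#` comments ignored, weight
#'   defaults to 1), `"adjacency"` (CSV with row/column headers; must be
#'   square and symmetric within `1e-9`, diagonal ignored, zeros mean no
#'   edge).  Guessed from the extension when omitted.
#' @param sep Delimiter for `edgelist`/`adjacency` (default: tab for
#'   `.tsv`/`.txt`, comma otherwise).
#' @return A `cgraph`.
#' @export
read_graph_file <- function(path, format = NULL, sep = NULL) {
  format <- .check_format(format %||% .guess_format(path))
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
    gml = {
      ig <- tryCatch(igraph::read_graph(path, format = "gml"),
                     error = function(e)
                       stop("GML parse error in ", path, ": ",
                            conditionMessage(e)))
      from_igraph(ig)
    },
    graphml = {
      ig <- tryCatch(igraph::read_graph(path, format = "graphml"),
                     error = function(e)
                       stop("GraphML parse error in ", path, ": ",
                            conditionMessage(e)))
      from_igraph(ig)
    },
    json = .read_json_graph(path),
    edgelist = .read_edgelist(path, sep),
    adjacency = .read_adjacency(path, sep)
  )
}

#' Write a graph file
#'
#' Weights are written with full double precision; attribute kinds a format
#' cannot carry are stringified (GML) or dropped (edge list, adjacency)
#' with a warning.
#'
#' @param graph A `cgraph`.
#' @param path Output file.
#' @param format As in [read_graph_file()]; guessed from the extension when
#'   omitted.
#' @param sep Delimiter for `edgelist`/`adjacency`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = NULL, sep = NULL) {
  format <- .check_format(format %||% .guess_format(path))
  switch(format,
    gml = .write_gml(graph, path),
    graphml = igraph::write_graph(as_igraph(graph), path, format = "graphml"),
    json = .write_json_graph(graph, path),
    edgelist = .write_edgelist(graph, path, sep),
    adjacency = .write_adjacency(graph, path, sep)
  )
  invisible(path)
}

# --- GML ------------------------------------------------------------------
# Writer emits the classic dialect: node [ id <int> label "<id>" ],
# edge [ source <int> target <int> value <weight> ].  Attribute keys must be
# alphanumeric in GML, so other characters are replaced by underscores.

.gml_key <- function(name) gsub("[^A-Za-z0-9]", "_", name)

.gml_value <- function(v) {
  if (is.numeric(v)) sprintf("%.17g", v)
  else paste0("\"", gsub("\"", "'", as.character(v)), "\"")
}

.write_gml <- function(graph, path) {
  idx <- stats::setNames(seq_along(graph$nodes) - 1L, graph$nodes)
  lines <- c("graph [", "  directed 0")
  renamed <- names(graph$node_attrs)[.gml_key(names(graph$node_attrs)) !=
                                     names(graph$node_attrs)]
  renamed <- c(renamed,
               names(graph$edge_attrs)[.gml_key(names(graph$edge_attrs)) !=
                                       names(graph$edge_attrs)])
  if (length(renamed))
    warning("GML attribute keys sanitised: ",
            paste(unique(renamed), collapse = ", "))
  for (i in seq_along(graph$nodes)) {
    entry <- c(sprintf("  node ["),
               sprintf("    id %d", idx[[i]]),
               sprintf("    label %s", .gml_value(graph$nodes[i])))
    for (col in names(graph$node_attrs)) {
      v <- graph$node_attrs[[col]][i]
      if (!is.na(v))
        entry <- c(entry, sprintf("    %s %s", .gml_key(col), .gml_value(v)))
    }
    lines <- c(lines, entry, "  ]")
  }
  for (e in seq_len(n_edges(graph))) {
    entry <- c("  edge [",
               sprintf("    source %d", idx[[graph$edges$from[e]]]),
               sprintf("    target %d", idx[[graph$edges$to[e]]]),
               sprintf("    value %.17g", graph$edges$weight[e]))
    for (col in names(graph$edge_attrs)) {
      v <- graph$edge_attrs[[col]][e]
      if (!is.na(v))
        entry <- c(entry, sprintf("    %s %s", .gml_key(col), .gml_value(v)))
    }
    lines <- c(lines, entry, "  ]")
  }
  writeLines(c(lines, "]"), path)
}

# --- JSON graph -----------------------------------------------------------
# {"graph": {"directed": false,
#   "nodes": [{"id": ..., "metadata": {...}}, ...],
#   "edges": [{"source": ..., "target": ..., "metadata": {"weight": ...}}]}}

.write_json_graph <- function(graph, path) {
  nodes <- lapply(seq_along(graph$nodes), function(i) {
    meta <- list()
    for (col in names(graph$node_attrs)) {
      v <- graph$node_attrs[[col]][i]
      if (!is.na(v)) meta[[col]] <- v
    }
    c(list(id = graph$nodes[i]),
      if (length(meta)) list(metadata = meta))
  })
  edges <- lapply(seq_len(n_edges(graph)), function(e) {
    meta <- list(weight = graph$edges$weight[e])
    for (col in names(graph$edge_attrs)) {
      v <- graph$edge_attrs[[col]][e]
      if (!is.na(v)) meta[[col]] <- v
    }
    list(source = graph$edges$from[e], target = graph$edges$to[e],
         metadata = meta)
  })
  jsonlite::write_json(list(graph = list(directed = FALSE, nodes = nodes,
                                         edges = edges)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.read_json_graph <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("JSON parse error in ", path, ": ",
                         conditionMessage(e)))
  body <- doc$graph %||% doc
  nodes <- body$nodes %||% list()
  edges <- body$edges %||% list()
  ids <- vapply(nodes, function(nd) as.character(nd$id), character(1))
  g <- graph_new(ids)
  if (length(edges)) {
    from <- vapply(edges, function(e) as.character(e$source), character(1))
    to <- vapply(edges, function(e) as.character(e$target), character(1))
    w <- vapply(edges, function(e)
      as.numeric(e$metadata$weight %||% e$weight %||% 1), numeric(1))
    g <- add_edges(g, from, to, w)
  }
  # collect metadata columns
  ncols <- unique(unlist(lapply(nodes, function(nd) names(nd$metadata))))
  for (col in ncols) {
    vals <- vapply(nodes, function(nd) {
      v <- nd$metadata[[col]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
    num <- suppressWarnings(as.numeric(vals))
    ok <- !is.na(vals)
    v_final <- if (any(ok) && !anyNA(num[ok])) num else vals
    g <- set_node_attr(g, col, stats::setNames(v_final, ids))
  }
  if (length(edges)) {
    ecols <- setdiff(unique(unlist(lapply(edges, function(e)
      names(e$metadata)))), "weight")
    if (length(ecols)) {
      cp <- .canonical_pairs(
        vapply(edges, function(e) as.character(e$source), character(1)),
        vapply(edges, function(e) as.character(e$target), character(1)))
      key_in <- .edge_key(cp$from, cp$to)
      okey <- .edge_key(g$edges$from, g$edges$to)
      ord <- match(okey, key_in)
      for (col in ecols) {
        vals <- vapply(edges, function(e) {
          v <- e$metadata[[col]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))[ord]
        num <- suppressWarnings(as.numeric(vals))
        ok <- !is.na(vals)
        g <- set_edge_attr(g, col,
                           if (any(ok) && !anyNA(num[ok])) num else vals)
      }
    }
  }
  g
}

# --- edge list ------------------------------------------------------------

.read_edgelist <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!ncol(df) %in% c(2, 3))
    stop("edge list must have 2 or 3 columns, found ", ncol(df))
  w <- if (ncol(df) == 3) as.numeric(df[[3]]) else rep(1, nrow(df))
  g <- graph_new()
  add_edges(g, as.character(df[[1]]), as.character(df[[2]]), w)
}

.write_edgelist <- function(graph, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (ncol(graph$node_attrs) || ncol(graph$edge_attrs))
    warning("edge list format cannot carry attributes; they are dropped")
  df <- data.frame(from = graph$edges$from, to = graph$edges$to,
                   weight = sprintf("%.17g", graph$edges$weight))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

# --- adjacency matrix -----------------------------------------------------

.read_adjacency <- function(path, sep = NULL, tol = 1e-9) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("adjacency matrix must be square, got ", nrow(m), "x", ncol(m))
  if (!identical(rownames(m), colnames(m)))
    stop("adjacency row and column names differ")
  asym <- abs(m - t(m)) > tol
  diag(asym) <- FALSE
  if (any(asym)) {
    ij <- which(asym, arr.ind = TRUE)[1, ]
    stop(sprintf("adjacency matrix not symmetric at [%s, %s]: %g vs %g",
                 rownames(m)[ij[1]], colnames(m)[ij[2]],
                 m[ij[1], ij[2]], m[ij[2], ij[1]]))
  }
  ids <- rownames(m)
  g <- graph_new(ids)
  ut <- upper.tri(m)
  hit <- which(ut & m != 0, arr.ind = TRUE)
  if (nrow(hit))
    g <- add_edges(g, ids[hit[, 1]], ids[hit[, 2]], m[hit])
  g
}

.write_adjacency <- function(graph, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  if (ncol(graph$node_attrs) || ncol(graph$edge_attrs))
    warning("adjacency format cannot carry attributes; they are dropped")
  n <- n_nodes(graph)
  m <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (n_edges(graph)) {
    fi <- match(graph$edges$from, graph$nodes)
    ti <- match(graph$edges$to, graph$nodes)
    m[cbind(fi, ti)] <- graph$edges$weight
    m[cbind(ti, fi)] <- graph$edges$weight
  }
  out <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Convert a graph file between formats
#'
#' @param in_path,out_path Input and output files.
#' @param from,to Formats, guessed from extensions when omitted.
#' @return `out_path`, invisibly.
#' @export
convert_graph <- function(in_path, out_path, from = NULL, to = NULL) {
  g <- read_graph_file(in_path, format = from)
  write_graph_file(g, out_path, format = to)
}
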
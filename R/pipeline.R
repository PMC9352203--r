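# End-to-end pipeline: an ordered list of stages (correlate, transform,
# cluster, metrics, layout, encode, write) driven by a YAML config or an
# in-memory list, with per-stage node/edge logging.  The command-line
# wrapper in inst/cli/corgraph is a thin shim over run_pipeline() and the
# individual exported functions.

.pipeline_stages <- c("read_matrix", "correlate", "read_graph", "transform",
                      "cluster", "metrics", "layout", "encode", "write_graph",
                      "write_layout")

#' Run an analysis pipeline
#'
#' Executes stages in order.  Stage names and their parameters:
#' \describe{
#'   \item{read_matrix}{`path`, `annotation_columns`, `transpose`}
#'   \item{correlate}{`r_min`, `method`, `polarity`, `inclusive`}
#'   \item{read_graph}{`path`, `format`}
#'   \item{transform}{`stack` -- list of transform specs, see [apply_stack()]}
#'   \item{cluster}{`algorithm` (`"louvain"`/`"mcl"`), `granularity`,
#'     `weighted`, `attribute` (column name)}
#'   \item{metrics}{`metrics` -- subset of degree/pagerank/betweenness/eccentricity}
#'   \item{layout}{`dims`, `out` (TSV path, optional)}
#'   \item{encode}{`attribute`, `channel` (`"categorical"`/`"numeric"`)}
#'   \item{write_graph}{`path`, `format`}
#' }
#' A `seed` at the top level feeds every seeded stage.
#'
#' @param config Path to a YAML file, or an equivalent list with `stages`
#'   (named stage list in order) and optionally `seed`.
#' @param verbose Print the per-stage log to stderr.
#' @return A list with `graph`, `matrix`, `assignment`, `layout` (whichever
#'   stages produced) and `log` (data frame of per-stage counts).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("config has no stages")
  seed <- config$seed %||% 1
  # validate before executing anything
  for (i in seq_along(stages)) {
    nm <- stages[[i]]$stage %||% names(stages)[i]
    if (is.null(nm) || !nm %in% .pipeline_stages)
      stop("unknown pipeline stage '", nm %||% "<missing>", "' at position ", i)
    extra <- setdiff(names(stages[[i]]),
                     c("stage", .stage_params(nm)))
    if (length(extra))
      stop("unknown parameter(s) for stage '", nm, "': ",
           paste(extra, collapse = ", "))
  }
  state <- list(graph = NULL, matrix = NULL, assignment = NULL, layout = NULL)
  log <- data.frame(stage = character(), nodes = integer(), edges = integer(),
                    seconds = numeric(), stringsAsFactors = FALSE)
  for (i in seq_along(stages)) {
    spec <- stages[[i]]
    nm <- spec$stage %||% names(stages)[i]
    t0 <- proc.time()[["elapsed"]]
    state <- tryCatch(
      .run_stage(nm, spec, state, seed),
      error = function(e) stop("pipeline stage '", nm, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    dt <- proc.time()[["elapsed"]] - t0
    nn <- if (!is.null(state$graph)) n_nodes(state$graph) else NA_integer_
    ne <- if (!is.null(state$graph)) n_edges(state$graph) else NA_integer_
    log <- rbind(log, data.frame(stage = nm, nodes = nn, edges = ne,
                                 seconds = round(dt, 3),
                                 stringsAsFactors = FALSE))
    if (verbose)
      message(sprintf("[%s] nodes=%s edges=%s (%.2fs)", nm, nn, ne, dt))
  }
  state$log <- log
  state
}

.stage_params <- function(nm) {
  switch(nm,
    read_matrix = c("path", "annotation_columns", "transpose", "sep"),
    correlate = c("r_min", "method", "polarity", "inclusive", "min_obs",
                  "block_size"),
    read_graph = c("path", "format", "sep"),
    transform = "stack",
    cluster = c("algorithm", "granularity", "weighted", "attribute"),
    metrics = "metrics",
    layout = c("dims", "out", "max_iter", "tol"),
    encode = c("attribute", "channel", "scope"),
    write_graph = c("path", "format"),
    write_layout = "path")
}

.run_stage <- function(nm, spec, state, seed) {
  need_graph <- function() {
    if (is.null(state$graph)) stop("no graph yet; run correlate/read_graph first")
    state$graph
  }
  switch(nm,
    read_matrix = {
      state$matrix <- read_matrix(spec$path,
        annotation_columns = spec$annotation_columns %||% character(),
        transpose = spec$transpose %||% FALSE, sep = spec$sep)
      state
    },
    correlate = {
      if (is.null(state$matrix)) stop("no matrix loaded; run read_matrix first")
      state$graph <- build_correlation_graph(state$matrix,
        r_min = spec$r_min,
        method = spec$method %||% "pearson",
        polarity = spec$polarity %||% "positive_only",
        inclusive = spec$inclusive %||% FALSE,
        min_obs = spec$min_obs %||% 3,
        block_size = spec$block_size %||% 512)
      state
    },
    read_graph = {
      state$graph <- read_graph_file(spec$path, format = spec$format,
                                     sep = spec$sep)
      state
    },
    transform = {
      state$graph <- apply_stack(need_graph(), .parse_stack(spec$stack))
      state
    },
    cluster = {
      g <- need_graph()
      alg <- spec$algorithm %||% "louvain"
      state$assignment <- if (alg == "louvain") {
        louvain_cluster(g, granularity = spec$granularity %||% 1,
                        weighted = spec$weighted %||% TRUE, seed = seed)
      } else if (alg == "mcl") {
        mcl_cluster(g, granularity = spec$granularity %||% 2,
                    weighted = spec$weighted %||% TRUE)
      } else stop("unknown clustering algorithm '", alg, "'")
      default_name <- if (alg == "louvain") "Louvain Cluster" else "MCL Cluster"
      state$graph <- set_cluster_attr(g, state$assignment,
                                      spec$attribute %||% default_name)
      state
    },
    metrics = {
      state$graph <- annotate_metrics(need_graph(),
        metrics = spec$metrics %||% c("degree", "pagerank", "betweenness",
                                      "eccentricity"))
      state
    },
    layout = {
      state$layout <- force_layout(need_graph(), dims = spec$dims %||% 3,
                                   seed = seed,
                                   max_iter = spec$max_iter %||% 2000,
                                   tol = spec$tol %||% 1e-3)
      if (!is.null(spec$out)) write_layout(state$layout, spec$out)
      state
    },
    encode = {
      g <- need_graph()
      enc <- if (identical(spec$channel, "numeric")) {
        encode_numeric(g, spec$attribute, scope = spec$scope %||% "nodes")
      } else {
        encode_categorical(g, spec$attribute, scope = spec$scope %||% "nodes")
      }
      state$graph <- apply_encoding(g, enc)
      state
    },
    write_graph = {
      write_graph_file(need_graph(), spec$path, format = spec$format)
      state
    },
    write_layout = {
      if (is.null(state$layout)) stop("no layout computed")
      write_layout(state$layout, spec$path)
      state
    })
}

# YAML gives plain lists; predicates may arrive as strings like
# "weight >= 0.85" and are parsed into one-sided formulas
.parse_stack <- function(stack) {
  lapply(stack, function(spec) {
    if (is.character(spec$predicate))
      spec$predicate <- stats::as.formula(paste("~", spec$predicate))
    spec
  })
}
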
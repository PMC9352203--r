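# Planted-structure generators: every downstream step (correlation,
# transforms, clustering, metrics, layout) can be exercised against known
# ground truth without external data.  All generators are bit-reproducible
# for a fixed seed.

#' Planted-module data matrix
#'
#' Rows fall into modules sharing a latent Gaussian profile; each row is the
#' module profile plus independent Gaussian noise scaled so the expected
#' within-module Pearson correlation is `rho`.  Cross-module profiles are
#' independent (expected correlation 0).  Emulates the shape of co-varying
#' feature blocks (coexpressed gene modules, correlated SNV profiles);
#' it does not model counts, dropout or library-size effects of real data.
#'
#' @param n_modules Number of modules; default 5.
#' @param rows_per_module Rows per module; default 20.
#' @param n_cols Observations per row; default 30.
#' @param rho Target expected within-module Pearson correlation in (0, 1);
#'   default 0.95.
#' @param seed Integer seed.
#' @return List with `matrix` (a `data_matrix` whose row annotation
#'   `Module` holds the truth) and `labels` (named character vector).
#' @export
planted_module_matrix <- function(n_modules = 5, rows_per_module = 20,
                                  n_cols = 30, rho = 0.95, seed = 1) {
  stopifnot(n_modules >= 1, rows_per_module >= 1, n_cols >= 2,
            rho > 0, rho < 1)
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  noise_sd <- sqrt((1 - rho) / rho)     # var share giving corr = rho
  ids <- character(0); rows <- list(); labels <- character(0)
  for (m in seq_len(n_modules)) {
    profile <- stats::rnorm(n_cols)
    for (r in seq_len(rows_per_module)) {
      id <- sprintf("M%02d_R%02d", m, r)
      ids <- c(ids, id)
      rows[[id]] <- profile + stats::rnorm(n_cols, sd = noise_sd)
      labels[id] <- sprintf("module_%d", m)
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- sprintf("obs_%02d", seq_len(n_cols))
  ann <- data.frame(Module = unname(labels), row.names = ids,
                    stringsAsFactors = FALSE)
  list(matrix = data_matrix(values, ann), labels = labels)
}

#' Planted-partition (stochastic block) graph
#'
#' Nodes fall into blocks; a same-block pair gets an edge with probability
#' `p_in`, a cross-block pair with `p_out`.  Weights are drawn uniformly
#' from `w_in` / `w_out` respectively, so within-block edges are typically
#' stronger.
#'
#' @param block_sizes Integer vector of block sizes, e.g. `rep(20, 4)`.
#' @param p_in,p_out Edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param w_in,w_out Length-2 weight ranges; defaults `c(0.7, 1)` and
#'   `c(0.1, 0.4)`.
#' @param seed Integer seed.
#' @return List with `graph` (a `cgraph` whose node attribute `Block` holds
#'   the truth) and `labels` (named character vector).
#' @export
planted_partition_graph <- function(block_sizes = rep(20, 4),
                                    p_in = 0.3, p_out = 0.02,
                                    w_in = c(0.7, 1), w_out = c(0.1, 0.4),
                                    seed = 1) {
  stopifnot(p_out >= 0, p_in <= 1, p_out < p_in)
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  n <- sum(block_sizes)
  block <- rep(seq_along(block_sizes), block_sizes)
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- utils::combn(n, 2)
  same <- block[pairs[1, ]] == block[pairs[2, ]]
  p <- ifelse(same, p_in, p_out)
  hit <- stats::runif(ncol(pairs)) < p
  w <- numeric(sum(hit))
  hs <- same[hit]
  w[hs] <- stats::runif(sum(hs), w_in[1], w_in[2])
  w[!hs] <- stats::runif(sum(!hs), w_out[1], w_out[2])
  g <- graph_new(ids)
  if (any(hit))
    g <- add_edges(g, ids[pairs[1, hit]], ids[pairs[2, hit]], w)
  labels <- stats::setNames(sprintf("block_%d", block), ids)
  g <- set_node_attr(g, "Block", labels, kind = "categorical")
  list(graph = g, labels = labels)
}

#' Balanced rooted tree graph
#'
#' A depth-`depth` tree with `branching` children per internal node,
#' returned as an undirected graph with a numeric `level` node attribute
#' (root = 0).  A stand-in for taxonomy-like tree shapes.
#'
#' @param depth Tree depth (>= 1); the root alone has depth 0.
#' @param branching Children per node (>= 1).
#' @return A `cgraph` with `(branching^(depth+1) - 1) / (branching - 1)`
#'   nodes (or `depth + 1` when `branching = 1`).
#' @export
toy_tree <- function(depth, branching) {
  stopifnot(depth >= 1, branching >= 1)
  nodes <- "t0"
  level <- c(t0 = 0)
  edges_from <- character(0); edges_to <- character(0)
  frontier <- "t0"
  counter <- 0L
  for (d in seq_len(depth)) {
    nxt <- character(0)
    for (parent in frontier) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        id <- sprintf("t%d", counter)
        nodes <- c(nodes, id)
        level[id] <- d
        edges_from <- c(edges_from, parent)
        edges_to <- c(edges_to, id)
        nxt <- c(nxt, id)
      }
    }
    frontier <- nxt
  }
  g <- graph_new(nodes)
  g <- add_edges(g, edges_from, edges_to, 1)
  set_node_attr(g, "level", level)
}

#' Dosage-style data matrix
#'
#' Integer allele-dosage values (0/1/2) for individuals falling into
#' population blocks, with block-specific allele frequencies per variant so
#' same-block individuals have correlated dosage profiles -- the shape of a
#' genotype matrix used for individual-similarity graphs.
#'
#' @param n_blocks Number of population blocks; default 4.
#' @param rows_per_block Individuals per block; default 25.
#' @param n_cols Variants; default 200.
#' @param divergence Spread of block allele frequencies (0..1); larger
#'   separates blocks more.  Default 0.6.
#' @param seed Integer seed.
#' @return List with `matrix` (`data_matrix`, annotation `Population`) and
#'   `labels`.
#' @export
dosage_matrix <- function(n_blocks = 4, rows_per_block = 25, n_cols = 200,
                          divergence = 0.6, seed = 1) {
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  base_freq <- stats::runif(n_cols, 0.05, 0.95)
  ids <- character(0); rows <- list(); labels <- character(0)
  for (b in seq_len(n_blocks)) {
    shift <- stats::runif(n_cols, -divergence / 2, divergence / 2)
    freq <- pmin(0.99, pmax(0.01, base_freq + shift))
    for (r in seq_len(rows_per_block)) {
      id <- sprintf("B%02d_I%03d", b, r)
      ids <- c(ids, id)
      rows[[id]] <- stats::rbinom(n_cols, 2, freq)
      labels[id] <- sprintf("pop_%d", b)
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- sprintf("snv_%04d", seq_len(n_cols))
  storage.mode(values) <- "double"
  ann <- data.frame(Population = unname(labels), row.names = ids,
                    stringsAsFactors = FALSE)
  list(matrix = data_matrix(values, ann), labels = labels)
}
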
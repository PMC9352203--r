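# Seeded force-directed layout per component, then concentric placement of
# components around the largest.  The iteration is exposed through max_iter
# so callers can step a layout incrementally; a fixed seed gives bit-identical
# coordinates.

#' Force-directed graph layout
#'
#' Lays out each connected component independently with a spring embedder
#' (repulsion `k^2/d` between all pairs via a Barnes-Hut octree, attraction
#' `w d^2/k` along edges, displacement capped by a geometrically cooling
#' step limit), then arranges the components concentrically, largest at the
#' origin and the rest on rings of increasing radius in size order.
#'
#' Initial positions are drawn uniformly in the unit cube from `seed`, so a
#' given graph, seed and parameter set yields bit-identical coordinates.
#'
#' @param graph A `cgraph`.
#' @param dims 2 or 3 (default 3).
#' @param seed Integer seed for the initial positions.
#' @param max_iter Iteration cap per component; default 2000.
#' @param tol Stop when mean per-node displacement falls below
#'   `tol * ideal_length`; default 1e-3.
#' @param ideal_length Ideal edge length (layout unit); default 1.
#' @param theta Barnes-Hut opening angle; default 0.8.
#' @param cooling Geometric cooling factor per iteration; default 0.95.
#' @param arrange Arrange components concentrically (default `TRUE`); when
#'   `FALSE` every component stays centred at the origin.
#' @return A `layout_result`: `coords` (matrix, row names = node ids),
#'   `dims`, `component_offsets` (data frame: rank, x, y, z, radius),
#'   `converged`, `iterations_run`.
#' @export
force_layout <- function(graph, dims = 3, seed = 1, max_iter = 2000,
                         tol = 1e-3, ideal_length = 1, theta = 0.8,
                         cooling = 0.95, arrange = TRUE) {
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  n <- n_nodes(graph)
  coords <- matrix(numeric(0), 0, dims,
                   dimnames = list(NULL, c("x", "y", "z")[seq_len(dims)]))
  if (!n) {
    return(structure(list(coords = coords, dims = dims,
                          component_offsets = .empty_offsets(),
                          converged = TRUE, iterations_run = 0L),
                     class = "layout_result"))
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))

  comp <- graph_components(graph)
  ranks <- sort(unique(comp$component_of))
  layouts <- vector("list", length(ranks))
  converged <- TRUE
  iterations <- 0L
  # draw all initial positions at once so per-component layouts are
  # independent of how many components precede them
  init_all <- matrix(stats::runif(n * dims), n, dims)
  rownames(init_all) <- graph$nodes
  for (ri in seq_along(ranks)) {
    members <- graph$nodes[comp$component_of == ranks[ri]]
    sub <- .induced_subgraph(graph, members)
    if (length(members) == 1) {
      xy <- matrix(0, 1, dims, dimnames = list(members, NULL))
      layouts[[ri]] <- list(coords = xy, converged = TRUE, iterations = 0L)
      next
    }
    fi <- match(sub$edges$from, sub$nodes) - 1L
    ti <- match(sub$edges$to, sub$nodes) - 1L
    res <- .fr_layout_cpp(init_all[sub$nodes, , drop = FALSE], fi, ti,
                          abs(sub$edges$weight), dims, as.integer(max_iter),
                          tol, ideal_length, theta, cooling)
    xy <- res$coords
    rownames(xy) <- sub$nodes
    xy <- sweep(xy, 2, colMeans(xy))       # centre component at origin
    layouts[[ri]] <- list(coords = xy, converged = res$converged,
                          iterations = res$iterations)
    converged <- converged && res$converged
    iterations <- max(iterations, res$iterations)
  }
  arranged <- if (arrange) {
    arrange_components(layouts, dims = dims, node_radius = 0.5 * ideal_length)
  } else {
    list(coords = do.call(rbind, lapply(layouts, `[[`, "coords")),
         offsets = .empty_offsets())
  }
  coords <- arranged$coords[graph$nodes, , drop = FALSE]
  colnames(coords) <- c("x", "y", "z")[seq_len(dims)]
  structure(list(coords = coords, dims = dims,
                 component_offsets = arranged$offsets,
                 converged = converged, iterations_run = iterations),
            class = "layout_result")
}

#' @export
print.layout_result <- function(x, ...) {
  cat(sprintf("<layout_result> %d nodes in %dD; %s after %d iterations\n",
              nrow(x$coords), x$dims,
              if (x$converged) "converged" else "not converged",
              x$iterations_run))
  invisible(x)
}

.empty_offsets <- function() {
  data.frame(rank = integer(), x = numeric(), y = numeric(), z = numeric(),
             radius = numeric())
}

#' Arrange component layouts concentrically
#'
#' Places independently laid-out components into one scene: the largest
#' (rank 0) at the origin, the rest on rings of increasing radius in rank
#' order, advancing to a wider ring when the current one is full.  Bounding
#' spheres never overlap: neighbouring placements are padded by 10% of the
#' larger radius.
#'
#' @param layouts List (in component rank order) of layouts, each with a
#'   `coords` matrix (row names = node ids) centred at the origin.
#' @param dims 2 or 3.
#' @param node_radius Slack added around each component's furthest node so
#'   singletons get a nonzero extent; default 0.5.
#' @return List with `coords` (all nodes, translated) and `offsets`
#'   (data frame: rank, x, y, z, radius).
#' @export
arrange_components <- function(layouts, dims = 3, node_radius = 0.5) {
  coords_list <- lapply(layouts, function(l) l$coords)
  radii <- vapply(coords_list, function(xy) {
    if (!nrow(xy)) return(node_radius)
    max(sqrt(rowSums(xy^2))) + node_radius
  }, numeric(1))
  k <- length(coords_list)
  centres <- matrix(0, k, 3)
  if (k > 1) {
    pad <- function(a, b) 0.1 * max(a, b)
    inner <- radii[1]                   # outer extent of everything placed
    i <- 2L
    while (i <= k) {
      ring_r <- inner + radii[i] + pad(inner, radii[i])
      theta <- 0
      first_on_ring <- i
      r_first <- radii[i]
      outer <- inner
      while (i <= k) {
        r_i <- radii[i]
        # later components must not dip inside the previously placed extent
        if (i > first_on_ring && ring_r - r_i - pad(inner, r_i) < inner) break
        if (i > first_on_ring) {
          r_prev <- radii[i - 1L]
          gap_prev <- (r_i + r_prev + pad(r_i, r_prev)) / (2 * ring_r)
          gap_first <- (r_i + r_first + pad(r_i, r_first)) / (2 * ring_r)
          if (gap_prev >= 1) break      # ring too tight for this pair
          need <- 2 * asin(gap_prev)
          close_gap <- if (gap_first >= 1) 2 * pi else 2 * asin(gap_first)
          if (theta + need + close_gap > 2 * pi) break  # ring full
          theta <- theta + need
        }
        centres[i, 1] <- ring_r * cos(theta)
        centres[i, 2] <- ring_r * sin(theta)
        outer <- max(outer, ring_r + r_i)
        i <- i + 1L
      }
      inner <- outer
    }
  }
  out <- vector("list", k)
  for (j in seq_len(k)) {
    xy <- coords_list[[j]]
    if (nrow(xy))
      out[[j]] <- sweep(xy, 2, centres[j, seq_len(ncol(xy))], "+")
  }
  offsets <- data.frame(rank = seq_len(k) - 1L,
                        x = centres[, 1], y = centres[, 2], z = centres[, 3],
                        radius = radii)
  list(coords = do.call(rbind, out), offsets = offsets)
}

#' Write layout coordinates to TSV
#'
#' @param layout A `layout_result`.
#' @param path Output path (columns: node id, x, y and z when 3D).
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  df <- data.frame(id = rownames(layout$coords), layout$coords,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
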
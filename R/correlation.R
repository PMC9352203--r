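# All-vs-all row correlation and thresholded graph construction.  Pearson or
# Spearman, pairwise-complete handling of missing values, and a blocked
# construction path so that only the thresholded edge list is materialised --
# the full n x n matrix never needs to be held when n is large.

#' All-vs-all row correlation matrix
#'
#' Computes the correlation between every pair of rows.  Spearman is Pearson
#' on within-row ranks (average ranks for ties).  Missing values are handled
#' by pairwise exclusion; a pair with fewer than `min_obs` shared non-missing
#' observations gets `NA` (and no edge downstream), since two shared points
#' always give r = +/-1.
#'
#' @param dm A `data_matrix`, or a numeric matrix with row names.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_obs Minimum shared observations per pair; default 3.
#' @return Symmetric matrix with unit diagonal, entries in `[-1, 1]` or `NA`.
#' @examples
#' m <- data_matrix(matrix(c(1, 2, 3, 3, 2, 1), 2, 3, byrow = TRUE,
#'                  dimnames = list(c("up", "down"), c("s1", "s2", "s3"))))
#' correlation_matrix(m)["up", "down"]   # -1
#' @export
correlation_matrix <- function(dm, method = c("pearson", "spearman"),
                               min_obs = 3) {
  method <- match.arg(method)
  x <- if (inherits(dm, "data_matrix")) dm$values else as.matrix(dm)
  if (ncol(x) < 2) stop("need at least 2 columns to correlate")
  xr <- if (method == "spearman") .row_ranks(x) else x
  r <- suppressWarnings(stats::cor(t(xr), use = "pairwise.complete.obs"))
  shared <- crossprod(!t(is.na(x)))
  r[shared < min_obs] <- NA_real_
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  r
}

# rank within rows, average ranks for ties, NA kept in place
.row_ranks <- function(x) {
  t(apply(x, 1, function(row) {
    out <- rep(NA_real_, length(row))
    ok <- !is.na(row)
    out[ok] <- rank(row[ok], ties.method = "average")
    out
  }))
}

#' Build a thresholded correlation graph
#'
#' One node per matrix row; an edge joins rows i and j when their correlation
#' passes the threshold.  With `polarity = "positive_only"` only positive
#' correlations qualify (`r > r_min`, or `>=` when `inclusive`); with
#' `"absolute"` the magnitude is tested (`|r| > r_min`) and the signed value
#' is kept as the edge weight.  Row annotations become node attributes.
#'
#' Correlations are computed in row blocks so memory stays proportional to
#' `block_size^2` rather than the full matrix when only the thresholded edge
#' list is needed.
#'
#' @param dm A `data_matrix`.
#' @param r_min Threshold in `[-1, 1]`.
#' @param method `"pearson"` or `"spearman"`.
#' @param polarity `"positive_only"` (default) or `"absolute"`.
#' @param inclusive Keep edges at `r >= r_min` instead of the default strict
#'   `r > r_min` (the convention used for thresholds quoted as "r > 0.85").
#' @param min_obs Minimum shared non-missing observations per pair.
#' @param block_size Rows per block in the blocked computation.
#' @param drop_constant Remove (near-)constant rows first; default `TRUE`.
#' @return A `cgraph` whose edge weights are the signed correlations.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(80), 4, 20,
#'             dimnames = list(c("A", "B", "C", "D"), paste0("s", 1:20)))
#' m["B", ] <- 2 * m["A", ]        # perfectly correlated with A
#' m["C", ] <- -m["A", ]           # perfectly anti-correlated
#' g <- build_correlation_graph(data_matrix(m), r_min = 0.9)
#' g$edges                         # A--B only under positive_only polarity
#' @export
build_correlation_graph <- function(dm, r_min,
                                    method = c("pearson", "spearman"),
                                    polarity = c("positive_only", "absolute"),
                                    inclusive = FALSE, min_obs = 3,
                                    block_size = 512, drop_constant = TRUE) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  if (!is.finite(r_min) || r_min < -1 || r_min > 1)
    stop("r_min must lie in [-1, 1]")
  if (!inherits(dm, "data_matrix")) dm <- data_matrix(dm)
  if (drop_constant) {
    dc <- suppressWarnings(drop_constant_rows(dm))
    dm <- dc$matrix
  }
  x <- dm$values
  n <- nrow(x)
  ids <- rownames(x)
  g <- graph_new(ids)
  if (r_min == 1 && !inclusive)
    warning("strict threshold at r_min = 1 admits no edges")
  if (n >= 2 && ncol(x) >= 2) {
    xr <- if (method == "spearman") .row_ranks(x) else x
    has_na <- anyNA(x)
    pass <- if (inclusive) function(v) v >= r_min else function(v) v > r_min
    blocks <- split(seq_len(n), ceiling(seq_len(n) / block_size))
    ef <- list(); et <- list(); ew <- list(); bi <- 0L
    for (a in seq_along(blocks)) {
      ia <- blocks[[a]]
      for (b in a:length(blocks)) {
        ib <- blocks[[b]]
        r <- suppressWarnings(stats::cor(t(xr[ia, , drop = FALSE]),
                                         t(xr[ib, , drop = FALSE]),
                                         use = "pairwise.complete.obs"))
        if (has_na) {
          shared <- (!is.na(x[ia, , drop = FALSE])) %*%
            t(!is.na(x[ib, , drop = FALSE]))
          r[shared < min_obs] <- NA_real_
        }
        test <- if (polarity == "absolute") abs(r) else r
        hit <- which(!is.na(test) & pass(test), arr.ind = TRUE)
        if (nrow(hit)) {
          gi <- ia[hit[, 1]]; gj <- ib[hit[, 2]]
          keep <- gi < gj          # upper triangle only, no self pairs
          if (any(keep)) {
            bi <- bi + 1L
            ef[[bi]] <- ids[gi[keep]]
            et[[bi]] <- ids[gj[keep]]
            ew[[bi]] <- r[hit[, , drop = FALSE]][keep]
          }
        }
      }
    }
    if (bi)
      g <- add_edges(g, unlist(ef), unlist(et), unlist(ew))
  }
  ann <- dm$row_annotations
  for (col in names(ann)) {
    vals <- ann[[col]]
    names(vals) <- rownames(ann)
    g <- set_node_attr(g, col, vals)
  }
  g
}
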
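# Attribute-to-visual mapping: categorical attributes get palette colours
# (ordered by value frequency), numeric attributes get an affine colour ramp
# and size spectrum between their observed min and max.  Encodings are plain
# per-element colour/size vectors that any renderer can consume; they
# serialise into graph files as `colour` and `size` attributes.

#' Default categorical palette
#'
#' Twenty maximally-distinct hex colours; categorical encodings cycle
#' through it (with a warning) when an attribute has more values.
#' @return Character vector of hex colours.
#' @export
default_palette <- function() {
  c("#E6194B", "#3CB44B", "#FFE119", "#4363D8", "#F58231",
    "#911EB4", "#46F0F0", "#F032E6", "#BCF60C", "#FABEBE",
    "#008080", "#E6BEFF", "#9A6324", "#FFFAC8", "#800000",
    "#AAFFC3", "#808000", "#FFD8B1", "#000075", "#808080")
}

.missing_grey <- "#BEBEBE"

#' Encode a categorical attribute as colours
#'
#' Distinct values are ordered by frequency (descending, ties lexicographic)
#' and assigned palette colours in that order, so the most common category
#' always gets the first palette colour regardless of node order.  Missing
#' values map to neutral grey.
#'
#' @param graph A `cgraph`.
#' @param attribute Name of a categorical node or edge attribute.
#' @param scope `"nodes"` or `"edges"`.
#' @param palette Colour vector; defaults to [default_palette()].
#' @return A `visual_encoding`: `values` (hex colours per element; named by
#'   id for nodes), `channel = "colour"`, `mapping` (value -> colour).
#' @export
encode_categorical <- function(graph, attribute, scope = c("nodes", "edges"),
                               palette = default_palette()) {
  scope <- match.arg(scope)
  vals <- .encoding_attr(graph, attribute, scope)
  kind <- graph$attr_kinds[[scope]][attribute]
  if (identical(unname(kind), "numeric"))
    stop("attribute '", attribute,
         "' is numeric; use encode_numeric() for spectra")
  vals <- as.character(vals)
  freq <- table(vals[!is.na(vals)])
  lev <- names(freq)[order(-freq, names(freq), method = "radix")]
  if (length(lev) > length(palette))
    warning(length(lev), " categories exceed the ", length(palette),
            "-colour palette; colours will cycle")
  colour_of <- stats::setNames(
    palette[((seq_along(lev) - 1) %% length(palette)) + 1], lev)
  out <- unname(colour_of[vals])
  out[is.na(out)] <- .missing_grey
  if (scope == "nodes") names(out) <- graph$nodes
  structure(list(scope = scope, channel = "colour", attribute = attribute,
                 values = out, mapping = colour_of),
            class = "visual_encoding")
}

#' Encode a numeric attribute as a colour/size spectrum
#'
#' Each value is rescaled to `t = (v - min) / (max - min)` (clamped; `t =
#' 0.5` throughout when the attribute is constant), then mapped to a linear
#' sRGB interpolation along `ramp` and an affine size `s_min + t * (s_max -
#' s_min)` -- the classic "small white to big red" spectrum by default.
#' Missing values get grey and the minimum size.
#'
#' @param graph A `cgraph`.
#' @param attribute Name of a numeric node or edge attribute.
#' @param scope `"nodes"` or `"edges"`.
#' @param ramp Two or more colours to interpolate; default white to red.
#' @param sizes Length-2 numeric `[s_min, s_max]`; default `c(0.5, 2)`.
#' @return A `visual_encoding` with `values` (hex colours), `sizes` and the
#'   `(min, max)` domain in `mapping`.
#' @export
encode_numeric <- function(graph, attribute, scope = c("nodes", "edges"),
                           ramp = c("#FFFFFF", "#FF0000"),
                           sizes = c(0.5, 2.0)) {
  scope <- match.arg(scope)
  v <- .encoding_attr(graph, attribute, scope)
  if (!is.numeric(v))
    stop("attribute '", attribute, "' is not numeric")
  if (all(is.na(v)))
    stop("attribute '", attribute, "' has no non-missing values")
  lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
  t <- if (hi == lo) ifelse(is.na(v), NA_real_, 0.5) else (v - lo) / (hi - lo)
  t <- pmin(1, pmax(0, t))
  ramp_fun <- grDevices::colorRamp(ramp)               # linear sRGB
  cols <- rep(.missing_grey, length(v))
  ok <- !is.na(t)
  if (any(ok)) {
    rgb <- round(ramp_fun(t[ok]))
    cols[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3],
                               maxColorValue = 255)
  }
  sz <- rep(sizes[1], length(v))
  sz[ok] <- sizes[1] + t[ok] * (sizes[2] - sizes[1])
  if (scope == "nodes") { names(cols) <- graph$nodes; names(sz) <- graph$nodes }
  structure(list(scope = scope, channel = "colour+size", attribute = attribute,
                 values = cols, sizes = sz,
                 mapping = list(min = lo, max = hi, ramp = ramp,
                                size_range = sizes)),
            class = "visual_encoding")
}

#' @export
print.visual_encoding <- function(x, ...) {
  cat(sprintf("<visual_encoding> %s of %s from attribute '%s' (%d elements)\n",
              x$channel, x$scope, x$attribute, length(x$values)))
  invisible(x)
}

.encoding_attr <- function(graph, attribute, scope) {
  tab <- if (scope == "nodes") graph$node_attrs else graph$edge_attrs
  if (scope == "edges" && attribute == "weight") return(graph$edges$weight)
  if (!attribute %in% names(tab))
    stop("no ", sub("s$", "", scope), " attribute '", attribute, "'")
  tab[[attribute]]
}

#' Apply an encoding to a graph
#'
#' Writes the encoding into `colour` (hex text) and, for numeric spectra,
#' `size` attribute columns so the styling survives serialisation.
#'
#' @param graph A `cgraph`.
#' @param encoding A `visual_encoding`.
#' @return The styled graph.
#' @export
apply_encoding <- function(graph, encoding) {
  if (encoding$scope == "nodes") {
    graph <- set_node_attr(graph, "colour", encoding$values, kind = "text")
    if (!is.null(encoding$sizes))
      graph <- set_node_attr(graph, "size", unname(encoding$sizes))
  } else {
    graph <- set_edge_attr(graph, "colour", unname(encoding$values),
                           kind = "text")
    if (!is.null(encoding$sizes))
      graph <- set_edge_attr(graph, "size", unname(encoding$sizes))
  }
  graph
}
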
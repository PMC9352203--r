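# Numeric tables from which correlation graphs are built.  Rows are the
# entities to be correlated (genes, cells, individuals); columns are the
# observations (samples, principal components, SNV dosages).  Non-numeric
# metadata columns can be split off as row annotations and later become node
# attributes on the correlation graph.

#' Construct a data matrix
#'
#' @param values Numeric matrix with unique row and column names.
#' @param row_annotations Optional data frame of per-row metadata, row names
#'   matching the matrix rows.
#' @return An object of class `data_matrix`.
#' @export
data_matrix <- function(values, row_annotations = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    if (nrow(values)) stop("values must have row names")
    dimnames(values) <- list(character(0), colnames(values))
  }
  if (is.null(colnames(values))) {
    if (ncol(values)) stop("values must have column names")
    dimnames(values) <- list(rownames(values), character(0))
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicate row ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate column ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  storage.mode(values) <- "double"
  if (!is.null(row_annotations)) {
    miss <- setdiff(rownames(values), rownames(row_annotations))
    if (length(miss))
      stop("row_annotations missing rows: ", paste(utils::head(miss, 5), collapse = ", "))
    row_annotations <- row_annotations[rownames(values), , drop = FALSE]
  } else {
    row_annotations <- data.frame(row.names = rownames(values))
  }
  structure(list(values = values, row_annotations = row_annotations),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d rows x %d cols", nrow(x$values), ncol(x$values)))
  if (ncol(x$row_annotations))
    cat(";", ncol(x$row_annotations), "annotation column(s):",
        paste(names(x$row_annotations), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' Read a numeric table from CSV/TSV
#'
#' First row holds column names and first column row names.  Cells that are
#' empty, `NA` or `NaN` are treated as explicitly missing (excluded pairwise
#' during correlation, never imputed as zero).  Rows with more than half of
#' their values missing are dropped with a warning.
#'
#' @param path File path; delimiter inferred from the extension (`.tsv`/`.txt`
#'   = tab, otherwise comma) unless `sep` is given.
#' @param annotation_columns Character vector of column names to split into
#'   `row_annotations` rather than the numeric block.
#' @param transpose If `TRUE`, transpose after reading (annotations dropped).
#' @param sep Field delimiter override.
#' @return A `data_matrix`.
#' @export
read_matrix <- function(path, annotation_columns = character(),
                        transpose = FALSE, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA", "NaN"), comment.char = "")
  if (!ncol(raw)) stop("no columns in ", path)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- raw[, -1, drop = FALSE]
  unknown <- setdiff(annotation_columns, names(body))
  if (length(unknown))
    stop("annotation columns not found: ", paste(unknown, collapse = ", "))
  ann <- body[, annotation_columns, drop = FALSE]
  num <- body[, setdiff(names(body), annotation_columns), drop = FALSE]
  for (j in seq_along(num)) {
    col <- num[[j]]
    if (!is.numeric(col)) {
      bad <- !is.na(col) & is.na(suppressWarnings(as.numeric(col)))
      if (any(bad))
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                     col[bad][1], ids[bad][1], names(num)[j]))
      num[[j]] <- as.numeric(col)
    }
  }
  values <- as.matrix(num)
  rownames(values) <- ids
  rownames(ann) <- ids
  # drop rows that are mostly missing
  frac_na <- rowMeans(is.na(values))
  if (any(frac_na > 0.5)) {
    dropped <- ids[frac_na > 0.5]
    warning(length(dropped), " row(s) with >50% missing values dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    values <- values[frac_na <= 0.5, , drop = FALSE]
    ann <- ann[frac_na <= 0.5, , drop = FALSE]
  }
  dm <- data_matrix(values, ann)
  if (transpose) dm <- transpose_matrix(dm) else dm
}

#' Write a data matrix to CSV/TSV
#'
#' Annotation columns are written after the row-name column, before the
#' numeric block, so `read_matrix` round-trips with the same
#' `annotation_columns`.
#'
#' @param dm A `data_matrix`.
#' @param path Output path; delimiter from extension unless `sep` given.
#' @param sep Field delimiter override.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(dm, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  out <- cbind(data.frame(id = rownames(dm$values), stringsAsFactors = FALSE),
               dm$row_annotations, as.data.frame(dm$values, check.names = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Transpose a data matrix
#'
#' Rows and columns swap roles, switching which entity gets correlated (for
#' example, from individuals to the variants measured on them).  Row
#' annotations do not transfer and are dropped with a warning.
#'
#' @param dm A `data_matrix`.
#' @return The transposed `data_matrix`.
#' @export
transpose_matrix <- function(dm) {
  if (ncol(dm$row_annotations))
    warning("row annotations dropped on transpose")
  data_matrix(t(dm$values))
}

#' Remove rows with (near-)zero variance
#'
#' Pearson correlation is undefined for constant rows; rows whose sample
#' variance is below `tol` are removed before graph construction.
#'
#' @param dm A `data_matrix`.
#' @param tol Variance threshold; default `1e-12`.
#' @return A list with `matrix` (the filtered `data_matrix`) and `removed`
#'   (character vector of removed row ids).
#' @export
drop_constant_rows <- function(dm, tol = 1e-12) {
  v <- apply(dm$values, 1, stats::var, na.rm = TRUE)
  v[is.na(v)] <- 0   # rows with a single non-missing value
  const <- v < tol
  removed <- rownames(dm$values)[const]
  if (all(const)) {
    warning("all rows constant; returning empty matrix")
    empty <- dm$values[integer(0), , drop = FALSE]
    rownames(empty) <- character(0)      # dropped to NULL by the subset
    return(list(matrix = data_matrix(empty), removed = removed))
  }
  list(matrix = data_matrix(dm$values[!const, , drop = FALSE],
                            dm$row_annotations[!const, , drop = FALSE]),
       removed = removed)
}
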
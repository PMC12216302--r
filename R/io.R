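# Plain-text interchange: grid matrices and injection rows as CSV,
# partitions and nucleus geometry as JSON.

#' Write a connectivity matrix to CSV
#'
#' Injection ids in the first column, grid cells as `r{row}c{col}` columns.
#' @param matrix a `connectivity_grid_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_matrix_csv <- function(matrix, path) {
  M <- matrix$values
  df <- data.frame(injection_id = rownames(M), M, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix from CSV
#' @param path CSV written by [write_grid_matrix_csv()] (or any CSV with an
#'   `injection_id` column and grid-cell columns).
#' @param grid a [grid_spec()].
#' @param rescale rescale rows by their maxima (default FALSE: a written
#'   matrix is already scaled).
#' @return a `connectivity_grid_matrix`.
#' @export
read_grid_matrix_csv <- function(path, grid = grid_spec(), rescale = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, setdiff(names(df), "injection_id"), drop = FALSE])
  rownames(M) <- df$injection_id
  connectivity_grid_matrix(M, grid = grid, rescale = rescale)
}

#' Write a domain partition to JSON
#' @param partition a [detect_domains()] partition.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(
    list(gamma = partition$gamma, seed = partition$seed,
         modularity = partition$modularity,
         membership = as.list(partition$membership)),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Write nucleus geometry to JSON
#' @param geometry a [nucleus_geometry()]; @param path output path.
#' @return `path`, invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  jsonlite::write_json(
    list(center = geometry$center,
         boundary = if (!is.null(geometry$boundary))
           apply(geometry$boundary, 1, as.numeric, simplify = FALSE),
         radius_um = geometry$radius_um,
         edge_threshold = geometry$edge_threshold),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read nucleus geometry from JSON
#' @param path JSON written by [write_geometry_json()] (center coordinates,
#'   optional polygon vertex list, optional radius and edge threshold).
#' @return a [nucleus_geometry()].
#' @export
read_geometry_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  boundary <- if (!is.null(j$boundary)) {
    if (is.matrix(j$boundary)) j$boundary
    else do.call(rbind, lapply(j$boundary, as.numeric))
  }
  nucleus_geometry(center = as.numeric(j$center), boundary = boundary,
                   radius_um = j$radius_um,
                   edge_threshold = j$edge_threshold %||% 0.2)
}
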
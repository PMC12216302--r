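# Grid-based tracer-label tabulation and connectional-domain detection.
#
# Segmented tracer label (binary pixel masks for anterograde axonal label,
# cell-position lists for retrograde label) is tabulated onto square pixel
# grids; per-injection grid rows are aggregated into a single
# injection x grid matrix; domains are detected as communities of a
# weighted bipartite graph (injections + grid cells as vertices, matrix
# entries as edge weights) by Louvain modularity maximization at a
# resolution parameter gamma.

#' Grid geometry specification
#'
#' @param grid_px pixels per grid-cell side (default 105).
#' @param pixel_um micrometres per pixel (default 0.6, so a 105 px cell is
#'   ~63 um on a side).
#' @param nucleus_mask optional logical matrix over grid cells (rows x
#'   cols); cells marked `FALSE` are dropped from tabulation.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(grid_px = 105L, pixel_um = 0.6, nucleus_mask = NULL) {
  if (grid_px <= 0 || pixel_um <= 0) .fail("grid_px and pixel_um must be positive")
  structure(list(grid_px = as.integer(grid_px), pixel_um = pixel_um,
                 nucleus_mask = nucleus_mask),
            class = "grid_spec")
}

## canonical grid-cell label, 0-based row-major
.grid_label <- function(row, col) sprintf("r%dc%d", row, col)

#' Tabulate segmented label onto the grid
#'
#' Anterograde label (a binary pixel mask, image rows = y) is quantified as
#' the percentage of each grid cell's `grid_px^2` pixels that are labeled;
#' retrograde label (a point list of cell positions) as the count of cells
#' per grid. Grid indices are 0-based, row-major, origin at the image
#' top-left.
#'
#' @param label for `kind = "anterograde"`, a logical/0-1 matrix of pixels;
#'   for `kind = "retrograde"`, a data.frame with columns `x_px`, `y_px`.
#' @param spec a [grid_spec()].
#' @param kind `"anterograde"` or `"retrograde"`.
#' @param injection_id identifier for the injection (ROI + tracer).
#' @return object of class `injection_grid_row`: list with `injection_id`,
#'   `tracer_kind`, `values` (named numeric by grid label), `spec`.
#' @export
tabulate_grid <- function(label, spec = grid_spec(), kind = c("anterograde", "retrograde"),
                          injection_id = "inj") {
  kind <- match.arg(kind)
  gpx <- spec$grid_px
  if (kind == "anterograde") {
    m <- as.matrix(label)
    if (!all(m %in% c(0, 1, FALSE, TRUE))) .fail("anterograde mask must be binary")
    mode(m) <- "numeric"
    nr <- ceiling(nrow(m) / gpx); nc <- ceiling(ncol(m) / gpx)
    vals <- numeric(0)
    for (r in seq_len(nr) - 1L) for (cc in seq_len(nc) - 1L) {
      rows <- (r * gpx + 1L):min((r + 1L) * gpx, nrow(m))
      cols <- (cc * gpx + 1L):min((cc + 1L) * gpx, ncol(m))
      vals[.grid_label(r, cc)] <- 100 * sum(m[rows, cols]) / (gpx^2)
    }
    if (sum(m) == 0) warning("empty anterograde mask for ", injection_id,
                             ": all-zero grid row")
  } else {
    pts <- as.data.frame(label)
    if (!all(c("x_px", "y_px") %in% names(pts))) {
      .fail("retrograde label must have columns x_px, y_px")
    }
    if (nrow(pts) == 0L) {
      warning("no retrograde cells for ", injection_id, ": all-zero grid row")
      vals <- numeric(0)
    } else {
      if (any(pts$x_px < 0 | pts$y_px < 0)) .fail("negative pixel coordinates")
      row <- floor(pts$y_px / gpx); col <- floor(pts$x_px / gpx)
      tab <- table(.grid_label(row, col))
      vals <- as.numeric(tab)
      names(vals) <- names(tab)
    }
  }
  if (!is.null(spec$nucleus_mask)) {
    keep_lab <- .grid_label(
      rep(seq_len(nrow(spec$nucleus_mask)) - 1L, ncol(spec$nucleus_mask)),
      rep(seq_len(ncol(spec$nucleus_mask)) - 1L, each = nrow(spec$nucleus_mask))
    )[as.vector(spec$nucleus_mask)]
    vals <- vals[names(vals) %in% keep_lab]
  }
  structure(list(injection_id = injection_id, tracer_kind = kind,
                 values = vals, spec = spec),
            class = "injection_grid_row")
}

#' Aggregate injection rows into a single connectivity matrix
#'
#' Rows are stacked over the union of their grid cells and each row is
#' rescaled to \[0, 1\] by its own maximum, making anterograde percentages
#' and retrograde cell counts commensurate. All-zero rows are dropped with
#' a warning; all-zero columns are retained but flagged in the
#' `zero_columns` attribute.
#'
#' @param rows list of [tabulate_grid()] rows sharing a grid spec.
#' @return object of class `connectivity_grid_matrix`: list with `values`
#'   (injections x grid cells numeric matrix, row/col named) and `grid`.
#' @export
aggregate_matrix <- function(rows) {
  stopifnot(length(rows) >= 1L, all(vapply(rows, inherits, logical(1),
                                           "injection_grid_row")))
  specs <- lapply(rows, function(r) r$spec[c("grid_px", "pixel_um")])
  if (length(unique(specs)) != 1L) .fail("rows have inconsistent grid specs")
  labs <- unique(unlist(lapply(rows, function(r) names(r$values))))
  ## sort labels by (row, col)
  rr <- as.integer(sub("^r(\\d+)c\\d+$", "\\1", labs))
  cc <- as.integer(sub("^r\\d+c(\\d+)$", "\\1", labs))
  labs <- labs[order(rr, cc)]
  M <- matrix(0, nrow = length(rows), ncol = length(labs),
              dimnames = list(vapply(rows, `[[`, "", "injection_id"), labs))
  for (i in seq_along(rows)) {
    v <- rows[[i]]$values
    if (length(v)) M[i, names(v)] <- v
  }
  rmax <- apply(M, 1, max)
  if (any(rmax == 0)) {
    warning("dropping all-zero rows: ", paste(rownames(M)[rmax == 0], collapse = ", "))
    M <- M[rmax > 0, , drop = FALSE]
    rmax <- rmax[rmax > 0]
  }
  if (!nrow(M)) .fail("no nonzero injection rows to aggregate")
  M <- M / rmax
  zero_cols <- colnames(M)[colSums(M) == 0]
  structure(list(values = M, grid = rows[[1]]$spec, zero_columns = zero_cols),
            class = "connectivity_grid_matrix")
}

#' Construct a connectivity matrix directly from values
#'
#' For matrices read from CSV or built synthetically; rows are rescaled by
#' their maxima as in [aggregate_matrix()] unless `rescale = FALSE`.
#'
#' @param values numeric matrix, injections x grid cells, with dimnames.
#' @param grid a [grid_spec()].
#' @param rescale rescale rows to max 1 (default TRUE).
#' @return a `connectivity_grid_matrix`.
#' @export
connectivity_grid_matrix <- function(values, grid = grid_spec(), rescale = TRUE) {
  values <- as.matrix(values)
  if (any(values < 0)) .fail("connectivity values must be non-negative")
  if (is.null(rownames(values))) rownames(values) <- paste0("inj", seq_len(nrow(values)))
  if (is.null(colnames(values))) {
    colnames(values) <- .grid_label(0L, seq_len(ncol(values)) - 1L)
  }
  if (rescale) {
    rmax <- apply(values, 1, max)
    if (any(rmax == 0)) .fail("all-zero injection rows present")
    values <- values / rmax
  }
  structure(list(values = values, grid = grid,
                 zero_columns = colnames(values)[colSums(values) == 0]),
            class = "connectivity_grid_matrix")
}

#' Detect connectional domains by Louvain modularity maximization
#'
#' Builds the weighted bipartite graph whose vertices are the injections
#' and the grid cells and whose edge weights are the matrix entries, then
#' runs multilevel (Louvain) modularity maximization at resolution `gamma`.
#' The run is deterministic given `seed`. Communities containing at least
#' one grid cell define connectional domains. All-zero grid columns are
#' excluded from the graph and reported as unassigned (`NA`).
#'
#' @param matrix a `connectivity_grid_matrix` (or plain numeric matrix).
#' @param gamma modularity resolution (default 0.75).
#' @param seed integer seed fixing the Louvain vertex-visitation order.
#' @return object of class `domain_partition`: list with `membership`
#'   (named integer vector over injections and grid cells; `NA` for
#'   zero columns), `injections`, `grids`, `gamma`, `modularity`, `seed`.
#' @export
detect_domains <- function(matrix, gamma = 0.75, seed = 1L) {
  M <- if (inherits(matrix, "connectivity_grid_matrix")) matrix$values else as.matrix(matrix)
  if (!nrow(M) || !ncol(M)) .fail("empty connectivity matrix")
  if (any(M < 0)) .fail("connectivity matrix must be non-negative")
  if (all(M == 0)) .fail("all-zero connectivity matrix")
  keep <- colSums(M) > 0
  Mk <- M[, keep, drop = FALSE]
  g <- igraph::graph_from_biadjacency_matrix(Mk, weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = gamma)
  memb <- igraph::membership(cl)
  membership <- rep(NA_integer_, nrow(M) + ncol(M))
  names(membership) <- c(rownames(M), colnames(M))
  membership[names(memb)] <- as.integer(memb)
  q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight,
                          resolution = gamma)
  structure(
    list(membership = membership, injections = rownames(M), grids = colnames(M),
         gamma = gamma, modularity = q, seed = as.integer(seed)),
    class = "domain_partition"
  )
}

#' @export
print.domain_partition <- function(x, ...) {
  k <- length(unique(stats::na.omit(x$membership)))
  cat("<domain_partition> ", k, " communities, gamma ", x$gamma,
      ", modularity ", sprintf("%.4f", x$modularity), ", seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Reorder a connectivity matrix by community
#'
#' Permutes rows and columns so that members of the same community are
#' contiguous (communities in ascending id order, names alphabetical within
#' a community, unassigned columns last); values are unchanged, placing the
#' detected domains along the matrix diagonal.
#'
#' @param matrix a `connectivity_grid_matrix`.
#' @param partition a [detect_domains()] partition covering the matrix.
#' @return a `connectivity_grid_matrix` with permuted rows and columns.
#' @export
reorder_matrix <- function(matrix, partition) {
  M <- if (inherits(matrix, "connectivity_grid_matrix")) matrix$values else as.matrix(matrix)
  if (!all(rownames(M) %in% names(partition$membership)) ||
      !all(colnames(M) %in% names(partition$membership))) {
    .fail("partition does not cover the matrix")
  }
  ro <- order(partition$membership[rownames(M)], rownames(M), na.last = TRUE)
  co <- order(partition$membership[colnames(M)], colnames(M), na.last = TRUE)
  out <- M[ro, co, drop = FALSE]
  if (inherits(matrix, "connectivity_grid_matrix")) {
    structure(list(values = out, grid = matrix$grid,
                   zero_columns = matrix$zero_columns),
              class = "connectivity_grid_matrix")
  } else {
    out
  }
}

#' Render a partition as a per-grid domain map
#'
#' @param partition a [detect_domains()] partition.
#' @param spec a [grid_spec()] (carried through for geometry; unused for
#'   the label table itself).
#' @return data.frame with columns `grid`, `row`, `col`, `community`
#'   (integer id; `NA` for unassigned cells), one row per grid cell,
#'   ordered row-major. Community ids form a deterministic palette index.
#' @export
render_domain_map <- function(partition, spec = grid_spec()) {
  g <- partition$grids
  data.frame(
    grid = g,
    row = as.integer(sub("^r(\\d+)c\\d+$", "\\1", g)),
    col = as.integer(sub("^r\\d+c(\\d+)$", "\\1", g)),
    community = as.integer(partition$membership[g]),
    stringsAsFactors = FALSE
  )
}
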
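# SWC reconstruction I/O, validation, and arc-length resampling into the
# ~1 um compartment representation that all morphometric and tropism
# statistics consume.
#
# A reconstruction is a rooted tree of typed 3D nodes (standard SWC type
# codes: 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite; other codes
# are preserved untouched). Coordinates and radii are micrometres.

#' SWC type codes treated as dendrite
#'
#' Basal (3) and apical (4) dendrites. All morphometric and tropism
#' statistics restrict to these codes by default; axons are excluded.
#' @export
DENDRITE_TYPES <- c(3L, 4L)

#' Construct a neuron reconstruction from a node table
#'
#' Validates the SWC invariants (unique ids, parents precede children or are
#' -1, single connected tree, at least one soma node) and normalizes node
#' order topologically. The soma position is the centroid of the soma-typed
#' nodes (a single root soma in the common case).
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (the standard seven SWC columns).
#' @param label neuron identifier.
#' @param nucleus optional nucleus tag (e.g. "AD", "AV", "AMd", "AMv").
#' @param domain optional connectional-domain tag.
#' @param line_numbers optional integer vector mapping node rows to source
#'   file lines, used to make parse errors name the offending line.
#' @return object of class `neuron_reconstruction`: a list with elements
#'   `nodes` (the validated, topologically ordered node table),
#'   `soma_position` (length-3 numeric, um), `label`, `nucleus`, `domain`.
#' @export
neuron_reconstruction <- function(nodes, label = "neuron", nucleus = NA_character_,
                                  domain = NA_character_, line_numbers = NULL) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes))) {
    .fail("nodes must be a data.frame with columns ", paste(required, collapse = ", "))
  }
  nodes <- nodes[, required]
  if (nrow(nodes) == 0L) .fail("reconstruction has no nodes")
  if (is.null(line_numbers)) line_numbers <- seq_len(nrow(nodes))
  loc <- function(i) paste0("line ", line_numbers[i])

  dup <- which(duplicated(nodes$id))
  if (length(dup)) .fail("duplicate node id ", nodes$id[dup[1]], " at ", loc(dup[1]))
  if (any(bad <- nodes$radius < 0)) {
    .fail("negative radius at ", loc(which(bad)[1]))
  }

  idx <- match(nodes$parent, nodes$id)            # NA for roots / dangling
  is_root <- nodes$parent == -1L
  dangling <- which(!is_root & is.na(idx))
  if (length(dangling)) {
    .fail("parent id ", nodes$parent[dangling[1]], " not found (node ",
          nodes$id[dangling[1]], " at ", loc(dangling[1]), ")")
  }
  if (sum(is_root) == 0L) .fail("no root node (parent -1) found")
  if (sum(is_root) > 1L) {
    .fail("multiple roots: reconstruction must be a single connected tree (second root at ",
          loc(which(is_root)[2]), ")")
  }
  if (any(self <- which(nodes$parent == nodes$id))) {
    .fail("node ", nodes$id[self[1]], " is its own parent at ", loc(self[1]))
  }

  ## Topological order by BFS from the root; unreached nodes imply a cycle
  ## (or a disconnected component, impossible here given a single root).
  n <- nrow(nodes)
  children <- split(seq_len(n), factor(idx, levels = seq_len(n)))
  order_out <- integer(n)
  head <- 1L; tail <- 1L
  order_out[1L] <- which(is_root)
  while (head <= tail) {
    kids <- children[[order_out[head]]]
    if (length(kids)) {
      order_out[(tail + 1L):(tail + length(kids))] <- kids
      tail <- tail + length(kids)
    }
    head <- head + 1L
  }
  if (tail < n) {
    off <- setdiff(seq_len(n), order_out[seq_len(tail)])[1]
    .fail("cycle detected involving node ", nodes$id[off], " at ", loc(off))
  }
  nodes <- nodes[order_out, , drop = FALSE]
  rownames(nodes) <- NULL

  soma_rows <- nodes$type == 1L
  if (!any(soma_rows)) .fail("no soma node (type 1) in reconstruction")
  soma_position <- c(
    mean(nodes$x[soma_rows]), mean(nodes$y[soma_rows]), mean(nodes$z[soma_rows])
  )

  structure(
    list(nodes = nodes, soma_position = soma_position, label = label,
         nucleus = nucleus, domain = domain),
    class = "neuron_reconstruction"
  )
}

#' @export
print.neuron_reconstruction <- function(x, ...) {
  cat("<neuron_reconstruction> ", x$label,
      if (!is.na(x$nucleus)) paste0(" [", x$nucleus,
        if (!is.na(x$domain)) paste0("/", x$domain), "]"), "\n", sep = "")
  cat("  nodes: ", nrow(x$nodes),
      " (dendritic: ", sum(x$nodes$type %in% DENDRITE_TYPES), ")\n", sep = "")
  cat("  soma: (", paste(sprintf("%.1f", x$soma_position), collapse = ", "),
      ") um\n", sep = "")
  invisible(x)
}

#' Read an SWC reconstruction file
#'
#' Parses standard whitespace-delimited seven-column SWC. `#`-prefixed
#' header lines are treated as comments; `# key = value` headers set the
#' reconstruction metadata fields `label`, `nucleus`, and `domain`.
#' Malformed records and structural defects (duplicate ids, dangling
#' parents, cycles, missing soma) raise errors that name the offending line.
#'
#' @param path path to an SWC file; coordinates are interpreted as um.
#' @param label neuron label; defaults to a `label` header if present, else
#'   the file name without extension.
#' @return a [neuron_reconstruction()].
#' @seealso [write_swc()], [resample_compartments()]
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) .fail("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(lines)
  is_comment <- startsWith(stripped, "#")
  is_blank <- stripped == ""

  meta <- list()
  for (h in stripped[is_comment]) {
    body <- trimws(sub("^#+", "", h))
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      if (nzchar(key)) meta[[tolower(key)]] <- val
    }
  }

  data_idx <- which(!is_comment & !is_blank)
  if (!length(data_idx)) .fail("no data records in SWC file: ", path)
  fields <- strsplit(stripped[data_idx], "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- data_idx[which(nf != 7L)[1]]
    .fail("expected 7 columns at line ", bad, " of ", path)
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  if (any(is.na(m))) {
    bad <- data_idx[which(rowSums(is.na(m)) > 0)[1]]
    .fail("non-numeric field at line ", bad, " of ", path)
  }
  nodes <- data.frame(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  label <- meta$label %||% sub("\\.[sS][wW][cC]$", "", basename(path))
  neuron_reconstruction(
    nodes, label = label,
    nucleus = meta$nucleus %||% NA_character_,
    domain = meta$domain %||% NA_character_,
    line_numbers = data_idx
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reconstruction to an SWC file
#'
#' Emits standard seven-column SWC preceded by `# key = value` header lines
#' recording the label, nucleus, and domain metadata, so that
#' `read_swc(write_swc(n, f))` is the identity on node records and metadata.
#'
#' @param neuron a [neuron_reconstruction()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(neuron, path) {
  stopifnot(inherits(neuron, "neuron_reconstruction"))
  if (nrow(neuron$nodes) == 0L) .fail("refusing to write a neuron with no nodes")
  hdr <- c(
    paste0("# label = ", neuron$label),
    if (!is.na(neuron$nucleus)) paste0("# nucleus = ", neuron$nucleus),
    if (!is.na(neuron$domain)) paste0("# domain = ", neuron$domain),
    "# columns: id type x y z radius parent"
  )
  rec <- sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                 neuron$nodes$id, neuron$nodes$type,
                 neuron$nodes$x, neuron$nodes$y, neuron$nodes$z,
                 neuron$nodes$radius, neuron$nodes$parent)
  tryCatch(
    suppressWarnings(writeLines(c(hdr, rec), path)),
    error = function(e) .fail("cannot write SWC to ", path, ": ",
                              conditionMessage(e))
  )
  invisible(path)
}

## --- internal tree decomposition ------------------------------------------

## Decompose the dendritic part of a reconstruction into unbranched paths.
## A path runs from its attachment point (soma or a bifurcation node) to the
## next bifurcation or tip; a "bifurcation" is any dendritic node with >= 2
## dendritic children. Stems leaving the soma have branch order 1; order
## increments by one at every bifurcation (a trifurcation increments once).
## Returns a list of paths: list(coords = m x 3 matrix including the
## attachment point, node_idx, order, type).
.dendritic_paths <- function(neuron, types = DENDRITE_TYPES) {
  nodes <- neuron$nodes
  n <- nrow(nodes)
  pidx <- match(nodes$parent, nodes$id)
  is_dend <- nodes$type %in% types

  kids <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(pidx[i]) && is_dend[i]) {
      kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)   # dendritic children only
    }
  }
  n_dkids <- lengths(kids)

  ## Stems: dendritic nodes whose parent is non-dendritic (usually soma).
  stem_starts <- which(is_dend & !is.na(pidx) & !is_dend[pidx])
  ## A dendritic node with parent -1 would be a dendrite-rooted tree; treat
  ## its first node as its own attachment point.
  rootless <- which(is_dend & is.na(pidx))

  coords <- as.matrix(nodes[, c("x", "y", "z")])
  paths <- list()
  walk <- function(start, attach, order) {
    node_seq <- start
    cur <- start
    while (n_dkids[cur] == 1L) {
      cur <- kids[[cur]][1]
      node_seq <- c(node_seq, cur)
    }
    pts <- coords[c(attach, node_seq), , drop = FALSE]
    paths[[length(paths) + 1L]] <<- list(
      coords = pts, node_idx = node_seq, order = order,
      type = nodes$type[start], end_node = cur,
      is_tip = n_dkids[cur] == 0L
    )
    if (n_dkids[cur] >= 2L) {
      for (k in kids[[cur]]) walk(k, cur, order + 1L)
    }
  }
  for (s in stem_starts) walk(s, pidx[s], 1L)
  for (s in rootless) walk(s, s, 1L)
  paths
}

#' Resample a reconstruction into ~fixed-length compartments
#'
#' Each unbranched dendritic path is arc-length interpolated into
#' consecutive directed compartments of length `step_um`, the final
#' compartment of each path carrying the positive remainder (<= `step_um`),
#' so branch points and tips are preserved exactly and total length is
#' conserved. A path of length L yields `ceiling(L / step_um)` compartments.
#'
#' @param neuron a [neuron_reconstruction()].
#' @param step_um target compartment (internode) length in um; default 1.
#' @param types SWC type codes to include; default dendrites (3, 4).
#' @return object of class `compartment_series`: a list with
#'   `compartments` (data.frame: `x0,y0,z0` origin, `x1,y1,z1` endpoint,
#'   `length` um, `type`, `branch_order`, `path`), `neuron_label`,
#'   `step_um`, and `soma_position`.
#' @export
resample_compartments <- function(neuron, step_um = 1, types = DENDRITE_TYPES) {
  stopifnot(inherits(neuron, "neuron_reconstruction"))
  if (!is.numeric(step_um) || length(step_um) != 1L || step_um <= 0) {
    .fail("step_um must be a single positive number")
  }
  paths <- .dendritic_paths(neuron, types)
  if (!length(paths)) .fail("neuron '", neuron$label, "' has no compartments of types ",
                            paste(types, collapse = ","))
  out <- vector("list", length(paths))
  for (p in seq_along(paths)) {
    pts <- paths[[p]]$coords
    seg <- diff(pts)
    seglen <- .rownorms(seg)
    keep <- seglen > 1e-12           # drop zero-length records (duplicated points)
    if (!any(keep)) next
    pts <- pts[c(TRUE, keep), , drop = FALSE]
    cum <- c(0, cumsum(seglen[keep]))
    L <- cum[length(cum)]
    brk <- seq(0, L, by = step_um)
    ## sub-1e-6-um remainders are coordinate-precision noise, not geometry:
    ## snap onto the last breakpoint instead of emitting a degenerate
    ## compartment
    if (L - brk[length(brk)] > 1e-6) brk <- c(brk, L) else brk[length(brk)] <- L
    ## Interpolate each coordinate along arc length; breakpoints hit the
    ## original vertices only approximately, but path endpoints are exact.
    xi <- stats::approx(cum, pts[, 1], xout = brk)$y
    yi <- stats::approx(cum, pts[, 2], xout = brk)$y
    zi <- stats::approx(cum, pts[, 3], xout = brk)$y
    m <- length(brk) - 1L
    out[[p]] <- data.frame(
      x0 = xi[-length(xi)], y0 = yi[-length(yi)], z0 = zi[-length(zi)],
      x1 = xi[-1], y1 = yi[-1], z1 = zi[-1],
      length = diff(brk),
      type = paths[[p]]$type,
      branch_order = paths[[p]]$order,
      path = p
    )
  }
  comp <- do.call(rbind, out)
  structure(
    list(compartments = comp, neuron_label = neuron$label,
         step_um = step_um, soma_position = neuron$soma_position),
    class = "compartment_series"
  )
}

#' @export
print.compartment_series <- function(x, ...) {
  cat("<compartment_series> ", x$neuron_label, ": ",
      nrow(x$compartments), " compartments, step ", x$step_um, " um, total ",
      sprintf("%.1f", sum(x$compartments$length)), " um\n", sep = "")
  invisible(x)
}
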
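# Per-neuron dendritic morphometrics: total wiring, branch complexity,
# arbor extent, path distance, branch order, partition asymmetry, and
# Sholl intersection profiles.

## Dendritic edges of a reconstruction as a list: origin matrix `a`,
## endpoint matrix `b` (edge belongs to the child node's type).
.dendritic_edges <- function(neuron, types = DENDRITE_TYPES) {
  nodes <- neuron$nodes
  pidx <- match(nodes$parent, nodes$id)
  child <- which(nodes$type %in% types & !is.na(pidx))
  list(
    a = as.matrix(nodes[pidx[child], c("x", "y", "z"), drop = FALSE]),
    b = as.matrix(nodes[child, c("x", "y", "z"), drop = FALSE])
  )
}

#' Total dendritic length
#'
#' Sum of Euclidean inter-node distances over dendritic edges (an edge is
#' dendritic when its child node is), in um.
#'
#' @param neuron a [neuron_reconstruction()].
#' @param types SWC type codes counted as dendrite.
#' @return total length in um.
#' @export
total_length <- function(neuron, types = DENDRITE_TYPES) {
  e <- .dendritic_edges(neuron, types)
  if (nrow(e$a) == 0L) .fail("neuron '", neuron$label, "' has no dendritic nodes")
  sum(.rownorms(e$b - e$a))
}

#' Number of dendritic branches
#'
#' Counts unbranched dendritic segments delimited by the soma, bifurcation
#' points, and tips (a Y-shaped arbor has 3 branches).
#'
#' @inheritParams total_length
#' @return integer branch count.
#' @export
branch_count <- function(neuron, types = DENDRITE_TYPES) {
  length(.dendritic_paths(neuron, types))
}

#' Arbor height (dorsoventral extent)
#'
#' Extent of the dendritic arbor along one axis, `max - min` over the
#' dendritic nodes plus the soma they attach to (so a single 50 um vertical
#' dendrite has height 50). The default axis is y, which in the adopted
#' image convention increases from dorsal to ventral; unlike the other
#' features it is not rotation invariant.
#'
#' @inheritParams total_length
#' @param axis one of "x", "y", "z".
#' @return extent in um.
#' @export
arbor_height <- function(neuron, axis = "y", types = DENDRITE_TYPES) {
  axis <- match.arg(axis, c("x", "y", "z"))
  v <- neuron$nodes[neuron$nodes$type %in% c(1L, types), axis]
  if (!length(v)) return(0)
  max(v) - min(v)
}

#' Maximum dendritic path distance
#'
#' The along-the-tree distance from the soma to the farthest dendritic tip:
#' the maximum over tips of summed edge lengths on the soma-to-tip path.
#'
#' @inheritParams total_length
#' @return path distance in um.
#' @export
max_path_distance <- function(neuron, types = DENDRITE_TYPES) {
  paths <- .dendritic_paths(neuron, types)
  if (!length(paths)) return(0)
  ## accumulate path lengths down the decomposition; paths are emitted
  ## parent-before-child with attachment nodes shared, so walk by end_node.
  plen <- vapply(paths, function(p) sum(.rownorms(diff(p$coords))), numeric(1))
  start_node <- vapply(paths, function(p) p$node_idx[1], integer(1))
  end_node <- vapply(paths, function(p) p$end_node, integer(1))
  ## distance from soma to each path end
  dist_to_end <- numeric(length(paths))
  ## map: which path ends at the attachment of path i? Stems attach to soma.
  nodes <- neuron$nodes
  pidx <- match(nodes$parent, nodes$id)
  for (i in seq_along(paths)) {
    attach <- pidx[start_node[i]]
    up <- if (!is.na(attach)) match(attach, end_node) else NA_integer_
    base <- if (!is.na(up)) dist_to_end[up] else 0
    dist_to_end[i] <- base + plen[i]
  }
  tips <- vapply(paths, function(p) p$is_tip, logical(1))
  max(dist_to_end[tips])
}

#' Average branch order
#'
#' The branch order of every ~1 um resampled dendritic compartment (stems
#' leaving the soma have order 1; +1 at each bifurcation) averaged over all
#' compartments. Because compartments are near-equal length this
#' approximates the length-weighted mean order.
#'
#' @inheritParams total_length
#' @param step_um resampling step, um.
#' @return dimensionless mean order >= 1.
#' @export
average_branch_order <- function(neuron, step_um = 1, types = DENDRITE_TYPES) {
  series <- resample_compartments(neuron, step_um = step_um, types = types)
  mean(series$compartments$branch_order)
}

#' Partition asymmetry
#'
#' Mean over dendritic bifurcations of |n1 - n2| / (n1 + n2 - 2), where n1
#' and n2 are the numbers of tips in the two daughter subtrees; terminal
#' bifurcations (n1 = n2 = 1) contribute 0. Trifurcations are decomposed
#' into stacked binary splits. Returns `NA` for arbors with no bifurcation.
#'
#' @inheritParams total_length
#' @return value in \[0, 1\], or `NA_real_` if there is no bifurcation.
#' @export
partition_asymmetry <- function(neuron, types = DENDRITE_TYPES) {
  nodes <- neuron$nodes
  n <- nrow(nodes)
  pidx <- match(nodes$parent, nodes$id)
  is_dend <- nodes$type %in% types
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(pidx[i]) && is_dend[i]) kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)
  }
  n_dkids <- lengths(kids)
  ## tips below each dendritic node (child-before-parent accumulation works
  ## because nodes are topologically ordered: traverse in reverse)
  tips_below <- integer(n)
  for (i in rev(seq_len(n))) {
    if (!is_dend[i]) next
    tips_below[i] <- if (n_dkids[i] == 0L) 1L else sum(tips_below[kids[[i]]])
  }
  vals <- numeric(0)
  for (i in seq_len(n)) {
    if (!is_dend[i] || n_dkids[i] < 2L) next   # soma excluded (not dendritic)
    t <- tips_below[kids[[i]]]
    ## decompose k-furcations into stacked binary splits
    while (length(t) >= 2L) {
      n1 <- t[1]; n2 <- sum(t[-1])
      vals <- c(vals, if (n1 + n2 > 2L) abs(n1 - n2) / (n1 + n2 - 2) else 0)
      t <- t[-1]
    }
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Sholl intersection profile
#'
#' Counts intersections of dendritic edges with concentric spheres centered
#' on the soma, at radii `shell_um, 2*shell_um, ...` up to the maximal
#' Euclidean node distance from the soma. Each geometric intersection of a
#' straight edge with a sphere counts once (solutions of the segment-sphere
#' quadratic in the half-open parameter interval (0, 1], so an edge vertex
#' sitting on a sphere is counted once, not twice).
#'
#' @inheritParams total_length
#' @param shell_um shell spacing in um (default 50, the spacing used for
#'   thalamic arbors here).
#' @return data.frame with columns `radius` (um) and `crossings`; zero rows
#'   if the arbor lies entirely within the first shell.
#' @export
sholl_profile <- function(neuron, shell_um = 50, types = DENDRITE_TYPES) {
  if (shell_um <= 0) .fail("shell_um must be positive")
  e <- .dendritic_edges(neuron, types)
  soma <- neuron$soma_position
  if (nrow(e$a) == 0L) return(data.frame(radius = numeric(0), crossings = integer(0)))
  da <- .rownorms(sweep(e$a, 2, soma))
  db <- .rownorms(sweep(e$b, 2, soma))
  rmax <- max(da, db)
  if (rmax < shell_um) {
    return(data.frame(radius = numeric(0), crossings = integer(0)))
  }
  radii <- seq(shell_um, rmax, by = shell_um)
  ## segment-sphere intersection: |a + t (b-a) - soma|^2 = r^2, t in (0, 1]
  d <- e$b - e$a
  f <- sweep(e$a, 2, soma)
  A <- rowSums(d * d)
  B <- 2 * rowSums(f * d)
  C0 <- rowSums(f * f)
  crossings <- vapply(radii, function(r) {
    C <- C0 - r * r
    disc <- B * B - 4 * A * C
    cnt <- 0L
    ok <- which(disc >= 0 & A > 0)
    if (length(ok)) {
      sq <- sqrt(disc[ok])
      t1 <- (-B[ok] - sq) / (2 * A[ok])
      t2 <- (-B[ok] + sq) / (2 * A[ok])
      eps <- 1e-12
      cnt <- sum(t1 > eps & t1 <= 1 + eps) + sum(disc[ok] > eps & t2 > eps & t2 <= 1 + eps)
    }
    as.integer(cnt)
  }, integer(1))
  data.frame(radius = radii, crossings = crossings)
}

#' Full morphometric profile for one neuron
#'
#' Convenience wrapper computing all scalar features; Sholl profiles are
#' returned by [sholl_profile()] in long format separately.
#'
#' @inheritParams total_length
#' @param shell_um Sholl shell spacing, um.
#' @return one-row data.frame: `neuron_label`, `nucleus`, `domain`,
#'   `total_length`, `branch_count`, `height`, `max_path_distance`,
#'   `average_branch_order`, `partition_asymmetry`.
#' @export
morphometric_profile <- function(neuron, shell_um = 50, types = DENDRITE_TYPES) {
  data.frame(
    neuron_label = neuron$label,
    nucleus = neuron$nucleus,
    domain = neuron$domain,
    total_length = total_length(neuron, types),
    branch_count = branch_count(neuron, types),
    height = arbor_height(neuron, types = types),
    max_path_distance = max_path_distance(neuron, types),
    average_branch_order = average_branch_order(neuron, types = types),
    partition_asymmetry = partition_asymmetry(neuron, types),
    stringsAsFactors = FALSE
  )
}
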
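# Center-tropism statistics: angular deviation of dendritic compartments
# from the local center vector, the proportion of wiring closer to the
# nucleus center than the soma, edge/non-edge classification of somas, and
# the soma-distance vs deviation correlation.
#
# The "local core vector" of a compartment is the straight line from the
# compartment's origin point to the nucleus center; a deviation < pi/2
# means the compartment's endpoint is nearer the center than its origin.

#' Nucleus geometry for tropism and edge classification
#'
#' The center defaults to the centroid of the boundary polygon when one is
#' supplied. The boundary is a closed polygon in the section (x, y) plane;
#' alternatively a circular-nucleus `radius_um` may be given.
#'
#' @param center length-3 numeric (um), or `NULL` to use the boundary
#'   centroid.
#' @param boundary optional n x 2 matrix of polygon vertices (x, y) in um.
#' @param radius_um optional circular-boundary radius (um), used when no
#'   polygon is given.
#' @param edge_threshold edge band width: a fraction of the local
#'   center-to-boundary distance when <= 1 (default 0.2), otherwise an
#'   absolute distance in um.
#' @return object of class `nucleus_geometry`.
#' @export
nucleus_geometry <- function(center = NULL, boundary = NULL, radius_um = NULL,
                             edge_threshold = 0.2) {
  if (!is.null(boundary)) {
    boundary <- as.matrix(boundary)
    if (ncol(boundary) != 2L || nrow(boundary) < 3L) {
      .fail("boundary must be an n x 2 matrix with n >= 3")
    }
    ## drop an explicit closing vertex
    if (all(abs(boundary[1, ] - boundary[nrow(boundary), ]) < 1e-9)) {
      boundary <- boundary[-nrow(boundary), , drop = FALSE]
    }
  }
  if (is.null(center)) {
    if (is.null(boundary)) .fail("either center or boundary must be supplied")
    center <- c(colMeans(boundary), 0)
  }
  center <- as.numeric(center)
  if (length(center) == 2L) center <- c(center, 0)
  if (length(center) != 3L || any(!is.finite(center))) {
    .fail("center must be a finite 2- or 3-vector")
  }
  if (!is.null(boundary) && !.point_in_polygon(center[1:2], boundary)) {
    .fail("center must lie inside the boundary polygon")
  }
  if (edge_threshold <= 0) .fail("edge_threshold must be positive")
  structure(
    list(center = center, boundary = boundary, radius_um = radius_um,
         edge_threshold = edge_threshold),
    class = "nucleus_geometry"
  )
}

## even-odd point-in-polygon test (2D)
.point_in_polygon <- function(p, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((poly[i, 2] > p[2]) != (poly[j, 2] > p[2])) &&
        (p[1] < (poly[j, 1] - poly[i, 1]) * (p[2] - poly[i, 2]) /
           (poly[j, 2] - poly[i, 2]) + poly[i, 1])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

## distance from center to boundary along the ray through point q (2D);
## NA when the ray never meets the polygon (should not happen for a center
## inside a closed polygon).
.local_radius <- function(geometry, q) {
  c2 <- geometry$center[1:2]
  if (!is.null(geometry$boundary)) {
    u <- q[1:2] - c2
    nu <- sqrt(sum(u * u))
    if (nu < 1e-12) {
      ## soma at the center: use the minimal center-to-vertex distance
      return(min(sqrt(rowSums(sweep(geometry$boundary, 2, c2)^2))))
    }
    u <- u / nu
    poly <- geometry$boundary
    n <- nrow(poly)
    best <- Inf
    for (i in seq_len(n)) {
      a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
      e <- b - a
      den <- u[1] * (-e[2]) - u[2] * (-e[1])
      if (abs(den) < 1e-14) next
      rhs <- a - c2
      t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
      s <- (u[1] * rhs[2] - u[2] * rhs[1]) / den
      if (t > 0 && s >= -1e-12 && s <= 1 + 1e-12) best <- min(best, t)
    }
    if (!is.finite(best)) return(NA_real_)
    best
  } else if (!is.null(geometry$radius_um)) {
    geometry$radius_um
  } else {
    .fail("geometry needs a boundary polygon or radius_um for edge classification")
  }
}

#' Angular deviation of compartments from the center vector
#'
#' For each compartment, the angle in \[0, pi\] between the compartment
#' vector (origin to endpoint) and its local core vector (origin to the
#' nucleus center). Compartments whose origin coincides with the center are
#' flagged `NA` and excluded from averages.
#'
#' @param series a `compartment_series` (see [resample_compartments()]), or
#'   a data.frame with columns `x0,y0,z0,x1,y1,z1`.
#' @param center length-3 numeric, um.
#' @param planar if `TRUE`, measure angles in the section (x, y) plane only.
#' @return numeric vector of angles in radians, one per compartment.
#' @export
compartment_deviation <- function(series, center, planar = FALSE) {
  comp <- if (inherits(series, "compartment_series")) series$compartments else series
  o <- as.matrix(comp[, c("x0", "y0", "z0")])
  e <- as.matrix(comp[, c("x1", "y1", "z1")])
  center <- as.numeric(center)
  v <- e - o                              # compartment vector
  w <- sweep(-o, 2, -center)              # origin -> center
  if (planar) { v[, 3] <- 0; w[, 3] <- 0 }
  nv <- .rownorms(v); nw <- .rownorms(w)
  ang <- rep(NA_real_, nrow(comp))
  ok <- nv > 1e-12 & nw > 1e-12
  cosang <- rowSums(v[ok, , drop = FALSE] * w[ok, , drop = FALSE]) / (nv[ok] * nw[ok])
  ang[ok] <- acos(pmin(1, pmax(-1, cosang)))
  ang
}

#' Average angular deviation of a neuron from the nucleus center
#'
#' The per-compartment deviations averaged across all dendritic
#' compartments (unweighted by default; compartments are ~1 um so this
#' approximates length weighting, which is also available).
#'
#' @inheritParams compartment_deviation
#' @param weighted if `TRUE`, weight compartments by length.
#' @return mean deviation in radians, in \[0, pi\].
#' @export
average_angular_deviation <- function(series, center, weighted = FALSE,
                                      planar = FALSE) {
  comp <- if (inherits(series, "compartment_series")) series$compartments else series
  ang <- compartment_deviation(comp, center, planar = planar)
  ok <- !is.na(ang)
  if (!any(ok)) .fail("all compartments excluded (origins at the center?)")
  if (weighted) {
    sum(ang[ok] * comp$length[ok]) / sum(comp$length[ok])
  } else {
    mean(ang[ok])
  }
}

#' Proportion of dendritic wiring closer to the center than the soma
#'
#' Length-weighted fraction of compartments whose midpoint lies nearer the
#' nucleus center than the soma does.
#'
#' @inheritParams compartment_deviation
#' @param soma length-3 numeric soma position, um.
#' @return fraction in \[0, 1\].
#' @export
proportion_closer_than_soma <- function(series, soma, center) {
  comp <- if (inherits(series, "compartment_series")) series$compartments else series
  if (!nrow(comp)) .fail("empty compartment series")
  mid <- (as.matrix(comp[, c("x0", "y0", "z0")]) +
          as.matrix(comp[, c("x1", "y1", "z1")])) / 2
  dmid <- .rownorms(sweep(mid, 2, as.numeric(center)))
  dsoma <- .norm3(as.numeric(soma) - as.numeric(center))
  tot <- sum(comp$length)
  if (tot <= 0) .fail("total compartment length is zero")
  sum(comp$length[dmid < dsoma]) / tot
}

#' Classify a soma as edge or non-edge
#'
#' A neuron is "edge" when its soma lies within the edge band of the
#' nucleus boundary: distance(soma, boundary) <= threshold, where the
#' threshold defaults to 20% of the local center-to-boundary distance along
#' the center-to-soma ray. Somas outside the boundary are classified edge
#' with a warning. Classification uses the section (x, y) plane.
#'
#' @param soma length-3 (or 2) numeric soma position, um.
#' @param geometry a [nucleus_geometry()].
#' @return `"edge"` or `"non-edge"`.
#' @export
classify_edge <- function(soma, geometry) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  soma <- as.numeric(soma)
  R <- .local_radius(geometry, soma)
  if (is.na(R)) .fail("could not determine local radius for soma")
  d <- sqrt(sum((soma[1:2] - geometry$center[1:2])^2))
  if (d > R + 1e-9) {
    warning("soma lies outside the nucleus boundary; classifying as edge")
    return("edge")
  }
  thr <- geometry$edge_threshold
  band <- if (thr <= 1) thr * R else thr
  if (R - d <= band) "edge" else "non-edge"
}

#' Tropism profile for one neuron
#'
#' @param neuron a [neuron_reconstruction()].
#' @param geometry a [nucleus_geometry()].
#' @param step_um resampling step, um.
#' @param weighted,planar passed to [average_angular_deviation()].
#' @return one-row data.frame: `neuron_label`, `soma_center_distance` (um),
#'   `average_angular_deviation` (rad), `deviation_deg`,
#'   `proportion_closer`, `edge_class`.
#' @export
tropism_profile <- function(neuron, geometry, step_um = 1, weighted = FALSE,
                            planar = FALSE) {
  series <- resample_compartments(neuron, step_um = step_um)
  dev <- average_angular_deviation(series, geometry$center, weighted = weighted,
                                   planar = planar)
  data.frame(
    neuron_label = neuron$label,
    soma_center_distance = .norm3(neuron$soma_position - geometry$center),
    average_angular_deviation = dev,
    deviation_deg = rad_to_deg(dev),
    proportion_closer = proportion_closer_than_soma(series, neuron$soma_position,
                                                    geometry$center),
    edge_class = classify_edge(neuron$soma_position, geometry),
    stringsAsFactors = FALSE
  )
}

#' Correlation between soma distance and average deviation
#'
#' Pearson correlation (with two-sided p) between each neuron's
#' soma-to-center distance and its average angular deviation, across a
#' cohort of tropism profiles. A negative r means neurons farther from the
#' center orient their dendrites more strongly toward it.
#'
#' @param profiles data.frame with columns `soma_center_distance` and
#'   `average_angular_deviation` (e.g. rbind of [tropism_profile()] rows).
#' @return a `stat_result` (see [pearson_correlation()]).
#' @export
deviation_vs_distance <- function(profiles) {
  if (nrow(profiles) < 3L) .fail("need at least 3 profiles")
  pearson_correlation(profiles$soma_center_distance,
                      profiles$average_angular_deviation)
}
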
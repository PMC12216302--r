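# Whole-brain projection-profile normalization and 2D hierarchical
# clustering.
#
# For each tracing case, an ROI's connectivity fraction f is its share of
# all labeled signal in that case (f = count / sum of all ROI counts), and
# its connectivity density d is the fraction per unit ROI area rescaled so
# the case maximum is 1 (d = (f / area) / max_j(f_j / area_j)).

#' Connectivity fraction
#'
#' @param roi_counts named non-negative numeric vector of per-ROI labeled
#'   pixel or cell counts for one case.
#' @return named vector of fractions summing to 1.
#' @export
connectivity_fraction <- function(roi_counts) {
  counts <- as.numeric(roi_counts)
  if (any(counts < 0)) .fail("ROI counts must be non-negative")
  s <- sum(counts)
  if (s <= 0) .fail("all ROI counts are zero")
  f <- counts / s
  names(f) <- names(roi_counts)
  f
}

#' Connectivity density
#'
#' @param fractions named fractions from [connectivity_fraction()].
#' @param roi_areas named positive areas in a common spatial unit; every
#'   ROI with a nonzero fraction must have a positive area.
#' @return named vector of densities with maximum exactly 1.
#' @export
connectivity_density <- function(fractions, roi_areas) {
  f <- as.numeric(fractions)
  a <- as.numeric(roi_areas[names(fractions)])
  if (any(is.na(a) & f > 0) || any(a[!is.na(a)] <= 0 & f[!is.na(a)] > 0)) {
    .fail("missing or non-positive area for an ROI with nonzero fraction")
  }
  raw <- ifelse(f > 0, f / a, 0)
  m <- max(raw)
  if (m <= 0) .fail("all densities are zero")
  d <- raw / m
  names(d) <- names(fractions)
  d
}

#' Per-case projection table
#'
#' Computes and stores fractions and densities for one case. ROIs with zero
#' area and zero count are dropped with a warning.
#'
#' @param roi_counts named counts; @param roi_areas named areas;
#' @param case_id case identifier.
#' @return object of class `case_projection_table`: list with `case_id`,
#'   `roi_counts`, `roi_areas`, `fractions`, `densities`.
#' @export
case_projection_table <- function(roi_counts, roi_areas, case_id = "case") {
  if (is.null(names(roi_counts)) || is.null(names(roi_areas))) {
    .fail("roi_counts and roi_areas must be named by ROI")
  }
  dead <- names(roi_counts)[roi_counts == 0 &
                              (is.na(roi_areas[names(roi_counts)]) |
                                 roi_areas[names(roi_counts)] == 0)]
  if (length(dead)) {
    warning("dropping ROIs with zero count and zero/missing area: ",
            paste(dead, collapse = ", "))
    roi_counts <- roi_counts[setdiff(names(roi_counts), dead)]
  }
  f <- connectivity_fraction(roi_counts)
  d <- connectivity_density(f, roi_areas)
  structure(list(case_id = case_id, roi_counts = roi_counts,
                 roi_areas = roi_areas[names(roi_counts)],
                 fractions = f, densities = d),
            class = "case_projection_table")
}

#' 2D hierarchical clustering of a cases x ROIs density table
#'
#' Rows (cases) and columns (ROIs) are clustered independently by
#' agglomerative linkage; the default is average linkage on correlation
#' distance (1 - Pearson r), with Euclidean/Ward available. Leaf ordering
#' is the deterministic `hclust` order. A constant matrix (zero distance
#' everywhere) falls back to the input ordering.
#'
#' @param density_table numeric matrix or data.frame, cases x ROIs.
#' @param linkage one of "average", "complete", "single", "ward.D2".
#' @param distance "correlation" or "euclidean".
#' @return list with `row_order`, `col_order` (integer permutations),
#'   `row_hclust`, `col_hclust` (`hclust` objects or `NULL` on fallback).
#' @export
hierarchical_cluster <- function(density_table, linkage = "average",
                                 distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage, c("average", "complete", "single", "ward.D2"))
  M <- as.matrix(density_table)
  if (nrow(M) < 2L || ncol(M) < 2L) .fail("need at least a 2 x 2 table")
  if (any(!is.finite(M))) .fail("density table must be finite")
  dfun <- function(X) {
    if (distance == "correlation") {
      ## rows with zero variance get correlation 0 with everything
      cc <- suppressWarnings(stats::cor(t(X)))
      cc[!is.finite(cc)] <- 0
      stats::as.dist(1 - cc)
    } else {
      stats::dist(X)
    }
  }
  side <- function(X) {
    d <- dfun(X)
    if (all(d < 1e-12)) return(list(order = seq_len(nrow(X)), hclust = NULL))
    h <- stats::hclust(d, method = linkage)
    list(order = h$order, hclust = h)
  }
  r <- side(M)
  cl <- side(t(M))
  list(row_order = r$order, col_order = cl$order,
       row_hclust = r$hclust, col_hclust = cl$hclust)
}
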
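# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive (enumeration, brute force, direct formula)
# and never call the code paths they check.

## Build a neuron from inline SWC text (rows "id type x y z r parent"),
## exercising the real parser.
swc_text_neuron <- function(text, ...) {
  f <- withr::local_tempfile(fileext = ".swc", .local_envir = parent.frame())
  writeLines(trimws(strsplit(text, "\n")[[1]]), f)
  read_swc(f)
}

## Straight dendrite of given length along +y in `step`-um segments.
straight_neuron <- function(length_um = 10, step = 1) {
  n <- ceiling(length_um / step)
  ys <- c(seq(step, by = step, length.out = n - 1), length_um)
  rows <- c("1 1 0 0 0 5 -1",
            sprintf("%d 3 0 %.6f 0 1 %d", seq_len(n) + 1L, ys, seq_len(n)))
  swc_text_neuron(paste(rows, collapse = "\n"))
}

## Y-shaped arbor: stem along +y of stem_um, daughters at +/-45 degrees of
## limb_um each.
y_neuron <- function(stem_um = 10, limb_um = 5) {
  h <- limb_um / sqrt(2)
  swc_text_neuron(sprintf(
    "1 1 0 0 0 5 -1
     2 3 0 %f 0 1 1
     3 3 %f %f 0 1 2
     4 3 %f %f 0 1 2",
    stem_um, h, stem_um + h, -h, stem_um + h))
}

## Perfect binary dendritic tree of given depth (depth 1 = single stem).
## Segments have unit length; geometry fans out in x with depth in y.
binary_tree_neuron <- function(depth = 3) {
  rows <- c("1 1 0 0 0 5 -1")
  nid <- 1L
  level <- data.frame(id = 1L, x = 0)
  for (d in seq_len(depth)) {
    nxt <- NULL
    for (i in seq_len(nrow(level))) {
      kids <- if (d == 1L) 1L else 2L   # one stem, then bifurcations
      for (k in seq_len(kids)) {
        nid <- nid + 1L
        x <- level$x[i] + (if (kids == 2L) (k - 1.5) * 2^(depth - d) else 0)
        rows <- c(rows, sprintf("%d 3 %f %d 0 1 %d", nid, x, d, level$id[i]))
        nxt <- rbind(nxt, data.frame(id = nid, x = x))
      }
    }
    level <- nxt
  }
  swc_text_neuron(paste(rows, collapse = "\n"))
}

## Adjusted Rand index, direct contingency-table formula.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (abs(denom) < 1e-12) return(1)
  (sij - expected) / denom
}

## All set partitions of 1..n as membership vectors (restricted-growth
## strings); B(8) = 4140, fine for exhaustive modularity search.
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, k) {
    i <- length(memb) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- memb; return(invisible()) }
    for (g in seq_len(k + 1L)) rec(c(memb, g), max(k, g))
  }
  rec(integer(0), 0L)
  out
}

## Exhaustive maximum modularity of a small igraph at resolution gamma.
exhaustive_modularity <- function(g, gamma) {
  n <- igraph::vcount(g)
  stopifnot(n <= 10)
  w <- igraph::E(g)$weight
  best <- -Inf
  for (memb in all_partitions(n)) {
    q <- igraph::modularity(g, memb, weights = w, resolution = gamma)
    if (q > best) best <- q
  }
  best
}

## Brute-force maximum root-to-tip path distance by exhaustive tip walk.
oracle_max_path <- function(neuron, types = c(3L, 4L)) {
  nodes <- neuron$nodes
  pidx <- match(nodes$parent, nodes$id)
  is_d <- nodes$type %in% types
  has_child <- seq_len(nrow(nodes)) %in% pidx[is_d]
  tips <- which(is_d & !has_child)
  best <- 0
  for (t in tips) {
    d <- 0; i <- t
    while (!is.na(pidx[i]) && is_d[i]) {
      j <- pidx[i]
      d <- d + sqrt(sum((nodes[i, c("x", "y", "z")] - nodes[j, c("x", "y", "z")])^2))
      i <- j
    }
    best <- max(best, d)
  }
  best
}

## Brute-force Sholl crossings: sign changes of (distance - r) across the
## endpoints of finely resampled compartments. The step must be well below
## the segment scale, or excursions across a shell shorter than one step
## are missed (0.1 um resolves every crossing the generators produce).
oracle_sholl <- function(neuron, shell_um = 50, step = 0.1) {
  s <- resample_compartments(neuron, step_um = step)$compartments
  soma <- neuron$soma_position
  d0 <- sqrt((s$x0 - soma[1])^2 + (s$y0 - soma[2])^2 + (s$z0 - soma[3])^2)
  d1 <- sqrt((s$x1 - soma[1])^2 + (s$y1 - soma[2])^2 + (s$z1 - soma[3])^2)
  rmax <- max(d0, d1)
  if (rmax < shell_um) {
    return(data.frame(radius = numeric(0), crossings = integer(0)))
  }
  radii <- seq(shell_um, rmax, by = shell_um)
  data.frame(radius = radii, crossings = vapply(radii, function(r) {
    sum((d0 - r) * (d1 - r) < 0 | (d1 == r & d0 != r))
  }, numeric(1)))
}

## Direct arccos deviation oracle for one compartment row.
oracle_deviation <- function(o, e, center) {
  v <- e - o
  w <- center - o
  acos(max(-1, min(1, sum(v * w) / sqrt(sum(v^2) * sum(w^2)))))
}
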
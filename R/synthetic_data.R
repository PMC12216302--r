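# Seeded synthetic generators for every input the pipeline consumes:
# stochastic neuron trees with controllable center-tropism, study-sized
# cohorts with edge/non-edge structure, the two-component morphological
# feature mixture, planted-domain injection x grid matrices, and per-case
# ROI count tables. Every generator is a pure function of (config, seed);
# generated objects always satisfy the validation contracts of the
# consuming modules.

## Draw one unit vector from a von-Mises-Fisher distribution on the sphere
## with mean direction mu and concentration kappa (kappa = 0 -> uniform).
.rvmf1 <- function(mu, kappa) {
  if (kappa < 1e-9) {
    v <- stats::rnorm(3)
    return(v / .norm3(v))
  }
  u <- stats::runif(1)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  ## orthonormal basis perpendicular to mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu
  e1 <- e1 / .norm3(e1)
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  phi <- stats::runif(1, 0, 2 * pi)
  w * mu + sqrt(max(0, 1 - w^2)) * (cos(phi) * e1 + sin(phi) * e2)
}

#' Configuration for the stochastic neuron generator
#'
#' @param soma_position,center length-3 numeric, um.
#' @param tropism_kappa concentration (>= 0) of segment directions around
#'   the local toward-center direction; 0 gives isotropic growth.
#' @param target_branches desired number of unbranched dendritic segments.
#' @param mean_segment_um mean inter-node segment length, um.
#' @param branch_prob per-step probability of an early bifurcation while
#'   the branch budget remains.
#' @param mean_path_steps mean number of segments per unbranched path.
#' @param parent_blend weight in \[0, 1) of the parent direction in the
#'   vMF mean (the remainder points at the center); smooths paths without
#'   affecting the kappa = 0 isotropy contract.
#' @param n_stems number of primary dendrites leaving the soma.
#' @param seed integer seed.
#' @return list of class `neuron_gen_config`.
#' @export
neuron_gen_config <- function(soma_position = c(150, 0, 0), center = c(0, 0, 0),
                              tropism_kappa = 0, target_branches = 30L,
                              mean_segment_um = 5, branch_prob = 0.1,
                              mean_path_steps = 8, parent_blend = 0.3,
                              n_stems = 2L, seed = 1L) {
  if (tropism_kappa < 0) .fail("tropism_kappa must be >= 0")
  if (target_branches < 1L) .fail("target_branches must be >= 1")
  if (mean_segment_um <= 0 || mean_path_steps < 1) .fail("invalid segment geometry")
  if (branch_prob < 0 || branch_prob > 1) .fail("branch_prob must be in [0, 1]")
  if (parent_blend < 0 || parent_blend >= 1) .fail("parent_blend must be in [0, 1)")
  structure(as.list(environment()), class = "neuron_gen_config")
}

#' Generate one synthetic neuron reconstruction
#'
#' Stochastic recursive tree growth from the soma: segments of
#' ~`mean_segment_um` whose directions are drawn from a von-Mises-Fisher
#' distribution with concentration `tropism_kappa` around a blend of the
#' parent direction and the local toward-center direction; unbranched paths
#' run a geometric number of steps and bifurcate (or, with `branch_prob`,
#' bifurcate early) until `target_branches` is reached. With kappa = 0
#' growth is directionally isotropic and the expected angular deviation
#' from the center is pi/2; increasing kappa strengthens center-tropism.
#' Reproducible: the output is a pure function of the config (including its
#' seed) and passes reconstruction validation.
#'
#' @param config a [neuron_gen_config()].
#' @param label neuron label.
#' @param nucleus,domain optional metadata tags.
#' @return a [neuron_reconstruction()].
#' @export
generate_neuron <- function(config, label = "syn", nucleus = "synthetic",
                            domain = NA_character_) {
  stopifnot(inherits(config, "neuron_gen_config"))
  set.seed(config$seed)
  soma <- as.numeric(config$soma_position)
  center <- as.numeric(config$center)
  kap <- config$tropism_kappa
  blend <- config$parent_blend

  ids <- 1L; types <- 1L
  xyz <- matrix(soma, nrow = 1)
  radius <- 6; parent <- -1L
  next_id <- 2L

  new_dir <- function(pos, prev) {
    cdir <- center - pos
    ncd <- .norm3(cdir)
    mu <- if (ncd < 1e-9) prev else {
      m <- blend * prev + (1 - blend) * cdir / ncd
      nm <- .norm3(m)
      if (nm < 1e-9) cdir / ncd else m / nm
    }
    .rvmf1(mu, kap)
  }

  branches <- 0L
  ## frontier entries: list(pos, dir, parent_id, steps_left)
  frontier <- list()
  spawn <- function(pos, dir, parent_id) {
    list(pos = pos, dir = dir, parent_id = parent_id,
         steps_left = 1L + stats::rpois(1, max(0, config$mean_path_steps - 1)))
  }
  for (s in seq_len(min(config$n_stems, config$target_branches))) {
    d0 <- .rvmf1(.unit(if (.norm3(center - soma) > 1e-9) center - soma else c(1, 0, 0)), kap)
    frontier[[length(frontier) + 1L]] <- spawn(soma, d0, 1L)
    branches <- branches + 1L
  }

  while (length(frontier)) {
    pick <- if (length(frontier) == 1L) 1L else sample.int(length(frontier), 1L)
    tip <- frontier[[pick]]
    frontier[[pick]] <- NULL
    repeat {
      seg <- config$mean_segment_um * stats::runif(1, 0.7, 1.3)
      dir <- new_dir(tip$pos, tip$dir)
      pos <- tip$pos + seg * dir
      ids <- c(ids, next_id); types <- c(types, 3L)
      xyz <- rbind(xyz, pos)
      radius <- c(radius, 0.5)
      parent <- c(parent, tip$parent_id)
      this_id <- next_id; next_id <- next_id + 1L
      tip$pos <- pos; tip$dir <- dir; tip$parent_id <- this_id
      tip$steps_left <- tip$steps_left - 1L
      want_branch <- branches + 2L <= config$target_branches + 1L &&
        (tip$steps_left <= 0L || stats::runif(1) < config$branch_prob)
      if (want_branch) {
        for (k in 1:2) {
          frontier[[length(frontier) + 1L]] <- spawn(pos, .rvmf1(dir, 4), this_id)
        }
        branches <- branches + 2L
        break
      }
      if (tip$steps_left <= 0L) break         # terminate this path
    }
  }

  nodes <- data.frame(id = ids, type = types, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], radius = radius, parent = parent)
  neuron_reconstruction(nodes, label = label, nucleus = nucleus, domain = domain)
}

#' Generate a study-sized cohort of synthetic neurons
#'
#' Two presets mirror the study's sample sizes:
#'
#' * `"amd-edge-study"`: 72 neurons in a circular nucleus of radius 250 um
#'   - 27 with somas in the edge band (>= 84% of the local radius) and 45
#'   non-edge - with tropism concentration increasing with soma distance
#'   (kappa = kappa_max (d/R)^2) and edge neurons given smaller branch
#'   budgets, emulating the reported edge phenotype.
#' * `"paper-cohort"`: 109 neurons - 10 AD, 17 AV, 82 AM; the 82 AM split
#'   into 72 AMd (domains: core 12, dorsal 12, dorsomedial 11, lateral 20,
#'   medial 17 - the `"amd-edge-study"` construction) and 10 AMv.
#'
#' @param preset `"amd-edge-study"` or `"paper-cohort"`.
#' @param seed integer seed.
#' @param kappa_max tropism concentration at the boundary (default 8).
#' @return list with `neurons` (list of reconstructions), `geometry`
#'   (the AMd [nucleus_geometry()]), and `metadata` (data.frame: label,
#'   nucleus, domain, edge_class, soma_distance, kappa).
#' @export
generate_cohort <- function(preset = c("amd-edge-study", "paper-cohort"),
                            seed = 1L, kappa_max = 8) {
  preset <- match.arg(preset)
  R <- 250
  theta <- seq(0, 2 * pi, length.out = 73L)[-73L]
  boundary <- cbind(R * cos(theta), R * sin(theta))
  geometry <- nucleus_geometry(center = c(0, 0, 0), boundary = boundary)

  make_group <- function(n, dist_range, nucleus, domains, size_mean, tag, base_seed) {
    set.seed(base_seed)
    dist <- stats::runif(n, dist_range[1], dist_range[2]) * R
    ang <- stats::runif(n, 0, 2 * pi)
    zoff <- stats::rnorm(n, 0, 5)
    nb <- pmax(8L, round(stats::rnorm(n, size_mean, size_mean / 6)))
    out <- vector("list", n)
    meta <- vector("list", n)
    for (i in seq_len(n)) {
      soma <- c(dist[i] * cos(ang[i]), dist[i] * sin(ang[i]), zoff[i])
      kap <- kappa_max * (dist[i] / R)^2
      cfg <- neuron_gen_config(
        soma_position = soma, center = c(0, 0, 0), tropism_kappa = kap,
        target_branches = nb[i], seed = .child_seed(base_seed, i)
      )
      lab <- sprintf("%s-%03d", tag, i)
      dom <- if (length(domains)) domains[i] else NA_character_
      out[[i]] <- generate_neuron(cfg, label = lab, nucleus = nucleus, domain = dom)
      meta[[i]] <- data.frame(label = lab, nucleus = nucleus, domain = dom,
                              soma_distance = dist[i], kappa = kap,
                              target_branches = nb[i], stringsAsFactors = FALSE)
    }
    list(neurons = out, meta = do.call(rbind, meta))
  }

  amd_domains <- c(rep("AMd.core", 12), rep("AMd.dorsal", 12),
                   rep("AMd.dorsomedial", 11), rep("AMd.lateral", 20),
                   rep("AMd.medial", 17))
  ## 27 edge (>= 0.84 R, inside the 20% edge band) + 45 non-edge (<= 0.72 R)
  edge <- make_group(27, c(0.84, 0.97), "AMd",
                     amd_domains[seq_len(27)], 38, "amd-edge",
                     .child_seed(seed, 101))
  nonedge <- make_group(45, c(0.15, 0.72), "AMd",
                        amd_domains[27 + seq_len(45)], 68, "amd-non",
                        .child_seed(seed, 202))
  amd <- list(neurons = c(edge$neurons, nonedge$neurons),
              meta = rbind(edge$meta, nonedge$meta))

  if (preset == "amd-edge-study") {
    neurons <- amd$neurons
    meta <- amd$meta
  } else {
    ad <- make_group(10, c(0.2, 0.8), "AD", character(0), 30, "ad",
                     .child_seed(seed, 303))
    av <- make_group(17, c(0.2, 0.8), "AV", character(0), 32, "av",
                     .child_seed(seed, 404))
    amv <- make_group(10, c(0.2, 0.8), "AMv", character(0), 55, "amv",
                      .child_seed(seed, 505))
    neurons <- c(ad$neurons, av$neurons, amd$neurons, amv$neurons)
    meta <- rbind(ad$meta, av$meta, amd$meta, amv$meta)
  }
  meta$edge_class <- vapply(neurons, function(n)
    classify_edge(n$soma_position, geometry), character(1))
  rownames(meta) <- NULL
  list(neurons = neurons, geometry = geometry, metadata = meta)
}

#' Generate the two-component morphological feature mixture
#'
#' 109 neurons: 84 Type-1 rows with total dendritic length ~ N(3645, 1428)
#' um and branch count ~ N(51, 16), and 25 Type-2 rows with length ~
#' N(8976, 1998) um and branch count ~ N(126, 27) - the component
#' parameters reported for the two morphological types. Negative draws are
#' resampled (truncation at 0).
#'
#' @param seed integer seed.
#' @return data.frame: `neuron_label`, `total_length`, `branch_count`,
#'   `component` (planted 1/2).
#' @export
generate_type_mixture <- function(seed = 1L) {
  set.seed(seed)
  rtnorm <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  n1 <- 84L; n2 <- 25L
  data.frame(
    neuron_label = sprintf("mix-%03d", seq_len(n1 + n2)),
    total_length = c(rtnorm(n1, 3645, 1428), rtnorm(n2, 8976, 1998)),
    branch_count = c(rtnorm(n1, 51, 16), rtnorm(n2, 126, 27)),
    component = rep(1:2, c(n1, n2))
  )
}

#' Generate injection grid rows with planted domain structure
#'
#' Each injection is assigned a planted domain; grid cells are partitioned
#' into contiguous blocks, one per domain. An injection's row has high
#' coverage on its domain's block (uniform 60-95%) plus clipped Gaussian
#' noise elsewhere. Repeated injections of the same ROI share a planted
#' domain, as repeated real injections would. Rows alternate anterograde
#' (percent coverage) and retrograde (cell counts) tracer kinds.
#'
#' @param n_injections number of injections (default 19).
#' @param planted_domains number of planted domains (default 4).
#' @param grid_shape `c(rows, cols)` of the grid (default `c(4, 8)`).
#' @param noise_sd Gaussian noise SD on the \[0, 1\] coverage scale
#'   (default 0.05).
#' @param seed integer seed.
#' @param n_repeated how many injections are repeats of the first ROI.
#' @return list of `injection_grid_row`s with attributes
#'   `planted_injection` and `planted_grid` (integer domain labels).
#' @export
generate_grid_cases <- function(n_injections = 19L, planted_domains = 4L,
                                grid_shape = c(4L, 8L), noise_sd = 0.05,
                                seed = 1L, n_repeated = 2L) {
  ncell <- prod(grid_shape)
  if (planted_domains > min(n_injections, ncell)) {
    .fail("planted_domains must be <= min(n_injections, grid cells)")
  }
  set.seed(seed)
  spec <- grid_spec()
  cell_domain <- sort(rep_len(seq_len(planted_domains), ncell))
  inj_domain <- rep_len(seq_len(planted_domains), n_injections)
  rowlab <- as.integer((seq_len(ncell) - 1) %/% grid_shape[2])
  collab <- as.integer((seq_len(ncell) - 1) %% grid_shape[2])
  labs <- .grid_label(rowlab, collab)
  rois <- sprintf("ROI%02d", seq_len(n_injections))
  if (n_repeated > 0) {
    reps <- min(n_repeated, n_injections - 1)
    rois[seq_len(reps + 1)] <- sprintf("SUBd-%d", seq_len(reps + 1))
    inj_domain[seq_len(reps + 1)] <- inj_domain[1]
  }
  rows <- vector("list", n_injections)
  for (i in seq_len(n_injections)) {
    sig <- ifelse(cell_domain == inj_domain[i], stats::runif(ncell, 0.6, 0.95), 0)
    sig <- pmin(1, pmax(0, sig + stats::rnorm(ncell, 0, noise_sd)))
    kind <- if (i %% 2L == 1L) "anterograde" else "retrograde"
    vals <- if (kind == "anterograde") 100 * sig else round(200 * sig)
    names(vals) <- labs
    rows[[i]] <- structure(
      list(injection_id = sprintf("%s-%s", rois[i], substr(kind, 1, 4)),
           tracer_kind = kind, values = vals, spec = spec),
      class = "injection_grid_row"
    )
  }
  attr(rows, "planted_injection") <- inj_domain
  attr(rows, "planted_grid") <- cell_domain
  rows
}

#' Generate a synthetic per-case ROI count table
#'
#' ROI counts follow a log-normal profile (a few strong targets, a long
#' tail), with uniform ROI areas.
#'
#' @param n_rois number of ROIs.
#' @param profile_shape `"lognormal"` (default) or `"uniform"`.
#' @param seed integer seed.
#' @param case_id case identifier.
#' @return a [case_projection_table()].
#' @export
generate_case_counts <- function(n_rois = 20L, profile_shape = c("lognormal", "uniform"),
                                 seed = 1L, case_id = "syn-case") {
  profile_shape <- match.arg(profile_shape)
  if (n_rois < 1L) .fail("n_rois must be >= 1")
  set.seed(seed)
  counts <- if (profile_shape == "lognormal") {
    round(stats::rlnorm(n_rois, meanlog = 4, sdlog = 1.2))
  } else {
    round(stats::runif(n_rois, 0, 200))
  }
  if (all(counts == 0)) counts[1] <- 1
  names(counts) <- sprintf("ROI%02d", seq_len(n_rois))
  areas <- stats::runif(n_rois, 0.5, 5)
  names(areas) <- names(counts)
  case_projection_table(counts, areas, case_id = case_id)
}
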